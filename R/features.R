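# Sliding-window EMG features: MAV, MWL, DRMS, STFT band means, SWT cD3.
#
# Single-window reference implementations are exported (and serve as the
# oracle for the vectorized assembly path); assemble_features() evaluates
# the chosen feature on the trailing window at each kept timestep and
# decimates the feature stream to 20 Hz by plain stride subsampling.

# Daubechies-2 decomposition filters (standard orthonormal coefficients).
db2_dec_lo <- c(-0.12940952255092145, 0.22414386804185735,
                0.83651630373780790, 0.48296291314469025)
db2_dec_hi <- c(-0.48296291314469025, 0.83651630373780790,
                -0.22414386804185735, -0.12940952255092145)

#' Feature specification
#'
#' @param feature one of `MAV`, `MWL`, `DRMS`, `STFT`, `SWT`, `ALL`
#'   (the concatenation of all five).
#' @param window_ms feature window length in milliseconds (the evaluated
#'   grid is 100-500 ms in 100 ms steps).
#' @param stft_hann Hanning window length in samples for the short-time
#'   Fourier transform.
#' @param stft_hop STFT hop in samples (half the Hanning length: 50%
#'   overlap).
#' @param stft_bands list of `c(lo, hi)` band edges in Hz; a frequency bin
#'   belongs to a band if its center lies in the closed interval, so the
#'   printed low/mid overlap at 60-70 Hz is preserved.
#' @param trim_ms head trim applied to every trial before feature
#'   decimation; fixed at the longest grid window (500 ms) for all
#'   configurations so the row count never depends on the chosen window
#'   lengths.
#' @param out_fs feature output rate in Hz.
#' @return An object of class `feature_spec`.
#' @export
feature_spec <- function(feature = c("ALL", "MAV", "MWL", "DRMS", "STFT", "SWT"),
                         window_ms = 500,
                         stft_hann = 64,
                         stft_hop = 32,
                         stft_bands = list(c(1, 70), c(60, 100), c(100, 250)),
                         trim_ms = 500,
                         out_fs = 20) {
  feature <- match.arg(feature)
  stopifnot_scalar_pos(window_ms, "window_ms")
  stopifnot_scalar_pos(out_fs, "out_fs")
  stopifnot(length(stft_bands) == 3)
  structure(list(feature = feature, window_ms = window_ms,
                 stft_hann = as.integer(stft_hann),
                 stft_hop = as.integer(stft_hop),
                 stft_bands = stft_bands,
                 trim_ms = trim_ms, out_fs = out_fs),
            class = "feature_spec")
}

feature_components <- function(feature) {
  switch(feature,
         MAV = "MAV", MWL = "MWL", DRMS = "DRMS", SWT = "SWT",
         STFT = c("STFTlow", "STFTmid", "STFThig"),
         ALL = c("MAV", "MWL", "DRMS", "STFTlow", "STFTmid", "STFThig", "SWT"))
}

#' Feature/label timestamps: trim then stride subsample
#'
#' Returns the sample indices (at the preprocessed rate `fs`) at which
#' features and labels are evaluated: the first `trim_ms` of each trial is
#' discarded (the longest grid window, independent of the configured window
#' lengths, so every configuration yields the same row count) and the
#' remainder is subsampled by stride `fs / out_fs` (500 -> 20 Hz keeps
#' every 25th sample).
#'
#' @param n trial length in samples at rate `fs`.
#' @param fs sampling rate in Hz.
#' @param trim_ms head trim in milliseconds.
#' @param out_fs output rate in Hz.
#' @return Integer vector of kept 1-based sample indices.
#' @export
kept_indices <- function(n, fs = 500, trim_ms = 500, out_fs = 20) {
  trim <- round(trim_ms / 1000 * fs)
  stride <- round(fs / out_fs)
  if (trim + 1 > n) return(integer(0))
  seq.int(trim + 1L, n, by = stride)
}

#' Time-domain window features: MAV, MWL, DRMS
#'
#' For a window `x` of length `L`:
#' * `MAV` - mean absolute value, `mean(|x|)`;
#' * `MWL` - mean waveform length, `sum(|diff(x)|) / (L - 1)`;
#' * `DRMS` - difference root mean square, `sqrt(sum(diff(x)^2) / (L - 1))`.
#' The `L - 1` denominators follow the printed feature definitions (the
#' first-difference sums have `L - 1` terms).
#'
#' @param window numeric vector.
#' @param kind `"MAV"`, `"MWL"` or `"DRMS"`.
#' @return A single numeric value.
#' @export
time_domain_feature <- function(window, kind = c("MAV", "MWL", "DRMS")) {
  kind <- match.arg(kind)
  L <- length(window)
  if (kind == "MAV") {
    if (L < 1) stop("window too short", call. = FALSE)
    return(sum(abs(window)) / L)
  }
  if (L < 2) stop("window too short (MWL/DRMS need >= 2 samples)",
                  call. = FALSE)
  d <- diff(window)
  switch(kind,
         MWL = sum(abs(d)) / (L - 1),
         DRMS = sqrt(sum(d^2) / (L - 1)))
}

# Periodic Hanning window.
hann_window <- function(n) 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / n))

stft_band_bins <- function(spec, fs) {
  n <- spec$stft_hann
  freq <- (seq_len(n %/% 2 + 1) - 1) * fs / n
  lapply(spec$stft_bands, function(b) which(freq >= b[1] & freq <= b[2]))
}

#' STFT band-averaged magnitude feature (Low, Mid, Hig)
#'
#' Computes the magnitude spectrogram of one window with a 64-sample
#' periodic Hanning window and 50% overlap, averages it over time
#' (`MeanSpec`), then averages the mean spectrum over the frequency bins
#' whose centers fall in the 1-70, 60-100 and 100-250 Hz bands (closed
#' intervals; the low/mid overlap is intentional).
#'
#' @param window numeric vector of length at least `stft_hann`.
#' @param spec a [feature_spec()].
#' @param fs sampling rate of the window in Hz.
#' @return Named numeric vector `c(STFTlow, STFTmid, STFThig)`.
#' @export
stft_band_feature <- function(window, spec = feature_spec("STFT"), fs = 500) {
  L <- length(window)
  nh <- spec$stft_hann
  if (L < nh) {
    stop(sprintf("window (%d samples) shorter than the Hanning window (%d)",
                 L, nh), call. = FALSE)
  }
  h <- hann_window(nh)
  starts <- seq.int(1L, L - nh + 1L, by = spec$stft_hop)
  spec_sum <- numeric(nh %/% 2 + 1)
  for (s in starts) {
    frame <- window[s:(s + nh - 1)] * h
    spec_sum <- spec_sum + Mod(fft(frame))[seq_len(nh %/% 2 + 1)]
  }
  mean_spec <- spec_sum / length(starts)
  bins <- stft_band_bins(spec, fs)
  out <- vapply(bins, function(b) mean(mean_spec[b]), numeric(1))
  names(out) <- c("STFTlow", "STFTmid", "STFThig")
  out
}

#' Stationary wavelet transform cD3 feature (reference implementation)
#'
#' Pads the window symmetrically to the next multiple of 8 samples, runs a
#' 3-level undecimated (a-trous) db2 analysis with periodic boundary
#' handling, crops the level-3 detail coefficients back to the window
#' extent, and returns their mean absolute value. At a 500 Hz sampling rate
#' the cD3 band is roughly 31-62.5 Hz.
#'
#' @param window numeric vector of length at least 8.
#' @param spec a [feature_spec()] (the wavelet is fixed at db2, level 3).
#' @return A single nonnegative numeric value.
#' @export
swt_feature <- function(window, spec = feature_spec("SWT")) {
  L <- length(window)
  if (L < 8) stop("window shorter than 8 samples", call. = FALSE)
  N <- ceiling(L / 8) * 8
  pad <- N - L
  pl <- pad %/% 2
  pr <- pad - pl
  a <- c(if (pl > 0) window[pl:1] else numeric(0),
         window,
         if (pr > 0) window[L:(L - pr + 1)] else numeric(0))
  circ_conv <- function(x, f, step) {
    N <- length(x)
    y <- numeric(N)
    for (k in seq_along(f)) {
      shift <- (k - 1) * step
      idx <- ((seq_len(N) - 1 - shift) %% N) + 1
      y <- y + f[k] * x[idx]
    }
    y
  }
  a <- circ_conv(a, db2_dec_lo, 1L)   # level 1 approximation
  a <- circ_conv(a, db2_dec_lo, 2L)   # level 2 approximation
  d3 <- circ_conv(a, db2_dec_hi, 4L)  # level 3 detail
  mean(abs(d3[(pl + 1):(pl + L)]))
}

# Vectorized STFT band features for all kept windows of all channels in one
# batched FFT call. Returns an array (windows x 3 bands x channels).
stft_features_all <- function(x, kept, L, spec, fs) {
  nh <- spec$stft_hann
  if (L < nh) {
    stop(sprintf("feature window (%d samples) shorter than the Hanning window (%d)",
                 L, nh), call. = FALSE)
  }
  h <- hann_window(nh)
  offs <- seq.int(0L, L - nh, by = spec$stft_hop)
  nf <- length(offs)
  nk <- length(kept)
  nch <- ncol(x)
  n <- nrow(x)
  starts <- rep(kept - L + 1L, each = nf) + offs   # frame starts, all windows
  idx <- outer(0:(nh - 1L), starts, "+")           # nh x (nf * nk)
  idx_all <- as.vector(outer(as.vector(idx), (seq_len(nch) - 1L) * n, "+"))
  frames <- matrix(x[idx_all], nrow = nh) * h      # nh x (nf * nk * nch)
  nb <- nh %/% 2 + 1
  mod <- Mod(mvfft(frames)[seq_len(nb), , drop = FALSE])
  dim(mod) <- c(nb, nf, nk * nch)
  mean_spec <- colSums(aperm(mod, c(2, 1, 3))) / nf   # nb x (nk * nch)
  bins <- stft_band_bins(spec, fs)
  out <- array(NA_real_, c(nk, 3, nch))
  for (b in 1:3) {
    out[, b, ] <- colMeans(mean_spec[bins[[b]], , drop = FALSE])
  }
  out
}

#' Assemble the feature matrix of one recording
#'
#' Evaluates the configured feature on the trailing `window_ms` window of
#' every channel at the kept timesteps ([kept_indices()]: 500 ms head trim,
#' stride subsampling to 20 Hz). Columns are channel-major with component
#' names, e.g. `ch01_MAV ... ch01_SWT, ch02_MAV, ...`; `ALL` yields 7
#' columns per channel (MAV, MWL, DRMS, 3 STFT bands, SWT).
#'
#' @param rec an [emg_recording()] at stage `normalized` (or
#'   `preprocessed`, for the no-normalization baseline).
#' @param spec a [feature_spec()].
#' @return A `feature_matrix`: numeric matrix (timesteps x columns) with
#'   attributes `kept` (source sample indices), `fs_feature` and `spec`.
#' @export
assemble_features <- function(rec, spec = feature_spec()) {
  stopifnot(inherits(rec, "emg_recording"), inherits(spec, "feature_spec"))
  x <- rec$samples
  n <- nrow(x)
  L <- window_samples(spec$window_ms, rec$fs)
  kept <- kept_indices(n, rec$fs, spec$trim_ms, spec$out_fs)
  if (length(kept) == 0 || kept[1] - L < 0) {
    stop(sprintf("trial (%d samples) shorter than the longest grid window",
                 n), call. = FALSE)
  }
  comps <- feature_components(spec$feature)
  n_ch <- ncol(x)
  out <- matrix(NA_real_, length(kept), n_ch * length(comps))
  colnames(out) <- paste(rep(sprintf("ch%02d", seq_len(n_ch)),
                             each = length(comps)),
                         rep(comps, n_ch), sep = "_")
  stft <- if (spec$feature %in% c("STFT", "ALL")) {
    stft_features_all(x, kept, L, spec, rec$fs)
  }
  for (ch in seq_len(n_ch)) {
    block <- NULL
    if (spec$feature %in% c("MAV", "MWL", "DRMS", "ALL")) {
      td <- td_features_win(x[, ch], kept, L)
      block <- switch(spec$feature,
                      MAV = td[, 1, drop = FALSE],
                      MWL = td[, 2, drop = FALSE],
                      DRMS = td[, 3, drop = FALSE],
                      ALL = td[, 1:3, drop = FALSE])
    }
    if (spec$feature %in% c("STFT", "ALL")) {
      block <- cbind(block, stft[, , ch])
    }
    if (spec$feature %in% c("SWT", "ALL")) {
      block <- cbind(block,
                     swt_cd3_win(x[, ch], kept, L, db2_dec_lo, db2_dec_hi))
    }
    out[, (ch - 1) * length(comps) + seq_along(comps)] <- block
  }
  structure(out, kept = kept, fs_feature = spec$out_fs, spec = spec,
            class = c("feature_matrix", class(out)))
}

# Windowed SD, MAV and centered MAV of a recording at the kept timesteps;
# the raw-signal statistics behind the normalization diagnostic.
windowed_aux <- function(rec, window_ms = 500, trim_ms = 500, out_fs = 20) {
  L <- window_samples(window_ms, rec$fs)
  kept <- kept_indices(nrow(rec$samples), rec$fs, trim_ms, out_fs)
  nch <- ncol(rec$samples)
  sd_m <- mav_m <- cmav_m <- matrix(NA_real_, length(kept), nch)
  for (ch in seq_len(nch)) {
    td <- td_features_win(rec$samples[, ch], kept, L)
    sd_m[, ch] <- td[, 4]
    mav_m[, ch] <- td[, 1]
    cmav_m[, ch] <- td[, 5]
  }
  list(sd = sd_m, mav = mav_m, cmav = cmav_m)
}

#' Windowed standard deviation of a recording
#'
#' Population SD of the trailing `window_ms` window per channel at the kept
#' timesteps - the quantity correlated against MAV in the normalization
#' diagnostic.
#'
#' @param rec an [emg_recording()].
#' @param window_ms window length in milliseconds.
#' @param trim_ms,out_fs trimming/decimation as in [kept_indices()].
#' @return Matrix (timesteps x channels) of window SDs.
#' @export
windowed_sd <- function(rec, window_ms = 500, trim_ms = 500, out_fs = 20) {
  L <- window_samples(window_ms, rec$fs)
  kept <- kept_indices(nrow(rec$samples), rec$fs, trim_ms, out_fs)
  out <- vapply(seq_len(ncol(rec$samples)),
                function(ch) td_features_win(rec$samples[, ch], kept, L)[, 4],
                numeric(length(kept)))
  colnames(out) <- rec$channel_labels
  out
}
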