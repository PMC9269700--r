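#' Normalization specification
#'
#' @param method `"swn"` (sliding-window normalization), `"zscore"`
#'   (training-statistics z-score) or `"none"`.
#' @param window_ms SWN window length in milliseconds; required iff
#'   `method = "swn"`. The evaluated grid in this package is 100-500 ms in
#'   100 ms steps, but any length of at least 2 samples is accepted.
#' @param zero_variance_policy what to do when a sliding window has zero
#'   variance: `"zero"` emits zeros for the affected samples (streaming must
#'   not halt) or `"error"` stops.
#' @return An object of class `normalization_spec`.
#' @export
normalization_spec <- function(method = c("swn", "zscore", "none"),
                               window_ms = NULL,
                               zero_variance_policy = c("zero", "error")) {
  method <- match.arg(method)
  zero_variance_policy <- match.arg(zero_variance_policy)
  if (method == "swn") {
    if (is.null(window_ms)) {
      stop("`window_ms` is required for method = \"swn\"", call. = FALSE)
    }
    stopifnot_scalar_pos(window_ms, "window_ms")
  } else if (!is.null(window_ms)) {
    window_ms <- NULL  # irrelevant for zscore/none
  }
  structure(list(method = method, window_ms = window_ms,
                 zero_variance_policy = zero_variance_policy),
            class = "normalization_spec")
}

window_samples <- function(window_ms, fs) {
  L <- round(window_ms / 1000 * fs)
  if (L < 2) {
    stop(sprintf("window of %g ms is < 2 samples at %g Hz", window_ms, fs),
         call. = FALSE)
  }
  as.integer(L)
}

#' Normalize a single sliding window (reference implementation)
#'
#' Centers and scales one window to mean 0 and population standard
#' deviation 1: `(x_n - m) / s` with `m` the window mean and
#' `s = sqrt(mean((x - m)^2))`. A zero-variance window emits zeros with a
#' warning (default policy) or an error.
#'
#' This is the per-window definition of sliding-window normalization; the
#' streaming operation [sliding_window_normalize()] emits the last element
#' of this transform at every time step.
#'
#' @param window numeric vector (one channel's trailing window).
#' @param zero_variance_policy `"zero"` or `"error"`.
#' @return The normalized window (same length).
#' @export
swn_window <- function(window, zero_variance_policy = c("zero", "error")) {
  zero_variance_policy <- match.arg(zero_variance_policy)
  L <- length(window)
  if (L < 1) stop("empty window", call. = FALSE)
  m <- sum(window) / L
  s <- sqrt(sum((window - m)^2) / L)
  if (s == 0) {
    if (zero_variance_policy == "error") {
      stop("zero-variance window", call. = FALSE)
    }
    warning("zero-variance window: emitting zeros")
    return(rep(0, L))
  }
  (window - m) / s
}

#' Streaming sliding-window normalization of an EMG recording
#'
#' For each channel independently and each time step t, normalizes the
#' trailing `L_norm`-sample window to mean 0 / population SD 1 and emits the
#' newest sample: `y_t = (x_t - m_t) / s_t`. The output at t therefore
#' depends only on inputs in `(t - L_norm, t]` (causality), and any
#' per-channel rescaling of the input leaves the output unchanged (scale
#' invariance) - the mechanism by which SWN needs no calibration reference.
#'
#' During warm-up (t < L_norm) the window expands from the first sample;
#' these samples are flagged via the `warm_up` attribute and are removed
#' downstream by the feature-extraction trimming rule (which always trims
#' the longest grid window, 500 ms, regardless of the configured lengths).
#'
#' @param rec an [emg_recording()] at stage `preprocessed`.
#' @param spec a [normalization_spec()] with `method = "swn"`.
#' @return An `emg_recording` at stage `normalized`; attribute `warm_up`
#'   gives the number of leading expanding-window samples per channel.
#' @export
sliding_window_normalize <- function(rec, spec) {
  stopifnot(inherits(rec, "emg_recording"),
            inherits(spec, "normalization_spec"))
  if (spec$method != "swn") {
    stop("spec$method must be \"swn\"", call. = FALSE)
  }
  L <- window_samples(spec$window_ms, rec$fs)
  if (nrow(rec$samples) <= L) {
    stop("recording must be longer than the normalization window",
         call. = FALSE)
  }
  res <- swn_stream(rec$samples, L)
  if (res$n_zero_windows > 0) {
    if (spec$zero_variance_policy == "error") {
      stop(sprintf("%d zero-variance windows", res$n_zero_windows),
           call. = FALSE)
    }
    warning(sprintf("%d zero-variance windows: emitted zeros",
                    res$n_zero_windows))
  }
  out <- rec
  out$samples <- res$y
  colnames(out$samples) <- rec$channel_labels
  out <- advance_stage(out, "normalized")
  out$normalization <- spec
  attr(out, "warm_up") <- L - 1L
  out
}

#' Z-score normalization with training statistics
#'
#' Computes per-channel mean and population standard deviation on the
#' training recording only and applies them to both recordings:
#' `(x - mu_train) / sigma_train`. Normalized training data has per-channel
#' mean 0 and SD 1; test data is transformed with the same statistics
#' (no test-set leakage). This is the calibration-requiring baseline SWN is
#' designed to replace.
#'
#' @param train,test [emg_recording()]s at stage `preprocessed` with the
#'   same channels.
#' @return List with elements `train`, `test` (stage `normalized`) and
#'   `stats` (a `zscore_stats` object with `mean` and `sd` per channel).
#' @export
zscore_normalize <- function(train, test) {
  stopifnot(inherits(train, "emg_recording"),
            inherits(test, "emg_recording"),
            ncol(train$samples) == ncol(test$samples))
  stats <- zscore_stats(train$samples)
  list(train = apply_zscore(train, stats),
       test = apply_zscore(test, stats),
       stats = stats)
}

#' Per-channel z-score statistics of a training set
#'
#' @param x numeric matrix (time x channels) of training samples, or a list
#'   of such matrices that are pooled (e.g. the training trials of one
#'   subject).
#' @return A `zscore_stats` object: per-channel `mean` and population `sd`.
#' @export
zscore_stats <- function(x) {
  if (is.list(x)) {
    if (length(x) == 0) stop("empty training data", call. = FALSE)
    x <- do.call(rbind, x)
  }
  x <- as.matrix(x)
  if (nrow(x) < 1) stop("empty training data", call. = FALSE)
  mu <- colMeans(x)
  sdv <- sqrt(colMeans((x - rep(mu, each = nrow(x)))^2))
  zero <- which(sdv == 0)
  if (length(zero)) {
    stop(sprintf("zero-variance training channel: %s",
                 paste(colnames(x)[zero] %||% zero, collapse = ", ")),
         call. = FALSE)
  }
  structure(list(mean = mu, sd = sdv), class = "zscore_stats")
}

apply_zscore <- function(rec, stats) {
  out <- rec
  out$samples <- sweep(sweep(rec$samples, 2, stats$mean), 2, stats$sd, "/")
  out <- advance_stage(out, "normalized")
  out$normalization <- normalization_spec("zscore")
  out
}

#' Apply a normalization specification to a recording
#'
#' Dispatches on the spec's method: `swn` runs the streaming normalizer,
#' `zscore` requires precomputed training statistics, `none` passes samples
#' through unchanged (identity on samples, stage advanced to `normalized`).
#'
#' @param rec an [emg_recording()] at stage `preprocessed`.
#' @param spec a [normalization_spec()].
#' @param stats a `zscore_stats` object (required for `method = "zscore"`).
#' @return An `emg_recording` at stage `normalized`.
#' @export
apply_normalization <- function(rec, spec, stats = NULL) {
  switch(spec$method,
         swn = sliding_window_normalize(rec, spec),
         zscore = {
           if (is.null(stats)) {
             stop("method \"zscore\" needs training statistics", call. = FALSE)
           }
           apply_zscore(rec, stats)
         },
         none = {
           out <- advance_stage(rec, "normalized")
           out$normalization <- spec
           out
         })
}
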