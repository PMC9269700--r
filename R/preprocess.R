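#' Causal EMG preprocessing: low-pass, decimate, high-pass
#'
#' Conditions raw EMG with a causal (forward-only) filter chain applied per
#' channel: a 3rd-order Butterworth low-pass at `lowpass_hz`, decimation to
#' `target_fs` by keeping every `fs/target_fs`-th sample, and a 3rd-order
#' Butterworth high-pass at `highpass_hz`. Forward-only filtering preserves
#' real-time feasibility: the output at time t depends only on inputs up to
#' t.
#'
#' The low-pass cutoff is clamped just below the input Nyquist frequency
#' (0.999 of the normalized band edge) so the digital design stays valid for
#' any input rate whose Nyquist does not exceed the nominal 500 Hz cutoff.
#'
#' @param rec an [emg_recording()] at stage `raw`.
#' @param target_fs output sampling rate in Hz; `rec$fs` must be an integer
#'   multiple.
#' @param lowpass_hz anti-alias low-pass cutoff in Hz.
#' @param highpass_hz post-decimation high-pass cutoff in Hz.
#' @return An `emg_recording` at stage `preprocessed` with `fs = target_fs`.
#' @export
preprocess_emg <- function(rec, target_fs = 500, lowpass_hz = 500,
                           highpass_hz = 30) {
  stopifnot(inherits(rec, "emg_recording"))
  if (rec$stage != "raw") {
    stop("preprocess_emg() expects a raw recording", call. = FALSE)
  }
  if (rec$fs %% target_fs != 0) {
    stop(sprintf("input rate %g Hz is not an integer multiple of the target rate %g Hz",
                 rec$fs, target_fs), call. = FALSE)
  }
  factor <- rec$fs / target_fs
  n <- nrow(rec$samples)
  if (n < 12) {
    warning("recording shorter than the filter warm-up length; ",
            "output is transient-dominated")
  }
  w_lp <- min(lowpass_hz / (rec$fs / 2), 0.999)
  lp <- signal::butter(3, w_lp, type = "low")
  x <- iir_filter_cols(rec$samples, lp$b, lp$a)
  x <- x[seq(1, n, by = factor), , drop = FALSE]
  hp <- signal::butter(3, highpass_hz / (target_fs / 2), type = "high")
  x <- iir_filter_cols(x, hp$b, hp$a)
  out <- rec
  out$samples <- x
  colnames(out$samples) <- rec$channel_labels
  out$fs <- target_fs
  advance_stage(out, "preprocessed")
}
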