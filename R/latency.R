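#' Per-tick latency of preprocessing and normalization
#'
#' Measures the wall time of one real-time prediction tick - causal
#' preprocessing of the raw sample buffer plus (optionally) sliding-window
#' normalization of the newest window - executed every `tick_s` seconds of
#' simulated streaming input. This is a diagnostic for real-time
#' feasibility on the target hardware; it plays no role in the accuracy
#' evaluation.
#'
#' @param n_channels,fs_emg stream geometry.
#' @param window_ms SWN window length in milliseconds (post-decimation).
#' @param tick_s tick period in seconds (20 ms = 50 Hz prediction rate).
#' @param buffer_s raw-buffer length kept for filtering, in seconds.
#' @param n_ticks number of timed ticks.
#' @param seed seed for the synthetic raw stream.
#' @return List with mean/median per-tick seconds with (`swn`) and without
#'   (`none`) normalization.
#' @export
benchmark_latency <- function(n_channels = 12, fs_emg = 2000,
                              window_ms = 500, tick_s = 0.02,
                              buffer_s = 0.6, n_ticks = 200, seed = 1L) {
  n_buf <- round(buffer_s * fs_emg)
  n_new <- round(tick_s * fs_emg)
  factor <- 4L
  target_fs <- fs_emg / factor
  L <- window_samples(window_ms, target_fs)
  lp <- signal::butter(3, min(500 / (fs_emg / 2), 0.999), type = "low")
  hp <- signal::butter(3, 30 / (target_fs / 2), type = "high")
  buffer <- with_seed(seed, matrix(rnorm(n_buf * n_channels), n_buf, n_channels))
  tick <- function(normalize) {
    x <- iir_filter_cols(buffer, lp$b, lp$a)
    x <- x[seq(1, nrow(x), by = factor), , drop = FALSE]
    x <- iir_filter_cols(x, hp$b, hp$a)
    if (normalize) {
      tail_win <- x[(nrow(x) - L + 1):nrow(x), , drop = FALSE]
      invisible(swn_stream(tail_win, L)$y[L, ])
    }
    invisible(NULL)
  }
  time_loop <- function(normalize) {
    times <- numeric(n_ticks)
    for (i in seq_len(n_ticks)) {
      new <- matrix(rnorm(n_new * n_channels), n_new, n_channels)
      buffer <<- rbind(buffer[-seq_len(n_new), , drop = FALSE], new)
      t0 <- proc.time()[["elapsed"]]
      tick(normalize)
      times[i] <- proc.time()[["elapsed"]] - t0
    }
    times
  }
  t_none <- time_loop(FALSE)
  t_swn <- time_loop(TRUE)
  list(none = c(mean_s = mean(t_none), median_s = stats::median(t_none)),
       swn = c(mean_s = mean(t_swn), median_s = stats::median(t_swn)),
       tick_s = tick_s)
}
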