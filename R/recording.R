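#' Multi-channel EMG recording
#'
#' Samples are stored time-in-rows, channels-in-columns, with sampling rate,
#' channel labels, a processing-stage tag and trial/session/subject
#' metadata. Stage transitions are restricted to
#' raw -> preprocessed -> normalized.
#'
#' @param samples numeric matrix, time x channels.
#' @param fs sampling rate in Hz.
#' @param channel_labels optional character vector of channel names.
#' @param stage processing stage tag.
#' @param meta named list of provenance (subject, trial, session, movement).
#' @return An object of class `emg_recording`.
#' @export
emg_recording <- function(samples, fs,
                          channel_labels = NULL,
                          stage = c("raw", "preprocessed", "normalized"),
                          meta = list()) {
  samples <- as.matrix(samples)
  stage <- match.arg(stage)
  stopifnot_scalar_pos(fs, "fs")
  if (anyNA(samples)) stop("EMG samples must not contain NA", call. = FALSE)
  if (is.null(channel_labels)) {
    channel_labels <- sprintf("ch%02d", seq_len(ncol(samples)))
  }
  stopifnot(length(channel_labels) == ncol(samples))
  colnames(samples) <- channel_labels
  structure(list(samples = samples, fs = fs,
                 channel_labels = channel_labels,
                 stage = stage, meta = meta),
            class = "emg_recording")
}

emg_stages <- c("raw", "preprocessed", "normalized")

# Enforce the allowed stage progression when a stage transforms a recording.
advance_stage <- function(rec, to) {
  from <- match(rec$stage, emg_stages)
  dest <- match(to, emg_stages)
  if (is.na(dest) || dest != from + 1L) {
    stop(sprintf("invalid stage transition %s -> %s", rec$stage, to),
         call. = FALSE)
  }
  rec$stage <- to
  rec
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf("<emg_recording> %d samples x %d channels @ %g Hz [%s]\n",
              nrow(x$samples), ncol(x$samples), x$fs, x$stage))
  if (length(x$meta)) {
    cat("  meta:", paste(names(x$meta), unlist(lapply(x$meta, format)),
                         sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.emg_recording <- function(x) dim(x$samples)
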