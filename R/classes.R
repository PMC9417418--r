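#' Multichannel EEG recording
#'
#' Container for a uniformly sampled multichannel EEG signal in microvolts.
#' The signal is stored as a channels x samples matrix; row names carry the
#' channel labels.
#'
#' @param signal numeric matrix, channels x samples, in microvolts.
#' @param labels character vector of channel labels, one per row of `signal`.
#' @param fs sampling rate in Hz. Sleep analyses require `fs >= 100`.
#' @param reference free-text descriptor of the current reference
#'   (e.g. `"raw"`, `"avg-mastoid"`).
#' @param start_s recording start time in seconds (offset applied to all
#'   reported event times).
#'
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(signal, labels = rownames(signal), fs,
                          reference = "raw", start_s = 0) {
  signal <- as.matrix(signal)
  if (is.null(labels)) labels <- sprintf("ch%02d", seq_len(nrow(signal)))
  stopifnot(is.numeric(signal), length(labels) == nrow(signal))
  if (anyNA(signal) || any(!is.finite(signal)))
    stop("eeg_recording: signal contains NA or non-finite values")
  if (!is.numeric(fs) || length(fs) != 1L || fs < 100)
    stop("eeg_recording: sampling rate must be a single value >= 100 Hz")
  rownames(signal) <- labels
  structure(
    list(signal = signal, labels = as.character(labels), fs = fs,
         reference = reference, start_s = start_s),
    class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s), ref: %s\n",
              nrow(x$signal), ncol(x$signal), x$fs,
              ncol(x$signal) / x$fs, x$reference))
  invisible(x)
}

#' Duration of an EEG recording in seconds
#' @param rec an `eeg_recording`.
#' @return Duration in seconds.
#' @export
eeg_duration <- function(rec) ncol(rec$signal) / rec$fs

#' Hypnogram (epoch-level sleep staging)
#'
#' @param stages character vector of per-epoch stages, each one of
#'   `"W"`, `"N1"`, `"N2"`, `"N3"`, `"REM"`.
#' @param epoch_len_s epoch length in seconds (30 by convention).
#' @param lights_off_s lights-off time in seconds from recording start.
#' @param lights_on_s lights-on time in seconds (default: end of staging).
#'
#' @return An object of class `hypnogram`.
#' @export
hypnogram <- function(stages, epoch_len_s = 30, lights_off_s = 0,
                      lights_on_s = length(stages) * epoch_len_s) {
  stages <- as.character(stages)
  bad <- setdiff(unique(stages), c("W", "N1", "N2", "N3", "REM"))
  if (length(bad))
    stop("hypnogram: unknown stage label(s): ", paste(bad, collapse = ", "))
  if (epoch_len_s <= 0) stop("hypnogram: epoch_len_s must be positive")
  structure(
    list(stages = stages, epoch_len_s = epoch_len_s,
         lights_off_s = lights_off_s, lights_on_s = lights_on_s),
    class = "hypnogram")
}

#' @export
print.hypnogram <- function(x, ...) {
  tab <- table(factor(x$stages, levels = c("W", "N1", "N2", "N3", "REM")))
  cat(sprintf("<hypnogram> %d epochs of %g s: %s\n", length(x$stages),
              x$epoch_len_s,
              paste(sprintf("%s=%d", names(tab), tab), collapse = " ")))
  invisible(x)
}

#' Artifact mask (sample-level exclusion intervals)
#'
#' @param start_s,end_s numeric vectors of interval bounds in seconds.
#' @param reason character vector of reason tags (recycled).
#'
#' @return A data.frame of class `artifact_mask` with columns
#'   `start_s`, `end_s`, `reason`.
#' @export
artifact_mask <- function(start_s = numeric(), end_s = numeric(),
                          reason = "artifact") {
  if (length(start_s) != length(end_s))
    stop("artifact_mask: start_s and end_s lengths differ")
  if (any(end_s < start_s))
    stop("artifact_mask: negative-length interval")
  out <- data.frame(start_s = as.numeric(start_s), end_s = as.numeric(end_s),
                    reason = rep_len(as.character(reason),
                                     length.out = length(start_s)),
                    stringsAsFactors = FALSE)
  class(out) <- c("artifact_mask", "data.frame")
  out
}

#' Region-of-interest electrode layout
#'
#' Maps electrode labels to named scalp regions. Electrodes absent from
#' every region are implicitly in `"none"`.
#'
#' @param ... named character vectors, one per ROI
#'   (e.g. `occipital = c("E70","E75","E83")`).
#' @return A named list of class `roi_layout`.
#' @export
roi_layout <- function(...) {
  rois <- list(...)
  if (length(rois) == 1L && is.list(rois[[1]]) && is.null(names(rois)[1]))
    rois <- rois[[1]]
  if (is.null(names(rois)) || any(names(rois) == ""))
    stop("roi_layout: every ROI must be named")
  rois <- lapply(rois, as.character)
  if (any(lengths(rois) == 0L)) stop("roi_layout: empty ROI")
  all_ch <- unlist(rois, use.names = FALSE)
  if (anyDuplicated(all_ch))
    stop("roi_layout: ROIs must be disjoint; duplicated: ",
         paste(unique(all_ch[duplicated(all_ch)]), collapse = ", "))
  structure(rois, class = "roi_layout")
}
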