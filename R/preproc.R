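#' Re-reference an EEG recording to the average mastoid
#'
#' Subtracts the mean of the two mastoid channels from every channel.
#'
#' @param rec an [eeg_recording()].
#' @param mastoid_labels character vector of length 2 naming the mastoid
#'   channels.
#' @return The re-referenced `eeg_recording` (reference descriptor updated).
#' @export
rereference_mastoids <- function(rec, mastoid_labels) {
  stopifnot(inherits(rec, "eeg_recording"))
  missing_ch <- setdiff(mastoid_labels, rec$labels)
  if (length(missing_ch))
    stop("mastoid channel(s) not found: ", paste(missing_ch, collapse = ", "),
         "; available: ", paste(rec$labels, collapse = ", "))
  if (length(mastoid_labels) != 2L)
    stop("exactly two mastoid labels required")
  ref <- colMeans(rec$signal[mastoid_labels, , drop = FALSE])
  rec$signal <- sweep(rec$signal, 2L, ref, "-")
  rec$reference <- "avg-mastoid"
  rec
}

#' Filter an EEG recording (zero-phase)
#'
#' Applies, in order, an optional high-pass (Chebyshev II or Butterworth),
#' optional notch filters, and an optional band-pass, all forward-backward
#' (zero phase distortion).
#'
#' @param rec an [eeg_recording()].
#' @param highpass high-pass cutoff in Hz, or `NULL`.
#' @param notch numeric vector of notch center frequencies in Hz (each
#'   removed with a 2nd-order Butterworth band-stop, +/- 2 Hz).
#' @param bandpass length-2 numeric band edges in Hz, or `NULL`.
#' @param hp_type `"cheby2"` (default) or `"butter"` for the high-pass.
#' @return The filtered `eeg_recording`.
#' @export
filter_recording <- function(rec, highpass = NULL, notch = numeric(),
                             bandpass = NULL, hp_type = c("cheby2", "butter")) {
  stopifnot(inherits(rec, "eeg_recording"))
  hp_type <- match.arg(hp_type)
  nyq <- rec$fs / 2
  cuts <- c(highpass, notch, bandpass)
  if (length(cuts) && any(cuts >= nyq))
    stop(sprintf("filter cutoff >= Nyquist (%g Hz)", nyq))
  if (!is.null(highpass)) {
    flt <- if (hp_type == "cheby2")
      signal::cheby2(3, 20, (highpass / 2) / nyq, type = "high")
    else signal::butter(2, highpass / nyq, type = "high")
    rec$signal <- filtfilt_mat(flt, rec$signal)
  }
  for (f0 in notch) {
    flt <- signal::butter(2, c(f0 - 2, f0 + 2) / nyq, type = "stop")
    rec$signal <- filtfilt_mat(flt, rec$signal)
  }
  if (!is.null(bandpass)) {
    flt <- signal::butter(3, bandpass / nyq, type = "pass")
    rec$signal <- filtfilt_mat(flt, rec$signal)
  }
  rec
}

#' Screen channels by outlying statistical moments
#'
#' Computes variance, skewness, and excess kurtosis per channel and flags
#' channels whose robust z-score (median/MAD) on any moment exceeds the
#' threshold. Intended to catch channels with temporary or permanent loss
#' of scalp contact (flat or erratic signal).
#'
#' @param rec an [eeg_recording()] with at least 8 channels.
#' @param z_thresh robust z-score threshold (default 4).
#' @return Character vector of flagged channel labels (possibly empty).
#' @export
detect_bad_channels <- function(rec, z_thresh = 4) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (nrow(rec$signal) < 8)
    stop("detect_bad_channels: need >= 8 channels for robust screening")
  moments <- cbind(
    variance = apply(rec$signal, 1L, stats::var),
    skewness = apply(rec$signal, 1L, e1071::skewness),
    kurtosis = apply(rec$signal, 1L, e1071::kurtosis))
  moments[!is.finite(moments)] <- 0  # flat channels: skew/kurt undefined
  flagged <- rep(FALSE, nrow(moments))
  degenerate <- TRUE
  for (j in seq_len(ncol(moments))) {
    m <- moments[, j]
    s <- stats::mad(m)
    if (s == 0) next
    degenerate <- FALSE
    flagged <- flagged | abs(m - stats::median(m)) / s > z_thresh
  }
  if (degenerate) {
    warning("detect_bad_channels: all moments degenerate (constant recording?); no flags")
    return(character())
  }
  rec$labels[flagged]
}

#' Select artifact-free NREM segments
#'
#' Returns maximal contiguous intervals staged N2 or N3, minus masked
#' artifact intervals, clipped to the recording span.
#'
#' @param rec an [eeg_recording()].
#' @param hyp a [hypnogram()] aligned to the recording start.
#' @param mask an [artifact_mask()] (may be empty).
#' @return A data.frame with columns `start_s`, `end_s`, `stage`; attribute
#'   `total_s` gives the summed duration. Empty (with a warning) if no NREM
#'   is present.
#' @export
select_nrem <- function(rec, hyp, mask = artifact_mask()) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(hyp, "hypnogram"))
  dur <- eeg_duration(rec)
  el <- hyp$epoch_len_s
  st <- hyp$stages
  segs <- list()
  r <- rle(st)
  ends <- cumsum(r$lengths)
  starts <- c(0L, utils::head(ends, -1L))
  for (k in seq_along(r$values)) {
    if (!r$values[k] %in% c("N2", "N3")) next
    run <- data.frame(start_s = starts[k] * el, end_s = ends[k] * el)
    run <- clip_intervals(run, dur)
    if (!nrow(run)) next
    kept <- interval_setdiff(run, clip_intervals(as.data.frame(mask), dur))
    if (nrow(kept)) {
      kept$stage <- r$values[k]
      segs[[length(segs) + 1L]] <- kept
    }
  }
  out <- if (length(segs)) do.call(rbind, segs) else
    data.frame(start_s = numeric(), end_s = numeric(), stage = character())
  out <- out[order(out$start_s), , drop = FALSE]
  rownames(out) <- NULL
  if (!nrow(out)) warning("select_nrem: no artifact-free NREM present")
  attr(out, "total_s") <- sum(out$end_s - out$start_s)
  out
}

#' Band definitions for night and morning spectral analyses
#'
#' @param set `"night"` (SWA 0.5-4 Hz, sigma 9-15 Hz; 10 s windows) or
#'   `"morning"` (theta/alpha/low beta/high beta/gamma; 4 s windows).
#' @return A data.frame with columns `band`, `lo`, `hi` and attribute
#'   `segment_len_s`.
#' @export
band_defs <- function(set = c("night", "morning")) {
  set <- match.arg(set)
  out <- if (set == "night") {
    structure(data.frame(band = c("swa", "sigma"),
                         lo = c(0.5, 9), hi = c(4, 15)),
              segment_len_s = 10)
  } else {
    structure(data.frame(
      band = c("theta", "alpha", "low_beta", "high_beta", "gamma"),
      lo = c(4, 8, 12, 20, 30), hi = c(8, 12, 20, 30, 45)),
      segment_len_s = 4)
  }
  out
}

#' Absolute band power over NREM segments
#'
#' Each analysis segment is tiled into consecutive non-overlapping windows
#' of `segment_len_s`; windows crossing a segment boundary are dropped. Per
#' window and channel a Hamming-windowed FFT power spectrum is computed,
#' transformed to dB per bin, and averaged over the band's frequency bins
#' (bin assignment: `lo <= f < hi`); the channel band power is the mean over
#' windows.
#'
#' @param rec an [eeg_recording()].
#' @param segments data.frame of analysis intervals (`start_s`, `end_s`),
#'   e.g. from [select_nrem()].
#' @param bands data.frame (`band`, `lo`, `hi`) as from [band_defs()].
#' @param segment_len_s FFT window length in seconds (default from `bands`
#'   attribute, else 10).
#' @param per_bin_db if `TRUE` (default) dB is taken per bin before band
#'   averaging; `FALSE` averages linear power over bins first, then dB.
#' @param eps floor for zero-power bins before the log transform.
#' @return A data.frame (`channel`, `band`, `power_db`, `n_windows`).
#' @export
band_power <- function(rec, segments, bands = band_defs("night"),
                       segment_len_s = NULL, per_bin_db = TRUE,
                       eps = 1e-12) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (is.null(segment_len_s))
    segment_len_s <- attr(bands, "segment_len_s") %||% 10
  fs <- rec$fs
  nwin <- round(segment_len_s * fs)
  # collect window start samples
  win_starts <- integer()
  for (k in seq_len(nrow(segments))) {
    i0 <- floor(segments$start_s[k] * fs) + 1L
    i1 <- floor(segments$end_s[k] * fs)
    n_fit <- (i1 - i0 + 1L) %/% nwin
    if (n_fit > 0)
      win_starts <- c(win_starts, i0 + (seq_len(n_fit) - 1L) * nwin)
  }
  if (!length(win_starts))
    stop("band_power: no analysis segment can hold a full window of ",
         segment_len_s, " s")
  freqs <- (seq_len(floor(nwin / 2) + 1L) - 1L) * fs / nwin
  band_sel <- lapply(seq_len(nrow(bands)), function(b) {
    sel <- freqs >= bands$lo[b] & freqs < bands$hi[b]
    if (!any(sel)) stop("band_power: empty band ", bands$band[b])
    sel
  })
  res <- expand.grid(channel = rec$labels, band = bands$band,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  res$power_db <- NA_real_
  res$n_windows <- length(win_starts)
  acc <- matrix(0, nrow = nrow(rec$signal), ncol = nrow(bands))
  for (s0 in win_starts) {
    seg <- rec$signal[, s0:(s0 + nwin - 1L), drop = FALSE]
    for (ch in seq_len(nrow(seg))) {
      psd <- hamming_psd(seg[ch, ], fs)
      for (b in seq_len(nrow(bands))) {
        p <- psd$power[band_sel[[b]]]
        acc[ch, b] <- acc[ch, b] + if (per_bin_db)
          mean(10 * log10(pmax(p, eps)))
        else 10 * log10(max(mean(p), eps))
      }
    }
  }
  acc <- acc / length(win_starts)
  for (b in seq_len(nrow(bands)))
    res$power_db[res$band == bands$band[b]] <- acc[, b]
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Sleep macrostructure parameters from a hypnogram
#'
#' Computes sleep latency (lights-off to first N2 epoch), WASO, stage-shift
#' rate, fragmentation rate (transitions to wake or to a lighter NREM
#' stage, per hour of sleep), stage durations, and REM latency. Stage depth
#' ordering is W < N1 < N2 < N3; REM is its own class (transitions into REM
#' are not lightenings, transitions to W always fragment).
#'
#' @param hyp a [hypnogram()] with a lights-off marker.
#' @return A one-row data.frame: `sleep_latency_min`, `waso_min`,
#'   `shift_rate_h`, `fragmentation_h`, `n2_min`, `n3_min`, `rem_min`,
#'   `rem_latency_min`, `tst_min`. Latencies are `NA` (with a warning) when
#'   the defining epoch never occurs.
#' @export
macrostructure <- function(hyp) {
  stopifnot(inherits(hyp, "hypnogram"))
  st <- hyp$stages
  el_min <- hyp$epoch_len_s / 60
  off_ep <- floor(hyp$lights_off_s / hyp$epoch_len_s) + 1L
  st <- st[off_ep:length(st)]
  first_n2 <- match("N2", st)
  if (is.na(first_n2)) {
    warning("macrostructure: no N2 epoch; latency undefined")
    onset <- NA_integer_
  } else onset <- first_n2
  lat <- (first_n2 - 1L) * el_min
  depth <- c(W = 0, N1 = 1, N2 = 2, N3 = 3)
  waso <- shift_rate <- frag <- rem_lat <- NA_real_
  tst_min <- NA_real_
  if (!is.na(onset)) {
    post <- st[onset:length(st)]
    waso <- sum(post == "W") * el_min
    tst_min <- sum(post != "W") * el_min
    trans <- which(post[-1L] != post[-length(post)])
    n_shift <- length(trans)
    from <- post[trans]; to <- post[trans + 1L]
    # awakenings plus NREM lightenings; REM is its own class
    n_frag <- sum(to == "W" | (from %in% c("N2", "N3") & to %in% c("N1", "N2") &
                                 depth[to] < depth[from]))
    hrs <- tst_min / 60
    shift_rate <- if (hrs > 0) n_shift / hrs else NA_real_
    frag <- if (hrs > 0) n_frag / hrs else NA_real_
    first_rem <- match("REM", post)
    rem_lat <- if (is.na(first_rem)) NA_real_ else (first_rem - 1L) * el_min
  }
  data.frame(sleep_latency_min = lat, waso_min = waso,
             shift_rate_h = shift_rate, fragmentation_h = frag,
             n2_min = sum(st == "N2") * el_min,
             n3_min = sum(st == "N3") * el_min,
             rem_min = sum(st == "REM") * el_min,
             rem_latency_min = rem_lat, tst_min = tst_min)
}
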