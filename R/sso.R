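#' Condition a channel for slow-oscillation detection
#'
#' Zero-phase band-pass (0.1-6 Hz by default: 2nd-order Butterworth
#' high-pass then 4th-order Butterworth low-pass, each forward-backward)
#' restricting the signal to the slow band before zero-crossing analysis.
#'
#' @param x numeric signal vector (microvolts).
#' @param fs sampling rate in Hz.
#' @param band length-2 numeric, conditioning band edges in Hz.
#' @return The conditioned signal vector.
#' @export
sso_condition <- function(x, fs, band = c(0.1, 6)) {
  nyq <- fs / 2
  if (any(band >= nyq)) stop("sso_condition: band edge >= Nyquist")
  hp <- signal::butter(2, band[1] / nyq, type = "high")
  lp <- signal::butter(4, band[2] / nyq, type = "low")
  signal::filtfilt(lp, signal::filtfilt(hp, x))
}

#' Detect slow-oscillation waves on one channel
#'
#' Enumerates consecutive zero-crossing pairs of the (slow-band
#' conditioned) signal inside the supplied NREM segments. A candidate wave
#' is a negative-going zero crossing followed by a positive-going one,
#' separated by `dur_range` seconds, whose negative peak and
#' negative-to-positive amplitude clear the relaxed completion floors. The
#' `full_fledged` flag marks waves that additionally satisfy the strict
#' criteria: negative peak at or below `neg_thresh` (default -80 uV) and
#' peak-to-peak amplitude of at least `np_thresh` (default 140 uV). The
#' positive peak is searched between the second zero crossing and the next
#' negative-going crossing. slope+ is |negative peak| divided by the time
#' from the negative peak to the second zero crossing (uV/s);
#' `slope_mode = "max_derivative"` instead reports the maximum first
#' derivative between the negative and positive peaks.
#'
#' @param x numeric channel signal (conditioned; microvolts).
#' @param fs sampling rate in Hz.
#' @param segments data.frame (`start_s`, `end_s`) of NREM intervals;
#'   default: the whole signal.
#' @param neg_thresh,np_thresh full-fledged amplitude criteria (uV).
#' @param dur_range allowed zero-crossing separation in seconds.
#' @param completion_neg,completion_np relaxed floors for sub-threshold
#'   waves kept as cluster-completion candidates (uV).
#' @param slope_mode `"from_neg_peak"` (default) or `"max_derivative"`.
#' @return A data.frame, one row per wave: `channel` (NA here; filled by
#'   multi-channel wrappers), `t_zc1`, `t_negpeak`, `t_zc2`, `t_pospeak`,
#'   `neg_amp`, `pos_amp`, `np_amp`, `slope_pos`, `full_fledged`.
#' @export
detect_sso_waves <- function(x, fs, segments = NULL,
                             neg_thresh = -80, np_thresh = 140,
                             dur_range = c(0.3, 1.0),
                             completion_neg = -30, completion_np = 50,
                             slope_mode = c("from_neg_peak", "max_derivative")) {
  slope_mode <- match.arg(slope_mode)
  if (is.null(segments))
    segments <- data.frame(start_s = 0, end_s = length(x) / fs)
  waves <- list()
  for (k in seq_len(nrow(segments))) {
    i0 <- floor(segments$start_s[k] * fs) + 1L
    i1 <- min(ceiling(segments$end_s[k] * fs), length(x))
    if (i1 - i0 < fs * dur_range[1]) next
    s <- x[i0:i1]
    sgn <- sign(s)
    sgn[sgn == 0] <- 1  # exact zeros treated as non-negative
    flips <- which(sgn[-1L] != sgn[-length(s)])  # crossing between i, i+1
    if (length(flips) < 2L) next
    down <- flips[sgn[flips] > 0]   # negative-going
    up <- flips[sgn[flips] < 0]     # positive-going
    for (z1 in down) {
      z2 <- up[up > z1]
      if (!length(z2)) next
      z2 <- z2[1L]
      dt <- (z2 - z1) / fs
      if (dt < dur_range[1] || dt > dur_range[2]) next
      half <- s[(z1 + 1L):z2]
      neg_amp <- min(half)
      i_neg <- z1 + which.min(half)
      z3 <- down[down > z2]
      z3 <- if (length(z3)) z3[1L] else length(s)
      posseg <- s[(z2 + 1L):z3]
      pos_amp <- max(posseg)
      i_pos <- z2 + which.max(posseg)
      np <- pos_amp - neg_amp
      if (neg_amp > completion_neg || np < completion_np) next
      slope <- if (slope_mode == "from_neg_peak")
        abs(neg_amp) / ((z2 - i_neg) / fs)
      else max(diff(s[i_neg:i_pos])) * fs
      waves[[length(waves) + 1L]] <- data.frame(
        t_zc1 = (i0 - 1L + z1 - 1L) / fs,
        t_negpeak = (i0 - 1L + i_neg - 1L) / fs,
        t_zc2 = (i0 - 1L + z2 - 1L) / fs,
        t_pospeak = (i0 - 1L + i_pos - 1L) / fs,
        neg_amp = neg_amp, pos_amp = pos_amp, np_amp = np,
        slope_pos = slope,
        full_fledged = neg_amp <= neg_thresh && np >= np_thresh)
    }
  }
  out <- if (length(waves)) do.call(rbind, waves) else
    data.frame(t_zc1 = numeric(), t_negpeak = numeric(), t_zc2 = numeric(),
               t_pospeak = numeric(), neg_amp = numeric(),
               pos_amp = numeric(), np_amp = numeric(),
               slope_pos = numeric(), full_fledged = logical())
  cbind(channel = rep(NA_character_, nrow(out)), out)
}

#' Detect slow-oscillation waves on every channel of a recording
#'
#' Convenience wrapper: conditions each channel with [sso_condition()]
#' (unless `condition = FALSE`) and runs [detect_sso_waves()].
#'
#' @param rec an [eeg_recording()].
#' @param segments NREM segments from [select_nrem()].
#' @param condition logical; apply slow-band conditioning first.
#' @param ... passed to [detect_sso_waves()].
#' @return Row-bound wave table with `channel` filled in.
#' @export
detect_sso_recording <- function(rec, segments = NULL, condition = TRUE, ...) {
  stopifnot(inherits(rec, "eeg_recording"))
  out <- lapply(seq_along(rec$labels), function(ch) {
    x <- rec$signal[ch, ]
    if (condition) x <- sso_condition(x, rec$fs)
    w <- detect_sso_waves(x, rec$fs, segments, ...)
    w$channel <- rec$labels[ch]
    w
  })
  do.call(rbind, out)
}

#' Cluster per-channel slow-oscillation waves into multi-channel events
#'
#' Full-fledged waves whose negative peaks fall within `tol_s` of each
#' other (chained linkage: each successive member within `tol_s` of the
#' previous) form one event. Channels without a full-fledged member are
#' completed with their closest sub-threshold wave (timing-valid, above the
#' relaxed amplitude floors) whose negative peak lies within `tol_s` of the
#' event reference (the earliest member negative peak). Full-fledged
#' singletons are retained as events, so K-complex-like isolated waves are
#' kept.
#'
#' @param waves wave table from [detect_sso_recording()] (must carry
#'   `channel`, `t_negpeak`, `full_fledged`).
#' @param tol_s clustering tolerance between negative peaks (default 0.2).
#' @return The wave table restricted to event members, with added columns
#'   `event_id` and `event_ref_s` (event reference time). Attribute
#'   `n_events` gives the event count.
#' @export
cluster_sso_events <- function(waves, tol_s = 0.2) {
  ff <- waves[waves$full_fledged, , drop = FALSE]
  if (!nrow(ff)) {
    out <- cbind(waves[0, , drop = FALSE],
                 event_id = integer(), event_ref_s = numeric())
    attr(out, "n_events") <- 0L
    return(out)
  }
  ff <- ff[order(ff$t_negpeak), , drop = FALSE]
  gap <- c(0, diff(ff$t_negpeak))
  ff$event_id <- cumsum(gap > tol_s) + 1L
  sub <- waves[!waves$full_fledged, , drop = FALSE]
  members <- list()
  for (ev in unique(ff$event_id)) {
    mem <- ff[ff$event_id == ev, , drop = FALSE]
    ref <- min(mem$t_negpeak)
    mem$event_ref_s <- ref
    if (nrow(sub)) {
      cand <- sub[!(sub$channel %in% mem$channel) &
                    abs(sub$t_negpeak - ref) <= tol_s, , drop = FALSE]
      if (nrow(cand)) {
        # one completion wave per channel: the closest to the reference
        cand <- cand[order(abs(cand$t_negpeak - ref)), , drop = FALSE]
        cand <- cand[!duplicated(cand$channel), , drop = FALSE]
        cand$event_id <- ev
        cand$event_ref_s <- ref
        mem <- rbind(mem, cand)
      }
    }
    members[[length(members) + 1L]] <- mem
  }
  out <- do.call(rbind, members)
  # a sub-threshold wave may sit within tolerance of two events: keep the
  # assignment closest to its reference
  out <- out[order(abs(out$t_negpeak - out$event_ref_s)), , drop = FALSE]
  out <- out[!duplicated(paste(out$channel, out$t_negpeak)), , drop = FALSE]
  out <- out[order(out$event_id, out$channel), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_events") <- length(unique(out$event_id))
  out
}

#' Per-channel slow-oscillation feature set
#'
#' Detection rate (waves per minute of artifact-free NREM), mean
#' negative-to-positive amplitude, and mean slope+ per channel. Rates are
#' reported both over all event-member waves (`rate_min`) and over
#' full-fledged waves only (`rate_ff_min`); channels without waves get rate
#' 0 and `NA` (flagged) amplitude/slope summaries.
#'
#' @param events clustered wave table from [cluster_sso_events()] (or any
#'   wave table with `channel`, `np_amp`, `slope_pos`, `full_fledged`).
#' @param nrem_min artifact-free NREM duration in minutes (> 0).
#' @param channels channel labels to report (default: those present).
#' @return A data.frame (`channel`, `n_waves`, `rate_min`, `rate_ff_min`,
#'   `np_amp`, `slope_pos`).
#' @export
characterize_sso <- function(events, nrem_min,
                             channels = sort(unique(events$channel))) {
  if (!is.numeric(nrem_min) || nrem_min <= 0)
    stop("characterize_sso: nrem_min must be > 0")
  out <- lapply(channels, function(ch) {
    w <- events[events$channel == ch, , drop = FALSE]
    data.frame(channel = ch, n_waves = nrow(w),
               rate_min = nrow(w) / nrem_min,
               rate_ff_min = sum(w$full_fledged) / nrem_min,
               np_amp = if (nrow(w)) mean(w$np_amp) else NA_real_,
               slope_pos = if (nrow(w)) mean(w$slope_pos) else NA_real_)
  })
  do.call(rbind, out)
}

#' Sigma power preceding slow-oscillation waves
#'
#' For each event-member wave, the 9-15 Hz power (Hamming-windowed FFT, dB
#' per bin averaged over band bins) in the 1 s raw-signal window ending at
#' the wave's first zero crossing (`anchor = "t_zc1"`; configurable to the
#' negative peak). Waves with less than 1 s of preceding signal are skipped
#' and counted.
#'
#' @param rec the raw (unconditioned) [eeg_recording()].
#' @param events clustered wave table from [cluster_sso_events()].
#' @param band sigma band edges in Hz (default `c(9, 15)`).
#' @param window_s window length in seconds before the anchor.
#' @param anchor `"t_zc1"` or `"t_negpeak"`.
#' @return A data.frame (`channel`, `pre_sigma_db`, `n_used`, `n_skipped`);
#'   `pre_sigma_db` is `NA`-flagged when every wave was too early.
#' @export
pre_sso_sigma <- function(rec, events, band = c(9, 15), window_s = 1,
                          anchor = c("t_zc1", "t_negpeak")) {
  stopifnot(inherits(rec, "eeg_recording"))
  anchor <- match.arg(anchor)
  fs <- rec$fs
  nwin <- round(window_s * fs)
  out <- lapply(sort(unique(events$channel)), function(ch) {
    w <- events[events$channel == ch, , drop = FALSE]
    x <- rec$signal[match(ch, rec$labels), ]
    t_anchor <- w[[anchor]]
    i_end <- floor(t_anchor * fs)  # sample index of the anchor
    ok <- i_end - nwin + 1L >= 1L
    vals <- vapply(i_end[ok], function(ie)
      band_db(x[(ie - nwin + 1L):ie], fs, band[1], band[2]), numeric(1))
    if (!any(ok) && nrow(w))
      warning("pre_sso_sigma: all waves on ", ch, " precede ", window_s, " s")
    data.frame(channel = ch,
               pre_sigma_db = if (length(vals)) mean(vals) else NA_real_,
               n_used = sum(ok), n_skipped = sum(!ok))
  })
  do.call(rbind, out)
}
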