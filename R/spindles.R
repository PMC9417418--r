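#' Sigma band-pass filter for spindle detection
#'
#' Zero-phase Chebyshev II band-pass with stopband edges at 11 and 17 Hz
#' (order 5, 15 dB single-pass stopband attenuation; forward-backward
#' application yields >= 30 dB at the stopband edges and an essentially
#' flat 12-16 Hz passband).
#'
#' @param x numeric signal vector, or an [eeg_recording()].
#' @param fs sampling rate in Hz (ignored when `x` is a recording).
#' @param stopband stopband edges in Hz (default `c(11, 17)`).
#' @return Filtered signal of the same shape/class as the input.
#' @export
sigma_bandpass <- function(x, fs = NULL, stopband = c(11, 17)) {
  if (inherits(x, "eeg_recording")) {
    x$signal <- t(apply(x$signal, 1L, sigma_bandpass, fs = x$fs,
                        stopband = stopband))
    return(x)
  }
  if (is.null(fs)) stop("sigma_bandpass: fs required for a plain vector")
  nyq <- fs / 2
  if (stopband[2] >= nyq)
    stop("sigma_bandpass: upper stopband edge >= Nyquist; rate too low")
  flt <- signal::cheby2(5, 15, stopband / nyq, type = "pass")
  signal::filtfilt(flt, x)
}

#' Envelope-distance amplitude signal
#'
#' Upper and lower envelopes of the sigma-band filtered signal are built by
#' shape-preserving (monotone Hermite) interpolation through successive
#' local maxima and minima respectively; the amplitude signal is their
#' point-by-point distance, clipped at zero. Beyond the first/last
#' extremum the envelopes are held constant. A signal with fewer than two
#' extrema on one side yields a constant envelope there (flat signal gives
#' distance zero).
#'
#' @param x sigma-band filtered signal vector.
#' @return Non-negative amplitude signal of the same length.
#' @export
amplitude_signal <- function(x) {
  n <- length(x)
  d <- diff(x)
  # strict local extrema (plateaus contribute their first sample)
  s <- sign(d)
  nz <- s != 0
  imax <- which(diff(s[nz]) < 0)
  imin <- which(diff(s[nz]) > 0)
  idx_nz <- which(nz)
  peak_at <- function(k) idx_nz[k] + 1L
  env_of <- function(idx) {
    if (length(idx) == 0L) return(rep(mean(x), n))
    if (length(idx) == 1L) return(rep(x[idx], n))
    f <- stats::splinefun(idx, x[idx], method = "monoH.FC")
    e <- f(seq_len(n))
    e[seq_len(n) < idx[1]] <- x[idx[1]]
    e[seq_len(n) > idx[length(idx)]] <- x[idx[length(idx)]]
    e
  }
  upper <- env_of(peak_at(imax))
  lower <- env_of(peak_at(imin))
  pmax(upper - lower, 0)
}

#' Per-channel adaptive spindle threshold
#'
#' For each NREM period the mean of the amplitude signal plus twice its
#' standard deviation is computed; the channel threshold is the average of
#' the per-period values weighted by the period lengths.
#'
#' @param amp amplitude signal vector from [amplitude_signal()].
#' @param fs sampling rate in Hz.
#' @param periods data.frame (`start_s`, `end_s`) of NREM periods.
#' @param min_period_s periods shorter than this are excluded (default 30).
#' @return A list of class `channel_threshold`: `theta` (uV) and `periods`
#'   (data.frame `start_s`, `end_s`, `length_s`, `mean`, `sd`, `value`).
#' @export
spindle_threshold <- function(amp, fs, periods, min_period_s = 30) {
  per <- periods[periods$end_s - periods$start_s >= min_period_s, ,
                 drop = FALSE]
  if (!nrow(per))
    stop("spindle_threshold: no NREM period of >= ", min_period_s, " s")
  rows <- lapply(seq_len(nrow(per)), function(k) {
    i0 <- floor(per$start_s[k] * fs) + 1L
    i1 <- min(floor(per$end_s[k] * fs), length(amp))
    a <- amp[i0:i1]
    m <- mean(a); sdv <- stats::sd(a)
    data.frame(start_s = per$start_s[k], end_s = per$end_s[k],
               length_s = per$end_s[k] - per$start_s[k],
               mean = m, sd = sdv, value = m + 2 * sdv)
  })
  pt <- do.call(rbind, rows)
  structure(list(theta = sum(pt$length_s * pt$value) / sum(pt$length_s),
                 periods = pt),
            class = "channel_threshold")
}

#' @export
print.channel_threshold <- function(x, ...) {
  cat(sprintf("<channel_threshold> theta = %.2f uV over %d period(s)\n",
              x$theta, nrow(x$periods)))
  invisible(x)
}

#' Detect sleep spindles on one channel
#'
#' Candidate intervals are runs where the amplitude signal exceeds
#' `multiplier` times the channel threshold, restricted to NREM periods;
#' runs separated by less than `merge_gap_s` are merged, and events are
#' kept when their duration falls within `dur_range`. Each event's sigma
#' power is the mean per-bin dB power in `power_band` over the event
#' interval of the raw signal (Hamming-windowed FFT).
#'
#' @param x raw channel signal (for event sigma power); may be `NULL` to
#'   skip power computation.
#' @param amp amplitude signal from [amplitude_signal()].
#' @param fs sampling rate in Hz.
#' @param threshold a `channel_threshold` from [spindle_threshold()] (or a
#'   bare numeric theta).
#' @param periods data.frame (`start_s`, `end_s`) of NREM periods.
#' @param multiplier detection level as a multiple of theta (default 2;
#'   the sensitivity of event counts to this factor is reported by
#'   [spindle_sensitivity()]).
#' @param merge_gap_s merge gap in seconds (default 0.25).
#' @param dur_range event duration bounds in seconds (default
#'   `c(0.3, 3)`).
#' @param power_band band for per-event power in Hz (default `c(12, 16)`).
#' @return A data.frame (`channel`, `onset_s`, `offset_s`, `duration_s`,
#'   `peak_amp`, `sigma_power_db`).
#' @export
detect_spindles <- function(x, amp, fs, threshold, periods = NULL,
                            multiplier = 2, merge_gap_s = 0.25,
                            dur_range = c(0.3, 3), power_band = c(12, 16)) {
  theta <- if (inherits(threshold, "channel_threshold")) threshold$theta
  else as.numeric(threshold)
  if (is.null(periods))
    periods <- data.frame(start_s = 0, end_s = length(amp) / fs)
  level <- multiplier * theta
  events <- list()
  for (k in seq_len(nrow(periods))) {
    i0 <- floor(periods$start_s[k] * fs) + 1L
    i1 <- min(floor(periods$end_s[k] * fs), length(amp))
    if (i1 <= i0) next
    above <- amp[i0:i1] > level
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- c(1L, utils::head(ends, -1L) + 1L)
    runs <- data.frame(start = starts[r$values], end = ends[r$values])
    if (!nrow(runs)) next
    # merge runs separated by < merge_gap_s
    merged <- runs[1, , drop = FALSE]
    if (nrow(runs) > 1) for (j in 2:nrow(runs)) {
      if ((runs$start[j] - merged$end[nrow(merged)] - 1L) / fs < merge_gap_s)
        merged$end[nrow(merged)] <- runs$end[j]
      else merged <- rbind(merged, runs[j, ])
    }
    merged$dur <- (merged$end - merged$start + 1L) / fs
    merged <- merged[merged$dur >= dur_range[1] & merged$dur <= dur_range[2], ,
                     drop = FALSE]
    if (!nrow(merged)) next
    for (j in seq_len(nrow(merged))) {
      a0 <- i0 + merged$start[j] - 1L
      a1 <- i0 + merged$end[j] - 1L
      pow <- if (is.null(x)) NA_real_ else
        band_db(x[a0:a1], fs, power_band[1], power_band[2])
      events[[length(events) + 1L]] <- data.frame(
        onset_s = (a0 - 1L) / fs, offset_s = a1 / fs,
        duration_s = merged$dur[j], peak_amp = max(amp[a0:a1]),
        sigma_power_db = pow)
    }
  }
  out <- if (length(events)) do.call(rbind, events) else
    data.frame(onset_s = numeric(), offset_s = numeric(),
               duration_s = numeric(), peak_amp = numeric(),
               sigma_power_db = numeric())
  cbind(channel = rep(NA_character_, nrow(out)), out)
}

#' Detect spindles on every channel of a recording
#'
#' Runs [sigma_bandpass()], [amplitude_signal()], [spindle_threshold()],
#' and [detect_spindles()] per channel.
#'
#' @param rec an [eeg_recording()].
#' @param periods NREM periods from [select_nrem()].
#' @param ... passed to [detect_spindles()].
#' @return List with `events` (row-bound event table) and `thresholds`
#'   (per-channel data.frame `channel`, `theta`).
#' @export
detect_spindles_recording <- function(rec, periods, ...) {
  stopifnot(inherits(rec, "eeg_recording"))
  evs <- list(); ths <- list()
  for (ch in seq_along(rec$labels)) {
    raw <- rec$signal[ch, ]
    filt <- sigma_bandpass(raw, rec$fs)
    amp <- amplitude_signal(filt)
    th <- spindle_threshold(amp, rec$fs, periods)
    e <- detect_spindles(raw, amp, rec$fs, th, periods, ...)
    e$channel <- rec$labels[ch]
    evs[[ch]] <- e
    ths[[ch]] <- data.frame(channel = rec$labels[ch], theta = th$theta)
  }
  list(events = do.call(rbind, evs), thresholds = do.call(rbind, ths))
}

#' Spindle density and power per channel
#'
#' @param events event table from [detect_spindles_recording()].
#' @param nrem_min artifact-free NREM minutes (> 0).
#' @param channels channel labels to report (default: those present).
#' @return A data.frame (`channel`, `n_events`, `density_min`,
#'   `spindle_power_db`); power is `NA`-flagged on channels without
#'   events.
#' @export
spindle_metrics <- function(events, nrem_min,
                            channels = sort(unique(events$channel))) {
  if (!is.numeric(nrem_min) || nrem_min <= 0)
    stop("spindle_metrics: nrem_min must be > 0")
  out <- lapply(channels, function(ch) {
    e <- events[events$channel == ch, , drop = FALSE]
    data.frame(channel = ch, n_events = nrow(e),
               density_min = nrow(e) / nrem_min,
               spindle_power_db = if (nrow(e)) mean(e$sigma_power_db)
               else NA_real_)
  })
  do.call(rbind, out)
}

#' Event-count sensitivity to the detection multiplier
#'
#' Reports spindle event counts at multipliers 1, 1.5, and 2 of the
#' adaptive threshold, documenting how strict the compound
#' threshold-times-multiplier rule is on a given channel.
#'
#' @inheritParams detect_spindles
#' @param multipliers numeric vector of levels to evaluate.
#' @return A data.frame (`multiplier`, `n_events`).
#' @export
spindle_sensitivity <- function(amp, fs, threshold, periods = NULL,
                                multipliers = c(1, 1.5, 2), ...) {
  counts <- vapply(multipliers, function(m)
    nrow(detect_spindles(NULL, amp, fs, threshold, periods,
                         multiplier = m, ...)), numeric(1))
  data.frame(multiplier = multipliers, n_events = counts)
}
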