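#' Simulation specification for synthetic NREM EEG
#'
#' Defaults emulate a high-density sleep study scale: 500 Hz sampling,
#' 1/f background at 20 uV RMS, slow-oscillation waves at 5/min with
#' negative peaks of -110 to -150 uV and peak-to-peak amplitudes of 190 to
#' 260 uV (K-complex scale, with unambiguous margin above the detection
#' criteria after slow-band conditioning), and 12.5-14.5 Hz spindle packets
#' at 2/min with 55-70 uV peak envelopes under a raised-cosine.
#'
#' @param duration_s recording length in seconds (>= 60).
#' @param n_channels number of channels.
#' @param fs sampling rate in Hz (must exceed twice the highest
#'   synthesized frequency).
#' @param noise_alpha spectral exponent of the 1/f^alpha background.
#' @param noise_rms background RMS in uV (0 gives a noiseless record).
#' @param sso_rate_min slow-oscillation waves per minute per channel.
#' @param sso_neg_amp,sso_np_amp,sso_down_dur,sso_up_dur length-2 ranges
#'   (uniform draws) for negative-peak amplitude (uV), peak-to-peak
#'   amplitude (uV), down-phase (zero-crossing separation, s) and up-phase
#'   duration (s).
#' @param spindle_rate_min spindle events per minute per channel.
#' @param spindle_dur,spindle_freq,spindle_amp length-2 ranges for packet
#'   duration (s), carrier frequency (Hz), and peak envelope (uV).
#' @param occupancy_max maximum fraction of the recording that events may
#'   occupy per channel; denser requests raise a capacity error.
#' @param stages hypnogram stages; default: first half N2, second half N3.
#' @param epoch_len_s hypnogram epoch length.
#' @param seed integer seed fixing all draws.
#' @return A list of class `simulation_spec`.
#' @export
simulation_spec <- function(duration_s = 600, n_channels = 8, fs = 500,
                            noise_alpha = 1, noise_rms = 20,
                            sso_rate_min = 5,
                            sso_neg_amp = c(-150, -110),
                            sso_np_amp = c(190, 260),
                            sso_down_dur = c(0.45, 0.8),
                            sso_up_dur = c(0.35, 0.6),
                            spindle_rate_min = 2,
                            spindle_dur = c(1.2, 1.8),
                            spindle_freq = c(12.5, 14.5),
                            spindle_amp = c(55, 70),
                            occupancy_max = 0.4,
                            stages = NULL, epoch_len_s = 30,
                            seed = 1L) {
  if (duration_s < 60) stop("simulation_spec: duration_s must be >= 60")
  if (sso_rate_min < 0 || spindle_rate_min < 0)
    stop("simulation_spec: rates must be >= 0")
  if (fs <= 2 * max(spindle_freq))
    stop("simulation_spec: fs must exceed twice the highest synthesized frequency")
  if (is.null(stages)) {
    n_ep <- ceiling(duration_s / epoch_len_s)
    stages <- rep(c("N2", "N3"), c(ceiling(n_ep / 2), floor(n_ep / 2)))
  }
  structure(as.list(environment()), class = "simulation_spec")
}

#' 1/f^alpha background noise
#'
#' Spectrally shaped Gaussian noise: white noise is Fourier-transformed,
#' scaled by f^(-alpha/2) (DC removed), inverted, and rescaled to the
#' requested RMS.
#'
#' @param n number of samples.
#' @param fs sampling rate in Hz.
#' @param alpha spectral exponent (1 = pink).
#' @param rms target root-mean-square amplitude.
#' @return Numeric vector of length `n`.
#' @export
pink_noise <- function(n, fs, alpha = 1, rms = 1) {
  if (rms == 0) return(numeric(n))
  X <- stats::fft(stats::rnorm(n))
  k <- seq_len(n) - 1L
  k2 <- pmin(k, n - k)          # symmetric frequency index
  scale <- ifelse(k2 == 0, 0, k2^(-alpha / 2))
  x <- Re(stats::fft(X * scale, inverse = TRUE)) / n
  x * rms / stats::sd(x)
}

# biphasic half-sine slow-oscillation template sampled at fs
sso_template <- function(fs, neg_amp, np_amp, down_dur, up_dur) {
  n1 <- round(down_dur * fs); n2 <- round(up_dur * fs)
  t1 <- (seq_len(n1) - 1L) / fs
  t2 <- (seq_len(n2) - 1L) / fs
  c(neg_amp * sin(pi * t1 / down_dur),
    (np_amp + neg_amp) * sin(pi * t2 / up_dur))
}

# raised-cosine spindle packet sampled at fs
spindle_template <- function(fs, dur, freq, amp) {
  t <- (seq_len(round(dur * fs)) - 1L) / fs
  amp * 0.5 * (1 - cos(2 * pi * t / dur)) * sin(2 * pi * freq * t)
}

# place n_ev events of given durations without overlap (0.5 s guard)
place_events <- function(n_ev, durs, duration_s, margin = 1, guard = 0.5,
                         occupied = NULL) {
  placed <- occupied %||% data.frame(start = numeric(), end = numeric())
  onsets <- numeric(n_ev)
  for (j in seq_len(n_ev)) {
    ok <- FALSE
    for (try in seq_len(2000L)) {
      o <- stats::runif(1, margin, duration_s - durs[j] - margin)
      if (!nrow(placed) ||
          all(o + durs[j] + guard < placed$start | o > placed$end + guard)) {
        ok <- TRUE; break
      }
    }
    if (!ok)
      stop("synthetic EEG: cannot place requested events without overlap; ",
           "reduce rates (capacity error)")
    placed <- rbind(placed, data.frame(start = o, end = o + durs[j]))
    onsets[j] <- o
  }
  list(onsets = onsets, occupied = placed)
}

#' Generate a ground-truthed synthetic NREM EEG recording
#'
#' Background is 1/f^alpha noise; each embedded slow oscillation is a
#' biphasic half-sine template (down phase then up phase) with known
#' negative-peak amplitude, peak-to-peak amplitude, and zero-crossing
#' separation; each spindle is a sinusoid under a raised-cosine envelope.
#' Events are placed per channel without overlap (capacity error when the
#' requested rates cannot fit). All draws are fixed by `spec$seed`.
#'
#' @param spec a [simulation_spec()].
#' @return A list: `rec` ([eeg_recording()]), `hyp` ([hypnogram()]),
#'   `mask` (empty [artifact_mask()]), and `truth` with data.frames
#'   `sso_events` (`channel`, `t_negpeak`, `neg_amp`, `np_amp`,
#'   `duration_s`) and `spindle_events` (`channel`, `onset_s`, `offset_s`,
#'   `freq_hz`, `peak_amp`).
#' @export
generate_nrem_eeg <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  n <- round(spec$duration_s * spec$fs)
  n_sso <- round(spec$sso_rate_min * spec$duration_s / 60)
  n_spi <- round(spec$spindle_rate_min * spec$duration_s / 60)
  # capacity pre-check on expected occupancy
  exp_occ <- (n_sso * (mean(spec$sso_down_dur) + mean(spec$sso_up_dur)) +
                n_spi * mean(spec$spindle_dur)) / spec$duration_s
  if (exp_occ > spec$occupancy_max)
    stop(sprintf(
      "synthetic EEG: requested event occupancy %.2f exceeds limit %.2f (capacity error)",
      exp_occ, spec$occupancy_max))
  sig <- matrix(0, nrow = spec$n_channels, ncol = n)
  labels <- sprintf("ch%02d", seq_len(spec$n_channels))
  sso_gt <- list(); spi_gt <- list()
  for (ch in seq_len(spec$n_channels)) {
    x <- pink_noise(n, spec$fs, spec$noise_alpha, spec$noise_rms)
    occupied <- NULL
    if (n_sso > 0) {
      d1 <- stats::runif(n_sso, spec$sso_down_dur[1], spec$sso_down_dur[2])
      d2 <- stats::runif(n_sso, spec$sso_up_dur[1], spec$sso_up_dur[2])
      na <- stats::runif(n_sso, spec$sso_neg_amp[1], spec$sso_neg_amp[2])
      np <- stats::runif(n_sso, spec$sso_np_amp[1], spec$sso_np_amp[2])
      pl <- place_events(n_sso, d1 + d2, spec$duration_s)
      occupied <- pl$occupied
      for (j in seq_len(n_sso)) {
        tem <- sso_template(spec$fs, na[j], np[j], d1[j], d2[j])
        i0 <- round(pl$onsets[j] * spec$fs) + 1L
        idx <- i0:(i0 + length(tem) - 1L)
        x[idx] <- x[idx] + tem
        sso_gt[[length(sso_gt) + 1L]] <- data.frame(
          channel = labels[ch],
          t_negpeak = (i0 - 1L) / spec$fs + d1[j] / 2,
          neg_amp = na[j], np_amp = np[j], duration_s = d1[j])
      }
    }
    if (n_spi > 0) {
      dd <- stats::runif(n_spi, spec$spindle_dur[1], spec$spindle_dur[2])
      ff <- stats::runif(n_spi, spec$spindle_freq[1], spec$spindle_freq[2])
      aa <- stats::runif(n_spi, spec$spindle_amp[1], spec$spindle_amp[2])
      pl <- place_events(n_spi, dd, spec$duration_s, occupied = occupied)
      for (j in seq_len(n_spi)) {
        tem <- spindle_template(spec$fs, dd[j], ff[j], aa[j])
        i0 <- round(pl$onsets[j] * spec$fs) + 1L
        idx <- i0:(i0 + length(tem) - 1L)
        x[idx] <- x[idx] + tem
        spi_gt[[length(spi_gt) + 1L]] <- data.frame(
          channel = labels[ch], onset_s = (i0 - 1L) / spec$fs,
          offset_s = (i0 - 1L) / spec$fs + dd[j],
          freq_hz = ff[j], peak_amp = aa[j])
      }
    }
    sig[ch, ] <- x
  }
  empty_sso <- data.frame(channel = character(), t_negpeak = numeric(),
                          neg_amp = numeric(), np_amp = numeric(),
                          duration_s = numeric())
  empty_spi <- data.frame(channel = character(), onset_s = numeric(),
                          offset_s = numeric(), freq_hz = numeric(),
                          peak_amp = numeric())
  list(
    rec = eeg_recording(sig, labels, spec$fs),
    hyp = hypnogram(spec$stages, spec$epoch_len_s),
    mask = artifact_mask(),
    truth = list(
      sso_events = if (length(sso_gt)) do.call(rbind, sso_gt) else empty_sso,
      spindle_events = if (length(spi_gt)) do.call(rbind, spi_gt) else empty_spi))
}

#' Generate a gamma-distributed binocular-rivalry timeline
#'
#' Percepts alternate between the two eyes with phase durations drawn from
#' gamma distributions (shape `shape`, scaled to the requested means);
#' mixed interludes are inserted between dominance phases so that the
#' expected fraction of phases reported as mixed equals `mixed_fraction`.
#' Phases tile the block without gaps; the final phase is truncated at the
#' block end and flagged.
#'
#' @param mean_dur_dep,mean_dur_ndep mean phase durations (s) of the
#'   deprived and non-deprived eye percepts.
#' @param mixed_fraction expected fraction of phases that are mixed
#'   (`0 <= mixed_fraction < 1`).
#' @param block_len_s block length in seconds (default 180).
#' @param shape gamma shape parameter (default 3.5).
#' @param mean_dur_mixed mean mixed-phase duration (s).
#' @param seed optional integer seed.
#' @param ... passed to [rivalry_timeline()] (`block_id`, `acquired_min`,
#'   `eye_mapping`).
#' @return A `rivalry_timeline`.
#' @export
generate_rivalry_timeline <- function(mean_dur_dep, mean_dur_ndep,
                                      mixed_fraction = 0, block_len_s = 180,
                                      shape = 3.5, mean_dur_mixed = 1,
                                      seed = NULL, ...) {
  if (mean_dur_dep <= 0 || mean_dur_ndep <= 0)
    stop("generate_rivalry_timeline: means must be > 0")
  if (mixed_fraction < 0 || mixed_fraction >= 1)
    stop("generate_rivalry_timeline: mixed_fraction must be in [0, 1)")
  if (block_len_s <= 0)
    stop("generate_rivalry_timeline: block_len_s must be > 0")
  if (!is.null(seed)) set.seed(seed)
  q <- mixed_fraction / (1 - mixed_fraction)  # P(mixed after a dominance phase)
  means <- c(deprived_eye = mean_dur_dep, nondeprived_eye = mean_dur_ndep)
  eye <- sample(names(means), 1L)
  t <- 0; rows <- list()
  while (t < block_len_s) {
    dur <- stats::rgamma(1, shape = shape, scale = means[[eye]] / shape)
    rows[[length(rows) + 1L]] <- data.frame(percept = eye, onset_s = t,
                                            offset_s = t + dur)
    t <- t + dur
    if (t < block_len_s && q > 0 && stats::runif(1) < q) {
      dm <- stats::rgamma(1, shape = shape, scale = mean_dur_mixed / shape)
      rows[[length(rows) + 1L]] <- data.frame(percept = "mixed", onset_s = t,
                                              offset_s = t + dm)
      t <- t + dm
    }
    eye <- setdiff(names(means), eye)
  }
  ev <- do.call(rbind, rows)
  ev$truncated <- FALSE
  last <- nrow(ev)
  ev$truncated[last] <- ev$offset_s[last] > block_len_s
  ev$offset_s[last] <- min(ev$offset_s[last], block_len_s)
  ev <- ev[ev$offset_s > ev$onset_s, , drop = FALSE]
  rivalry_timeline(ev, block_len_s = block_len_s, ...)
}

#' Generate a rank-correlated synthetic subject cohort
#'
#' A latent Gaussian drives the deprivation index before sleep
#' (log-normal, monotone in the latent) and, through a Gaussian copula,
#' each coupled sleep-feature change score, so that the population
#' Spearman correlation between `di_before` and each coupled feature
#' equals `target_rho` (the copula converts the target Spearman rho to the
#' latent Pearson correlation via `r = 2 sin(pi rho / 6)`, exact for the
#' bivariate normal). Null features are independent of the latent. The
#' deprivation index after sleep is coupled to the one before at Spearman
#' `rho_after` (default 0.18, a weak within-subject association).
#'
#' @param n_subjects number of subjects (>= 4).
#' @param target_rho target Spearman correlation (|rho| <= 1) between
#'   `di_before` and each coupled feature change.
#' @param noise_sd additional latent jitter on coupled features (0 keeps
#'   the copula calibration exact; > 0 attenuates the realized rho).
#' @param coupled named numeric vector of scales for coupled feature
#'   changes.
#' @param null_features named numeric vector of scales for null features.
#' @param rho_after Spearman coupling of `di_after` to `di_before`.
#' @param seed optional integer seed.
#' @return A data.frame (`subject`, `plasticity`, `di_before`, `di_after`,
#'   one `d_<feature>` column per feature) with attributes `target_rho`,
#'   `coupled`, `null_features`.
#' @export
generate_cohort <- function(n_subjects = 15, target_rho = -0.7,
                            noise_sd = 0,
                            coupled = c(sso_rate = 1.5, slope_pos = 80,
                                        spindle_power = 1.5,
                                        sigma_power = 1.2,
                                        pre_sso_sigma = 1.3),
                            null_features = c(swa_power = 1.5,
                                              spindle_density = 0.4,
                                              np_amp = 8),
                            rho_after = 0.18, seed = NULL) {
  if (n_subjects < 4)
    stop("generate_cohort: need n_subjects >= 4 for stable rank correlation")
  if (abs(target_rho) > 1) stop("generate_cohort: |target_rho| must be <= 1")
  if (!is.null(seed)) set.seed(seed)
  u <- stats::rnorm(n_subjects)                 # latent: high u = high DI
  r <- 2 * sin(pi * target_rho / 6)
  r_aft <- 2 * sin(pi * rho_after / 6)
  out <- data.frame(subject = sprintf("s%02d", seq_len(n_subjects)),
                    plasticity = -u,
                    di_before = exp(log(0.77) + 0.2 * u),
                    di_after = exp(log(0.87) + 0.2 *
                                     (r_aft * u + sqrt(1 - r_aft^2) *
                                        stats::rnorm(n_subjects))))
  for (f in names(coupled)) {
    z <- r * u + sqrt(max(0, 1 - r^2)) * stats::rnorm(n_subjects) +
      noise_sd * stats::rnorm(n_subjects)
    out[[paste0("d_", f)]] <- coupled[[f]] * z
  }
  for (f in names(null_features))
    out[[paste0("d_", f)]] <- null_features[[f]] * stats::rnorm(n_subjects)
  structure(out, target_rho = target_rho, coupled = names(coupled),
            null_features = names(null_features))
}
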