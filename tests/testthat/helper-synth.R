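# Small fixture builders shared across test files.

# Recording holding a single injected SSO template on one channel.
single_sso_recording <- function(neg = -100, np = 160, d1 = 0.6, d2 = 0.5,
                                 fs = 500, dur_s = 20, at_s = 10,
                                 n_channels = 1) {
  n <- fs * dur_s
  sig <- matrix(0, n_channels, n)
  tem <- sleepod:::sso_template(fs, neg, np, d1, d2)
  i0 <- at_s * fs + 1L
  for (ch in seq_len(n_channels))
    sig[ch, i0:(i0 + length(tem) - 1L)] <- tem
  eeg_recording(sig, fs = fs)
}

# Phase-stats from explicit alternating eye-phase durations.
stats_from_durations <- function(dep, ndep) {
  evs <- list(); t <- 0
  for (i in seq_len(max(length(dep), length(ndep)))) {
    if (i <= length(dep)) {
      evs[[length(evs) + 1L]] <- data.frame(percept = "deprived_eye",
                                            onset_s = t, offset_s = t + dep[i])
      t <- t + dep[i]
    }
    if (i <= length(ndep)) {
      evs[[length(evs) + 1L]] <- data.frame(percept = "nondeprived_eye",
                                            onset_s = t,
                                            offset_s = t + ndep[i])
      t <- t + ndep[i]
    }
  }
  tl <- rivalry_timeline(do.call(rbind, evs), block_len_s = t + 1)
  compute_phase_stats(tl)
}
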