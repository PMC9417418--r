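test_that("an injected template is detected with sample-accurate landmarks", {
  fs <- 500
  rec <- single_sso_recording(neg = -100, np = 160, d1 = 0.6, d2 = 0.5,
                              fs = fs, at_s = 10)
  w <- detect_sso_waves(rec$signal[1, ], fs)
  expect_equal(nrow(w), 1)
  expect_true(w$full_fledged)
  expect_lt(abs(w$t_zc1 - 10), 1.5 / fs)
  expect_lt(abs(w$t_negpeak - 10.3), 1.5 / fs)
  expect_lt(abs(w$t_zc2 - 10.6), 1.5 / fs)
  expect_equal(w$neg_amp, -100, tolerance = 1e-9)
  expect_equal(w$np_amp, 160, tolerance = 1e-9)
})

test_that("waves failing a printed criterion are not full-fledged", {
  fs <- 500
  # negative peak above -80 uV
  w <- detect_sso_waves(single_sso_recording(neg = -70, np = 150)$signal[1, ], fs)
  expect_equal(sum(w$full_fledged), 0)
  # zero crossings 1.2 s apart
  w <- detect_sso_waves(single_sso_recording(neg = -100, np = 160,
                                             d1 = 1.2)$signal[1, ], fs)
  expect_equal(nrow(w), 0)
  # peak-to-peak below 140 uV
  w <- detect_sso_waves(single_sso_recording(neg = -90, np = 130)$signal[1, ], fs)
  expect_equal(sum(w$full_fledged), 0)
})

test_that("detector equals the exhaustive zero-crossing-pair oracle", {
  for (s in 1:50) {
    x <- random_slow_trace(seed = 4000 + s)
    w <- detect_sso_waves(x, 128)
    ff <- w[w$full_fledged, ]
    orc <- oracle_sso(x, 128)
    expect_equal(nrow(ff), nrow(orc), info = paste("trace", s))
    if (nrow(orc)) {
      expect_equal(sort(ff$t_negpeak), sort(orc$t_negpeak),
                   tolerance = 1e-9, info = paste("trace", s))
      expect_equal(sort(ff$np_amp), sort(orc$np_amp), tolerance = 1e-9)
    }
  }
})

test_that("synchronous waves cluster into one event, distant ones split", {
  fs <- 500
  rec3 <- single_sso_recording(n_channels = 3, fs = fs)
  waves <- detect_sso_recording(rec3, condition = FALSE)
  ev <- cluster_sso_events(waves)
  expect_equal(attr(ev, "n_events"), 1)
  expect_equal(nrow(ev), 3)
  # two full-fledged waves 500 ms apart on different channels: two events
  sig <- matrix(0, 2, fs * 20)
  tem <- sleepod:::sso_template(fs, -100, 160, 0.6, 0.5)
  sig[1, (5 * fs):(5 * fs + length(tem) - 1)] <- tem
  sig[2, (5.5 * fs):(5.5 * fs + length(tem) - 1)] <- tem
  waves <- detect_sso_recording(eeg_recording(sig, fs = fs),
                                condition = FALSE)
  ev <- cluster_sso_events(waves)
  expect_equal(attr(ev, "n_events"), 2)
})

test_that("sub-threshold concurrent waves complete an event, flagged as such", {
  fs <- 500
  sig <- matrix(0, 2, fs * 20)
  full <- sleepod:::sso_template(fs, -100, 160, 0.6, 0.5)
  small <- sleepod:::sso_template(fs, -50, 110, 0.6, 0.5)
  sig[1, (5 * fs):(5 * fs + length(full) - 1)] <- full
  sig[2, (5 * fs):(5 * fs + length(small) - 1)] <- small
  waves <- detect_sso_recording(eeg_recording(sig, fs = fs),
                                condition = FALSE)
  ev <- cluster_sso_events(waves)
  expect_equal(attr(ev, "n_events"), 1)
  expect_equal(nrow(ev), 2)
  expect_false(ev$full_fledged[ev$channel == "ch02"])
})

test_that("clustering is invariant to channel order", {
  sim <- generate_nrem_eeg(simulation_spec(duration_s = 120, n_channels = 4,
                                           seed = 17))
  segs <- select_nrem(sim$rec, sim$hyp, sim$mask)
  waves <- detect_sso_recording(sim$rec, segs)
  ev1 <- cluster_sso_events(waves)
  set.seed(2); waves_perm <- waves[sample(nrow(waves)), ]
  ev2 <- cluster_sso_events(waves_perm)
  key <- function(e) e[order(e$channel, e$t_negpeak),
                       c("channel", "t_negpeak", "event_id")]
  k1 <- key(ev1); k2 <- key(ev2)
  expect_equal(k1$channel, k2$channel)
  expect_equal(k1$t_negpeak, k2$t_negpeak)
  # same partition: event ids agree up to relabeling
  expect_equal(as.integer(factor(k1$event_id, levels = unique(k1$event_id))),
               as.integer(factor(k2$event_id, levels = unique(k2$event_id))))
})

test_that("rates, amplitudes and slope+ follow their definitions", {
  waves <- data.frame(channel = "c1",
                      np_amp = rep(180, 30), slope_pos = rep(300, 30),
                      full_fledged = TRUE)
  feat <- characterize_sso(waves, nrem_min = 15)
  expect_equal(feat$rate_min, 2.0)
  # slope+ = |neg peak| / (t_zc2 - t_negpeak): -100 uV over 0.25 s -> 400 uV/s
  fs <- 500
  w <- detect_sso_waves(single_sso_recording(neg = -100, np = 160,
                                             d1 = 0.5)$signal[1, ], fs)
  expect_equal(w$slope_pos, 100 / 0.25, tolerance = 0.02)
  # channel without waves: rate 0, flagged summaries
  feat <- characterize_sso(waves, 15, channels = c("c1", "c2"))
  expect_equal(feat$rate_min[feat$channel == "c2"], 0)
  expect_true(is.na(feat$np_amp[feat$channel == "c2"]))
  expect_error(characterize_sso(waves, 0), "nrem_min")
  # rate additivity: waves pooled over two disjoint stretches of 10 + 5 min
  w2 <- waves[1:12, ]
  expect_equal(characterize_sso(rbind(waves, w2), 15)$rate_min[1],
               (nrow(waves) + nrow(w2)) / 15)
})

test_that("pre-event sigma power sees a tone confined to the pre-SSO second", {
  fs <- 500
  set.seed(5)
  n <- fs * 30
  bg <- rnorm(n, sd = 3)
  tem <- sleepod:::sso_template(fs, -100, 160, 0.6, 0.5)
  x <- bg
  x[(10 * fs):(10 * fs + length(tem) - 1)] <- x[(10 * fs):(10 * fs + length(tem) - 1)] + tem
  t_pre <- seq(9 * fs, 10 * fs - 1) / fs
  x[(9 * fs):(10 * fs - 1)] <- x[(9 * fs):(10 * fs - 1)] + 20 * sin(2 * pi * 13 * t_pre)
  rec <- eeg_recording(matrix(x, 1), "c1", fs)
  waves <- detect_sso_recording(rec)   # slow-band conditioned detection path
  ev <- cluster_sso_events(waves)
  ps <- pre_sso_sigma(rec, ev)
  bg_sigma <- sleepod:::band_db(bg[1:(1 * fs)], fs, 9, 15)
  expect_gt(ps$pre_sigma_db - bg_sigma, 10)
  expect_equal(ps$n_skipped, 0)
})

test_that("waves too close to the recording start are skipped and counted", {
  fs <- 500
  rec <- single_sso_recording(at_s = 0.2, dur_s = 10, fs = fs)
  waves <- detect_sso_recording(rec, condition = FALSE)
  ev <- cluster_sso_events(waves)
  expect_warning(ps <- pre_sso_sigma(rec, ev), "precede")
  expect_equal(ps$n_skipped, 1)
  expect_true(is.na(ps$pre_sigma_db))
})
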