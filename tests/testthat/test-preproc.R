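test_that("mastoid re-reference equals the hand-computed subtraction", {
  set.seed(3)
  sig <- matrix(rnorm(4 * 1000), 4, 1000)
  rec <- eeg_recording(sig, c("a", "b", "M1", "M2"), fs = 250)
  rr <- rereference_mastoids(rec, c("M1", "M2"))
  expect_equal(rr$signal,
               sweep(sig, 2, colMeans(sig[3:4, ]), "-"),
               ignore_attr = TRUE)
  expect_equal(rr$reference, "avg-mastoid")
  # zero mastoids leave signals unchanged; common offset is rejected
  sig0 <- sig; sig0[3:4, ] <- 0
  rec0 <- eeg_recording(sig0, c("a", "b", "M1", "M2"), fs = 250)
  expect_equal(rereference_mastoids(rec0, c("M1", "M2"))$signal[1, ],
               sig0[1, ], ignore_attr = TRUE)
  recc <- eeg_recording(sig + 7, c("a", "b", "M1", "M2"), fs = 250)
  expect_equal(mean(rereference_mastoids(recc, c("M1", "M2"))$signal),
               mean(rereference_mastoids(rec, c("M1", "M2"))$signal))
  expect_error(rereference_mastoids(rec, c("M1", "nope")), "available")
})

test_that("notch and high-pass filters meet their attenuation specs", {
  fs <- 500
  t <- seq(0, 40, by = 1 / fs)
  mid <- t > 10 & t < 30
  mk <- function(x) eeg_recording(matrix(x, 1), "c1", fs)
  # 50 Hz sinusoid through notch(50): residual < 5 %
  y <- filter_recording(mk(sin(2 * pi * 50 * t)), notch = 50)$signal[1, ]
  expect_lt(sd(y[mid]) / sd(sin(2 * pi * 50 * t)[mid]), 0.05)
  # DC through highpass(0.1) -> mean ~ 0
  y <- filter_recording(mk(rep(5, length(t))), highpass = 0.1)$signal[1, ]
  expect_lt(abs(mean(y[mid])), 0.2)
  # 10 Hz passband tone through highpass + double notch: amplitude within 2 %
  tone <- sin(2 * pi * 10 * t)
  y <- filter_recording(mk(tone), highpass = 0.1,
                        notch = c(50, 100))$signal[1, ]
  expect_lt(abs(sd(y[mid]) / sd(tone[mid]) - 1), 0.02)
  expect_error(filter_recording(mk(tone), highpass = 300), "Nyquist")
})

test_that("moment screening flags planted bad channels and only those", {
  set.seed(8)
  n <- 32
  sig <- matrix(rnorm(n * 5000, sd = 10), n, 5000)
  labels <- sprintf("E%02d", 1:n)
  # one 10x amplitude channel
  sig_bad <- sig; sig_bad[17, ] <- rnorm(5000, sd = 100)
  flag <- detect_bad_channels(eeg_recording(sig_bad, labels, 250))
  expect_equal(flag, "E17")
  # one flat channel is caught through the variance moment
  sig_flat <- sig; sig_flat[5, ] <- 0
  flag <- detect_bad_channels(eeg_recording(sig_flat, labels, 250))
  expect_equal(flag, "E05")
  # identical channels: nothing to flag, warning about degeneracy
  sig_id <- matrix(rep(rnorm(5000), each = n), n, 5000)
  expect_warning(flag <- detect_bad_channels(eeg_recording(sig_id, labels, 250)),
                 "degenerate")
  expect_length(flag, 0)
})

test_that("NREM selection respects stages, masks, and interval arithmetic", {
  fs <- 250
  rec <- eeg_recording(matrix(0, 1, fs * 300), "c1", fs)
  # all N3, empty mask: one segment spanning the recording
  segs <- select_nrem(rec, hypnogram(rep("N3", 10)))
  expect_equal(nrow(segs), 1)
  expect_equal(c(segs$start_s, segs$end_s), c(0, 300))
  # middle epoch masked: two segments around it
  segs <- select_nrem(rec, hypnogram(rep("N2", 10)),
                      artifact_mask(150, 180))
  expect_equal(segs$start_s, c(0, 180))
  expect_equal(segs$end_s, c(150, 300))
  expect_equal(attr(segs, "total_s"), 270)
  # all wake: empty with warning
  expect_warning(segs <- select_nrem(rec, hypnogram(rep("W", 10))), "no")
  expect_equal(nrow(segs), 0)
})

test_that("NREM segments are disjoint and their length matches interval math", {
  fs <- 250
  rec <- eeg_recording(matrix(0, 1, fs * 600), "c1", fs)
  set.seed(12)
  for (i in 1:10) {
    stages <- sample(c("W", "N1", "N2", "N3", "REM"), 20, replace = TRUE)
    n_mask <- sample(0:4, 1)
    starts <- sort(runif(n_mask, 0, 590))
    mask <- artifact_mask(starts, starts + runif(n_mask, 1, 20))
    segs <- suppressWarnings(select_nrem(rec, hypnogram(stages), mask))
    if (nrow(segs) > 1) {
      o <- order(segs$start_s)
      expect_true(all(segs$start_s[o][-1] >= segs$end_s[o][-nrow(segs)]))
    }
    # oracle: per-second membership count
    sec <- seq(0.5, 599.5, by = 1)
    ep <- pmin(floor(sec / 30) + 1, 20)
    in_nrem <- stages[ep] %in% c("N2", "N3")
    in_mask <- rep(FALSE, length(sec))
    for (k in seq_len(nrow(mask)))
      in_mask <- in_mask | (sec > mask$start_s[k] & sec < mask$end_s[k])
    expect_equal(attr(segs, "total_s"), sum(in_nrem & !in_mask),
                 tolerance = 0.02)
  }
})

test_that("band power concentrates a 2 Hz tone in the slow-wave band", {
  fs <- 250
  t <- seq(0, 120 - 1 / fs, by = 1 / fs)
  rec <- eeg_recording(matrix(50 * sin(2 * pi * 2 * t), 1), "c1", fs)
  segs <- data.frame(start_s = 0, end_s = 120)
  bands <- data.frame(band = c("swa", "rest"), lo = c(0.5, 4), hi = c(4, 125))
  bp <- band_power(rec, segs, bands, segment_len_s = 10, per_bin_db = FALSE)
  lin <- 10^(bp$power_db / 10)
  # per-bin mean linear power -> band totals via bin counts
  nb <- function(lo, hi) sum(seq(0, 125, by = 0.1) >= lo &
                               seq(0, 125, by = 0.1) < hi)
  tot <- lin[1] * nb(0.5, 4) + lin[2] * nb(4, 125)
  expect_gt(lin[1] * nb(0.5, 4) / tot, 0.99)
})

test_that("white noise yields equal SWA and sigma per-bin dB power", {
  set.seed(19)
  fs <- 100
  rec <- eeg_recording(matrix(rnorm(fs * 1100), 1), "c1", fs)
  bp <- band_power(rec, data.frame(start_s = 0, end_s = 1100),
                   band_defs("night"))
  expect_gte(bp$n_windows[1], 100)
  expect_lt(abs(diff(bp$power_db)), 0.5)
})

test_that("band power is channel-order and segment-order invariant, and scales by 6.02 dB", {
  set.seed(23)
  fs <- 100
  sig <- matrix(rnorm(2 * fs * 120), 2, fs * 120)
  rec <- eeg_recording(sig, c("a", "b"), fs)
  segs <- data.frame(start_s = c(0, 60), end_s = c(50, 115))
  bp <- band_power(rec, segs, band_defs("night"))
  # identical channels give identical rows
  rec_dup <- eeg_recording(sig[c(1, 1), ], c("a", "b"), fs)
  bp_dup <- band_power(rec_dup, segs, band_defs("night"))
  expect_equal(bp_dup$power_db[bp_dup$channel == "a"],
               bp_dup$power_db[bp_dup$channel == "b"])
  # channel permutation
  rec_perm <- eeg_recording(sig[2:1, ], c("b", "a"), fs)
  bp_perm <- band_power(rec_perm, segs, band_defs("night"))
  for (chn in c("a", "b"))
    expect_equal(sort(bp$power_db[bp$channel == chn]),
                 sort(bp_perm$power_db[bp_perm$channel == chn]))
  # segment order
  bp_rev <- band_power(rec, segs[2:1, ], band_defs("night"))
  expect_equal(sort(bp$power_db), sort(bp_rev$power_db))
  # amplitude doubling
  rec2 <- eeg_recording(2 * sig, c("a", "b"), fs)
  bp2 <- band_power(rec2, segs, band_defs("night"))
  expect_equal(bp2$power_db - bp$power_db,
               rep(20 * log10(2), nrow(bp)), tolerance = 1e-9)
})

test_that("macrostructure parameters match hand counts", {
  # sleep latency: two wake epochs before N2
  m <- macrostructure(hypnogram(c("W", "W", rep("N2", 6))))
  expect_equal(m$sleep_latency_min, 1.0)
  # all-N2 night: no wake after onset, no fragmentation
  m <- macrostructure(hypnogram(rep("N2", 12)))
  expect_equal(m$waso_min, 0)
  expect_equal(m$fragmentation_h, 0)
  expect_equal(m$shift_rate_h, 0)
  # lightening and REM latency by hand
  m <- macrostructure(hypnogram(c("W", "N2", "N3", "N2", "REM")))
  expect_equal(m$rem_latency_min, 1.5)
  expect_equal(m$sleep_latency_min, 0.5)
  # transitions: N2->N3, N3->N2 (1 lightening), N2->REM; TST = 2 min
  expect_equal(m$fragmentation_h, 1 / (2 / 60))
  expect_equal(m$shift_rate_h, 3 / (2 / 60))
  expect_equal(m$n2_min, 1)
  expect_equal(m$rem_min, 0.5)
  # no N2 at all: latency flagged undefined
  expect_warning(m <- macrostructure(hypnogram(c("W", "N1", "W"))), "N2")
  expect_true(is.na(m$sleep_latency_min))
})
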