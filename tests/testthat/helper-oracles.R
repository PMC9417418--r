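# Independent brute-force oracles used to cross-check the package's
# implementations. Written as plain sample-by-sample loops, deliberately
# naive.

# Enumerate every consecutive (negative-going, positive-going) zero-crossing
# pair and apply the three printed slow-oscillation criteria.
oracle_sso <- function(x, fs, neg_thresh = -80, np_thresh = 140,
                       dur_range = c(0.3, 1.0)) {
  pos <- x >= 0
  res <- list()
  i <- 1L
  n <- length(x)
  while (i < n) {
    if (pos[i] && !pos[i + 1L]) {          # negative-going crossing at i
      j <- i + 1L
      while (j < n && !pos[j + 1L]) j <- j + 1L   # j: last negative sample
      if (j < n) {                          # positive-going crossing at j
        dt <- (j - i) / fs
        if (dt >= dur_range[1] && dt <= dur_range[2]) {
          neg <- min(x[(i + 1L):j])
          k <- j + 1L
          while (k < n && pos[k + 1L]) k <- k + 1L
          posmax <- max(x[(j + 1L):k])
          if (neg <= neg_thresh && (posmax - neg) >= np_thresh)
            res[[length(res) + 1L]] <-
              c(t_negpeak = (i + which.min(x[(i + 1L):j]) - 1L) / fs,
                neg_amp = neg, np_amp = posmax - neg)
        }
      }
      i <- j
    } else i <- i + 1L
  }
  if (length(res)) as.data.frame(do.call(rbind, res)) else
    data.frame(t_negpeak = numeric(), neg_amp = numeric(),
               np_amp = numeric())
}

# Sample-by-sample thresholding with run merging and duration filtering.
oracle_spindle_runs <- function(amp, fs, level, merge_gap_s = 0.25,
                                dur_range = c(0.3, 3)) {
  above <- amp > level
  runs <- list()
  i <- 1L
  while (i <= length(above)) {
    if (above[i]) {
      j <- i
      while (j < length(above) && above[j + 1L]) j <- j + 1L
      runs[[length(runs) + 1L]] <- c(start = i, end = j)
      i <- j + 1L
    } else i <- i + 1L
  }
  if (!length(runs)) return(data.frame(onset_s = numeric(),
                                       offset_s = numeric()))
  m <- list(runs[[1L]])
  for (r in runs[-1L]) {
    last <- m[[length(m)]]
    if ((r["start"] - last["end"] - 1L) / fs < merge_gap_s)
      m[[length(m)]]["end"] <- r["end"]
    else m[[length(m) + 1L]] <- r
  }
  out <- as.data.frame(do.call(rbind, m))
  out$dur <- (out$end - out$start + 1L) / fs
  out <- out[out$dur >= dur_range[1] & out$dur <= dur_range[2], ]
  data.frame(onset_s = (out$start - 1L) / fs, offset_s = out$end / fs)
}

# Spearman rho through explicit midranks and the product-moment formula.
oracle_spearman_rho <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Benjamini-Hochberg step-up by hand.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(1, adj)[order(o)]
}

# Wilcoxon signed-rank V by direct enumeration of signed ranks.
oracle_wilcoxon_v <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  r <- rank(abs(d))
  sum(r[d > 0])
}

# One-factor within-subject sum-of-squares decomposition by hand.
oracle_rm_ss <- function(values, subject, level) {
  grand <- mean(values)
  ss_total <- sum((values - grand)^2)
  lv_means <- tapply(values, level, mean)
  sb_means <- tapply(values, subject, mean)
  n_s <- length(unique(subject)); n_l <- length(unique(level))
  ss_level <- n_s * sum((lv_means - grand)^2)
  ss_subj <- n_l * sum((sb_means - grand)^2)
  list(ss_level = ss_level, ss_subj = ss_subj,
       ss_err = ss_total - ss_level - ss_subj, ss_total = ss_total,
       F = (ss_level / (n_l - 1)) /
         ((ss_total - ss_level - ss_subj) / ((n_l - 1) * (n_s - 1))))
}

# A random slow-band-rich trace for detector/oracle equivalence testing.
random_slow_trace <- function(seed, fs = 128, dur_s = 30) {
  set.seed(seed)
  x <- sleepod::pink_noise(fs * dur_s, fs, alpha = 1.6, rms = 70)
  sleepod::sso_condition(x, fs)
}
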