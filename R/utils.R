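# Internal numerics shared across modules.

# One-sided power spectrum of a Hamming-windowed segment.
# Returns data.frame(freq, power) with power as a density (uV^2/Hz),
# normalized so that band integrals approximate the segment's variance share.
hamming_psd <- function(x, fs) {
  n <- length(x)
  w <- signal::hamming(n)
  xw <- x * w
  X <- stats::fft(xw)
  nh <- floor(n / 2) + 1L
  p <- (Mod(X[seq_len(nh)])^2) / (fs * sum(w^2))
  # double everything except DC (and Nyquist when n even)
  scale2 <- rep(2, nh); scale2[1] <- 1
  if (n %% 2 == 0) scale2[nh] <- 1
  data.frame(freq = (seq_len(nh) - 1L) * fs / n, power = p * scale2)
}

# Mean per-bin dB power in [lo, hi) of a Hamming-windowed segment.
band_db <- function(x, fs, lo, hi, eps = 1e-12) {
  psd <- hamming_psd(x, fs)
  sel <- psd$freq >= lo & psd$freq < hi
  if (!any(sel)) stop(sprintf("no FFT bins in band [%g, %g) Hz", lo, hi))
  mean(10 * log10(pmax(psd$power[sel], eps)))
}

# Clip intervals (data.frame start_s/end_s) to [0, dur] and drop empties.
clip_intervals <- function(iv, dur) {
  if (!nrow(iv)) return(iv)
  iv$start_s <- pmax(iv$start_s, 0)
  iv$end_s <- pmin(iv$end_s, dur)
  iv[iv$end_s > iv$start_s, , drop = FALSE]
}

# Interval subtraction on a millisecond grid via IRanges.
# a, b: data.frames with start_s/end_s. Returns a minus b (merged, sorted).
interval_setdiff <- function(a, b) {
  to_ir <- function(d) IRanges::IRanges(
    start = as.integer(round(d$start_s * 1000)) + 1L,
    end = as.integer(round(d$end_s * 1000)))
  ra <- IRanges::reduce(to_ir(a))
  res <- if (is.null(b) || !nrow(b)) ra else
    IRanges::setdiff(ra, IRanges::reduce(to_ir(b)))
  data.frame(start_s = (IRanges::start(res) - 1L) / 1000,
             end_s = IRanges::end(res) / 1000)
}

# Zero-phase filter application along rows of a channels x samples matrix.
filtfilt_mat <- function(flt, mat) {
  t(apply(mat, 1L, function(x) signal::filtfilt(flt, x)))
}

# Derive a stream-specific 32-bit seed from a base seed.
derive_seed <- function(seed, offset) {
  (as.integer(seed) + 1000003L * as.integer(offset)) %% 2147483647L
}
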