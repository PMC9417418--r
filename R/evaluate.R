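#' Recall and precision of detected events against ground truth
#'
#' Greedy one-to-one matching per channel. Point events (slow-oscillation
#' negative peaks) match when their times differ by at most `tol_s`;
#' interval events (spindles) match when the detected interval overlaps
#' the true interval enlarged by `tol_s` on both sides.
#'
#' @param truth data.frame of true events: `channel` plus `t` (point) or
#'   `onset_s`/`offset_s` (interval).
#' @param detected data.frame of detected events, same convention.
#' @param type `"point"` or `"interval"`.
#' @param tol_s matching tolerance in seconds (default 0.25).
#' @return A list: `recall`, `precision`, `n_truth`, `n_detected`,
#'   `n_matched`.
#' @export
event_recovery <- function(truth, detected, type = c("point", "interval"),
                           tol_s = 0.25) {
  type <- match.arg(type)
  n_matched <- 0L
  for (ch in unique(c(truth$channel, detected$channel))) {
    tr <- truth[truth$channel == ch, , drop = FALSE]
    de <- detected[detected$channel == ch, , drop = FALSE]
    if (!nrow(tr) || !nrow(de)) next
    if (type == "point") {
      tr <- tr[order(tr$t), , drop = FALSE]
      de <- de[order(de$t), , drop = FALSE]
      used <- rep(FALSE, nrow(de))
      for (i in seq_len(nrow(tr))) {
        dt <- abs(de$t - tr$t[i])
        cand <- which(!used & dt <= tol_s)
        if (length(cand)) {
          used[cand[which.min(dt[cand])]] <- TRUE
          n_matched <- n_matched + 1L
        }
      }
    } else {
      used <- rep(FALSE, nrow(de))
      for (i in seq_len(nrow(tr))) {
        lo <- tr$onset_s[i] - tol_s
        hi <- tr$offset_s[i] + tol_s
        cand <- which(!used & de$onset_s < hi & de$offset_s > lo)
        if (length(cand)) {
          mid <- (tr$onset_s[i] + tr$offset_s[i]) / 2
          d_mid <- abs((de$onset_s[cand] + de$offset_s[cand]) / 2 - mid)
          used[cand[which.min(d_mid)]] <- TRUE
          n_matched <- n_matched + 1L
        }
      }
    }
  }
  list(recall = if (nrow(truth)) n_matched / nrow(truth) else NA_real_,
       precision = if (nrow(detected)) n_matched / nrow(detected) else NA_real_,
       n_truth = nrow(truth), n_detected = nrow(detected),
       n_matched = n_matched)
}
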