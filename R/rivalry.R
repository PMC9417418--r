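#' Construct a binocular-rivalry percept timeline
#'
#' @param events data.frame with columns `percept` (one of
#'   `"deprived_eye"`, `"nondeprived_eye"`, `"mixed"`), `onset_s`,
#'   `offset_s`, and optionally `truncated` (phase cut by block end).
#' @param block_len_s block duration in seconds (default 180).
#' @param block_id block identifier.
#' @param acquired_min minutes since patch removal / awakening (used by
#'   [bin_morning_blocks()]).
#' @param eye_mapping free-text tag recording the eye-to-orientation
#'   assignment.
#' @return A data.frame of class `rivalry_timeline`.
#' @export
rivalry_timeline <- function(events, block_len_s = 180, block_id = 1L,
                             acquired_min = NA_real_, eye_mapping = NA_character_) {
  req <- c("percept", "onset_s", "offset_s")
  if (!all(req %in% names(events)))
    stop("rivalry_timeline: events must have columns ",
         paste(req, collapse = ", "))
  bad <- setdiff(unique(events$percept),
                 c("deprived_eye", "nondeprived_eye", "mixed"))
  if (length(bad))
    stop("rivalry_timeline: unknown percept(s): ", paste(bad, collapse = ", "))
  if (any(events$offset_s <= events$onset_s))
    stop("rivalry_timeline: offsets must exceed onsets")
  if (any(events$onset_s < 0) || any(events$offset_s > block_len_s + 1e-9))
    stop("rivalry_timeline: events outside [0, block_len_s]")
  o <- order(events$onset_s)
  events <- events[o, , drop = FALSE]
  if (nrow(events) > 1 &&
      any(events$onset_s[-1] < events$offset_s[-nrow(events)] - 1e-9))
    stop("rivalry_timeline: overlapping events")
  if (is.null(events$truncated)) events$truncated <- FALSE
  structure(events, class = c("rivalry_timeline", "data.frame"),
            block_len_s = block_len_s, block_id = block_id,
            acquired_min = acquired_min, eye_mapping = eye_mapping)
}

#' Mean phase durations and dominance totals
#'
#' Pools phase durations across the supplied blocks and computes, per
#' percept, the mean phase duration (MPD, s), total dominance time (s),
#' and phase count. Phases truncated by the block end are censored and
#' excluded from MPDs (but counted in total dominance time). Mixed phases
#' are tallied separately and never enter the eye MPDs.
#'
#' @param timelines a `rivalry_timeline` or list of them.
#' @return A data.frame of class `phase_stats` (`percept`, `mpd_s`,
#'   `total_s`, `n_phases`); `mpd_s` is `NA`-flagged for percepts with no
#'   (uncensored) phase.
#' @export
compute_phase_stats <- function(timelines) {
  if (inherits(timelines, "rivalry_timeline")) timelines <- list(timelines)
  if (!length(timelines)) stop("compute_phase_stats: no blocks supplied")
  ev <- do.call(rbind, lapply(timelines, function(tl) {
    stopifnot(inherits(tl, "rivalry_timeline"))
    as.data.frame(tl)
  }))
  if (!nrow(ev)) stop("compute_phase_stats: empty timeline")
  ev$dur <- ev$offset_s - ev$onset_s
  out <- lapply(c("deprived_eye", "nondeprived_eye", "mixed"), function(p) {
    ph <- ev[ev$percept == p, , drop = FALSE]
    full <- ph[!ph$truncated, , drop = FALSE]
    data.frame(percept = p,
               mpd_s = if (nrow(full)) mean(full$dur) else NA_real_,
               total_s = sum(ph$dur), n_phases = nrow(full))
  })
  out <- do.call(rbind, out)
  class(out) <- c("phase_stats", "data.frame")
  out
}

mpd_of <- function(stats, percept, label) {
  v <- stats$mpd_s[stats$percept == percept]
  if (!length(v) || is.na(v) || v <= 0)
    stop("deprivation index undefined: ", label, " (", percept,
         ") mean phase duration missing or non-positive")
  v
}

#' Deprivation index from baseline and post-deprivation phase statistics
#'
#' The ratio-of-ratios plasticity index
#' `DI = (baseMPD_dep / depMPD_dep) * (depMPD_ndep / baseMPD_ndep)`,
#' where `MPD_dep` / `MPD_ndep` are the mean phase durations of the
#' deprived and non-deprived eye and `base` / `dep` index the baseline and
#' post-deprivation measurements. `DI = 1` means no change of the eyes'
#' relative dominance; `DI < 1` a relative boost of the deprived
#' (pre-deprivation dominant) eye.
#'
#' @param base `phase_stats` of the baseline measurement.
#' @param dep `phase_stats` of the post-deprivation measurement.
#' @param timepoint optional label (e.g. `"before"`, `"after"`).
#' @return A one-row data.frame of class `deprivation_index` (`timepoint`,
#'   `di`).
#' @export
compute_deprivation_index <- function(base, dep, timepoint = NA_character_) {
  di <- (mpd_of(base, "deprived_eye", "baseline") /
           mpd_of(dep, "deprived_eye", "post-deprivation")) *
    (mpd_of(dep, "nondeprived_eye", "post-deprivation") /
       mpd_of(base, "nondeprived_eye", "baseline"))
  structure(data.frame(timepoint = timepoint, di = di),
            class = c("deprivation_index", "data.frame"))
}

#' Morning-bin definitions
#'
#' @param set `"morning"` (bins 0-8, 10-18, 30 min) or `"control"`
#'   (0-8, 10-18, 30-48, 60-93, 120-123 min).
#' @return Named list of length-2 numeric bin bounds (minutes, inclusive).
#' @export
morning_bins <- function(set = c("morning", "control")) {
  set <- match.arg(set)
  if (set == "morning")
    list("0-8" = c(0, 8), "10-18" = c(10, 18), "30" = c(30, 30))
  else
    list("0-8" = c(0, 8), "10-18" = c(10, 18), "30-48" = c(30, 48),
         "60-93" = c(60, 93), "120-123" = c(120, 123))
}

#' Pool morning rivalry blocks into acquisition-time bins
#'
#' Each block is assigned to the bin containing its acquisition minute
#' (blocks outside every bin are excluded with a warning) and per-bin
#' phase statistics are computed with [compute_phase_stats()].
#'
#' @param blocks list of `rivalry_timeline`s whose `acquired_min`
#'   attribute is set.
#' @param bins bin list as from [morning_bins()].
#' @return Named list of `phase_stats`, one per non-empty bin.
#' @export
bin_morning_blocks <- function(blocks, bins = morning_bins("morning")) {
  mins <- vapply(blocks, function(b) attr(b, "acquired_min"), numeric(1))
  if (anyNA(mins))
    stop("bin_morning_blocks: every block needs an acquisition minute")
  assign <- rep(NA_integer_, length(blocks))
  for (k in seq_along(bins))
    assign[is.na(assign) & mins >= bins[[k]][1] & mins <= bins[[k]][2]] <- k
  if (anyNA(assign))
    warning("bin_morning_blocks: block(s) at minute ",
            paste(mins[is.na(assign)], collapse = ", "),
            " fall outside all bins; excluded")
  out <- list()
  for (k in seq_along(bins)) {
    sel <- which(assign == k)
    if (length(sel)) out[[names(bins)[k]]] <- compute_phase_stats(blocks[sel])
  }
  out
}
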