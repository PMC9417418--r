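#' Write an EEG recording as CSV matrix + JSON sidecar
#'
#' The signal is stored samples x channels in a headered CSV; the sidecar
#' `<path>.json` records sampling rate, labels, reference, start time, and
#' sample count so the pair is self-describing.
#'
#' @param rec an [eeg_recording()].
#' @param path output CSV path (sidecar written next to it).
#' @return `path`, invisibly.
#' @export
write_eeg <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  dt <- data.table::as.data.table(t(rec$signal))
  data.table::setnames(dt, rec$labels)
  data.table::fwrite(dt, path)
  jsonlite::write_json(
    list(fs = rec$fs, labels = rec$labels, reference = rec$reference,
         start_s = rec$start_s, n_samples = ncol(rec$signal), unit = "uV"),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

#' Read an EEG recording written by [write_eeg()]
#'
#' @param path CSV path; `<path>.json` sidecar must exist.
#' @return An [eeg_recording()].
#' @export
read_eeg <- function(path) {
  if (!file.exists(path)) stop("read_eeg: no such file: ", path)
  sc_path <- sidecar_path(path)
  if (!file.exists(sc_path))
    stop("read_eeg: missing sidecar ", sc_path,
         " (unit and rate would be ambiguous; refusing to guess)")
  sc <- jsonlite::read_json(sc_path, simplifyVector = TRUE)
  if (!identical(sc$unit, "uV"))
    stop("read_eeg: sidecar unit is ", sc$unit %||% "absent",
         ", expected uV; refusing silent rescale")
  dt <- data.table::fread(path)
  if (!identical(names(dt), as.character(sc$labels)))
    stop("read_eeg: CSV header does not match sidecar labels")
  if (nrow(dt) != sc$n_samples)
    stop(sprintf("read_eeg: truncated file: %d samples read, sidecar says %d",
                 nrow(dt), sc$n_samples))
  eeg_recording(t(as.matrix(dt)), sc$labels, sc$fs, sc$reference, sc$start_s)
}

#' Write / read a hypnogram as two-column TSV
#'
#' Columns `epoch` (0-based index) and `stage`; epoch length and
#' lights-off are kept in `#`-comment header lines.
#'
#' @param hyp a [hypnogram()].
#' @param path TSV path.
#' @return `path` (write) or a [hypnogram()] (read).
#' @export
write_hypnogram <- function(hyp, path) {
  stopifnot(inherits(hyp, "hypnogram"))
  con <- file(path, "w")
  writeLines(c(sprintf("# epoch_len_s\t%g", hyp$epoch_len_s),
               sprintf("# lights_off_s\t%g", hyp$lights_off_s),
               "epoch\tstage"), con)
  utils::write.table(data.frame(epoch = seq_along(hyp$stages) - 1L,
                                stage = hyp$stages),
                     con, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  close(con)
  invisible(path)
}

#' @rdname write_hypnogram
#' @export
read_hypnogram <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get_num <- function(key, default) {
    m <- grep(paste0("^# ", key), hdr, value = TRUE)
    if (length(m)) as.numeric(sub(".*\t", "", m[1])) else default
  }
  tab <- utils::read.table(text = lines[!grepl("^#", lines)], sep = "\t",
                           header = TRUE, stringsAsFactors = FALSE)
  tab <- tab[order(tab$epoch), ]
  hypnogram(tab$stage, epoch_len_s = get_num("epoch_len_s", 30),
            lights_off_s = get_num("lights_off_s", 0))
}

#' Write / read an artifact mask as CSV
#' @param mask an [artifact_mask()].
#' @param path CSV path.
#' @return `path` (write) or an [artifact_mask()] (read).
#' @export
write_artifact_mask <- function(mask, path) {
  utils::write.csv(as.data.frame(mask), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_artifact_mask
#' @export
read_artifact_mask <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  artifact_mask(d$start_s, d$end_s, d$reason)
}

#' Write / read a rivalry timeline as CSV + JSON sidecar
#'
#' Event CSV columns: `percept`, `onset_s`, `offset_s`, `truncated`; the
#' sidecar stores block length, id, acquisition minute, and eye mapping.
#'
#' @param tl a `rivalry_timeline`.
#' @param path CSV path.
#' @return `path` (write) or a `rivalry_timeline` (read).
#' @export
write_rivalry <- function(tl, path) {
  stopifnot(inherits(tl, "rivalry_timeline"))
  utils::write.csv(as.data.frame(tl), path, row.names = FALSE)
  jsonlite::write_json(
    list(block_len_s = attr(tl, "block_len_s"),
         block_id = attr(tl, "block_id"),
         acquired_min = attr(tl, "acquired_min"),
         eye_mapping = attr(tl, "eye_mapping")),
    sidecar_path(path), auto_unbox = TRUE, digits = NA, null = "null",
    na = "null")
  invisible(path)
}

#' @rdname write_rivalry
#' @export
read_rivalry <- function(path) {
  ev <- utils::read.csv(path, stringsAsFactors = FALSE)
  sc <- if (file.exists(sidecar_path(path)))
    jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  else list()
  rivalry_timeline(ev,
                   block_len_s = sc$block_len_s %||% max(ev$offset_s),
                   block_id = sc$block_id %||% NA,
                   acquired_min = if (is.null(sc$acquired_min)) NA_real_
                   else as.numeric(sc$acquired_min),
                   eye_mapping = sc$eye_mapping %||% NA_character_)
}

#' Write simulation ground truth as JSON
#' @param truth ground-truth list from [generate_nrem_eeg()].
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, dataframe = "columns", digits = NA)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  gt <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(gt, as.data.frame)
}

#' Read a deposited per-figure source-data table
#'
#' Expected CSV layouts (documented column mapping for the article's
#' deposited per-figure tables):
#' \describe{
#'   \item{di_long}{columns `subject`, `condition`, `timepoint`, `di` —
#'     per-subject deprivation indices across timepoints.}
#'   \item{feature_scatter}{columns `subject`, `di`, `value` — an
#'     ROI-averaged feature change against a deprivation index.}
#' }
#' @param path CSV path.
#' @param layout one of `"di_long"`, `"feature_scatter"`.
#' @return A validated data.frame.
#' @export
read_source_data <- function(path, layout = c("di_long", "feature_scatter")) {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop("read_source_data: no such file: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- switch(layout,
                di_long = c("subject", "condition", "timepoint", "di"),
                feature_scatter = c("subject", "di", "value"))
  miss <- setdiff(req, names(d))
  if (length(miss))
    stop("read_source_data: missing column(s): ", paste(miss, collapse = ", "))
  d
}

#' Recompute deprivation-index statistics from a per-subject DI table
#'
#' Per timepoint of the requested condition: mean DI and a two-tailed
#' one-sample t-test against 1 (FDR-corrected over timepoints); plus the
#' Spearman correlation between the `before` and `after` timepoints and a
#' one-factor repeated-measures ANOVA over timepoints.
#'
#' @param di_table data.frame in the `di_long` layout of
#'   [read_source_data()].
#' @param condition condition to analyse (default `"MDnight"`).
#' @return A list: `means` (data.frame `timepoint`, `mean_di`, `se`),
#'   `t_tests` (stats data.frame with `p_fdr`), `spearman_before_after`,
#'   `anova` (rm-ANOVA table).
#' @export
reproduce_di_stats <- function(di_table, condition = "MDnight") {
  d <- di_table[di_table$condition == condition, , drop = FALSE]
  if (!nrow(d)) stop("reproduce_di_stats: condition not present")
  tps <- unique(d$timepoint)
  means <- do.call(rbind, lapply(tps, function(tp) {
    v <- d$di[d$timepoint == tp]
    data.frame(timepoint = tp, mean_di = mean(v),
               se = stats::sd(v) / sqrt(length(v)), n = length(v))
  }))
  tt <- do.call(rbind, lapply(tps, function(tp)
    t_test_vs(d$di[d$timepoint == tp], mu = 1, comparison = tp)))
  tt$p_fdr <- fdr_bh(tt$p)$p_fdr
  wide <- stats::reshape(d[c("subject", "timepoint", "di")],
                         idvar = "subject", timevar = "timepoint",
                         direction = "wide")
  sp <- if (all(c("di.before", "di.after") %in% names(wide)))
    spearman_test(wide$di.before, wide$di.after, "di_before vs di_after")
  else NULL
  an <- rm_anova(d, dv = "di", subject = "subject", within = "timepoint")
  list(means = means, t_tests = tt, spearman_before_after = sp, anova = an)
}

#' Recompute a feature-change vs deprivation-index correlation
#'
#' @param scatter data.frame in the `feature_scatter` layout of
#'   [read_source_data()].
#' @return A one-row stats data.frame from [spearman_test()].
#' @export
reproduce_feature_correlation <- function(scatter) {
  spearman_test(scatter$di, scatter$value, "di vs feature change")
}
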