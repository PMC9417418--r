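#' Average channel-level features over regions of interest
#'
#' Unweighted mean over the member channels of each ROI, per feature
#' column. Channels flagged bad should be excluded upstream; an ROI
#' emptied of usable channels yields `NA` features with `n_channels = 0`.
#'
#' @param features data.frame with a `channel` column and numeric feature
#'   columns.
#' @param layout an [roi_layout()].
#' @return A data.frame (`roi`, `n_channels`, one column per feature).
#' @export
roi_average <- function(features, layout) {
  stopifnot(inherits(layout, "roi_layout"), "channel" %in% names(features))
  feat_cols <- setdiff(names(features), "channel")
  out <- lapply(names(layout), function(roi) {
    sel <- features[features$channel %in% layout[[roi]], , drop = FALSE]
    row <- data.frame(roi = roi, n_channels = nrow(sel))
    for (f in feat_cols)
      row[[f]] <- if (nrow(sel)) mean(sel[[f]]) else NA_real_
    row
  })
  do.call(rbind, out)
}

#' Between-night change scores
#'
#' Per-subject signed difference, deprivation night minus control night,
#' for every feature column. Subjects missing either night are dropped
#' with a message.
#'
#' @param table data.frame with columns `subject`, `condition` (values
#'   `"MDnight"`, `"Cnight"`), optional grouping columns (e.g. `roi`), and
#'   numeric feature columns.
#' @param by additional key columns (default: `"roi"` when present).
#' @return A data.frame keyed by subject (and `by`), with `d_<feature>`
#'   change columns.
#' @export
condition_change <- function(table, by = intersect("roi", names(table))) {
  stopifnot(all(c("subject", "condition") %in% names(table)))
  feat_cols <- setdiff(names(table), c("subject", "condition", by))
  keys <- unique(table[c("subject", by)])
  rows <- list()
  for (k in seq_len(nrow(keys))) {
    sel <- table
    for (col in c("subject", by))
      sel <- sel[sel[[col]] == keys[[col]][k], , drop = FALSE]
    md <- sel[sel$condition == "MDnight", , drop = FALSE]
    cn <- sel[sel$condition == "Cnight", , drop = FALSE]
    if (nrow(md) != 1L || nrow(cn) != 1L) {
      message("condition_change: dropping ", keys$subject[k],
              " (missing night)")
      next
    }
    row <- keys[k, , drop = FALSE]
    for (f in feat_cols) row[[paste0("d_", f)]] <- md[[f]] - cn[[f]]
    rows[[length(rows) + 1L]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

stat_result <- function(test, n, statistic, p, effect_name, effect,
                        comparison = NA_character_) {
  data.frame(test = test, comparison = comparison, n = n,
             statistic = statistic, p = p, p_fdr = NA_real_,
             effect_name = effect_name, effect = effect)
}

#' Spearman rank correlation
#'
#' Midrank-tied Spearman rho with a two-sided p-value (exact permutation
#' distribution for small samples without ties, t approximation
#' otherwise, as implemented by [stats::cor.test()]). Pairs with missing
#' values are dropped pairwise.
#'
#' @param x,y paired numeric vectors.
#' @param comparison optional descriptor.
#' @return A one-row stats data.frame (`test`, `n`, `statistic` = rho,
#'   `p`, `p_fdr` placeholder, `effect`).
#' @export
spearman_test <- function(x, y, comparison = NA_character_) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4) stop("spearman_test: need >= 4 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("spearman_test: constant input; rho undefined")
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  stat_result("spearman", length(x), unname(ct$estimate), ct$p.value,
              "rho", unname(ct$estimate), comparison)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values and the rejection set at level `q`.
#'
#' @param p numeric vector of raw p-values in `[0, 1]`.
#' @param q FDR level (default 0.05).
#' @return A list: `p_fdr` (monotone adjusted values) and `reject`
#'   (logical).
#' @export
fdr_bh <- function(p, q = 0.05) {
  if (!length(p)) stop("fdr_bh: empty input")
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("fdr_bh: p-values outside [0,1]")
  adj <- stats::p.adjust(p, method = "BH")
  list(p_fdr = adj, reject = !is.na(adj) & adj <= q)
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test on paired samples; zero differences are
#' dropped (Wilcoxon convention). When every difference is zero the
#' result is degenerate with `p = 1`.
#'
#' @param x,y paired numeric vectors.
#' @param comparison optional descriptor.
#' @return A one-row stats data.frame with `statistic` = V (sum of
#'   positive signed ranks) and effect size r = Z / sqrt(n).
#' @export
wilcoxon_signed_rank <- function(x, y, comparison = NA_character_) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  d <- x - y
  nz <- sum(d != 0)
  if (nz == 0) {
    res <- stat_result("wilcoxon_signed_rank", 0, NA_real_, 1,
                       "r", NA_real_, comparison)
    res$degenerate <- TRUE
    return(res)
  }
  if (nz < 5)
    warning("wilcoxon_signed_rank: fewer than 5 non-zero differences")
  wt <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE,
                                            exact = nz < 50))
  z <- stats::qnorm(wt$p.value / 2, lower.tail = FALSE) * sign(wt$statistic -
                                                                 nz * (nz + 1) / 4)
  res <- stat_result("wilcoxon_signed_rank", nz, unname(wt$statistic),
                     wt$p.value, "r", unname(z / sqrt(nz)), comparison)
  res$degenerate <- FALSE
  res
}

#' One-sample and paired t-tests against no change
#'
#' Two-tailed one-sample t-test of deprivation indices against `mu = 1`
#' (no change), with Cohen's d = |mean - mu| / SD. With `y` supplied the
#' paired variant tests `x - y` against 0.
#'
#' @param x numeric vector (deprivation indices), n >= 3.
#' @param y optional paired vector.
#' @param mu null value (default 1).
#' @param comparison optional descriptor.
#' @return A one-row stats data.frame (`statistic` = t, `df` column
#'   added).
#' @export
t_test_vs <- function(x, y = NULL, mu = 1, comparison = NA_character_) {
  if (!is.null(y)) {
    ok <- stats::complete.cases(x, y)
    d <- x[ok] - y[ok]; mu0 <- 0
  } else {
    d <- x[!is.na(x)]; mu0 <- mu
  }
  if (length(d) < 3) stop("t_test_vs: need n >= 3")
  if (stats::sd(d) == 0) {
    if (isTRUE(all.equal(mean(d), mu0))) {
      # constant sample at the null: no evidence of change, flagged degenerate
      res <- stat_result(if (is.null(y)) "t_one_sample" else "t_paired",
                         length(d), 0, 1, "cohens_d", 0, comparison)
      res$df <- length(d) - 1L
      res$degenerate <- TRUE
      return(res)
    }
    stop("t_test_vs: zero variance")
  }
  tt <- stats::t.test(d, mu = mu0)
  res <- stat_result(if (is.null(y)) "t_one_sample" else "t_paired",
                     length(d), unname(tt$statistic), tt$p.value,
                     "cohens_d", abs(mean(d) - mu0) / stats::sd(d),
                     comparison)
  res$df <- unname(tt$parameter)
  res$degenerate <- FALSE
  res
}

#' Repeated-measures ANOVA (within-subject factors)
#'
#' One- or two-factor fully within-subject ANOVA via [stats::aov()] with
#' `Error(subject/...)` strata. Effects are tested against their own
#' subject-by-effect error stratum; partial eta squared is
#' `SS_effect / (SS_effect + SS_error)`. Subjects with missing cells are
#' dropped listwise with a message.
#'
#' @param data long-format data.frame.
#' @param dv name of the dependent-variable column.
#' @param subject name of the subject column.
#' @param within character vector (length 1 or 2) of within-factor
#'   columns.
#' @return A data.frame, one row per effect (`effect`, `df1`, `df2`, `F`,
#'   `p`, `pes` = partial eta squared).
#' @export
rm_anova <- function(data, dv, subject, within) {
  stopifnot(length(within) %in% 1:2, all(c(dv, subject, within) %in% names(data)))
  df <- data[stats::complete.cases(data[c(dv, subject, within)]), , drop = FALSE]
  df[[subject]] <- factor(df[[subject]])
  for (w in within) df[[w]] <- factor(df[[w]])
  n_cells <- prod(vapply(within, function(w) nlevels(df[[w]]), numeric(1)))
  cnt <- table(df[[subject]])
  keep <- names(cnt)[cnt == n_cells]
  if (length(keep) < nlevels(df[[subject]]))
    message("rm_anova: dropping ", nlevels(df[[subject]]) - length(keep),
            " subject(s) with missing cells")
  df <- df[df[[subject]] %in% keep, , drop = FALSE]
  df[[subject]] <- droplevels(df[[subject]])
  if (nlevels(df[[subject]]) < 2) stop("rm_anova: fewer than 2 complete subjects")
  rhs <- paste(within, collapse = " * ")
  err <- paste0("Error(", subject, "/(", rhs, "))")
  fml <- stats::as.formula(paste(dv, "~", rhs, "+", err))
  fit <- stats::aov(fml, data = df)
  sm <- summary(fit)
  # scale for declaring a sum of squares numerically zero
  ss_scale <- sum((df[[dv]] - mean(df[[dv]]))^2)
  rows <- list()
  for (stratum in sm) {
    tab <- stratum[[1]]
    terms <- trimws(rownames(tab))
    resid_i <- which(terms == "Residuals")
    if (!length(resid_i)) next
    ss_err <- tab[resid_i, "Sum Sq"]; df_err <- tab[resid_i, "Df"]
    for (i in setdiff(seq_len(nrow(tab)), resid_i)) {
      ss_eff <- tab[i, "Sum Sq"]
      degen <- ss_eff <= 1e-12 * max(ss_scale, .Machine$double.xmin)
      rows[[length(rows) + 1L]] <- data.frame(
        effect = terms[i], df1 = tab[i, "Df"], df2 = df_err,
        F = if (degen) 0 else tab[i, "F value"],
        p = if (degen) 1 else tab[i, "Pr(>F)"],
        pes = if (degen) 0 else ss_eff / (ss_eff + ss_err))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Correlate change scores with a deprivation index across a cohort
#'
#' Runs [spearman_test()] of each feature column against the index column
#' and applies Benjamini-Hochberg FDR over the family.
#'
#' @param table cohort table (e.g. from [generate_cohort()] or
#'   [condition_change()] merged with DIs).
#' @param di_col name of the deprivation-index column.
#' @param feature_cols names of feature columns (default: all `d_`
#'   columns).
#' @param q FDR level.
#' @return Stats data.frame, one row per feature, with `p_fdr` and
#'   `reject` filled.
#' @export
correlate_features <- function(table, di_col = "di_before",
                               feature_cols = grep("^d_", names(table),
                                                   value = TRUE),
                               q = 0.05) {
  res <- do.call(rbind, lapply(feature_cols, function(f)
    spearman_test(table[[di_col]], table[[f]],
                  comparison = paste(di_col, "vs", f))))
  adj <- fdr_bh(res$p, q)
  res$p_fdr <- adj$p_fdr
  res$reject <- adj$reject
  res
}
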