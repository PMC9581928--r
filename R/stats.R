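# Cohort-level statistics with the organoid as the unit of analysis: ROIs
# are averaged within each organoid first, then means, SDs, inter-/intra-
# organoid coefficients of variation, and group tests are computed over
# organoids.

.checkTable <- function(table) {
  need <- c("organoid_id", "roi_id", "metric", "value")
  if (!all(need %in% names(table)))
    stop("measurement table needs columns ", paste(need, collapse = ", "))
  key <- paste(table$organoid_id, table$roi_id, table$metric,
               if (is.null(table$group)) "" else table$group)
  if (anyDuplicated(key))
    stop("duplicated (organoid, roi, metric) rows in the measurement table")
  if (any(!is.finite(table$value)))
    stop("non-finite values in the measurement table")
  invisible(table)
}

.metricRows <- function(table, metric, group = NULL) {
  .checkTable(table)
  if (!metric %in% table$metric)
    stop("metric '", metric, "' not found; available: ",
         paste(sort(unique(table$metric)), collapse = ", "))
  rows <- table[table$metric == metric, , drop = FALSE]
  if (!is.null(group)) {
    if (is.null(rows$group)) stop("table has no group column")
    rows <- rows[rows$group %in% group, , drop = FALSE]
  }
  rows
}

#' Organoid-level summary of a metric
#'
#' Averages ROIs within each organoid, then reports the mean and sample SD
#' across organoids (the "mean +/- SD over n organoids" convention).
#'
#' @param table measurement `data.frame` with columns `organoid_id`,
#'   `roi_id`, `metric`, `value` (optionally `group`).
#' @param metric metric name.
#' @param group optional group filter.
#' @return list with `perOrganoid` (data.frame `organoid_id`, `mean`),
#'   `mean`, `sd` (`NA` for a single organoid), `n` (organoids).
#' @export
summarizeCohort <- function(table, metric, group = NULL) {
  rows <- .metricRows(table, metric, group)
  if (nrow(rows) == 0L) stop("no rows for metric '", metric, "'")
  per <- aggregate(rows$value, by = list(organoid_id = rows$organoid_id),
                   FUN = mean)
  names(per)[2] <- "mean"
  list(perOrganoid = per,
       mean = mean(per$mean),
       sd = if (nrow(per) >= 2) sd(per$mean) else NA_real_,
       n = nrow(per))
}

#' Inter- and intra-organoid coefficients of variation
#'
#' Interorganoid COV: SD of the per-organoid means over their mean, in
#' percent.  Intraorganoid COV (default `"mean_of_cov"`): the mean over
#' organoids of each organoid's within-ROI SD/mean, in percent.  The
#' `"pooled"` alternative uses the square root of the mean within-organoid
#' variance over the grand mean.
#'
#' @param table,metric,group as in [summarizeCohort()].
#' @param intraMethod `"mean_of_cov"` (default) or `"pooled"`.
#' @return list with `interCov`, `intraCov` (percent), `n` organoids.
#' @export
covPartition <- function(table, metric, group = NULL,
                         intraMethod = c("mean_of_cov", "pooled")) {
  intraMethod <- match.arg(intraMethod)
  rows <- .metricRows(table, metric, group)
  sp <- split(rows$value, rows$organoid_id)
  if (length(sp) < 2L) stop("need at least 2 organoids")
  means <- vapply(sp, mean, numeric(1))
  grand <- mean(means)
  if (grand == 0) stop("zero mean: COV undefined")
  interCov <- 100 * sd(means) / grand
  multi <- sp[vapply(sp, length, integer(1)) >= 2L]
  intraCov <- if (length(multi) == 0L) NA_real_ else if
    (intraMethod == "mean_of_cov") {
    if (any(vapply(multi, mean, numeric(1)) == 0))
      stop("zero within-organoid mean: COV undefined")
    100 * mean(vapply(multi, function(v) sd(v) / mean(v), numeric(1)))
  } else {
    100 * sqrt(mean(vapply(multi, var, numeric(1)))) / grand
  }
  list(interCov = interCov, intraCov = intraCov, n = length(sp),
       intraMethod = intraMethod)
}

#' Compare groups on organoid-level means
#'
#' ROIs are averaged within organoids; organoids are the experimental
#' units.  Two groups are compared with an unpaired two-sided Student's
#' t test (equal variances); three or more with one-way ANOVA followed by
#' Tukey's honest-significant-difference post hoc test (p values adjusted
#' for multiple comparisons).  Significance is called at p < 0.05.
#'
#' If every observation is identical the degenerate result (statistic 0,
#' p = 1) is returned; if within-group variance is zero but means differ,
#' the statistic is infinite with p = 0.  Both carry `degenerate = TRUE`.
#'
#' @param table measurement table (must contain a `group` column).
#' @param metric metric name.
#' @param groups character vector of group labels (2 for `t_test`, >= 3
#'   for `anova_tukey`).
#' @param method `"t_test"` or `"anova_tukey"`.
#' @param alpha significance level.
#' @return list with `method`, `statistic`, `df`, `p`, `significant`,
#'   `groupMeans`, and for the ANOVA branch `pairwise` (Tukey-adjusted
#'   data.frame).
#' @export
compareGroups <- function(table, metric, groups,
                          method = c("t_test", "anova_tukey"),
                          alpha = 0.05) {
  method <- match.arg(method)
  rows <- .metricRows(table, metric, groups)
  per <- aggregate(rows$value,
                   by = list(group = rows$group,
                             organoid_id = rows$organoid_id),
                   FUN = mean)
  names(per)[3] <- "value"
  per$group <- factor(per$group, levels = groups)
  counts <- vapply(split(per$value, per$group), length, integer(1))
  if (any(counts < 2))
    stop("every group needs at least 2 organoids; got: ",
         paste(sprintf("%s=%d", names(counts), counts), collapse = ", "))
  gm <- tapply(per$value, per$group, mean)
  if (method == "t_test") {
    if (length(groups) != 2L) stop("t_test requires exactly 2 groups")
    a <- per$value[per$group == groups[1]]
    b <- per$value[per$group == groups[2]]
    df <- length(a) + length(b) - 2L
    if (var(a) == 0 && var(b) == 0) {
      stat <- if (mean(a) == mean(b)) 0 else Inf
      p <- if (mean(a) == mean(b)) 1 else 0
      return(list(method = method, statistic = stat, df = df, p = p,
                  significant = p < alpha, groupMeans = gm,
                  degenerate = TRUE))
    }
    tt <- t.test(a, b, var.equal = TRUE)
    list(method = method, statistic = unname(tt$statistic),
         df = unname(tt$parameter), p = tt$p.value,
         significant = tt$p.value < alpha, groupMeans = gm,
         degenerate = FALSE)
  } else {
    if (length(groups) < 3L) stop("anova_tukey requires at least 3 groups")
    if (all(tapply(per$value, per$group, var) == 0)) {
      same <- length(unique(gm)) == 1L
      return(list(method = method, statistic = if (same) 0 else Inf,
                  df = c(length(groups) - 1L, nrow(per) - length(groups)),
                  p = if (same) 1 else 0, significant = !same,
                  groupMeans = gm, pairwise = NULL, degenerate = TRUE))
    }
    fit <- aov(value ~ group, data = per)
    an <- summary(fit)[[1]]
    tk <- TukeyHSD(fit)$group
    pw <- data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                     p_adj = tk[, "p adj"],
                     significant = tk[, "p adj"] < alpha,
                     row.names = NULL)
    list(method = method, statistic = an["group", "F value"],
         df = c(an["group", "Df"], an["Residuals", "Df"]),
         p = an["group", "Pr(>F)"],
         significant = an["group", "Pr(>F)"] < alpha,
         groupMeans = gm, pairwise = pw, degenerate = FALSE)
  }
}

#' Write a deterministic analysis report
#'
#' Serializes a named list of results to CSV (flat tables) or JSON with
#' keys in sorted order, so identical results give byte-identical files.
#'
#' @param results non-empty named list (JSON) or data.frame (CSV).
#' @param path output file path.
#' @param format `"json"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
writeReport <- function(results, path, format = c("json", "csv")) {
  format <- match.arg(format)
  if (length(results) == 0L) stop("results are empty: nothing to write")
  if (format == "json") {
    ord <- results[order(names(results))]
    jsonlite::write_json(ord, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    df <- as.data.frame(results)
    df <- df[, order(names(df)), drop = FALSE]
    write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}
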