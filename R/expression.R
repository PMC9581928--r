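# Fovea-versus-periphery expression comparison: reference group mean
# vectors, per-cell Pearson correlation on the gene intersection,
# correlation deltas, gene-set eigengenes, and Z-scores.

.assayMatrix <- function(x) {
  if (is(x, "SummarizedExperiment"))
    SummarizedExperiment::assay(x, 1)
  else as.matrix(x)
}

.scaleTag <- function(x, default = "counts") {
  if (is(x, "SummarizedExperiment")) {
    s <- S4Vectors::metadata(x)$scale
    if (!is.null(s)) return(s)
  }
  default
}

.log10p1 <- function(m) log10(m + 1)

#' Build per-(donor, region, cell type) mean expression vectors
#'
#' Computes the arithmetic mean expression vector of every annotated
#' reference group.  Raw counts (scale tag `"counts"`) are transformed
#' `log10(x + 1)` first so correlations downstream are computed on the
#' log scale; already-transformed references are averaged as stored.
#' Three donors x two regions x three cell types give the full grid of 18
#' vectors; empty groups are omitted with a warning.
#'
#' @param ref a [SummarizedExperiment::SummarizedExperiment] with `colData`
#'   columns `donor`, `region`, `cell_type`.
#' @return a [ReferenceProfiles].
#' @export
buildReferenceVectors <- function(ref) {
  cd <- as.data.frame(SummarizedExperiment::colData(ref))
  need <- c("donor", "region", "cell_type")
  if (!all(need %in% names(cd)))
    stop("reference colData needs columns donor, region, cell_type")
  m <- .assayMatrix(ref)
  scale <- .scaleTag(ref)
  if (identical(scale, "counts")) {
    m <- .log10p1(m)
    scale <- "log10p1"
  }
  key <- interaction(cd$donor, cd$region, cd$cell_type, drop = FALSE)
  grid <- expand.grid(donor = unique(cd$donor), region = unique(cd$region),
                      cell_type = unique(cd$cell_type),
                      stringsAsFactors = FALSE)
  prof <- NULL
  groups <- NULL
  for (i in seq_len(nrow(grid))) {
    sel <- cd$donor == grid$donor[i] & cd$region == grid$region[i] &
      cd$cell_type == grid$cell_type[i]
    if (!any(sel)) {
      warning(sprintf("empty reference group %s/%s/%s omitted",
                      grid$donor[i], grid$region[i], grid$cell_type[i]))
      next
    }
    prof <- cbind(prof, rowMeans(m[, sel, drop = FALSE]))
    groups <- rbind(groups, grid[i, , drop = FALSE])
  }
  colnames(prof) <- paste(groups$donor, groups$region, groups$cell_type,
                          sep = ".")
  new("ReferenceProfiles", profiles = prof,
      groups = as.data.frame(groups, row.names = NULL), scale = scale)
}

#' Correlate query cells against reference mean vectors
#'
#' Pearson correlation of every query cell against every reference group
#' mean, computed on the intersection of the genes present in both sets.
#' Raw query counts are `log10(x + 1)` transformed to match the reference
#' scale.  Cells or reference vectors with zero variance on the
#' intersection yield `NA` correlations, recorded with a reason.
#'
#' @param query a [SummarizedExperiment::SummarizedExperiment] (or matrix)
#'   of query cells; optional `colData` column `cell_type` is carried over.
#' @param refs a [ReferenceProfiles].
#' @return `CorrelationTable`: a long `data.frame` with columns `cell`,
#'   `cell_type` (query annotation, `NA` if absent), `donor`, `region`,
#'   `ref_cell_type`, `r`, `missing_reason`.
#' @export
correlateCells <- function(query, refs) {
  stopifnot(is(refs, "ReferenceProfiles"))
  qm <- .assayMatrix(query)
  if (identical(.scaleTag(query), "counts")) qm <- .log10p1(qm)
  genes <- intersect(rownames(qm), rownames(refs@profiles))
  if (length(genes) < 2L)
    stop("gene intersection between query and reference has fewer than 2 genes")
  qm <- qm[genes, , drop = FALSE]
  pm <- refs@profiles[genes, , drop = FALSE]
  qVar <- apply(qm, 2, sd) == 0
  pVar <- apply(pm, 2, sd) == 0
  r <- suppressWarnings(cor(qm, pm))  # cells x groups; NA on zero variance
  qTypes <- if (is(query, "SummarizedExperiment") &&
                "cell_type" %in%
                  names(SummarizedExperiment::colData(query)))
    SummarizedExperiment::colData(query)$cell_type
  else rep(NA_character_, ncol(qm))
  nQ <- ncol(qm); nG <- ncol(pm)
  out <- data.frame(
    cell = rep(colnames(qm), times = nG),
    cell_type = rep(qTypes, times = nG),
    donor = rep(refs@groups$donor, each = nQ),
    region = rep(refs@groups$region, each = nQ),
    ref_cell_type = rep(refs@groups$cell_type, each = nQ),
    r = as.vector(r))
  out$missing_reason <- ifelse(
    is.na(out$r),
    ifelse(rep(qVar, times = nG), "zero-variance cell",
           "zero-variance reference vector"),
    NA_character_)
  out
}

#' Per-cell fovea-minus-periphery correlation delta
#'
#' For each query cell and donor, the difference between its correlation
#' with the foveal and the peripheral mean vector of the cell's own type:
#' `delta = r(fovea) - r(periphery)`.  Positive deltas indicate a more
#' fovea-like transcriptome.  Cells without a `cell_type` annotation, or
#' with a missing region for a donor, get `NA`.
#'
#' @param table a `CorrelationTable` from [correlateCells()].
#' @return `data.frame` with columns `cell`, `cell_type`, `donor`,
#'   `r_fovea`, `r_periphery`, `delta`.
#' @seealso [deltaSummary()]
#' @export
correlationDelta <- function(table) {
  own <- table[!is.na(table$cell_type) &
                 table$ref_cell_type == table$cell_type, , drop = FALSE]
  if (nrow(own) == 0L)
    stop("no rows with matching query/reference cell type; is the query annotated?")
  fov <- own[own$region == "fovea", c("cell", "cell_type", "donor", "r")]
  per <- own[own$region == "periphery", c("cell", "donor", "r")]
  names(fov)[names(fov) == "r"] <- "r_fovea"
  names(per)[names(per) == "r"] <- "r_periphery"
  out <- merge(fov, per, by = c("cell", "donor"), all = TRUE, sort = TRUE)
  out$delta <- out$r_fovea - out$r_periphery
  out[order(out$cell, out$donor),
      c("cell", "cell_type", "donor", "r_fovea", "r_periphery", "delta")]
}

#' Median correlation delta per cell type (and donor)
#'
#' @param delta output of [correlationDelta()].
#' @param byDonor also split by donor?
#' @return `data.frame` of median deltas.
#' @export
deltaSummary <- function(delta, byDonor = FALSE) {
  f <- if (byDonor) list(cell_type = delta$cell_type, donor = delta$donor)
  else list(cell_type = delta$cell_type)
  agg <- aggregate(delta$delta, by = f, FUN = median, na.rm = TRUE)
  names(agg)[ncol(agg)] <- "median_delta"
  agg
}

#' Gene-set eigengene (first principal component)
#'
#' Summarizes a genes-of-interest (GOI) list as one score per sample: the
#' first principal component of the gene-centred GOI x samples submatrix.
#' The sign is fixed so the score correlates positively with the mean GOI
#' expression across samples.  Expression should be on a
#' variance-stabilized scale (`log2(x + 1)` of normalized counts is the
#' accepted stand-in, tagged in the result).
#'
#' @param expr numeric matrix (genes x samples) with gene rownames, or a
#'   [SummarizedExperiment::SummarizedExperiment].
#' @param goi character vector of gene identifiers (>= 2 must map).
#' @return list with `scores` (named per-sample eigengene),
#'   `varianceExplained` (percent), `genesUsed`, `unmapped`, `scale`.
#' @export
goiEigengene <- function(expr, goi) {
  m <- .assayMatrix(expr)
  scale <- .scaleTag(expr, default = "unspecified")
  goi <- unique(goi)
  mapped <- intersect(goi, rownames(m))
  unmapped <- setdiff(goi, rownames(m))
  if (length(mapped) < 2L)
    stop("fewer than 2 GOI genes map to the expression matrix; missing: ",
         paste(unmapped, collapse = ", "))
  sub <- m[mapped, , drop = FALSE]
  pc <- prcomp(t(sub), center = TRUE, scale. = FALSE)
  scores <- pc$x[, 1]
  ve <- 100 * pc$sdev[1]^2 / sum(pc$sdev^2)
  meanExpr <- colMeans(sub)
  s <- sum(scores * (meanExpr - mean(meanExpr)))
  if (s < 0) scores <- -scores
  list(scores = scores, varianceExplained = ve, genesUsed = mapped,
       unmapped = unmapped, scale = scale)
}

#' Z-score standardization
#'
#' Subtracts the mean and divides by the sample (n - 1) standard
#' deviation.  A zero-spread input returns all zeros with a warning.  For
#' heatmap use, apply per gene across samples via [rowZscores()].
#'
#' @param values numeric vector of length >= 2.
#' @return standardized vector.
#' @examples
#' zscore(c(1, 2, 3))
#' @export
zscore <- function(values) {
  if (length(values) < 2L) stop("need at least 2 values")
  s <- sd(values)
  if (s == 0) {
    warning("zero spread: returning zeros")
    return(rep(0, length(values)))
  }
  (values - mean(values)) / s
}

#' @rdname zscore
#' @param m numeric matrix (genes x samples).
#' @export
rowZscores <- function(m) {
  t(apply(m, 1, function(v) {
    s <- sd(v)
    if (s == 0) rep(0, length(v)) else (v - mean(v)) / s
  }))
}
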