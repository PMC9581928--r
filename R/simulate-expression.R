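# Reference/query expression generator: per-(donor, region, cell type)
# log-normal mean profiles with a declared fraction of region-informative
# genes, Poisson count sampling, and recorded query-cell identities.

#' Generate synthetic reference and query expression sets
#'
#' Builds a reference of single cells from `nDonors` donors x 2 regions
#' (fovea, periphery) x 3 cell types (cone, rod, MG) and a query set whose
#' cells have a known region identity.  Gene baseline means are log-normal;
#' each cell type has its own marker genes (elevated mean); a fraction of
#' genes carries a region effect of `regionEffectSize` on the natural-log
#' mean scale, half up in fovea and half down, so fovea and periphery means
#' differ in both directions.  Counts are Poisson (optionally with an extra
#' per-cell log-normal factor).
#'
#' @param nGenes number of genes.
#' @param nRefCellsPerGroup reference cells per (donor, region, cell type).
#' @param nQueryCells query cells.
#' @param regionEffectSize ln-scale shift applied to region-informative
#'   genes (>= 0).
#' @param regionAffectedFraction fraction of genes carrying a region effect.
#' @param queryRegionMix named probabilities (`fovea`, `periphery`) for the
#'   true identity of each query cell.
#' @param noiseModel `"poisson"` or `"lognormal_poisson"` (adds a per-cell
#'   lognormal size factor, sd 0.2 on the ln scale).
#' @param nDonors number of reference donors.
#' @param seed integer seed.
#' @return list with `reference` and `query`
#'   ([SummarizedExperiment::SummarizedExperiment] objects; assay
#'   `"counts"`, scale tag in `metadata()$scale`, annotations in
#'   `colData()`: reference has `donor`, `region`, `cell_type`; query has
#'   `cell_type` and its true identity in `true_region`).
#' @export
generateExpressionSets <- function(nGenes = 500, nRefCellsPerGroup = 30,
                                   nQueryCells = 150, regionEffectSize = 1,
                                   regionAffectedFraction = 0.1,
                                   queryRegionMix = c(fovea = 0.5,
                                                      periphery = 0.5),
                                   noiseModel = c("poisson",
                                                  "lognormal_poisson"),
                                   nDonors = 3, seed = 1) {
  if (regionEffectSize < 0) stop("regionEffectSize must be non-negative")
  noiseModel <- match.arg(noiseModel)
  if (abs(sum(queryRegionMix) - 1) > 1e-9)
    stop("queryRegionMix must sum to 1")
  .withSeed(seed, {
    regions <- c("fovea", "periphery")
    types <- c("cone", "rod", "MG")
    donors <- paste0("donor", seq_len(nDonors))
    genes <- sprintf("G%04d", seq_len(nGenes))

    baseMu <- rnorm(nGenes, log(5), 1)          # ln-scale baseline
    typeEffect <- matrix(0, nGenes, length(types),
                         dimnames = list(genes, types))
    markerN <- max(1L, round(0.1 * nGenes))
    for (t in seq_along(types)) {
      idx <- ((t - 1L) * markerN + seq_len(markerN) - 1L) %% nGenes + 1L
      typeEffect[idx, t] <- 1.5
    }
    nAff <- round(regionAffectedFraction * nGenes)
    affected <- sample.int(nGenes, nAff)
    regionShift <- numeric(nGenes)              # + = up in fovea
    if (nAff > 0) {
      half <- seq_len(ceiling(nAff / 2))
      regionShift[affected[half]] <- regionEffectSize
      regionShift[affected[-half]] <- -regionEffectSize
    }
    donorEffect <- matrix(rnorm(nGenes * nDonors, 0, 0.1), nGenes,
                          dimnames = list(genes, donors))

    lnLambda <- function(donor, region, type) {
      mu <- baseMu + typeEffect[, type] +
        (if (region == "fovea") regionShift / 2 else -regionShift / 2)
      if (!is.null(donor)) mu <- mu + donorEffect[, donor]
      mu
    }
    drawCells <- function(mu, n) {
      lam <- exp(mu)
      sz <- if (noiseModel == "lognormal_poisson")
        exp(rnorm(n, 0, 0.2)) else rep(1, n)
      matrix(rpois(length(lam) * n, outer(lam, sz)), nGenes, n)
    }

    refCounts <- NULL
    refAnno <- NULL
    for (d in donors) for (r in regions) for (t in types) {
      cnt <- drawCells(lnLambda(d, r, t), nRefCellsPerGroup)
      refCounts <- cbind(refCounts, cnt)
      refAnno <- rbind(refAnno, data.frame(
        donor = rep(d, nRefCellsPerGroup), region = r, cell_type = t))
    }
    rownames(refCounts) <- genes
    colnames(refCounts) <- sprintf("ref%04d", seq_len(ncol(refCounts)))

    qRegion <- sample(names(queryRegionMix), nQueryCells, replace = TRUE,
                      prob = queryRegionMix)
    qType <- sample(types, nQueryCells, replace = TRUE)
    qCounts <- matrix(0L, nGenes, nQueryCells,
                      dimnames = list(genes,
                                      sprintf("cell%04d",
                                              seq_len(nQueryCells))))
    for (i in seq_len(nQueryCells))
      qCounts[, i] <- drawCells(lnLambda(NULL, qRegion[i], qType[i]), 1)

    reference <- SummarizedExperiment::SummarizedExperiment(
      assays = list(counts = refCounts),
      colData = S4Vectors::DataFrame(refAnno,
                                     row.names = colnames(refCounts)),
      metadata = list(scale = "counts"))
    query <- SummarizedExperiment::SummarizedExperiment(
      assays = list(counts = qCounts),
      colData = S4Vectors::DataFrame(cell_type = qType,
                                     true_region = qRegion,
                                     row.names = colnames(qCounts)),
      metadata = list(scale = "counts"))
    list(reference = reference, query = query)
  })
}
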