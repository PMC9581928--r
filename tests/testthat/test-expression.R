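makeSE <- function(m, scale = "log10p1", ...) {
  cd <- list(...)
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = m),
    colData = if (length(cd)) S4Vectors::DataFrame(cd, row.names = colnames(m))
              else S4Vectors::DataFrame(row.names = colnames(m)),
    metadata = list(scale = scale))
}

test_that("buildReferenceVectors averages per group on the stored scale", {
  genes <- paste0("g", 1:5)
  m <- matrix(rpois(5 * 18, 8), 5, 18,
              dimnames = list(genes, paste0("c", 1:18)))
  anno <- expand.grid(donor = paste0("d", 1:3),
                      region = c("fovea", "periphery"),
                      cell_type = c("cone", "rod", "MG"),
                      stringsAsFactors = FALSE)
  se <- makeSE(m, scale = "counts", donor = anno$donor,
               region = anno$region, cell_type = anno$cell_type)
  refs <- buildReferenceVectors(se)
  expect_equal(ncol(refs@profiles), 18)
  expect_equal(refs@scale, "log10p1")
  # one cell per group: the mean is that cell (transformed)
  for (i in 1:18) {
    g <- refs@groups[i, ]
    sel <- anno$donor == g$donor & anno$region == g$region &
      anno$cell_type == g$cell_type
    expect_equal(unname(refs@profiles[, i]), unname(log10(m[, sel] + 1)))
  }
})

test_that("duplicating cells leaves group means unchanged; brute-force check", {
  set.seed(51)
  genes <- paste0("g", 1:20)
  n <- 12
  m <- matrix(runif(20 * n, 0, 3), 20, n,
              dimnames = list(genes, paste0("c", 1:n)))
  anno <- data.frame(donor = rep(c("d1", "d2"), each = 6),
                     region = rep(c("fovea", "periphery"), times = 6),
                     cell_type = rep(c("cone", "rod", "MG"), times = 4))
  se <- makeSE(m, scale = "log10p1", donor = anno$donor,
               region = anno$region, cell_type = anno$cell_type)
  refs <- suppressWarnings(buildReferenceVectors(se))
  # brute force per-gene averaging
  for (i in seq_len(ncol(refs@profiles))) {
    g <- refs@groups[i, ]
    sel <- which(anno$donor == g$donor & anno$region == g$region &
                   anno$cell_type == g$cell_type)
    want <- apply(m[, sel, drop = FALSE], 1, function(v) sum(v) / length(v))
    expect_equal(unname(refs@profiles[, i]), unname(want))
  }
  # duplicate every cell: means unchanged
  se2 <- makeSE(cbind(m, m), scale = "log10p1",
                donor = rep(anno$donor, 2), region = rep(anno$region, 2),
                cell_type = rep(anno$cell_type, 2))
  refs2 <- suppressWarnings(buildReferenceVectors(se2))
  expect_equal(refs2@profiles, refs@profiles)
})

test_that("correlateCells reproduces exact and formula correlations", {
  set.seed(52)
  genes <- paste0("g", 1:50)
  prof <- matrix(runif(50 * 2, 0, 2), 50, 2,
                 dimnames = list(genes, c("a", "b")))
  refs <- new("ReferenceProfiles", profiles = prof,
              groups = data.frame(donor = "d1",
                                  region = c("fovea", "periphery"),
                                  cell_type = "cone"),
              scale = "log10p1")
  # query equal to a reference vector: r = 1; its negation around the
  # mean: r = -1
  q <- cbind(prof[, 1], 2 * mean(prof[, 1]) - prof[, 1])
  colnames(q) <- c("same", "anti")
  rownames(q) <- genes
  tab <- correlateCells(makeSE(q, scale = "log10p1", cell_type = c("cone", "cone")), refs)
  expect_equal(tab$r[tab$cell == "same" & tab$region == "fovea"], 1)
  expect_equal(tab$r[tab$cell == "anti" & tab$region == "fovea"], -1)

  # random cells against both vectors: textbook formula oracle
  qr <- matrix(runif(50 * 4), 50, 4,
               dimnames = list(genes, paste0("q", 1:4)))
  tab2 <- correlateCells(makeSE(qr, scale = "log10p1"), refs)
  for (i in 1:4) for (j in 1:2) {
    got <- tab2$r[tab2$cell == paste0("q", i) &
                    tab2$region == refs@groups$region[j]]
    expect_equal(got, oracleCor(qr[, i], prof[, j]))
  }
})

test_that("correlateCells is invariant to gene order and extra genes", {
  set.seed(53)
  genes <- paste0("g", 1:30)
  prof <- matrix(runif(60), 30, 2, dimnames = list(genes, c("a", "b")))
  refs <- new("ReferenceProfiles", profiles = prof,
              groups = data.frame(donor = "d1",
                                  region = c("fovea", "periphery"),
                                  cell_type = "rod"),
              scale = "log10p1")
  q <- matrix(runif(30 * 2), 30, 2, dimnames = list(genes, c("c1", "c2")))
  base <- correlateCells(makeSE(q, "log10p1"), refs)
  # permute gene order
  perm <- sample(30)
  qPerm <- q[perm, , drop = FALSE]
  permTab <- correlateCells(makeSE(qPerm, "log10p1"), refs)
  expect_equal(permTab$r, base$r)
  # append genes absent from the reference
  extra <- rbind(q, matrix(runif(10), 5, 2,
                           dimnames = list(paste0("x", 1:5), NULL)))
  extraTab <- correlateCells(makeSE(extra, "log10p1"), refs)
  expect_equal(extraTab$r, base$r)
})

test_that("degenerate correlation inputs are reported, not invented", {
  genes <- paste0("g", 1:10)
  prof <- matrix(c(runif(10), rep(2, 10)), 10, 2,
                 dimnames = list(genes, c("a", "flat")))
  refs <- new("ReferenceProfiles", profiles = prof,
              groups = data.frame(donor = "d1",
                                  region = c("fovea", "periphery"),
                                  cell_type = "MG"),
              scale = "log10p1")
  q <- matrix(runif(10), 10, 1, dimnames = list(genes, "c1"))
  tab <- correlateCells(makeSE(q, "log10p1"), refs)
  expect_true(is.na(tab$r[tab$region == "periphery"]))
  expect_equal(tab$missing_reason[tab$region == "periphery"],
               "zero-variance reference vector")
  # too-small intersection
  qBad <- matrix(runif(2), 1, 2, dimnames = list("g1", c("c1", "c2")))
  expect_error(correlateCells(makeSE(qBad, "log10p1"), refs),
               "fewer than 2")
})

test_that("correlationDelta subtracts periphery from fovea per donor", {
  tab <- data.frame(
    cell = rep(c("c1", "c2"), each = 4),
    cell_type = "cone",
    donor = rep(c("d1", "d1", "d2", "d2"), 2),
    region = rep(c("fovea", "periphery"), 4),
    ref_cell_type = "cone",
    r = c(0.6, 0.3, 0.5, 0.5, 0.2, 0.8, NA, 0.1))
  d <- correlationDelta(tab)
  expect_equal(d$delta[d$cell == "c1" & d$donor == "d1"], 0.3)
  expect_equal(d$delta[d$cell == "c1" & d$donor == "d2"], 0)
  expect_equal(d$delta[d$cell == "c2" & d$donor == "d1"], -0.6)
  expect_true(is.na(d$delta[d$cell == "c2" & d$donor == "d2"]))
})

test_that("foveal-identity synthetic cells show positive median deltas", {
  es <- generateExpressionSets(nGenes = 300, nRefCellsPerGroup = 15,
                               nQueryCells = 60,
                               queryRegionMix = c(fovea = 1, periphery = 0),
                               seed = 54)
  refs <- buildReferenceVectors(es$reference)
  dl <- correlationDelta(correlateCells(es$query, refs))
  med <- deltaSummary(dl)
  expect_true(all(med$median_delta > 0))
})

test_that("goiEigengene summarizes a gene set as its first PC", {
  # all GOI genes share one profile: scores recover it, 100% variance
  prof <- c(1, 4, 2, 6, 3, 5)
  m <- rbind(outer(c(1, 2, 3), prof), matrix(runif(18), 3, 6))
  rownames(m) <- paste0("g", 1:6)
  colnames(m) <- paste0("s", 1:6)
  eg <- goiEigengene(m, c("g1", "g2", "g3"))
  expect_equal(eg$varianceExplained, 100)
  expect_gt(cor(eg$scores, prof), 0.999)

  # gene order permutation leaves scores unchanged
  eg2 <- goiEigengene(m, c("g3", "g1", "g2"))
  expect_equal(eg2$scores, eg$scores)

  # unmapped identifiers are listed; too few is an error
  expect_error(goiEigengene(m, c("g1", "zz1", "zz2")), "zz1")

  # random matrix against the longhand eigen-decomposition oracle
  set.seed(55)
  r <- matrix(rnorm(60), 10, 6,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
  egR <- goiEigengene(r, paste0("g", 1:10))
  want <- oracleEigengene(r)
  expect_equal(abs(egR$scores), abs(want$scores), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(egR$varianceExplained, want$varExplained, tolerance = 1e-8)
})

test_that("eigengene sign follows mean GOI expression", {
  set.seed(56)
  m <- matrix(rnorm(40), 8, 5,
              dimnames = list(paste0("g", 1:8), paste0("s", 1:5)))
  eg <- goiEigengene(m, paste0("g", 1:8))
  expect_gte(sum(eg$scores * (colMeans(m[eg$genesUsed, ]) -
                                mean(colMeans(m[eg$genesUsed, ])))), 0)
})

test_that("zscore uses the sample standard deviation", {
  expect_equal(zscore(c(1, 2, 3)), c(-1, 0, 1))
  expect_warning(z0 <- zscore(rep(4, 5)), "zero spread")
  expect_equal(z0, rep(0, 5))
  expect_error(zscore(3), "at least 2")

  set.seed(57)
  v <- rnorm(40, 10, 3)
  z <- zscore(v)
  expect_equal(mean(z), 0)
  expect_equal(sd(z), 1)
  expect_equal(z, (v - mean(v)) / sd(v))

  m <- rbind(a = c(1, 2, 3), b = c(5, 5, 5))
  rz <- rowZscores(m)
  expect_equal(unname(rz["a", ]), c(-1, 0, 1))
  expect_equal(unname(rz["b", ]), c(0, 0, 0))
})
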