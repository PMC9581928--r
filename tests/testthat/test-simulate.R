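# Small configurations keep the generator tests fast while exercising the
# same code paths as the full-size defaults.
smallSection <- function(totalCells = 150, ...) {
  sectionConfig(roiWidthUm = 60, roiHeightUm = 80,
                totalCells = totalCells, ...)
}

test_that("identical config and seed give bit-identical outputs", {
  a <- generateCrossSection(smallSection(seed = 3))
  b <- generateCrossSection(smallSection(seed = 3))
  expect_identical(a$image@channels, b$image@channels)
  expect_identical(truthCells(a$truth), truthCells(b$truth))

  m1 <- generateEnfaceMosaic(mosaicConfig(seed = 4))
  m2 <- generateEnfaceMosaic(mosaicConfig(seed = 4))
  expect_identical(m1$image@channels, m2$image@channels)

  w1 <- generateWholemount(c(a = 0.3), fieldSizeUm = 40, seed = 5)
  w2 <- generateWholemount(c(a = 0.3), fieldSizeUm = 40, seed = 5)
  expect_identical(w1$image@channels, w2$image@channels)

  e1 <- generateExpressionSets(nGenes = 60, nRefCellsPerGroup = 3,
                               nQueryCells = 5, seed = 6)
  e2 <- generateExpressionSets(nGenes = 60, nRefCellsPerGroup = 3,
                               nQueryCells = 5, seed = 6)
  expect_identical(SummarizedExperiment::assay(e1$reference),
                   SummarizedExperiment::assay(e2$reference))
})

test_that("section config invariants are enforced", {
  expect_error(generateCrossSection(
    sectionConfig(cellFractions = c(cone = 0.5, rod = 0.4, mg = 0.2,
                                    other = 0.1))), "sum to 1")
  expect_error(sectionConfig(totalCells = 100, roiWidthUm = 10,
                             roiHeightUm = 10) |> generateCrossSection(),
               "retries")
})

test_that("zero extrusion gives zero ectopic truth; bands place cells", {
  sec <- generateCrossSection(smallSection(seed = 8))
  tr <- truthCells(sec$truth)
  expect_false(any(tr$extruded))
  # every nucleus basal to the true boundary
  bnd <- sec$truth@boundary
  expect_true(all(tr$y_px > bnd$y_px[round(tr$x_px)]))

  # degenerate band: all cones collapse onto the band centre
  deg <- generateCrossSection(smallSection(
    seed = 9, totalCells = 50,
    lamination = list(cone = c(0.05, 0), rod = c(0.4, 0.1),
                      mg = c(0.6, 0.1), other = c(0.8, 0.1))))
  dtr <- truthCells(deg$truth)
  expect_true(all(dtr$depth_fraction[dtr$class == "cone"] == 0.05))
})

test_that("class counts fall in the multinomial 99% interval", {
  cfg <- sectionConfig(totalCells = 400, seed = 10)
  tr <- truthCells(generateCrossSection(cfg)$truth)
  cnt <- table(factor(tr$class, c("cone", "rod", "mg", "other")))
  p <- c(0.28, 0.25, 0.25, 0.22)
  for (i in 1:4) {
    expect_gte(cnt[i], qbinom(0.005, 400, p[i]))
    expect_lte(cnt[i], qbinom(0.995, 400, p[i]))
  }
})

test_that("truth nuclei are local maxima of the noiseless nuclei channel", {
  sec <- generateCrossSection(smallSection(seed = 11, noiseSd = 0))
  dapi <- maxProject(sec$image, "dapi")
  tr <- truthCells(sec$truth)
  for (k in seq_len(nrow(tr))) {
    r <- round(tr$y_px[k]); c <- round(tr$x_px[k])
    nb <- dapi[max(1, r - 1):min(nrow(dapi), r + 1),
               max(1, c - 1):min(ncol(dapi), c + 1)]
    expect_gte(dapi[r, c], max(nb) - 1e-9)
  }
})

test_that("inner segments are rendered apical and DAPI-negative", {
  sec <- generateCrossSection(smallSection(seed = 12, pisCount = 8,
                                           noiseSd = 0))
  pc <- truthConfig(sec$truth)$pis_centers
  expect_equal(nrow(pc), 8)
  dapi <- maxProject(sec$image, "dapi")
  rcv <- maxProject(sec$image, "rcvrn")
  bnd <- sec$truth@boundary
  for (k in seq_len(nrow(pc))) {
    r <- round(pc$y_px[k]); c <- round(pc$x_px[k])
    expect_lt(r, bnd$y_px[c])          # strictly apical
    expect_gt(rcv[r, c], 0.5)          # marker positive
    expect_equal(dapi[r, c], 0)        # nuclei channel masked out
  }
})

test_that("jitter-free mosaics form an exact hexagonal lattice", {
  mo <- generateEnfaceMosaic(mosaicConfig(fieldSizeUm = 40,
                                          meanSpacingUm = 5,
                                          jitterSdUm = 0, seed = 13))
  tr <- truthCells(mo$truth)
  spacingPx <- 5 / 0.25
  d <- as.matrix(dist(tr[, c("x_px", "y_px")]))
  diag(d) <- Inf
  nn <- apply(d, 1, min)
  expect_true(all(abs(nn - spacingPx) <= 0.5))
})

test_that("density-specified mosaics hit the expected count", {
  mo <- generateEnfaceMosaic(mosaicConfig(fieldSizeUm = 100,
                                          densityPerMm2 = 27000,
                                          jitterSdUm = 0.5, seed = 14))
  n <- nrow(truthCells(mo$truth))
  expect_gte(n, qpois(0.005, 270))
  expect_lte(n, qpois(0.995, 270))
})

test_that("mosaic class fraction and spacing guards work", {
  mo <- generateEnfaceMosaic(mosaicConfig(class1Fraction = 1, seed = 15))
  expect_true(all(truthCells(mo$truth)$class == "type1"))
  expect_error(generateEnfaceMosaic(mosaicConfig(meanSpacingUm = 2)),
               "spacing")
  expect_error(mosaicConfig(meanSpacingUm = 5, densityPerMm2 = 1000),
               "exactly one")
})

test_that("wholemount coverage is achieved within 0.01 for every channel", {
  for (seed in 1:3) {
    wm <- generateWholemount(c(pis = 0.73, mg = 0.39, x = 0.5),
                             fieldSizeUm = 50, seed = seed)
    cov <- truthCoverages(wm$truth)
    expect_lt(abs(cov[["pis"]] - 0.73), 0.01)
    expect_lt(abs(cov[["mg"]] - 0.39), 0.01)
    expect_lt(abs(cov[["x"]] - 0.5), 0.01)
  }
  z <- generateWholemount(c(a = 0), fieldSizeUm = 30, seed = 1)
  expect_equal(unname(truthCoverages(z$truth)["a"]), 0)
  expect_lt(max(getChannel(z$image, "a")), 0.2)
  expect_error(generateWholemount(c(a = 1.2)), "\\[0, 1\\]")
})

test_that("cohorts have the right shape and conserve the simplex", {
  base <- smallSection()
  coh <- generateCohort(5, 6, base, betweenSd = 0.02, withinSd = 0.01,
                        seed = 16)
  expect_length(coh$rois, 30)
  lat <- coh$latents
  orgCols <- grep("^organoid_(cone|rod|mg|other)", names(lat))
  roiCols <- grep("^roi_(cone|rod|mg|other)", names(lat))
  expect_true(all(abs(rowSums(lat[, orgCols]) - 1) < 1e-9))
  expect_true(all(abs(rowSums(lat[, roiCols]) - 1) < 1e-9))

  # zero dispersion: every ROI inherits the base fractions exactly
  coh0 <- generateCohort(2, 2, base, 0, 0, seed = 17)
  expect_true(all(abs(as.matrix(coh0$latents[, roiCols]) -
    matrix(base@cellFractions, 4, 4, byrow = TRUE)) < 1e-12))
})

test_that("expression sets carry 18 reference groups and query truth", {
  es <- generateExpressionSets(nGenes = 80, nRefCellsPerGroup = 2,
                               nQueryCells = 10, seed = 18)
  cd <- SummarizedExperiment::colData(es$reference)
  expect_equal(nrow(unique(as.data.frame(cd))), 18)
  expect_equal(ncol(es$reference), 36)
  qd <- SummarizedExperiment::colData(es$query)
  expect_true(all(qd$true_region %in% c("fovea", "periphery")))
  expect_error(generateExpressionSets(regionEffectSize = -1),
               "non-negative")
})
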