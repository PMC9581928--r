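test_that("a flat slab yields a flat boundary with chord arc length", {
  st <- slabStack(top = 50)
  b <- estimateApicalBoundary(st, c("glia", "dapi"))
  expect_true(all(abs(b@y - 50) <= 1))
  expect_equal(arcLengthUm(b), (ncol(getChannel(st, "glia")) - 1) * 0.5,
               tolerance = 0.02)
})

test_that("a sinusoidal border gives arc length above the chord", {
  nr <- 100; nc <- 200
  top <- round(40 + 6 * sin(2 * pi * seq_len(nc) / 80))
  glia <- matrix(0, nr, nc)
  for (j in seq_len(nc)) glia[top[j]:nr, j] <- 0.8
  st <- ImageStack(list(dapi = glia * 0.5, glia = glia), pixelSize = 0.5)
  b <- estimateApicalBoundary(st, "glia")
  chord <- (nc - 1) * 0.5
  expect_gt(arcLengthUm(b), chord)
  # numerical polyline length of the true curve
  truthLen <- sum(sqrt(1 + diff(40 + 6 * sin(2 * pi * seq_len(nc) / 80))^2)) * 0.5
  expect_equal(arcLengthUm(b), truthLen, tolerance = 0.05)
})

test_that("a small detached apical blob does not move the boundary", {
  blob <- matrix(0, 100, 120)
  blob[20:22, 60:62] <- 0.9              # ~2 um^2 at 0.5 um/px
  plain <- estimateApicalBoundary(slabStack(top = 50), "glia")
  withBlob <- estimateApicalBoundary(slabStack(top = 50, extra = blob),
                                     "glia")
  expect_equal(withBlob@y, plain@y)
  expect_error(
    estimateApicalBoundary(
      ImageStack(list(glia = matrix(0, 10, 10)), pixelSize = 0.5), "glia"),
    "empty")
})

test_that("countEctopic applies the strictly-apical rule", {
  b <- flatBoundary(width = 200, y = 50, pixelSize = 0.5)
  pts <- data.frame(x_px = c(30, 60, 90, 120), y_px = c(40, 45, 50, 70),
                    marker_flag = TRUE)
  res <- countEctopic(pts, b)
  expect_equal(res$count, 2)              # y = 50 is NOT ectopic
  expect_equal(res$ectopic, c(TRUE, TRUE, FALSE, FALSE))

  # arc length 200 um with 3 ectopic -> 1.5 per 100 um
  b2 <- flatBoundary(width = 401, y = 50, pixelSize = 0.5)
  pts3 <- data.frame(x_px = c(10, 20, 30), y_px = c(10, 10, 10),
                     marker_flag = TRUE)
  expect_equal(countEctopic(pts3, b2)$per100um, 1.5)

  # marker-negative points are ignored
  ptsNeg <- data.frame(x_px = 30, y_px = 10, marker_flag = FALSE)
  expect_equal(countEctopic(ptsNeg, b)$count, 0)
})

test_that("generator extrusion is recovered within the binomial interval", {
  cfg <- sectionConfig(roiWidthUm = 80, roiHeightUm = 100, totalCells = 300,
                       extrusionFraction = c(cone = 0.2, rod = 0.2,
                                             mg = 0, other = 0),
                       seed = 21)
  sec <- generateCrossSection(cfg)
  tr <- truthCells(sec$truth)
  nPR <- sum(tr$class %in% c("cone", "rod"))
  nExt <- sum(tr$extruded)
  expect_gte(nExt, qbinom(0.005, nPR, 0.2))
  expect_lte(nExt, qbinom(0.995, nPR, 0.2))

  # pipeline recovery judged against the same binomial interval
  m <- measureSection(sec$image)
  expect_gte(m$metrics[["ectopic_count"]], qbinom(0.005, nPR, 0.2))
  expect_lte(m$metrics[["ectopic_count"]], qbinom(0.995, nPR, 0.2))
})

test_that("countPIS counts DAPI-negative apical components", {
  nr <- 100; nc <- 120
  marker <- matrix(FALSE, nr, nc)
  nuclei <- matrix(FALSE, nr, nc)
  b <- flatBoundary(nc, 60, pixelSize = 1)
  # 5 disjoint apical blobs
  for (cx in c(10, 30, 50, 70, 90)) marker[20:23, cx:(cx + 3)] <- TRUE
  res <- countPIS(marker, nuclei, b, pixelSizeUm = 1)
  expect_equal(res$count, 5)
  expect_equal(res$per100um, 5 * 100 / arcLengthUm(b))

  # a blob fully overlapping a nucleus is excluded
  nuclei[20:23, 10:13] <- TRUE
  expect_equal(countPIS(marker, nuclei, b, 1)$count, 4)

  # blobs basal to the boundary never count
  basal <- matrix(FALSE, nr, nc); basal[80:83, 10:13] <- TRUE
  expect_equal(countPIS(basal, nuclei, b, 1)$count, 0)
})

test_that("countPIS matches a flood-fill oracle on random blob fields", {
  set.seed(22)
  for (i in 1:20) {
    nr <- 40; nc <- 50
    marker <- matrix(runif(nr * nc) > 0.8, nr, nc)
    nuclei <- matrix(runif(nr * nc) > 0.7, nr, nc)
    bY <- 25
    b <- flatBoundary(nc, bY, pixelSize = 1)
    got <- countPIS(marker, nuclei, b, pixelSizeUm = 1, minSizeUm2 = 2,
                    maxNuclearOverlap = 0.1)
    apical <- marker
    apical[bY:nr, ] <- FALSE             # rows >= boundary are not apical
    lab <- oracleLabel4(apical)
    want <- 0
    for (k in seq_len(max(lab))) {
      px <- which(lab == k)
      if (length(px) < 2) next           # area >= 2 um^2 at 1 um/px
      if (mean(nuclei[px]) > 0.1) next
      want <- want + 1
    }
    expect_equal(got$count, want)
  }
})

test_that("generated inner segments are recovered by the pipeline", {
  for (s in 1:3) {
    sec <- generateCrossSection(sectionConfig(pisCount = 15,
                                              seed = 130 + s))
    m <- measureSection(sec$image)
    expect_lte(abs(m$metrics[["pis_count"]] - 15), 3)
  }
})

test_that("cellsPer100um normalizes counts by arc length", {
  b <- flatBoundary(201, 30, pixelSize = 1)   # arc length 200 um
  pts <- data.frame(x_px = runif(40, 1, 200), y_px = runif(40, 31, 90),
                    class = "cone")
  expect_equal(cellsPer100um(pts, b, "cone"), 20)
  b1 <- flatBoundary(201, 30, pixelSize = 0.5) # arc length 100 um
  expect_equal(cellsPer100um(pts, b1, "cone"), 40)
  expect_equal(cellsPer100um(pts[0, ], b, "cone"), 0)
})

test_that("enfaceAreaFractions recovers constructed and generated coverage", {
  half <- matrix(0, 160, 160); half[, 1:80] <- 1
  st <- ImageStack(list(pis = half), pixelSize = 0.5)
  expect_equal(enfaceAreaFractions(st, "pis")[["pis"]], 0.5)

  wm <- generateWholemount(c(pis = 0.73), fieldSizeUm = 80, seed = 23)
  got <- enfaceAreaFractions(wm$image, "pis")
  expect_lt(abs(got[["pis"]] - 0.73), 0.04)

  zero <- ImageStack(list(pis = matrix(0, 160, 160)), pixelSize = 0.5)
  expect_equal(suppressWarnings(enfaceAreaFractions(zero, "pis"))[["pis"]],
               0)
  small <- ImageStack(list(pis = half), pixelSize = 0.25)  # 40 um side
  expect_error(enfaceAreaFractions(small, "pis"), "minimum side")
})
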