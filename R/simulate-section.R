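# Ground-truth generator for cross-section ROIs: layered nuclei of several
# cell classes basal to an undulating apical border, optional extruded
# (ectopic) nuclei apical to it, and DAPI-negative inner-segment blobs.

#' Build a cross-section generator configuration
#'
#' Defaults emulate a 100-um-wide ROI over the full epithelial depth of a
#' mature organoid section: 500 nuclei at a 28/25/25/22% cone/rod/
#' Mueller-glia/other composition, photoreceptor nuclei banded apically,
#' glia mid-depth, no extrusion and no inner segments.
#'
#' @param roiWidthUm,roiHeightUm ROI extent (um).
#' @param pixelSizeUm um per pixel.
#' @param cellFractions named fractions (must sum to 1).
#' @param totalCells nuclei to place.
#' @param lamination named list per class: `"uniform"` or `c(center, sd)`
#'   depth-fraction band.
#' @param extrusionFraction named per-class ectopy probability.
#' @param pisCount inner-segment blobs to render.
#' @param boundaryAmplitudeUm,boundaryWavelengthUm,boundaryOffsetUm apical
#'   border undulation and mean depth.
#' @param nucleusRadiusUm rendered nucleus radius.
#' @param minSpacingUm hard-core minimum nucleus centre distance.
#' @param noiseSd additive Gaussian channel noise.
#' @param seed integer seed.
#' @return a [SectionConfig].
#' @export
sectionConfig <- function(
    roiWidthUm = 100, roiHeightUm = 120, pixelSizeUm = 0.5,
    cellFractions = c(cone = 0.28, rod = 0.25, mg = 0.25, other = 0.22),
    totalCells = 500,
    lamination = list(cone = c(0.12, 0.12), rod = c(0.30, 0.14),
                      mg = c(0.55, 0.15), other = c(0.78, 0.12)),
    extrusionFraction = c(cone = 0, rod = 0, mg = 0, other = 0),
    pisCount = 0,
    boundaryAmplitudeUm = 2, boundaryWavelengthUm = 50,
    boundaryOffsetUm = 12,
    nucleusRadiusUm = 1.5, minSpacingUm = 2.2, noiseSd = 0.02, seed = 1) {
  classes <- names(cellFractions)
  lam <- lamination[classes]
  names(lam) <- classes
  lam[vapply(lam, is.null, logical(1))] <- list("uniform")
  ext <- setNames(rep(0, length(classes)), classes)
  ext[names(extrusionFraction)] <- extrusionFraction
  new("SectionConfig",
      roiWidthUm = roiWidthUm, roiHeightUm = roiHeightUm,
      pixelSizeUm = pixelSizeUm, cellFractions = cellFractions,
      totalCells = totalCells, lamination = lam,
      extrusionFraction = ext, pisCount = pisCount,
      boundaryAmplitudeUm = boundaryAmplitudeUm,
      boundaryWavelengthUm = boundaryWavelengthUm,
      boundaryOffsetUm = boundaryOffsetUm,
      nucleusRadiusUm = nucleusRadiusUm, minSpacingUm = minSpacingUm,
      noiseSd = noiseSd, seed = seed)
}

.configAsList <- function(cfg) {
  sl <- methods::slotNames(class(cfg))
  out <- lapply(sl, function(s) methods::slot(cfg, s))
  names(out) <- sl
  out
}

#' Generate a synthetic cross-section ROI with ground truth
#'
#' Renders a multi-channel image of a retinal cross-section: a `dapi`
#' nuclei channel (sum of isotropic Gaussians, sigma = nucleus radius / 2),
#' one near-binary marker channel per cell class (`cone`, `rod`, `mg`), a
#' combined photoreceptor channel `rcvrn` (cone + rod disks plus
#' DAPI-negative inner-segment half-disks apical to the border), and a
#' `glia` channel filling the tissue below the apical boundary.  The ROI's
#' x axis runs along the apical surface; the y axis points apical (row 1)
#' to basal.  Non-extruded nuclei lie basal to the boundary; extruded
#' nuclei lie 1-6 um apical to it; inner segments are masked out of the
#' nuclei channel so their DAPI overlap is exactly zero.
#'
#' @param cfg a [SectionConfig].
#' @return list with elements `image` ([ImageStack]) and `truth`
#'   ([GroundTruth]; cells carry `x_px`, `y_px`, `class`, `extruded`,
#'   `depth_fraction`).
#' @export
generateCrossSection <- function(cfg) {
  stopifnot(is(cfg, "SectionConfig"))
  methods::validObject(cfg)
  .withSeed(cfg@seed, .renderCrossSection(cfg))
}

.renderCrossSection <- function(cfg) {
  ps <- cfg@pixelSizeUm
  W <- round(cfg@roiWidthUm / ps)
  H <- round(cfg@roiHeightUm / ps)
  classes <- names(cfg@cellFractions)
  rPx <- cfg@nucleusRadiusUm / ps
  eps <- max(1.5, rPx)             # basal clearance below the border (px)

  phase <- runif(1, 0, 2 * pi)
  bRow <- function(xPx) {
    pmax(2, cfg@boundaryOffsetUm / ps +
           (cfg@boundaryAmplitudeUm / ps) *
             sin(2 * pi * (xPx * ps) / cfg@boundaryWavelengthUm + phase))
  }

  n <- cfg@totalCells
  cls <- if (n > 0)
    sample(classes, n, replace = TRUE, prob = cfg@cellFractions)
  else character(0)
  extr <- unname(vapply(cls, function(k) runif(1) < cfg@extrusionFraction[[k]],
                        logical(1)))
  depth <- numeric(n)
  for (k in classes) {
    ix <- which(cls == k & !extr)
    if (!length(ix)) next
    lam <- cfg@lamination[[k]]
    depth[ix] <- if (identical(lam, "uniform")) runif(length(ix)) else
      .truncNorm01(length(ix), lam[1], lam[2])
  }

  margin <- rPx + 1
  # centres are snapped to the pixel grid so every truth nucleus is an
  # exact local maximum of the rendered (noiseless) nuclei channel
  cand <- function(k) {
    x <- runif(1, 1 + margin, W - margin)
    b <- bRow(x)
    if (extr[k]) {
      lo <- max(1 + margin, b - 8 / ps)
      hi <- max(lo, b - 2.5 / ps)
      y <- runif(1, lo, hi)
    } else {
      top <- b + eps
      y <- top + depth[k] * (H - margin - top)
    }
    round(c(x, y))
  }
  minD2 <- (cfg@minSpacingUm / ps)^2
  # when random retries jam near the packing limit, fall back to the free
  # grid site nearest the cell's intended depth (deterministic)
  fallbackSite <- function(k, px, py) {
    xs <- seq.int(ceiling(1 + margin), floor(W - margin))
    bs <- bRow(xs)
    if (extr[k]) {
      ylo <- ceiling(pmax(1 + margin, bs - 8 / ps))
      yhi <- floor(pmax(ylo, bs - 2.5 / ps))
    } else {
      ylo <- ceiling(bs + eps)
      yhi <- rep(floor(H - margin), length(xs))
    }
    nY <- pmax(yhi - ylo + 1L, 0L)
    sx <- rep(xs, times = nY)
    sy <- unlist(lapply(seq_along(xs), function(i)
      if (nY[i] > 0L) seq.int(ylo[i], yhi[i]) else integer(0)))
    if (!length(sx)) return(NULL)
    dmin <- rep(Inf, length(sx))
    for (j in seq_along(px))
      dmin <- pmin(dmin, (sx - px[j])^2 + (sy - py[j])^2)
    ok <- dmin >= minD2
    if (!any(ok)) return(NULL)
    sx <- sx[ok]; sy <- sy[ok]
    bOk <- bRow(sx)
    target <- if (extr[k]) bOk - 5.25 / ps else
      (bOk + eps) + depth[k] * (H - margin - bOk - eps)
    i <- order(abs(sy - target), sy, sx)[1]
    c(sx[i], sy[i])
  }
  pos <- matrix(NA_real_, n, 2, dimnames = list(NULL, c("x", "y")))
  px <- numeric(0); py <- numeric(0)
  for (k in seq_len(n)) {
    p <- NULL
    for (try in seq_len(3000)) {
      q <- cand(k)
      if (length(px) == 0L ||
          min((px - q[1])^2 + (py - q[2])^2) >= minD2) {
        p <- q
        break
      }
    }
    if (is.null(p)) p <- fallbackSite(k, px, py)
    if (is.null(p))
      stop(sprintf(
        "could not place nucleus %d of %d: no free site left after 3000 retries; ROI too small for the requested count at min spacing %.2f px",
        k, n, sqrt(minD2)))
    pos[k, ] <- p
    px <- c(px, p[1]); py <- c(py, p[2])
  }

  dapi <- matrix(0, H, W)
  marker <- lapply(classes, function(k) matrix(0, H, W))
  names(marker) <- classes
  sigma <- rPx / 2
  mrPx <- 1.25 * rPx
  for (k in seq_len(n)) {
    dapi <- .addGaussian(dapi, pos[k, 1], pos[k, 2], sigma, 1)
    marker[[cls[k]]] <- .addDisk(marker[[cls[k]]], pos[k, 1], pos[k, 2],
                                 mrPx, 1)
  }

  # Inner segments: marker-positive half-disks 1-3 um apical of the border,
  # away from extruded nuclei, zero DAPI by construction.
  pisR <- 1.5 / ps
  pis <- matrix(0, H, W)
  pisXY <- NULL
  if (cfg@pisCount > 0) {
    ex <- pos[extr, , drop = FALSE]
    candPis <- function(k) {
      x <- round(runif(1, 1 + pisR, W - pisR))
      b <- bRow(x)
      y <- round(max(1 + pisR, b - runif(1, 1, 3) / ps - pisR))
      if (nrow(ex) &&
          min((ex[, 1] - x)^2 + (ex[, 2] - y)^2) < (2.5 / ps)^2)
        return(NULL)  # too close to an extruded nucleus: retry
      c(x, y)
    }
    pisXY <- .placeHardCore(cfg@pisCount, candPis, 3.5 / ps,
                            what = "inner segment")
    for (k in seq_len(nrow(pisXY)))
      pis <- .addDisk(pis, pisXY[k, 1], pisXY[k, 2], pisR, 1,
                      half = "apical")
    dapi[pis > 0] <- 0
  }

  xcols <- seq_len(W)
  glia <- outer(seq_len(H), bRow(xcols), `>=`) * 0.8
  rcvrn <- pmax(marker[["cone"]], marker[["rod"]], pis)

  noisy <- function(m) .clamp0(m + matrix(rnorm(length(m), 0, cfg@noiseSd),
                                          nrow(m)))
  channels <- c(list(dapi = noisy(dapi)),
                lapply(marker[setdiff(classes, "other")], noisy),
                list(rcvrn = noisy(rcvrn), glia = noisy(glia)))

  cells <- data.frame(
    x_px = pos[, 1], y_px = pos[, 2], class = cls,
    extruded = extr, depth_fraction = ifelse(extr, NA_real_, depth))
  truth <- new("GroundTruth",
    cells = cells,
    boundary = data.frame(x_px = xcols, y_px = bRow(xcols)),
    coverages = numeric(0),
    config = .configAsList(cfg))
  if (!is.null(pisXY))
    truth@config$pis_centers <- data.frame(x_px = pisXY[, 1],
                                           y_px = pisXY[, 2])
  list(image = ImageStack(channels, pixelSize = ps), truth = truth)
}

#' Map a target latent per-class COV to a between-organoid sd
#'
#' The cohort generator perturbs each class fraction additively and
#' renormalizes onto the simplex; to first order the renormalized fraction
#' of class *j* has sd `sd * sqrt((1 - f_j)^2 + f_j^2 (K - 1))`.  This
#' helper inverts that relation so a cohort can be generated at a stated
#' latent coefficient of variation for one class.
#'
#' @param fractions named base fractions.
#' @param class class whose latent COV is targeted.
#' @param cov target coefficient of variation (e.g. 0.05 for 5%).
#' @return the `betweenSd` to pass to [generateCohort()].
#' @export
covToBetweenSd <- function(fractions, class, cov) {
  f <- fractions[[class]]
  K <- length(fractions)
  cov * f / sqrt((1 - f)^2 + f^2 * (K - 1))
}

#' Generate a cohort of cross-section ROIs with organoid structure
#'
#' Draws latent per-organoid class fractions around the base configuration
#' (additive Gaussian dispersion `betweenSd` per class, clipped to the
#' simplex and renormalized), then per-ROI realizations with dispersion
#' `withinSd`, and renders each ROI with [generateCrossSection()].
#'
#' @param nOrganoids,roisPerOrganoid cohort dimensions.
#' @param base a [SectionConfig] supplying everything but the fractions.
#' @param betweenSd,withinSd additive sds on the fraction scale (>= 0).
#' @param seed integer master seed; per-ROI seeds are derived from it.
#' @param group group label attached to every ROI (e.g. "CTRL").
#' @return list with `rois` (list of `list(organoid_id, roi_id, group,
#'   image, truth)`) and `latents` (data.frame of the latent organoid- and
#'   ROI-level fractions).
#' @export
generateCohort <- function(nOrganoids, roisPerOrganoid, base,
                           betweenSd = 0, withinSd = 0, seed = 1,
                           group = "CTRL") {
  stopifnot(is(base, "SectionConfig"), betweenSd >= 0, withinSd >= 0)
  classes <- names(base@cellFractions)
  nRoi <- nOrganoids * roisPerOrganoid
  seeds <- .childSeeds(seed, nRoi + 1L)
  latent <- .withSeed(seeds[nRoi + 1L], {
    orgF <- t(vapply(seq_len(nOrganoids), function(o) {
      .renormSimplex(base@cellFractions + rnorm(length(classes), 0, betweenSd))
    }, numeric(length(classes))))
    colnames(orgF) <- classes
    roiF <- matrix(NA_real_, nRoi, length(classes),
                   dimnames = list(NULL, classes))
    i <- 0L
    for (o in seq_len(nOrganoids)) for (r in seq_len(roisPerOrganoid)) {
      i <- i + 1L
      roiF[i, ] <- .renormSimplex(orgF[o, ] +
                                    rnorm(length(classes), 0, withinSd))
    }
    list(orgF = orgF, roiF = roiF)
  })
  rois <- vector("list", nRoi)
  latRows <- list()
  i <- 0L
  for (o in seq_len(nOrganoids)) for (r in seq_len(roisPerOrganoid)) {
    i <- i + 1L
    roiF <- setNames(latent$roiF[i, ], classes)
    cfg <- base
    cfg@cellFractions <- roiF
    cfg@seed <- seeds[i]
    sec <- generateCrossSection(cfg)
    rois[[i]] <- list(organoid_id = o, roi_id = r, group = group,
                      image = sec$image, truth = sec$truth)
    latRows[[i]] <- data.frame(
      organoid_id = o, roi_id = r,
      setNames(as.list(latent$orgF[o, ]), paste0("organoid_", classes)),
      setNames(as.list(roiF), paste0("roi_", classes)),
      check.names = FALSE)
  }
  list(rois = rois, latents = do.call(rbind, latRows))
}

# Clip to the non-negative orthant and renormalize to sum 1.
.renormSimplex <- function(f) {
  f <- pmax(f, 0)
  s <- sum(f)
  if (s <= 0) stop("all fractions clipped to zero")
  f / s
}
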