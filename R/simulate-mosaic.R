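# En-face mosaic generator: two diameter classes of disk-shaped cells on a
# jittered hexagonal lattice, plus binary-texture wholemount fields with
# prescribed per-channel coverage fractions.

#' Build a mosaic generator configuration
#'
#' Exactly one of `meanSpacingUm` or `densityPerMm2` must be given; for a
#' hexagonal lattice the two are related by
#' `density = 2 / (sqrt(3) * spacing^2)`.  Diameter defaults give a larger
#' cone-like type 1 and a smaller rod-like type 2.
#'
#' @param fieldSizeUm side of the square field (um).
#' @param meanSpacingUm hexagonal lattice spacing (um), or `NA`.
#' @param densityPerMm2 target density, or `NA`.
#' @param jitterSdUm Gaussian positional jitter sd (um).
#' @param class1Fraction fraction of type-1 (larger) cells.
#' @param diameterMeans,diameterSds named (`type1`, `type2`) diameter
#'   distributions (um).
#' @param pixelSizeUm um per pixel.
#' @param noiseSd additive Gaussian channel noise.
#' @param seed integer seed.
#' @return a [MosaicConfig].
#' @export
mosaicConfig <- function(fieldSizeUm = 40, meanSpacingUm = NA_real_,
                         densityPerMm2 = NA_real_, jitterSdUm = 0.5,
                         class1Fraction = 0.5,
                         diameterMeans = c(type1 = 3.2, type2 = 2.2),
                         diameterSds = c(type1 = 0.25, type2 = 0.25),
                         pixelSizeUm = 0.25, noiseSd = 0.02, seed = 1) {
  if (is.na(meanSpacingUm) && is.na(densityPerMm2)) meanSpacingUm <- 5
  new("MosaicConfig", fieldSizeUm = fieldSizeUm,
      meanSpacingUm = meanSpacingUm, densityPerMm2 = densityPerMm2,
      jitterSdUm = jitterSdUm, class1Fraction = class1Fraction,
      diameterMeans = diameterMeans, diameterSds = diameterSds,
      pixelSizeUm = pixelSizeUm, noiseSd = noiseSd, seed = seed)
}

#' Generate a synthetic en-face photoreceptor mosaic
#'
#' Places cell centres on a hexagonal lattice (random phase), applies
#' Gaussian jitter, assigns each cell to the larger (type 1) or smaller
#' (type 2) diameter class, and renders near-binary disks into a single
#' `cells` channel.  Truth lists exact centres, classes and diameters.
#'
#' @param cfg a [MosaicConfig].
#' @return list with `image` ([ImageStack]) and `truth` ([GroundTruth]).
#' @export
generateEnfaceMosaic <- function(cfg) {
  stopifnot(is(cfg, "MosaicConfig"))
  methods::validObject(cfg)
  spacing <- if (!is.na(cfg@meanSpacingUm)) cfg@meanSpacingUm else
    sqrt(2 / (sqrt(3) * cfg@densityPerMm2 / 1e6))
  maxD <- cfg@diameterMeans + 3 * cfg@diameterSds
  if (spacing < sum(maxD) / 2)
    stop(sprintf(
      "lattice spacing %.2f um is below the sum of maximal cell radii (%.2f um): cells cannot be separated",
      spacing, sum(maxD) / 2))
  .withSeed(cfg@seed, {
    ps <- cfg@pixelSizeUm
    L <- cfg@fieldSizeUm
    rowStep <- spacing * sqrt(3) / 2
    ox <- runif(1, 0, spacing); oy <- runif(1, 0, rowStep)
    rows <- seq(-2 * rowStep + oy, L + 2 * rowStep, by = rowStep)
    centres <- do.call(rbind, lapply(seq_along(rows), function(i) {
      shift <- if (i %% 2 == 0) spacing / 2 else 0
      xs <- seq(-2 * spacing + ox + shift, L + 2 * spacing, by = spacing)
      cbind(xs, rows[i])
    }))
    if (cfg@jitterSdUm > 0)
      centres <- centres + matrix(rnorm(length(centres), 0, cfg@jitterSdUm),
                                  ncol = 2)
    keep <- centres[, 1] >= ps & centres[, 1] <= L &
            centres[, 2] >= ps & centres[, 2] <= L
    centres <- centres[keep, , drop = FALSE]
    n <- nrow(centres)
    cls <- ifelse(runif(n) < cfg@class1Fraction, "type1", "type2")
    diam <- pmax(0.5, rnorm(n, cfg@diameterMeans[cls], cfg@diameterSds[cls]))
    npx <- round(L / ps)
    img <- matrix(0, npx, npx)
    xPx <- centres[, 1] / ps; yPx <- centres[, 2] / ps
    for (k in seq_len(n))
      img <- .addDisk(img, xPx[k], yPx[k], (diam[k] / 2) / ps, 1)
    img <- .clamp0(img + matrix(rnorm(length(img), 0, cfg@noiseSd), npx))
    truth <- new("GroundTruth",
      cells = data.frame(x_px = xPx, y_px = yPx, class = cls,
                         diameter_um = diam, extruded = FALSE),
      boundary = data.frame(),
      coverages = numeric(0),
      config = c(.configAsList(cfg), list(spacing_um = spacing)))
    list(image = ImageStack(list(cells = img), pixelSize = ps),
         truth = truth)
  })
}

#' Generate wholemount fields with prescribed coverage fractions
#'
#' For each named channel, thresholds a smoothed Gaussian random field at
#' the rank corresponding to the requested coverage, so the true foreground
#' fraction equals the request to within one pixel.  Foreground is rendered
#' near 1, background near 0, plus additive noise.
#'
#' @param coverages named numeric vector of target fractions in \[0, 1\].
#' @param fieldSizeUm side of the square field (um).
#' @param pixelSizeUm um per pixel.
#' @param smoothUm Gaussian correlation length of the texture (um).
#' @param noiseSd additive Gaussian channel noise.
#' @param seed integer seed.
#' @return list with `image` ([ImageStack]) and `truth` ([GroundTruth];
#'   `truthCoverages()` returns the achieved foreground fractions).
#' @export
generateWholemount <- function(coverages, fieldSizeUm = 100,
                               pixelSizeUm = 0.5, smoothUm = 3,
                               noiseSd = 0.02, seed = 1) {
  if (any(coverages < 0 | coverages > 1))
    stop("coverages must lie in [0, 1]")
  if (is.null(names(coverages)) || any(!nzchar(names(coverages))))
    stop("coverages must be a named vector")
  .withSeed(seed, {
    npx <- round(fieldSizeUm / pixelSizeUm)
    channels <- list()
    achieved <- numeric(0)
    for (ch in names(coverages)) {
      field <- .gaussSmooth(matrix(rnorm(npx * npx), npx),
                            smoothUm / pixelSizeUm)
      k <- round(coverages[[ch]] * npx * npx)
      fg <- matrix(FALSE, npx, npx)
      if (k > 0) {
        thr <- sort(field, decreasing = TRUE)[k]
        fg <- field >= thr
        # rank threshold: ties are virtually impossible in a continuous field
      }
      img <- .clamp0(fg * 1 + matrix(rnorm(npx * npx, 0, noiseSd), npx))
      channels[[ch]] <- img
      achieved[ch] <- mean(fg)
    }
    truth <- new("GroundTruth",
      cells = data.frame(), boundary = data.frame(),
      coverages = achieved,
      config = list(requested = coverages, fieldSizeUm = fieldSizeUm,
                    pixelSizeUm = pixelSizeUm, smoothUm = smoothUm,
                    noiseSd = noiseSd, seed = seed))
    list(image = ImageStack(channels, pixelSize = pixelSizeUm),
         truth = truth)
  })
}
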