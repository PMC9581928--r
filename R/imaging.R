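# Low-level image operators mirroring the Fiji-macro primitives used for
# organoid ROI quantification: global mean threshold, area fractions,
# smoothed local-maxima nucleus detection, and disk colocalization.

#' Global mean threshold
#'
#' Binarizes an image at the arithmetic mean of all pixel intensities; a
#' pixel is foreground iff its intensity is strictly greater than the mean
#' (the "mean" auto-threshold rule).  A constant image yields a valid empty
#' mask with the `constant` provenance flag set and a warning.
#'
#' @param image numeric matrix, or a 3D array (max-projected first).
#' @param channel optional channel name recorded in the provenance.
#' @return a [BinaryMask]; threshold recoverable via [maskThreshold()].
#' @examples
#' meanThreshold(matrix(c(0, 0, 10, 10), 2, 2))
#' @export
meanThreshold <- function(image, channel = "") {
  if (length(dim(image)) == 3L) image <- maxProject(image)
  stopifnot(is.matrix(image), length(image) > 0)
  thr <- mean(image)
  constant <- (max(image) == min(image))
  if (constant)
    warning("constant image: mean threshold yields an empty mask")
  new("BinaryMask", mask = image > thr, channel = channel,
      threshold = thr, constant = constant)
}

#' Foreground area fraction
#'
#' Fraction of reference pixels that are also mask foreground, i.e.
#' `|mask & reference| / |reference|`.  With `reference = "all"` the
#' denominator is the whole ROI.  This is the "marker area normalized to
#' DAPI" measurement when `reference` is a nuclei mask.
#'
#' @param mask a [BinaryMask] or logical matrix.
#' @param reference a [BinaryMask], logical matrix, or `"all"`.
#' @return fraction in \[0, 1\].
#' @export
areaFraction <- function(mask, reference = "all") {
  m <- if (is(mask, "BinaryMask")) mask@mask else mask
  stopifnot(is.logical(m))
  if (identical(reference, "all")) {
    r <- matrix(TRUE, nrow(m), ncol(m))
  } else {
    r <- if (is(reference, "BinaryMask")) reference@mask else reference
  }
  if (!identical(dim(m), dim(r))) stop("mask and reference shapes differ")
  denom <- sum(r)
  if (denom == 0) stop("empty reference mask: area fraction undefined")
  sum(m & r) / denom
}

# Gaussian smoothing with replicated borders; sigma in pixels.
.gaussSmooth <- function(image, sigmaPx) {
  if (sigmaPx <= 0) return(image)
  sz <- 2L * as.integer(ceiling(3 * sigmaPx)) + 1L
  brush <- EBImage::makeBrush(sz, shape = "Gaussian", sigma = sigmaPx)
  as.matrix(EBImage::filter2(image, brush, boundary = "replicate"))
}

#' Detect nuclei as smoothed local intensity maxima
#'
#' Gaussian-smooths the image (sigma = `minSeparationUm / 4`), finds pixels
#' that are maximal within their 8-neighbourhood and at least `minIntensity`
#' after smoothing, then greedily suppresses maxima closer than
#' `minSeparationUm` to an already accepted (stronger) one.  Ties are broken
#' by intensity, then by row-major pixel order, so detection is
#' deterministic.
#'
#' @param image numeric matrix (2D); z-stacks should be max-projected first.
#' @param pixelSizeUm micrometres per pixel.
#' @param minSeparationUm minimum distance between reported nuclei (> 0).
#' @param minIntensity minimum smoothed intensity of a reported maximum.
#' @return point-set `data.frame` with columns `x_px`, `y_px`, `intensity`
#'   (smoothed), ordered by decreasing intensity.  May have zero rows.
#' @export
detectNuclei <- function(image, pixelSizeUm, minSeparationUm = 1.8,
                         minIntensity = 0.25) {
  stopifnot(is.matrix(image), pixelSizeUm > 0, minSeparationUm > 0)
  sm <- .gaussSmooth(image, (minSeparationUm / 4) / pixelSizeUm)
  cand <- .localMaxima(sm, minIntensity)
  if (nrow(cand) == 0L)
    return(data.frame(x_px = numeric(0), y_px = numeric(0),
                      intensity = numeric(0)))
  # intensity desc, then row, then column: deterministic tie-break
  ord <- order(-cand$intensity, cand$y_px, cand$x_px)
  cand <- cand[ord, , drop = FALSE]
  minSepPx <- minSeparationUm / pixelSizeUm
  keep <- .suppressByDistance(cand$x_px, cand$y_px, minSepPx)
  out <- cand[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# 8-neighbourhood maxima (>= all neighbours) at or above minIntensity.
.localMaxima <- function(img, minIntensity) {
  nr <- nrow(img); nc <- ncol(img)
  pad <- matrix(-Inf, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- img
  isMax <- matrix(TRUE, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    nb <- pad[(2:(nr + 1L)) + dr, (2:(nc + 1L)) + dc]
    isMax <- isMax & (img >= nb)
  }
  isMax <- isMax & (img >= minIntensity)
  idx <- which(isMax, arr.ind = TRUE)
  data.frame(x_px = as.numeric(idx[, 2]), y_px = as.numeric(idx[, 1]),
             intensity = img[isMax])
}

# Greedy minimum-distance suppression; input must already be sorted by
# priority.  Returns a logical keep vector.
.suppressByDistance <- function(x, y, minDist) {
  n <- length(x)
  keep <- logical(n)
  ax <- numeric(0); ay <- numeric(0)
  minD2 <- minDist^2
  for (i in seq_len(n)) {
    if (length(ax) == 0L ||
        min((ax - x[i])^2 + (ay - y[i])^2) >= minD2) {
      keep[i] <- TRUE
      ax <- c(ax, x[i]); ay <- c(ay, y[i])
    }
  }
  keep
}

#' Flag points lying on mask foreground
#'
#' A point is flagged marker-positive iff at least half of the mask pixels
#' inside the disk of radius `radiusUm` around it are foreground (pixels
#' outside the image are ignored).  With `radiusUm = 0` the flag is the mask
#' value at the point's pixel.
#'
#' @param points point-set `data.frame` with columns `x_px`, `y_px`.
#' @param mask a [BinaryMask] or logical matrix.
#' @param radiusUm disk radius in micrometres (>= 0).
#' @param pixelSizeUm micrometres per pixel.
#' @param minFraction foreground fraction required for a positive flag.
#' @return `points` with logical column `marker_flag` and numeric column
#'   `marker_fraction` appended.
#' @export
colocalize <- function(points, mask, radiusUm, pixelSizeUm,
                       minFraction = 0.5) {
  m <- if (is(mask, "BinaryMask")) mask@mask else mask
  stopifnot(is.logical(m), radiusUm >= 0, pixelSizeUm > 0)
  nr <- nrow(m); nc <- ncol(m)
  n <- nrow(points)
  frac <- numeric(n)
  rPx <- radiusUm / pixelSizeUm
  off <- expand.grid(dr = -ceiling(rPx):ceiling(rPx),
                     dc = -ceiling(rPx):ceiling(rPx))
  off <- off[off$dr^2 + off$dc^2 <= rPx^2 + 1e-9, , drop = FALSE]
  for (i in seq_len(n)) {
    r0 <- round(points$y_px[i]); c0 <- round(points$x_px[i])
    if (r0 < 1 || r0 > nr || c0 < 1 || c0 > nc)
      stop(sprintf("point %d at (%.1f, %.1f) lies outside the image",
                   i, points$x_px[i], points$y_px[i]))
    rr <- r0 + off$dr; cc <- c0 + off$dc
    ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
    frac[i] <- mean(m[cbind(rr[ok], cc[ok])])
  }
  points$marker_fraction <- frac
  points$marker_flag <- frac >= minFraction
  points
}
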