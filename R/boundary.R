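# Apical boundary estimation and the boundary-referenced phenotype metrics:
# ectopic (extruded) cell counts, inner-segment (PIS) counts, per-100-um
# cell counts, and en-face area fractions.

#' Estimate the apical tissue boundary
#'
#' Builds a tissue mask as the union of the mean-thresholded tissue channels
#' (nuclei plus glial markers), removes connected components smaller than
#' `minComponentUm2` and keeps the largest remaining component (within one
#' ROI the epithelium is a single contiguous slab; everything detached from
#' it, however large, is candidate extruded material), then records, per
#' image column, the apical-most (smallest-row) foreground pixel.  Columns
#' without tissue are linearly interpolated from their neighbours; the
#' profile is median-filtered over a `smoothUm` window.
#'
#' @param stack an [ImageStack].
#' @param tissueChannels character vector of channel names.
#' @param minComponentUm2 minimum component area kept as tissue.
#' @param smoothUm median-filter window (micrometres).
#' @return a [BoundaryCurve] with one vertex per image column.
#' @export
estimateApicalBoundary <- function(stack, tissueChannels,
                                   minComponentUm2 = 50, smoothUm = 5) {
  stopifnot(is(stack, "ImageStack"), length(tissueChannels) >= 1)
  ps <- pixelSize(stack)
  un <- NULL
  for (ch in tissueChannels) {
    m <- suppressWarnings(meanThreshold(maxProject(stack, ch), ch))@mask
    un <- if (is.null(un)) m else (un | m)
  }
  if (!any(un)) stop("tissue mask is empty: cannot locate a boundary")
  lab <- .labelComponents(un)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes * ps^2 >= minComponentUm2)
  if (length(keep) == 0L) stop("no tissue component of at least ",
                               minComponentUm2, " um^2")
  keep <- keep[which.max(sizes[keep])]
  un <- matrix(lab == keep, nrow(un), ncol(un))
  nc <- ncol(un)
  top <- rep(NA_real_, nc)
  for (j in seq_len(nc)) {
    w <- which(un[, j])
    if (length(w)) top[j] <- w[1]
  }
  if (anyNA(top)) {
    ok <- which(!is.na(top))
    top <- stats::approx(ok, top[ok], xout = seq_len(nc), rule = 2)$y
  }
  k <- max(3L, as.integer(round(smoothUm / ps)))
  if (k %% 2L == 0L) k <- k + 1L
  k <- min(k, if (nc %% 2L == 1L) nc else nc - 1L)
  y <- as.numeric(stats::runmed(top, k, endrule = "median"))
  # short mean filter to relax the integer-row staircase, which otherwise
  # inflates the polyline arc length on sloped borders
  y <- .movingAvg(y, max(3L, as.integer(round(2 / ps)) %/% 2L * 2L + 1L))
  new("BoundaryCurve", x = as.numeric(seq_len(nc)), y = y, pixelSize = ps)
}

# Connected components, 4-connectivity (EBImage::bwlabel convention).
.labelComponents <- function(mask) {
  storage.mode(mask) <- "double"
  matrix(as.integer(EBImage::bwlabel(mask)), nrow(mask), ncol(mask))
}

#' Count ectopic (extruded) cells
#'
#' A point is ectopic iff its row lies strictly apical of (smaller than) the
#' interpolated boundary row at its column; a point exactly on the boundary
#' is not ectopic.  When the point set carries a logical `marker_flag`
#' column only flagged (marker-positive) points are considered, matching the
#' definition of an extruded photoreceptor as a marker-positive cell with
#' its nucleus apical to the epithelial border.
#'
#' @param points point-set `data.frame` with columns `x_px`, `y_px` and
#'   optionally `marker_flag`.
#' @param boundary a [BoundaryCurve] spanning the ROI.
#' @return list with `count`, `per100um` (count normalized to 100 um of
#'   boundary arc length), and the logical vector `ectopic`.
#' @export
countEctopic <- function(points, boundary) {
  stopifnot(is(boundary, "BoundaryCurve"))
  if (!is.null(points$marker_flag)) points <- points[points$marker_flag, , drop = FALSE]
  if (nrow(points) == 0L)
    return(list(count = 0L, per100um = 0, ectopic = logical(0)))
  by <- boundaryRowAt(boundary, points$x_px)
  ect <- points$y_px < by
  al <- arcLengthUm(boundary)
  if (al <= 0) stop("boundary arc length is zero")
  list(count = sum(ect), per100um = sum(ect) * 100 / al, ectopic = ect)
}

#' Count photoreceptor inner segments (PIS)
#'
#' PIS are connected components of the photoreceptor-marker foreground
#' restricted to the region strictly apical of the boundary, with area at
#' least `minSizeUm2` and a nuclei-mask overlap fraction of at most
#' `maxNuclearOverlap` (the DAPI-negative rule).  The count is normalized to
#' 100 um of apical surface arc length measured within the ROI.
#'
#' @param markerMask photoreceptor-marker [BinaryMask] or logical matrix.
#' @param nucleiMask nuclei [BinaryMask] or logical matrix (same shape).
#' @param boundary a [BoundaryCurve] for the same image.
#' @param pixelSizeUm micrometres per pixel.
#' @param minSizeUm2 minimum blob area (suppresses single-pixel noise).
#' @param maxNuclearOverlap maximum tolerated nuclei-overlap fraction.
#' @return list with `count`, `per100um`, and a data.frame `components`
#'   (one row per accepted blob: area_um2, nuclear_overlap, x_px, y_px).
#' @export
countPIS <- function(markerMask, nucleiMask, boundary, pixelSizeUm,
                     minSizeUm2 = 1, maxNuclearOverlap = 0.1) {
  mm <- if (is(markerMask, "BinaryMask")) markerMask@mask else markerMask
  nm <- if (is(nucleiMask, "BinaryMask")) nucleiMask@mask else nucleiMask
  stopifnot(identical(dim(mm), dim(nm)), is(boundary, "BoundaryCurve"))
  by <- boundaryRowAt(boundary, seq_len(ncol(mm)))
  apical <- outer(seq_len(nrow(mm)), by, `<`)
  lab <- .labelComponents(mm & apical)
  nlab <- max(lab)
  comps <- data.frame(area_um2 = numeric(0), nuclear_overlap = numeric(0),
                      x_px = numeric(0), y_px = numeric(0))
  if (nlab > 0) {
    for (k in seq_len(nlab)) {
      px <- which(lab == k)
      area <- length(px) * pixelSizeUm^2
      if (area < minSizeUm2) next
      ov <- mean(nm[px])
      if (ov > maxNuclearOverlap) next
      rc <- arrayInd(px, dim(mm))
      comps <- rbind(comps, data.frame(
        area_um2 = area, nuclear_overlap = ov,
        x_px = mean(rc[, 2]), y_px = mean(rc[, 1])))
    }
  }
  al <- arcLengthUm(boundary)
  list(count = nrow(comps), per100um = nrow(comps) * 100 / al,
       components = comps)
}

#' Marker-positive cells per 100 um of apical surface
#'
#' Counts the class-labelled points anywhere in the ROI and normalizes to
#' the boundary arc length, the per-100-um convention of serial-section
#' cell counting.
#'
#' @param points point-set `data.frame`; column `class` used when `class`
#'   is given.
#' @param boundary a [BoundaryCurve].
#' @param class optional class label to count (default: all points).
#' @return count per 100 um (numeric).
#' @export
cellsPer100um <- function(points, boundary, class = NULL) {
  stopifnot(is(boundary, "BoundaryCurve"))
  al <- arcLengthUm(boundary)
  if (al <= 0) stop("boundary arc length is zero")
  n <- if (is.null(class)) nrow(points) else sum(points$class == class)
  n * 100 / al
}

#' En-face marker area fractions
#'
#' For each requested channel: maximum-intensity projection, global mean
#' threshold, then the foreground fraction over the whole ROI.  Used to
#' quantify inner-segment coverage and glial seal-like scar coverage on
#' wholemount projections.
#'
#' @param stack an [ImageStack].
#' @param channels character vector of channel names.
#' @param minRoiUm minimum ROI side length in micrometres; smaller ROIs are
#'   rejected.
#' @return named numeric vector of fractions in \[0, 1\].
#' @export
enfaceAreaFractions <- function(stack, channels, minRoiUm = 69) {
  stopifnot(is(stack, "ImageStack"))
  d <- dim(stack@channels[[1]])[1:2]
  side <- d * pixelSize(stack)
  if (any(side < minRoiUm - 1e-9))
    stop(sprintf("ROI %.1f x %.1f um is below the minimum side of %g um",
                 side[1], side[2], minRoiUm))
  out <- vapply(channels, function(ch) {
    m <- suppressWarnings(meanThreshold(maxProject(stack, ch), ch))
    areaFraction(m, "all")
  }, numeric(1))
  names(out) <- channels
  out
}
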