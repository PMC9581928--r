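# Radial (apical-to-basal) lamination profiling: each ROI is divided into
# ten equal depth sections and the relative number of detected cell
# positions (count basis) or above-threshold pixels (pixel basis) per
# section is reported.

.binDepths <- function(depth) {
  # depth fraction in [0,1); exactly 1 falls into the last bin
  ok <- depth >= 0 & depth <= 1
  b <- pmin(floor(depth[ok] * 10) + 1L, 10L)
  list(bins = tabulate(b, 10L), nExcluded = sum(!ok), n = sum(ok))
}

.makeProfile <- function(binInfo, source) {
  n <- binInfo$n
  fr <- if (n > 0) binInfo$bins / n else rep(0, 10)
  p <- new("RadialProfile", fractions = fr, n = as.numeric(n),
           source = source)
  attr(p, "nExcluded") <- binInfo$nExcluded
  p
}

.extentAt <- function(tissueExtent, cols) {
  if (is.list(tissueExtent)) {
    ap <- tissueExtent$apical; ba <- tissueExtent$basal
    if (length(ap) != length(ba))
      stop("per-column extent needs apical and basal vectors of equal length")
    if (any(cols < 1L) || any(cols > length(ap)))
      stop("object column outside the per-column extent")
    cbind(ap[cols], ba[cols])
  } else {
    cbind(rep(tissueExtent[1], length(cols)),
          rep(tissueExtent[2], length(cols)))
  }
}

#' @rdname radialProfile
#' @aliases radialProfile,data.frame-method radialProfile,BinaryMask-method
setMethod("radialProfile", signature(objects = "data.frame"),
  function(objects, tissueExtent, source = "count") {
    if (nrow(objects) == 0L)
      return(.makeProfile(list(bins = rep(0L, 10), nExcluded = 0L, n = 0L),
                          source))
    ext <- .extentAt(tissueExtent, pmax(1L, as.integer(round(objects$x_px))))
    depth <- (objects$y_px - ext[, 1]) / (ext[, 2] - ext[, 1])
    .makeProfile(.binDepths(depth), source)
  })

setMethod("radialProfile", signature(objects = "BinaryMask"),
  function(objects, tissueExtent, source = "pixel") {
    m <- objects@mask
    idx <- which(m, arr.ind = TRUE)
    if (nrow(idx) == 0L)
      return(.makeProfile(list(bins = rep(0L, 10), nExcluded = 0L, n = 0L),
                          source))
    ext <- .extentAt(tissueExtent, idx[, 2])
    depth <- (idx[, 1] - ext[, 1]) / (ext[, 2] - ext[, 1])
    .makeProfile(.binDepths(depth), source)
  })

#' Dyslamination index
#'
#' Scores how evenly a radial profile is spread across the ten depth bins:
#' `1 - TV(p, uniform) / 0.9`, where `TV` is the total-variation distance
#' (half the L1 distance) and `0.9` is the distance between a single-bin
#' profile and the uniform one.  A perfectly laminated marker concentrated
#' in one bin scores 0; complete radial redistribution (uniform) scores 1.
#' The index depends on bin fractions only through their deviation from
#' uniformity, so it is invariant to permuting bins.  This summary is a
#' convenience addition on top of the ten-bin distributions and is labelled
#' as such in reports.
#'
#' @param profile a [RadialProfile] with `n > 0`.
#' @return scalar in \[0, 1\].
#' @export
dyslaminationIndex <- function(profile) {
  stopifnot(is(profile, "RadialProfile"))
  if (profile@n == 0) stop("profile is empty: index undefined")
  tv <- 0.5 * sum(abs(profile@fractions - 0.1))
  1 - tv / 0.9
}
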