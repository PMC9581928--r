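# End-to-end measurement of a cross-section ROI: nucleus detection, class
# assignment by marker colocalization, boundary estimation, ectopy, inner
# segments, and the per-100-um / fraction-of-total summaries, plus the
# cohort loop that produces a tidy measurement table.

#' Measure a cross-section ROI
#'
#' Runs the counting pipeline on a multi-channel section image: detects
#' nuclei on the `dapi` channel, assigns each nucleus to a class by disk
#' colocalization against the mean-thresholded marker channels (ties go to
#' the best-covered marker; unassigned nuclei count as "other"), estimates
#' the apical boundary from the glia + nuclei channels, and derives
#' composition fractions, per-100-um counts, ectopic photoreceptor counts,
#' and inner-segment counts.
#'
#' @param stack an [ImageStack] with a `dapi` channel, marker channels
#'   among `markerChannels`, and the channels named in `tissueChannels`.
#' @param markerChannels named character vector mapping class labels to
#'   channel names.
#' @param tissueChannels channels defining the tissue for the boundary.
#' @param pisChannel photoreceptor channel used for inner-segment counting
#'   (`NULL` to skip).
#' @param minSeparationUm,minIntensity nucleus detection parameters.
#' @param colocRadiusUm colocalization disk radius (um).
#' @param minPisSizeUm2 minimum inner-segment component area.  The default
#'   (2.5 um^2) sits below any plausible inner segment but above the
#'   sub-nuclear marker-disk slivers that one-pixel boundary
#'   discretization can expose.
#' @return list with `points` (detected nuclei with `class`), `boundary`
#'   ([BoundaryCurve]), `pis` (see [countPIS()], or `NULL`), and `metrics`
#'   (named numeric vector).
#' @export
measureSection <- function(stack,
                           markerChannels = c(cone = "cone", rod = "rod",
                                              mg = "mg"),
                           tissueChannels = c("glia", "dapi"),
                           pisChannel = "rcvrn",
                           minSeparationUm = 1.8, minIntensity = 0.25,
                           colocRadiusUm = 1.5, minPisSizeUm2 = 2.5) {
  stopifnot(is(stack, "ImageStack"))
  ps <- pixelSize(stack)
  dapi <- maxProject(stack, "dapi")
  pts <- detectNuclei(dapi, ps, minSeparationUm, minIntensity)
  markerChannels <- markerChannels[markerChannels %in% channelNames(stack)]
  fracs <- matrix(0, nrow(pts), length(markerChannels),
                  dimnames = list(NULL, names(markerChannels)))
  masks <- list()
  for (cl in names(markerChannels)) {
    masks[[cl]] <- suppressWarnings(
      meanThreshold(maxProject(stack, markerChannels[[cl]]),
                    markerChannels[[cl]]))
    if (nrow(pts))
      fracs[, cl] <- colocalize(pts, masks[[cl]], colocRadiusUm,
                                ps)$marker_fraction
  }
  cls <- rep("other", nrow(pts))
  if (nrow(pts) && length(markerChannels)) {
    best <- max.col(fracs, ties.method = "first")
    hit <- fracs[cbind(seq_len(nrow(pts)), best)] >= 0.5
    cls[hit] <- colnames(fracs)[best[hit]]
  }
  pts$class <- cls

  boundary <- estimateApicalBoundary(stack, tissueChannels)
  al <- arcLengthUm(boundary)

  prPts <- pts[pts$class %in% c("cone", "rod"), , drop = FALSE]
  ect <- countEctopic(prPts, boundary)

  pis <- NULL
  if (!is.null(pisChannel) && pisChannel %in% channelNames(stack)) {
    mm <- suppressWarnings(
      meanThreshold(maxProject(stack, pisChannel), pisChannel))
    nmask <- suppressWarnings(meanThreshold(dapi, "dapi"))
    pis <- countPIS(mm, nmask, boundary, ps, minSizeUm2 = minPisSizeUm2)
  }

  nTot <- nrow(pts)
  classes <- c(names(markerChannels), "other")
  counts <- vapply(classes, function(k) sum(cls == k), numeric(1))
  metrics <- c(
    n_total = nTot,
    setNames(counts / max(nTot, 1), paste0("frac_", classes)),
    setNames(counts * 100 / al, paste0("per100_", classes)),
    ectopic_count = ect$count,
    ectopic_per100 = ect$per100um,
    pis_count = if (is.null(pis)) NA_real_ else pis$count,
    pis_per100 = if (is.null(pis)) NA_real_ else pis$per100um,
    arc_length_um = al)
  list(points = pts, boundary = boundary, pis = pis, metrics = metrics)
}

#' Measure every ROI of a synthetic cohort
#'
#' Applies [measureSection()] to each ROI of a [generateCohort()] result
#' and returns a tidy measurement table suitable for [summarizeCohort()],
#' [covPartition()] and [compareGroups()].
#'
#' @param cohort result of [generateCohort()], or a list of
#'   `list(organoid_id, roi_id, group, image)` records.
#' @param ... passed to [measureSection()].
#' @return `data.frame` with columns `organoid_id`, `roi_id`, `group`,
#'   `metric`, `value`.
#' @export
measureCohort <- function(cohort, ...) {
  rois <- if (!is.null(cohort$rois)) cohort$rois else cohort
  out <- vector("list", length(rois))
  for (i in seq_along(rois)) {
    rec <- rois[[i]]
    m <- measureSection(rec$image, ...)$metrics
    m <- m[!is.na(m)]
    out[[i]] <- data.frame(
      organoid_id = rec$organoid_id, roi_id = rec$roi_id,
      group = if (is.null(rec$group)) "CTRL" else rec$group,
      metric = names(m), value = unname(m), row.names = NULL)
  }
  do.call(rbind, out)
}
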