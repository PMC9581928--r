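# Photoreceptor mosaic geometry: segmentation of en-face fields, two-type
# size classification, and Voronoi/nearest-neighbour statistics with the
# edge-cell exclusion rule.

#' Segment an en-face mosaic into labelled cells
#'
#' Mean-thresholds the (max-projected) channel, splits touching cells by
#' watershedding the Euclidean distance map, and returns per-cell
#' centroids, equivalent diameters and an edge flag for labels touching
#' the image border.
#'
#' @param stack an [ImageStack].
#' @param channel channel name (default first channel).
#' @param minAreaUm2 discard components smaller than this area.
#' @return point-set `data.frame` with columns `x_px`, `y_px`,
#'   `diameter_um` (equivalent circular diameter), `area_um2`, `is_edge`.
#' @export
segmentMosaic <- function(stack, channel = channelNames(stack)[1],
                          minAreaUm2 = 1) {
  stopifnot(is(stack, "ImageStack"))
  ps <- pixelSize(stack)
  img <- maxProject(stack, channel)
  mask <- meanThreshold(img, channel)@mask
  lab <- matrix(as.integer(
    EBImage::watershed(EBImage::distmap(mask), tolerance = 1)),
    nrow(mask), ncol(mask))
  nlab <- max(lab)
  if (nlab == 0L)
    return(data.frame(x_px = numeric(0), y_px = numeric(0),
                      diameter_um = numeric(0), area_um2 = numeric(0),
                      is_edge = logical(0)))
  idx <- which(lab > 0)
  rc <- arrayInd(idx, dim(lab))
  k <- lab[idx]
  area <- tabulate(k, nlab)
  cy <- tapply(rc[, 1], k, mean)
  cx <- tapply(rc[, 2], k, mean)
  onBorder <- rc[, 1] == 1 | rc[, 1] == nrow(lab) |
              rc[, 2] == 1 | rc[, 2] == ncol(lab)
  edge <- as.logical(tapply(onBorder, k, any))
  out <- data.frame(
    x_px = as.numeric(cx), y_px = as.numeric(cy),
    diameter_um = 2 * sqrt(area * ps^2 / pi),
    area_um2 = area * ps^2, is_edge = edge)
  out <- out[out$area_um2 >= minAreaUm2, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify cells into a larger and a smaller subpopulation
#'
#' Deterministic one-dimensional two-component clustering on equivalent
#' diameter: centres start at the 25th and 75th percentiles, points are
#' iteratively reassigned to the nearer centre until stable.  Type 1 is the
#' larger-mean component (cone-like), type 2 the smaller (rod-like).
#'
#' @param cells point-set `data.frame` with a `diameter_um` column and at
#'   least two rows.
#' @return `cells` with a `class` column (`"type1"` / `"type2"`) appended;
#'   attribute `single_class` is `TRUE` (with a warning) when all diameters
#'   are identical and only one class is returned.
#' @export
classifyTwoTypes <- function(cells) {
  d <- cells$diameter_um
  if (is.null(d) || length(d) < 2L)
    stop("need at least 2 cells with diameters")
  if (max(d) == min(d)) {
    warning("all diameters identical: returning a single class")
    cells$class <- "type1"
    attr(cells, "single_class") <- TRUE
    return(cells)
  }
  centres <- as.numeric(quantile(d, c(0.25, 0.75), type = 7))
  if (centres[1] == centres[2]) centres <- range(d)
  assign <- integer(length(d))
  for (it in 1:100) {
    newAssign <- ifelse(abs(d - centres[1]) <= abs(d - centres[2]), 1L, 2L)
    if (identical(newAssign, assign)) break
    assign <- newAssign
    for (k in 1:2) if (any(assign == k)) centres[k] <- mean(d[assign == k])
  }
  # type 1 = larger mean diameter
  means <- c(mean(d[assign == 1L]), mean(d[assign == 2L]))
  large <- which.max(means)
  cells$class <- ifelse(assign == large, "type1", "type2")
  attr(cells, "single_class") <- FALSE
  cells
}

#' Voronoi and nearest-neighbour statistics of a cell mosaic
#'
#' Tessellates the point pattern inside the rectangular field.  Voronoi
#' neighbours are Delaunay-adjacent points whose shared Voronoi edge lies in
#' the field.  A cell is an edge cell iff its Voronoi polygon is clipped by
#' the field boundary (which covers unbounded polygons) or it was already
#' flagged (`is_edge` column, e.g. a rendered label touching the border).
#' Edge cells are excluded from the neighbour-count, neighbour-distance,
#' nearest-neighbour-distance and diameter summaries.
#'
#' @param points point-set `data.frame` with `x_px`, `y_px` and optionally
#'   `is_edge`, `class`, `diameter_um`.
#' @param fieldBounds `c(xmin, xmax, ymin, ymax)` in pixels.
#' @param pixelSizeUm micrometres per pixel (distances are reported in um).
#' @return list with `cells` (per-cell data.frame: `n_neighbors`,
#'   `mean_neighbor_dist_um`, `nn_dist_um`, `is_edge`) and `summary`
#'   (interior-cell means, total count, density per mm2, class counts).
#' @export
voronoiStats <- function(points, fieldBounds, pixelSizeUm = 1) {
  n <- nrow(points)
  if (n < 3L) stop("need at least 3 points for a tessellation")
  xy <- cbind(points$x_px - mean(points$x_px),
              points$y_px - mean(points$y_px))
  if (svd(xy, nu = 0, nv = 0)$d[2] < 1e-9)
    stop("degenerate geometry: points are collinear")
  dd <- tryCatch(
    deldir::deldir(points$x_px, points$y_px, rw = fieldBounds,
                   suppressMsge = TRUE),
    error = function(e) stop("degenerate geometry: ", conditionMessage(e)))
  seg <- dd$dirsgs
  nb <- vector("list", n)
  clipped <- logical(n)
  for (i in seq_len(nrow(seg))) {
    a <- seg$ind1[i]; b <- seg$ind2[i]
    nb[[a]] <- c(nb[[a]], b)
    nb[[b]] <- c(nb[[b]], a)
    if (seg$bp1[i] || seg$bp2[i]) clipped[c(a, b)] <- TRUE
  }
  isEdge <- clipped
  if (!is.null(points$is_edge)) isEdge <- isEdge | points$is_edge
  px <- points$x_px; py <- points$y_px
  nNb <- integer(n); meanD <- rep(NA_real_, n); nnD <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    v <- unique(nb[[i]])
    nNb[i] <- length(v)
    if (length(v)) {
      dists <- sqrt((px[v] - px[i])^2 + (py[v] - py[i])^2) * pixelSizeUm
      meanD[i] <- mean(dists)
      nnD[i] <- min(dists)  # nearest neighbour is always Delaunay-adjacent
    }
  }
  cells <- data.frame(points, n_neighbors = nNb,
                      mean_neighbor_dist_um = meanD, nn_dist_um = nnD,
                      is_edge = isEdge)
  interior <- !isEdge
  areaMm2 <- (fieldBounds[2] - fieldBounds[1]) *
             (fieldBounds[4] - fieldBounds[3]) * pixelSizeUm^2 / 1e6
  summary <- list(
    n_cells = n,
    n_interior = sum(interior),
    density_per_mm2 = n / areaMm2,
    mean_neighbors = mean(nNb[interior]),
    mean_neighbor_dist_um = mean(meanD[interior], na.rm = TRUE),
    mean_nn_dist_um = mean(nnD[interior], na.rm = TRUE),
    mean_diameter_um = if (is.null(points$diameter_um)) NA_real_ else
      mean(points$diameter_um[interior]),
    class_counts = if (is.null(points$class)) NULL else
      table(points$class)
  )
  list(cells = cells, summary = summary)
}

#' Cell density
#'
#' @param points point-set `data.frame` (or anything with `nrow`).
#' @param roiAreaMm2 ROI area in square millimetres (> 0).
#' @return cells per square millimetre.
#' @examples
#' cellDensity(data.frame(x = 1:270), roiAreaMm2 = 0.01)  # 27,000 / mm2
#' @export
cellDensity <- function(points, roiAreaMm2) {
  if (roiAreaMm2 <= 0) stop("roiAreaMm2 must be positive")
  nrow(points) / roiAreaMm2
}
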