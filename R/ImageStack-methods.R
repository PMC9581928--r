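#' Construct an ImageStack
#'
#' @param channels named list of numeric matrices or 3D arrays (z in the
#'   third dimension); all must share 2D dimensions.
#' @param pixelSize micrometres per pixel.
#' @param zStep z-slice spacing in micrometres (optional).
#' @return an [ImageStack].
#' @examples
#' st <- ImageStack(list(dapi = matrix(0, 4, 4)), pixelSize = 0.5)
#' channelNames(st)
#' @export
ImageStack <- function(channels, pixelSize, zStep = NA_real_) {
  channels <- lapply(channels, function(m) {
    storage.mode(m) <- "double"
    m
  })
  new("ImageStack", channels = channels, pixelSize = as.numeric(pixelSize),
      zStep = as.numeric(zStep))
}

#' @rdname ImageStack-class
#' @aliases channelNames,ImageStack-method
setMethod("channelNames", "ImageStack", function(x) names(x@channels))

#' @rdname ImageStack-class
#' @aliases getChannel,ImageStack-method
setMethod("getChannel", "ImageStack", function(x, channel) {
  if (!channel %in% names(x@channels))
    stop("unknown channel '", channel, "'; available: ",
         paste(names(x@channels), collapse = ", "))
  x@channels[[channel]]
})

#' @rdname ImageStack-class
#' @aliases pixelSize,ImageStack-method
setMethod("pixelSize", "ImageStack", function(x) x@pixelSize)

#' @rdname ImageStack-class
#' @param object an `ImageStack`.
setMethod("show", "ImageStack", function(object) {
  d <- dim(object@channels[[1]])
  cat(sprintf("ImageStack: %d x %d px (%.3g um/px), %d channel(s): %s\n",
              d[1], d[2], object@pixelSize, length(object@channels),
              paste(names(object@channels), collapse = ", ")))
  invisible(NULL)
})

setMethod("maxProject", signature(x = "ImageStack", channel = "character"),
  function(x, channel) maxProject(getChannel(x, channel)))

#' @rdname maxProject
#' @aliases maxProject,array,missing-method maxProject,ImageStack,character-method
setMethod("maxProject", signature(x = "array", channel = "missing"),
  function(x, channel) {
    if (length(dim(x)) == 2L) return(x)
    if (length(dim(x)) != 3L) stop("expected a 2D or 3D array")
    apply(x, c(1, 2), max)
  })

#' @rdname BinaryMask-class
#' @param x a [BinaryMask].
#' @param ... unused.
#' @export
as.matrix.BinaryMask <- function(x, ...) x@mask

#' @rdname BinaryMask-class
#' @export
maskThreshold <- function(x) {
  stopifnot(is(x, "BinaryMask"))
  x@threshold
}

#' @rdname BinaryMask-class
#' @param object a `BinaryMask`.
setMethod("show", "BinaryMask", function(object) {
  cat(sprintf(
    "BinaryMask: %d x %d px, %d foreground (threshold %.4g%s)\n",
    nrow(object@mask), ncol(object@mask), sum(object@mask),
    object@threshold, if (object@constant) ", constant input" else ""))
  invisible(NULL)
})

#' @rdname BoundaryCurve-class
#' @aliases arcLengthUm,BoundaryCurve-method
setMethod("arcLengthUm", "BoundaryCurve", function(x) {
  sum(sqrt(diff(x@x)^2 + diff(x@y)^2)) * x@pixelSize
})

#' Boundary row at arbitrary column positions
#'
#' Linear interpolation of the boundary polyline; constant extrapolation
#' beyond the first/last vertex.
#'
#' @param boundary a [BoundaryCurve].
#' @param x numeric column positions (pixels).
#' @return numeric boundary rows.
#' @export
boundaryRowAt <- function(boundary, x) {
  stopifnot(is(boundary, "BoundaryCurve"))
  stats::approx(boundary@x, boundary@y, xout = x, rule = 2)$y
}

#' @rdname BoundaryCurve-class
#' @param object a `BoundaryCurve`.
setMethod("show", "BoundaryCurve", function(object) {
  cat(sprintf("BoundaryCurve: %d vertices, arc length %.2f um\n",
              length(object@x), arcLengthUm(object)))
  invisible(NULL)
})

#' @rdname RadialProfile-class
#' @aliases binFractions,RadialProfile-method
setMethod("binFractions", "RadialProfile", function(x) x@fractions)

#' @rdname RadialProfile-class
#' @param object a `RadialProfile`.
setMethod("show", "RadialProfile", function(object) {
  cat(sprintf("RadialProfile (%s), n = %g\n", object@source, object@n))
  cat(" ", paste(sprintf("%.3f", object@fractions), collapse = " "), "\n")
  invisible(NULL)
})

#' @rdname GroundTruth-class
#' @param object a `GroundTruth`.
setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth: %d cells, %s boundary, %d coverage channel(s)\n",
              nrow(object@cells),
              if (nrow(object@boundary)) "with" else "no",
              length(object@coverages)))
  invisible(NULL)
})

#' @rdname GroundTruth-class
#' @param x a `GroundTruth`.
#' @export
truthCells <- function(x) {
  stopifnot(is(x, "GroundTruth"))
  x@cells
}

#' @rdname GroundTruth-class
#' @export
truthCoverages <- function(x) {
  stopifnot(is(x, "GroundTruth"))
  x@coverages
}

#' @rdname GroundTruth-class
#' @export
truthConfig <- function(x) {
  stopifnot(is(x, "GroundTruth"))
  x@config
}

#' @rdname ReferenceProfiles-class
#' @param object a `ReferenceProfiles`.
setMethod("show", "ReferenceProfiles", function(object) {
  cat(sprintf("ReferenceProfiles: %d genes x %d group means (scale: %s)\n",
              nrow(object@profiles), ncol(object@profiles), object@scale))
  invisible(NULL)
})
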