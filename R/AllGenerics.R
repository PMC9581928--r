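#' @rdname ImageStack-class
#' @param x an object.
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' @rdname ImageStack-class
#' @param channel channel name.
#' @export
setGeneric("getChannel", function(x, channel) standardGeneric("getChannel"))

#' @rdname ImageStack-class
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' Maximum-intensity projection of a channel
#'
#' Projects a (possibly z-stacked) channel to 2D by the per-pixel maximum
#' over slices.  2D input is returned unchanged.
#'
#' @param x an [ImageStack] or a numeric matrix/array.
#' @param channel channel name (for `ImageStack` input).
#' @return numeric matrix.
#' @examples
#' st <- ImageStack(list(dapi = array(c(0, 2, 1, 0), c(1, 2, 2))), pixelSize = 1)
#' maxProject(st, "dapi")
#' @export
setGeneric("maxProject", function(x, channel) standardGeneric("maxProject"))

#' @rdname BoundaryCurve-class
#' @param x a [BoundaryCurve].
#' @export
setGeneric("arcLengthUm", function(x) standardGeneric("arcLengthUm"))

#' @rdname RadialProfile-class
#' @param x a [RadialProfile].
#' @export
setGeneric("binFractions", function(x) standardGeneric("binFractions"))

#' Ten-bin apical-to-basal profile
#'
#' Assigns objects (rows of a point set) or foreground pixels (of a
#' [BinaryMask]) to ten equal depth bins between the apical and basal tissue
#' rows, and returns the normalized per-bin fractions.  Depth fraction `d`
#' in \[0, 1) maps to bin `floor(10 d) + 1`; `d = 1` maps to bin 10.  Objects
#' outside the extent are excluded and counted in the `nExcluded` attribute.
#'
#' @param objects a point-set `data.frame` (columns `x_px`, `y_px`) or a
#'   [BinaryMask].
#' @param tissueExtent either `c(apical_row, basal_row)` applied to every
#'   column, or a list with numeric vectors `apical` and `basal`, one entry
#'   per image column.
#' @param source label stored in the profile (marker name and basis).
#' @return a [RadialProfile]; attribute `nExcluded` reports dropped objects.
#' @export
setGeneric("radialProfile",
  function(objects, tissueExtent, source = "") standardGeneric("radialProfile"))
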