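#' @import methods
#' @importFrom stats cor sd quantile rnorm runif rbinom rpois qnorm pnorm
#'   median aov TukeyHSD t.test prcomp var setNames aggregate approx runmed
#' @importFrom utils read.csv write.csv
NULL

#' Multi-channel fluorescence image with physical pixel scale
#'
#' An `ImageStack` holds named intensity channels of a single region of
#' interest (ROI).  Each channel is either a 2D matrix (rows = image rows,
#' columns = image columns) or a 3D array whose third dimension indexes
#' z-slices.  All channels share dimensions.  Physical scale is carried as
#' micrometres per pixel; the apical tissue side is at row 1 by convention.
#'
#' @slot channels named list of numeric matrices or 3D arrays.
#' @slot pixelSize micrometres per pixel (> 0).
#' @slot zStep distance between z-slices in micrometres (`NA` for 2D data).
#'
#' @seealso [ImageStack()], [getChannel()], [maxProject()]
#' @export
setClass("ImageStack",
  representation(channels = "list", pixelSize = "numeric", zStep = "numeric"),
  prototype(channels = list(), pixelSize = 1, zStep = NA_real_)
)

setValidity("ImageStack", function(object) {
  ch <- object@channels
  if (length(ch) == 0L) return("ImageStack needs at least one channel")
  if (is.null(names(ch)) || any(!nzchar(names(ch))) || anyDuplicated(names(ch)))
    return("channels must have unique non-empty names")
  dims <- lapply(ch, function(m) dim(m)[1:2])
  if (!all(vapply(dims, identical, logical(1), dims[[1]])))
    return("all channels must share 2D dimensions")
  if (length(object@pixelSize) != 1L || !is.finite(object@pixelSize) ||
      object@pixelSize <= 0)
    return("pixelSize must be a single positive number")
  TRUE
})

#' Binary mask with thresholding provenance
#'
#' Product of [meanThreshold()]: a logical matrix plus a record of the source
#' channel and the threshold applied.  `constant = TRUE` flags the degenerate
#' case of a constant input image (empty mask by the strict `>` rule).
#'
#' @slot mask logical matrix.
#' @slot channel name of the source channel ("" if unknown).
#' @slot threshold numeric threshold that produced the mask.
#' @slot constant logical; input image had zero intensity spread.
#'
#' @export
setClass("BinaryMask",
  representation(mask = "matrix", channel = "character",
                 threshold = "numeric", constant = "logical"),
  prototype(channel = "", threshold = NA_real_, constant = FALSE)
)

setValidity("BinaryMask", function(object) {
  if (!is.logical(object@mask)) return("mask must be a logical matrix")
  TRUE
})

#' Apical tissue boundary as an ordered polyline
#'
#' The apical epithelial border (outer-limiting-membrane proxy) expressed as
#' one boundary row per image column.  Smaller row index = apical.  Arc length
#' is the polyline length in micrometres and is never shorter than the
#' straight-line ROI width.
#'
#' @slot x integer image columns (strictly increasing, 1-based).
#' @slot y numeric boundary rows (1-based, may be fractional).
#' @slot pixelSize micrometres per pixel.
#'
#' @seealso [estimateApicalBoundary()], [arcLengthUm()], [boundaryRowAt()]
#' @export
setClass("BoundaryCurve",
  representation(x = "numeric", y = "numeric", pixelSize = "numeric")
)

setValidity("BoundaryCurve", function(object) {
  if (length(object@x) != length(object@y))
    return("x and y must have equal length")
  if (length(object@x) < 2L) return("boundary needs at least 2 vertices")
  if (any(diff(object@x) <= 0)) return("x must be strictly increasing")
  if (object@pixelSize <= 0) return("pixelSize must be positive")
  TRUE
})

#' Ten-bin apical-to-basal distribution of a marker
#'
#' Fractions of objects (detected nuclei) or pixels falling into ten equal
#' depth bins between the apical and basal tissue surface.  Fractions sum to
#' one when at least one object was included.
#'
#' @slot fractions numeric length-10 vector, each in \[0, 1\].
#' @slot n number of included objects/pixels.
#' @slot source free-text description (marker name, "count" vs "pixel" basis).
#'
#' @seealso [radialProfile()], [dyslaminationIndex()]
#' @export
setClass("RadialProfile",
  representation(fractions = "numeric", n = "numeric", source = "character"),
  prototype(source = "")
)

setValidity("RadialProfile", function(object) {
  f <- object@fractions
  if (length(f) != 10L) return("profile must have exactly 10 bins")
  if (any(f < -1e-12 | f > 1 + 1e-12)) return("bin fractions must lie in [0,1]")
  if (object@n > 0 && abs(sum(f) - 1) > 1e-9)
    return("bin fractions must sum to 1 when n > 0")
  if (object@n == 0 && any(f != 0))
    return("empty profile must be all zero")
  TRUE
})

#' Ground truth accompanying a synthetic image
#'
#' Records every object the generator placed, so pipeline output can be
#' scored by parameter recovery: cell centres with class labels and
#' extruded/ectopic flags, the true apical boundary, true per-channel
#' coverage fractions, and an echo of the generating configuration.
#'
#' @slot cells data.frame with one row per rendered cell (columns `x_px`,
#'   `y_px`, `class`, and, where applicable, `extruded`, `diameter_um`).
#' @slot boundary data.frame (`x_px`, `y_px`) of the true apical border, or
#'   an empty data.frame when not applicable.
#' @slot coverages named numeric vector of true foreground fractions.
#' @slot config list echoing the generator configuration (includes the seed).
#'
#' @export
setClass("GroundTruth",
  representation(cells = "data.frame", boundary = "data.frame",
                 coverages = "numeric", config = "list"),
  prototype(cells = data.frame(), boundary = data.frame(),
            coverages = numeric(0), config = list())
)

#' Reference mean expression vectors
#'
#' One mean expression vector per (donor, region, cell type) reference group,
#' on a declared scale.  The full 3 donors x 2 regions x 3 cell types grid
#' gives 18 vectors; subsets are permitted but flagged by downstream checks.
#'
#' @slot profiles numeric matrix, genes x groups.
#' @slot groups data.frame with columns `donor`, `region`, `cell_type`
#'   aligned with the columns of `profiles`.
#' @slot scale character scale tag, e.g. "log10p1" or "counts".
#'
#' @seealso [buildReferenceVectors()], [correlateCells()]
#' @export
setClass("ReferenceProfiles",
  representation(profiles = "matrix", groups = "data.frame", scale = "character")
)

setValidity("ReferenceProfiles", function(object) {
  if (ncol(object@profiles) != nrow(object@groups))
    return("profiles columns must match groups rows")
  need <- c("donor", "region", "cell_type")
  if (!all(need %in% names(object@groups)))
    return("groups needs columns donor, region, cell_type")
  if (is.null(rownames(object@profiles)))
    return("profiles must carry gene identifiers as rownames")
  TRUE
})

#' Configuration for synthetic cross-section ROIs
#'
#' Parameters of [generateCrossSection()].  Defaults emulate a 100-um-wide
#' ROI spanning the epithelial depth of a day-200 organoid section with a
#' cone/rod/Mueller-glia/other composition of 28/25/25/22%.
#'
#' @slot roiWidthUm,roiHeightUm ROI extent in micrometres.
#' @slot pixelSizeUm micrometres per pixel.
#' @slot cellFractions named fractions (cone, rod, mg, other) summing to 1.
#' @slot totalCells number of nuclei to place.
#' @slot lamination named list per class: either "uniform" or
#'   `c(center, sd)` of a truncated-normal depth fraction in \[0, 1\].
#' @slot extrusionFraction named per-class probability of rendering a cell
#'   apical (ectopic) to the boundary.
#' @slot pisCount number of DAPI-negative inner-segment blobs.
#' @slot boundaryAmplitudeUm,boundaryWavelengthUm apical border undulation.
#' @slot boundaryOffsetUm mean apical border depth from row 1.
#' @slot nucleusRadiusUm rendered nucleus radius.
#' @slot minSpacingUm hard-core minimum distance between nucleus centres.
#' @slot noiseSd additive Gaussian noise sd on rendered channels.
#' @slot seed integer random seed.
#'
#' @seealso [sectionConfig()]
#' @export
setClass("SectionConfig",
  representation(
    roiWidthUm = "numeric", roiHeightUm = "numeric", pixelSizeUm = "numeric",
    cellFractions = "numeric", totalCells = "numeric", lamination = "list",
    extrusionFraction = "numeric", pisCount = "numeric",
    boundaryAmplitudeUm = "numeric", boundaryWavelengthUm = "numeric",
    boundaryOffsetUm = "numeric", nucleusRadiusUm = "numeric",
    minSpacingUm = "numeric", noiseSd = "numeric", seed = "numeric"
  )
)

setValidity("SectionConfig", function(object) {
  f <- object@cellFractions
  if (abs(sum(f) - 1) > 1e-9)
    return(sprintf("cell fractions must sum to 1 (got %.12f)", sum(f)))
  if (any(f < 0)) return("cell fractions must be non-negative")
  if (object@pixelSizeUm <= 0) return("pixelSizeUm must be positive")
  if (any(object@extrusionFraction < 0 | object@extrusionFraction > 1))
    return("extrusion fractions must lie in [0,1]")
  for (lam in object@lamination) {
    if (is.character(lam)) {
      if (!identical(lam, "uniform")) return("lamination must be 'uniform' or c(center, sd)")
    } else if (length(lam) != 2L || lam[2] < 0) {
      return("lamination bands need c(center, sd) with sd >= 0")
    }
  }
  if (object@noiseSd < 0) return("noiseSd must be non-negative")
  if (object@totalCells < 0 || object@pisCount < 0)
    return("counts must be non-negative")
  TRUE
})

#' Configuration for synthetic en-face photoreceptor mosaics
#'
#' Parameters of [generateEnfaceMosaic()].  Exactly one of `meanSpacingUm`
#' (hexagonal lattice constant) or `densityPerMm2` must be set; the other is
#' derived.  Two diameter classes emulate the larger (type 1, cone-like) and
#' smaller (type 2, rod-like) subpopulations.
#'
#' @slot fieldSizeUm side of the square field in micrometres.
#' @slot meanSpacingUm lattice spacing in micrometres (`NA` if density given).
#' @slot densityPerMm2 target density (`NA` if spacing given).
#' @slot jitterSdUm Gaussian positional jitter sd.
#' @slot class1Fraction fraction of cells assigned to type 1.
#' @slot diameterMeans,diameterSds named (`type1`, `type2`) diameter
#'   distributions in micrometres.
#' @slot pixelSizeUm micrometres per pixel.
#' @slot noiseSd additive Gaussian noise sd.
#' @slot seed integer random seed.
#'
#' @seealso [mosaicConfig()]
#' @export
setClass("MosaicConfig",
  representation(
    fieldSizeUm = "numeric", meanSpacingUm = "numeric", densityPerMm2 = "numeric",
    jitterSdUm = "numeric", class1Fraction = "numeric",
    diameterMeans = "numeric", diameterSds = "numeric",
    pixelSizeUm = "numeric", noiseSd = "numeric", seed = "numeric"
  )
)

setValidity("MosaicConfig", function(object) {
  if (is.na(object@meanSpacingUm) == is.na(object@densityPerMm2))
    return("exactly one of meanSpacingUm / densityPerMm2 must be specified")
  if (object@jitterSdUm < 0) return("jitterSdUm must be >= 0")
  if (object@class1Fraction < 0 || object@class1Fraction > 1)
    return("class1Fraction must lie in [0,1]")
  if (object@pixelSizeUm <= 0) return("pixelSizeUm must be positive")
  if (!all(c("type1", "type2") %in% names(object@diameterMeans)))
    return("diameterMeans needs entries type1 and type2")
  TRUE
})
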