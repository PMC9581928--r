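# Plain-format I/O: multi-page TIFF with a JSON metadata sidecar for image
# stacks, CSV for point sets and ground truth, dense CSV or sparse triplet
# CSV for expression matrices, and one-identifier-per-line gene lists.

#' Write / read an ImageStack as multi-page TIFF plus JSON sidecar
#'
#' Channels (and z-slices) are written as consecutive 32-bit float TIFF
#' pages; channel names, pixel size, z-step and the page layout go into a
#' `<basename>.json` sidecar next to the TIFF.
#'
#' @param stack an [ImageStack].
#' @param path output TIFF path (sidecar derived by swapping the extension).
#' @return `path`, invisibly.
#' @export
writeImageStack <- function(stack, path) {
  stopifnot(is(stack, "ImageStack"))
  pages <- list()
  layout <- list()
  scales <- list()
  for (ch in channelNames(stack)) {
    m <- getChannel(stack, ch)
    if (length(dim(m)) == 2L) m <- array(m, c(dim(m), 1L))
    nz <- dim(m)[3]
    layout[[ch]] <- nz
    # TIFF pages hold [0, 1]; remember the intensity scale per channel
    sc <- max(m, 1e-12)
    scales[[ch]] <- sc
    for (z in seq_len(nz)) pages[[length(pages) + 1L]] <- m[, , z] / sc
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  meta <- list(channels = layout, intensity_scale = scales,
               pixel_size_um = pixelSize(stack))
  if (!is.na(stack@zStep)) meta$z_step_um <- stack@zStep
  jsonlite::write_json(meta, .sidecarPath(path), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

.sidecarPath <- function(path) sub("\\.[Tt][Ii][Ff]+$", ".json", path)

#' @rdname writeImageStack
#' @param path TIFF path written by `writeImageStack`.
#' @export
readImageStack <- function(path) {
  meta <- jsonlite::read_json(.sidecarPath(path), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  channels <- list()
  i <- 0L
  for (ch in names(meta$channels)) {
    nz <- meta$channels[[ch]]
    sc <- if (is.null(meta$intensity_scale[[ch]])) 1 else
      meta$intensity_scale[[ch]]
    slices <- lapply(pages[i + seq_len(nz)], function(p) p * sc)
    i <- i + nz
    channels[[ch]] <- if (nz == 1L) slices[[1]] else
      array(unlist(slices), c(dim(slices[[1]]), nz))
  }
  ImageStack(channels, pixelSize = meta$pixel_size_um,
             zStep = if (is.null(meta$z_step_um)) NA_real_ else
               meta$z_step_um)
}

#' Write / read ground truth as CSV plus JSON config echo
#'
#' @param truth a [GroundTruth].
#' @param csvPath path for the per-object CSV.
#' @param jsonPath path for the config echo (default: swap extension).
#' @return `csvPath`, invisibly.
#' @export
writeGroundTruth <- function(truth, csvPath,
                             jsonPath = sub("\\.csv$", ".json", csvPath)) {
  stopifnot(is(truth, "GroundTruth"))
  write.csv(truth@cells, csvPath, row.names = FALSE)
  cfg <- truth@config
  cfg <- cfg[!vapply(cfg, is.data.frame, logical(1))]
  cfg$coverages <- as.list(truth@coverages)
  jsonlite::write_json(cfg, jsonPath, auto_unbox = TRUE, digits = NA,
                       force = TRUE, pretty = TRUE)
  invisible(csvPath)
}

#' Point-set CSV I/O
#'
#' @param points point-set `data.frame`.
#' @param path CSV path.
#' @return the point set (`readPointSet`) or `path` (`writePointSet`),
#'   invisibly for the writer.
#' @export
writePointSet <- function(points, path) {
  write.csv(points, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writePointSet
#' @export
readPointSet <- function(path) read.csv(path)

#' Read an expression matrix into a SummarizedExperiment
#'
#' Dense layout: a CSV with gene identifiers in the first column and one
#' column per cell.  Triplet layout: a CSV with columns `gene`, `cell`,
#' `count` (missing pairs are zero).  Cell annotations (TSV/CSV with a
#' `cell` column) are attached as `colData`.
#'
#' @param countsPath CSV path.
#' @param layout `"dense"` or `"triplet"`.
#' @param annotationPath optional annotation table path.
#' @param scale scale tag stored in `metadata()$scale`.
#' @return a [SummarizedExperiment::SummarizedExperiment].
#' @export
readExpressionMatrix <- function(countsPath, layout = c("dense", "triplet"),
                                 annotationPath = NULL, scale = "counts") {
  layout <- match.arg(layout)
  if (layout == "dense") {
    df <- read.csv(countsPath, check.names = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
  } else {
    tr <- read.csv(countsPath)
    stopifnot(all(c("gene", "cell", "count") %in% names(tr)))
    genes <- sort(unique(tr$gene)); cells <- sort(unique(tr$cell))
    m <- matrix(0, length(genes), length(cells),
                dimnames = list(genes, cells))
    m[cbind(match(tr$gene, genes), match(tr$cell, cells))] <- tr$count
  }
  if (anyDuplicated(rownames(m))) stop("duplicated gene identifiers")
  cd <- S4Vectors::DataFrame(row.names = colnames(m))
  if (!is.null(annotationPath)) {
    sep <- if (grepl("\\.tsv$", annotationPath)) "\t" else ","
    an <- read.csv(annotationPath, sep = sep)
    stopifnot("cell" %in% names(an))
    an <- an[match(colnames(m), an$cell), , drop = FALSE]
    cd <- S4Vectors::DataFrame(an[, setdiff(names(an), "cell"),
                                  drop = FALSE],
                               row.names = colnames(m))
  }
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = m), colData = cd,
    metadata = list(scale = scale))
}

#' Read a genes-of-interest list (one identifier per line)
#'
#' @param path text file path; blank lines and `#` comments are skipped.
#' @return character vector of identifiers.
#' @export
readGeneList <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x) & !startsWith(x, "#")]
}
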