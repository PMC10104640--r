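## Format I/O: 8-bit grayscale TIFF/PNG images, binary PNG masks, JSON
## graphs, CSV tables and phantom-bundle export. Matrices are (row = y,
## col = x); files are written in conventional image orientation.

#' Write a grayscale image (8-bit TIFF or PNG)
#'
#' Intensities are clamped to [0, 255] and quantised to 8 bits.
#'
#' @param image [GrayImage-class] or matrix on the 0-255 scale.
#' @param path output path ending in .tif/.tiff or .png.
#' @export
writeGrayImage <- function(image, path) {
  m <- if (is(image, "GrayImage")) image@.Data else as.matrix(image)
  m <- round(pmin(pmax(m, 0), 255)) / 255
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff"))
    tiff::writeTIFF(m, path, bits.per.sample = 8L)
  else if (ext == "png") png::writePNG(m, path)
  else stop("unsupported image extension: ", ext)
  invisible(path)
}

#' Read a grayscale image
#'
#' @param path .tif/.tiff or .png file.
#' @param channel channel tag for the returned [GrayImage-class].
#' @param rescale16 how to treat 16-bit TIFF input: `"error"` (default)
#'   refuses with a conversion hint, `"rescale"` maps the full range onto
#'   0-255.
#' @return a [GrayImage-class].
#' @export
readGrayImage <- function(path, channel = "bright_field",
                          rescale16 = c("error", "rescale")) {
  rescale16 <- match.arg(rescale16)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    m <- tiff::readTIFF(path, as.is = TRUE)
    if (is.list(m)) m <- m[[1]]
    if (length(dim(m)) == 3) m <- m[, , 1]
    if (max(m) > 255) {
      if (rescale16 == "error")
        stop("16-bit TIFF detected; pass rescale16 = \"rescale\" or ",
             "convert the file to 8 bits")
      m <- m / 257
    }
  } else if (ext == "png") {
    m <- png::readPNG(path)
    if (length(dim(m)) == 3) m <- m[, , 1]
    m <- m * 255
  } else stop("unsupported image extension: ", ext)
  GrayImage(pmin(pmax(m, 0), 255), channel = channel)
}

#' Write / read a binary mask as PNG
#' @param mask a [VesselMask-class] (or [SkeletonMatrix-class]).
#' @param path .png path.
#' @export
writeVesselMask <- function(mask, path) {
  png::writePNG(.maskMat(mask) * 1.0, path)
  invisible(path)
}

#' @rdname writeVesselMask
#' @export
readVesselMask <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  VesselMask((m > 0.5) * 1L)
}

#' Write a vessel graph to JSON
#'
#' Nodes, edges (with levels), per-edge pixel paths, raster dimensions and
#' pixel pitch are preserved; the round trip through [readGraphJSON()] is
#' lossless.
#'
#' @param graph a [VesselGraph-class].
#' @param path .json path.
#' @param concentrations optional per-edge concentrations stored alongside.
#' @export
writeGraphJSON <- function(graph, path, concentrations = NULL) {
  obj <- list(
    dim = graph@dim, pixel_pitch_um = graph@pixelPitch,
    nodes = graph@nodes,
    edges = graph@edges,
    paths = lapply(graph@paths, function(p) unname(as.matrix(p))))
  if (!is.null(concentrations)) obj$concentrations <- concentrations
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       na = "null")
  invisible(path)
}

#' @rdname writeGraphJSON
#' @return [readGraphJSON()] returns the reconstructed
#'   [VesselGraph-class] (with a `concentrations` attribute when present).
#' @export
readGraphJSON <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  nodes <- as.data.frame(obj$nodes)
  edges <- as.data.frame(obj$edges)
  if (nrow(edges) && !"level" %in% names(edges))
    edges$level <- NA_integer_
  if (nrow(edges)) edges$level <- as.integer(edges$level)
  paths <- lapply(obj$paths, function(p) {
    p <- as.matrix(p); storage.mode(p) <- "integer"
    colnames(p) <- c("y", "x"); p
  })
  g <- VesselGraph(nodes, edges, paths,
                   dim = unlist(obj$dim), pixelPitch = obj$pixel_pitch_um)
  if (!is.null(obj$concentrations))
    attr(g, "concentrations") <- unlist(obj$concentrations)
  g
}

#' Write / read a CSV table (deterministic formatting)
#' @param x data.frame.
#' @param path .csv path.
#' @export
writeTableCSV <- function(x, path) {
  write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTableCSV
#' @export
readTableCSV <- function(path) read.csv(path)

#' Export a phantom bundle to a directory
#'
#' Writes `bright_field.tif`, `fluorescent.tif`, `mask.png`, `graph.json`
#' (with the truth concentrations) and a `spec.yaml` echo of the generating
#' parameters.
#'
#' @param bundle a [PhantomBundle-class].
#' @param dir output directory (created if needed).
#' @export
writePhantomBundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeGrayImage(bundle@brightField, file.path(dir, "bright_field.tif"))
  writeGrayImage(bundle@fluorescent, file.path(dir, "fluorescent.tif"))
  writeVesselMask(bundle@truthMask, file.path(dir, "mask.png"))
  writeGraphJSON(bundle@truthGraph, file.path(dir, "graph.json"),
                 concentrations = bundle@truthConcentration)
  s <- bundle@spec
  sl <- lapply(setNames(slotNames(s), slotNames(s)), function(n) slot(s, n))
  yaml::write_yaml(sl, file.path(dir, "spec.yaml"))
  invisible(dir)
}
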