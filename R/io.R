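# Image and table I/O. Images are read into numeric matrices normalized to
# [0, 1] regardless of the file's bit depth, and written as 8- or 16-bit
# grayscale TIFF.

#' Read a grayscale image
#'
#' @param path TIFF or PNG file.
#' @return numeric matrix in `[0, 1]` (the first channel of multi-channel
#'   files).
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                tif = , tiff = tiff::readTIFF(path),
                png = png::readPNG(path),
                stop2("unsupported image format: ", ext))
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  img
}

#' Write a grayscale image as TIFF
#'
#' @param img numeric matrix in `[0, 1]`.
#' @param path output path.
#' @param bits 8 or 16 bits per sample.
#' @export
write_image <- function(img, path, bits = 16) {
  check_image(img)
  if (!bits %in% c(8, 16)) stop2("bits must be 8 or 16")
  tiff::writeTIFF(img, path, bits.per.sample = bits)
  invisible(path)
}

#' Write a label matrix as 16-bit TIFF
#'
#' Labels are stored as intensities `label / 65535` so they round-trip
#' exactly for up to 65535 regions.
#'
#' @param labels integer label matrix.
#' @param path output path.
#' @export
write_labels <- function(labels, path) {
  if (max(labels) > 65535L) stop2("more than 65535 labels")
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16)
  invisible(path)
}

#' Read a label matrix written by [write_labels()]
#'
#' @param path 16-bit label TIFF.
#' @return integer label matrix.
#' @export
read_labels <- function(path) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  matrix(as.integer(round(m * 65535)), nrow(m))
}

#' Write a synthetic scene to disk
#'
#' Writes each image channel as 16-bit TIFF, the ground-truth tables as CSV
#' (0-based pixel coordinates, row/col order) and the generating spec as a
#' JSON sidecar.
#'
#' @param scene a list returned by one of the scene generators.
#' @param dir output directory (created if needed).
#' @param spec the generating spec, stored as `spec.json`.
#' @param bits TIFF bit depth (8 or 16).
#' @return `dir`, invisibly.
#' @export
write_scene <- function(scene, dir, spec = NULL, bits = 16) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(scene)) {
    obj <- scene[[nm]]
    if (is.matrix(obj) && is.numeric(obj)) {
      write_image(obj, file.path(dir, paste0(nm, ".tif")), bits)
    }
  }
  if (!is.null(scene$truth)) {
    for (nm in names(scene$truth)) {
      obj <- scene$truth[[nm]]
      if (is.data.frame(obj))
        write.csv(obj, file.path(dir, paste0("truth_", nm, ".csv")),
                  row.names = FALSE)
    }
  }
  if (!is.null(spec)) {
    jsonlite::write_json(unclass(spec), file.path(dir, "spec.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}
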