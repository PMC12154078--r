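# File interfaces: 16-bit single-channel TIFF images, CSV tables with pinned
# numeric formatting (so reruns are byte-identical), JSON truth sidecars.

#' Read a single-channel grayscale image (TIFF or PNG)
#'
#' Multi-channel images are averaged to one channel; values are returned as a
#' numeric matrix on the file's native \[0, 1\] scale.
#'
#' @param path path to a `.tif`/`.tiff` or `.png` file.
#' @return numeric matrix.
#' @export
read_gray_image <- function(path) {
  stop_if_not(file.exists(path), paste0("file not found: ", path))
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stop("unsupported image format: .", ext, call. = FALSE))
  if (length(dim(img)) == 3L) img <- apply(img, c(1, 2), mean)
  img
}

#' Write a matrix as a 16-bit single-channel TIFF
#'
#' The image is min-max rescaled to \[0, 1\] before writing.
#'
#' @param img numeric matrix.
#' @param path output path.
#' @export
write_gray_tiff <- function(img, path) {
  tiff::writeTIFF(rescale01(img), path, bits.per.sample = 16)
  invisible(path)
}

# CSV with pinned numeric formatting: reruns must be byte-identical
write_csv_pinned <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.10g", x))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
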