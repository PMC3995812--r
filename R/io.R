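#' Read an 8-bit RGB image (PNG or TIFF)
#'
#' @param path file path ending in .png, .tif or .tiff.
#' @return H x W x 3 numeric array of intensities in 0-255.
#' @export
read_image_rgb <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = tiff::readTIFF(path),
    stop("unsupported image format: ", ext))
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3L))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]  # drop alpha
  if (dim(img)[3] != 3L) stop("expected an RGB image: ", path)
  round(img * 255)
}

#' @rdname read_image_rgb
#' @param img H x W x 3 array of 8-bit intensities.
#' @export
write_image_rgb <- function(img, path) {
  ext <- tolower(tools::file_ext(path))
  x <- img / 255
  switch(ext,
    png = png::writePNG(x, path),
    tif = , tiff = tiff::writeTIFF(x, path, bits.per.sample = 8L),
    stop("unsupported image format: ", ext))
  invisible(path)
}

#' Read / write binary masks as 8-bit PNG (0 = background, 255 = foreground)
#' @param path file path.
#' @export
read_mask <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  m > 0.5
}

#' @rdname read_mask
#' @param mask logical matrix.
#' @export
write_mask <- function(mask, path) {
  png::writePNG((mask & TRUE) * 1, path)
  invisible(path)
}

#' Write a per-sample score table as CSV
#'
#' One row per sample: the score panel plus the threshold and registration
#' metadata needed to re-derive it.
#'
#' @param scores data.frame as produced by [run_score_batch()].
#' @param path output CSV path.
#' @export
write_scores_csv <- function(scores, path) {
  utils::write.csv(scores, path, row.names = FALSE)
  invisible(path)
}

#' Write a cohort table as CSV
#' @param cohort data.frame as produced by [simulate_cohort()].
#' @param path output CSV path.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
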