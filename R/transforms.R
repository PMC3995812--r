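#' 2-D affine transforms between serial-section images
#'
#' An affine transform maps 0-based (row, col) pixel coordinates of one
#' section onto another as `q = A[, 1:2] %*% p + A[, 3]` with `p`, `q`
#' column vectors. Throughout the package the transform maps coordinates of
#' the IHC (cytokeratin) section onto the ISH section.
#'
#' @param m numeric 2x3 matrix (linear part in columns 1:2, translation in
#'   column 3).
#' @return an object of class `affine2d` (a 2x3 matrix).
#' @export
affine_transform <- function(m) {
  m <- as.matrix(m)
  if (!is.numeric(m) || !all(dim(m) == c(2L, 3L))) {
    stop("affine transform must be a numeric 2x3 matrix")
  }
  if (!all(is.finite(m))) stop("affine transform must be finite")
  if (abs(det(m[, 1:2])) <= 1e-6) {
    stop("linear part of affine transform is (near-)singular")
  }
  structure(m, class = "affine2d")
}

#' Similarity transform from interpretable parameters
#'
#' Builds translation + rotation + isotropic scale about a center point,
#' the transform family used for serial-section alignment.
#'
#' @param translation numeric length-2, (row, col) shift in pixels.
#' @param rotation_deg rotation angle in degrees (counter-clockwise in
#'   (row, col) coordinates).
#' @param scale isotropic scale factor (> 0).
#' @param center numeric length-2 fixed point of rotation/scaling, 0-based
#'   (row, col); defaults to the origin.
#' @return an `affine2d` transform.
#' @export
similarity_transform <- function(translation = c(0, 0), rotation_deg = 0,
                                 scale = 1, center = c(0, 0)) {
  stopifnot(length(translation) == 2L, length(center) == 2L,
            is.finite(rotation_deg), is.finite(scale), scale > 0)
  th <- rotation_deg * pi / 180
  R <- scale * matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L, 2L)
  b <- as.numeric(center) - R %*% as.numeric(center) + as.numeric(translation)
  affine_transform(cbind(R, b))
}

#' @export
identity_transform <- function() affine_transform(cbind(diag(2), c(0, 0)))

#' Apply a transform to 0-based (row, col) points
#'
#' @param tf an `affine2d` transform.
#' @param pts 2 x n matrix of points (rows: row-coord, col-coord), or a
#'   length-2 vector.
#' @return 2 x n matrix of mapped points.
#' @export
transform_points <- function(tf, pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, nrow = 2L)
  tf[, 1:2, drop = FALSE] %*% pts + tf[, 3]
}

#' Invert an affine transform
#' @param tf an `affine2d` transform.
#' @export
invert_transform <- function(tf) {
  Ainv <- solve(tf[, 1:2, drop = FALSE])
  affine_transform(cbind(Ainv, -Ainv %*% tf[, 3]))
}

#' Compose two transforms (apply `b` first, then `a`)
#' @param a,b `affine2d` transforms.
#' @export
compose_transforms <- function(a, b) {
  A <- a[, 1:2, drop = FALSE]
  affine_transform(cbind(A %*% b[, 1:2, drop = FALSE], A %*% b[, 3] + a[, 3]))
}

#' Decompose a similarity-like transform into parameters
#'
#' Reports the rotation angle, isotropic scale and the translation of a
#' given center point. Exact for similarity transforms; for general affines
#' the rotation/scale of the first column is reported.
#'
#' @param tf an `affine2d` transform.
#' @param center point (0-based row, col) whose displacement is reported as
#'   the translation.
#' @return list with `translation`, `rotation_deg`, `scale`.
#' @export
transform_params <- function(tf, center = c(0, 0)) {
  A <- tf[, 1:2, drop = FALSE]
  scale <- sqrt(abs(det(A)))
  rot <- atan2(A[2, 1], A[1, 1]) * 180 / pi
  tr <- as.numeric(transform_points(tf, center)) - as.numeric(center)
  list(translation = tr, rotation_deg = rot, scale = scale)
}

#' Read / write transforms as JSON
#'
#' The JSON records the six coefficients row-major together with the
#' coordinate convention so files are self-describing.
#'
#' @param tf an `affine2d` transform.
#' @param path file path.
#' @export
write_transform <- function(tf, path) {
  jsonlite::write_json(
    list(matrix_row_major = as.numeric(t(unclass(tf))),
         convention = "0-based (row, col); q = A[,1:2] p + A[,3]; maps IHC to ISH coordinates"),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  affine_transform(matrix(as.numeric(x$matrix_row_major), 2L, 3L, byrow = TRUE))
}

#' @export
print.affine2d <- function(x, ...) {
  cat("<affine2d> maps (row,col) IHC -> ISH\n")
  print(unclass(x))
  p <- transform_params(x)
  cat(sprintf("rotation %.3f deg, scale %.4f, translation of origin (%.2f, %.2f)\n",
              p$rotation_deg, p$scale, p$translation[1], p$translation[2]))
  invisible(x)
}
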