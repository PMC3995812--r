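#' Convert an 8-bit RGB brightfield image to optical density
#'
#' Per channel, `OD = -log10((I + 1) / 256)`: the Beer-Lambert transform
#' with a +1 offset so that a fully black pixel stays finite. Pure white
#' (255, 255, 255) maps to OD 0 exactly; a black pixel to -log10(1/256).
#'
#' @param img H x W x 3 numeric array of 8-bit intensities (0-255).
#' @return H x W x 3 array of optical densities (>= 0).
#' @export
rgb_to_od <- function(img) {
  if (length(dim(img)) != 3L || dim(img)[3] != 3L) {
    stop("expected an H x W x 3 RGB array")
  }
  if (min(img) < 0 || max(img) > 255) stop("intensities must be in [0, 255]")
  -log10((img + 1) / 256)
}

#' Render optical densities back to 8-bit RGB
#'
#' Exact inverse of [rgb_to_od()] up to integer rounding:
#' `I = round(256 * 10^-OD - 1)`, clamped to 0-255.
#'
#' @param od H x W x 3 array of optical densities.
#' @return H x W x 3 array of 8-bit intensities.
#' @export
od_to_rgb <- function(od) {
  i <- round(256 * 10^(-od) - 1)
  i[i < 0] <- 0
  i[i > 255] <- 255
  i
}

#' Construct a stain matrix
#'
#' Columns are unit vectors in 3-channel OD space, one per stain (at most
#' three). Vectors are normalized to unit L2 norm; non-negative and
#' non-collinear vectors are required so the least-squares unmixing is
#' well-posed.
#'
#' @param ... named numeric length-3 vectors, e.g.
#'   `stain_matrix(dab = c(0.27, 0.57, 0.78), hematoxylin = c(0.65, 0.70, 0.29))`.
#' @return 3 x k matrix of class `stain_matrix` with stain names as
#'   column names.
#' @export
stain_matrix <- function(...) {
  vs <- list(...)
  if (length(vs) == 1L && is.list(vs[[1]]) && !is.numeric(vs[[1]])) vs <- vs[[1]]
  if (length(vs) < 1L || length(vs) > 3L) stop("1 to 3 stains required")
  if (is.null(names(vs)) || any(names(vs) == "")) stop("stains must be named")
  m <- vapply(vs, function(v) {
    v <- as.numeric(v)
    if (length(v) != 3L || any(!is.finite(v)) || any(v < 0) || sum(v) == 0) {
      stop("each stain vector must be 3 non-negative finite numbers, not all zero")
    }
    v / sqrt(sum(v^2))
  }, numeric(3))
  m <- matrix(m, nrow = 3L, dimnames = list(c("R", "G", "B"), names(vs)))
  if (ncol(m) > 1L && kappa(m) > 1e6) {
    stop("stain vectors are collinear; unmixing would be singular")
  }
  structure(m, class = "stain_matrix")
}

#' Default stain matrices for the two section types
#'
#' `"ihc"`: brown DAB chromogen plus hematoxylin counterstain, using the
#' standard Ruifrok-Johnston OD vectors. `"ish"`: blue NBT/BCIP chromogen
#' plus nuclear-fast-red counterstain; no standardized colorimetry exists
#' for these, so the package defines fixed defaults (a blue precipitate
#' absorbs red/green, a red counterstain absorbs green/blue) that the
#' synthetic renderer shares, and users can override with measured vectors.
#'
#' @param type `"ihc"` or `"ish"`.
#' @return a [stain_matrix()].
#' @export
default_stain_matrix <- function(type = c("ihc", "ish")) {
  type <- match.arg(type)
  if (type == "ihc") {
    stain_matrix(dab = c(0.268, 0.570, 0.776),
                 hematoxylin = c(0.650, 0.704, 0.286))
  } else {
    stain_matrix(blue = c(0.740, 0.620, 0.260),
                 nuclear_fast_red = c(0.210, 0.720, 0.660))
  }
}

#' Read / write stain matrices as JSON (stain name -> 3 floats)
#' @param stains a [stain_matrix()].
#' @param path file path.
#' @export
write_stain_matrix <- function(stains, path) {
  l <- lapply(seq_len(ncol(stains)), function(j) as.numeric(stains[, j]))
  names(l) <- colnames(stains)
  jsonlite::write_json(l, path, digits = NA)
  invisible(path)
}

#' @rdname write_stain_matrix
#' @export
read_stain_matrix <- function(path) {
  stain_matrix(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' Unmix an OD image into per-stain concentration maps
#'
#' Least-squares projection of each pixel's OD vector onto the stain basis
#' (Moore-Penrose pseudo-inverse); negative concentrations are clamped to
#' zero. On images rendered through the same stain matrix without noise the
#' projection is exact.
#'
#' @param od H x W x 3 OD array from [rgb_to_od()].
#' @param stains a [stain_matrix()].
#' @return object of class `stain_od_maps`: a named list of H x W matrices
#'   (one per stain, OD units, >= 0).
#' @export
unmix <- function(od, stains) {
  if (length(dim(od)) != 3L || dim(od)[3] != 3L) stop("expected H x W x 3 OD array")
  if (!inherits(stains, "stain_matrix")) stains <- stain_matrix(stains)
  d <- dim(od)
  pinv <- solve(crossprod(stains), t(unclass(stains)))   # k x 3
  flat <- matrix(od, ncol = 3L)                          # (H*W) x 3
  conc <- flat %*% t(pinv)                               # (H*W) x k
  conc[conc < 0] <- 0
  maps <- lapply(seq_len(ncol(conc)), function(j) matrix(conc[, j], d[1], d[2]))
  names(maps) <- colnames(stains)
  structure(maps, dim_source = d[1:2], class = "stain_od_maps")
}

#' Threshold a stain OD map into a binary mask
#'
#' Default is Otsu's method on the OD histogram, which reproduces the
#' manual "set a threshold for the signal" step deterministically; a fixed
#' OD threshold can be supplied instead. Pixels with `OD >= threshold` are
#' positive. The chosen threshold is recorded in the mask attributes.
#'
#' @param map numeric matrix, one channel of a `stain_od_maps`.
#' @param method `"otsu"` or `"fixed"`.
#' @param fixed_value OD threshold when `method = "fixed"` (> 0).
#' @return logical matrix with attributes `threshold` and `method`.
#' @export
threshold_stain <- function(map, method = c("otsu", "fixed"), fixed_value = NULL) {
  method <- match.arg(method)
  if (!is.matrix(map) || !all(is.finite(map))) stop("map must be a finite numeric matrix")
  if (method == "fixed") {
    if (is.null(fixed_value) || !is.finite(fixed_value) || fixed_value <= 0) {
      stop("fixed_value must be a positive OD when method = 'fixed'")
    }
    thr <- fixed_value
  } else {
    rng <- range(map)
    if (diff(rng) < .Machine$double.eps^0.5) {
      stop("constant-valued map: Otsu is undefined, use method = 'fixed'")
    }
    thr <- EBImage::otsu(EBImage::Image(map), range = rng)
  }
  structure(map >= thr, threshold = as.numeric(thr), method = method)
}
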