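#' @keywords internal
sample_bilinear <- function(src, r, c, fill = NA_real_) {
  H <- nrow(src); W <- ncol(src)
  out <- rep(fill, length(r))
  ok <- r >= 0 & r <= H - 1 & c >= 0 & c <= W - 1
  if (!any(ok)) return(out)
  r <- r[ok]; c <- c[ok]
  r0 <- floor(r); c0 <- floor(c)
  fr <- r - r0; fc <- c - c0
  r1 <- pmin(r0 + 1, H - 1); c1 <- pmin(c0 + 1, W - 1)
  v00 <- src[r0 + 1 + c0 * H]; v01 <- src[r0 + 1 + c1 * H]
  v10 <- src[r1 + 1 + c0 * H]; v11 <- src[r1 + 1 + c1 * H]
  out[ok] <- (1 - fr) * ((1 - fc) * v00 + fc * v01) +
    fr * ((1 - fc) * v10 + fc * v11)
  out
}

#' @keywords internal
sample_nearest <- function(src, r, c, fill = NA_real_) {
  H <- nrow(src); W <- ncol(src)
  rn <- round(r); cn <- round(c)
  out <- rep(fill, length(r))
  ok <- rn >= 0 & rn <= H - 1 & cn >= 0 & cn <= W - 1
  out[ok] <- src[rn[ok] + 1 + cn[ok] * H]
  out
}

#' Warp an image into the coordinate frame of another section
#'
#' Resamples `src` onto a `target_dim` grid through an affine transform
#' that maps source (row, col) coordinates to target coordinates: every
#' target pixel is pulled back through the inverse transform and
#' interpolated in the source.
#'
#' @param src numeric matrix (single channel).
#' @param tf `affine2d` transform, source -> target coordinates.
#' @param target_dim integer length-2 (rows, cols) of the output grid;
#'   defaults to `dim(src)`.
#' @param interp `"bilinear"` or `"nearest"`.
#' @param fill value for target pixels whose preimage falls outside `src`.
#' @return numeric matrix of size `target_dim`.
#' @export
warp_image <- function(src, tf, target_dim = dim(src),
                       interp = c("bilinear", "nearest"), fill = NA_real_) {
  interp <- match.arg(interp)
  inv <- invert_transform(tf)
  H <- target_dim[1]; W <- target_dim[2]
  q <- rbind(rep(0:(H - 1), times = W), rep(0:(W - 1), each = H))
  p <- transform_points(inv, q)
  v <- if (interp == "bilinear") sample_bilinear(src, p[1, ], p[2, ], fill)
       else sample_nearest(src, p[1, ], p[2, ], fill)
  matrix(v, H, W)
}

#' Warp a binary mask between section coordinate frames
#'
#' Nearest-neighbor resampling so the mask stays binary; target pixels
#' mapped from outside the source are `FALSE`.
#'
#' @param mask logical matrix.
#' @param tf `affine2d` transform, mask (source) -> target coordinates.
#' @param target_dim integer length-2 (rows, cols); defaults to `dim(mask)`.
#' @return logical matrix of size `target_dim`.
#' @export
warp_mask <- function(mask, tf, target_dim = dim(mask)) {
  w <- warp_image(mask * 1, tf, target_dim, interp = "nearest", fill = 0)
  w > 0.5
}

#' Total optical density of an RGB tile
#'
#' Sum of the three channel ODs; the stain-agnostic tissue-density map
#' used as the registration similarity channel.
#'
#' @param img H x W x 3 8-bit RGB array.
#' @return numeric matrix.
#' @export
total_od <- function(img) {
  od <- rgb_to_od(img)
  od[, , 1] + od[, , 2] + od[, , 3]
}

#' @keywords internal
ncc <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 32L) return(-Inf)
  a <- a[ok]; b <- b[ok]
  a <- a - mean(a); b <- b - mean(b)
  d <- sqrt(sum(a^2) * sum(b^2))
  if (d <= 0) return(-Inf)
  sum(a * b) / d
}

#' @keywords internal
downsample2 <- function(m) {
  H <- 2L * (nrow(m) %/% 2L); W <- 2L * (ncol(m) %/% 2L)
  m <- m[seq_len(H), seq_len(W)]
  0.25 * (m[seq(1, H, 2), seq(1, W, 2)] + m[seq(2, H, 2), seq(1, W, 2)] +
          m[seq(1, H, 2), seq(2, W, 2)] + m[seq(2, H, 2), seq(2, W, 2)])
}

# Map a full-resolution transform into pyramid-level coordinates
# (level pixel i covers full-res pixels k*i .. k*i+k-1, center k*i+(k-1)/2).
#' @keywords internal
transform_at_level <- function(tf, k) {
  if (k == 1) return(tf)
  D <- affine_transform(cbind(k * diag(2), c((k - 1) / 2, (k - 1) / 2)))
  compose_transforms(invert_transform(D), compose_transforms(tf, D))
}

#' @keywords internal
params_to_transform <- function(par, model, center) {
  switch(model,
    translation = similarity_transform(translation = par[1:2], center = center),
    rigid = similarity_transform(translation = par[1:2], rotation_deg = par[3],
                                 center = center),
    similarity = similarity_transform(translation = par[1:2],
                                      rotation_deg = par[3],
                                      scale = exp(par[4]), center = center),
    affine = affine_transform(matrix(par, 2L, 3L)))
}

#' Register two serial-section tiles
#'
#' Finds the transform (IHC/moving coordinates -> ISH/fixed coordinates)
#' maximizing the normalized cross-correlation (NCC) of the two total-OD
#' maps. The search is a coarse-to-fine image pyramid: a deterministic
#' multi-start grid over rotations, scales and integer shifts at the
#' coarsest level, followed by Nelder-Mead refinement at every level. No
#' randomness is involved, so results are reproducible by construction.
#'
#' @param moving,fixed H x W x 3 8-bit RGB arrays (the IHC and ISH tiles).
#' @param model transform family: `"translation"`, `"rigid"`,
#'   `"similarity"` (default: translation + rotation + isotropic scale) or
#'   `"affine"`.
#' @param n_levels pyramid levels (>= 3; level k downsamples by 2^(k-1)).
#' @param max_shift largest translation searched, full-resolution pixels.
#' @param rot_grid rotation starts in degrees (ignored for translation).
#' @param scale_grid scale starts (similarity/affine only).
#' @return object of class `registration_result`: list with `transform`
#'   (`affine2d`), `similarity_final` and `similarity_init` (NCC at the
#'   optimum / at the identity), `n_levels`, `model`, `converged`.
#' @export
register_sections <- function(moving, fixed, model = c("similarity",
                              "translation", "rigid", "affine"),
                              n_levels = 3L, max_shift = 24,
                              rot_grid = seq(-6, 6, by = 2),
                              scale_grid = c(0.95, 1, 1.05)) {
  model <- match.arg(model)
  mv <- total_od(moving); fx <- total_od(fixed)
  if (max(mv) < 0.1 || max(fx) < 0.1) stop("no tissue signal")
  n_levels <- max(3L, as.integer(n_levels))
  center <- (dim(fx) - 1) / 2

  pyr_m <- list(mv); pyr_f <- list(fx)
  for (l in seq_len(n_levels - 1L)) {
    pyr_m[[l + 1L]] <- downsample2(pyr_m[[l]])
    pyr_f[[l + 1L]] <- downsample2(pyr_f[[l]])
  }

  obj <- function(par, mod, m_img, f_img, k) {
    tf <- tryCatch(params_to_transform(par, mod, center), error = function(e) NULL)
    if (is.null(tf)) return(1)   # singular candidate: worst score
    w <- warp_image(m_img, transform_at_level(tf, k), dim(f_img))
    s <- ncc(w, f_img)
    if (!is.finite(s)) 1 else -s
  }

  # --- coarse multi-start: rotation x scale grid + exhaustive integer shift
  kc <- 2L^(n_levels - 1L)
  mc <- pyr_m[[n_levels]]; fc <- pyr_f[[n_levels]]
  smax <- max(1L, ceiling(max_shift / kc))
  rots <- if (model == "translation") 0 else rot_grid
  scls <- if (model %in% c("similarity", "affine")) scale_grid else 1
  best <- list(score = -Inf, par = c(0, 0, 0, 0))
  for (s in scls) for (th in rots) {
    w <- warp_image(mc, transform_at_level(
      similarity_transform(rotation_deg = th, scale = s, center = center), kc),
      dim(fc))
    for (di in -smax:smax) for (dj in -smax:smax) {
      # shift w by (di, dj) in the fixed frame via index overlap
      ri_w <- max(1, 1 - di):min(nrow(fc), nrow(fc) - di)
      ci_w <- max(1, 1 - dj):min(ncol(fc), ncol(fc) - dj)
      sc <- ncc(w[ri_w, ci_w], fc[ri_w + di, ci_w + dj])
      if (sc > best$score) best <- list(score = sc, par = c(di * kc, dj * kc, th, log(s)))
    }
  }

  npar <- switch(model, translation = 2L, rigid = 3L, similarity = 4L, affine = 4L)
  par <- best$par[seq_len(npar)]

  # --- refine coarse-to-fine (similarity parameterization)
  mod <- if (model == "affine") "similarity" else model
  for (l in n_levels:1) {
    k <- 2L^(l - 1L)
    passes <- if (l == n_levels) 2L else 1L
    for (pass in seq_len(passes)) {
      op <- stats::optim(par, obj, mod = mod, m_img = pyr_m[[l]],
                         f_img = pyr_f[[l]], k = k, method = "Nelder-Mead",
                         control = list(maxit = if (l == 1L) 250 else 400,
                                        reltol = 1e-9,
                                        parscale = c(2, 2, 0.5, 0.02)[seq_len(npar)]))
      par <- op$par
    }
  }

  if (model == "affine") {
    a0 <- as.numeric(params_to_transform(par, "similarity", center))
    op <- stats::optim(a0, obj, mod = "affine", m_img = pyr_m[[1]],
                       f_img = pyr_f[[1]], k = 1L, method = "Nelder-Mead",
                       control = list(maxit = 1000, reltol = 1e-10,
                                      parscale = c(0.01, 0.01, 0.01, 0.01, 2, 2)))
    tf <- params_to_transform(op$par, "affine", center)
    final <- -op$value
  } else {
    tf <- params_to_transform(par, mod, center)
    final <- -obj(par, mod, pyr_m[[1]], pyr_f[[1]], 1L)
  }

  init <- ncc(mv, fx)
  if (final < init) {  # never return worse than the unaligned overlap
    tf <- identity_transform()
    final <- init
  }
  structure(list(transform = tf, similarity_final = final,
                 similarity_init = init, n_levels = n_levels, model = model,
                 converged = is.finite(final) && final >= init),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  p <- transform_params(x$transform, c(0, 0))
  cat(sprintf("<registration_result> model=%s NCC %.4f (init %.4f), %d levels\n",
              x$model, x$similarity_final, x$similarity_init, x$n_levels))
  print(x$transform)
  invisible(x)
}
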