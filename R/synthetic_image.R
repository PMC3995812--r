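#' @keywords internal
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# white noise blurred to a correlation length `sigma`, renormalized to sd 1
#' @keywords internal
smooth_noise_field <- function(h, w, sigma) {
  z <- matrix(stats::rnorm(h * w), h, w)
  z <- as.matrix(EBImage::gblur(EBImage::Image(z), sigma = sigma))
  (z - mean(z)) / stats::sd(z)
}

#' Configuration for the synthetic serial-section image generator
#'
#' Describes one simulated pair of serial sections: a cytokeratin IHC tile
#' (brown DAB in the tumor nests + hematoxylin counterstain) and a
#' chromogenic ISH tile (blue NBT/BCIP chromogen in positive patches +
#' nuclear fast red counterstain), the second misaligned relative to the
#' first by a small affine transform as serial sections are on the
#' scanner.
#'
#' @param tile_height,tile_width tile size in pixels (>= 64).
#' @param tumor_fraction nominal fraction of the ROI covered by tumor
#'   nests, in `[0, 1]` (overlapping nests can realize slightly less).
#' @param n_nests number of elliptical tumor nests.
#' @param blue_positive_fraction_stroma,blue_positive_fraction_tumor
#'   fraction of compartment pixels carrying blue chromogen, in `[0, 1]`.
#' @param blue_od_shape,blue_od_scale shape/scale of the per-pixel
#'   Gamma-distributed blue optical density on positive pixels (> 0).
#' @param dab_od_mean mean DAB optical density on tumor pixels (> 0).
#' @param misalignment `affine2d` transform applied to the ISH section
#'   (IHC -> ISH coordinates); `NULL` uses the default small shift plus
#'   rotation about the tile center.
#' @param noise_sd additive RGB noise standard deviation, 8-bit units.
#' @param seed random seed; identical seed + config gives bit-identical
#'   output.
#' @return validated list of class `image_sim_config`.
#' @export
image_sim_config <- function(tile_height = 160L, tile_width = 160L,
                             tumor_fraction = 0.35, n_nests = 6L,
                             blue_positive_fraction_stroma = 0.35,
                             blue_positive_fraction_tumor = 0.05,
                             blue_od_shape = 16, blue_od_scale = 0.028,
                             dab_od_mean = 0.5, misalignment = NULL,
                             noise_sd = 2, seed = 1L) {
  chk_frac <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0 || x > 1) {
      stop(sprintf("invalid config field '%s': must be a fraction in [0, 1]", nm))
    }
  }
  chk_pos <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
      stop(sprintf("invalid config field '%s': must be > 0", nm))
    }
  }
  if (!is.numeric(tile_height) || tile_height < 64) {
    stop("invalid config field 'tile_height': must be >= 64")
  }
  if (!is.numeric(tile_width) || tile_width < 64) {
    stop("invalid config field 'tile_width': must be >= 64")
  }
  chk_frac(tumor_fraction, "tumor_fraction")
  chk_frac(blue_positive_fraction_stroma, "blue_positive_fraction_stroma")
  chk_frac(blue_positive_fraction_tumor, "blue_positive_fraction_tumor")
  chk_pos(blue_od_shape, "blue_od_shape")
  chk_pos(blue_od_scale, "blue_od_scale")
  chk_pos(dab_od_mean, "dab_od_mean")
  if (!is.numeric(n_nests) || n_nests < 0) {
    stop("invalid config field 'n_nests': must be >= 0")
  }
  if (!is.numeric(noise_sd) || noise_sd < 0) {
    stop("invalid config field 'noise_sd': must be >= 0")
  }
  if (is.null(misalignment)) {
    misalignment <- similarity_transform(
      translation = c(6.5, -4.25), rotation_deg = 1.5, scale = 1,
      center = c((tile_height - 1) / 2, (tile_width - 1) / 2))
  }
  if (!inherits(misalignment, "affine2d")) {
    stop("invalid config field 'misalignment': must be an affine2d transform")
  }
  structure(list(
    tile_height = as.integer(tile_height), tile_width = as.integer(tile_width),
    tumor_fraction = tumor_fraction, n_nests = as.integer(n_nests),
    blue_positive_fraction_stroma = blue_positive_fraction_stroma,
    blue_positive_fraction_tumor = blue_positive_fraction_tumor,
    blue_od_shape = blue_od_shape, blue_od_scale = blue_od_scale,
    dab_od_mean = dab_od_mean, misalignment = misalignment,
    noise_sd = noise_sd, seed = as.integer(seed)),
    class = "image_sim_config")
}

#' @keywords internal
render_tile <- function(conc, stains, noise_sd) {
  # conc: named list of concentration matrices matching stain columns
  h <- nrow(conc[[1]]); w <- ncol(conc[[1]])
  od <- array(0, c(h, w, 3))
  m <- unclass(stains)
  for (j in seq_along(conc)) {
    for (ch in 1:3) od[, , ch] <- od[, , ch] + m[ch, j] * conc[[j]]
  }
  img <- od_to_rgb(od)
  if (noise_sd > 0) {
    img <- round(img + array(stats::rnorm(length(img), sd = noise_sd), dim(img)))
    img[img < 0] <- 0; img[img > 255] <- 255
  }
  img
}

#' Simulate a pair of serial-section tiles with known ground truth
#'
#' Draws one tissue scene — an inset rectangular ROI holding elliptical
#' tumor nests in a stromal background, a shared nuclear-counterstain
#' texture, clumpy blue-chromogen patches covering the configured fraction
#' of each compartment with per-pixel Gamma optical densities, and DAB in
#' the nests — then renders the scene twice through Beer-Lambert mixing
#' with the package default stain matrices: once as the IHC section and
#' once, warped by the configured misalignment, as the ISH section.
#' Ground-truth masks and scores are taken from the drawn per-pixel ODs
#' before rendering, so every downstream stage can be validated against
#' them.
#'
#' @param config an [image_sim_config()].
#' @return object of class `synthetic_image_pair`: list with `ihc_image`,
#'   `ish_image` (H x W x 3 8-bit arrays), `roi_mask`, `tumor_mask_true`,
#'   `stroma_mask_true`, `blue_mask_true`, `blue_od_true` (all in
#'   IHC-image coordinates), `misalignment_true`, scalar truths
#'   `tbs_true`, `tbt_true`, `tsa_true`, the full `panel_true`, and
#'   `config`.
#' @export
simulate_image_pair <- function(config = image_sim_config()) {
  if (!inherits(config, "image_sim_config")) {
    stop("config must be an image_sim_config")
  }
  with_seed(config$seed, {
    H <- config$tile_height; W <- config$tile_width
    pad <- 32L
    Hc <- H + 2L * pad; Wc <- W + 2L * pad

    # canvas coordinate grids (0-based, tile frame: canvas - pad)
    rr <- matrix(rep(0:(Hc - 1), Wc), Hc, Wc) - pad
    cc <- matrix(rep(0:(Wc - 1), each = Hc), Hc, Wc) - pad

    # ROI: rectangle inset 12 px from the tile border (tile frame)
    inset <- 12
    roi_canvas <- rr >= inset & rr <= H - 1 - inset &
                  cc >= inset & cc <= W - 1 - inset

    # tumor nests: union of random ellipses inside the ROI
    tumor_canvas <- matrix(FALSE, Hc, Wc)
    if (config$tumor_fraction > 0 && config$n_nests > 0) {
      target <- config$tumor_fraction * sum(roi_canvas)
      wts <- stats::runif(config$n_nests, 0.5, 1.5)
      areas <- target * wts / sum(wts)
      for (i in seq_len(config$n_nests)) {
        q <- stats::runif(1, 0.5, 1)               # axis ratio
        a <- sqrt(areas[i] / (pi * q)); b <- q * a
        phi <- stats::runif(1, 0, pi)
        cr <- stats::runif(1, inset + b, H - 1 - inset - b)
        ccn <- stats::runif(1, inset + b, W - 1 - inset - b)
        u <- (rr - cr) * cos(phi) + (cc - ccn) * sin(phi)
        v <- -(rr - cr) * sin(phi) + (cc - ccn) * cos(phi)
        tumor_canvas <- tumor_canvas | (u^2 / a^2 + v^2 / b^2 <= 1)
      }
      tumor_canvas <- tumor_canvas & roi_canvas
    }
    stroma_canvas <- roi_canvas & !tumor_canvas

    # shared nuclear texture, multi-scale so it survives pyramid smoothing;
    # epithelial nests are cell-dense, so the counterstain is darker there
    # on both sections - this shared structure is what registration locks on
    tex <- 0.30 * smooth_noise_field(Hc, Wc, 1.2) +
           0.30 * smooth_noise_field(Hc, Wc, 2.5) +
           0.25 * smooth_noise_field(Hc, Wc, 8)
    counter <- pmax(0.6 + 0.2 * tumor_canvas + tex, 0.05)

    # clumpy blue-positive patches with exact per-compartment fractions
    patch_set <- function(compartment, frac) {
      if (frac <= 0 || !any(compartment)) return(matrix(FALSE, Hc, Wc))
      g <- smooth_noise_field(Hc, Wc, 5)
      if (frac >= 1) return(compartment)
      thr <- stats::quantile(g[compartment], 1 - frac, names = FALSE)
      g > thr
    }
    pos_s <- patch_set(stroma_canvas, config$blue_positive_fraction_stroma)
    pos_t <- patch_set(tumor_canvas, config$blue_positive_fraction_tumor)
    blue_pos <- (pos_s & !tumor_canvas) | (pos_t & tumor_canvas)

    blue <- matrix(0, Hc, Wc)
    npos <- sum(blue_pos)
    if (npos > 0) {
      blue[blue_pos] <- stats::rgamma(npos, shape = config$blue_od_shape,
                                      scale = config$blue_od_scale)
    }

    dab <- matrix(0, Hc, Wc)
    ntum <- sum(tumor_canvas)
    if (ntum > 0) {
      dab[tumor_canvas] <- stats::rgamma(ntum, shape = 25,
                                         scale = config$dab_od_mean / 25)
    }

    # ground truth on the tile region, in IHC (scene) coordinates
    tile_r <- pad + seq_len(H); tile_c <- pad + seq_len(W)
    roi_mask <- roi_canvas[tile_r, tile_c]
    tumor_mask <- tumor_canvas[tile_r, tile_c]
    stroma_mask <- stroma_canvas[tile_r, tile_c]
    blue_mask_true <- blue_pos[tile_r, tile_c]
    blue_od_true <- blue[tile_r, tile_c]
    comp_true <- build_compartments(roi_mask, tumor_mask)
    panel_true <- compute_scores(blue_od_true, blue_mask_true, comp_true)

    # render the IHC section (scene frame, tile crop)
    ihc <- render_tile(list(dab = dab[tile_r, tile_c],
                            hematoxylin = counter[tile_r, tile_c]),
                       default_stain_matrix("ihc"), config$noise_sd)

    # render the ISH section: scene warped by the misalignment
    inv <- invert_transform(config$misalignment)
    q <- rbind(rep(0:(H - 1), times = W), rep(0:(W - 1), each = H))
    p <- transform_points(inv, q) + pad       # tile frame -> canvas index
    blue_w <- matrix(sample_bilinear(blue, p[1, ], p[2, ], fill = 0), H, W)
    counter_w <- matrix(sample_bilinear(counter, p[1, ], p[2, ], fill = 0), H, W)
    ish <- render_tile(list(blue = blue_w, nuclear_fast_red = counter_w),
                       default_stain_matrix("ish"), config$noise_sd)

    structure(list(
      ihc_image = ihc, ish_image = ish,
      roi_mask = roi_mask, tumor_mask_true = tumor_mask,
      stroma_mask_true = stroma_mask, blue_mask_true = blue_mask_true,
      blue_od_true = blue_od_true,
      misalignment_true = config$misalignment,
      tbs_true = panel_true$tbs, tbt_true = panel_true$tbt,
      tsa_true = panel_true$tsa, panel_true = panel_true,
      config = config), class = "synthetic_image_pair")
  })
}

#' Write a synthetic pair to disk with its ground-truth sidecar
#'
#' Writes `<prefix>_ihc.png`, `<prefix>_ish.png`, the ROI and ground-truth
#' masks as 8-bit PNGs (0 background / 255 foreground) and
#' `<prefix>_truth.json` holding the misalignment, true scores and the
#' generating configuration.
#'
#' @param pair a [simulate_image_pair()] result.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix, e.g. a sample id.
#' @return invisibly, a named list of the written paths.
#' @export
write_image_pair <- function(pair, dir, prefix = "sample") {
  stopifnot(inherits(pair, "synthetic_image_pair"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(s) file.path(dir, paste0(prefix, "_", s))
  write_image_rgb(pair$ihc_image, p("ihc.png"))
  write_image_rgb(pair$ish_image, p("ish.png"))
  write_mask(pair$roi_mask, p("roi.png"))
  write_mask(pair$tumor_mask_true, p("tumor_true.png"))
  write_mask(pair$stroma_mask_true, p("stroma_true.png"))
  cfg <- unclass(pair$config)
  cfg$misalignment <- as.numeric(t(unclass(cfg$misalignment)))
  jsonlite::write_json(list(
    misalignment_row_major = as.numeric(t(unclass(pair$misalignment_true))),
    tbs_true = pair$tbs_true, tbt_true = pair$tbt_true,
    tsa_true = pair$tsa_true, panel_true = unclass(pair$panel_true),
    config = cfg, seed = pair$config$seed),
    p("truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(list(ihc = p("ihc.png"), ish = p("ish.png"), roi = p("roi.png"),
                 truth = p("truth.json")))
}
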