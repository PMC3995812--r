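#' Build ROI / tumor / stroma compartment masks
#'
#' Implements the virtual-double-staining compartment split in the ISH
#' frame: the tumor compartment is the warped cytokeratin (DAB) mask
#' restricted to the region of interest, the stroma is the remainder of
#' the ROI. By construction `tumor` is a subset of `roi`, `stroma` is
#' `roi AND NOT tumor`, the two are disjoint and their union is `roi`.
#'
#' @param roi logical matrix, region of interest (the manually delineated
#'   tumor area) in ISH coordinates.
#' @param dab_mask_warped logical matrix, tumor-epithelium mask after
#'   warping into ISH coordinates.
#' @return object of class `compartment_masks`: list of logical matrices
#'   `roi`, `tumor`, `stroma`.
#' @export
build_compartments <- function(roi, dab_mask_warped) {
  if (!identical(dim(roi), dim(dab_mask_warped))) stop("mask shapes differ")
  roi <- roi & TRUE; dab_mask_warped <- dab_mask_warped & TRUE
  if (!any(roi)) stop("empty ROI")
  tumor <- dab_mask_warped & roi
  structure(list(roi = roi, tumor = tumor, stroma = roi & !tumor),
            class = "compartment_masks")
}

#' Compute the TBS / TBT / TSA score panel
#'
#' The stromal score is
#' `TBS = blue_area_stroma x mean_blue_od_stroma`, i.e. the number of
#' chromogen-positive stromal pixels times their mean blue optical
#' density — algebraically the integrated blue OD over the positive
#' stromal set. `TBT` is the same quantity in the tumor compartment and
#' `TSA` the total stroma area (pixels). "Intensity" is blue-chromogen OD,
#' which is linear in chromogen amount, so the area-times-mean product has
#' a physical meaning (total chromogen). The mean over an empty positive
#' set is defined as 0, hence TBS = 0 exactly when no positive stromal
#' pixel exists.
#'
#' @param blue_od numeric matrix, blue-chromogen OD map (ISH frame).
#' @param blue_mask logical matrix, chromogen-positive pixels.
#' @param comp a [build_compartments()] result in the same frame.
#' @return object of class `score_panel`: list with `blue_area_stroma`,
#'   `mean_blue_od_stroma`, `tbs`, `blue_area_tumor`, `mean_blue_od_tumor`,
#'   `tbt`, `tsa`, `negative_stroma_area`.
#' @export
compute_scores <- function(blue_od, blue_mask, comp) {
  if (!identical(dim(blue_od), dim(blue_mask)) ||
      !identical(dim(blue_od), dim(comp$roi))) stop("shape mismatch")
  one <- function(mask) {
    pos <- blue_mask & mask
    area <- sum(pos)
    m <- if (area > 0) mean(blue_od[pos]) else 0
    list(area = area, mean = m)
  }
  s <- one(comp$stroma); t <- one(comp$tumor)
  tsa <- sum(comp$stroma)
  structure(list(
    blue_area_stroma = s$area, mean_blue_od_stroma = s$mean,
    tbs = s$area * s$mean,
    blue_area_tumor = t$area, mean_blue_od_tumor = t$mean,
    tbt = t$area * t$mean,
    tsa = tsa, negative_stroma_area = tsa - s$area),
    class = "score_panel")
}

#' @export
print.score_panel <- function(x, ...) {
  cat(sprintf(paste0("<score_panel>\n  TBS %.2f (area %d x mean OD %.4f)\n",
                     "  TBT %.2f (area %d x mean OD %.4f)\n",
                     "  TSA %d px (negative stroma %d px)\n"),
              x$tbs, x$blue_area_stroma, x$mean_blue_od_stroma,
              x$tbt, x$blue_area_tumor, x$mean_blue_od_tumor,
              x$tsa, x$negative_stroma_area))
  invisible(x)
}

#' Overlap statistics between two binary masks
#'
#' Dice coefficient `2|a n b| / (|a| + |b|)` plus the two containment
#' fractions. Conventions: Dice of two empty masks is 0; a containment
#' fraction with an empty reference is 0.
#'
#' @param a,b logical matrices of equal shape.
#' @return list with `dice`, `a_in_b`, `b_in_a`.
#' @export
mask_overlap <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("shape mismatch")
  na <- sum(a); nb <- sum(b); ni <- sum(a & b)
  list(dice = if (na + nb > 0) 2 * ni / (na + nb) else 0,
       a_in_b = if (na > 0) ni / na else 0,
       b_in_a = if (nb > 0) ni / nb else 0)
}
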