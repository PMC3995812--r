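#' Score one sample: virtual double staining end to end
#'
#' Chains the per-sample steps: unmix the IHC tile and threshold the DAB
#' map into a tumor-epithelium mask; register the IHC tile onto the ISH
#' tile; warp the DAB mask (and the ROI, when drawn on the IHC section)
#' into ISH coordinates; unmix the ISH tile and threshold the blue
#' chromogen; build the ROI/tumor/stroma compartments and compute the
#' TBS/TBT/TSA panel. Entirely deterministic.
#'
#' @param ihc,ish H x W x 3 8-bit RGB arrays (cytokeratin IHC and
#'   chromogenic ISH serial sections).
#' @param roi optional logical matrix delineating the tumor area; `NULL`
#'   uses the whole tile.
#' @param roi_frame `"ihc"` (default: the ROI is drawn on the IHC section
#'   and is warped along with the tumor mask) or `"ish"`.
#' @param stains_ihc,stains_ish stain matrices; package defaults when
#'   `NULL`.
#' @param threshold_method `"otsu"` or `"fixed"` for both chromogens.
#' @param dab_threshold,blue_threshold fixed OD thresholds when
#'   `threshold_method = "fixed"`.
#' @param registration_model transform family for [register_sections()].
#' @param min_object_area if > 0, connected chromogen components smaller
#'   than this many pixels are removed (no cleanup by default).
#' @return list with `scores` (a `score_panel`), `registration`,
#'   `thresholds` (named OD values), `masks` (blue/tumor/compartments in
#'   ISH coordinates).
#' @export
score_sample <- function(ihc, ish, roi = NULL, roi_frame = c("ihc", "ish"),
                         stains_ihc = NULL, stains_ish = NULL,
                         threshold_method = c("otsu", "fixed"),
                         dab_threshold = NULL, blue_threshold = NULL,
                         registration_model = "similarity",
                         min_object_area = 0) {
  roi_frame <- match.arg(roi_frame)
  threshold_method <- match.arg(threshold_method)
  if (is.null(stains_ihc)) stains_ihc <- default_stain_matrix("ihc")
  if (is.null(stains_ish)) stains_ish <- default_stain_matrix("ish")

  ihc_maps <- unmix(rgb_to_od(ihc), stains_ihc)
  dab_mask <- threshold_stain(ihc_maps[[1]], threshold_method,
                              fixed_value = dab_threshold)

  reg <- register_sections(ihc, ish, model = registration_model)
  target <- dim(ish)[1:2]
  dab_warped <- warp_mask(dab_mask, reg$transform, target)

  if (is.null(roi)) {
    roi_ish <- matrix(TRUE, target[1], target[2])
  } else if (roi_frame == "ihc") {
    roi_ish <- warp_mask(roi, reg$transform, target)
  } else {
    roi_ish <- roi
  }

  ish_maps <- unmix(rgb_to_od(ish), stains_ish)
  blue_mask <- threshold_stain(ish_maps[[1]], threshold_method,
                               fixed_value = blue_threshold)
  if (min_object_area > 0) {
    lab <- EBImage::bwlabel(EBImage::Image(blue_mask * 1))
    sz <- table(lab[lab > 0])
    small <- as.integer(names(sz)[sz < min_object_area])
    blue_mask <- structure(blue_mask & !(as.matrix(lab) %in% small),
                           threshold = attr(blue_mask, "threshold"),
                           method = attr(blue_mask, "method"),
                           dim = dim(blue_mask))
  }

  comp <- build_compartments(roi_ish, dab_warped)
  scores <- compute_scores(ish_maps[[1]], blue_mask, comp)
  list(scores = scores, registration = reg,
       thresholds = c(dab = attr(dab_mask, "threshold"),
                      blue = attr(blue_mask, "threshold")),
       masks = list(blue = blue_mask, tumor = comp$tumor,
                    stroma = comp$stroma, roi = roi_ish))
}

#' Score a batch of samples from a manifest
#'
#' Runs [score_sample()] for every manifest row. Failures are isolated
#' per sample: the error is recorded and the run continues, since batch
#' slide processing routinely hits bad files. Deterministic given the
#' manifest and settings.
#'
#' @param manifest `data.frame` with columns `sample_id`, `ihc_path`,
#'   `ish_path` and optionally `roi_path` (empty/NA = whole tile).
#' @param out_csv optional path: write the score table as CSV.
#' @param ... passed to [score_sample()].
#' @return list with `scores` (`data.frame`, one row per succeeded
#'   sample: panel fields plus `threshold_dab`, `threshold_blue`,
#'   `registration_score`) and `failures` (`data.frame` of `sample_id`,
#'   `error`).
#' @export
run_score_batch <- function(manifest, out_csv = NULL, ...) {
  need <- c("sample_id", "ihc_path", "ish_path")
  if (!all(need %in% names(manifest))) {
    stop("manifest needs columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(manifest$sample_id)) stop("duplicated sample_id in manifest")
  rows <- list(); fails <- list()
  for (i in seq_len(nrow(manifest))) {
    sid <- manifest$sample_id[i]
    res <- tryCatch({
      ihc <- read_image_rgb(manifest$ihc_path[i])
      ish <- read_image_rgb(manifest$ish_path[i])
      roi <- NULL
      if ("roi_path" %in% names(manifest) && !is.na(manifest$roi_path[i]) &&
          nzchar(manifest$roi_path[i])) {
        roi <- read_mask(manifest$roi_path[i])
      }
      s <- score_sample(ihc, ish, roi = roi, ...)
      data.frame(sample_id = sid,
                 tbs = s$scores$tbs, tbt = s$scores$tbt, tsa = s$scores$tsa,
                 blue_area_stroma = s$scores$blue_area_stroma,
                 mean_blue_od_stroma = s$scores$mean_blue_od_stroma,
                 blue_area_tumor = s$scores$blue_area_tumor,
                 mean_blue_od_tumor = s$scores$mean_blue_od_tumor,
                 threshold_dab = unname(s$thresholds["dab"]),
                 threshold_blue = unname(s$thresholds["blue"]),
                 registration_score = s$registration$similarity_final,
                 stringsAsFactors = FALSE)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      fails[[length(fails) + 1L]] <- data.frame(sample_id = sid,
                                                error = conditionMessage(res),
                                                stringsAsFactors = FALSE)
    } else {
      rows[[length(rows) + 1L]] <- res
    }
  }
  if (length(rows) == 0L) {
    stop("all samples failed (", length(fails), " failures); first error: ",
         fails[[1]]$error)
  }
  scores <- do.call(rbind, rows)
  failures <- if (length(fails)) do.call(rbind, fails) else
    data.frame(sample_id = character(0), error = character(0))
  if (!is.null(out_csv)) write_scores_csv(scores, out_csv)
  list(scores = scores, failures = failures)
}

#' Run the survival workflow on measured scores plus clinical data
#'
#' Joins the per-sample scores onto the clinical table (1:1 on
#' `sample_id` = `patient_id`), assigns score tertiles, runs the Spearman
#' screen, univariate Cox models over every clinical variable present,
#' the backward-eliminated multivariate model (candidates: variables with
#' univariate score-test p below `candidate_alpha`, with the score
#' entering as the per-tertile-step term), PH diagnostics on the final
#' model, and tertile survival curves with the log-rank test.
#'
#' @param scores `data.frame` with `sample_id` and the score column, or
#'   `NULL` to use a score column already present in `clinical`.
#' @param clinical clinical `data.frame` (see [simulate_cohort()]).
#' @param score_column score used for tertiles (default `"tbs"`).
#' @param candidate_alpha univariate significance level feeding the
#'   multivariate candidate set.
#' @param removal_alpha backward-elimination removal threshold.
#' @param out_dir optional directory: writes `univariate.csv`,
#'   `multivariate.csv`, `curves.csv` and `bundle.json`.
#' @return list with `cohort` (joined table incl. `score_tertile`),
#'   `tertiles`, `spearman`, `univariate` (`data.frame`),
#'   `univariate_fits`, `multivariate` (fit + trace), `ph`, `curves`.
#' @export
run_survival <- function(scores, clinical, score_column = "tbs",
                         candidate_alpha = 0.05, removal_alpha = 0.10,
                         out_dir = NULL) {
  d <- clinical
  if (!is.null(scores)) {
    orphans_s <- setdiff(scores$sample_id, clinical$patient_id)
    orphans_c <- setdiff(clinical$patient_id, scores$sample_id)
    if (length(orphans_s) || length(orphans_c)) {
      stop("score/clinical id mismatch; orphaned ids: ",
           paste(c(orphans_s, orphans_c), collapse = ", "))
    }
    d[[score_column]] <-
      scores[[score_column]][match(d$patient_id, scores$sample_id)]
  }
  if (sum(d$event) == 0L) stop("no events")

  tert <- assign_tertiles(d[[score_column]], d$patient_id)
  d$score_tertile <- tert$index            # numeric per-step term
  d$score_tertile_f <- tert$label          # factor for univariate/curves

  clin_vars <- intersect(c("age", "gender", "site", "t_status", "n_status",
                           "stage", "grade", "perineural", "margin",
                           "pack_years", "treatment"), names(d))
  spear <- spearman_screen(d, score_column,
                           variables = setdiff(clin_vars, score_column))

  uni_vars <- c(clin_vars, "score_tertile_f")
  fits <- lapply(uni_vars, function(v)
    tryCatch(cox_univariate(d, v), error = function(e) NULL))
  names(fits) <- uni_vars
  uni <- do.call(rbind, lapply(uni_vars, function(v) {
    f <- fits[[v]]
    if (is.null(f)) return(NULL)
    data.frame(variable = v, level = f$variables, hr = unname(f$hr),
               ci_lower = unname(f$ci_lower), ci_upper = unname(f$ci_upper),
               wald_p = unname(f$p), score_p = f$score_p,
               logrank_p = f$logrank_p, stringsAsFactors = FALSE)
  }))

  term_p <- vapply(fits, function(f) if (is.null(f)) NA_real_ else f$score_p,
                   numeric(1))
  candidates <- names(term_p)[!is.na(term_p) & term_p < candidate_alpha]
  candidates <- sub("^score_tertile_f$", "score_tertile", candidates)
  multi <- if (length(candidates)) {
    cox_multivariate_backward(d, candidates, removal_alpha = removal_alpha)
  } else NULL

  ph <- if (!is.null(multi) && !is.null(multi$fit)) ph_test(multi$fit) else NULL
  curves <- survival_curves(d, tert)

  bundle <- list(cohort = d, tertiles = tert, spearman = spear,
                 univariate = uni, univariate_fits = fits,
                 multivariate = multi, ph = ph, curves = curves)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(uni, file.path(out_dir, "univariate.csv"),
                     row.names = FALSE)
    if (!is.null(multi) && !is.null(multi$fit)) {
      mf <- multi$fit
      utils::write.csv(data.frame(variable = mf$variables, hr = unname(mf$hr),
                                  ci_lower = unname(mf$ci_lower),
                                  ci_upper = unname(mf$ci_upper),
                                  wald_p = unname(mf$p)),
                       file.path(out_dir, "multivariate.csv"),
                       row.names = FALSE)
    }
    utils::write.csv(curves$km_curves, file.path(out_dir, "curves.csv"),
                     row.names = FALSE)
    json <- list(
      tertile_sizes = tert$sizes, spearman = spear, univariate = uni,
      multivariate = if (!is.null(multi) && !is.null(multi$fit)) list(
        retained = multi$retained, hr = as.list(multi$fit$hr),
        ci_lower = as.list(multi$fit$ci_lower),
        ci_upper = as.list(multi$fit$ci_upper), p = as.list(multi$fit$p),
        trace = multi$trace, ties = multi$fit$ties) else NULL,
      ph = ph,
      logrank = list(chisq = curves$logrank_chisq, df = curves$logrank_df,
                     p = curves$logrank_p))
    jsonlite::write_json(json, file.path(out_dir, "bundle.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  bundle
}
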