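#' Apply the cohort selection filter
#'
#' Keeps manifest rows whose exclusion reason is `"none"` and reports the
#' count of each exclusion reason.
#'
#' @param manifest `data.frame` with one row per selected case and a
#'   `reason` column with values in `none`, `misclassified`,
#'   `insufficient_material`, `poor_quality`.
#' @return list with `cohort` (retained rows), `exclusions` (named counts
#'   per reason), `n_selected`, `n_retained`.
#' @export
filter_cohort <- function(manifest) {
  if (!is.data.frame(manifest) || nrow(manifest) == 0L) stop("empty cohort")
  if (!"reason" %in% names(manifest)) stop("manifest needs a 'reason' column")
  allowed <- c("none", "misclassified", "insufficient_material", "poor_quality")
  bad <- setdiff(unique(manifest$reason), allowed)
  if (length(bad)) stop("unknown exclusion reason: ", paste(bad, collapse = ", "))
  keep <- manifest$reason == "none"
  excl <- table(factor(manifest$reason[!keep], levels = allowed[-1]))
  list(cohort = manifest[keep, , drop = FALSE],
       exclusions = stats::setNames(as.integer(excl), names(excl)),
       n_selected = nrow(manifest), n_retained = sum(keep))
}

#' Split a score into tertiles
#'
#' Patients are sorted by score (ties broken by patient id), the first
#' `ceiling(n/3)` ranks form the lower tertile and the last `ceiling(n/3)`
#' the upper; the remainder is the middle tertile. For n = 86 this yields
#' the 29 / 28 / 29 split used for the stromal score.
#'
#' @param values numeric score per patient.
#' @param ids tie-breaking identifiers (defaults to input order).
#' @return object of class `tertile_assignment`: list with `index`
#'   (integer 0 = lower, 1 = middle, 2 = upper, in input order), `label`
#'   (factor lower/middle/upper), `sizes`, `cut_ranks`.
#' @export
assign_tertiles <- function(values, ids = seq_along(values)) {
  n <- length(values)
  if (n < 3L) stop("at least 3 values required for tertiles")
  if (any(!is.finite(values))) stop("scores must be finite")
  ord <- order(values, ids)
  k <- ceiling(n / 3)
  idx_sorted <- c(rep(0L, k), rep(1L, n - 2L * k), rep(2L, k))
  index <- integer(n)
  index[ord] <- idx_sorted
  label <- factor(c("lower", "middle", "upper")[index + 1L],
                  levels = c("lower", "middle", "upper"))
  structure(list(index = index, label = label,
                 sizes = as.integer(table(label)),
                 cut_ranks = c(k, n - k)),
            class = "tertile_assignment")
}

#' Spearman screen of clinical variables against a score
#'
#' Rank correlation (average ranks for ties) of each variable with the
#' score; two-sided p-values from the t approximation. Categorical
#' variables enter as their level codes. A constant variable has no
#' defined correlation and is reported as `NA` with a warning.
#'
#' @param cohort clinical `data.frame`.
#' @param score_column name of the score column (default `"tbs"`).
#' @param variables character vector of column names to screen.
#' @return `data.frame` with `variable`, `n`, `rho`, `p`.
#' @export
spearman_screen <- function(cohort, score_column = "tbs",
                            variables = setdiff(names(cohort),
                              c("patient_id", score_column,
                                "time_to_recurrence", "event"))) {
  s <- cohort[[score_column]]
  if (is.null(s)) stop("score column not found: ", score_column)
  rows <- lapply(variables, function(v) {
    x <- cohort[[v]]
    if (is.null(x)) stop("variable not found: ", v)
    if (is.character(x)) x <- factor(x)
    if (is.factor(x)) x <- as.integer(x)
    ok <- is.finite(x) & is.finite(s)
    if (sum(ok) < 4L) stop("fewer than 4 complete pairs for ", v)
    if (length(unique(x[ok])) < 2L) {
      warning("constant variable '", v, "': Spearman correlation undefined")
      return(data.frame(variable = v, n = sum(ok), rho = NA_real_, p = NA_real_))
    }
    ct <- suppressWarnings(stats::cor.test(s[ok], x[ok], method = "spearman",
                                           exact = FALSE))
    data.frame(variable = v, n = sum(ok), rho = unname(ct$estimate),
               p = ct$p.value)
  })
  do.call(rbind, rows)
}

#' @keywords internal
surv_formula <- function(terms) {
  stats::as.formula(paste("survival::Surv(time_to_recurrence, event) ~",
                          paste(terms, collapse = " + ")))
}

#' @keywords internal
prep_model_data <- function(cohort) {
  d <- cohort
  for (v in names(d)) if (is.character(d[[v]])) {
    lev <- unique(d[[v]])
    # reference level first: use the package's conventional orderings
    pref <- c("male", "tongue", "T1-2", "N0", "I-II", "well_moderate", "no",
              "clear", "surgery", "lower")
    d[[v]] <- factor(d[[v]], levels = c(intersect(pref, lev),
                                        setdiff(sort(lev), pref)))
  }
  d
}

#' @keywords internal
cox_fit_object <- function(fit, data, ties, logrank_p = NA_real_) {
  s <- summary(fit)
  co <- s$coefficients
  ci <- s$conf.int
  flags <- character(0)
  if (any(abs(co[, "coef"]) > 15)) {
    flags <- c(flags, "possible monotone likelihood / complete separation")
  }
  structure(list(
    variables = rownames(co),
    coef = stats::setNames(co[, "coef"], rownames(co)),
    hr = stats::setNames(ci[, "exp(coef)"], rownames(co)),
    ci_lower = stats::setNames(ci[, 3], rownames(co)),
    ci_upper = stats::setNames(ci[, 4], rownames(co)),
    p = stats::setNames(co[, "Pr(>|z|)"], rownames(co)),
    score_p = unname(s$sctest["pvalue"]),
    logrank_p = logrank_p,
    ties = ties, n = s$n, n_events = unname(s$nevent),
    converged = length(flags) == 0L,
    flags = flags, fit = fit, data = data), class = "cox_fit")
}

#' Univariate Cox proportional-hazards fit
#'
#' Maximizes the Cox partial likelihood for a single covariate (Efron tie
#' handling by default, Breslow available to mirror SPSS output).
#' Categorical variables enter with their first level as reference; one
#' hazard ratio with Wald 95% CI and p-value is reported per
#' non-reference level, plus the overall score test and, for categorical
#' variables, the log-rank p. Levels without events and monotone
#' likelihoods are flagged rather than dropped silently.
#'
#' @param cohort clinical `data.frame` with `time_to_recurrence` and
#'   `event`.
#' @param variable column name.
#' @param ties `"efron"` or `"breslow"`.
#' @return object of class `cox_fit`.
#' @export
cox_univariate <- function(cohort, variable, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  if (!variable %in% names(cohort)) stop("variable not found: ", variable)
  if (sum(cohort$event) == 0L) stop("no events")
  d <- prep_model_data(cohort)
  x <- d[[variable]]
  if (length(unique(x)) < 2L) stop("variable has fewer than 2 distinct values")
  fit <- survival::coxph(surv_formula(variable), data = d, ties = ties, x = TRUE)
  lr <- NA_real_
  flags <- character(0)
  if (is.factor(x)) {
    ev <- tapply(d$event, x, sum)
    if (any(ev == 0, na.rm = TRUE)) {
      flags <- "level with zero events: estimate unstable"
    }
    sd_ <- survival::survdiff(surv_formula(variable), data = d)
    lr <- stats::pchisq(sd_$chisq, length(sd_$n) - 1, lower.tail = FALSE)
  }
  out <- cox_fit_object(fit, d, ties, logrank_p = lr)
  out$flags <- c(out$flags, flags)
  out$converged <- out$converged && !length(flags)
  out
}

#' Multivariate Cox model with backward elimination
#'
#' Fits all candidate variables jointly, then iteratively removes the
#' variable with the largest Wald p-value at or above `removal_alpha`
#' (multi-degree-of-freedom Wald test for factors), refitting until every
#' remaining variable is below the threshold. The default threshold is
#' 0.10 rather than 0.05 so that borderline factors (p just below 0.10)
#' survive, matching how published backward-eliminated models commonly
#' retain borderline terms.
#'
#' @param cohort clinical `data.frame`.
#' @param candidate_variables character vector of column names entering
#'   the full model.
#' @param removal_alpha removal threshold on the Wald p-value.
#' @param ties `"efron"` or `"breslow"`.
#' @return list with `fit` (final `cox_fit`, or `NULL` if every candidate
#'   was eliminated), `retained`, and `trace` (`data.frame` of removal
#'   steps with the p-value at removal).
#' @export
cox_multivariate_backward <- function(cohort, candidate_variables,
                                      removal_alpha = 0.10,
                                      ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  if (length(candidate_variables) == 0L) stop("empty candidate set")
  miss <- setdiff(candidate_variables, names(cohort))
  if (length(miss)) stop("candidates not in cohort: ", paste(miss, collapse = ", "))
  if (sum(cohort$event) == 0L) stop("no events")
  d <- prep_model_data(cohort)
  terms <- candidate_variables
  trace <- data.frame(step = integer(0), removed = character(0),
                      p = numeric(0), stringsAsFactors = FALSE)
  step <- 0L
  repeat {
    fit <- survival::coxph(surv_formula(terms), data = d, ties = ties, x = TRUE)
    pt <- term_wald_p(fit, terms, d)
    worst <- which.max(pt)
    if (pt[worst] < removal_alpha) break
    step <- step + 1L
    trace <- rbind(trace, data.frame(step = step, removed = terms[worst],
                                     p = unname(pt[worst])))
    terms <- terms[-worst]
    if (length(terms) == 0L) {
      return(list(fit = NULL, retained = character(0), trace = trace))
    }
  }
  list(fit = cox_fit_object(fit, d, ties), retained = terms, trace = trace)
}

# per-term Wald p-values (chi-square on all coefficients of the term)
#' @keywords internal
term_wald_p <- function(fit, terms, data) {
  asg <- fit$assign
  b <- stats::coef(fit)
  V <- stats::vcov(fit)
  vapply(seq_along(terms), function(i) {
    j <- asg[[i]]
    bi <- b[j]
    stat <- as.numeric(t(bi) %*% solve(V[j, j, drop = FALSE]) %*% bi)
    stats::pchisq(stat, df = length(j), lower.tail = FALSE)
  }, numeric(1), USE.NAMES = FALSE) -> p
  stats::setNames(p, terms)
}

#' Proportional-hazards diagnostic from scaled Schoenfeld residuals
#'
#' For each model variable, the scaled Schoenfeld residuals are
#' correlated with the (untransformed) event times; a non-zero
#' correlation indicates a time-varying coefficient, i.e. a violation of
#' the proportional-hazards assumption. Two-sided p-values come from the
#' t-test on the Pearson correlation; `pass` flags variables at
#' `alpha = 0.05`.
#'
#' @param fit a `cox_fit` from [cox_univariate()] or the backward model.
#' @param alpha significance level for the pass flag.
#' @return `data.frame` with `variable`, `rho`, `p`, `pass`, plus
#'   attribute `n_events`.
#' @export
ph_test <- function(fit, alpha = 0.05) {
  if (!inherits(fit, "cox_fit")) stop("fit must be a cox_fit")
  sfit <- fit$fit
  if (sfit$nevent < 3L) stop("fewer than 3 events: PH test undefined")
  res <- stats::residuals(sfit, type = "scaledsch")
  if (is.null(dim(res))) res <- matrix(res, ncol = 1,
                                       dimnames = list(names(res), fit$variables[1]))
  times <- as.numeric(rownames(res))
  rows <- lapply(seq_len(ncol(res)), function(j) {
    ct <- stats::cor.test(res[, j], times, method = "pearson")
    data.frame(variable = colnames(res)[j], rho = unname(ct$estimate),
               p = ct$p.value, pass = ct$p.value >= alpha)
  })
  out <- do.call(rbind, rows)
  attr(out, "n_events") <- nrow(res)
  out
}

#' Survival curves and log-rank test by group
#'
#' Cox-regression survival curves (Breslow baseline cumulative hazard
#' from a fit on the group indicators, raised to `exp(beta_g)` per group)
#' together with Kaplan-Meier curves and the k-group log-rank test.
#'
#' @param cohort clinical `data.frame` with `time_to_recurrence`, `event`.
#' @param group a [assign_tertiles()] result or a factor/vector with one
#'   group label per patient.
#' @return list with `cox_curves` and `km_curves` (`data.frame`s of
#'   `time`, `survival`, `n_risk`, `group`), `logrank_chisq`,
#'   `logrank_df`, `logrank_p`, and the underlying `cox_fit`.
#' @export
survival_curves <- function(cohort, group) {
  g <- if (inherits(group, "tertile_assignment")) group$label else factor(group)
  if (length(g) != nrow(cohort)) stop("group length must match cohort rows")
  g <- droplevels(g)
  if (nlevels(g) < 2L) stop("at least 2 groups required")
  ev_by_g <- tapply(cohort$event, g, sum)
  if (sum(ev_by_g > 0) < 2L) stop("at least 2 groups with events required")
  d <- cohort
  d$.group <- g
  fit <- survival::coxph(surv_formula(".group"), data = d, ties = "breslow", x = TRUE)
  bh <- survival::basehaz(fit, centered = FALSE)
  betas <- c(0, stats::coef(fit))
  names(betas) <- levels(g)
  cox_curves <- do.call(rbind, lapply(levels(g), function(l) {
    data.frame(time = bh$time,
               survival = exp(-bh$hazard * exp(betas[[l]])),
               group = l, stringsAsFactors = FALSE)
  }))
  km <- survival::survfit(surv_formula(".group"), data = d)
  km_curves <- data.frame(
    time = km$time, survival = km$surv, n_risk = km$n.risk,
    group = rep(sub("^\\.group=", "", names(km$strata)), km$strata),
    stringsAsFactors = FALSE)
  sd_ <- survival::survdiff(surv_formula(".group"), data = d)
  df <- length(sd_$n) - 1
  list(cox_curves = cox_curves, km_curves = km_curves,
       logrank_chisq = unname(sd_$chisq), logrank_df = df,
       logrank_p = stats::pchisq(sd_$chisq, df, lower.tail = FALSE),
       fit = cox_fit_object(fit, d, "breslow"))
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("<cox_fit> n=%d events=%d ties=%s%s\n", x$n, x$n_events, x$ties,
              if (x$converged) "" else "  [flagged]"))
  tab <- data.frame(HR = round(x$hr, 3),
                    `CI95` = sprintf("(%.2f, %.2f)", x$ci_lower, x$ci_upper),
                    p = signif(x$p, 3))
  print(tab)
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' @export
print.tertile_assignment <- function(x, ...) {
  cat(sprintf("<tertile_assignment> sizes %s (cut ranks %d, %d)\n",
              paste(x$sizes, collapse = "/"), x$cut_ranks[1], x$cut_ranks[2]))
  invisible(x)
}
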