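# Per-subject annual rates of change from linear mixed models.
#
# For every brain region (and for each cognitive score) a model
# value ~ time with subject-level random intercepts and random slopes is
# fitted by REML; the per-subject slope is the fixed slope plus the
# empirical best linear predictor of the subject's random slope deviation.
# Singular fits fall back to independent random effects and then to a
# random-intercept-only model, with the fallback recorded in the
# diagnostics rather than silently imputed.

fit_lme_slopes <- function(df) {
  # df: subject_id, time_years, value
  df$subject_id <- factor(df$subject_id)
  fits <- list(
    full = value ~ time_years + (1 + time_years | subject_id),
    diag = value ~ time_years + (1 + time_years || subject_id),
    intercept = value ~ time_years + (1 | subject_id)
  )
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            check.conv.grad = "ignore",
                            check.conv.hess = "ignore")
  chosen <- NULL; structure_used <- NA_character_; converged <- FALSE
  for (nm in names(fits)) {
    fit <- tryCatch(
      suppressWarnings(suppressMessages(
        lme4::lmer(fits[[nm]], data = df, REML = TRUE, control = ctrl))),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (nm != "intercept" && lme4::isSingular(fit, tol = 1e-6)) {
      if (is.null(chosen)) { chosen <- fit; structure_used <- nm }
      next
    }
    chosen <- fit; structure_used <- nm; converged <- TRUE
    break
  }
  if (is.null(chosen))
    stop_config("mixed model failed for all random-effects structures")

  fix_slope <- unname(lme4::fixef(chosen)["time_years"])
  re <- lme4::ranef(chosen)$subject_id
  subj <- levels(df$subject_id)
  dev <- if ("time_years" %in% colnames(re)) re[subj, "time_years"] else rep(0, length(subj))
  inter <- unname(lme4::fixef(chosen)["(Intercept)"]) +
    (if ("(Intercept)" %in% colnames(re)) re[subj, "(Intercept)"] else rep(0, length(subj)))
  vc <- as.data.frame(lme4::VarCorr(chosen))
  list(slopes = setNames(fix_slope + dev, subj),
       intercepts = setNames(inter, subj),
       fixed_slope = fix_slope,
       structure = structure_used,
       converged = converged,
       sigma = vc$sdcor[vc$grp == "Residual"],
       varcomp = vc)
}

validate_visit_df <- function(visits, value_col = "suvr") {
  req <- c("subject_id", "time_years", "region_id", value_col)
  miss <- setdiff(req, names(visits))
  if (length(miss))
    stop_config("visit table missing column(s): %s", paste(miss, collapse = ", "))
  invisible(visits)
}

#' Per-subject annual rate of change for one region
#'
#' Fits `suvr ~ time` with subject-level random intercept and random slope
#' (REML) and returns each subject's slope as the fixed slope plus the
#' predicted random-slope deviation, together with the model intercept at
#' baseline and fit diagnostics.
#'
#' @param visits long-format data.frame with columns `subject_id`,
#'   `time_years`, `region_id`, `suvr`.
#' @param region_id region to fit.
#' @return list with `slopes` (named per subject, SUVR/year),
#'   `baselines` (fitted value at t = 0), `fixed_slope`, `structure`
#'   ("full", "diag" or "intercept"), `converged`, `sigma`, `varcomp`.
#' @export
fit_region_lme <- function(visits, region_id) {
  validate_visit_df(visits)
  df <- visits[visits$region_id == region_id,
               c("subject_id", "time_years", "suvr")]
  if (!nrow(df)) stop_config("no visits for region %s", region_id)
  names(df)[3] <- "value"
  nvis <- table(df$subject_id)
  if (sum(nvis >= 2) < 10)
    warning("fewer than 10 subjects with >= 2 visits; slopes may be unstable")
  fit <- fit_lme_slopes(df)
  names(fit)[names(fit) == "intercepts"] <- "baselines"
  fit
}

#' Fit all regions and assemble the slope matrix
#'
#' Maps [fit_region_lme()] over every region (ascending region ID) and
#' assembles the subjects x regions matrix of annual rates, the matching
#' matrix of fitted baselines, and a per-region diagnostics table.
#' Per-region failures are recorded in the diagnostics (slopes `NA`), not
#' raised.
#'
#' @param visits long-format visit table (see [fit_region_lme()]).
#' @param regions integer vector of region IDs; default: all in `visits`.
#' @return object of class `slope_matrix`: list with `slopes`,
#'   `baselines` (subjects x regions matrices), `diagnostics` (data.frame)
#'   and `subjects`.
#' @export
fit_all_regions <- function(visits, regions = NULL) {
  validate_visit_df(visits)
  if (is.null(regions)) regions <- sort(unique(visits$region_id))
  subjects <- sort(unique(as.character(visits$subject_id)))
  slopes <- baselines <- matrix(NA_real_, length(subjects), length(regions),
                                dimnames = list(subjects, regions))
  diag_list <- vector("list", length(regions))
  for (k in seq_along(regions)) {
    r <- regions[k]
    fit <- tryCatch(fit_region_lme(visits, r), error = function(e) e)
    if (inherits(fit, "error")) {
      diag_list[[k]] <- data.frame(region_id = r, converged = FALSE,
                                   structure = NA_character_, sigma = NA_real_,
                                   error = conditionMessage(fit))
      next
    }
    slopes[names(fit$slopes), k] <- fit$slopes
    baselines[names(fit$baselines), k] <- fit$baselines
    diag_list[[k]] <- data.frame(region_id = r, converged = fit$converged,
                                 structure = fit$structure, sigma = fit$sigma,
                                 error = NA_character_)
  }
  structure(list(slopes = slopes, baselines = baselines,
                 diagnostics = do.call(rbind, diag_list),
                 subjects = subjects),
            class = "slope_matrix")
}

#' Mean rate of change over a meta-ROI
#'
#' @param sm a `slope_matrix`.
#' @param regions region IDs forming the meta-ROI (e.g. the temporal
#'   meta-ROI approximating Braak stages I-IV).
#' @return named per-subject mean slope over the member regions (SUVR/yr).
#' @export
meta_roi_rate <- function(sm, regions) {
  stopifnot(inherits(sm, "slope_matrix"))
  regions <- as.character(as.integer(regions))
  if (!length(regions)) stop_config("meta-ROI is empty")
  missing <- setdiff(regions, colnames(sm$slopes))
  if (length(missing))
    stop_config("meta-ROI region(s) not fitted: %s", paste(missing, collapse = ", "))
  rowMeans(sm$slopes[, regions, drop = FALSE])
}

#' Annual percent rate of change
#'
#' 100 x (mean slope over the regions) / (mean fitted baseline over the
#' regions), per subject. Group averages are then plain means of the
#' per-subject values.
#'
#' @param sm a `slope_matrix`.
#' @param regions region IDs to aggregate over (default: all fitted).
#' @return named per-subject percent change per year.
#' @export
percent_rate <- function(sm, regions = NULL) {
  stopifnot(inherits(sm, "slope_matrix"))
  if (is.null(regions)) regions <- colnames(sm$slopes)
  regions <- as.character(as.integer(regions))
  sl <- rowMeans(sm$slopes[, regions, drop = FALSE])
  bl <- rowMeans(sm$baselines[, regions, drop = FALSE])
  100 * sl / bl
}

#' Per-subject cognitive slopes
#'
#' Fits the same random-slope mixed model to longitudinal cognitive scores
#' (one model per measure) and returns per-subject annual rates of change.
#' Only subjects with at least two assessments of a measure receive a
#' slope.
#'
#' @param cognition long-format data.frame with columns `subject_id`,
#'   `time_years`, `measure`, `score`.
#' @param measures measures to fit; default: all present.
#' @return data.frame `subject_id`, `measure`, `slope`, plus attribute
#'   `"diagnostics"`.
#' @export
fit_cognitive_slopes <- function(cognition, measures = NULL) {
  req <- c("subject_id", "time_years", "measure", "score")
  miss <- setdiff(req, names(cognition))
  if (length(miss))
    stop_config("cognition table missing column(s): %s", paste(miss, collapse = ", "))
  if (is.null(measures)) measures <- sort(unique(cognition$measure))
  out <- list(); diags <- list()
  for (m in measures) {
    df <- cognition[cognition$measure == m, ]
    nvis <- table(df$subject_id)
    keep <- names(nvis)[nvis >= 2]
    df <- df[df$subject_id %in% keep, c("subject_id", "time_years", "score")]
    names(df)[3] <- "value"
    fit <- fit_lme_slopes(df)
    out[[m]] <- data.frame(subject_id = names(fit$slopes), measure = m,
                           slope = unname(fit$slopes))
    diags[[m]] <- data.frame(measure = m, structure = fit$structure,
                             converged = fit$converged, sigma = fit$sigma)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "diagnostics") <- do.call(rbind, diags)
  res
}
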