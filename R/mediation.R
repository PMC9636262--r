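# Bootstrap causal mediation.
#
# Three OLS fits define the paths: c (exposure -> outcome), a (exposure ->
# mediator) and, jointly, b (mediator -> outcome | exposure) and c'
# (direct effect). The mediated effect is c - c', which for linear models
# with shared covariates equals a * b exactly. Inference uses a
# nonparametric subject-resampling bootstrap with percentile confidence
# intervals; the proportion mediated is (c - c') / c expressed in percent.

ols_coefs <- function(X, y) {
  # X includes the intercept column; returns named coefficients
  fit <- .lm.fit(X, y)
  setNames(fit$coefficients, colnames(X))
}

#' Bootstrap mediation analysis
#'
#' @param exposure,mediator,outcome numeric vectors (one value per
#'   subject).
#' @param covariates optional data.frame of covariates entering all three
#'   path models (e.g. age and sex; age, sex and education for the
#'   cognitive chain).
#' @param n_boot bootstrap iterations (default 1000).
#' @param seed integer seed for the resampling (required for
#'   reproducibility).
#' @param standardize z-score exposure, mediator, outcome and continuous
#'   covariates first (default TRUE).
#' @param conf_level confidence level for the percentile intervals.
#' @return object of class `mediation_result`: list with `paths` (a, b, c,
#'   c_prime, mediated = c - c_prime), `ci` (percentile intervals per
#'   path), `prop_mediated` (percent; `NA` and flagged when |c| < 1e-8),
#'   `prop_ci`, `significant` (mediated-effect CI excludes 0), `n`,
#'   `n_boot`.
#' @export
mediate <- function(exposure, mediator, outcome, covariates = NULL,
                    n_boot = 1000L, seed, standardize = TRUE,
                    conf_level = 0.95) {
  if (missing(seed)) stop_config("`seed` is required")
  df <- data.frame(x = exposure, m = mediator, y = outcome)
  if (!is.null(covariates)) df <- cbind(df, covariates)
  ok <- complete.cases(df)
  df <- df[ok, , drop = FALSE]
  n <- nrow(df)
  if (n < 30L) warning("fewer than 30 complete cases; mediation unstable")
  if (standardize) {
    for (nm in names(df)) {
      v <- df[[nm]]
      if (is.numeric(v) && length(unique(v)) > 2L) df[[nm]] <- zscore(v)
    }
  }
  C <- if (ncol(df) > 3L) as.matrix(df[, -(1:3), drop = FALSE]) else NULL
  X1 <- cbind(`(Intercept)` = 1, x = df$x, C)
  X2 <- cbind(`(Intercept)` = 1, m = df$m, x = df$x, C)
  paths_from <- function(idx) {
    c_tot <- ols_coefs(X1[idx, , drop = FALSE], df$y[idx])[["x"]]
    a <- ols_coefs(X1[idx, , drop = FALSE], df$m[idx])[["x"]]
    cb <- ols_coefs(X2[idx, , drop = FALSE], df$y[idx])
    b <- cb[["m"]]; c_prime <- cb[["x"]]
    c(a = a, b = b, c = c_tot, c_prime = c_prime, mediated = c_tot - c_prime)
  }
  est <- paths_from(seq_len(n))

  set.seed(seed)
  boot <- matrix(NA_real_, n_boot, 5L,
                 dimnames = list(NULL, names(est)))
  for (i in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    b_est <- tryCatch(paths_from(idx), error = function(e) rep(NA_real_, 5))
    boot[i, ] <- b_est
  }
  probs <- c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2)
  ci <- t(apply(boot, 2, quantile, probs = probs, na.rm = TRUE))

  degenerate <- abs(est[["c"]]) < 1e-8
  prop <- if (degenerate) NA_real_ else 100 * est[["mediated"]] / est[["c"]]
  prop_boot <- ifelse(abs(boot[, "c"]) < 1e-8, NA_real_,
                      100 * boot[, "mediated"] / boot[, "c"])
  prop_ci <- if (degenerate) c(NA_real_, NA_real_)
             else quantile(prop_boot, probs = probs, na.rm = TRUE)
  structure(list(
    paths = est, ci = ci,
    prop_mediated = prop, prop_ci = prop_ci,
    prop_flag = if (degenerate) "total effect ~ 0; proportion undefined"
                else if (!is.na(prop) && (prop < 0 || prop > 100))
                  "inconsistent path signs; proportion outside [0, 100]"
                else NA_character_,
    significant = ci["mediated", 1] > 0 | ci["mediated", 2] < 0,
    n = n, n_boot = n_boot, conf_level = conf_level),
    class = "mediation_result")
}

#' @exportS3Method base::print
print.mediation_result <- function(x, ...) {
  cat("Mediation (n =", x$n, ",", x$n_boot, "bootstrap draws)\n")
  p <- x$paths
  cat(sprintf("  a = %.3f  b = %.3f  c = %.3f  c' = %.3f  c-c' = %.3f\n",
              p["a"], p["b"], p["c"], p["c_prime"], p["mediated"]))
  cat(sprintf("  mediated effect CI [%.3f, %.3f]%s\n",
              x$ci["mediated", 1], x$ci["mediated", 2],
              if (isTRUE(x$significant)) " *" else ""))
  if (!is.na(x$prop_mediated))
    cat(sprintf("  proportion mediated = %.1f%%\n", x$prop_mediated))
  if (!is.na(x$prop_flag)) cat(" ", x$prop_flag, "\n")
  invisible(x)
}

#' Region-wise mediation map
#'
#' Mediation of the regional amyloid -> regional tau rate association by
#' soluble p-tau, run region by region (by default restricted to regions
#' with an FDR-significant amyloid total effect, mirroring the progressive
#' regression maps) and summarised as the mean proportion mediated.
#'
#' @param sm a `slope_matrix` (outcome per region).
#' @param subjects data.frame with `subject_id`, `csf_ptau` and the
#'   covariate columns.
#' @param abeta_regional subjects x regions amyloid matrix (rownames =
#'   subject IDs).
#' @param covariates character vector of covariate columns in `subjects`
#'   (default age and sex).
#' @param regions integer vector of region IDs to test; `NULL` selects
#'   regions with an FDR-significant amyloid effect in model M1.
#' @param n_boot,seed,alpha bootstrap iterations, seed, and significance
#'   level for the map.
#' @return list with `map` (data.frame: region_id, prop_mediated,
#'   mediated, ci_lo, ci_hi, significant), `mean_prop` (mean percent
#'   proportion mediated across significantly mediated regions) and
#'   `regions_tested`.
#' @export
regional_mediation_map <- function(sm, subjects, abeta_regional,
                                   covariates = c("age", "sex"),
                                   regions = NULL, n_boot = 1000L, seed,
                                   alpha = 0.05) {
  stopifnot(inherits(sm, "slope_matrix"))
  if (missing(seed)) stop_config("`seed` is required")
  if (is.null(regions)) {
    m1 <- fit_regional_maps(sm, subjects, abeta_regional, model = "M1",
                            alpha = alpha)
    regions <- m1$region_id[m1$term == "abeta" & m1$significant]
  }
  regions <- as.integer(regions)
  if (!length(regions))
    return(list(map = data.frame(), mean_prop = NA_real_,
                regions_tested = integer()))
  subj <- sm$subjects
  si <- subjects[match(subj, subjects$subject_id), ]
  cov_df <- si[, covariates, drop = FALSE]
  rows <- vector("list", length(regions))
  for (i in seq_along(regions)) {
    r <- as.character(regions[i])
    med <- mediate(exposure = abeta_regional[subj, r],
                   mediator = log(si$csf_ptau),
                   outcome = sm$slopes[, r],
                   covariates = cov_df,
                   n_boot = n_boot, seed = seed + i)
    rows[[i]] <- data.frame(region_id = regions[i],
                            prop_mediated = med$prop_mediated,
                            mediated = med$paths[["mediated"]],
                            ci_lo = med$ci["mediated", 1],
                            ci_hi = med$ci["mediated", 2],
                            significant = med$significant)
  }
  map <- do.call(rbind, rows)
  list(map = map,
       mean_prop = mean(map$prop_mediated[map$significant], na.rm = TRUE),
       regions_tested = regions)
}
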