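# Connectivity-gradient spreading statistic.
#
# For each subject, the annual tau accumulation rate of every non-epicenter
# region is regressed on the region's graph distance to the subject's tau
# epicenters, both z-scored across regions. The resulting standardized
# slope ("gradient beta", equal to the Pearson correlation) is negative
# when accumulation is faster in regions more strongly connected to the
# epicenters. Non-epicenter regions are also split into connectivity
# quartiles Q1 (closest 25%) to Q4 for the p-tau-by-quartile analysis.

#' Per-subject gradient beta
#'
#' Simple regression of z-scored regional tau rate on z-scored distance to
#' the epicenters; the standardized slope equals the Pearson correlation of
#' the two vectors.
#'
#' @param rates per-region annual tau rates (non-epicenter regions).
#' @param distances matching per-region distances to the epicenters.
#' @param min_regions minimum number of complete region pairs (default 30).
#' @return list with `beta`, `r2`, `n`.
#' @export
gradient_beta <- function(rates, distances, min_regions = 30L) {
  if (length(rates) != length(distances))
    stop_config("rates and distances differ in length")
  ok <- is.finite(rates) & is.finite(distances)
  if (sum(ok) < min_regions)
    stop_config("only %d regions with finite rate and distance (need %d)",
                sum(ok), min_regions)
  x <- distances[ok]; y <- rates[ok]
  if (sd(x) == 0 || sd(y) == 0)
    stop_config("zero-variance input to gradient_beta")
  beta <- unname(cor(x, y))
  list(beta = beta, r2 = beta^2, n = sum(ok))
}

#' Split non-epicenter regions into connectivity quartiles
#'
#' Regions are ranked by ascending distance (strongest connectivity first)
#' and divided into four consecutive rank blocks whose cumulative sizes are
#' `ceiling(k * n / 4)`; for n = 190 this gives sizes 48/47/48/47. Ties are
#' broken by region ID.
#'
#' @param distances named numeric vector of distances to the epicenters
#'   (names are region IDs).
#' @return integer vector of quartile labels 1-4, same names and order as
#'   `distances`.
#' @export
quartile_split <- function(distances) {
  n <- length(distances)
  if (n < 4L) stop_config("need at least 4 regions")
  ids <- if (!is.null(names(distances))) as.integer(names(distances)) else seq_len(n)
  ord <- order(distances, ids)
  cuts <- ceiling(seq_len(4L) * n / 4)
  sizes <- diff(c(0L, cuts))
  q <- integer(n)
  q[ord] <- rep(1:4, times = sizes)
  names(q) <- names(distances)
  q
}

#' Mean tau rate per connectivity quartile
#'
#' @param rates per-region rates aligned with `assignment`.
#' @param assignment quartile labels from [quartile_split()].
#' @return data.frame `quartile`, `n_regions`, `mean_rate`.
#' @export
quartile_rates <- function(rates, assignment) {
  if (length(rates) != length(assignment))
    stop_config("rates and assignment differ in length")
  data.frame(quartile = 1:4,
             n_regions = as.integer(tabulate(assignment, 4)),
             mean_rate = vapply(1:4, function(q)
               mean(rates[assignment == q]), numeric(1)))
}

#' Two-way mixed ANOVA of quartile rates by p-tau status
#'
#' Split-plot ANOVA with p-tau positivity as the between-subject factor and
#' connectivity quartile as the within-subject factor, computed from the
#' classical sums-of-squares decomposition. Also reports the between-group
#' Cohen's d (pooled-sd denominator) per quartile. Subjects with a missing
#' quartile mean are excluded (logged via attribute `"n_excluded"`).
#'
#' @param qmeans subjects x 4 matrix of per-quartile mean tau rates.
#' @param status logical or 2-level factor of p-tau positivity per subject.
#' @return list with `anova` (data.frame: effect, df1, df2, ss, F, p) and
#'   `cohens_d` (per quartile).
#' @export
ptau_quartile_anova <- function(qmeans, status) {
  qmeans <- as.matrix(qmeans)
  if (ncol(qmeans) != 4L) stop_config("`qmeans` must have 4 columns (Q1-Q4)")
  if (nrow(qmeans) != length(status))
    stop_config("status length does not match subjects")
  status <- factor(status)
  if (nlevels(status) != 2L) stop_config("status must have exactly 2 levels")
  ok <- complete.cases(qmeans) & !is.na(status)
  n_excluded <- sum(!ok)
  qmeans <- qmeans[ok, , drop = FALSE]; status <- status[ok]
  N <- nrow(qmeans); a <- 2L; q <- 4L
  if (min(table(status)) < 2L) stop_config("each group needs >= 2 subjects")

  grand <- mean(qmeans)
  subj_mean <- rowMeans(qmeans)
  grp_mean <- tapply(subj_mean, status, mean)
  n_g <- as.vector(table(status))
  q_mean <- colMeans(qmeans)
  cell_mean <- apply(qmeans, 2, function(col) tapply(col, status, mean))

  ss_total <- sum((qmeans - grand)^2)
  ss_subjects <- q * sum((subj_mean - grand)^2)
  ss_group <- q * sum(n_g * (grp_mean - grand)^2)
  ss_subj_err <- ss_subjects - ss_group
  ss_quartile <- N * sum((q_mean - grand)^2)
  ss_cells <- sum(rep(n_g, q) * (cell_mean - grand)^2)
  ss_inter <- ss_cells - ss_group - ss_quartile
  ss_win_err <- ss_total - ss_subjects - ss_quartile - ss_inter

  df_g <- a - 1L; df_se <- N - a
  df_q <- q - 1L; df_i <- df_g * df_q; df_we <- df_se * df_q
  f_group <- (ss_group / df_g) / (ss_subj_err / df_se)
  f_quart <- (ss_quartile / df_q) / (ss_win_err / df_we)
  f_inter <- (ss_inter / df_i) / (ss_win_err / df_we)
  an <- data.frame(
    effect = c("status", "quartile", "status:quartile"),
    df1 = c(df_g, df_q, df_i), df2 = c(df_se, df_we, df_we),
    ss = c(ss_group, ss_quartile, ss_inter),
    F = c(f_group, f_quart, f_inter),
    p = c(stats::pf(f_group, df_g, df_se, lower.tail = FALSE),
          stats::pf(f_quart, df_q, df_we, lower.tail = FALSE),
          stats::pf(f_inter, df_i, df_we, lower.tail = FALSE)))

  pos <- levels(status)[2]
  d <- vapply(1:4, function(k) {
    x1 <- qmeans[status == pos, k]; x0 <- qmeans[status != pos, k]
    sp <- sqrt(((length(x1) - 1) * var(x1) + (length(x0) - 1) * var(x0)) /
                 (length(x1) + length(x0) - 2))
    (mean(x1) - mean(x0)) / sp
  }, numeric(1))
  out <- list(anova = an, cohens_d = setNames(d, paste0("Q", 1:4)))
  attr(out, "n_excluded") <- n_excluded
  out
}

vif_values <- function(X) {
  # X: numeric model matrix without intercept column
  X <- as.matrix(X)
  if (ncol(X) < 2L) return(setNames(rep(1, ncol(X)), colnames(X)))
  sds <- apply(X, 2, sd)
  if (any(sds == 0)) return(setNames(rep(Inf, ncol(X)), colnames(X)))
  R <- cor(X)
  inv <- tryCatch(solve(R), error = function(e) NULL)
  if (is.null(inv)) return(setNames(rep(Inf, ncol(X)), colnames(X)))
  setNames(diag(inv), colnames(X))
}

#' Association between gradient beta and p-tau across subjects
#'
#' Standardized regression of the per-subject gradient beta on (log) p-tau,
#' adjusting for covariates (by default global amyloid, age and sex), with
#' an optional additional adjustment for baseline tau. Continuous variables
#' are z-scored; binary covariates are left as coded.
#'
#' @param beta per-subject gradient betas.
#' @param ptau per-subject soluble p-tau concentrations (pg/ml);
#'   log-transformed before z-scoring when `log_ptau = TRUE`.
#' @param covariates data.frame of covariates (numeric columns with more
#'   than 2 distinct values are z-scored).
#' @param baseline_tau optional per-subject baseline tau to additionally
#'   adjust for.
#' @param log_ptau log-transform p-tau first (default TRUE).
#' @return list with `coefficients` (data.frame: term, estimate, se, t, p),
#'   `vif`, `n`.
#' @export
beta_vs_ptau <- function(beta, ptau, covariates = NULL, baseline_tau = NULL,
                         log_ptau = TRUE) {
  df <- data.frame(beta = beta,
                   ptau = if (log_ptau) log(ptau) else ptau)
  if (!is.null(covariates)) df <- cbind(df, covariates)
  if (!is.null(baseline_tau)) df$baseline_tau <- baseline_tau
  ok <- complete.cases(df)
  df <- df[ok, , drop = FALSE]
  # the outcome is already a standardized correlation; predictors are
  # z-scored so coefficients are per-SD effects on beta
  for (nm in setdiff(names(df), "beta")) {
    v <- df[[nm]]
    if (is.numeric(v) && length(unique(v)) > 2L) df[[nm]] <- zscore(v)
  }
  fit <- lm(beta ~ ., data = df)
  sm <- summary(fit)$coefficients
  co <- data.frame(term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
                   t = sm[, 3], p = sm[, 4], row.names = NULL)
  vifs <- vif_values(as.matrix(df[, setdiff(names(df), "beta"), drop = FALSE]))
  if (any(is.finite(vifs) & vifs > 10) || any(!is.finite(vifs)))
    warning("high collinearity among predictors (VIF > 10)")
  list(coefficients = co, vif = vifs, n = nrow(df))
}
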