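# Region-wise progressive regression maps with FDR control.
#
# In each of the 200 parcels the annual tau accumulation rate is regressed
# on progressively richer predictor sets, always adjusting for age and
# sex: M1 regional amyloid alone, M2 soluble p-tau alone, M3 both, M4 both
# plus baseline regional tau. Continuous variables are z-scored so the
# coefficients are standardized; Benjamini-Hochberg correction is applied
# per predictor map across regions.

MODEL_PREDICTORS <- list(
  M1 = "abeta",
  M2 = "ptau",
  M3 = c("abeta", "ptau"),
  M4 = c("abeta", "ptau", "baseline_tau")
)

#' Benjamini-Hochberg FDR correction
#'
#' Step-up adjusted p-values across a family of tests with significance
#' flags at `alpha`. Non-finite p-values are excluded from the family (and
#' reported back as `NA`).
#'
#' @param p raw p-values in `[0, 1]`.
#' @param alpha significance level on the adjusted values (default 0.05).
#' @return data.frame `p`, `p_adj`, `significant`.
#' @export
fdr_correct <- function(p, alpha = 0.05) {
  p <- as.numeric(p)
  ok <- is.finite(p)
  if (any(p[ok] < 0 | p[ok] > 1))
    stop_config("p-values must lie in [0, 1]")
  if (sum(!ok))
    message(sum(!ok), " non-finite p-value(s) excluded from FDR family")
  adj <- rep(NA_real_, length(p))
  adj[ok] <- p.adjust(p[ok], method = "BH")
  data.frame(p = p, p_adj = adj,
             significant = !is.na(adj) & adj < alpha)
}

#' Region-wise progressive regression maps
#'
#' For each region, OLS of the z-scored regional tau rate on the model's
#' z-scored predictors plus age (z-scored) and sex (binary, as coded).
#' Returns the standardized coefficient, raw and FDR-adjusted p-value
#' (corrected per predictor map across regions) and the VIF per predictor.
#'
#' @param sm a `slope_matrix` (outcome: regional tau rate).
#' @param subjects data.frame with columns `subject_id`, `csf_ptau`,
#'   `age`, `sex` (and anything else the model needs).
#' @param abeta_regional subjects x regions matrix of regional amyloid
#'   SUVR (rownames = subject IDs), required for M1/M3/M4.
#' @param baseline_tau subjects x regions matrix of baseline tau SUVR,
#'   required for M4 (defaults to the fitted baselines in `sm`).
#' @param model one of "M1".."M4".
#' @param alpha FDR significance level.
#' @param min_extra regions are flagged unestimable when the number of
#'   complete cases is below `predictors + min_extra` (default 5).
#' @return data.frame (class `regional_map`) with one row per region x
#'   predictor: `region_id`, `model`, `term`, `beta`, `p`, `p_fdr`,
#'   `significant`, `vif`, `n`.
#' @export
fit_regional_maps <- function(sm, subjects, abeta_regional = NULL,
                              baseline_tau = NULL, model = "M3",
                              alpha = 0.05, min_extra = 5L) {
  stopifnot(inherits(sm, "slope_matrix"))
  model <- match.arg(model, names(MODEL_PREDICTORS))
  preds <- MODEL_PREDICTORS[[model]]
  if ("abeta" %in% preds && is.null(abeta_regional))
    stop_config("model %s needs `abeta_regional`", model)
  if ("baseline_tau" %in% preds && is.null(baseline_tau))
    baseline_tau <- sm$baselines
  subj <- sm$subjects
  si <- subjects[match(subj, subjects$subject_id), ]

  rows <- list()
  for (k in seq_len(ncol(sm$slopes))) {
    rid <- as.integer(colnames(sm$slopes)[k])
    df <- data.frame(rate = sm$slopes[, k],
                     ptau = log(si$csf_ptau),
                     age = si$age, sex = si$sex)
    if ("abeta" %in% preds) df$abeta <- abeta_regional[subj, k]
    if ("baseline_tau" %in% preds) df$baseline_tau <- baseline_tau[subj, k]
    keep <- c("rate", preds, "age", "sex")
    df <- df[, keep]
    ok <- complete.cases(df)
    df <- df[ok, , drop = FALSE]
    n <- nrow(df)
    if (n < length(preds) + 2L + min_extra) {
      rows[[length(rows) + 1L]] <-
        data.frame(region_id = rid, model = model, term = preds,
                   beta = NA_real_, p = NA_real_, vif = NA_real_, n = n)
      next
    }
    for (nm in names(df)) {
      v <- df[[nm]]
      if (length(unique(v)) > 2L) {
        s <- sd(v)
        df[[nm]] <- if (s > 0) (v - mean(v)) / s else v
      }
    }
    fit <- lm(rate ~ ., data = df)
    smry <- summary(fit)$coefficients
    vifs <- vif_values(as.matrix(df[, -1, drop = FALSE]))
    # aliased (perfectly collinear) predictors are dropped by lm; report NA
    beta <- p <- setNames(rep(NA_real_, length(preds)), preds)
    got <- intersect(preds, rownames(smry))
    beta[got] <- smry[got, 1]
    p[got] <- smry[got, 4]
    rows[[length(rows) + 1L]] <-
      data.frame(region_id = rid, model = model, term = preds,
                 beta = beta, p = p, vif = vifs[preds], n = n)
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res$p_fdr <- NA_real_; res$significant <- FALSE
  for (tm in unique(res$term)) {
    idx <- res$term == tm
    fc <- fdr_correct(res$p[idx], alpha)
    res$p_fdr[idx] <- fc$p_adj
    res$significant[idx] <- fc$significant
  }
  class(res) <- c("regional_map", "data.frame")
  res
}
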