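# Two-component Gaussian mixture machinery: regional tau-positivity
# probabilities, GMM-derived biomarker cutoffs and epicenter selection.
#
# Baseline tau-PET is strongly right-skewed: most regions of most subjects
# carry only non-specific signal. A 2-component mixture per region
# separates non-specific from "high tau" signal; the posterior of the
# higher-mean component is a probabilistic positivity measure that needs no
# a-priori threshold.

#' Fit a univariate two-component Gaussian mixture by EM
#'
#' EM with multiple restarts and a k-means++-style initialisation (first
#' centre drawn uniformly, second with probability proportional to squared
#' distance from the first). Components are ordered by mean. The fit is
#' flagged ambiguous when the two-component model is not clearly better
#' than a single Gaussian (delta-BIC < `bic_margin`) or when the component
#' means are separated by less than one pooled within-component standard
#' deviation; ambiguous regions must not be used for posteriors and are
#' excluded from epicenter selection.
#'
#' @param x numeric vector of baseline values across subjects (finite).
#' @param n_restarts EM restarts (default 20).
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter maximum EM iterations per restart.
#' @param bic_margin delta-BIC (2 vs 1 component) below which the fit is
#'   flagged ambiguous.
#' @param min_separation minimum mean separation in pooled within-component
#'   standard deviations.
#' @param seed optional integer seed for the restarts.
#' @return object of class `region_gmm` with fields `means`, `sds`,
#'   `weights` (ordered by mean), `loglik`, `bic1`, `bic2`, `delta_bic`,
#'   `separation`, `ambiguous`, `n`.
#' @export
fit_region_gmm <- function(x, n_restarts = 20L, tol = 1e-8, max_iter = 500L,
                           bic_margin = 10, min_separation = 1, seed = NULL) {
  x <- as.numeric(x)
  if (any(!is.finite(x))) stop_config("`x` contains non-finite values")
  n <- length(x)
  if (n < 4L) stop_config("need at least 4 observations")
  if (n < 50L)
    warning("fewer than 50 observations; mixture fit may be unstable")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }

  # single-Gaussian reference fit (MLE)
  mu0 <- mean(x)
  s0 <- sqrt(mean((x - mu0)^2))
  degenerate <- s0 == 0
  loglik1 <- if (degenerate) Inf else sum(dnorm(x, mu0, s0, log = TRUE))
  bic1 <- if (degenerate) -Inf else -2 * loglik1 + 2 * log(n)

  make_fit <- function(means, sds, weights, loglik, ambiguous, sep, bic2) {
    structure(list(means = means, sds = sds, weights = weights,
                   loglik = loglik, bic1 = bic1, bic2 = bic2,
                   delta_bic = bic1 - bic2, separation = sep,
                   ambiguous = ambiguous, n = n),
              class = "region_gmm")
  }
  if (degenerate)
    return(make_fit(c(mu0, mu0), c(0, 0), c(0.5, 0.5), Inf, TRUE, 0, -Inf))

  sd_floor <- max(1e-6 * s0, 1e-12)
  em_once <- function(mu, s, w) {
    ll_old <- -Inf
    for (iter in seq_len(max_iter)) {
      # E step in log space for stability
      lp1 <- log(w[1]) + dnorm(x, mu[1], s[1], log = TRUE)
      lp2 <- log(w[2]) + dnorm(x, mu[2], s[2], log = TRUE)
      m <- pmax(lp1, lp2)
      den <- m + log(exp(lp1 - m) + exp(lp2 - m))
      g2 <- exp(lp2 - den)
      g1 <- 1 - g2
      ll <- sum(den)
      # M step
      n1 <- sum(g1); n2 <- sum(g2)
      if (n1 < 1e-10 || n2 < 1e-10) return(NULL)
      mu <- c(sum(g1 * x) / n1, sum(g2 * x) / n2)
      s <- sqrt(c(sum(g1 * (x - mu[1])^2) / n1,
                  sum(g2 * (x - mu[2])^2) / n2))
      s <- pmax(s, sd_floor)
      w <- c(n1, n2) / n
      if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll) + tol)) break
      ll_old <- ll
    }
    list(mu = mu, s = s, w = w, loglik = ll)
  }

  best <- NULL
  for (r in seq_len(n_restarts)) {
    c1 <- x[sample.int(n, 1L)]
    d2 <- (x - c1)^2
    c2 <- if (all(d2 == 0)) c1 + s0 else x[sample.int(n, 1L, prob = d2)]
    assign1 <- abs(x - c1) <= abs(x - c2)
    s_init <- pmax(c(sd(x[assign1]), sd(x[!assign1])), s0 / 10)
    s_init[!is.finite(s_init)] <- s0 / 2
    fit <- em_once(c(c1, c2), s_init, c(mean(assign1), mean(!assign1)))
    if (!is.null(fit) && (is.null(best) || fit$loglik > best$loglik))
      best <- fit
  }
  if (is.null(best))
    return(make_fit(c(mu0, mu0), c(s0, s0), c(0.5, 0.5), loglik1, TRUE, 0, bic1))

  ord <- order(best$mu)
  mu <- best$mu[ord]; s <- best$s[ord]; w <- best$w[ord]
  bic2 <- -2 * best$loglik + 5 * log(n)
  pooled_sd <- sqrt(w[1] * s[1]^2 + w[2] * s[2]^2)
  sep <- if (pooled_sd > 0) (mu[2] - mu[1]) / pooled_sd else 0
  ambiguous <- (bic1 - bic2) < bic_margin || sep < min_separation
  make_fit(mu, s, w, best$loglik, ambiguous, sep, bic2)
}

#' Posterior probability of the high-tau component
#'
#' Bayes' rule on the two component densities: the probability that a value
#' belongs to the higher-mean ("high tau") component.
#'
#' @param fit a non-ambiguous `region_gmm`.
#' @param x numeric values on the scale of the fitted data.
#' @return posterior probabilities in `[0, 1]`.
#' @export
tau_probability <- function(fit, x) {
  stopifnot(inherits(fit, "region_gmm"))
  if (fit$ambiguous)
    stop_config("ambiguous mixture fit; region belongs on the exclusion list")
  lp1 <- log(fit$weights[1]) + dnorm(x, fit$means[1], fit$sds[1], log = TRUE)
  lp2 <- log(fit$weights[2]) + dnorm(x, fit$means[2], fit$sds[2], log = TRUE)
  1 / (1 + exp(lp1 - lp2))
}

#' GMM-derived biomarker cutoff
#'
#' The value between the two component means where the posterior of the
#' high component equals 0.5, found by bisection to `tol`.
#'
#' @param fit a non-ambiguous `region_gmm`.
#' @param tol bisection tolerance on x (default 1e-8).
#' @return the cutoff value.
#' @export
gmm_cutoff <- function(fit, tol = 1e-8) {
  stopifnot(inherits(fit, "region_gmm"))
  if (fit$ambiguous)
    stop_config("ambiguous mixture fit; no cutoff defined")
  f <- function(x) tau_probability(fit, x) - 0.5
  lo <- fit$means[1]; hi <- fit$means[2]
  flo <- f(lo); fhi <- f(hi)
  if (flo * fhi > 0)
    stop_config(paste0("posterior does not cross 0.5 between the means ",
                       sprintf("(means %.4g/%.4g, weights %.3g/%.3g)",
                               fit$means[1], fit$means[2],
                               fit$weights[1], fit$weights[2])))
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (fm == 0) return(mid)
    if (flo * fm < 0) { hi <- mid } else { lo <- mid; flo <- fm }
  }
  (lo + hi) / 2
}

#' Select subject-level tau epicenters
#'
#' Each region's baseline SUVR is weighted by its posterior probability of
#' being in the high-tau mixture component; the `top_k` regions with the
#' highest weighted score are the subject's epicenters. Regions on the
#' exclusion list (ambiguous mixture fits) are never selected. Ties are
#' broken by lower region ID.
#'
#' @param suvr numeric vector of baseline SUVR, one value per region
#'   (positions are region IDs 1..n).
#' @param fits list of `region_gmm`, one per region.
#' @param exclude integer IDs excluded from selection (ambiguous regions in
#'   `fits` are excluded automatically).
#' @param top_k number of epicenters (default 10).
#' @return data.frame with `rank`, `region_id`, `score` (non-increasing).
#' @export
select_epicenters <- function(suvr, fits, exclude = integer(), top_k = 10L) {
  n <- length(suvr)
  if (length(fits) != n)
    stop_config("need one mixture fit per region (%d != %d)", length(fits), n)
  ambiguous <- vapply(fits, function(f) isTRUE(f$ambiguous), logical(1))
  excl <- union(as.integer(exclude), which(ambiguous))
  eligible <- setdiff(seq_len(n), excl)
  if (length(eligible) < top_k)
    stop_config("only %d eligible regions; need %d", length(eligible), top_k)
  score <- vapply(eligible, function(r)
    tau_probability(fits[[r]], suvr[r]) * suvr[r], numeric(1))
  ord <- order(-score, eligible)[seq_len(top_k)]
  data.frame(rank = seq_len(top_k),
             region_id = eligible[ord],
             score = score[ord])
}

#' Group-level tau epicenters
#'
#' The subject-level weighted scores are averaged across the subject set
#' and the `top_k` regions of the mean score are selected under the same
#' tie rule (lower region ID first).
#'
#' @param score_matrix subjects x regions matrix of posterior-weighted SUVR
#'   scores (columns are region IDs 1..n).
#' @param exclude region IDs excluded from selection.
#' @param top_k number of epicenters (default 10).
#' @return data.frame with `rank`, `region_id`, `score`.
#' @export
group_epicenters <- function(score_matrix, exclude = integer(), top_k = 10L) {
  score_matrix <- as.matrix(score_matrix)
  n <- ncol(score_matrix)
  eligible <- setdiff(seq_len(n), as.integer(exclude))
  if (length(eligible) < top_k)
    stop_config("only %d eligible regions; need %d", length(eligible), top_k)
  mscore <- colMeans(score_matrix[, eligible, drop = FALSE])
  ord <- order(-mscore, eligible)[seq_len(top_k)]
  data.frame(rank = seq_len(top_k),
             region_id = eligible[ord],
             score = mscore[ord])
}

#' Compute the posterior-weighted SUVR score matrix for a cohort
#'
#' Convenience wrapper producing the subjects x regions matrix of
#' `tau_probability * SUVR` scores consumed by [group_epicenters()].
#' Excluded (ambiguous) regions get `NA` columns.
#'
#' @param suvr_matrix subjects x regions baseline SUVR.
#' @param fits list of `region_gmm`, one per region.
#' @return list with `scores` (matrix) and `excluded` (region IDs with
#'   ambiguous fits).
#' @export
epicenter_scores <- function(suvr_matrix, fits) {
  suvr_matrix <- as.matrix(suvr_matrix)
  n <- ncol(suvr_matrix)
  if (length(fits) != n)
    stop_config("need one mixture fit per region")
  ambiguous <- which(vapply(fits, function(f) isTRUE(f$ambiguous), logical(1)))
  scores <- matrix(NA_real_, nrow(suvr_matrix), n,
                   dimnames = dimnames(suvr_matrix))
  for (r in setdiff(seq_len(n), ambiguous))
    scores[, r] <- tau_probability(fits[[r]], suvr_matrix[, r]) * suvr_matrix[, r]
  list(scores = scores, excluded = ambiguous)
}
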