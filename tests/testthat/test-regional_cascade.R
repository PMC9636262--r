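test_that("BH correction matches the brute-force step-up definition", {
  p <- c(0.01, 0.02, 0.03, 0.04)
  out <- fdr_correct(p)
  expect_equal(out$p_adj, rep(0.04, 4))
  expect_true(all(out$significant))

  expect_false(any(fdr_correct(rep(1, 10))$significant))
  expect_equal(fdr_correct(0.03)$p_adj, 0.03)  # single test: adjusted = raw

  set.seed(30)
  for (i in 1:200) {
    p <- runif(sample(5:200, 1))
    out <- fdr_correct(p)
    expect_equal(out$p_adj, bh_bruteforce(p), tolerance = 1e-14)
    expect_true(all(out$p_adj >= out$p - 1e-15))
  }

  suppressMessages(nn <- fdr_correct(c(0.01, NA, 0.5)))
  expect_true(is.na(nn$p_adj[2]) && !nn$significant[2])
  expect_error(fdr_correct(c(0.5, 2)), "\\[0, 1\\]")
})

make_map_fixture <- function(n_sub, n_reg, beta_ptau = 0, seed = 1,
                             noise = 1) {
  set.seed(seed)
  ids <- sprintf("S%03d", seq_len(n_sub))
  subjects <- data.frame(subject_id = ids,
                         csf_ptau = exp(rnorm(n_sub, 5, 0.5)),
                         age = rnorm(n_sub, 70, 8),
                         sex = rbinom(n_sub, 1, 0.5))
  zp <- scale(log(subjects$csf_ptau))[, 1]
  slopes <- matrix(beta_ptau * zp, n_sub, n_reg) +
    matrix(rnorm(n_sub * n_reg, 0, noise), n_sub)
  dimnames(slopes) <- list(ids, seq_len(n_reg))
  abeta <- matrix(rnorm(n_sub * n_reg, 0.6, 0.1), n_sub,
                  dimnames = dimnames(slopes))
  sm <- structure(list(slopes = slopes, baselines = slopes * 0 + 1.2,
                       diagnostics = NULL, subjects = ids),
                  class = "slope_matrix")
  list(sm = sm, subjects = subjects, abeta = abeta, zp = zp)
}

test_that("regional maps recover a constructed uniform p-tau effect", {
  # outcome built with unit population variance so the fully standardized
  # coefficient equals the generating 0.47 in every region
  fx <- make_map_fixture(400, 12, beta_ptau = 0.47, seed = 2,
                         noise = sqrt(1 - 0.47^2))
  maps <- fit_regional_maps(fx$sm, fx$subjects, fx$abeta, model = "M2")
  est <- maps$beta[maps$term == "ptau"]
  expect_equal(mean(est), 0.47, tolerance = 0.05)
  expect_true(all(maps$significant[maps$term == "ptau"]))
  expect_true(all(maps$vif[maps$term == "ptau"] >= 1))
})

test_that("regional OLS equals the closed-form normal-equations solve", {
  fx <- make_map_fixture(10, 3, beta_ptau = 0.3, seed = 5, noise = 0.5)
  maps <- fit_regional_maps(fx$sm, fx$subjects, fx$abeta, model = "M3",
                            min_extra = 0)
  r <- 2
  sc <- function(x) if (length(unique(x)) > 2) (x - mean(x)) / sd(x) else x
  X <- cbind(1, sc(fx$abeta[, r]), sc(log(fx$subjects$csf_ptau)),
             sc(fx$subjects$age), fx$subjects$sex)
  y <- sc(fx$sm$slopes[, r])
  beta_hat <- solve(t(X) %*% X, t(X) %*% y)
  got <- maps[maps$region_id == r, ]
  expect_equal(got$beta[got$term == "abeta"], beta_hat[2, 1], tolerance = 1e-10)
  expect_equal(got$beta[got$term == "ptau"], beta_hat[3, 1], tolerance = 1e-10)
})

test_that("duplicated predictors blow up the VIF and are flagged", {
  fx <- make_map_fixture(40, 4, seed = 6)
  baseline <- fx$abeta   # baseline tau identical to amyloid -> collinear
  maps <- fit_regional_maps(fx$sm, fx$subjects, fx$abeta,
                            baseline_tau = baseline, model = "M4")
  expect_true(all(!is.finite(maps$vif[maps$term == "abeta"]) |
                    maps$vif[maps$term == "abeta"] > 100))
})

test_that("adding baseline tau (M3 -> M4) never increases residual SS", {
  fx <- make_map_fixture(50, 6, beta_ptau = 0.3, seed = 7, noise = 0.4)
  baseline <- matrix(rnorm(50 * 6, 1.3, 0.1), 50,
                     dimnames = dimnames(fx$abeta))
  rss <- function(model, bt = NULL) {
    vapply(seq_len(6), function(r) {
      sc <- function(x) if (length(unique(x)) > 2) (x - mean(x)) / sd(x) else x
      df <- data.frame(y = sc(fx$sm$slopes[, r]), ab = sc(fx$abeta[, r]),
                       pt = sc(log(fx$subjects$csf_ptau)),
                       age = sc(fx$subjects$age), sex = fx$subjects$sex)
      if (!is.null(bt)) df$bt <- sc(bt[, r])
      sum(lm(y ~ ., df)$residuals^2)
    }, numeric(1))
  }
  expect_true(all(rss("M4", baseline) <= rss("M3") + 1e-12))
})

test_that("global-null maps flag few regions after FDR", {
  hits <- vapply(1:40, function(i) {
    fx <- make_map_fixture(50, 20, beta_ptau = 0, seed = 100 + i)
    maps <- fit_regional_maps(fx$sm, fx$subjects, fx$abeta, model = "M2")
    mean(maps$significant[maps$term == "ptau"])
  }, numeric(1))
  expect_lte(mean(hits), 0.05)
})
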