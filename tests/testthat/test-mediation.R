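test_that("full mediation is recovered exactly in the noiseless limit", {
  set.seed(40)
  x <- rnorm(100)
  m <- 0.8 * x + 1e-6 * rnorm(100)  # mediator not perfectly collinear
  y <- 0.75 * m                     # outcome fully carried by the mediator
  res <- mediate(x, m, y, n_boot = 100, seed = 1, standardize = FALSE)
  expect_equal(unname(res$paths["c_prime"]), 0, tolerance = 1e-10)
  expect_equal(res$prop_mediated, 100, tolerance = 1e-8)
  expect_true(res$significant)
})

test_that("a*b equals c - c' to numerical precision on arbitrary data", {
  set.seed(41)
  for (i in 1:20) {
    n <- sample(40:120, 1)
    x <- rnorm(n); m <- rnorm(n, 0.3 * x); y <- rnorm(n, 0.2 * x + 0.5 * m)
    covs <- data.frame(age = rnorm(n), sex = rbinom(n, 1, 0.5))
    res <- mediate(x, m, y, covariates = covs, n_boot = 2, seed = i)
    expect_equal(unname(res$paths["a"] * res$paths["b"]),
                 unname(res$paths["mediated"]), tolerance = 1e-10)
  }
})

test_that("bootstrap is reproducible and degenerate totals are flagged", {
  set.seed(42)
  x <- rnorm(60); m <- rnorm(60, 0.5 * x); y <- rnorm(60, 0.5 * m)
  r1 <- mediate(x, m, y, n_boot = 200, seed = 7)
  r2 <- mediate(x, m, y, n_boot = 200, seed = 7)
  expect_identical(r1$ci, r2$ci)
  expect_true(all(r1$ci[, 1] <= r1$ci[, 2]))

  # orthogonal construction with c = 0 exactly
  x0 <- rep(c(-1, 1), 30)
  y0 <- rep(c(1, 1, -1, -1), 15)
  r0 <- mediate(x0, rnorm(60), y0, n_boot = 50, seed = 3,
                standardize = FALSE)
  expect_true(is.na(r0$prop_mediated))
  expect_match(r0$prop_flag, "undefined")
})

test_that("null mediation covers zero and CIs widen as n shrinks", {
  set.seed(43)
  cover <- vapply(1:60, function(i) {
    n <- 100
    x <- rnorm(n); m <- rnorm(n, 0.6 * x); y <- rnorm(n, 0.5 * x)  # y indep of m | x
    r <- mediate(x, m, y, n_boot = 300, seed = 1000 + i)
    r$ci["mediated", 1] <= 0 && 0 <= r$ci["mediated", 2]
  }, logical(1))
  expect_gte(mean(cover), 0.85)

  widths <- vapply(c(200, 100, 50), function(n) {
    sim <- simulate_mediation_cohort(n, 0.6, seed = 99)
    r <- mediate(sim$data$x, sim$data$m, sim$data$y, n_boot = 300, seed = 5)
    unname(diff(r$ci["mediated", ]))
  }, numeric(1))
  expect_true(all(diff(widths) > 0))
})

test_that("proportion mediated is invariant to affine rescaling when standardized", {
  sim <- simulate_mediation_cohort(150, 0.7, seed = 8)
  d <- sim$data
  r1 <- mediate(d$x, d$m, d$y, n_boot = 50, seed = 2)
  r2 <- mediate(10 + 3 * d$x, d$m, 100 * d$y - 4, n_boot = 50, seed = 2)
  expect_equal(r1$prop_mediated, r2$prop_mediated, tolerance = 1e-8)
  expect_equal(unname(r1$paths), unname(r2$paths), tolerance = 1e-8)
})

test_that("exact-proportion generator encodes its stated truth", {
  sim <- simulate_mediation_cohort(50000, 0.7, seed = 11)
  d <- sim$data
  a_hat <- coef(lm(m ~ x, d))[2]
  fit2 <- coef(lm(y ~ m + x, d))
  prop <- a_hat * fit2["m"] / coef(lm(y ~ x, d))[2] * 100
  expect_equal(unname(prop), 70, tolerance = 2)
})

test_that("regional mediation maps summarise per-region proportions", {
  set.seed(44)
  n <- 80; n_reg <- 5
  ids <- sprintf("S%03d", 1:n)
  stage <- rnorm(n)
  ptau <- exp(5 + 0.8 * stage + 0.3 * rnorm(n))
  abeta <- matrix(0.6 + 0.1 * stage + rnorm(n * n_reg, 0, 0.02), n,
                  dimnames = list(ids, 1:n_reg))
  slopes <- matrix(0.05 * scale(log(ptau))[, 1], n, n_reg,
                   dimnames = list(ids, 1:n_reg)) +
    matrix(rnorm(n * n_reg, 0, 0.01), n)
  sm <- structure(list(slopes = slopes, baselines = slopes * 0 + 1.2,
                       diagnostics = NULL, subjects = ids),
                  class = "slope_matrix")
  subjects <- data.frame(subject_id = ids, csf_ptau = ptau,
                         age = rnorm(n, 70, 5), sex = rbinom(n, 1, 0.5))
  res <- regional_mediation_map(sm, subjects, abeta, regions = 1:n_reg,
                                n_boot = 200, seed = 9)
  expect_equal(nrow(res$map), n_reg)
  # rate depends on amyloid only through p-tau: near-full mediation
  expect_gt(res$mean_prop, 60)

  # permuting the mediator kills the mediation signal
  subjects$csf_ptau <- sample(subjects$csf_ptau)
  res0 <- regional_mediation_map(sm, subjects, abeta, regions = 1:n_reg,
                                 n_boot = 200, seed = 10)
  expect_lte(sum(res0$map$significant), 2)
})
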