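test_that("gradient beta is the correlation of z-scored rate and distance", {
  set.seed(20)
  d <- runif(190, 1, 5)
  expect_equal(gradient_beta(-d, d)$beta, -1)
  expect_equal(gradient_beta(d, d)$beta, 1)

  r <- rnorm(190)
  gb <- gradient_beta(r, d)
  expect_equal(gb$beta, cor(scale(d)[, 1], scale(r)[, 1]), tolerance = 1e-12)
  expect_equal(gb$r2, gb$beta^2)

  expect_error(gradient_beta(rep(1, 190), d), "zero-variance")
  expect_error(gradient_beta(r[1:10], d[1:10]), "need 30")
})

test_that("permuted rates give near-zero betas at the sampling bound", {
  set.seed(21)
  d <- runif(190, 1, 5)
  r <- -d + rnorm(190, 0, 0.5)
  betas <- replicate(1000, gradient_beta(sample(r), d)$beta)
  expect_lt(abs(mean(betas)), 0.02)
  expect_gt(mean(abs(betas) < 2 / sqrt(190)), 0.90)
})

test_that("quartile split gives 48/47/48/47 blocks ranked by connectivity", {
  set.seed(22)
  d <- setNames(runif(190, 1, 6), sample(1:200, 190))
  q <- quartile_split(d)
  expect_equal(as.integer(table(q)), c(48, 47, 48, 47))
  # Q1 holds the 48 closest regions
  expect_setequal(names(q)[q == 1], names(sort(d)[1:48]))

  # distances increasing with region ID: Q1 = lowest IDs
  d2 <- setNames(seq(1, 2, length.out = 190), 1:190)
  q2 <- quartile_split(d2)
  expect_setequal(names(q2)[q2 == 1], as.character(1:48))

  # ties at a block boundary resolve by region ID
  d3 <- setNames(rep(1, 8), 1:8)
  q3 <- quartile_split(d3)
  expect_identical(unname(q3), rep(1:4, each = 2))
})

test_that("quartile means conserve the overall mean rate", {
  set.seed(23)
  d <- setNames(runif(190, 1, 6), 1:190)
  r <- rnorm(190, 0.02, 0.01)
  q <- quartile_split(d)
  qr <- quartile_rates(r, q)
  expect_equal(sum(qr$mean_rate * qr$n_regions) / sum(qr$n_regions),
               mean(r), tolerance = 1e-12)
  qc <- quartile_rates(rep(0.02, 190), q)
  expect_true(all(abs(qc$mean_rate - 0.02) < 1e-12))
})

test_that("mixed ANOVA matches aov and hand-built sums of squares", {
  # pure interaction, zero noise, 2 subjects per group
  base <- c(1, 2, 3, 4)
  inter <- c(0.5, 0, 0, -0.5)
  qm <- rbind(base + inter, base + inter, base - inter, base - inter)
  status <- c(TRUE, TRUE, FALSE, FALSE)
  res <- ptau_quartile_anova(qm, status)
  an <- res$anova
  # group main effect and quartile x nothing: quartile SS from base pattern
  expect_equal(an$ss[an$effect == "status"], 0, tolerance = 1e-12)
  ss_inter_expected <- 4 * sum(inter^2)   # N * sum over cells of deviation^2
  expect_equal(an$ss[an$effect == "status:quartile"], ss_inter_expected,
               tolerance = 1e-10)

  # identical groups: interaction SS = 0
  qm2 <- rbind(base, base, base, base)
  res2 <- ptau_quartile_anova(qm2 + rnorm(16, 0, 1e-12), status)
  expect_lt(res2$anova$ss[3], 1e-20)

  # random balanced fixture: agree with stats::aov
  set.seed(24)
  qm3 <- matrix(rnorm(40, 0.02, 0.01), 10, 4) +
    outer(rep(c(0, 0.01), each = 5), c(0.03, 0.02, 0.01, 0))
  st3 <- rep(c(FALSE, TRUE), each = 5)
  res3 <- ptau_quartile_anova(qm3, st3)
  long <- data.frame(y = as.vector(qm3),
                     subj = factor(rep(1:10, 4)),
                     q = factor(rep(1:4, each = 10)),
                     g = factor(rep(st3, 4)))
  av <- summary(aov(y ~ g * q + Error(subj / q), data = long))
  f_aov_g <- av[["Error: subj"]][[1]]["g", "F value"]
  f_aov_q <- av[["Error: subj:q"]][[1]]["q", "F value"]
  f_aov_i <- av[["Error: subj:q"]][[1]]["g:q", "F value"]
  expect_equal(res3$anova$F, c(f_aov_g, f_aov_q, f_aov_i), tolerance = 1e-8)

  # Cohen's d uses the pooled sd
  d1 <- res3$cohens_d[1]
  x1 <- qm3[st3, 1]; x0 <- qm3[!st3, 1]
  sp <- sqrt((4 * var(x1) + 4 * var(x0)) / 8)
  expect_equal(unname(d1), (mean(x1) - mean(x0)) / sp)
})

test_that("beta_vs_ptau recovers constructed effects and shifts cleanly", {
  set.seed(25)
  n <- 80
  ptau <- exp(rnorm(n, 5, 0.5))
  zp <- scale(log(ptau))[, 1]
  beta <- -0.5 * zp
  res <- suppressWarnings(beta_vs_ptau(beta, ptau))  # exact fit by design
  est <- res$coefficients$estimate[res$coefficients$term == "ptau"]
  expect_equal(est, -0.5, tolerance = 1e-8)

  # adding a constant to all betas changes the intercept only
  res2 <- suppressWarnings(beta_vs_ptau(beta + 10, ptau))
  est2 <- res2$coefficients$estimate[res2$coefficients$term == "ptau"]
  expect_equal(est2, est, tolerance = 1e-8)

  # covariate adjustment leaves a pure p-tau effect intact
  covs <- data.frame(age = rnorm(n, 70, 8), sex = rbinom(n, 1, 0.5))
  res3 <- beta_vs_ptau(beta + rnorm(n, 0, 0.05), ptau, covariates = covs)
  est3 <- res3$coefficients$estimate[res3$coefficients$term == "ptau"]
  expect_lt(abs(est3 + 0.5), 0.1)
  expect_true(all(res3$vif < 2))
})
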