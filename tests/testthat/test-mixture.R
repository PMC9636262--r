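test_that("EM recovers well-separated two-component mixtures", {
  fx <- make_gmm_fixture()
  fit <- fit_region_gmm(fx$x, seed = 1)
  expect_false(fit$ambiguous)
  expect_lt(max(abs(fit$means - fx$means)), 0.05)
  expect_lt(max(abs(fit$sds - fx$sds)), 0.05)
  expect_lt(max(abs(fit$weights - fx$weights)), 0.05)
  # deterministic under the same seed
  fit2 <- fit_region_gmm(fx$x, seed = 1)
  expect_identical(fit$means, fit2$means)
})

test_that("EM agrees with an independent mixture fitter on the fixture", {
  skip_if_not_installed("mclust")
  suppressMessages(withr::local_package("mclust"))
  fx <- make_gmm_fixture()
  fit <- fit_region_gmm(fx$x, seed = 1)
  mc <- mclust::Mclust(fx$x, G = 2, modelNames = "V", verbose = FALSE)
  expect_lt(max(abs(sort(fit$means) - sort(as.vector(mc$parameters$mean)))),
            0.01)
})

test_that("degenerate and weakly separated data are flagged ambiguous", {
  expect_warning(fit_region_gmm(rnorm(30), seed = 1), "fewer than 50")
  fit <- fit_region_gmm(rep(1.5, 60))
  expect_true(fit$ambiguous)
  expect_error(tau_probability(fit, 1), "ambiguous")
  expect_error(gmm_cutoff(fit), "ambiguous")

  set.seed(6)
  uni <- rnorm(500, 1.5, 0.1)        # a single Gaussian
  fu <- fit_region_gmm(uni, seed = 2)
  expect_true(fu$ambiguous)
})

test_that("posterior equals the closed-form Bayes oracle", {
  fx <- make_gmm_fixture()
  fit <- fit_region_gmm(fx$x, seed = 1)
  grid <- seq(0.8, 3.2, length.out = 200)
  post <- tau_probability(fit, grid)
  oracle <- oracle_posterior(grid, fit$means, fit$sds, fit$weights)
  expect_equal(post, oracle, tolerance = 1e-10)
  expect_equal(post + (1 - post), rep(1, length(grid)))
  expect_gt(tau_probability(fit, 2.5), 0.99)
  expect_lt(tau_probability(fit, 1.2), 0.01)
})

test_that("posterior is monotone when component sds are equal", {
  fit <- structure(list(means = c(1, 3), sds = c(0.4, 0.4),
                        weights = c(0.6, 0.4), ambiguous = FALSE),
                   class = "region_gmm")
  p <- tau_probability(fit, seq(-1, 5, length.out = 400))
  expect_true(all(diff(p) >= 0))
  # midpoint of equal-sd equal-weight symmetric components is exactly 0.5
  sym <- structure(list(means = c(1, 3), sds = c(0.4, 0.4),
                        weights = c(0.5, 0.5), ambiguous = FALSE),
                   class = "region_gmm")
  expect_equal(tau_probability(sym, 2), 0.5, tolerance = 1e-12)
})

test_that("GMM cutoffs solve posterior = 0.5 and sit between the means", {
  sym <- structure(list(means = c(1, 3), sds = c(0.4, 0.4),
                        weights = c(0.5, 0.5), ambiguous = FALSE),
                   class = "region_gmm")
  expect_equal(gmm_cutoff(sym), 2, tolerance = 1e-7)

  uneq <- structure(list(means = c(1, 3), sds = c(0.3, 0.6),
                         weights = c(0.7, 0.3), ambiguous = FALSE),
                    class = "region_gmm")
  cut <- gmm_cutoff(uneq)
  grid <- seq(1, 3, length.out = 2e5)
  oracle <- grid[which.min(abs(oracle_posterior(grid, uneq$means, uneq$sds,
                                                uneq$weights) - 0.5))]
  expect_equal(cut, oracle, tolerance = 1e-4)
  expect_gt(cut, uneq$means[1]); expect_lt(cut, uneq$means[2])

  # the cutoff classifies the fit's own sample exactly like posterior > 0.5
  fx <- make_gmm_fixture()
  fit <- fit_region_gmm(fx$x, seed = 1)
  cc <- gmm_cutoff(fit)
  expect_identical(fx$x > cc, tau_probability(fit, fx$x) > 0.5)
})

test_that("epicenter selection ranks by weighted score with exclusions", {
  n <- 20
  fits <- lapply(1:n, function(i)
    structure(list(means = c(1, 2.5), sds = c(0.1, 0.2),
                   weights = c(0.5, 0.5), ambiguous = FALSE),
              class = "region_gmm"))
  suvr <- seq(3, 1.1, length.out = n)  # scores strictly decreasing in ID
  sel <- select_epicenters(suvr, fits)
  expect_identical(sel$region_id, 1:10)
  expect_true(all(diff(sel$score) <= 0))

  # excluding the top region promotes rank 11
  sel2 <- select_epicenters(suvr, fits, exclude = 1L)
  expect_identical(sel2$region_id, 2:11)

  # ambiguous fits are excluded automatically
  fits[[2]]$ambiguous <- TRUE
  sel3 <- select_epicenters(suvr, fits)
  expect_false(2L %in% sel3$region_id)

  expect_error(select_epicenters(suvr[1:9], fits[1:9]), "eligible")
})

test_that("mixture-weighted selection recovers seeded epicenters in amyloid-positive subjects", {
  cfg <- cohort_config(n_per_group = c(cn_neg = 30, cu_pos = 20,
                                       mci_pos = 20, ad = 15),
                       n_regions = 100, n_modules = 5, seed = 33)
  coh <- simulate_cohort(cfg)
  visits <- validate_visit_table(coh$visits, n_regions = 100)
  base <- visits[visits$time_years == 0, ]
  subj <- sort(unique(base$subject_id))
  bl <- matrix(NA_real_, length(subj), 100, dimnames = list(subj, 1:100))
  bl[cbind(match(base$subject_id, subj), base$region_id)] <- base$suvr
  fits <- lapply(1:100, function(r)
    suppressWarnings(fit_region_gmm(bl[, r], seed = r)))
  temporal <- coh$ground_truth$temporal_module
  pos <- coh$subjects$subject_id[coh$subjects$group %in%
                                   c("cu_pos", "mci_pos", "ad")]
  frac <- vapply(pos, function(s) {
    sel <- select_epicenters(bl[s, ], fits)
    mean(sel$region_id %in% temporal)
  }, numeric(1))
  expect_gte(mean(frac), 0.8)
})

test_that("group epicenters average subject scores deterministically", {
  set.seed(7)
  scores <- matrix(runif(5 * 30, 0.5, 2), 5, 30)
  g <- group_epicenters(scores)
  expect_equal(nrow(g), 10)
  # single-subject group equals that subject's own ranking
  one <- group_epicenters(scores[1, , drop = FALSE])
  expect_identical(one$region_id,
                   order(-scores[1, ], seq_len(30))[1:10])
  # permuting subjects changes nothing
  perm <- group_epicenters(scores[sample(5), , drop = FALSE])
  expect_identical(g$region_id, perm$region_id)
})
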