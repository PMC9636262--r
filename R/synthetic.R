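# Synthetic cohort generator with known ground truth.
#
# The generator encodes the working model of the cascade: a latent disease
# stage drives both amyloid load and soluble p-tau; baseline tau seeds in
# temporal-lobe epicenters; each region's true accumulation rate combines
# a p-tau-scaled connectivity term that decays with graph distance from
# the epicenters (g(d) = exp(-lambda d), distances normalised by their
# cohort mean) and a local self-replication term on baseline tau; and
# cognitive decline is driven by the tau accumulation rate in the regions
# most connected to the epicenters (Q1), with the direct p-tau path solved
# so that the cognitive-chain proportion mediated equals a configured
# target. Every cohort ships its ground truth.

#' Configuration for a synthetic cohort
#'
#' Defaults mirror the reference cohort: group sizes 204/65/65/66
#' (amyloid-negative controls, amyloid-positive cognitively unimpaired,
#' amyloid-positive MCI, AD dementia), 200 cortical parcels in 7 network
#' modules, 2-4 annual tau-PET visits, log-normal group p-tau with an
#' AD-stage plateau (AD mean at most 1.2 x the MCI-positive mean), and
#' rate parameters calibrated so the temporal meta-ROI percent rates
#' reproduce the observed ordering of roughly 0.7 / 3.3 / 9 percent per
#' year across controls, non-demented and dementia strata.
#'
#' @param n_per_group named counts for groups cn_neg, cu_pos, mci_pos, ad.
#' @param n_regions parcel count (default 200).
#' @param n_modules connectome community count (default 7; module 1 is the
#'   temporal module that seeds epicenters and defines the meta-ROI).
#' @param visits_range integer pair within `[2, 4]`: visits per subject.
#' @param visit_interval_years spacing between visits (years).
#' @param ptau_meanlog,ptau_sdlog log-scale location/scale of CSF p-tau
#'   (pg/ml) per group; natural-scale means must be monotone
#'   non-decreasing with AD <= plateau_factor x MCI-positive.
#' @param plateau_factor maximum AD / MCI-positive p-tau mean ratio
#'   (default 1.2).
#' @param kappa coupling of p-tau x connectivity on the tau rate.
#' @param rho self-replication coefficient on baseline tau.
#' @param lambda decay rate of the connectivity kernel
#'   `g(d) = exp(-lambda d / mean(d))`.
#' @param tau_amp per-group amplitude of epicenter-seeded baseline tau.
#' @param sigma_suvr residual SUVR noise sd per scan.
#' @param r0 baseline tau accumulation rate (SUVR/year).
#' @param gamma standardized effect of Q1 tau rate on cognitive decline.
#' @param prop_mediated_cognitive target proportion (0-1) of the p-tau ->
#'   cognition association mediated by the Q1 tau rate.
#' @param abeta_leak direct regional-amyloid term on the tau rate (0 gives
#'   full mediation of amyloid by p-tau in the regional chain).
#' @param ptau_ref reference p-tau (pg/ml) entering the rate term through
#'   `max(0, log(ptau / ptau_ref))`.
#' @param seed RNG seed for the cohort stream.
#' @return validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_per_group = c(cn_neg = 204, cu_pos = 65,
                                          mci_pos = 65, ad = 66),
                          n_regions = 200L, n_modules = 7L,
                          visits_range = c(2L, 4L),
                          visit_interval_years = 1.0,
                          ptau_meanlog = c(cn_neg = 3.66, cu_pos = 5.10,
                                           mci_pos = 6.02, ad = 6.20),
                          ptau_sdlog = c(cn_neg = 0.60, cu_pos = 0.55,
                                         mci_pos = 0.50, ad = 0.50),
                          plateau_factor = 1.2,
                          kappa = 0.04, rho = 0.15, lambda = 2,
                          tau_amp = c(cn_neg = 0.10, cu_pos = 0.38,
                                      mci_pos = 0.62, ad = 1.2),
                          sigma_suvr = 0.03, r0 = 0.002,
                          gamma = 0.45, prop_mediated_cognitive = 0.60,
                          abeta_leak = 0, ptau_ref = 114.4, seed = 1L) {
  cfg <- list(n_per_group = n_per_group, n_regions = as.integer(n_regions),
              n_modules = as.integer(n_modules),
              visits_range = as.integer(visits_range),
              visit_interval_years = visit_interval_years,
              ptau_meanlog = ptau_meanlog, ptau_sdlog = ptau_sdlog,
              plateau_factor = plateau_factor, kappa = kappa, rho = rho,
              lambda = lambda, tau_amp = tau_amp, sigma_suvr = sigma_suvr,
              r0 = r0, gamma = gamma,
              prop_mediated_cognitive = prop_mediated_cognitive,
              abeta_leak = abeta_leak, ptau_ref = ptau_ref,
              seed = as.integer(seed))
  for (nm in c("visit_interval_years", "plateau_factor", "lambda", "ptau_ref"))
    check_scalar(cfg[[nm]], nm, positive = TRUE)
  for (nm in c("kappa", "rho", "sigma_suvr", "r0", "gamma", "abeta_leak",
               "prop_mediated_cognitive"))
    check_scalar(cfg[[nm]], nm)
  if (cfg$sigma_suvr < 0) stop_config("sigma_suvr must be >= 0")
  if (!setequal(names(cfg$n_per_group), GROUP_LEVELS))
    stop_config("n_per_group must name groups %s",
                paste(GROUP_LEVELS, collapse = ", "))
  cfg$n_per_group <- cfg$n_per_group[GROUP_LEVELS]
  cfg$ptau_meanlog <- cfg$ptau_meanlog[GROUP_LEVELS]
  cfg$ptau_sdlog <- cfg$ptau_sdlog[GROUP_LEVELS]
  cfg$tau_amp <- cfg$tau_amp[GROUP_LEVELS]
  if (any(is.na(cfg$ptau_meanlog)) || any(cfg$ptau_sdlog <= 0))
    stop_config("p-tau parameters must cover every group with positive scales")
  if (cfg$n_regions < 20L || cfg$n_modules < 2L)
    stop_config("need n_regions >= 20 and n_modules >= 2")
  vr <- cfg$visits_range
  if (length(vr) != 2L || vr[1] > vr[2] || vr[1] < 2L || vr[2] > 4L)
    stop_config("visits_range must lie within [2, 4]")
  m <- exp(cfg$ptau_meanlog + cfg$ptau_sdlog^2 / 2)
  if (any(diff(m) < 0))
    stop_config("group p-tau means must be monotone non-decreasing")
  if (m[["ad"]] > cfg$plateau_factor * m[["mci_pos"]])
    stop_config("AD p-tau mean exceeds plateau_factor x MCI-positive mean")
  if (cfg$prop_mediated_cognitive <= 0 || cfg$prop_mediated_cognitive > 1)
    stop_config("prop_mediated_cognitive must be in (0, 1]")
  structure(cfg, class = "cohort_config")
}

#' Generate a modular synthetic connectome
#'
#' Weighted stochastic-block-model connectome: regions are assigned to
#' `n_modules` near-equal communities and within-module edge weights are
#' drawn stochastically larger than between-module weights. Symmetric,
#' nonnegative, zero diagonal; deterministic given the config seed.
#'
#' @param config a [cohort_config()].
#' @return list of class `synthetic_connectome` with `weights` (n x n),
#'   `modules` (integer assignment) and `n_regions`.
#' @export
make_connectome <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_regions; k <- config$n_modules
  set.seed(config$seed)
  modules <- sort(rep_len(seq_len(k), n))
  w <- matrix(0, n, n)
  ut <- which(upper.tri(w), arr.ind = TRUE)
  same <- modules[ut[, 1]] == modules[ut[, 2]]
  mu <- ifelse(same, 0.45, 0.15)
  sdw <- ifelse(same, 0.12, 0.08)
  vals <- pmax(0.01, rnorm(nrow(ut), mu, sdw))
  w[ut] <- vals
  w[ut[, c(2, 1)]] <- vals
  structure(list(weights = w, modules = modules, n_regions = n),
            class = "synthetic_connectome")
}

#' Simulate a longitudinal cohort with ground truth
#'
#' See the package vignette for the generative model. Returns the same
#' long-format tables the readers in this package validate, plus a ground
#' truth record sufficient to verify every downstream stage: true regional
#' rates, true epicenters (always inside the temporal module), the true
#' Q1 rate driving cognition, and the cognitive-chain mediation proportion
#' used during generation.
#'
#' @param config a [cohort_config()].
#' @param template a `synthetic_connectome` from [make_connectome()]
#'   (defaults to `make_connectome(config)`).
#' @return list of class `synthetic_cohort` with `visits`, `cognition`,
#'   `subjects`, `atlas`, `template`, `ground_truth`, `metadata`.
#' @export
simulate_cohort <- function(config, template = make_connectome(config)) {
  stopifnot(inherits(config, "cohort_config"),
            inherits(template, "synthetic_connectome"))
  if (template$n_regions != config$n_regions)
    stop_config("template dimensions do not match config")
  n_reg <- config$n_regions
  set.seed(config$seed + 1L)

  atlas <- data.frame(
    region_id = seq_len(n_reg),
    name = sprintf("Region_%03d", seq_len(n_reg)),
    network = paste0("Module", template$modules),
    meta_roi = template$modules == 1L)

  # distance structure used by the true rates (same path as the analysis)
  dc <- to_distance(build_template(template$weights, density = 0.30))
  offdiag <- dc$distances[upper.tri(dc$distances)]
  mean_dist <- mean(offdiag[is.finite(offdiag)])

  groups <- rep(GROUP_LEVELS, times = config$n_per_group)
  n_sub <- length(groups)
  gi <- match(groups, GROUP_LEVELS)
  ids <- sprintf("S%04d", seq_len(n_sub))

  stage_base <- c(0, 1, 2, 3)[gi]
  s <- stage_base + rnorm(n_sub, 0, 0.3)
  age_mu <- c(62.4, 71.7, 71.7, 72.7)[gi]
  age_sd <- c(15.0, 8.4, 8.4, 7.3)[gi]
  subjects <- data.frame(
    subject_id = ids, group = groups,
    age = age_mu + rnorm(n_sub) * age_sd,
    sex = rbinom(n_sub, 1L, 0.5),
    education = pmax(6, round(rnorm(n_sub, 12.5, 3.5))),
    csf_ptau = exp(rnorm(n_sub,
                         config$ptau_meanlog[gi] + 0.5 * (s - stage_base),
                         config$ptau_sdlog[gi])),
    csf_ab4240 = pmax(0.03, 0.10 - 0.025 * (1 - exp(-0.9 * pmax(s, 0))) +
                        rnorm(n_sub, 0, 0.004)),
    global_abeta_pet = 0.42 + 0.22 * (1 - exp(-0.9 * pmax(s, 0))) +
      rnorm(n_sub, 0, 0.02),
    offtarget_ratio = exp(rnorm(n_sub, log(1.1), 0.2)))

  # regional amyloid: global load with a mild temporal-lobe emphasis
  profile <- 1 + 0.10 * atlas$meta_roi
  abeta_regional <- outer(subjects$global_abeta_pet, profile) +
    matrix(rnorm(n_sub * n_reg, 0, 0.02), n_sub)
  dimnames(abeta_regional) <- list(ids, seq_len(n_reg))

  # subject-jittered epicenters inside the temporal module
  temporal <- which(template$modules == 1L)
  if (length(temporal) < 10L)
    stop_config("temporal module has %d regions; needs >= 10 for epicenters (increase n_regions or decrease n_modules)",
                length(temporal))
  canon <- exp(-0.15 * seq_along(temporal))
  epicenters <- lapply(seq_len(n_sub), function(i)
    sort(sample(temporal, 10L, prob = canon)))

  p_sc <- pmax(0, log(subjects$csf_ptau / config$ptau_ref))
  # within-group heterogeneity of tau burden (the cohort is a continuum,
  # not four point masses) and wider spatial spread of baseline tau at
  # later stages (Braak-like extension beyond the temporal lobe)
  amp <- config$tau_amp[gi] * exp(rnorm(n_sub, 0, 0.4) - 0.08)
  lambda_tau <- config$lambda / (1 + 0.5 * pmax(s - 1, 0))
  true_rates <- tau0 <- matrix(NA_real_, n_sub, n_reg,
                               dimnames = list(ids, seq_len(n_reg)))
  g_kernel <- matrix(NA_real_, n_sub, n_reg)
  for (i in seq_len(n_sub)) {
    epi <- epicenters[[i]]
    d_full <- numeric(n_reg)
    prof <- distance_to_epicenters(dc, epi)
    d_full[as.integer(names(prof))] <- prof
    g <- exp(-config$lambda * d_full / mean_dist)
    g_kernel[i, ] <- g
    g_tau <- exp(-lambda_tau[i] * d_full / mean_dist)
    tau0[i, ] <- 1.1 + amp[i] * g_tau + rnorm(n_reg, 0, 0.02)
    ab_z <- (abeta_regional[i, ] - mean(abeta_regional[i, ])) /
      max(sd(abeta_regional[i, ]), 1e-12)
    true_rates[i, ] <- config$r0 + config$kappa * p_sc[i] * g +
      config$rho * (tau0[i, ] - 1.1) + config$abeta_leak * ab_z
  }

  # observed longitudinal tau-PET
  sample_visits <- function(n) {
    choices <- config$visits_range[1]:config$visits_range[2]
    if (length(choices) == 1L) rep(choices, n)
    else sample(choices, n, replace = TRUE)
  }
  n_visits <- sample_visits(n_sub)
  visit_rows <- vector("list", n_sub)
  for (i in seq_len(n_sub)) {
    t_i <- (seq_len(n_visits[i]) - 1L) * config$visit_interval_years
    vals <- outer(rep(1, length(t_i)), tau0[i, ]) +
      outer(t_i, true_rates[i, ]) +
      matrix(rnorm(length(t_i) * n_reg, 0, config$sigma_suvr), length(t_i))
    visit_rows[[i]] <- data.frame(
      subject_id = ids[i],
      time_years = rep(t_i, times = n_reg),
      region_id = rep(seq_len(n_reg), each = length(t_i)),
      suvr = as.vector(vals))
  }
  visits <- do.call(rbind, visit_rows)

  # cognition: decline driven by the true Q1 tau rate, direct p-tau path
  # solved so the mediated share equals the configured proportion
  q1_regions <- vector("list", n_sub)
  q1rate <- numeric(n_sub)
  for (i in seq_len(n_sub)) {
    d_sub <- distance_to_epicenters(dc, epicenters[[i]])
    qa <- quartile_split(d_sub)
    q1_regions[[i]] <- as.integer(names(qa)[qa == 1L])
    q1rate[i] <- mean(true_rates[i, q1_regions[[i]]])
  }
  # the cognitive chain is analysed in the non-demented amyloid-positive
  # stratum, so the mediated share is calibrated on that subset
  nd <- groups %in% c("cu_pos", "mci_pos")
  if (sum(nd) < 3L) nd <- rep(TRUE, n_sub)
  sc <- function(x) (x - mean(x[nd])) / sd(x[nd])
  zq <- sc(q1rate)
  zp <- sc(log(subjects$csf_ptau))
  r_xm <- cor(zp[nd], zq[nd])
  prop <- config$prop_mediated_cognitive
  delta <- config$gamma * r_xm * (1 - prop) / prop
  cog_base <- c(-0.02, -0.15, -0.45, -1.2)[gi]
  cog_slope_true <- cog_base + 0.25 * (-(config$gamma * zq + delta * zp)) +
    rnorm(n_sub, 0, 0.05)
  comp0 <- c(0, -0.6, -1.4, -4.4)[gi] + rnorm(n_sub, 0, 0.4)
  mmse_slope_true <- 2.8 * (cog_slope_true - cog_base) +
    c(-0.05, -0.3, -0.8, -2.4)[gi] + rnorm(n_sub, 0, 0.05)
  mmse0 <- c(29, 28.5, 27.7, 20.1)[gi] + rnorm(n_sub, 0, 0.8)

  n_cog <- sample_visits(n_sub)
  cog_rows <- vector("list", n_sub)
  for (i in seq_len(n_sub)) {
    t_i <- (seq_len(n_cog[i]) - 1L) * config$visit_interval_years
    cog_rows[[i]] <- rbind(
      data.frame(subject_id = ids[i], time_years = t_i, measure = "composite",
                 score = comp0[i] + cog_slope_true[i] * t_i +
                   rnorm(length(t_i), 0, 0.15)),
      data.frame(subject_id = ids[i], time_years = t_i, measure = "mmse",
                 score = mmse0[i] + mmse_slope_true[i] * t_i +
                   rnorm(length(t_i), 0, 0.4)))
  }
  cognition <- do.call(rbind, cog_rows)

  ground_truth <- list(
    true_rates = true_rates, tau0 = tau0, g_kernel = g_kernel,
    epicenters = epicenters, temporal_module = temporal,
    q1_regions = q1_regions, q1rate = q1rate,
    cog_slope_true = cog_slope_true, mmse_slope_true = mmse_slope_true,
    prop_mediated_cognitive = prop, delta = delta, r_xm = r_xm,
    gradient_sign = if (config$kappa > 0) -1L else 0L)

  structure(list(visits = visits, cognition = cognition,
                 subjects = subjects, atlas = atlas, template = template,
                 abeta_regional = abeta_regional,
                 ground_truth = ground_truth,
                 metadata = list(config = unclass(config),
                                 seed = config$seed,
                                 generated = "taucascade synthetic cohort")),
            class = "synthetic_cohort")
}

#' Simulate an exact-proportion mediation dataset
#'
#' Linear structural model X -> M -> Y with a direct X -> Y path solved so
#' the population proportion mediated equals `prop_mediated`:
#' `M = a X + e`, `Y = (1 - p) c X + (p c / a) M + e`. All variables are
#' scaled to unit variance in the population.
#'
#' @param n subjects.
#' @param prop_mediated true proportion mediated in (0, 1].
#' @param total_effect population total effect c of X on Y.
#' @param a population path X -> M.
#' @param seed RNG seed.
#' @return list with `data` (data.frame x, m, y) and `truth` (a, b, c,
#'   c_prime, prop_mediated as percent).
#' @export
simulate_mediation_cohort <- function(n, prop_mediated, total_effect = 0.5,
                                      a = 0.7, seed = 1L) {
  if (prop_mediated <= 0 || prop_mediated > 1)
    stop_config("prop_mediated must be in (0, 1]")
  b <- prop_mediated * total_effect / a
  c_prime <- (1 - prop_mediated) * total_effect
  set.seed(seed)
  x <- rnorm(n)
  m <- a * x + sqrt(max(1e-6, 1 - a^2)) * rnorm(n)
  var_struct <- c_prime^2 + b^2 + 2 * a * b * c_prime
  sig_y <- sqrt(max(0.05, 1 - var_struct))
  y <- c_prime * x + b * m + sig_y * rnorm(n)
  list(data = data.frame(x = x, m = m, y = y),
       truth = list(a = a, b = b, c = total_effect, c_prime = c_prime,
                    prop_mediated = 100 * prop_mediated))
}

#' Write a synthetic cohort to a directory
#'
#' Emits the CSV formats the readers in this package consume (visits,
#' cognition, subjects, atlas), a ground-truth rates CSV and a JSON
#' metadata sidecar holding the resolved config and seed.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if absent).
#' @return invisible named vector of file paths.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(visits = file.path(dir, "visits.csv"),
             cognition = file.path(dir, "cognition.csv"),
             subjects = file.path(dir, "subjects.csv"),
             atlas = file.path(dir, "atlas.csv"),
             true_rates = file.path(dir, "ground_truth_rates.csv"),
             metadata = file.path(dir, "metadata.json"))
  write_csv_exact(cohort$visits, paths["visits"])
  write_csv_exact(cohort$cognition, paths["cognition"])
  write_csv_exact(cohort$subjects, paths["subjects"])
  write_csv_exact(cohort$atlas, paths["atlas"])
  tr <- as.data.frame(cohort$ground_truth$true_rates)
  tr <- cbind(subject_id = rownames(tr), tr)
  write_csv_exact(tr, paths["true_rates"])
  jsonlite::write_json(cohort$metadata, paths["metadata"],
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
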