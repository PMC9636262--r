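# End-to-end driver: QC -> slopes -> mixtures/epicenters -> connectome ->
# gradient -> regional maps -> mediation -> cognition, run separately per
# clinical stratum (non-demented amyloid-positive vs AD dementia by
# default), with a resolved-config record and optional output manifest.

#' Pipeline configuration
#'
#' @param cohort_config a [cohort_config()] for synthetic input (used when
#'   no external cohort is supplied to [run_pipeline()]).
#' @param density connectome edge density retained (default 0.30).
#' @param top_k epicenters per subject (default 10).
#' @param n_boot mediation bootstrap iterations (default 1000).
#' @param alpha FDR significance level (default 0.05).
#' @param offtarget_threshold off-target exclusion ratio (default 1.75).
#' @param ptau_cutoff,abeta_cutoff positivity cutoffs; `NULL` derives the
#'   p-tau cutoff from a mixture fit on the whole cohort's p-tau values.
#' @param strata named list of group-label vectors defining the analysis
#'   strata (default: non-demented amyloid-positive vs AD dementia).
#' @param seed analysis seed (bootstrap resampling, mixture restarts).
#' @return list of class `run_config`.
#' @export
run_config <- function(cohort_config = taucascade::cohort_config(),
                       density = 0.30, top_k = 10L, n_boot = 1000L,
                       alpha = 0.05, offtarget_threshold = 1.75,
                       ptau_cutoff = NULL, abeta_cutoff = 0.53,
                       strata = list(nondemented = c("cu_pos", "mci_pos"),
                                     ad = "ad"),
                       seed = 1L) {
  structure(list(cohort_config = cohort_config, density = density,
                 top_k = as.integer(top_k), n_boot = as.integer(n_boot),
                 alpha = alpha, offtarget_threshold = offtarget_threshold,
                 ptau_cutoff = ptau_cutoff, abeta_cutoff = abeta_cutoff,
                 strata = strata, seed = as.integer(seed)),
            class = "run_config")
}

abeta_matrix_from_cohort <- function(cohort) {
  # subjects x regions regional amyloid; synthetic cohorts carry it in the
  # generator output, external cohorts must supply it
  if (!is.null(cohort$abeta_regional)) return(cohort$abeta_regional)
  stop_config("cohort lacks regional amyloid data")
}

baseline_suvr_matrix <- function(visits) {
  base <- visits[visits$time_years == 0, ]
  subj <- sort(unique(as.character(base$subject_id)))
  regions <- sort(unique(base$region_id))
  m <- matrix(NA_real_, length(subj), length(regions),
              dimnames = list(subj, regions))
  m[cbind(match(as.character(base$subject_id), subj),
          match(base$region_id, regions))] <- base$suvr
  m
}

#' Run the full cascade analysis
#'
#' Executes, in order: subject QC (off-target exclusion, positivity
#' flags); per-region mixed-model slopes; pooled-cohort mixture fits and
#' subject epicenters; template thresholding and graph distances;
#' per-subject gradient betas and connectivity quartiles with the
#' p-tau-by-quartile interaction; progressive regional regression maps
#' (M1-M4) with FDR; the regional amyloid -> p-tau -> tau-rate mediation
#' map; cognitive slopes; and the two cognitive mediation chains (p-tau ->
#' Q1 rate -> cognition, p-tau -> gradient beta -> cognition). Stages
#' after QC are run separately within each configured stratum.
#'
#' @param config a [run_config()].
#' @param cohort a `synthetic_cohort` (or compatible list with `visits`,
#'   `cognition`, `subjects`, `atlas`, `template`); generated from
#'   `config$cohort_config` when `NULL`.
#' @param out_dir optional directory; when given, key tables are written
#'   there together with a manifest of file hashes.
#' @param stages character vector to restrict which analysis stages run
#'   (default all): "maps", "mediation_regional", "anova", "cognition".
#' @return list of class `cascade_run` with `qc`, `slopes`, `gmm`,
#'   `epicenters`, `distance`, per-stratum `strata` results and
#'   `resolved_config`.
#' @export
run_pipeline <- function(config = run_config(), cohort = NULL,
                         out_dir = NULL,
                         stages = c("maps", "mediation_regional", "anova",
                                    "cognition")) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(cohort)) cohort <- simulate_cohort(config$cohort_config)
  visits <- validate_visit_table(cohort$visits,
                                 n_regions = nrow(cohort$atlas))
  atlas <- validate_atlas(cohort$atlas, n_regions = nrow(cohort$atlas))

  # --- QC ---------------------------------------------------------------
  qc <- filter_offtarget(cohort$subjects, config$offtarget_threshold)
  subjects <- qc$subjects
  ptau_cut <- config$ptau_cutoff
  gmm_ptau <- NULL
  if (is.null(ptau_cut)) {
    gmm_ptau <- fit_region_gmm(log(subjects$csf_ptau), seed = config$seed)
    ptau_cut <- if (gmm_ptau$ambiguous) 114.4 else exp(gmm_cutoff(gmm_ptau))
  }
  subjects <- classify_positivity(subjects, ptau_cutoff = ptau_cut,
                                  abeta_cutoff = config$abeta_cutoff)
  keep_ids <- subjects$subject_id
  visits <- visits[visits$subject_id %in% keep_ids, ]
  cognition <- cohort$cognition[cohort$cognition$subject_id %in% keep_ids, ]

  # --- slopes -----------------------------------------------------------
  sm <- fit_all_regions(visits)

  # --- mixtures and epicenters (pooled over the whole cohort) -----------
  baseline <- baseline_suvr_matrix(visits)
  fits <- lapply(seq_len(ncol(baseline)), function(r)
    fit_region_gmm(baseline[, r], seed = config$seed + r))
  esc <- epicenter_scores(baseline, fits)
  epi_list <- lapply(rownames(baseline), function(sid) {
    sc <- esc$scores[sid, ]
    eligible <- which(!is.na(sc))
    ord <- order(-sc[eligible], eligible)[seq_len(config$top_k)]
    eligible[ord]
  })
  names(epi_list) <- rownames(baseline)

  # --- connectome -------------------------------------------------------
  template <- build_template(cohort$template$weights, density = config$density)
  dist <- to_distance(template)

  # --- per-stratum analyses --------------------------------------------
  stratum_results <- list()
  for (sname in names(config$strata)) {
    g <- config$strata[[sname]]
    sidx <- subjects$subject_id[subjects$group %in% g]
    sidx <- intersect(sidx, rownames(sm$slopes))
    if (length(sidx) < 10L) next
    res <- analyze_stratum(sidx, sm, dist, epi_list, subjects, cohort,
                           cognition, config, stages)
    stratum_results[[sname]] <- res
  }

  out <- structure(list(qc = qc, gmm_ptau = gmm_ptau,
                        ptau_cutoff = ptau_cut, subjects = subjects,
                        slopes = sm, gmm_excluded = esc$excluded,
                        epicenters = epi_list, template = template,
                        distance = dist, strata = stratum_results,
                        resolved_config = config),
                   class = "cascade_run")
  if (!is.null(out_dir)) write_run(out, out_dir)
  out
}

analyze_stratum <- function(sidx, sm, dist, epi_list, subjects, cohort,
                            cognition, config, stages) {
  slopes <- sm$slopes[sidx, , drop = FALSE]
  si <- subjects[match(sidx, subjects$subject_id), ]

  # gradient betas and quartile means
  betas <- numeric(length(sidx))
  qmeans <- matrix(NA_real_, length(sidx), 4,
                   dimnames = list(sidx, paste0("Q", 1:4)))
  for (i in seq_along(sidx)) {
    epi <- epi_list[[sidx[i]]]
    prof <- distance_to_epicenters(dist, epi)
    rates <- slopes[i, names(prof)]
    gb <- gradient_beta(rates, prof)
    betas[i] <- gb$beta
    qa <- quartile_split(prof)
    qmeans[i, ] <- quartile_rates(rates, qa)$mean_rate
  }

  res <- list(subjects = si, gradient_beta = setNames(betas, sidx),
              quartile_means = qmeans)

  if ("anova" %in% stages) {
    # the p-tau x quartile interaction needs both positivity levels; at the
    # dementia stage p-tau has plateaued and everyone is positive
    tab <- table(si$ptau_positive)
    res$anova <- if (length(tab) == 2L && min(tab) >= 2L)
      ptau_quartile_anova(qmeans, si$ptau_positive) else NULL
    res$beta_vs_ptau <- beta_vs_ptau(
      betas, si$csf_ptau,
      covariates = data.frame(abeta = si$global_abeta_pet,
                              age = si$age, sex = si$sex))
  }

  sm_str <- structure(list(slopes = slopes,
                           baselines = sm$baselines[sidx, , drop = FALSE],
                           diagnostics = sm$diagnostics, subjects = sidx),
                      class = "slope_matrix")
  abeta_reg <- if (!is.null(cohort$abeta_regional)) cohort$abeta_regional
               else NULL
  if ("maps" %in% stages && !is.null(abeta_reg)) {
    res$maps <- lapply(setNames(nm = names(MODEL_PREDICTORS)), function(m)
      fit_regional_maps(sm_str, si, abeta_reg, model = m,
                        alpha = config$alpha))
    if ("mediation_regional" %in% stages) {
      sig <- res$maps$M1
      regions <- sig$region_id[sig$term == "abeta" & sig$significant]
      res$mediation_regional <- regional_mediation_map(
        sm_str, si, abeta_reg, regions = regions,
        n_boot = config$n_boot, seed = config$seed)
    }
  }

  if ("cognition" %in% stages && !is.null(cognition) && nrow(cognition)) {
    cg <- cognition[cognition$subject_id %in% sidx, ]
    if (length(unique(cg$subject_id)) >= 10L) {
      cs <- fit_cognitive_slopes(cg)
      res$cognitive_slopes <- cs
      comp <- cs[cs$measure == "composite", ]
      m <- match(comp$subject_id, sidx)
      q1 <- qmeans[m, 1]
      covs <- data.frame(age = si$age[m], sex = si$sex[m],
                         education = si$education[m])
      res$mediation_q1 <- mediate(
        exposure = log(si$csf_ptau[m]), mediator = q1,
        outcome = comp$slope, covariates = covs,
        n_boot = config$n_boot, seed = config$seed + 10001L)
      res$mediation_beta <- mediate(
        exposure = log(si$csf_ptau[m]), mediator = betas[m],
        outcome = comp$slope, covariates = covs,
        n_boot = config$n_boot, seed = config$seed + 10002L)
    }
  }
  res
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  wr <- function(df, name) {
    p <- file.path(out_dir, name)
    write.csv(df, p, row.names = FALSE)
    paths[[name]] <<- p
  }
  sl <- as.data.frame(run$slopes$slopes)
  wr(cbind(subject_id = rownames(sl), sl), "slopes.csv")
  wr(run$slopes$diagnostics, "slope_diagnostics.csv")
  epi <- do.call(rbind, lapply(names(run$epicenters), function(s)
    data.frame(subject_id = s, rank = seq_along(run$epicenters[[s]]),
               region_id = run$epicenters[[s]])))
  wr(epi, "epicenters.csv")
  for (sname in names(run$strata)) {
    st <- run$strata[[sname]]
    wr(data.frame(subject_id = names(st$gradient_beta),
                  beta = st$gradient_beta), paste0("gradient_", sname, ".csv"))
    if (!is.null(st$maps))
      wr(do.call(rbind, st$maps), paste0("maps_", sname, ".csv"))
  }
  cfgp <- file.path(out_dir, "resolved_config.json")
  jsonlite::write_json(
    list(analysis = unclass(run$resolved_config[
      setdiff(names(run$resolved_config), "cohort_config")]),
      cohort = unclass(run$resolved_config$cohort_config)),
    cfgp, auto_unbox = TRUE, digits = NA, force = TRUE)
  paths[["resolved_config.json"]] <- cfgp
  manifest <- data.frame(file = names(paths),
                         md5 = vapply(paths, function(p)
                           as.character(tools::md5sum(p)), character(1)))
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
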