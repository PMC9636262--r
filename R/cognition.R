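# PACC5-like cognitive composite.
#
# Four tests (MMSE, ADAS-cog delayed recall, Trail-Making Test A, animal
# fluency) are z-scored against a reference population (cognitively
# unimpaired amyloid-negative participants over 50) and averaged with the
# memory test double-weighted so memory keeps the same share as in the
# original five-test composite: (2 z_recall + z_mmse + z_tmt + z_fluency)/5.
# Orientation is explicit configuration: tests scored so that higher means
# worse (TMT-A completion time, ADAS errors) are sign-flipped before
# averaging, making a higher composite always mean better cognition.

#' Composite specification
#'
#' @param tests test names.
#' @param weights positive weights (memory test = 2, others 1; must sum
#'   to 5 for the four-test composite).
#' @param orientation +1 when a higher raw score means better cognition,
#'   -1 when it means worse (flipped after z-scoring).
#' @return list of class `composite_spec`.
#' @export
composite_spec <- function(tests = c("adas_recall", "mmse", "tmt_a", "fluency"),
                           weights = c(adas_recall = 2, mmse = 1,
                                       tmt_a = 1, fluency = 1),
                           orientation = c(adas_recall = -1, mmse = 1,
                                           tmt_a = -1, fluency = 1)) {
  if (!setequal(tests, names(weights)) || !setequal(tests, names(orientation)))
    stop_config("weights and orientation must cover exactly the tests")
  if (any(weights <= 0)) stop_config("weights must be positive")
  if (!all(orientation %in% c(-1, 1)))
    stop_config("orientation must be +1 or -1 for every test")
  structure(list(tests = tests, weights = weights[tests],
                 orientation = orientation[tests]),
            class = "composite_spec")
}

#' Reference-population statistics for z-scoring
#'
#' Computes and caches the reference mean and standard deviation so that
#' follow-up visits are scored against the same baseline reference, never
#' refitted.
#'
#' @param reference numeric vector from the reference sample (n >= 10).
#' @return list with `mean`, `sd`, `n` (class `reference_stats`).
#' @export
reference_stats <- function(reference) {
  reference <- reference[is.finite(reference)]
  if (length(reference) < 10L)
    stop_config("reference sample needs >= 10 values")
  s <- sd(reference)
  if (s == 0) stop_config("reference sample has zero standard deviation")
  structure(list(mean = mean(reference), sd = s, n = length(reference)),
            class = "reference_stats")
}

#' Z-score against a reference population
#'
#' @param x values to score.
#' @param reference either a raw reference sample or cached
#'   [reference_stats()].
#' @return `(x - ref mean) / ref sd`.
#' @export
zscore_reference <- function(x, reference) {
  st <- if (inherits(reference, "reference_stats")) reference
        else reference_stats(reference)
  (x - st$mean) / st$sd
}

#' Compose the cognitive composite from per-test z-scores
#'
#' Applies the orientation signs, then the weighted average with weights
#' divided by their sum (5 for the default spec). A visit missing any
#' component gets an `NA` composite (complete-case, logged).
#'
#' @param z data.frame or matrix of per-test z-scores, columns named after
#'   the spec's tests; or a named vector for a single visit.
#' @param spec a [composite_spec()].
#' @return numeric composite per row.
#' @export
compose_composite <- function(z, spec = composite_spec()) {
  if (is.null(dim(z))) z <- as.data.frame(as.list(z))
  z <- as.data.frame(z)
  miss <- setdiff(spec$tests, names(z))
  if (length(miss))
    stop_config("missing component column(s): %s", paste(miss, collapse = ", "))
  zm <- as.matrix(z[, spec$tests, drop = FALSE])
  oriented <- sweep(zm, 2, spec$orientation, `*`)
  comp <- as.vector(oriented %*% spec$weights) / sum(spec$weights)
  n_na <- sum(is.na(comp))
  if (n_na) message(n_na, " visit(s) with a missing component; composite NA")
  comp
}

#' Build a longitudinal composite table from raw test scores
#'
#' Z-scores every test against reference statistics estimated once from
#' the baseline visits of the reference subjects, orients and averages per
#' visit, and returns a long table ready for [fit_cognitive_slopes()].
#'
#' @param scores long data.frame `subject_id`, `time_years`, `test`,
#'   `score`.
#' @param reference_ids subject IDs of the reference population
#'   (cognitively unimpaired amyloid-negative, age > 50).
#' @param spec a [composite_spec()].
#' @return list with `composite` (data.frame `subject_id`, `time_years`,
#'   `measure` = "composite", `score`) and `reference` (per-test cached
#'   stats).
#' @export
build_composite <- function(scores, reference_ids, spec = composite_spec()) {
  req <- c("subject_id", "time_years", "test", "score")
  miss <- setdiff(req, names(scores))
  if (length(miss))
    stop_config("scores table missing column(s): %s", paste(miss, collapse = ", "))
  ref_stats <- lapply(setNames(spec$tests, spec$tests), function(tt) {
    base <- scores$subject_id %in% reference_ids & scores$test == tt &
      scores$time_years == 0
    reference_stats(scores$score[base])
  })
  wide <- stats::reshape(scores, idvar = c("subject_id", "time_years"),
                         timevar = "test", direction = "wide")
  names(wide) <- sub("^score\\.", "", names(wide))
  z <- wide
  for (tt in spec$tests) z[[tt]] <- zscore_reference(wide[[tt]], ref_stats[[tt]])
  comp <- compose_composite(z[, spec$tests, drop = FALSE], spec)
  list(composite = data.frame(subject_id = wide$subject_id,
                              time_years = wide$time_years,
                              measure = "composite", score = comp),
       reference = ref_stats)
}
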