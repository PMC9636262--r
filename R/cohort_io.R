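# Tabular I/O, schema validation and subject-level quality control.
#
# All tables are plain CSV with a header row. Visit times are expressed in
# years from each subject's earliest visit; when calendar dates are given
# they are converted using 365.25 days per year. Boundary conventions are
# strict: a subject is excluded (or called positive) only when the value is
# strictly above the threshold, matching the "above" wording of the QC and
# positivity rules.

GROUP_LEVELS <- c("cn_neg", "cu_pos", "mci_pos", "ad")

#' Read and validate a long-format visit table
#'
#' Required columns: `subject_id`, `region_id`, a value column, and either
#' `time_years` or ISO-8601 `visit_date`. Times are re-anchored to years
#' from each subject's earliest visit. Duplicate (subject, time, region)
#' rows, negative times and subjects with fewer than two distinct time
#' points raise schema errors naming the offending rows.
#'
#' @param path CSV file path.
#' @param value_col name of the value column (default "suvr").
#' @param n_regions atlas size for the region-ID range check (default 200;
#'   `NULL` disables the check).
#' @return validated data.frame with `subject_id`, `time_years`,
#'   `region_id`, and the value column.
#' @export
read_visit_table <- function(path, value_col = "suvr", n_regions = 200L) {
  if (!file.exists(path)) stop_config("file not found: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  validate_visit_table(df, value_col = value_col, n_regions = n_regions)
}

#' Validate an in-memory visit table
#'
#' @inheritParams read_visit_table
#' @param df data.frame to validate.
#' @return the validated, time-anchored data.frame.
#' @export
validate_visit_table <- function(df, value_col = "suvr", n_regions = 200L) {
  need_time <- !("time_years" %in% names(df))
  req <- c("subject_id", if (need_time) "visit_date", "region_id", value_col)
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop_config("visit table missing column(s): %s", paste(miss, collapse = ", "))
  if (need_time) {
    dates <- as.Date(df$visit_date)
    if (any(is.na(dates)))
      stop_config("unparseable visit_date rows: %s",
                  paste(head(which(is.na(dates)), 5), collapse = ", "))
    base <- tapply(as.numeric(dates), df$subject_id, min)
    df$time_years <- as.numeric(
      (as.numeric(dates) - base[as.character(df$subject_id)]) / 365.25)
  }
  df$time_years <- as.numeric(df$time_years)
  if (any(!is.finite(df$time_years)))
    stop_config("non-finite time_years rows: %s",
                paste(head(which(!is.finite(df$time_years)), 5), collapse = ", "))
  if (any(df$time_years < 0))
    stop_config("negative time_years rows: %s",
                paste(head(which(df$time_years < 0), 5), collapse = ", "))
  # re-anchor to each subject's earliest visit
  base <- tapply(df$time_years, df$subject_id, min)
  df$time_years <- as.numeric(df$time_years - base[as.character(df$subject_id)])
  key <- paste(df$subject_id, df$time_years, df$region_id, sep = "\r")
  if (anyDuplicated(key))
    stop_config("duplicate (subject, time, region) rows: %s",
                paste(head(which(duplicated(key)), 5), collapse = ", "))
  if (!is.null(n_regions)) {
    rid <- suppressWarnings(as.integer(df$region_id))
    bad <- which(is.na(rid) | rid < 1L | rid > n_regions)
    if (length(bad))
      stop_config("region_id outside 1..%d at rows: %s", n_regions,
                  paste(head(bad, 5), collapse = ", "))
    df$region_id <- rid
  }
  tp <- tapply(df$time_years, df$subject_id, function(t) length(unique(t)))
  if (any(tp < 2))
    stop_config("subject(s) with < 2 distinct time points: %s",
                paste(head(names(tp)[tp < 2], 5), collapse = ", "))
  df[, c("subject_id", "time_years", "region_id", value_col)]
}

#' Write a visit table to CSV
#'
#' Doubles are written with 17 significant digits so a write/read cycle
#' reproduces the table bit-exactly.
#'
#' @param df visit table.
#' @param path output CSV path.
#' @export
write_visit_table <- function(df, path) {
  write_csv_exact(df, path)
  invisible(path)
}

write_csv_exact <- function(df, path) {
  out <- df
  for (nm in names(out))
    if (is.double(out[[nm]])) out[[nm]] <- sprintf("%.17g", out[[nm]])
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and validate a parcel atlas
#'
#' CSV columns: `region_id`, `name`, `network`, `meta_roi` (0/1 flag for
#' temporal meta-ROI membership). Region IDs must be exactly 1..n and the
#' meta-ROI a non-empty strict subset.
#'
#' @param path CSV file path.
#' @param n_regions expected number of regions (default 200).
#' @return validated data.frame.
#' @export
read_atlas <- function(path, n_regions = 200L) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  validate_atlas(df, n_regions)
}

#' @rdname read_atlas
#' @param df in-memory atlas data.frame.
#' @export
validate_atlas <- function(df, n_regions = 200L) {
  req <- c("region_id", "name", "network", "meta_roi")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop_config("atlas missing column(s): %s", paste(miss, collapse = ", "))
  if (!setequal(df$region_id, seq_len(n_regions)) ||
      nrow(df) != n_regions)
    stop_config("atlas must contain exactly region IDs 1..%d", n_regions)
  df$meta_roi <- as.logical(df$meta_roi)
  k <- sum(df$meta_roi)
  if (k == 0L || k == n_regions)
    stop_config("meta-ROI must be a non-empty strict subset of the atlas")
  df[order(df$region_id), ]
}

#' Exclude subjects with high off-target binding
#'
#' Retains subjects whose off-target (skull/meningeal to brain) SUVR ratio
#' is at or below the threshold; only ratios strictly above it are
#' excluded. Subjects with a missing ratio pass with a logged warning,
#' never silently excluded. Idempotent.
#'
#' @param subjects data.frame with `subject_id` and `offtarget_ratio`.
#' @param threshold exclusion threshold (default 1.75).
#' @return list with `subjects` (retained rows) and `log` (data.frame of
#'   excluded `subject_id` and `offtarget_ratio`).
#' @export
filter_offtarget <- function(subjects, threshold = 1.75) {
  if (!nrow(subjects))
    return(list(subjects = subjects,
                log = data.frame(subject_id = character(),
                                 offtarget_ratio = numeric())))
  ratio <- subjects$offtarget_ratio
  if (is.null(ratio)) {
    warning("no offtarget_ratio column; all subjects retained")
    ratio <- rep(NA_real_, nrow(subjects))
  }
  if (any(is.na(ratio)))
    warning(sum(is.na(ratio)), " subject(s) lack offtarget_ratio; retained")
  drop <- !is.na(ratio) & ratio > threshold
  list(subjects = subjects[!drop, , drop = FALSE],
       log = data.frame(subject_id = subjects$subject_id[drop],
                        offtarget_ratio = ratio[drop]))
}

#' Flag biomarker positivity from fixed cutoffs
#'
#' Adds `abeta_positive` and `ptau_positive` flags; a value strictly above
#' its cutoff is positive (a value exactly at the cutoff is negative).
#' Missing biomarkers yield `NA` flags with a message.
#'
#' @param subjects data.frame with `csf_ptau` and either
#'   `global_abeta_pet` or `csf_ab4240`.
#' @param ptau_cutoff p-tau cutoff in pg/ml (e.g. a GMM-derived 114.4).
#' @param abeta_cutoff amyloid-PET SUVR cutoff (e.g. 0.53).
#' @param ab4240_cutoff CSF Ab42/40 ratio cutoff, positive when strictly
#'   below (ratio falls with amyloid load; default 0.08); used when PET is
#'   unavailable for a subject.
#' @return `subjects` with the two logical flag columns appended.
#' @export
classify_positivity <- function(subjects, ptau_cutoff, abeta_cutoff,
                                ab4240_cutoff = 0.08) {
  check_scalar(ptau_cutoff, "ptau_cutoff", positive = TRUE)
  check_scalar(abeta_cutoff, "abeta_cutoff", positive = TRUE)
  pt <- subjects$csf_ptau
  subjects$ptau_positive <- ifelse(is.na(pt), NA, pt > ptau_cutoff)
  pet <- if ("global_abeta_pet" %in% names(subjects)) subjects$global_abeta_pet
         else rep(NA_real_, nrow(subjects))
  csf <- if ("csf_ab4240" %in% names(subjects)) subjects$csf_ab4240
         else rep(NA_real_, nrow(subjects))
  ab <- ifelse(!is.na(pet), pet > abeta_cutoff,
               ifelse(!is.na(csf), csf < ab4240_cutoff, NA))
  subjects$abeta_positive <- ab
  n_unknown <- sum(is.na(subjects$ptau_positive)) + sum(is.na(ab))
  if (n_unknown)
    message(n_unknown, " positivity flag(s) unknown (missing biomarker)")
  subjects
}
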