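# Functional connectome template construction and graph distances.
#
# The analysis treats strongly connected region pairs as "close": subject
# Fisher-z matrices are averaged, thresholded to a fixed edge density, edge
# weights are converted to lengths (1/weight) and all-pairs shortest paths
# give the distance-based connectome used by the spreading statistic.

#' Censor high-motion frames from an fMRI run
#'
#' Frames whose framewise displacement (FD) exceeds `fd_threshold` are
#' censored together with the one preceding and the two following frames.
#' A run is flagged as unusable when the censored fraction reaches
#' `max_censored_fraction`.
#'
#' @param fd numeric vector of framewise displacement per frame (mm),
#'   length >= 10, all finite.
#' @param fd_threshold displacement above which a frame is censored (mm).
#' @param max_censored_fraction runs with a censored fraction at or above
#'   this value are flagged `retain = FALSE`.
#' @return list with `keep` (logical per frame), `censored_fraction` and
#'   `retain`.
#' @export
scrub_frames <- function(fd, fd_threshold = 1.0, max_censored_fraction = 0.30) {
  if (!is.numeric(fd) || length(fd) < 10L)
    stop_config("`fd` must be a numeric vector of length >= 10")
  if (any(!is.finite(fd)))
    stop_config("`fd` contains non-finite values")
  n <- length(fd)
  bad <- which(fd > fd_threshold)
  censored <- logical(n)
  for (i in bad) {
    lo <- max(1L, i - 1L)
    hi <- min(n, i + 2L)
    censored[lo:hi] <- TRUE
  }
  frac <- mean(censored)
  list(keep = !censored,
       censored_fraction = frac,
       retain = frac < max_censored_fraction)
}

#' Subject functional connectivity from ROI time series
#'
#' Pearson correlations between ROI-averaged time series mapped through the
#' Fisher z-transform (`atanh`). Correlations of +/-1 are clipped to
#' +/-(1 - 1e-7) before the transform. Zero-variance ROIs get zero edges
#' with a warning. The diagonal is zero.
#'
#' @param ts numeric matrix, frames x ROIs, with >= 2 rows.
#' @return symmetric ROI x ROI Fisher-z matrix with zero diagonal.
#' @export
fc_from_timeseries <- function(ts) {
  ts <- as.matrix(ts)
  if (nrow(ts) < 2L)
    stop_config("need at least 2 retained frames")
  sds <- apply(ts, 2L, sd)
  flat <- which(sds == 0 | !is.finite(sds))
  r <- suppressWarnings(cor(ts))
  if (length(flat)) {
    warning(sprintf("%d zero-variance ROI(s); their edges set to 0", length(flat)))
    r[flat, ] <- 0
    r[, flat] <- 0
  }
  r[!is.finite(r)] <- 0
  clip <- 1 - 1e-7
  r[r > clip] <- clip
  r[r < -clip] <- -clip
  z <- atanh(r)
  diag(z) <- 0
  z
}

#' Average subject matrices and threshold to a fixed edge density
#'
#' Element-wise mean of the subject Fisher-z matrices; negative mean edges
#' are dropped (path lengths require positive weights), then the
#' `floor(density * n * (n - 1) / 2)` strongest undirected edges are
#' retained and all others zeroed. Ties at the density boundary are broken
#' deterministically by weight (descending) then by lower (i, j) index.
#'
#' @param fc_list a single matrix or list of symmetric n x n matrices.
#' @param density fraction of undirected edges to retain (default 0.30).
#' @return object of class `connectivity_template`: list with `weights`
#'   (n x n), `density`, `n_edges` and `n_subjects`.
#' @export
build_template <- function(fc_list, density = 0.30) {
  if (is.matrix(fc_list)) fc_list <- list(fc_list)
  if (!length(fc_list)) stop_config("need at least one subject matrix")
  check_scalar(density, "density", positive = TRUE)
  dims <- vapply(fc_list, function(m) dim(as.matrix(m)), integer(2))
  if (length(unique(dims[1, ])) != 1L || any(dims[1, ] != dims[2, ]))
    stop_config("subject matrices must share square dimensions")
  n <- dims[1, 1]
  avg <- Reduce(`+`, lapply(fc_list, as.matrix)) / length(fc_list)
  avg <- (avg + t(avg)) / 2
  diag(avg) <- 0
  avg[avg < 0] <- 0

  m_keep <- floor(density * n * (n - 1) / 2)
  ut <- which(upper.tri(avg), arr.ind = TRUE)
  w <- avg[ut]
  ord <- order(-w, ut[, 1], ut[, 2])
  keep <- ord[seq_len(min(m_keep, sum(w > 0)))]
  out <- matrix(0, n, n)
  ik <- ut[keep, , drop = FALSE]
  out[ik] <- avg[ik]
  out[ik[, c(2, 1), drop = FALSE]] <- avg[ik]
  structure(list(weights = out, density = density,
                 n_edges = nrow(ik), n_subjects = length(fc_list)),
            class = "connectivity_template")
}

#' Convert a thresholded connectivity template to graph distances
#'
#' Retained edges get length 1/weight; all-pairs shortest paths (Dijkstra)
#' over the resulting weighted graph give the distance-based connectome in
#' which strongly connected regions are close. Unreachable pairs are kept
#' as `Inf` and flagged in the reachability mask.
#'
#' @param template a `connectivity_template` (or a nonnegative symmetric
#'   weight matrix).
#' @return object of class `distance_connectome`: list with `distances`
#'   (n x n, `Inf` for unreachable pairs), `reachable` (logical mask) and
#'   `n_regions`.
#' @export
to_distance <- function(template) {
  w <- if (inherits(template, "connectivity_template")) template$weights
       else as.matrix(template)
  if (any(w < 0)) stop_config("edge weights must be nonnegative")
  n <- nrow(w)
  len <- ifelse(w > 0, 1 / w, 0)
  g <- igraph::graph_from_adjacency_matrix(len, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  d <- igraph::distances(g, algorithm = "dijkstra")
  dimnames(d) <- NULL
  structure(list(distances = d, reachable = is.finite(d), n_regions = n),
            class = "distance_connectome")
}

#' Mean graph distance of every non-epicenter region to the epicenters
#'
#' @param dist a `distance_connectome`.
#' @param epicenters integer vector of unique epicenter region IDs.
#' @return named numeric vector over the non-epicenter regions: arithmetic
#'   mean of the graph distances to the epicenter nodes (restricted to
#'   reachable epicenters, with a warning when some are unreachable).
#'   Errors if a region is unreachable from every epicenter.
#' @export
distance_to_epicenters <- function(dist, epicenters) {
  stopifnot(inherits(dist, "distance_connectome"))
  epicenters <- as.integer(epicenters)
  if (anyDuplicated(epicenters))
    stop_config("duplicate epicenter IDs")
  n <- dist$n_regions
  if (any(epicenters < 1L | epicenters > n))
    stop_config("epicenter IDs outside atlas range 1..%d", n)
  others <- setdiff(seq_len(n), epicenters)
  d <- dist$distances[others, epicenters, drop = FALSE]
  finite <- is.finite(d)
  dead <- others[rowSums(finite) == 0L]
  if (length(dead))
    stop_config("region(s) unreachable from all epicenters: %s",
                paste(dead, collapse = ", "))
  if (!all(finite))
    warning("some region-epicenter pairs unreachable; means use reachable epicenters only")
  prof <- rowSums(ifelse(finite, d, 0)) / rowSums(finite)
  names(prof) <- others
  prof
}
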