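# Temporal trajectories of a soundscape in the projected acoustic
# space, stabilised over the UMAP ensemble.

#' Time-ordered path of one (group, replicate) in an embedding
#'
#' @param points Embedding matrix (one row per sample).
#' @param samples Sample tibble aligned with `points` (needs
#'   `window_start` and the group/replicate columns).
#' @param group,replicate Category values selecting the path.
#' @param group_col,replicate_col Column names (defaults `"site"`,
#'   `"replicate"`).
#' @return The selected rows of `points`, ordered by `window_start`,
#'   with the times as a `window_start` attribute.
#' @export
path_points <- function(points, samples, group, replicate,
                        group_col = "site", replicate_col = "replicate") {
  idx <- which(samples[[group_col]] == group &
                 samples[[replicate_col]] == replicate)
  if (length(idx) == 0) {
    stop("no samples for ", group_col, " = ", group, ", ",
         replicate_col, " = ", replicate, call. = FALSE)
  }
  idx <- idx[order(samples$window_start[idx])]
  out <- points[idx, , drop = FALSE]
  attr(out, "window_start") <- samples$window_start[idx]
  out
}

# Reference point of a group within one embedding: the centroid of the
# group's first-time-window samples, pooled across replicates.
group_reference <- function(points, samples, group, group_col,
                            replicate_col) {
  gi <- which(samples[[group_col]] == group)
  reps <- unique(samples[[replicate_col]][gi])
  first_idx <- unlist(lapply(reps, function(r) {
    ri <- gi[samples[[replicate_col]][gi] == r]
    ri[samples$window_start[ri] == min(samples$window_start[ri])]
  }))
  colMeans(points[first_idx, , drop = FALSE])
}

#' Ensemble-stabilised relative trajectory of a group
#'
#' Within each embedding of the ensemble, a group's reference point is
#' the centroid of its first-time-window samples pooled across
#' replicates.  Each sample's distance to the reference is divided by
#' the mean distance from the reference to its `k` nearest sample
#' points (a scale the embedding's arbitrary units cancel out of), so
#' trajectories typically start near zero and hover around one once
#' they leave the reference neighborhood.  The per-time median and the
#' first/ninth deciles over the ensemble's repeats are reported.
#'
#' @param ensemble A `reef_ensemble` from [run_ensemble()].
#' @param group Category value of `group_col` to follow.
#' @param samples Sample tibble; defaults to the one stored in
#'   `ensemble`.
#' @param group_col,replicate_col Grouping columns (defaults `"site"`,
#'   `"replicate"`).
#' @param k Number of nearest neighbors defining the normalisation
#'   scale (default 100; reduced to the available sample count, and
#'   recorded in `k_used`).
#' @return A `reef_trajectory` tibble: `group`, `replicate`, `time`,
#'   `median_rel_distance`, `decile_low`, `decile_high`, `k_used`.
#' @export
relative_trajectory <- function(ensemble, group, samples = NULL,
                                group_col = "site",
                                replicate_col = "replicate", k = 100) {
  stopifnot(inherits(ensemble, "reef_ensemble"), k >= 1)
  if (is.null(samples)) samples <- ensemble$samples
  if (is.null(samples)) stop("no sample table available", call. = FALSE)
  n <- nrow(samples)
  k_used <- min(k, n - 1)
  gi <- which(samples[[group_col]] == group)
  if (length(gi) == 0) {
    stop("no samples for ", group_col, " = ", group, call. = FALSE)
  }
  # relative distances: one row per repeat, one column per group sample
  rel <- matrix(NA_real_, ensemble$n_repeats, length(gi))
  for (r in seq_len(ensemble$n_repeats)) {
    pts <- ensemble$embeddings[[r]]
    ref <- group_reference(pts, samples, group, group_col, replicate_col)
    dref <- sqrt(colSums((t(pts) - ref)^2))
    scale <- mean(sort(dref)[seq_len(k_used)])
    if (scale <= 0) {
      stop("degenerate normalisation: all points at the reference",
           call. = FALSE)
    }
    rel[r, ] <- dref[gi] / scale
  }
  med <- apply(rel, 2, stats::median)
  d1 <- apply(rel, 2, stats::quantile, probs = 0.1, names = FALSE, type = 7)
  d9 <- apply(rel, 2, stats::quantile, probs = 0.9, names = FALSE, type = 7)
  out <- tibble::tibble(
    group = group,
    replicate = samples[[replicate_col]][gi],
    time = samples$window_start[gi],
    median_rel_distance = med,
    decile_low = d1,
    decile_high = d9,
    k_used = k_used
  )
  out <- dplyr::arrange(out, .data$replicate, .data$time)
  class(out) <- c("reef_trajectory", class(out))
  out
}

#' Relative trajectories of every group
#'
#' @inheritParams relative_trajectory
#' @return A `reef_trajectory` tibble covering all groups.
#' @export
soundscape_trajectories <- function(ensemble, samples = NULL,
                                    group_col = "site",
                                    replicate_col = "replicate", k = 100) {
  if (is.null(samples)) samples <- ensemble$samples
  groups <- unique(samples[[group_col]])
  out <- dplyr::bind_rows(lapply(groups, function(g) {
    relative_trajectory(ensemble, g, samples, group_col, replicate_col, k)
  }))
  class(out) <- c("reef_trajectory", class(out))
  out
}
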