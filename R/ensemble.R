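# Ensemble of low-dimensional projections and the averaged distance
# matrix, plus stability and topology diagnostics.
#
# UMAP is stochastic: no single embedding is privileged, and metrics
# read off one embedding inherit its noise.  Repeating the projection N
# times and averaging the pairwise Euclidean distance matrices gives a
# stable substrate for silhouettes, clustering and trajectories.

#' Run an ensemble of low-dimensional projections
#'
#' For `method = "umap"`, repeat `r` is computed under seed
#' `base_seed + r` (single-threaded, so identical seeds reproduce
#' identical embeddings); the pairwise Euclidean distance matrices of
#' the repeats are averaged elementwise.  For `method = "pca"` the
#' projection is deterministic and `n_repeats` is forced to 1.
#'
#' @param features A `reef_features` object or a numeric matrix
#'   (samples x dimensions).
#' @param method `"umap"` or `"pca"`.
#' @param n_components Dimensionality of the projection (default 3).
#' @param n_repeats Number of independent repeats (default 100).
#' @param base_seed Seed offset; repeat `r` uses `base_seed + r`.
#' @param n_neighbors,min_dist UMAP neighborhood size and minimum
#'   distance, passed to the underlying implementation (its defaults;
#'   recorded in the result).
#' @return A `reef_ensemble` object: `embeddings` (list of
#'   `n_samples x n_components` matrices), `avg_distance`
#'   (`n_samples x n_samples`), `seeds`, `method`, `params`, and the
#'   `samples` tibble carried over from `features` (if any).
#' @export
run_ensemble <- function(features, method = c("umap", "pca"),
                         n_components = 3, n_repeats = 100, base_seed = 0,
                         n_neighbors = 15, min_dist = 0.1) {
  method <- match.arg(method)
  x <- if (inherits(features, "reef_features")) features$values else features
  samples <- if (inherits(features, "reef_features")) features$samples
  n <- nrow(x)
  if (n < n_components + 2) {
    stop("need at least n_components + 2 samples (have ", n, ")",
         call. = FALSE)
  }
  if (method == "pca") {
    n_repeats <- 1L
    p <- pca_project(x, n_components)
    embeddings <- list(p$points)
    seeds <- NA_integer_
  } else {
    stopifnot(n_repeats >= 1)
    k <- min(n_neighbors, n - 1)
    seeds <- base_seed + seq_len(n_repeats)
    embeddings <- lapply(seeds, function(s) {
      set.seed(s)
      uwot::umap(x, n_components = n_components, n_neighbors = k,
                 min_dist = min_dist, n_threads = 1, n_sgd_threads = 1,
                 verbose = FALSE)
    })
  }
  avg <- matrix(0, n, n)
  for (e in embeddings) avg <- avg + as.matrix(stats::dist(e))
  avg <- avg / length(embeddings)
  structure(
    list(method = method, n_components = n_components,
         n_repeats = length(embeddings), seeds = seeds,
         embeddings = embeddings, avg_distance = avg, samples = samples,
         params = list(n_neighbors = if (method == "umap") min(n_neighbors, n - 1),
                       min_dist = if (method == "umap") min_dist,
                       base_seed = base_seed)),
    class = "reef_ensemble"
  )
}

#' @export
print.reef_ensemble <- function(x, ...) {
  cat("<reef_ensemble> ", x$method, " x ", x$n_repeats, " repeats, ",
      nrow(x$avg_distance), " samples in ", x$n_components, "d\n", sep = "")
  invisible(x)
}

off_diagonal <- function(m) m[upper.tri(m)]

#' Distance-contrast metric of a distance matrix (IQR over median)
#'
#' The interquartile range of the pairwise distances divided by their
#' median: a scale-free measure of how contrasted the distances are.
#' Computed over the strict upper triangle.
#'
#' @param d A symmetric distance matrix.
#' @return A scalar; errors if the median pairwise distance is zero.
#' @export
iqm <- function(d) {
  v <- off_diagonal(as.matrix(d))
  if (length(v) < 1) stop("need at least 2 samples", call. = FALSE)
  med <- stats::median(v)
  if (med <= 0) stop("median pairwise distance is zero", call. = FALSE)
  q <- stats::quantile(v, c(0.25, 0.75), names = FALSE, type = 7)
  (q[2] - q[1]) / med
}

#' Convergence of the running-average distance matrix
#'
#' For each `n`, the distance matrices of the first `n` repeats are
#' averaged and compared with the average over the first `n - 1`: the
#' mean and maximum absolute elementwise differences, divided by the
#' mean off-diagonal entry of the previous running average ("relative"),
#' plus the [iqm()] of each running average.  With independent repeats
#' the relative differences decay like `1/sqrt(n)`.
#'
#' @param ensemble A `reef_ensemble` (or a list of distance matrices).
#' @return A tibble with columns `n`, `rel_mean_abs_diff`,
#'   `rel_max_abs_diff` (both `NA` at `n = 1`), `iqm`; class
#'   `reef_convergence`.
#' @export
convergence <- function(ensemble) {
  mats <- if (inherits(ensemble, "reef_ensemble")) {
    lapply(ensemble$embeddings, function(e) as.matrix(stats::dist(e)))
  } else {
    lapply(ensemble, as.matrix)
  }
  n_rep <- length(mats)
  rel_mean <- rel_max <- iqm_series <- rep(NA_real_, n_rep)
  run <- matrix(0, nrow(mats[[1]]), ncol(mats[[1]]))
  for (n in seq_len(n_rep)) {
    new_run <- run + (mats[[n]] - run) / n
    if (n >= 2) {
      diff <- abs(off_diagonal(new_run) - off_diagonal(run))
      denom <- mean(off_diagonal(run))
      rel_mean[n] <- mean(diff) / denom
      rel_max[n] <- max(diff) / denom
    }
    run <- new_run
    iqm_series[n] <- iqm(run)
  }
  out <- tibble::tibble(n = seq_len(n_rep), rel_mean_abs_diff = rel_mean,
                        rel_max_abs_diff = rel_max, iqm = iqm_series)
  class(out) <- c("reef_convergence", class(out))
  out
}

knn_index_matrix <- function(d, k) {
  n <- nrow(d)
  out <- matrix(0L, n, k)
  for (i in seq_len(n)) {
    dd <- d[i, ]
    dd[i] <- Inf
    out[i, ] <- order(dd)[seq_len(k)]
  }
  out
}

#' Degree of local preservation between two spaces
#'
#' The mean, over points, of the fraction of `k` nearest neighbors
#' (Euclidean, self excluded) shared between the high-dimensional
#' feature space and the low-dimensional embedding.
#'
#' @param high A `reef_features` object or matrix (the reference space).
#' @param low A points matrix with the same row order.
#' @param k Neighborhood size.
#' @return A fraction in `[0, 1]`.
#' @export
dlp <- function(high, low, k) {
  xh <- if (inherits(high, "reef_features")) high$values else high
  n <- nrow(xh)
  stopifnot(nrow(low) == n, k >= 1, k < n)
  dh <- as.matrix(stats::dist(xh))
  dl <- as.matrix(stats::dist(low))
  nh <- knn_index_matrix(dh, k)
  nl <- knn_index_matrix(dl, k)
  mean(vapply(seq_len(n),
              function(i) length(intersect(nh[i, ], nl[i, ])) / k,
              numeric(1)))
}

with_preserved_rng <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Random triplet accuracy between two spaces
#'
#' Uniformly samples `n_triplets` triplets `(i; j, k)` of distinct
#' points and reports the fraction whose distance ordering
#' `sign(d(i, j) - d(i, k))` agrees between the high-dimensional space
#' and the embedding.  Deterministic for a given `seed`.
#'
#' @inheritParams dlp
#' @param n_triplets Number of triplets to sample.
#' @param seed RNG seed (the caller's RNG state is preserved).
#' @return A fraction in `[0, 1]`.
#' @export
rta <- function(high, low, n_triplets = 10000, seed = 0) {
  xh <- if (inherits(high, "reef_features")) high$values else high
  n <- nrow(xh)
  stopifnot(nrow(low) == n, n >= 3, n_triplets >= 1)
  dh <- as.matrix(stats::dist(xh))
  dl <- as.matrix(stats::dist(low))
  with_preserved_rng(seed, {
    i <- sample.int(n, n_triplets, replace = TRUE)
    j <- sample.int(n - 1, n_triplets, replace = TRUE)
    k <- sample.int(n - 2, n_triplets, replace = TRUE)
    # map j, k into {1..n} \ {i} and {1..n} \ {i, j}
    j <- j + (j >= i)
    lo <- pmin(i, j); hi <- pmax(i, j)
    k <- k + (k >= lo)
    k <- k + (k >= hi)
    sh <- sign(dh[cbind(i, j)] - dh[cbind(i, k)])
    sl <- sign(dl[cbind(i, j)] - dl[cbind(i, k)])
    mean(sh == sl)
  })
}

#' Principal component projection
#'
#' Deterministic linear alternative to the UMAP ensemble.  Axis signs
#' are fixed so that each component's largest-magnitude loading is
#' positive.
#'
#' @param features A `reef_features` object or matrix.
#' @param n_components Number of components.
#' @return A list with `points` (scores matrix) and
#'   `explained_variance` (fraction per component, non-increasing).
#' @export
pca_project <- function(features, n_components) {
  x <- if (inherits(features, "reef_features")) features$values else features
  stopifnot(n_components <= min(nrow(x) - 1, ncol(x)))
  p <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  rot <- p$rotation[, seq_len(n_components), drop = FALSE]
  flip <- vapply(seq_len(ncol(rot)), function(j) {
    w <- rot[, j]
    sign(w[which.max(abs(w))])
  }, numeric(1))
  rot <- sweep(rot, 2, flip, "*")
  scores <- sweep(x, 2, colMeans(x)) %*% rot
  ev <- p$sdev^2 / sum(p$sdev^2)
  list(points = scores, explained_variance = ev[seq_len(n_components)])
}
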