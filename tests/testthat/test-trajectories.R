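# Build a fake ensemble with known embeddings and a matching sample
# table: `n_rep` copies of `points` (optionally jittered).
fake_ensemble <- function(points, samples, n_rep = 3, jitter = 0,
                          seed = 40) {
  set.seed(seed)
  embs <- lapply(seq_len(n_rep), function(r) {
    points + if (jitter > 0) matrix(stats::rnorm(length(points), 0, jitter),
                                    nrow(points)) else 0
  })
  structure(list(embeddings = embs, n_repeats = n_rep, samples = samples,
                 method = "umap", n_components = ncol(points)),
            class = "reef_ensemble")
}

traj_samples <- function(n_times, reps = c("rep1", "rep2"),
                         site = "siteA") {
  t0 <- as.POSIXct("2024-01-01 12:00:00", tz = "UTC")
  tibble::tibble(
    site = site,
    replicate = rep(reps, each = n_times),
    window_start = rep(t0 + 15 * (seq_len(n_times) - 1), length(reps))
  )
}

test_that("paths are time-ordered with one point per aggregated sample", {
  s <- traj_samples(5)
  pts <- matrix(stats::rnorm(20), 10, 2)
  p <- path_points(pts, s, "siteA", "rep1")
  expect_equal(nrow(p), 5)
  expect_equal(attr(p, "window_start"), s$window_start[1:5])
  p2 <- path_points(pts, s, "siteA", "rep2")
  expect_equal(nrow(p2), 5)
  expect_error(path_points(pts, s, "siteA", "rep9"), "no samples")
})

test_that("a sample at the reference point has zero relative distance", {
  s <- traj_samples(4, reps = "rep1")
  # first sample defines the reference (single replicate)
  pts <- rbind(c(0, 0), c(1, 0), c(2, 0), c(3, 0))
  en <- fake_ensemble(pts, s, n_rep = 3)
  tr <- relative_trajectory(en, "siteA", k = 2)
  expect_equal(tr$median_rel_distance[1], 0)
  expect_true(all(diff(tr$median_rel_distance) > 0))
  expect_equal(tr$k_used[1], 2)
})

test_that("relative distances are invariant to embedding scale", {
  s <- traj_samples(6)
  set.seed(41)
  pts <- matrix(stats::rnorm(24), 12, 2)
  t1 <- relative_trajectory(fake_ensemble(pts, s), "siteA", k = 3)
  t2 <- relative_trajectory(fake_ensemble(pts * 37, s), "siteA", k = 3)
  expect_equal(t1$median_rel_distance, t2$median_rel_distance,
               tolerance = 1e-9)
})

test_that("the median series lies inside the decile band", {
  s <- traj_samples(8)
  set.seed(42)
  pts <- matrix(stats::rnorm(32), 16, 2)
  en <- fake_ensemble(pts, s, n_rep = 9, jitter = 0.3)
  tr <- relative_trajectory(en, "siteA", k = 5)
  expect_true(all(tr$decile_low <= tr$median_rel_distance + 1e-12))
  expect_true(all(tr$median_rel_distance <= tr$decile_high + 1e-12))
  expect_true(all(tr$decile_low >= 0))
})

test_that("a stationary cloud hovers at an order-one relative distance", {
  set.seed(43)
  n_times <- 60
  s <- traj_samples(n_times, reps = "rep1")
  runs <- replicate(10, {
    pts <- matrix(stats::rnorm(n_times * 2), n_times, 2)
    en <- fake_ensemble(pts, s, n_rep = 1)
    tr <- relative_trajectory(en, "siteA", k = 20)
    mean(tr$median_rel_distance[-1])
  })
  m <- mean(runs)
  expect_gt(m, 1 / 3)
  expect_lt(m, 3)
})

test_that("a planted displaced block produces a trajectory peak", {
  set.seed(44)
  n_times <- 40
  s <- traj_samples(n_times, reps = "rep1")
  pts <- matrix(stats::rnorm(n_times * 3), n_times, 3)
  # displace a mid-series block by 10 pooled standard deviations
  block <- 18:24
  pts[block, ] <- pts[block, ] + 10 * stats::sd(pts)
  en <- fake_ensemble(pts, s, n_rep = 5, jitter = 0.1)
  tr <- relative_trajectory(en, "siteA", k = 10)
  peak <- max(tr$median_rel_distance[block])
  outside <- stats::median(tr$median_rel_distance[-block])
  expect_gt(peak, 2 * outside)
})

test_that("replicates with identical dynamics stay below the planted peak", {
  set.seed(45)
  n_times <- 30
  s <- traj_samples(n_times, reps = c("rep1", "rep2"))
  base <- matrix(stats::rnorm(n_times * 2), n_times, 2)
  pts <- rbind(base, base + matrix(stats::rnorm(n_times * 2, 0, 0.2),
                                   n_times, 2))
  block <- 14:18
  pts[block, ] <- pts[block, ] + 8 * stats::sd(base)   # perturb rep1 only
  en <- fake_ensemble(pts, s, n_rep = 4, jitter = 0.05)
  tr <- relative_trajectory(en, "siteA", k = 10)
  r1 <- tr[tr$replicate == "rep1", ]
  r2 <- tr[tr$replicate == "rep2", ]
  gap <- abs(r1$median_rel_distance - r2$median_rel_distance)
  expect_lt(stats::median(gap[-block]), max(gap[block]))
})
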