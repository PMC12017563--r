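make_features_matrix <- function(n = 40, d = 6, seed = 10) {
  set.seed(seed)
  matrix(stats::rnorm(n * d), n, d)
}

test_that("a single-repeat ensemble's average equals its own distance matrix", {
  x <- make_features_matrix()
  en <- run_ensemble(x, "umap", n_components = 2, n_repeats = 1,
                     base_seed = 3)
  expect_equal(en$avg_distance,
               as.matrix(stats::dist(en$embeddings[[1]])),
               ignore_attr = TRUE)
})

test_that("ensembles are reproducible under the same base seed", {
  x <- make_features_matrix()
  e1 <- run_ensemble(x, "umap", n_components = 2, n_repeats = 3,
                     base_seed = 7)
  e2 <- run_ensemble(x, "umap", n_components = 2, n_repeats = 3,
                     base_seed = 7)
  expect_identical(e1$avg_distance, e2$avg_distance)
  e3 <- run_ensemble(x, "umap", n_components = 2, n_repeats = 3,
                     base_seed = 8)
  expect_false(identical(e1$avg_distance, e3$avg_distance))
})

test_that("the averaged matrix is a mean of valid metrics", {
  x <- make_features_matrix(n = 25)
  en <- run_ensemble(x, "umap", n_components = 2, n_repeats = 4)
  d <- en$avg_distance
  expect_equal(d, t(d))
  expect_equal(unname(diag(d)), rep(0, nrow(d)))
  expect_true(all(d >= 0))
  # brute-force triangle inequality over all triples
  n <- nrow(d)
  viol <- 0
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    if (d[i, j] > d[i, k] + d[k, j] + 1e-9) viol <- viol + 1
    if (d[i, k] > d[i, j] + d[j, k] + 1e-9) viol <- viol + 1
    if (d[j, k] > d[j, i] + d[i, k] + 1e-9) viol <- viol + 1
  }
  expect_equal(viol, 0)
})

test_that("hand-built repeats average elementwise", {
  # two planted 3-point distance matrices via embeddings on a line
  e1 <- cbind(c(0, 1, 3), 0)
  e2 <- cbind(c(0, 2, 5), 0)
  fake <- structure(list(embeddings = list(e1, e2), n_repeats = 2),
                    class = "reef_ensemble")
  cv <- convergence(fake)
  d1 <- as.matrix(stats::dist(e1))
  d2 <- as.matrix(stats::dist(e2))
  # closed-form running-mean identity: avg2 - avg1 = (D2 - D1) / 2
  up <- upper.tri(d1)
  expect_equal(cv$rel_mean_abs_diff[2],
               mean(abs(d2[up] - d1[up]) / 2) / mean(d1[up]))
  expect_equal(cv$rel_max_abs_diff[2],
               max(abs(d2[up] - d1[up]) / 2) / mean(d1[up]))
})

test_that("identical repeats give a zero convergence series", {
  e <- cbind(stats::rnorm(8), stats::rnorm(8))
  fake <- structure(list(embeddings = rep(list(e), 5), n_repeats = 5),
                    class = "reef_ensemble")
  cv <- convergence(fake)
  expect_equal(cv$rel_mean_abs_diff[-1], rep(0, 4))
  expect_equal(cv$rel_max_abs_diff[-1], rep(0, 4))
})

test_that("i.i.d. repeats converge with a negative log-log slope", {
  set.seed(11)
  mats <- lapply(1:50, function(i) as.matrix(stats::dist(
    matrix(stats::rnorm(30 * 2), 30, 2))))
  cv <- convergence(mats)
  ok <- !is.na(cv$rel_mean_abs_diff)
  slope <- stats::coef(stats::lm(log(cv$rel_mean_abs_diff[ok]) ~
                                   log(cv$n[ok])))[2]
  expect_lt(slope, 0)
  # mean difference never exceeds max difference
  expect_true(all(cv$rel_mean_abs_diff[ok] <= cv$rel_max_abs_diff[ok]))
})

test_that("iqm matches the enumerated oracle and is scale free", {
  # 4 points on a line at 0, 1, 2, 4: distances {1, 2, 4, 1, 3, 2};
  # sorted 1,1,2,2,3,4 -> Q1 1.25, median 2, Q3 2.75 -> (2.75-1.25)/2
  d <- as.matrix(stats::dist(c(0, 1, 2, 4)))
  expect_equal(iqm(d), 0.75)
  expect_equal(iqm(5 * d), iqm(d))
  # equilateral: all distances equal -> 0
  tri <- matrix(1, 3, 3); diag(tri) <- 0
  expect_equal(iqm(tri), 0)
  expect_error(iqm(matrix(0, 3, 3)), "median")
})

test_that("projection increases distance contrast on clustered data", {
  # three high-dimensional Gaussian clusters: raw distances concentrate,
  # the projection ensemble spreads them
  set.seed(12)
  x <- rbind(matrix(stats::rnorm(50 * 40, 0), ncol = 40),
             matrix(stats::rnorm(50 * 40, 2), ncol = 40),
             matrix(stats::rnorm(50 * 40, -2), ncol = 40))
  x <- robust_scale(x)
  en <- run_ensemble(x, "umap", n_components = 2, n_repeats = 3)
  expect_gt(iqm(en$avg_distance), iqm(as.matrix(stats::dist(x))))
})

test_that("DLP is 1 for identity embeddings and k/(n-1) for random ones", {
  x <- make_features_matrix(n = 60, d = 4)
  expect_equal(dlp(x, x, k = 5), 1.0)
  expect_equal(dlp(x, x[, 1:4], k = 59), 1.0)
  set.seed(13)
  n <- 200; k <- 10
  x <- matrix(stats::rnorm(n * 5), n, 5)
  vals <- replicate(5, dlp(x, matrix(stats::rnorm(n * 3), n, 3), k = k))
  expect_equal(mean(vals), k / (n - 1), tolerance = 0.05)
})

test_that("RTA is 1 for identity, 0.5 for random, and seed-stable", {
  x <- make_features_matrix(n = 50, d = 4)
  expect_equal(rta(x, x, n_triplets = 2000, seed = 1), 1.0)
  set.seed(14)
  lowr <- matrix(stats::rnorm(50 * 3), 50, 3)
  v1 <- rta(x, lowr, n_triplets = 50000, seed = 2)
  expect_equal(v1, 0.5, tolerance = 0.05)
  expect_identical(v1, rta(x, lowr, n_triplets = 50000, seed = 2))
})

test_that("PCA projection is deterministic with honest variance fractions", {
  set.seed(15)
  # data exactly in a 2-plane embedded in 6 dims
  basis <- qr.Q(qr(matrix(stats::rnorm(36), 6, 6)))[, 1:2]
  x <- matrix(stats::rnorm(80 * 2), 80, 2) %*% t(basis)
  p <- pca_project(x, 2)
  expect_equal(sum(p$explained_variance), 1, tolerance = 1e-9)
  expect_identical(p$points, pca_project(x, 2)$points)
  # isotropic cloud: fractions roughly equal
  y <- matrix(stats::rnorm(3000 * 4), 3000, 4)
  pv <- pca_project(y, 4)$explained_variance
  expect_true(all(abs(pv - 0.25) < 0.05))
  expect_true(all(diff(pv) <= 1e-12))
})

test_that("pca ensembles collapse to a single deterministic repeat", {
  x <- make_features_matrix(n = 30)
  en <- run_ensemble(x, "pca", n_components = 2, n_repeats = 10)
  expect_equal(en$n_repeats, 1)
  expect_equal(en$avg_distance,
               as.matrix(stats::dist(en$embeddings[[1]])),
               ignore_attr = TRUE)
})
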