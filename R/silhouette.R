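# Pairwise silhouette analysis: how separated are two categories of a
# label in the averaged distance space?

#' Silhouette index between two categories of a label
#'
#' The distance matrix is restricted to the samples of the two
#' categories.  For each sample, `a` is its mean distance to its own
#' category (self excluded), `b` its mean distance to the other
#' category, and its silhouette is `(b - a) / max(a, b)` (0 when
#' `a = b = 0`, i.e. duplicate points).  The index is the mean
#' silhouette over the samples of both categories: near 1 for two
#' distinct clouds, near 0 when the categories share the same region
#' (slightly negative values are possible and reported unclamped).
#'
#' @param d Distance matrix over all samples (or a `reef_ensemble`,
#'   whose `avg_distance` is used).
#' @param categories Character vector of per-sample categories.
#' @param cat_a,cat_b The two categories to compare (must differ; each
#'   needs at least 2 samples).
#' @return A scalar in `[-1, 1]`.
#' @export
pairwise_silhouette <- function(d, categories, cat_a, cat_b) {
  if (inherits(d, "reef_ensemble")) d <- d$avg_distance
  d <- as.matrix(d)
  stopifnot(length(categories) == nrow(d))
  if (identical(cat_a, cat_b)) {
    stop("cat_a and cat_b must be different categories", call. = FALSE)
  }
  ia <- which(categories == cat_a)
  ib <- which(categories == cat_b)
  if (length(ia) < 2 || length(ib) < 2) {
    stop("each category needs at least 2 samples (", cat_a, ": ",
         length(ia), ", ", cat_b, ": ", length(ib), ")", call. = FALSE)
  }
  sil_one_side <- function(own, other) {
    a <- (rowSums(d[own, own, drop = FALSE])) / (length(own) - 1)
    b <- rowMeans(d[own, other, drop = FALSE])
    s <- ifelse(a == 0 & b == 0, 0, (b - a) / pmax(a, b))
    s
  }
  mean(c(sil_one_side(ia, ib), sil_one_side(ib, ia)))
}

#' Pairwise silhouette matrix for a categorical label
#'
#' Computes [pairwise_silhouette()] for every unordered pair of
#' categories.
#'
#' @inheritParams pairwise_silhouette
#' @param label_name Optional name recorded with the result.
#' @return A `reef_silhouette` object: symmetric `values` matrix with
#'   `NA` diagonal, ordered `categories`, `label_name`.
#' @export
silhouette_matrix <- function(d, categories, label_name = "label") {
  if (inherits(d, "reef_ensemble")) d <- d$avg_distance
  cats <- sort(unique(categories))
  if (length(cats) < 2) stop("need at least 2 categories", call. = FALSE)
  k <- length(cats)
  m <- matrix(NA_real_, k, k, dimnames = list(cats, cats))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      v <- pairwise_silhouette(d, categories, cats[i], cats[j])
      m[i, j] <- v
      m[j, i] <- v
    }
  }
  structure(list(values = m, categories = cats, label_name = label_name),
            class = "reef_silhouette")
}

#' @export
print.reef_silhouette <- function(x, ...) {
  cat("<reef_silhouette> '", x$label_name, "': ",
      length(x$categories), " categories, ",
      sum(!is.na(x$values[upper.tri(x$values)])), " pairs\n", sep = "")
  print(round(x$values, 3))
  invisible(x)
}
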