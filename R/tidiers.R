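# broom-style tidiers for the pipeline's result objects.

#' Tidy a feature matrix into a long tibble
#'
#' @param x A `reef_features` object.
#' @param ... Unused.
#' @return A tibble with one row per (sample, dimension):
#'   `sample_id`, the label columns, `dim`, `value`.
#' @export
tidy.reef_features <- function(x, ...) {
  wide <- dplyr::bind_cols(
    x$samples,
    tibble::as_tibble(x$values, .name_repair = "minimal")
  )
  tidyr::pivot_longer(wide, cols = colnames(x$values),
                      names_to = "dim", values_to = "value")
}

#' @export
glance.reef_features <- function(x, ...) {
  tibble::tibble(
    n_samples = nrow(x$values),
    n_dims = ncol(x$values),
    n_pruned = length(x$pruned),
    scaled = !is.null(x$scaling),
    integration_time_s = x$samples$integration_time_s[1]
  )
}

#' Tidy a projection ensemble
#'
#' @param x A `reef_ensemble`.
#' @param repeats Which repeats to include (default: the first).
#' @param ... Unused.
#' @return A tibble with `repeat`, `sample_id`, one column per
#'   component (`dim1`, `dim2`, ...), plus the sample labels when
#'   available.
#' @export
tidy.reef_ensemble <- function(x, repeats = 1, ...) {
  out <- dplyr::bind_rows(lapply(repeats, function(r) {
    e <- x$embeddings[[r]]
    colnames(e) <- paste0("dim", seq_len(ncol(e)))
    df <- tibble::as_tibble(e)
    df$sample_id <- seq_len(nrow(e))
    df$`repeat` <- r
    if (!is.null(x$samples)) df <- dplyr::bind_cols(df, x$samples[
      setdiff(names(x$samples), names(df))])
    df
  }))
  out
}

#' @export
glance.reef_ensemble <- function(x, ...) {
  tibble::tibble(
    method = x$method, n_components = x$n_components,
    n_repeats = x$n_repeats, n_samples = nrow(x$avg_distance),
    iqm_avg_distance = iqm(x$avg_distance)
  )
}

#' Tidy a silhouette matrix into category pairs
#'
#' @param x A `reef_silhouette`.
#' @param ... Unused.
#' @return A tibble with `category_a`, `category_b`, `silhouette`
#'   (unordered pairs, upper triangle).
#' @export
tidy.reef_silhouette <- function(x, ...) {
  idx <- which(upper.tri(x$values), arr.ind = TRUE)
  tibble::tibble(
    label = x$label_name,
    category_a = x$categories[idx[, 1]],
    category_b = x$categories[idx[, 2]],
    silhouette = x$values[idx]
  )
}

#' @export
tidy.reef_clusters <- function(x, ...) {
  tibble::tibble(sample_id = seq_along(x$labels), cluster = x$labels)
}

#' @export
glance.reef_clusters <- function(x, ...) {
  tibble::tibble(
    method = x$method, n_clusters = x$n_clusters,
    min_cluster_size = x$min_cluster_size, min_samples = x$min_samples,
    n_unassigned = sum(x$labels == -1L), n_samples = length(x$labels)
  )
}

#' @export
tidy.reef_contingency <- function(x, ...) {
  idx <- expand.grid(row = seq_along(x$clusters),
                     col = seq_along(x$categories))
  tibble::tibble(
    cluster = x$clusters[idx$row],
    category = x$categories[idx$col],
    percent = x$values[cbind(idx$row, idx$col)]
  )
}
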