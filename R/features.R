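# From per-second embeddings to the analysis feature matrix:
# aggregation over the integration time, pruning of uninformative
# dimensions, robust scaling.

new_reef_features <- function(values, samples, scaling = NULL,
                              pruned = character(), label_names = character()) {
  stopifnot(is.matrix(values), nrow(values) == nrow(samples))
  structure(
    list(values = values, samples = samples, scaling = scaling,
         pruned = pruned, label_names = label_names),
    class = "reef_features"
  )
}

#' @export
print.reef_features <- function(x, ...) {
  cat("<reef_features> ", nrow(x$values), " samples x ", ncol(x$values),
      " dimensions\n", sep = "")
  if (length(x$pruned)) {
    cat("  pruned constant dimensions: ", length(x$pruned), "\n", sep = "")
  }
  cat("  scaled: ", !is.null(x$scaling), "\n", sep = "")
  if (length(x$label_names)) {
    cat("  labels: ", paste(x$label_names, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Average consecutive per-second embeddings into integration windows
#'
#' Blocks of `integration_time_s` consecutive rows are averaged
#' arithmetically per dimension, without overlap; a trailing partial
#' block is discarded.
#'
#' @param emb Matrix of per-second embedding rows, in temporal order.
#' @param integration_time_s Positive integer number of seconds per
#'   window.
#' @return A matrix with one row per complete window.
#' @export
aggregate_embeddings <- function(emb, integration_time_s) {
  if (length(integration_time_s) != 1 || integration_time_s < 1 ||
      abs(integration_time_s - round(integration_time_s)) > 1e-9) {
    stop("integration_time_s must be a positive integer number of seconds",
         call. = FALSE)
  }
  k <- as.integer(round(integration_time_s))
  if (k == 1L) return(emb)
  n_blocks <- nrow(emb) %/% k
  if (n_blocks == 0) {
    return(emb[0, , drop = FALSE])
  }
  idx <- rep(seq_len(n_blocks), each = k)
  out <- rowsum(emb[seq_len(n_blocks * k), , drop = FALSE], idx) / k
  rownames(out) <- NULL
  out
}

#' Remove dimensions that carry no information
#'
#' Columns whose range (max minus min) over all samples is at most `tol`
#' are constant for the dataset and are removed; their names are kept in
#' the `pruned` field.
#'
#' @param x A `reef_features` object or a plain matrix.
#' @param tol Constantness tolerance (default `1e-12`).
#' @return Same type as `x` with constant columns dropped.
#' @export
prune_dims <- function(x, tol = 1e-12) {
  m <- if (inherits(x, "reef_features")) x$values else x
  if (nrow(m) < 2) stop("pruning needs at least 2 samples", call. = FALSE)
  rng <- apply(m, 2, function(col) max(col) - min(col))
  drop <- rng <= tol
  if (all(drop)) {
    stop("no informative dimensions: every column is constant", call. = FALSE)
  }
  kept <- m[, !drop, drop = FALSE]
  removed <- colnames(m)[drop]
  if (inherits(x, "reef_features")) {
    x$values <- kept
    x$pruned <- c(x$pruned, removed)
    x
  } else {
    attr(kept, "pruned") <- removed
    kept
  }
}

# Type-7 (linear interpolation) quantiles; the IQR convention matters
# and is declared.
column_scaling <- function(col) {
  q <- stats::quantile(col, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- q[3] - q[1]
  if (iqr <= 1e-12) {
    list(center = q[2], scale = max(col) - min(col), fallback = TRUE)
  } else {
    list(center = q[2], scale = iqr, fallback = FALSE)
  }
}

#' Robust-scale every dimension
#'
#' Each column is centred on its median and divided by its interquartile
#' range (type-7 quantiles).  A non-constant column whose IQR is zero
#' falls back to dividing by its range, and is flagged.
#'
#' @param x A `reef_features` object or a plain matrix (already pruned:
#'   constant columns are an error).
#' @return Same type as `x`, scaled; scaling parameters are stored in
#'   the `scaling` field (or attribute) as a tibble with columns
#'   `dim`, `center`, `scale`, `fallback`.
#' @export
robust_scale <- function(x) {
  m <- if (inherits(x, "reef_features")) x$values else x
  params <- lapply(seq_len(ncol(m)), function(j) column_scaling(m[, j]))
  centers <- vapply(params, `[[`, numeric(1), "center")
  scales <- vapply(params, `[[`, numeric(1), "scale")
  if (any(scales <= 0)) {
    stop("constant column encountered in robust_scale; prune first",
         call. = FALSE)
  }
  scaled <- sweep(sweep(m, 2, centers), 2, scales, "/")
  info <- tibble::tibble(
    dim = colnames(m) %||% as.character(seq_len(ncol(m))),
    center = centers, scale = scales,
    fallback = vapply(params, `[[`, logical(1), "fallback")
  )
  if (inherits(x, "reef_features")) {
    x$values <- scaled
    x$scaling <- info
    x
  } else {
    attr(scaled, "scaling") <- info
    scaled
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Embed one campaign row: read, filter, segment, embed, aggregate.
embed_one_recording <- function(path, sample_rate, embedding, spec, filt,
                                integration_time_s, aggregate_now) {
  wav <- read_wav(path)
  if (wav$sample_rate != sample_rate) {
    stop("sample rate mismatch in ", path, call. = FALSE)
  }
  x <- highpass(wav$samples, sample_rate, filt)
  seg <- segment_waveform(x, sample_rate, 1)
  if (nrow(seg) == 0) return(NULL)
  emb <- switch(embedding,
    mel_spectrum = mel_spectrum(seg, sample_rate, spec),
    mel_spectrogram = mel_spectrogram(seg, sample_rate, spec),
    cnn_embed(seg, sample_rate, adapter = embedding, spec = spec)
  )
  if (aggregate_now) aggregate_embeddings(emb, integration_time_s) else emb
}

#' Build the feature matrix of a campaign
#'
#' Runs the per-recording chain (high-pass filter, one-second
#' segmentation, embedding, aggregation over the integration time) and
#' the dataset-level chain (pruning of constant dimensions, robust
#' scaling).  The default order is aggregate, then prune, then scale;
#' `order = "prune_scale_first"` prunes and scales the per-second
#' embeddings before aggregating instead.
#'
#' @param campaign A campaign tibble from [read_campaign()].
#' @param embedding `"mel_spectrum"`, `"mel_spectrogram"`, or the name of
#'   a registered embedding adapter.
#' @param spec A [mel_spec()].
#' @param filt A [filter_spec()].
#' @param integration_time_s Integration time in seconds (default 15).
#' @param order `"aggregate_first"` (default) or `"prune_scale_first"`.
#' @param scale Apply robust scaling (default `TRUE`).
#' @return A `reef_features` object.  Its `samples` tibble has one row
#'   per integration window: `file`, `window_start`, the campaign label
#'   columns, and (when several labels exist) a `composite` label joining
#'   them with `"/"`.
#' @export
build_features <- function(campaign, embedding = "mel_spectrum",
                           spec = mel_spec(), filt = filter_spec(),
                           integration_time_s = 15,
                           order = c("aggregate_first", "prune_scale_first"),
                           scale = TRUE) {
  order <- match.arg(order)
  label_names <- attr(campaign, "label_names") %||%
    setdiff(names(campaign), c("file", "start", "sample_rate",
                               "duration_s", "n_samples"))
  sr <- campaign$sample_rate[1]
  aggregate_now <- order == "aggregate_first"
  blocks <- vector("list", nrow(campaign))
  sample_rows <- vector("list", nrow(campaign))
  for (i in seq_len(nrow(campaign))) {
    emb <- embed_one_recording(campaign$file[i], sr, embedding, spec, filt,
                               integration_time_s, aggregate_now)
    if (is.null(emb) || nrow(emb) == 0) next
    blocks[[i]] <- emb
    step_s <- if (aggregate_now) integration_time_s else 1
    n <- nrow(emb)
    row <- campaign[i, c("file", label_names)]
    sample_rows[[i]] <- dplyr::bind_cols(
      row[rep(1, n), , drop = FALSE],
      tibble::tibble(window_start = campaign$start[i] +
                       (seq_len(n) - 1) * step_s,
                     integration_time_s = step_s)
    )
  }
  keep <- !vapply(blocks, is.null, logical(1))
  values <- do.call(rbind, blocks[keep])
  samples <- dplyr::bind_rows(sample_rows[keep])
  if (length(label_names) > 1) {
    samples$composite <- do.call(paste, c(samples[label_names], sep = "/"))
    label_names <- c(label_names, "composite")
  }
  samples$sample_id <- seq_len(nrow(samples))
  fx <- new_reef_features(values, samples, label_names = label_names)
  if (order == "aggregate_first") {
    fx <- prune_dims(fx)
    if (scale) fx <- robust_scale(fx)
  } else {
    fx <- prune_dims(fx)
    if (scale) fx <- robust_scale(fx)
    # aggregate the scaled per-second rows recording by recording
    agg <- rowsum_aggregate(fx, integration_time_s)
    fx <- agg
  }
  fx
}

# Aggregate an (already pruned/scaled) per-second reef_features object
# into integration windows, per recording file.
rowsum_aggregate <- function(fx, integration_time_s) {
  k <- as.integer(round(integration_time_s))
  by_file <- split(seq_len(nrow(fx$samples)), fx$samples$file)
  # preserve original file order
  by_file <- by_file[unique(fx$samples$file)]
  vals <- list(); rows <- list()
  for (f in names(by_file)) {
    idx <- by_file[[f]]
    m <- aggregate_embeddings(fx$values[idx, , drop = FALSE], k)
    if (nrow(m) == 0) next
    sel <- fx$samples[idx[seq(1, by = k, length.out = nrow(m))], , drop = FALSE]
    sel$integration_time_s <- k
    vals[[f]] <- m; rows[[f]] <- sel
  }
  samples <- dplyr::bind_rows(rows)
  samples$sample_id <- seq_len(nrow(samples))
  new_reef_features(do.call(rbind, vals), samples, scaling = fx$scaling,
                    pruned = fx$pruned, label_names = fx$label_names)
}
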