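# Hierarchical density-based clustering (HDBSCAN) on a precomputed
# distance matrix: core distances, mutual-reachability graph, minimum
# spanning tree, single-linkage hierarchy, condensed tree, cluster
# stability, and excess-of-mass or leaf cluster selection.  Points the
# hierarchy judges too isolated are left unassigned (label -1).

lambda_eps <- 1e-12

# core distance: distance to the min_samples-th nearest neighbor,
# counting the point itself.
core_distances <- function(d, min_samples) {
  n <- nrow(d)
  k <- min(min_samples - 1L, n - 1L)
  if (k <= 0) return(rep(0, n))
  vapply(seq_len(n), function(i) sort(d[i, -i], partial = k)[k], numeric(1))
}

mutual_reachability <- function(d, core) {
  mr <- pmax(d, outer(core, core, pmax))
  diag(mr) <- 0
  mr
}

# Prim's algorithm on a dense weight matrix; returns (n-1) x 3 matrix
# of edges (i, j, w).
mst_prim <- function(w) {
  n <- nrow(w)
  in_tree <- logical(n)
  key <- rep(Inf, n)
  parent <- integer(n)
  in_tree[1] <- TRUE
  key <- w[1, ]
  parent[] <- 1L
  edges <- matrix(0, n - 1, 3)
  for (e in seq_len(n - 1)) {
    key[in_tree] <- Inf
    v <- which.min(key)
    edges[e, ] <- c(parent[v], v, key[v])
    in_tree[v] <- TRUE
    upd <- !in_tree & w[v, ] < key
    key[upd] <- w[v, upd]
    parent[upd] <- v
  }
  edges
}

# Single-linkage hierarchy from MST edges: leaves 1..n, internal nodes
# n+1..2n-1 in order of increasing merge distance.  Returns a list with
# `merges` ((n-1) x 2 child ids), `dist`, `size`.
single_linkage <- function(edges, n) {
  ord <- order(edges[, 3])
  edges <- edges[ord, , drop = FALSE]
  parent_uf <- seq_len(2L * n - 1L)   # union-find with path halving
  node_of <- seq_len(n)               # current tree node of each root
  size <- c(rep(1L, n), integer(n - 1L))
  merges <- matrix(0L, n - 1L, 2L)
  dist <- numeric(n - 1L)
  find <- function(x) {
    while (parent_uf[x] != x) {
      parent_uf[x] <<- parent_uf[parent_uf[x]]
      x <- parent_uf[x]
    }
    x
  }
  for (e in seq_len(n - 1L)) {
    ra <- find(edges[e, 1]); rb <- find(edges[e, 2])
    new_node <- n + e
    merges[e, ] <- c(node_of[ra], node_of[rb])
    dist[e] <- edges[e, 3]
    size[new_node] <- size[node_of[ra]] + size[node_of[rb]]
    parent_uf[ra] <- rb
    node_of[rb] <- new_node
  }
  list(merges = merges, dist = dist, size = size, n = n)
}

leaves_under <- function(tree, node) {
  out <- integer(0)
  stack <- node
  n <- tree$n
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (v <= n) out <- c(out, v)
    else stack <- c(stack, tree$merges[v - n, ])
  }
  out
}

# Condense the single-linkage tree: clusters persist while they hold at
# least min_cluster_size points; smaller offshoots fall out as points.
# Cluster ids are 1 (root), 2, ... in creation order.
condense_tree <- function(tree, min_cluster_size) {
  n <- tree$n
  cap <- 4L * n
  r_parent <- integer(cap); r_child <- integer(cap)
  r_point <- logical(cap); r_lambda <- numeric(cap); r_size <- integer(cap)
  n_rows <- 0L
  add_row <- function(parent, child, is_point, lambda, size) {
    n_rows <<- n_rows + 1L
    r_parent[n_rows] <<- parent; r_child[n_rows] <<- child
    r_point[n_rows] <<- is_point; r_lambda[n_rows] <<- lambda
    r_size[n_rows] <<- size
  }
  next_cl <- 2L
  stack <- list(c(node = 2L * n - 1L, cl = 1L))
  while (length(stack)) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    node <- top[["node"]]; cl <- top[["cl"]]
    ch <- tree$merges[node - n, ]
    lam <- 1 / max(tree$dist[node - n], lambda_eps)
    sz <- tree$size[ch]
    big <- sz >= min_cluster_size
    if (all(big)) {
      for (i in 1:2) {
        add_row(cl, next_cl, FALSE, lam, sz[i])
        if (ch[i] > n) stack[[length(stack) + 1L]] <-
            c(node = ch[i], cl = next_cl)
        next_cl <- next_cl + 1L
      }
    } else if (!any(big)) {
      for (p in c(leaves_under(tree, ch[1]), leaves_under(tree, ch[2]))) {
        add_row(cl, p, TRUE, lam, 1L)
      }
    } else {
      small <- ch[!big]; keep <- ch[big]
      for (p in leaves_under(tree, small)) add_row(cl, p, TRUE, lam, 1L)
      if (keep > n) {
        stack[[length(stack) + 1L]] <- c(node = keep, cl = cl)
      } else {
        add_row(cl, keep, TRUE, lam, 1L)  # unreachable: keep is big
      }
    }
  }
  idx <- seq_len(n_rows)
  list(parent = r_parent[idx], child = r_child[idx], is_point = r_point[idx],
       lambda = r_lambda[idx], size = r_size[idx],
       n_clusters = next_cl - 1L)
}

cluster_stability <- function(ct) {
  k <- ct$n_clusters
  birth <- numeric(k)  # root stays 0
  cl_rows <- which(!ct$is_point)
  birth[ct$child[cl_rows]] <- ct$lambda[cl_rows]
  stab <- numeric(k)
  for (r in seq_along(ct$parent)) {
    p <- ct$parent[r]
    stab[p] <- stab[p] + (ct$lambda[r] - birth[p]) * ct$size[r]
  }
  stab
}

cluster_children <- function(ct) {
  k <- ct$n_clusters
  ch <- vector("list", k)
  rows <- which(!ct$is_point)
  for (r in rows) ch[[ct$parent[r]]] <- c(ch[[ct$parent[r]]], ct$child[r])
  ch
}

descendants_of <- function(children, cl) {
  out <- integer(0)
  stack <- children[[cl]]
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    out <- c(out, v)
    stack <- c(stack, children[[v]])
  }
  out
}

select_clusters <- function(ct, method) {
  k <- ct$n_clusters
  children <- cluster_children(ct)
  if (k <= 1) return(integer(0))
  if (method == "leaf") {
    leaves <- which(vapply(children, length, integer(1)) == 0)
    return(setdiff(leaves, 1L))
  }
  stab <- cluster_stability(ct)
  selected <- rep(TRUE, k)
  selected[1] <- FALSE
  for (cl in seq.int(k, 2L)) {
    ch <- children[[cl]]
    sub <- sum(stab[ch])
    if (length(ch) && sub > stab[cl]) {
      selected[cl] <- FALSE
      stab[cl] <- sub
    } else if (selected[cl]) {
      selected[descendants_of(children, cl)] <- FALSE
    }
  }
  which(selected)
}

#' Density-based clustering of the averaged distance matrix
#'
#' HDBSCAN over a precomputed distance matrix.  `method = "eom"`
#' (excess of mass) selects the most stable clusters of the condensed
#' hierarchy and tends to be coarser; `method = "leaf"` takes the
#' hierarchy's leaves and is finer.  Samples too isolated to join any
#' cluster are labelled `-1`.  Cluster ids are renumbered by descending
#' cluster size, `0` first.
#'
#' @param d A square symmetric nonnegative distance matrix (e.g. the
#'   `avg_distance` of a [run_ensemble()] result, which may be passed
#'   directly).
#' @param min_cluster_size Minimum number of samples a cluster must
#'   hold (default 100).
#' @param method `"eom"` or `"leaf"`.
#' @param min_samples Density smoothing parameter (the neighbor rank
#'   defining core distances); defaults to `min_cluster_size`, and is
#'   recorded in the result.
#' @return A `reef_clusters` object: `labels` (integer per sample, `-1`
#'   unassigned), `n_clusters`, `cluster_sizes`, `method`,
#'   `min_cluster_size`, `min_samples`.
#' @export
cluster_soundscape <- function(d, min_cluster_size = 100,
                               method = c("eom", "leaf"),
                               min_samples = NULL) {
  method <- match.arg(method)
  if (inherits(d, "reef_ensemble")) d <- d$avg_distance
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || any(abs(d - t(d)) > 1e-8) || any(d < 0)) {
    stop("d must be a square symmetric nonnegative distance matrix",
         call. = FALSE)
  }
  stopifnot(min_cluster_size >= 2)
  if (is.null(min_samples)) min_samples <- min_cluster_size
  n <- nrow(d)
  labels <- rep(-1L, n)
  if (min_cluster_size <= n) {
    core <- core_distances(d, min_samples)
    mr <- mutual_reachability(d, core)
    tree <- single_linkage(mst_prim(mr), n)
    ct <- condense_tree(tree, min_cluster_size)
    sel <- select_clusters(ct, method)
    if (length(sel)) {
      # map each cluster to its lowest selected ancestor (or 0)
      parent_of <- integer(ct$n_clusters)
      rows <- which(!ct$is_point)
      parent_of[ct$child[rows]] <- ct$parent[rows]
      sel_set <- logical(ct$n_clusters)
      sel_set[sel] <- TRUE
      assign_of <- integer(ct$n_clusters)
      for (cl in seq_len(ct$n_clusters)) {
        v <- cl
        while (v != 0L && !sel_set[v]) v <- parent_of[v]
        assign_of[cl] <- v
      }
      pt_rows <- which(ct$is_point)
      lab_raw <- assign_of[ct$parent[pt_rows]]
      labels[ct$child[pt_rows]] <- lab_raw   # 0 = unassigned
      # renumber by descending size
      tab <- sort(table(labels[labels > 0]), decreasing = TRUE)
      remap <- stats::setNames(seq_along(tab) - 1L, names(tab))
      labels <- ifelse(labels > 0, remap[as.character(labels)], -1L)
      labels <- as.integer(labels)
    }
  }
  sizes <- table(factor(labels[labels >= 0]))
  structure(
    list(labels = labels, n_clusters = length(unique(labels[labels >= 0])),
         cluster_sizes = as.integer(sizes), method = method,
         min_cluster_size = as.integer(min_cluster_size),
         min_samples = as.integer(min_samples)),
    class = "reef_clusters"
  )
}

#' @export
print.reef_clusters <- function(x, ...) {
  cat("<reef_clusters> ", x$n_clusters, " clusters (", x$method,
      ", min size ", x$min_cluster_size, "); ",
      sum(x$labels == -1L), " unassigned of ", length(x$labels), "\n",
      sep = "")
  invisible(x)
}

#' Cluster-by-label contingency matrix (row percentages)
#'
#' For every unsupervised cluster (row; `-1` = unassigned first), the
#' percentage of its samples carrying each category of a predefined
#' label (columns).  Rows sum to 100.
#'
#' @param clusters A `reef_clusters` object (or integer label vector
#'   with `-1` for unassigned).
#' @param categories Character vector of per-sample categories.
#' @return A `reef_contingency` object wrapping the percentage matrix.
#' @export
contingency <- function(clusters, categories) {
  labs <- if (inherits(clusters, "reef_clusters")) clusters$labels else clusters
  stopifnot(length(labs) == length(categories))
  cl_levels <- sort(unique(labs))          # -1 first, then ascending ids
  cat_levels <- sort(unique(categories))
  counts <- table(factor(labs, levels = cl_levels),
                  factor(categories, levels = cat_levels))
  pct <- sweep(unclass(counts), 1, rowSums(counts), "/") * 100
  structure(list(values = pct, clusters = cl_levels,
                 categories = cat_levels),
            class = "reef_contingency")
}

#' @export
print.reef_contingency <- function(x, ...) {
  cat("<reef_contingency> ", length(x$clusters), " clusters x ",
      length(x$categories), " categories (row %)\n", sep = "")
  print(round(x$values, 1))
  invisible(x)
}

#' Purity of the best cluster-to-category mapping
#'
#' Assigns each cluster its majority category and reports the fraction
#' of clustered (non `-1`) samples whose category matches, a summary of
#' how well unsupervised clusters recover a predefined label.
#'
#' @inheritParams contingency
#' @return A fraction in `[0, 1]` (`NA` if nothing was clustered).
#' @export
cluster_purity <- function(clusters, categories) {
  labs <- if (inherits(clusters, "reef_clusters")) clusters$labels else clusters
  keep <- labs >= 0
  if (!any(keep)) return(NA_real_)
  tab <- table(labs[keep], categories[keep])
  sum(apply(tab, 1, max)) / sum(tab)
}
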