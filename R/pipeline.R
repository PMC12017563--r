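# Full-pipeline orchestration and the results bundle.

#' Pipeline run configuration
#'
#' Defaults follow the canonical reef-campaign settings: mel embedding
#' over 70-2000 Hz, 15-s integration (4 samples per one-minute file),
#' 3-d UMAP repeated 100 times, HDBSCAN with minimum cluster size 100,
#' trajectory normalisation over 100 nearest neighbors.
#'
#' @param embedding `"mel_spectrum"`, `"mel_spectrogram"` or a
#'   registered adapter name.
#' @param fmin,fmax Analysis band in Hz.
#' @param n_mels,n_fft,hop_s Mel/STFT parameters (see [mel_spec()]).
#' @param highpass_hz,highpass_order High-pass filter settings.
#' @param integration_time_s Integration time in seconds.
#' @param order Feature pipeline order (see [build_features()]).
#' @param projection `"umap"` or `"pca"`.
#' @param n_components,n_repeats,base_seed Ensemble settings.
#' @param min_cluster_size,cluster_method Clustering settings
#'   (`cluster_method` may list both `"eom"` and `"leaf"`).
#' @param trajectory_k Neighbors for trajectory normalisation.
#' @param group_col,replicate_col Labels used for trajectories.
#' @param diag_k,diag_triplets Neighborhood size and triplet count for
#'   the DLP/RTA diagnostics.
#' @return An object of class `run_config`.
#' @export
run_config <- function(embedding = "mel_spectrum", fmin = 70, fmax = 2000,
                       n_mels = 64, n_fft = 2048, hop_s = 0.01,
                       highpass_hz = 70, highpass_order = 8,
                       integration_time_s = 15,
                       order = "aggregate_first",
                       projection = "umap", n_components = 3,
                       n_repeats = 100, base_seed = 0,
                       min_cluster_size = 100,
                       cluster_method = c("eom", "leaf"),
                       trajectory_k = 100,
                       group_col = "site", replicate_col = "replicate",
                       diag_k = 10, diag_triplets = 10000) {
  structure(as.list(environment()), class = "run_config")
}

reefscape_version <- function() {
  as.character(utils::packageVersion("reefscape"))
}

#' Run the full soundscape pipeline
#'
#' Reads the campaign, builds the feature matrix, runs the projection
#' ensemble, and derives silhouette matrices (one per label whose
#' categories all hold at least two samples), cluster assignments with
#' label contingency, relative trajectories, and stability diagnostics.
#'
#' @param metadata Campaign metadata CSV path or data frame (see
#'   [read_campaign()]).
#' @param config A [run_config()].
#' @param out_path Optional HDF5 path; when given the bundle is written
#'   with [write_bundle()].
#' @param audio_root Passed to [read_campaign()].
#' @param quiet Suppress stage messages.
#' @return A `reef_bundle` list: `config`, `features`, `ensemble`,
#'   `silhouettes`, `clusters`, `contingencies`, `trajectories`,
#'   `diagnostics`, `version`.
#' @export
run_soundscape <- function(metadata, config = run_config(),
                           out_path = NULL, audio_root = NULL,
                           quiet = FALSE) {
  say <- function(...) if (!quiet) message("[reefscape] ", ...)
  t0 <- Sys.time()
  stage <- function(name, expr) {
    say(name, " ...")
    out <- tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    say(name, " done (", round(as.numeric(Sys.time() - t0, units = "secs"), 1),
        " s elapsed)")
    out
  }

  campaign <- stage("campaign_io", read_campaign(metadata, audio_root))
  mspec <- mel_spec(n_mels = config$n_mels, fmin = config$fmin,
                    fmax = config$fmax, n_fft = config$n_fft,
                    hop_s = config$hop_s)
  fspec <- filter_spec(cutoff_hz = config$highpass_hz,
                       order = config$highpass_order)
  features <- stage("features", build_features(
    campaign, embedding = config$embedding, spec = mspec, filt = fspec,
    integration_time_s = config$integration_time_s, order = config$order))

  ensemble <- stage("projection", run_ensemble(
    features, method = config$projection,
    n_components = config$n_components, n_repeats = config$n_repeats,
    base_seed = config$base_seed))

  silhouettes <- stage("silhouettes", {
    out <- list()
    for (lab in features$label_names) {
      cats <- features$samples[[lab]]
      if (length(unique(cats)) >= 2 && min(table(cats)) >= 2) {
        out[[lab]] <- silhouette_matrix(ensemble$avg_distance, cats, lab)
      }
    }
    out
  })

  methods <- config$cluster_method
  clusters <- stage("clustering", {
    stats::setNames(lapply(methods, function(m) {
      cluster_soundscape(ensemble$avg_distance,
                         min_cluster_size = config$min_cluster_size,
                         method = m)
    }), methods)
  })
  contingencies <- lapply(clusters, function(cl) {
    stats::setNames(lapply(features$label_names, function(lab) {
      contingency(cl, features$samples[[lab]])
    }), features$label_names)
  })

  trajectories <- stage("trajectories", soundscape_trajectories(
    ensemble, group_col = config$group_col,
    replicate_col = config$replicate_col, k = config$trajectory_k))

  diagnostics <- stage("diagnostics", {
    conv <- if (ensemble$n_repeats >= 2) convergence(ensemble)
    k <- min(config$diag_k, nrow(features$values) - 1)
    low <- ensemble$embeddings[[1]]
    list(convergence = conv,
         dlp = dlp(features, low, k = k),
         rta = rta(features, low, n_triplets = config$diag_triplets,
                   seed = config$base_seed),
         diag_k = k,
         iqm_features = iqm(as.matrix(stats::dist(features$values))),
         iqm_avg_distance = iqm(ensemble$avg_distance))
  })

  bundle <- structure(
    list(config = config, features = features, ensemble = ensemble,
         silhouettes = silhouettes, clusters = clusters,
         contingencies = contingencies, trajectories = trajectories,
         diagnostics = diagnostics, version = reefscape_version()),
    class = "reef_bundle")
  if (!is.null(out_path)) write_bundle(bundle, out_path)
  bundle
}

#' @export
print.reef_bundle <- function(x, ...) {
  cat("<reef_bundle> reefscape ", x$version, "\n", sep = "")
  cat("  samples: ", nrow(x$features$values), " x ",
      ncol(x$features$values), " dims\n", sep = "")
  cat("  ensemble: ", x$ensemble$method, " x ", x$ensemble$n_repeats,
      " (", x$ensemble$n_components, "d)\n", sep = "")
  cat("  silhouette labels: ", paste(names(x$silhouettes), collapse = ", "),
      "\n", sep = "")
  for (m in names(x$clusters)) {
    cat("  clusters [", m, "]: ", x$clusters[[m]]$n_clusters, "\n", sep = "")
  }
  invisible(x)
}

# --- HDF5 bundle -------------------------------------------------------

h5w <- function(obj, file, name) rhdf5::h5write(obj, file, name)

#' Write a results bundle to HDF5
#'
#' Group layout: `/config` (JSON echo), `/features`, `/ensemble`,
#' `/silhouette/<label>`, `/clusters/<method>`,
#' `/trajectories/<group>/<replicate>`, `/diagnostics`, `/version`.
#' The write goes to a temporary file first, so a failed run never
#' leaves a partial bundle at `path`.
#'
#' @param bundle A `reef_bundle`.
#' @param path Output HDF5 path.
#' @return `path`, invisibly.
#' @export
write_bundle <- function(bundle, path) {
  stopifnot(inherits(bundle, "reef_bundle"))
  tmp <- paste0(path, ".tmp")
  if (file.exists(tmp)) unlink(tmp)
  rhdf5::h5createFile(tmp)
  on.exit(rhdf5::h5closeAll(), add = TRUE)

  h5w(as.character(jsonlite::toJSON(unclass(bundle$config),
                                    auto_unbox = TRUE, null = "null")),
      tmp, "config")
  h5w(bundle$version, tmp, "version")

  fx <- bundle$features
  rhdf5::h5createGroup(tmp, "features")
  h5w(fx$values, tmp, "features/values")
  h5w(colnames(fx$values), tmp, "features/dim_names")
  h5w(fx$pruned, tmp, "features/pruned")
  h5w(fx$label_names, tmp, "features/label_names")
  if (!is.null(fx$scaling)) {
    rhdf5::h5createGroup(tmp, "features/scaling")
    h5w(fx$scaling$dim, tmp, "features/scaling/dim")
    h5w(fx$scaling$center, tmp, "features/scaling/center")
    h5w(fx$scaling$scale, tmp, "features/scaling/scale")
    h5w(fx$scaling$fallback, tmp, "features/scaling/fallback")
  }
  rhdf5::h5createGroup(tmp, "features/samples")
  for (cn in names(fx$samples)) {
    v <- fx$samples[[cn]]
    if (inherits(v, "POSIXct")) v <- format(v, "%Y-%m-%dT%H:%M:%S")
    h5w(v, tmp, paste0("features/samples/", cn))
  }

  en <- bundle$ensemble
  rhdf5::h5createGroup(tmp, "ensemble")
  h5w(en$method, tmp, "ensemble/method")
  h5w(en$n_components, tmp, "ensemble/n_components")
  h5w(en$seeds, tmp, "ensemble/seeds")
  h5w(en$avg_distance, tmp, "ensemble/avg_distance")
  emb <- simplify2array(en$embeddings)     # n x d x N
  h5w(emb, tmp, "ensemble/embeddings")

  rhdf5::h5createGroup(tmp, "silhouette")
  for (lab in names(bundle$silhouettes)) {
    g <- paste0("silhouette/", lab)
    rhdf5::h5createGroup(tmp, g)
    sm <- bundle$silhouettes[[lab]]
    h5w(sm$values, tmp, paste0(g, "/values"))
    h5w(sm$categories, tmp, paste0(g, "/categories"))
  }

  rhdf5::h5createGroup(tmp, "clusters")
  for (m in names(bundle$clusters)) {
    g <- paste0("clusters/", m)
    rhdf5::h5createGroup(tmp, g)
    cl <- bundle$clusters[[m]]
    h5w(cl$labels, tmp, paste0(g, "/labels"))
    h5w(cl$min_cluster_size, tmp, paste0(g, "/min_cluster_size"))
    h5w(cl$min_samples, tmp, paste0(g, "/min_samples"))
    for (lab in names(bundle$contingencies[[m]])) {
      cg <- paste0(g, "/contingency_", lab)
      rhdf5::h5createGroup(tmp, cg)
      co <- bundle$contingencies[[m]][[lab]]
      h5w(co$values, tmp, paste0(cg, "/values"))
      h5w(as.integer(co$clusters), tmp, paste0(cg, "/clusters"))
      h5w(co$categories, tmp, paste0(cg, "/categories"))
    }
  }

  rhdf5::h5createGroup(tmp, "trajectories")
  tr <- bundle$trajectories
  for (g in unique(tr$group)) {
    gg <- paste0("trajectories/", g)
    rhdf5::h5createGroup(tmp, gg)
    for (r in unique(tr$replicate[tr$group == g])) {
      rg <- paste0(gg, "/", r)
      rhdf5::h5createGroup(tmp, rg)
      sel <- tr[tr$group == g & tr$replicate == r, ]
      h5w(format(sel$time, "%Y-%m-%dT%H:%M:%S"), tmp, paste0(rg, "/time"))
      h5w(sel$median_rel_distance, tmp, paste0(rg, "/median"))
      h5w(sel$decile_low, tmp, paste0(rg, "/decile1"))
      h5w(sel$decile_high, tmp, paste0(rg, "/decile9"))
      h5w(sel$k_used[1], tmp, paste0(rg, "/k"))
    }
  }

  rhdf5::h5createGroup(tmp, "diagnostics")
  dg <- bundle$diagnostics
  if (!is.null(dg$convergence)) {
    rhdf5::h5createGroup(tmp, "diagnostics/convergence")
    for (cn in c("n", "rel_mean_abs_diff", "rel_max_abs_diff", "iqm")) {
      h5w(dg$convergence[[cn]], tmp, paste0("diagnostics/convergence/", cn))
    }
  }
  for (cn in c("dlp", "rta", "diag_k", "iqm_features", "iqm_avg_distance")) {
    if (!is.null(dg[[cn]])) h5w(dg[[cn]], tmp, paste0("diagnostics/", cn))
  }
  rhdf5::h5closeAll()
  file.rename(tmp, path)
  invisible(path)
}

#' Read a results bundle from HDF5
#'
#' Reloads every section written by [write_bundle()]; no original audio
#' is needed.
#'
#' @param path HDF5 path.
#' @return A `reef_bundle_loaded` list mirroring the written payloads.
#' @export
read_bundle <- function(path) {
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  raw <- rhdf5::h5read(path, "/")
  raw$config <- jsonlite::fromJSON(as.character(raw$config))
  structure(raw, class = "reef_bundle_loaded")
}

# Reshape a reloaded HDF5 bundle into the live-bundle sections
# export_csv() needs.
normalize_loaded_bundle <- function(raw) {
  sil <- lapply(raw$silhouette, function(sm) {
    v <- sm$values
    dimnames(v) <- list(sm$categories, sm$categories)
    list(values = v, categories = as.character(sm$categories))
  })
  clus <- names(raw$clusters)
  cont <- stats::setNames(lapply(clus, function(m) {
    sec <- raw$clusters[[m]]
    labs <- sub("^contingency_", "", grep("^contingency_", names(sec),
                                          value = TRUE))
    stats::setNames(lapply(labs, function(l) {
      co <- sec[[paste0("contingency_", l)]]
      v <- co$values
      dimnames(v) <- list(co$clusters, co$categories)
      list(values = v, clusters = as.integer(co$clusters),
           categories = as.character(co$categories))
    }), labs)
  }), clus)
  tr_rows <- list()
  for (g in names(raw$trajectories)) {
    for (r in names(raw$trajectories[[g]])) {
      sec <- raw$trajectories[[g]][[r]]
      tr_rows[[paste(g, r)]] <- tibble::tibble(
        group = g, replicate = r,
        time = as.POSIXct(as.character(sec$time),
                          format = "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
        median_rel_distance = as.numeric(sec$median),
        decile_low = as.numeric(sec$decile1),
        decile_high = as.numeric(sec$decile9))
    }
  }
  cv <- raw$diagnostics$convergence
  list(
    silhouettes = sil,
    clusters = stats::setNames(lapply(clus, function(m) m), clus),
    contingencies = cont,
    trajectories = dplyr::bind_rows(tr_rows),
    diagnostics = list(convergence = if (!is.null(cv)) tibble::tibble(
      n = as.integer(cv$n),
      rel_mean_abs_diff = as.numeric(cv$rel_mean_abs_diff),
      rel_max_abs_diff = as.numeric(cv$rel_max_abs_diff),
      iqm = as.numeric(cv$iqm)))
  )
}

#' Export one bundle section to CSV
#'
#' @param bundle A `reef_bundle` from [run_soundscape()], or a bundle
#'   reloaded from HDF5 with [read_bundle()].
#' @param what `"silhouette"`, `"contingency"`, `"trajectories"` or
#'   `"convergence"`.
#' @param out_csv Output path.
#' @param label Label name for silhouette/contingency sections.
#' @param method Cluster method for contingency (default first).
#' @return `out_csv`, invisibly.
#' @export
export_csv <- function(bundle, what, out_csv, label = NULL, method = NULL) {
  sections <- c("silhouette", "contingency", "trajectories", "convergence")
  if (!what %in% sections) {
    stop("unknown section '", what, "'; available: ",
         paste(sections, collapse = ", "), call. = FALSE)
  }
  if (inherits(bundle, "reef_bundle_loaded")) {
    bundle <- normalize_loaded_bundle(bundle)
  }
  df <- switch(what,
    silhouette = {
      label <- label %||% names(bundle$silhouettes)[1]
      sm <- bundle$silhouettes[[label]]
      if (is.null(sm)) stop("no silhouette matrix for label '", label, "'",
                            call. = FALSE)
      data.frame(category = sm$categories, sm$values, check.names = FALSE)
    },
    contingency = {
      method <- method %||% names(bundle$clusters)[1]
      label <- label %||% names(bundle$contingencies[[method]])[1]
      co <- bundle$contingencies[[method]][[label]]
      data.frame(cluster = co$clusters, co$values, check.names = FALSE)
    },
    trajectories = {
      tr <- bundle$trajectories
      data.frame(group = tr$group, replicate = tr$replicate,
                 time = format(tr$time, "%Y-%m-%dT%H:%M:%S"),
                 median = tr$median_rel_distance,
                 decile1 = tr$decile_low, decile9 = tr$decile_high)
    },
    convergence = as.data.frame(bundle$diagnostics$convergence)
  )
  utils::write.csv(df, out_csv, row.names = FALSE)
  invisible(out_csv)
}
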