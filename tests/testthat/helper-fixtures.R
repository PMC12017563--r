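# Shared fixtures, all generated in code at test time.

# A tiny mono 16-bit WAV on disk; returns its path.
write_test_wav <- function(samples, sample_rate = 8000,
                           path = tempfile(fileext = ".wav")) {
  write_wav(samples, sample_rate, path)
  path
}

# A minimal campaign on disk: `n` short recordings with a metadata CSV.
# Short files and a low sample rate keep unit tests fast.
make_tiny_campaign <- function(n = 3, duration_s = 2, sample_rate = 8000,
                               dir = tempfile("camp")) {
  dir.create(dir)
  rows <- lapply(seq_len(n), function(i) {
    set.seed(100 + i)
    fn <- sprintf("rec%02d.wav", i)
    write_wav(stats::rnorm(duration_s * sample_rate, sd = 0.1) +
                sin(2 * pi * 440 * seq_len(duration_s * sample_rate) /
                      sample_rate) * 0.2,
              sample_rate, file.path(dir, fn))
    data.frame(file = fn,
               start = sprintf("2023-11-16T12:%02d:00", 5 + 10 * (i - 1)),
               site = if (i %% 2) "siteA" else "siteB",
               replicate = "rep1")
  })
  csv <- file.path(dir, "metadata.csv")
  utils::write.csv(do.call(rbind, rows), csv, row.names = FALSE,
                   quote = FALSE)
  csv
}

# Independent silhouette oracle: direct per-point loop over the formula.
silhouette_oracle <- function(d, cats, a, b) {
  idx <- which(cats %in% c(a, b))
  s <- numeric(length(idx))
  for (q in seq_along(idx)) {
    i <- idx[q]
    own <- setdiff(which(cats == cats[i]), i)
    other <- which(cats == setdiff(c(a, b), cats[i]))
    ai <- mean(d[i, own])
    bi <- mean(d[i, other])
    s[q] <- if (ai == 0 && bi == 0) 0 else (bi - ai) / max(ai, bi)
  }
  mean(s)
}

# Euclidean distance matrix of two well separated planted blobs.
planted_blobs <- function(n_per = 150, gap = 20, sd = 1, dims = 2,
                          seed = 42) {
  set.seed(seed)
  x <- rbind(matrix(stats::rnorm(n_per * dims, 0, sd), ncol = dims),
             matrix(stats::rnorm(n_per * dims, gap, sd), ncol = dims))
  list(x = x, d = as.matrix(stats::dist(x)),
       truth = rep(c("A", "B"), each = n_per))
}

# The packaged three-site reduced reef campaign used by the deeper
# end-to-end tests; generated once per test session.
mini_campaign_csv <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      dir <- file.path(tempdir(), "reefscape-mini-campaign")
      if (!file.exists(file.path(dir, "metadata.csv"))) {
        meta <- generate_campaign(example_reef_campaign(seed = 1), dir)
      }
      cache <<- file.path(dir, "metadata.csv")
    }
    cache
  }
})

# One shared full pipeline run on the mini campaign (expensive; reused
# across acceptance-style tests).
mini_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- run_config(n_repeats = 20, min_cluster_size = 20)
      cache <<- run_soundscape(mini_campaign_csv(), cfg, quiet = TRUE)
    }
    cache
  }
})
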