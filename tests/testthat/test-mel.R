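test_that("mel spectrum has one natural-log energy per band and floors silence", {
  sr <- 44100
  seg <- stats::rnorm(sr) * 0.1
  v <- mel_spectrum(seg, sr)
  expect_equal(dim(v), c(1, 64))
  expect_true(all(is.finite(v)))
  silent <- mel_spectrum(rep(0, sr), sr)
  expect_equal(unname(silent[1, ]), rep(log(1e-12), 64))
})

test_that("a pure tone at a band's center frequency maximises that band", {
  sr <- 44100
  spec <- mel_spec()
  fb <- mel_filterbank(spec, sr, n_fft = sr)
  # pick a mid-range band and its center frequency (peak of the triangle)
  k <- 32
  freqs <- (seq_len(ncol(fb)) - 1) * sr / sr
  fc <- freqs[which.max(fb[k, ])]
  tone <- sin(2 * pi * fc * (0:(sr - 1)) / sr)
  # oracle: filterbank response x tone power spectrum
  ps <- (Mod(stats::fft(tone)[seq_len(sr %/% 2 + 1)])^2) / sr^2
  oracle_band <- which.max(as.vector(fb %*% ps))
  expect_equal(oracle_band, k)
  v <- mel_spectrum(tone, sr, spec)
  expect_equal(which.max(v[1, ]), k, ignore_attr = TRUE)
})

test_that("mel spectrogram realises 64 x 100 = 6400 values at a 441-sample hop", {
  sr <- 44100
  spec <- mel_spec()
  expect_equal(spec$hop_s * sr, 441)
  expect_equal(length(reefscape:::stft_frame_starts(sr, 441L)), 100)
  seg <- stats::rnorm(sr) * 0.05
  v <- mel_spectrogram(seg, sr, spec)
  expect_equal(ncol(v), 6400)
  expect_match(colnames(v)[1], "mel_b01_f001")
})

test_that("a stationary tone gives equal interior spectrogram frames", {
  sr <- 44100
  tone <- sin(2 * pi * 500 * (0:(sr - 1)) / sr) * 0.5
  m <- mel_spectrogram(tone, sr, flatten = FALSE)[[1]]
  # interior frames (full windows, away from edge padding)
  interior <- m[, 5:90]
  spread <- apply(interior, 1, function(r) max(r) - min(r))
  expect_lt(max(spread / abs(rowMeans(interior))), 1e-6)
})

test_that("amplitude scaling shifts log energies by exactly 2 log(c)", {
  sr <- 44100
  set.seed(5)
  seg <- stats::rnorm(sr) * 0.1
  for (c_ in c(2, 0.5)) {
    v1 <- mel_spectrum(seg, sr)
    v2 <- mel_spectrum(c_ * seg, sr)
    expect_equal(v2 - v1, matrix(2 * log(c_), 1, 64), tolerance = 1e-6,
                 ignore_attr = TRUE)
    s1 <- mel_spectrogram(seg, sr)
    s2 <- mel_spectrogram(c_ * seg, sr)
    expect_equal(unname(s2 - s1), matrix(2 * log(c_), 1, 6400),
                 tolerance = 1e-6)
  }
})

test_that("mel embeddings are deterministic", {
  sr <- 44100
  set.seed(6)
  seg <- stats::rnorm(sr)
  expect_identical(mel_spectrum(seg, sr), mel_spectrum(seg, sr))
  expect_identical(mel_spectrogram(seg, sr), mel_spectrogram(seg, sr))
})

test_that("embedding adapters enforce their declared contract", {
  sr <- 44100
  seg <- stats::rnorm(sr) * 0.1
  register_embedding_adapter("first10", function(m) as.numeric(m[1, 1:10]),
                             n_dims = 10)
  out <- cnn_embed(seg, sr, "first10")
  expect_equal(dim(out), c(1, 10))
  register_embedding_adapter("liar", function(m) numeric(64), n_dims = 128)
  expect_error(cnn_embed(seg, sr, "liar"), "declared 128")
  expect_error(cnn_embed(seg, sr, "unregistered"), "register")
})

test_that("adapters see only the first 0.96 s of frames", {
  sr <- 44100
  seg <- stats::rnorm(sr) * 0.1
  seen <- NULL
  register_embedding_adapter("probe", function(m) {
    seen <<- dim(m)
    numeric(5)
  }, n_dims = 5)
  cnn_embed(seg, sr, "probe")
  expect_equal(seen, c(64, 96))
})
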