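test_that("read_campaign returns one entry per row with header durations", {
  csv <- make_tiny_campaign(n = 3, duration_s = 2)
  camp <- read_campaign(csv)
  expect_equal(nrow(camp), 3)
  expect_equal(camp$duration_s, rep(2, 3))
  expect_equal(attr(camp, "label_names"), c("site", "replicate"))
  expect_s3_class(camp$start, "POSIXct")
  # row order preserved
  expect_equal(basename(camp$file), sprintf("rec%02d.wav", 1:3))
})

test_that("read_campaign errors name the offending row", {
  csv <- make_tiny_campaign(n = 2)
  tab <- utils::read.csv(csv)
  tab$file[2] <- "missing.wav"
  expect_error(read_campaign(tab, audio_root = dirname(csv)), "row 2")
  expect_error(read_campaign(data.frame(file = "a.wav", start = "x")),
               "label column")
})

test_that("high-pass filter rejects DC and passes the band, matching the analog response", {
  sr <- 44100
  spec <- filter_spec()   # 70 Hz, order 8, zero phase
  expect_equal(highpass(rep(0, sr), sr, spec), rep(0, sr))
  dc <- highpass(rep(0.5, sr), sr, spec)
  expect_lt(sqrt(mean(dc^2)), 1e-3 * 0.5)
  # steady-state gain oracle: |H(f)|^2 of the analog 8th-order
  # Butterworth prototype, squared magnitude from the forward-backward
  # pass: gain = 1 / (1 + (fc/f)^(2*order))
  t <- (0:(sr - 1)) / sr
  mid <- (sr %/% 4):(3 * sr %/% 4)
  for (f in c(1000, 35)) {
    x <- sin(2 * pi * f * t)
    y <- highpass(x, sr, spec)
    gain <- sqrt(mean(y[mid]^2)) / sqrt(mean(x[mid]^2))
    expect_equal(gain, 1 / (1 + (70 / f)^16), tolerance = 0.01)
  }
})

test_that("high-pass filter is linear and errors above Nyquist", {
  set.seed(3)
  sr <- 8000
  x <- stats::rnorm(2000)
  y <- stats::rnorm(2000)
  lhs <- highpass(2 * x + 3 * y, sr)
  rhs <- 2 * highpass(x, sr) + 3 * highpass(y, sr)
  expect_equal(lhs, rhs, tolerance = 1e-9)
  expect_error(highpass(x, 100, filter_spec(cutoff_hz = 70)), "Nyquist")
})

test_that("segmentation drops the remainder and is otherwise lossless", {
  sr <- 1000
  x <- stats::rnorm(60.5 * sr)
  seg <- segment_waveform(x, sr, 1)
  expect_equal(nrow(seg), 60)
  expect_equal(as.vector(t(seg)), x[1:(60 * sr)])   # bit-exact concat
  expect_equal(nrow(segment_waveform(x[1:sr], sr, 1)), 1)
  expect_equal(nrow(segment_waveform(x[1:10], sr, 1)), 0)
})

test_that("filtering is applied to whole recordings, not per segment", {
  sr <- 8000
  set.seed(4)
  x <- stats::rnorm(3 * sr)
  whole <- segment_waveform(highpass(x, sr), sr, 1)
  per_seg <- apply(segment_waveform(x, sr, 1), 1, highpass,
                   sample_rate = sr)
  # the two differ at segment boundaries: the pipeline's contract is
  # the whole-recording variant
  expect_false(isTRUE(all.equal(whole, t(per_seg), tolerance = 1e-6)))
  camp <- read_campaign(make_tiny_campaign(n = 1, duration_s = 3,
                                           sample_rate = sr))
  fx <- build_features(camp, spec = mel_spec(fmax = 2000),
                       integration_time_s = 1, scale = FALSE)
  wav <- read_wav(camp$file[1])
  ref <- mel_spectrum(segment_waveform(highpass(wav$samples, sr), sr, 1),
                      sr, mel_spec(fmax = 2000))
  # build_features prunes constant dims; compare on surviving ones
  expect_equal(unname(fx$values),
               unname(ref[, colnames(fx$values), drop = FALSE]),
               tolerance = 1e-12)
})

test_that("one recording day of the standard duty cycle holds 145 files", {
  # calendar oracle: enumerate starts from 12:05 to 12:05 next day
  starts <- seq(as.POSIXct("2023-11-16 12:05:00", tz = "UTC"),
                as.POSIXct("2023-11-17 12:05:00", tz = "UTC"),
                by = 600)
  expect_equal(length(campaign_schedule(600)), length(starts))
  expect_equal(length(campaign_schedule(600)), 145)
  # 3 sites x 3 days of that schedule list 1305 recordings
  expect_equal(3 * 3 * length(campaign_schedule(600)), 1305)
  expect_equal(length(campaign_schedule(3600)), 25)
})
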