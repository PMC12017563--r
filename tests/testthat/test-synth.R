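test_that("snap trains are Poisson processes rendered deterministically", {
  expect_equal(snap_train(0, 10, 8000, seed = 1), rep(0, 80000),
               ignore_attr = TRUE)
  x1 <- snap_train(50, 60, 44100, seed = 5)
  x2 <- snap_train(50, 60, 44100, seed = 5)
  expect_identical(x1, x2)
  # count within the central 99% Poisson interval of mean 3000
  n_snaps <- attr(x1, "n_snaps")
  expect_gte(n_snaps, stats::qpois(0.005, 3000))
  expect_lte(n_snaps, stats::qpois(0.995, 3000))
  expect_false(identical(x1, snap_train(50, 60, 44100, seed = 6)))
})

band_energy <- function(x, sr, f_lo, f_hi) {
  ps <- Mod(stats::fft(x)[seq_len(length(x) %/% 2 + 1)])^2
  f <- (seq_along(ps) - 1) * sr / length(x)
  sum(ps[f >= f_lo & f < f_hi])
}

test_that("fish-only scenes concentrate their energy below 1 kHz", {
  cfg <- scene_config(duration_s = 10, snap_rate_hz = 0,
                      fish_call_rate_hz = 2, fish_band = c(250, 600),
                      background_level = 0, seed = 3)
  x <- scene(cfg)
  x <- highpass(x, cfg$sample_rate)
  frac <- band_energy(x, cfg$sample_rate, 0, 1000) /
    band_energy(x, cfg$sample_rate, 0, cfg$sample_rate / 2)
  expect_gt(frac, 0.9)
})

test_that("boat passages add broadband energy across the analysis band", {
  quiet <- scene_config(duration_s = 10, snap_rate_hz = 5,
                        background_level = 0.02, seed = 4)
  boat <- scene_config(duration_s = 10, snap_rate_hz = 5,
                       background_level = 0.02,
                       boat_intervals = list(c(0, 10, 0.4)), seed = 4)
  xq <- scene(quiet); xb <- scene(boat)
  r <- band_energy(xb, 44100, 70, 2000) / band_energy(xq, 44100, 70, 2000)
  expect_gt(r, 10)
})

test_that("an all-zero configuration produces digital silence", {
  cfg <- scene_config(duration_s = 2, snap_rate_hz = 0,
                      fish_call_rate_hz = 0, background_level = 0, seed = 1)
  expect_equal(scene(cfg), rep(0, 2 * 44100))
})

test_that("scenes never clip", {
  cfg <- scene_config(duration_s = 5, snap_rate_hz = 500,
                      boat_intervals = list(c(0, 5, 2)), seed = 9)
  expect_lte(max(abs(scene(cfg))), 0.99 + 1e-12)
})

test_that("campaigns are written deterministically with matching metadata", {
  sites <- list(s1 = scene_config(duration_s = 2, snap_rate_hz = 10,
                                  background_level = 0.02))
  cfg <- campaign_config(sites, n_days = 1, day_s = 600,
                         cycle_period_s = 600, file_length_s = 2, seed = 7)
  d1 <- tempfile("c1"); d2 <- tempfile("c2")
  m1 <- generate_campaign(cfg, d1)
  m2 <- generate_campaign(cfg, d2)
  expect_equal(nrow(m1), 2)   # starts at 0 and 600 s, inclusive
  wavs1 <- list.files(d1, pattern = "wav$", full.names = TRUE)
  wavs2 <- list.files(d2, pattern = "wav$", full.names = TRUE)
  expect_equal(length(wavs1), nrow(m1))
  expect_identical(unname(tools::md5sum(wavs1)),
                   unname(tools::md5sum(wavs2)))
  # metadata is consumed verbatim by the campaign reader
  camp <- read_campaign(attr(m1, "metadata_csv"))
  expect_equal(nrow(camp), 2)
  expect_equal(camp$duration_s, rep(2, 2))
})

test_that("the canonical schedule produces the documented file counts", {
  # 1 site, 1 day, hourly cycle over a full day, inclusive: 25 files
  expect_equal(length(campaign_schedule(3600, 86400)), 25)
  # full reef schedule: 145 files/day/site
  expect_equal(length(campaign_schedule(600, 86400)), 145)
  # reduced example campaign: 7 files per hour-long site-day
  cfg <- example_reef_campaign()
  expect_equal(length(campaign_schedule(cfg$cycle_period_s, cfg$day_s)), 7)
})

test_that("period labels follow the fixed 06:00/18:00 day window", {
  sites <- list(s1 = scene_config(duration_s = 1, snap_rate_hz = 0,
                                  fish_call_rate_hz = 0,
                                  background_level = 0.01))
  cfg <- campaign_config(sites, n_days = 1, day_s = 21600,
                         cycle_period_s = 21600, file_length_s = 1,
                         first_start = "16:00:00", seed = 2)
  m <- generate_campaign(cfg, tempfile("p"))
  # files at 16:00 (day) and 22:00 (night)
  expect_equal(m$period, c("day", "night"))
})
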