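# Deterministic synthetic reef-soundscape generator.  Plants the sound
# classes a reef campaign contains -- snapping-shrimp click trains,
# low-frequency fish calls, broadband boat noise, broadband rain
# masking, a day/night activity cycle -- with known ground truth, so
# every pipeline stage can be tested without field recordings.  The
# event waveform shapes (exponentially decaying broadband clicks for
# snaps, short tone-pulse trains for fish calls) are inventions of this
# package, not species models.

#' Synthetic scene configuration
#'
#' @param duration_s Scene length in seconds (default 60, one file).
#' @param sample_rate Sampling rate in Hz (default 44100).
#' @param snap_rate_hz Poisson rate of shrimp snaps per second
#'   (default 50).
#' @param fish_call_rate_hz Poisson rate of fish calls per second
#'   (default 0.3).
#' @param fish_band Frequency band `(f_low, f_high)` of fish calls in
#'   Hz; `f_high` must be at most 1000 (fish choruses sit below 1 kHz).
#' @param boat_intervals List of `c(start, end, level)` triplets
#'   (seconds within the scene; level is a linear amplitude) of boat
#'   passages.
#' @param rain_intervals Same shape, for rain showers.
#' @param diel_night_gain Multiplier on `snap_rate_hz` at night
#'   (default 3: reefs get noisier after dark).
#' @param background_level Amplitude of the permanent broadband water
#'   background (default 0.02; 0 gives digital silence when all other
#'   components are off).
#' @param snap_level,fish_level Component amplitudes.
#' @param seed Scene RNG seed.
#' @return An object of class `scene_config`.
#' @export
scene_config <- function(duration_s = 60, sample_rate = 44100,
                         snap_rate_hz = 50, fish_call_rate_hz = 0.3,
                         fish_band = c(200, 800),
                         boat_intervals = list(),
                         rain_intervals = list(),
                         diel_night_gain = 3,
                         background_level = 0.02,
                         snap_level = 0.6, fish_level = 0.3,
                         seed = 1) {
  stopifnot(duration_s > 0, sample_rate > 0, snap_rate_hz >= 0,
            fish_call_rate_hz >= 0, length(fish_band) == 2,
            fish_band[1] < fish_band[2], fish_band[2] <= 1000,
            diel_night_gain >= 0, background_level >= 0)
  check_iv <- function(ivs) {
    for (iv in ivs) {
      stopifnot(length(iv) == 3, iv[1] >= 0, iv[2] <= duration_s,
                iv[1] < iv[2], iv[3] >= 0)
    }
  }
  check_iv(boat_intervals); check_iv(rain_intervals)
  structure(as.list(environment())[c(
    "duration_s", "sample_rate", "snap_rate_hz", "fish_call_rate_hz",
    "fish_band", "boat_intervals", "rain_intervals", "diel_night_gain",
    "background_level", "snap_level", "fish_level", "seed")],
    class = "scene_config")
}

# Poisson event times on [0, duration).
poisson_times <- function(rate_hz, duration_s) {
  n <- stats::rpois(1, rate_hz * duration_s)
  sort(stats::runif(n, 0, duration_s))
}

#' Snapping-shrimp click train
#'
#' Homogeneous-Poisson snap times; each snap is a broadband transient
#' shorter than 2 ms (white noise with an exponential decay envelope).
#' Deterministic for a given seed.
#'
#' @param rate_hz Snap rate per second.
#' @param duration_s Length in seconds.
#' @param sample_rate Hz.
#' @param seed RNG seed.
#' @param level Peak amplitude scale.
#' @return A numeric waveform.
#' @export
snap_train <- function(rate_hz, duration_s, sample_rate = 44100, seed = 1,
                       level = 0.6) {
  stopifnot(rate_hz >= 0)
  n <- as.integer(round(duration_s * sample_rate))
  x <- numeric(n)
  if (rate_hz == 0 || level == 0) return(x)
  with_preserved_rng(seed, {
    times <- poisson_times(rate_hz, duration_s)
    len <- as.integer(round(0.0015 * sample_rate))      # 1.5 ms
    env <- exp(-(seq_len(len) - 1) / (0.0003 * sample_rate))
    for (t0 in times) {
      i0 <- as.integer(floor(t0 * sample_rate)) + 1L
      i1 <- min(i0 + len - 1L, n)
      m <- i1 - i0 + 1L
      amp <- level * stats::runif(1, 0.3, 1)
      x[i0:i1] <- x[i0:i1] + amp * stats::rnorm(m) * env[seq_len(m)]
    }
    attr(x, "n_snaps") <- length(times)
    x
  })
}

# Fish calls: pulse trains of 3-8 short tone bursts at a base frequency
# drawn inside fish_band.
fish_calls <- function(rate_hz, band, duration_s, sample_rate, level) {
  n <- as.integer(round(duration_s * sample_rate))
  x <- numeric(n)
  if (rate_hz == 0 || level == 0) return(x)
  times <- poisson_times(rate_hz, duration_s)
  pulse_len <- as.integer(round(0.03 * sample_rate))    # 30 ms pulse
  tt <- (seq_len(pulse_len) - 1) / sample_rate
  env <- hann_window(pulse_len)
  for (t0 in times) {
    f <- stats::runif(1, band[1], band[2])
    n_pulses <- sample(3:8, 1)
    gap <- stats::runif(1, 0.04, 0.08)
    pulse <- sin(2 * pi * f * tt) * env
    for (p in seq_len(n_pulses) - 1) {
      i0 <- as.integer(floor((t0 + p * gap) * sample_rate)) + 1L
      if (i0 > n) break
      i1 <- min(i0 + pulse_len - 1L, n)
      m <- i1 - i0 + 1L
      x[i0:i1] <- x[i0:i1] + level * pulse[seq_len(m)]
    }
  }
  x
}

# Interval mask with 0.5-s linear ramps, evaluated per sample.
interval_envelope <- function(ivs, n, sample_rate) {
  env <- numeric(n)
  t <- (seq_len(n) - 1) / sample_rate
  for (iv in ivs) {
    ramp <- 0.5
    up <- pmin(1, pmax(0, (t - iv[1]) / ramp))
    down <- pmin(1, pmax(0, (iv[2] - t) / ramp))
    env <- pmax(env, iv[3] * pmin(up, down))
  }
  env
}

# Boat: broadband noise plus engine harmonics (fundamental ~120 Hz).
boat_component <- function(ivs, duration_s, sample_rate) {
  n <- as.integer(round(duration_s * sample_rate))
  if (length(ivs) == 0) return(numeric(n))
  env <- interval_envelope(ivs, n, sample_rate)
  if (all(env == 0)) return(numeric(n))
  t <- (seq_len(n) - 1) / sample_rate
  f0 <- 120
  harm <- rowSums(vapply(1:6, function(h) sin(2 * pi * h * f0 * t) / h,
                         numeric(n)))
  (0.5 * stats::rnorm(n) + 0.5 * harm) * env
}

# Rain: broadband masking noise.
rain_component <- function(ivs, duration_s, sample_rate) {
  n <- as.integer(round(duration_s * sample_rate))
  if (length(ivs) == 0) return(numeric(n))
  env <- interval_envelope(ivs, n, sample_rate)
  if (all(env == 0)) return(numeric(n))
  stats::rnorm(n) * env
}

#' Synthesise one scene
#'
#' Additive mixture of the configured components; the night flag
#' multiplies the snap rate by `diel_night_gain`.  The result is peak
#' normalised to at most 0.99.  Deterministic for a given
#' `config$seed`.
#'
#' @param config A [scene_config()].
#' @param night Apply the nocturnal snap-rate gain?
#' @return A numeric waveform of `duration_s * sample_rate` samples.
#' @export
scene <- function(config, night = FALSE) {
  stopifnot(inherits(config, "scene_config"))
  sr <- config$sample_rate
  n <- as.integer(round(config$duration_s * sr))
  rate <- config$snap_rate_hz * if (night) config$diel_night_gain else 1
  x <- snap_train(rate, config$duration_s, sr, seed = config$seed,
                  level = config$snap_level)
  x <- x + with_preserved_rng(config$seed + 1L, {
    fish_calls(config$fish_call_rate_hz, config$fish_band,
               config$duration_s, sr, config$fish_level)
  })
  x <- x + with_preserved_rng(config$seed + 2L, {
    boat_component(config$boat_intervals, config$duration_s, sr)
  })
  x <- x + with_preserved_rng(config$seed + 3L, {
    rain_component(config$rain_intervals, config$duration_s, sr)
  })
  x <- x + with_preserved_rng(config$seed + 4L, {
    if (config$background_level > 0) {
      config$background_level * stats::rnorm(n)
    } else numeric(n)
  })
  peak <- max(abs(x))
  if (peak > 0.99) x <- x * (0.99 / peak)
  x
}

#' Duty-cycle schedule of one recording day
#'
#' Start offsets (seconds) of the files recorded over 24 hours at one
#' file every `cycle_period_s`, from the first start to the same time
#' the next day, inclusive.  The canonical reef schedule (one 1-minute
#' file every 10 minutes) yields 145 files per day.
#'
#' @param cycle_period_s Seconds between file starts (default 600).
#' @param day_s Length of the recording day (default 86400).
#' @return Integer vector of start offsets, `0, cycle, ..., day_s`.
#' @export
campaign_schedule <- function(cycle_period_s = 600, day_s = 86400) {
  stopifnot(cycle_period_s > 0)
  seq(0L, as.integer(day_s), by = as.integer(cycle_period_s))
}

#' Synthetic campaign configuration
#'
#' @param sites Named list of [scene_config()]s, one per site.
#' @param n_days Number of recording days (replicates) per site.
#' @param start_date First recording date (ISO, local).
#' @param first_start Time of day the daily schedule starts
#'   (default `"12:05:00"`).
#' @param cycle_period_s Recording cycle (default 600 s: 1 file every
#'   10 min).
#' @param file_length_s File length (default 60 s).
#' @param day_s Length of each simulated recording day in seconds
#'   (default 86400; shorter values give reduced campaigns for quick
#'   runs while keeping the duty-cycle structure).
#' @param sunrise,sunset Times bounding the `"day"` period label
#'   (fixed 06:00/18:00).
#' @param events Optional data frame of campaign-level planted events
#'   with columns `site`, `day` (1-based), `start_s`, `end_s` (offsets
#'   in seconds from that day's first file start), `type` (`"rain"` or
#'   `"boat"`), `level`.
#' @param seed Campaign base seed; per-file seeds derive from it.
#' @return An object of class `campaign_config`.
#' @export
campaign_config <- function(sites, n_days = 3,
                            start_date = "2023-11-16",
                            first_start = "12:05:00",
                            cycle_period_s = 600, file_length_s = 60,
                            day_s = 86400,
                            sunrise = "06:00:00", sunset = "18:00:00",
                            events = NULL, seed = 1) {
  stopifnot(length(sites) >= 1, !is.null(names(sites)),
            cycle_period_s >= file_length_s, n_days >= 1, day_s > 0)
  for (s in sites) stopifnot(inherits(s, "scene_config"))
  structure(as.list(environment())[c(
    "sites", "n_days", "start_date", "first_start", "cycle_period_s",
    "file_length_s", "day_s", "sunrise", "sunset", "events", "seed")],
    class = "campaign_config")
}

seconds_of_day <- function(hms) {
  p <- as.integer(strsplit(hms, ":")[[1]])
  p <- c(p, 0L, 0L)[1:3]
  p[1] * 3600L + p[2] * 60L + p[3]
}

#' Generate a synthetic WAV campaign on disk
#'
#' Writes one `file_length_s` WAV per schedule slot per site per day,
#' plus a `metadata.csv` (columns `file`, `start`, `site`, `replicate`,
#' `period`) that [read_campaign()] consumes verbatim.  Fully
#' deterministic for a given configuration: re-running reproduces
#' byte-identical files.
#'
#' @param config A [campaign_config()].
#' @param out_dir Output directory (created if needed).
#' @return The metadata tibble, invisibly, with the CSV path in the
#'   `metadata_csv` attribute.
#' @export
generate_campaign <- function(config, out_dir) {
  stopifnot(inherits(config, "campaign_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  offsets <- campaign_schedule(config$cycle_period_s, config$day_s)
  day0 <- as.POSIXct(paste(config$start_date, config$first_start),
                     tz = "UTC")
  rise <- seconds_of_day(config$sunrise)
  set_ <- seconds_of_day(config$sunset)
  rows <- list()
  file_idx <- 0L
  for (si in seq_along(config$sites)) {
    site_name <- names(config$sites)[si]
    site_cfg <- config$sites[[si]]
    for (day in seq_len(config$n_days)) {
      day_start <- day0 + (day - 1) * 86400
      for (oi in seq_along(offsets)) {
        file_idx <- file_idx + 1L
        off <- offsets[oi]
        start <- day_start + off
        tod <- seconds_of_day(format(start, "%H:%M:%S"))
        night <- tod < rise || tod >= set_
        cfg <- site_cfg
        cfg$duration_s <- config$file_length_s
        cfg$seed <- (config$seed * 1009L + si * 101L * 10000L +
                       day * 100000L + oi * 7L) %% 2000000011L
        # overlay campaign-level events intersecting this file
        if (!is.null(config$events)) {
          ev <- config$events[config$events$site == site_name &
                                config$events$day == day, , drop = FALSE]
          for (e in seq_len(nrow(ev))) {
            a <- max(ev$start_s[e] - off, 0)
            b <- min(ev$end_s[e] - off, config$file_length_s)
            if (a < b) {
              iv <- list(c(a, b, ev$level[e]))
              if (ev$type[e] == "rain") {
                cfg$rain_intervals <- c(cfg$rain_intervals, iv)
              } else {
                cfg$boat_intervals <- c(cfg$boat_intervals, iv)
              }
            }
          }
        }
        x <- scene(cfg, night = night)
        fn <- sprintf("%s_rep%d_%04d.wav", site_name, day, oi)
        write_wav(x, site_cfg$sample_rate, file.path(out_dir, fn))
        rows[[file_idx]] <- tibble::tibble(
          file = fn,
          start = format(start, "%Y-%m-%dT%H:%M:%S"),
          site = site_name,
          replicate = paste0("rep", day),
          period = if (night) "night" else "day"
        )
      }
    }
  }
  meta <- dplyr::bind_rows(rows)
  csv <- file.path(out_dir, "metadata.csv")
  utils::write.csv(meta, csv, row.names = FALSE, quote = FALSE)
  attr(meta, "metadata_csv") <- csv
  invisible(meta)
}

#' Canonical three-site example campaign
#'
#' A reduced reef campaign with planted ground truth, used throughout
#' the documentation and tests: a `quiet` reference site, a
#' `quiet_variant` site with mildly elevated biological activity (a
#' nearby reef in a similar state), and a `boat` site identical to
#' `quiet` but exposed to continuous motor noise.  A rain shower is
#' planted in the middle third of the last day at the quiet site.
#'
#' @param n_days Recording days per site (default 3).
#' @param day_s Simulated day length in seconds (default 3600: one
#'   hour per site-day on the standard duty cycle, i.e. 7 files).
#' @param seed Campaign seed.
#' @return A [campaign_config()].
#' @export
example_reef_campaign <- function(n_days = 3, day_s = 3600, seed = 1) {
  sites <- list(
    quiet = scene_config(snap_rate_hz = 40, fish_call_rate_hz = 0.3,
                         fish_band = c(250, 600)),
    quiet_variant = scene_config(snap_rate_hz = 90, fish_call_rate_hz = 0.6,
                                 fish_band = c(350, 800)),
    boat = scene_config(snap_rate_hz = 40, fish_call_rate_hz = 0.3,
                        fish_band = c(250, 600))
  )
  events <- data.frame(site = "boat", day = seq_len(n_days), start_s = 0,
                       end_s = day_s + 60, type = "boat", level = 0.5)
  if (n_days >= 3) {
    events <- rbind(events, data.frame(
      site = "quiet", day = n_days, start_s = day_s / 3,
      end_s = 2 * day_s / 3, type = "rain", level = 0.35))
  }
  campaign_config(sites, n_days = n_days, day_s = day_s, events = events,
                  seed = seed)
}
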