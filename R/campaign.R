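# Campaign input: per-file metadata table, preprocessing, segmentation.

#' Read a recording-campaign metadata table
#'
#' A campaign is described by a CSV with a header row and columns `file`
#' (WAV path, absolute or relative to `audio_root`), `start` (ISO-8601
#' local datetime, no timezone) and one column per categorical label
#' (e.g. `site`, `replicate`, `period`).  Duration and sample rate are
#' read back from each WAV header.
#'
#' @param metadata Path to the CSV file, or a data frame with the same
#'   columns.
#' @param audio_root Directory that relative `file` paths are resolved
#'   against.  Defaults to the directory of the CSV (or `"."` for a data
#'   frame).
#' @return A tibble with one row per recording: `file` (resolved path),
#'   `start` (POSIXct), the label columns, `sample_rate`, `duration_s`,
#'   `n_samples`.  Row order follows the table.  The label column names
#'   are recorded in the `label_names` attribute.
#' @export
read_campaign <- function(metadata, audio_root = NULL) {
  if (is.character(metadata)) {
    if (!file.exists(metadata)) stop("metadata file not found: ", metadata, call. = FALSE)
    if (is.null(audio_root)) audio_root <- dirname(metadata)
    tab <- utils::read.csv(metadata, stringsAsFactors = FALSE, check.names = FALSE)
  } else {
    tab <- as.data.frame(metadata, stringsAsFactors = FALSE)
    if (is.null(audio_root)) audio_root <- "."
  }
  required <- c("file", "start")
  if (!all(required %in% names(tab))) {
    stop("metadata must have columns 'file' and 'start'", call. = FALSE)
  }
  label_names <- setdiff(names(tab), required)
  if (length(label_names) < 1) {
    stop("metadata must have at least one label column besides 'file' and 'start'",
         call. = FALSE)
  }
  if (nrow(tab) == 0) stop("metadata table is empty", call. = FALSE)

  paths <- ifelse(grepl("^(/|[A-Za-z]:)", tab$file), tab$file,
                  file.path(audio_root, tab$file))
  sample_rate <- integer(nrow(tab))
  duration_s <- numeric(nrow(tab))
  n_samples <- integer(nrow(tab))
  for (i in seq_len(nrow(tab))) {
    if (!file.exists(paths[i])) {
      stop("row ", i, ": audio file not found: ", paths[i], call. = FALSE)
    }
    info <- wav_info(paths[i])
    if (info$n_channels != 1L) {
      stop("row ", i, ": non-mono WAV rejected: ", paths[i], call. = FALSE)
    }
    sample_rate[i] <- info$sample_rate
    duration_s[i] <- info$duration_s
    n_samples[i] <- info$n_samples
  }
  if (length(unique(sample_rate)) > 1) {
    stop("recordings have mixed sample rates (",
         paste(unique(sample_rate), collapse = ", "),
         "); resampling is not performed", call. = FALSE)
  }
  start <- as.POSIXct(tab$start, tz = "UTC",
                      tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
                                     "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M"))
  if (anyNA(start)) {
    stop("unparseable 'start' datetime in rows: ",
         paste(which(is.na(start)), collapse = ", "), call. = FALSE)
  }
  out <- tibble::tibble(file = paths, start = start)
  for (lab in label_names) out[[lab]] <- as.character(tab[[lab]])
  out$sample_rate <- sample_rate
  out$duration_s <- duration_s
  out$n_samples <- n_samples
  attr(out, "label_names") <- label_names
  out
}

#' High-pass filter specification
#'
#' Zero-phase Butterworth high-pass used to remove low-frequency flow and
#' handling noise below the band of interest.
#'
#' @param cutoff_hz Cut-off frequency in Hz (default 70).
#' @param order Filter order (default 8).
#' @param zero_phase Apply forward-backward for zero group delay
#'   (default `TRUE`); the effective magnitude response is then squared.
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(cutoff_hz = 70, order = 8, zero_phase = TRUE) {
  stopifnot(cutoff_hz > 0, order >= 1)
  structure(list(cutoff_hz = cutoff_hz, order = order, zero_phase = zero_phase),
            class = "filter_spec")
}

# Butterworth high-pass as cascaded second-order sections.  A direct-form
# (b, a) realisation of order 8 at 70 Hz / 44.1 kHz is numerically
# ill-conditioned; biquads are not.  Analog prototype poles, low-pass ->
# high-pass transform, bilinear mapping, unity gain pinned at Nyquist.
butter_highpass_sos <- function(cutoff_hz, order, sample_rate) {
  if (cutoff_hz >= sample_rate / 2) {
    stop("cutoff (", cutoff_hz, " Hz) must be below Nyquist (",
         sample_rate / 2, " Hz)", call. = FALSE)
  }
  stopifnot(order %% 2 == 0)  # conjugate pairs only
  fs2 <- 2 * sample_rate
  wc <- fs2 * tan(pi * cutoff_hz / sample_rate)
  k <- seq_len(order %/% 2)
  # left-half-plane prototype poles, upper half only
  p_lp <- exp(1i * pi * (2 * k + order - 1) / (2 * order))
  p_hp <- wc / p_lp
  z <- (fs2 + p_hp) / (fs2 - p_hp)
  lapply(z, function(p) {
    a <- c(1, -2 * Re(p), Mod(p)^2)
    b <- c(1, -2, 1)
    g <- sum(a * c(1, -1, 1)) / 4  # |H| = 1 at z = -1
    list(b = g * b, a = a)
  })
}

# One biquad pass with steady-state initial conditions: the filter state is
# initialised as if the input had been constant at x[1] forever, which
# removes the step transient exactly (cf. scipy.signal.lfilter_zi).
filter_biquad <- function(b, a, x) {
  .biquad_filter(b, a, x, x[1])
}

# Zero-phase biquad: odd-reflection padding at both ends, then forward and
# backward passes with matched initial conditions (scipy-style filtfilt).
filtfilt_biquad <- function(b, a, x, padlen) {
  n <- length(x)
  p <- min(n - 1L, padlen)
  ext <- if (p > 0) {
    c(2 * x[1] - x[(p + 1):2], x, 2 * x[n] - x[(n - 1):(n - p)])
  } else {
    x
  }
  y <- filter_biquad(b, a, ext)
  y <- rev(filter_biquad(b, a, rev(y)))
  y[(p + 1):(p + n)]
}

#' Apply the campaign high-pass filter to a waveform
#'
#' Forward-backward application (when `zero_phase`) doubles the effective
#' order of the magnitude response and cancels the group delay.
#'
#' @param samples Numeric waveform.
#' @param sample_rate Sampling rate in Hz.
#' @param spec A [filter_spec()].
#' @return Filtered waveform of identical length.
#' @export
highpass <- function(samples, sample_rate, spec = filter_spec()) {
  stopifnot(inherits(spec, "filter_spec"), length(samples) > 0)
  sos <- butter_highpass_sos(spec$cutoff_hz, spec$order, sample_rate)
  # transients at the cutoff decay on a ~sample_rate/cutoff scale
  padlen <- as.integer(3 * ceiling(sample_rate / spec$cutoff_hz))
  y <- samples
  for (sec in sos) {
    y <- if (spec$zero_phase) {
      filtfilt_biquad(sec$b, sec$a, y, padlen)
    } else {
      filter_biquad(sec$b, sec$a, y)
    }
  }
  y
}

#' Cut a waveform into fixed-length contiguous segments
#'
#' The recording is divided into consecutive non-overlapping segments of
#' `segment_length_s`; a trailing remainder shorter than one segment is
#' discarded.
#'
#' @param samples Numeric waveform.
#' @param sample_rate Sampling rate in Hz.
#' @param segment_length_s Segment length in seconds (default 1).
#' @return A matrix with one row per segment
#'   (`segment_length_s * sample_rate` columns).  Zero rows if the
#'   recording is shorter than one segment.  Row names give the offset in
#'   seconds from the recording start.
#' @export
segment_waveform <- function(samples, sample_rate, segment_length_s = 1) {
  stopifnot(segment_length_s > 0, sample_rate > 0)
  len <- as.integer(round(segment_length_s * sample_rate))
  n_seg <- length(samples) %/% len
  if (n_seg == 0) {
    m <- matrix(numeric(0), nrow = 0, ncol = len)
    return(m)
  }
  m <- matrix(samples[seq_len(n_seg * len)], nrow = n_seg, ncol = len,
              byrow = TRUE)
  rownames(m) <- format((seq_len(n_seg) - 1) * segment_length_s)
  m
}
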