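# Mel-frequency acoustic embeddings of one-second segments.
#
# Conventions (declared, since several dialects exist): HTK mel scale
# m = 2595 log10(1 + f/700); triangular filters with unit peak spanning
# [fmin, fmax]; Hann window; frames left-aligned at multiples of the hop
# with the last window zero-padded; power spectra |FFT|^2 / N^2; band
# energies floored at `mel_floor` before taking natural logs.

mel_floor <- 1e-12

hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

#' Mel embedding specification
#'
#' @param n_mels Number of mel bands (default 64).
#' @param fmin,fmax Band-edge frequencies in Hz (defaults 70 and 2000,
#'   the low-frequency band where most fish sounds and boat noise sit).
#' @param n_fft STFT window length in samples (default 2048).
#' @param hop_s STFT hop in seconds (default 0.01; 441 samples at
#'   44.1 kHz).
#' @return An object of class `mel_spec`.
#' @export
mel_spec <- function(n_mels = 64, fmin = 70, fmax = 2000,
                     n_fft = 2048, hop_s = 0.01) {
  stopifnot(n_mels >= 1, fmin >= 0, fmin < fmax, n_fft >= 2, hop_s > 0)
  structure(list(n_mels = n_mels, fmin = fmin, fmax = fmax,
                 n_fft = n_fft, hop_s = hop_s),
            class = "mel_spec")
}

#' Triangular mel filterbank matrix
#'
#' @param spec A [mel_spec()].
#' @param sample_rate Sampling rate in Hz.
#' @param n_fft FFT length the filterbank applies to (defaults to
#'   `spec$n_fft`; pass the segment length for whole-segment spectra).
#' @return An `n_mels x (n_fft %/% 2 + 1)` matrix of filter weights over
#'   the non-negative FFT bins.
#' @export
mel_filterbank <- function(spec, sample_rate, n_fft = spec$n_fft) {
  if (spec$fmax > sample_rate / 2) {
    stop("fmax (", spec$fmax, " Hz) above Nyquist", call. = FALSE)
  }
  n_bins <- n_fft %/% 2 + 1
  freqs <- (seq_len(n_bins) - 1) * sample_rate / n_fft
  edges <- mel_to_hz(seq(hz_to_mel(spec$fmin), hz_to_mel(spec$fmax),
                         length.out = spec$n_mels + 2))
  fb <- matrix(0, spec$n_mels, n_bins)
  for (k in seq_len(spec$n_mels)) {
    lo <- edges[k]; mid <- edges[k + 1]; hi <- edges[k + 2]
    up <- (freqs - lo) / (mid - lo)
    down <- (hi - freqs) / (hi - mid)
    fb[k, ] <- pmax(0, pmin(up, down))
  }
  rownames(fb) <- sprintf("mel_b%02d", seq_len(spec$n_mels))
  fb
}

# Power spectrum of each row of a segment matrix (non-negative bins).
# Returns (n_fft %/% 2 + 1) x n_seg.
power_spectrum_rows <- function(segmat, n_fft = ncol(segmat)) {
  n_bins <- n_fft %/% 2 + 1
  x <- t(segmat)
  if (nrow(x) < n_fft) {
    x <- rbind(x, matrix(0, n_fft - nrow(x), ncol(x)))
  }
  sp <- stats::mvfft(x)
  (Mod(sp[seq_len(n_bins), , drop = FALSE])^2) / n_fft^2
}

#' Mel-spectrum embedding of one-second segments
#'
#' One natural-log energy per mel band, computed from the power spectrum
#' of the whole segment.
#'
#' @param segments A waveform vector (one segment) or a matrix with one
#'   segment per row, as returned by [segment_waveform()].
#' @param sample_rate Sampling rate in Hz.
#' @param spec A [mel_spec()].
#' @return A matrix `n_segments x n_mels` of log band energies (a single
#'   vector input returns a 1-row matrix).  Columns are named
#'   `mel_b01 ...`.
#' @export
mel_spectrum <- function(segments, sample_rate, spec = mel_spec()) {
  if (is.vector(segments)) segments <- matrix(segments, nrow = 1)
  fb <- mel_filterbank(spec, sample_rate, n_fft = ncol(segments))
  # restrict to the bins the filterbank touches
  keep <- which(colSums(fb) > 0)
  out <- matrix(NA_real_, nrow(segments), spec$n_mels,
                dimnames = list(NULL, rownames(fb)))
  chunk <- max(1L, as.integer(2^24 / ncol(segments)))
  for (i0 in seq(1, nrow(segments), by = chunk)) {
    idx <- i0:min(i0 + chunk - 1, nrow(segments))
    ps <- power_spectrum_rows(segments[idx, , drop = FALSE])
    e <- fb[, keep, drop = FALSE] %*% ps[keep, , drop = FALSE]
    out[idx, ] <- t(log(pmax(e, mel_floor)))
  }
  out
}

# Hann window (periodic), the common STFT choice.
hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / n)

# STFT frame start indices for a segment of n samples: left-aligned,
# one frame per hop, last window zero-padded past the end.  A one-second
# segment at 44.1 kHz with a 441-sample hop yields exactly 100 frames.
stft_frame_starts <- function(n_samples, hop) {
  seq(1L, n_samples, by = hop)
}

#' Mel-spectrogram embedding of one-second segments
#'
#' Short-time power spectra over `n_fft`-sample Hann windows at hop
#' `hop_s`, pooled into mel bands and natural-log transformed.  With the
#' defaults at 44.1 kHz each one-second segment yields 64 bands x 100
#' frames = 6400 values.
#'
#' @inheritParams mel_spectrum
#' @param flatten Return one row of `n_mels * n_frames` values per
#'   segment (default) instead of a list of band-by-frame matrices.
#' @return If `flatten`, a matrix `n_segments x (n_mels * n_frames)`
#'   with band-major column order and names `mel_b<band>_f<frame>`;
#'   otherwise a list of `n_mels x n_frames` matrices.
#' @export
mel_spectrogram <- function(segments, sample_rate, spec = mel_spec(),
                            flatten = TRUE) {
  if (is.vector(segments)) segments <- matrix(segments, nrow = 1)
  hop <- spec$hop_s * sample_rate
  if (abs(hop - round(hop)) > 1e-9) {
    stop("hop_s * sample_rate must be an integer number of samples",
         call. = FALSE)
  }
  hop <- as.integer(round(hop))
  starts <- stft_frame_starts(ncol(segments), hop)
  n_frames <- length(starts)
  fb <- mel_filterbank(spec, sample_rate)
  keep <- which(colSums(fb) > 0)
  fbk <- fb[, keep, drop = FALSE]
  win <- hann_window(spec$n_fft)
  n_seg <- nrow(segments)
  dims <- as.vector(t(outer(seq_len(spec$n_mels), seq_len(n_frames),
                            function(b, f) sprintf("mel_b%02d_f%03d", b, f))))
  res <- matrix(NA_real_, n_seg,
                if (flatten) spec$n_mels * n_frames else 0)
  if (flatten) colnames(res) <- dims
  mats <- if (!flatten) vector("list", n_seg)
  for (s in seq_len(n_seg)) {
    x <- segments[s, ]
    frames <- matrix(0, spec$n_fft, n_frames)
    for (j in seq_len(n_frames)) {
      i1 <- starts[j]
      i2 <- min(i1 + spec$n_fft - 1L, length(x))
      frames[seq_len(i2 - i1 + 1L), j] <- x[i1:i2]
    }
    frames <- frames * win
    sp <- stats::mvfft(frames)
    ps <- (Mod(sp[seq_len(spec$n_fft %/% 2 + 1), , drop = FALSE])^2) /
      spec$n_fft^2
    e <- fbk %*% ps[keep, , drop = FALSE]        # n_mels x n_frames
    lg <- log(pmax(e, mel_floor))
    if (flatten) res[s, ] <- as.vector(t(lg)) else mats[[s]] <- lg
  }
  if (flatten) res else mats
}

# --- external embedding adapter ---------------------------------------

the_adapters <- new.env(parent = emptyenv())

#' Register an external embedding adapter
#'
#' An adapter maps the first 0.96 s of a segment's mel-spectrogram (a
#' `n_mels x 96` matrix at default hop) to a fixed-length numeric vector,
#' e.g. a pretrained CNN embedding.  No network weights ship with this
#' package; without an adapter the mel embeddings are the supported
#' acoustic spaces.
#'
#' @param name Adapter name.
#' @param fn Function taking the truncated mel-spectrogram matrix and
#'   returning a numeric vector of length `n_dims`.
#' @param n_dims Declared output dimensionality.
#' @return `name`, invisibly.
#' @export
register_embedding_adapter <- function(name, fn, n_dims) {
  stopifnot(is.function(fn), n_dims >= 1)
  assign(name, list(fn = fn, n_dims = as.integer(n_dims)), envir = the_adapters)
  invisible(name)
}

#' Embed segments through a registered adapter
#'
#' The segment's mel-spectrogram is truncated to its first 0.96 s of
#' frames before the adapter is applied (the trailing 0.04 s is unused).
#'
#' @inheritParams mel_spectrum
#' @param adapter Name of a registered adapter.
#' @return A matrix `n_segments x n_dims`.
#' @export
cnn_embed <- function(segments, sample_rate, adapter, spec = mel_spec()) {
  if (!exists(adapter, envir = the_adapters)) {
    stop("no embedding adapter registered as '", adapter,
         "'; register one with register_embedding_adapter() or use the ",
         "mel_spectrum / mel_spectrogram embeddings", call. = FALSE)
  }
  ad <- get(adapter, envir = the_adapters)
  mats <- mel_spectrogram(segments, sample_rate, spec, flatten = FALSE)
  n_keep <- as.integer(floor(0.96 / spec$hop_s))
  out <- matrix(NA_real_, length(mats), ad$n_dims,
                dimnames = list(NULL, sprintf("%s_%03d", adapter,
                                              seq_len(ad$n_dims))))
  for (s in seq_along(mats)) {
    m <- mats[[s]]
    v <- ad$fn(m[, seq_len(min(n_keep, ncol(m))), drop = FALSE])
    if (length(v) != ad$n_dims || anyNA(v)) {
      stop("adapter '", adapter, "' declared ", ad$n_dims,
           " dimensions but returned ", length(v), call. = FALSE)
    }
    out[s, ] <- v
  }
  out
}
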