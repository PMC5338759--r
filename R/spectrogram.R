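# Peripheral auditory model: cochlear filterbank -> hair-cell transduction
# (compression + low-pass) -> lateral inhibition (spectral derivative,
# half-wave rectified) -> per-band envelope at the output frame rate.

#' Filterbank parameters
#'
#' 128 gammatone-like filters equally spaced on a log-frequency axis between
#' `f_min` and `f_max`. The hair-cell stage applies sign-preserving
#' power-law compression (default cube root) followed by a second-order
#' low-pass; the output envelope is sampled at `frame_rate`.
#'
#' @param n_channels number of filters (>= 2).
#' @param f_min,f_max passband limits in Hz, `f_min < f_max`.
#' @param frame_rate output envelope rate in Hz (1 kHz gives 1-ms frames,
#'   matching the EEG analysis grid).
#' @param hc_cutoff hair-cell low-pass cutoff in Hz.
#' @param compression_exponent power-law exponent in (0, 1].
#' @return object of class `filterbank_params`.
#' @export
filterbank_params <- function(n_channels = 128, f_min = 80, f_max = 8000,
                              frame_rate = 1000, hc_cutoff = 2000,
                              compression_exponent = 1 / 3) {
  if (n_channels < 2L) stop_invalid("`n_channels` must be >= 2")
  if (!(f_min > 0 && f_min < f_max)) stop_invalid("need 0 < f_min < f_max")
  if (compression_exponent <= 0 || compression_exponent > 1)
    stop_invalid("`compression_exponent` must be in (0, 1]")
  cf <- exp(seq(log(f_min), log(f_max), length.out = n_channels))
  stopifnot(all(diff(cf) > 0))
  structure(list(n_channels = as.integer(n_channels), f_min = f_min,
                 f_max = f_max, center_frequencies = cf,
                 frame_rate = frame_rate, hc_cutoff = hc_cutoff,
                 compression_exponent = compression_exponent),
            class = "filterbank_params")
}

# Equivalent rectangular bandwidth (Glasberg & Moore).
erb_bandwidth <- function(cf) 24.7 * (4.37 * cf / 1000 + 1)

# Slaney-style 4th-order gammatone as four second-order sections
# (rows: b0 b1 b2 a1 a2), peak gain normalized to 1 at cf.
gammatone_sos <- function(cf, fs) {
  T <- 1 / fs
  b <- 1.019 * 2 * pi * erb_bandwidth(cf)
  arg <- 2 * pi * cf * T
  ebt <- exp(b * T)
  a1 <- -2 * cos(arg) / ebt
  a2 <- exp(-2 * b * T)
  s1 <- sqrt(3 + 2^1.5); s2 <- sqrt(3 - 2^1.5)
  b1s <- c(-(2 * T * cos(arg) / ebt + 2 * s1 * T * sin(arg) / ebt) / 2,
           -(2 * T * cos(arg) / ebt - 2 * s1 * T * sin(arg) / ebt) / 2,
           -(2 * T * cos(arg) / ebt + 2 * s2 * T * sin(arg) / ebt) / 2,
           -(2 * T * cos(arg) / ebt - 2 * s2 * T * sin(arg) / ebt) / 2)
  sos <- cbind(b0 = rep(T, 4), b1 = b1s, b2 = 0, a1 = a1, a2 = a2)
  # normalize the cascade's magnitude at cf numerically
  z <- exp(-1i * arg)
  h <- prod((sos[, 1] + sos[, 2] * z + sos[, 3] * z^2) /
              (1 + sos[, 4] * z + sos[, 5] * z^2))
  sos[1, 1:3] <- sos[1, 1:3] / abs(h)
  sos
}

hair_cell_lpf_sos <- function(fs, cutoff) {
  if (cutoff >= fs / 2) return(NULL)
  bf <- signal::butter(2, 2 * cutoff / fs, type = "low")
  matrix(c(bf$b, bf$a[2], bf$a[3]), 1, 5)
}

as_waveform <- function(wave, fs = NULL) {
  if (inherits(wave, "waveform")) return(wave)
  if (is.null(fs)) stop_invalid("`fs` required for a bare numeric waveform")
  structure(list(samples = as.numeric(wave), fs = fs), class = "waveform")
}

#' Cochlear filterbank decomposition
#'
#' One band-limited signal per channel at the audio rate. Intended for
#' signals of moderate length; [compute_auditory_spectrogram()] streams the
#' same per-channel chain without materializing this matrix.
#'
#' @param wave a `waveform` (or numeric vector with `fs`).
#' @param params a [filterbank_params()].
#' @param fs sampling rate when `wave` is a bare vector.
#' @return channels x samples matrix.
#' @export
cochlear_filterbank <- function(wave, params = filterbank_params(),
                                fs = NULL) {
  wave <- as_waveform(wave, fs)
  if (wave$fs < 2 * params$f_max)
    stop_invalid("sampling rate below 2 * f_max")
  out <- matrix(0, params$n_channels, length(wave$samples))
  for (ch in seq_len(params$n_channels))
    out[ch, ] <- .sos_filter(wave$samples,
                             gammatone_sos(params$center_frequencies[ch],
                                           wave$fs))
  rownames(out) <- sprintf("ch%03d", seq_len(params$n_channels))
  out
}

#' Hair-cell stage
#'
#' Sign-preserving power-law compression followed by a low-pass filter,
#' applied to each band. Monotone: pointwise larger inputs give pointwise
#' larger-or-equal outputs.
#'
#' @param bands channels x samples matrix from [cochlear_filterbank()].
#' @param fs audio sampling rate in Hz.
#' @param params a [filterbank_params()].
#' @return matrix of the same shape.
#' @export
hair_cell_stage <- function(bands, fs, params = filterbank_params()) {
  lpf <- hair_cell_lpf_sos(fs, params$hc_cutoff)
  out <- bands
  for (ch in seq_len(nrow(bands))) {
    y <- .pow_compress(bands[ch, ], params$compression_exponent)
    if (!is.null(lpf)) y <- .sos_filter(y, lpf)
    out[ch, ] <- y
  }
  out
}

#' Lateral inhibition
#'
#' First-order derivative along the spectral (channel) axis followed by
#' half-wave rectification. The first channel is differenced against itself
#' (replicate padding), so a spectrally flat input maps to zero everywhere
#' while the channel count is preserved.
#'
#' @param bands channels x samples matrix.
#' @return matrix of the same shape, non-negative.
#' @export
lateral_inhibition <- function(bands) {
  if (nrow(bands) < 2L) stop_invalid("lateral inhibition needs >= 2 channels")
  out <- bands - bands[c(1L, seq_len(nrow(bands) - 1L)), , drop = FALSE]
  out[out < 0] <- 0
  out
}

#' Per-band envelope at the output frame rate
#'
#' Mean of each consecutive frame (rectified input assumed), i.e. boxcar
#' smoothing plus decimation.
#'
#' @param bands channels x samples matrix (non-negative).
#' @param fs input sampling rate.
#' @param frame_rate output frame rate; `fs / frame_rate` must be integer.
#' @return channels x frames matrix.
#' @export
envelope_frames <- function(bands, fs, frame_rate) {
  len <- fs / frame_rate
  if (abs(len - round(len)) > 1e-9)
    stop_invalid("fs must be an integer multiple of frame_rate")
  len <- as.integer(round(len))
  t(vapply(seq_len(nrow(bands)),
           function(ch) .frame_mean(bands[ch, ], len),
           numeric(ceiling(ncol(bands) / len))))
}

#' Compute the auditory spectrogram of a waveform
#'
#' Full peripheral chain (filterbank, hair cell, lateral inhibition,
#' envelope), streamed channel-by-channel so long recordings never require
#' the full band matrix in memory. Deterministic.
#'
#' @param wave a `waveform` or numeric vector.
#' @param params a [filterbank_params()].
#' @param fs sampling rate when `wave` is a bare vector.
#' @return an [auditory_spectrogram()].
#' @export
compute_auditory_spectrogram <- function(wave, params = filterbank_params(),
                                         fs = NULL) {
  wave <- as_waveform(wave, fs)
  if (wave$fs < 2 * params$f_max)
    stop_invalid("sampling rate below 2 * f_max")
  len <- wave$fs / params$frame_rate
  if (abs(len - round(len)) > 1e-9)
    stop_invalid("audio fs must be an integer multiple of frame_rate")
  len <- as.integer(round(len))
  lpf <- hair_cell_lpf_sos(wave$fs, params$hc_cutoff)
  gt <- do.call(rbind, lapply(params$center_frequencies, gammatone_sos,
                              fs = wave$fs))
  vals <- .auditory_chain(wave$samples, gt,
                          lpf %||% matrix(0, 0, 5),
                          params$compression_exponent, len)
  auditory_spectrogram(vals, params$center_frequencies, params$frame_rate)
}
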