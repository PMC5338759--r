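# EEG preprocessing: zero-phase band-pass filtering, per-channel
# normalization, artifact-epoch rejection, utterance-onset exclusion, and
# the PRP band-power diagnostic.

#' Zero-phase FIR band-pass filter
#'
#' Windowed-sinc (Hamming) band-pass applied by FFT convolution with the
#' symmetric kernel centered, so the group delay is exactly zero samples.
#' The default 2-15 Hz band brackets the syllabic-rate energy of the PRP.
#'
#' @param rec an [eeg_recording()].
#' @param low,high cutoff frequencies in Hz, `0 < low < high < fs/2`.
#' @param transition transition width of the high-pass edge in Hz; the
#'   low-pass edge uses a transition of `high / 2`, which keeps its impulse
#'   response compact (negligible time-domain ringing near evoked
#'   components) while still attenuating one octave above the passband by
#'   well over 40 dB.
#' @return filtered [eeg_recording()].
#' @export
bandpass_filter <- function(rec, low = 2, high = 15, transition = 1) {
  fs <- rec$fs
  if (!(low > 0 && low < high && high < fs / 2))
    stop_invalid("need 0 < low < high < fs/2")
  h <- fir_bandpass_kernel(fs, low, high, transition)
  out <- rec$values
  for (e in seq_len(nrow(out)))
    out[e, ] <- fft_conv_centered(rec$values[e, ], h)
  eeg_recording(out, fs, rec$electrode_labels, rec$reference)
}

# Symmetric FIR band-pass built as the cascade (convolution) of a sharp
# windowed-sinc high-pass at `low` and a gentle windowed-sinc low-pass at
# `high`. Both factors are zero-phase; so is the cascade.
fir_bandpass_kernel <- function(fs, low, high, transition = 1) {
  even <- function(n) if (n %% 2L == 1L) n + 1L else n
  n_hp <- even(ceiling(3.3 * fs / transition))
  n_lp <- even(ceiling(3.3 * fs / (high / 2)))
  h_hp <- signal::fir1(n_hp, 2 * low / fs, type = "high")
  h_lp <- signal::fir1(n_lp, 2 * high / fs, type = "low")
  convolve(h_hp, rev(h_lp), type = "open")
}

#' Normalize each channel to zero mean and unit variance
#'
#' Channels with (numerically) zero variance cannot be normalized; they are
#' dropped with a warning.
#'
#' @param rec an [eeg_recording()].
#' @return z-scored [eeg_recording()].
#' @export
zscore_channels <- function(rec) {
  mu <- rowMeans(rec$values)
  sdv <- apply(rec$values, 1L, sd)
  bad <- sdv < .Machine$double.eps^0.5
  if (any(bad)) {
    warning("excluding constant channel(s): ",
            paste(rec$electrode_labels[bad], collapse = ", "))
    if (all(bad)) stop_invalid("all channels constant")
  }
  vals <- (rec$values[!bad, , drop = FALSE] - mu[!bad]) / sdv[!bad]
  eeg_recording(vals, rec$fs, rec$electrode_labels[!bad], rec$reference)
}

#' Decimate a band-limited recording to the analysis rate
#'
#' Simple sample picking; apply after [bandpass_filter()], whose 15 Hz upper
#' edge makes the signal band-limited far below the new Nyquist rate.
#'
#' @param rec an [eeg_recording()].
#' @param to target rate in Hz; `fs / to` must be an integer.
#' @return resampled [eeg_recording()].
#' @export
resample_recording <- function(rec, to = 1000) {
  fac <- rec$fs / to
  if (abs(fac - round(fac)) > 1e-9)
    stop_invalid("fs must be an integer multiple of the target rate")
  fac <- as.integer(round(fac))
  if (fac == 1L) return(rec)
  idx <- seq(1L, ncol(rec$values), by = fac)
  eeg_recording(rec$values[, idx, drop = FALSE], to, rec$electrode_labels,
                rec$reference)
}

#' Reject artifact-contaminated epochs
#'
#' An epoch is dropped iff any sample of any electrode exceeds the magnitude
#' threshold (in z-units of the normalized recording).
#'
#' @param epochs an `epoch_set` extracted from z-scored data.
#' @param threshold magnitude threshold, default 10.
#' @return a `rejection_mask`: list with `keep` (logical per epoch) and
#'   `fraction` (dropped / total).
#' @export
reject_artifact_epochs <- function(epochs, threshold = 10) {
  n <- dim(epochs$epochs)[1]
  keep <- vapply(seq_len(n),
                 function(i) all(abs(epochs$epochs[i, , ]) <= threshold),
                 logical(1))
  structure(list(keep = keep, fraction = 1 - mean(keep),
                 threshold = threshold),
            class = "rejection_mask")
}

#' Exclude tokens near utterance onsets
#'
#' Removes every token whose onset falls within `window_ms` of its
#' utterance's first token onset, suppressing the dominant
#' acoustic-onset response.
#'
#' @param alignment a [phoneme_alignment()].
#' @param window_ms exclusion window in ms (default 500).
#' @return filtered [phoneme_alignment()].
#' @export
exclude_utterance_onset_tokens <- function(alignment, window_ms = 500) {
  if (nrow(alignment) == 0L || window_ms <= 0) return(alignment)
  first <- tapply(alignment$onset, alignment$utterance, min)
  keep <- alignment$onset >=
    first[as.character(alignment$utterance)] + window_ms / 1000 - 1e-9
  out <- alignment[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("phoneme_alignment", "data.frame")
  out
}

#' Spectral power of the average PRP
#'
#' Power of a PRP time course on a frequency grid (discrete-frequency
#' periodogram of the demeaned series), used to locate the spectral peak of
#' the evoked response (expected near the ~8 Hz syllabic rate for speech).
#'
#' @param prp_series numeric PRP time course (one electrode, or an average).
#' @param fs sampling rate of the series in Hz.
#' @param freq_grid frequencies to evaluate, Hz.
#' @return list with `freq`, `power` (raw periodogram), `smoothed`,
#'   `peak_freq` and `clear_peak` (FALSE when no smoothed bin exceeds 3x the
#'   median smoothed power; a raw short-series periodogram is too erratic
#'   for that rule, so a 9-bin running mean is applied first).
#' @export
prp_band_power <- function(prp_series, fs, freq_grid = seq(2, 30, by = 0.5)) {
  x <- as.numeric(prp_series)
  n <- length(x)
  if (n < fs / min(freq_grid))
    stop_invalid("series shorter than one cycle of the lowest frequency")
  if (all(x == 0))
    return(list(freq = freq_grid, power = numeric(length(freq_grid)),
                smoothed = numeric(length(freq_grid)),
                peak_freq = NA_real_, clear_peak = FALSE))
  x <- x - mean(x)
  t <- (seq_len(n) - 1L) / fs
  power <- vapply(freq_grid, function(f)
    Mod(sum(x * exp(-2i * pi * f * t)))^2 / n^2, numeric(1))
  half <- 4L
  smoothed <- vapply(seq_along(power), function(i) {
    mean(power[max(1L, i - half):min(length(power), i + half)])
  }, numeric(1))
  clear <- max(smoothed) > 3 * median(smoothed)
  list(freq = freq_grid, power = power, smoothed = smoothed,
       peak_freq = freq_grid[which.max(power)], clear_peak = clear)
}
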