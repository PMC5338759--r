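# Core data containers. Matrices are electrode x time (EEG) and
# frequency x time (spectrograms); times are seconds externally and sample
# indices internally; token intervals are half-open [onset, offset).

#' EEG recording container
#'
#' @param values electrode x time numeric matrix.
#' @param fs sampling rate in Hz.
#' @param electrode_labels character vector, one per row.
#' @param reference free-text reference description.
#' @return object of class `eeg_recording`.
#' @export
eeg_recording <- function(values, fs, electrode_labels = NULL,
                          reference = "linked earlobes") {
  values <- as.matrix(values)
  if (!is.numeric(fs) || fs <= 0) stop_invalid("`fs` must be > 0")
  if (is.null(electrode_labels))
    electrode_labels <- paste0("E", seq_len(nrow(values)))
  if (length(electrode_labels) != nrow(values))
    stop_invalid("label count must equal electrode (row) count")
  rownames(values) <- electrode_labels
  structure(list(values = values, fs = fs,
                 electrode_labels = electrode_labels,
                 reference = reference),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d electrodes x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$values), ncol(x$values), x$fs, ncol(x$values) / x$fs))
  invisible(x)
}

#' Phoneme alignment container
#'
#' Sequence of phone tokens with half-open `[onset, offset)` intervals in
#' seconds, a speaker id and an utterance id per token. Tokens must be
#' ordered and non-overlapping within an utterance.
#'
#' @param label,onset,offset,speaker,utterance parallel vectors.
#' @return object of class `phoneme_alignment` (a data.frame).
#' @export
phoneme_alignment <- function(label, onset, offset, speaker, utterance) {
  df <- data.frame(label = as.character(label), onset = as.numeric(onset),
                   offset = as.numeric(offset),
                   speaker = as.character(speaker),
                   utterance = as.integer(utterance),
                   stringsAsFactors = FALSE)
  validate_alignment(df)
  class(df) <- c("phoneme_alignment", "data.frame")
  df
}

validate_alignment <- function(df) {
  if (nrow(df) == 0L) return(invisible(df))
  if (any(df$offset <= df$onset)) {
    i <- which(df$offset <= df$onset)[1L]
    stop_invalid(sprintf("token %d ('%s'): offset <= onset", i, df$label[i]))
  }
  for (u in unique(df$utterance)) {
    sub <- df[df$utterance == u, ]
    if (is.unsorted(sub$onset, strictly = FALSE))
      stop_invalid(sprintf("utterance %s: intervals out of order", u))
    if (nrow(sub) > 1L && any(sub$onset[-1L] < sub$offset[-nrow(sub)] - 1e-9))
      stop_invalid(sprintf("utterance %s: overlapping intervals", u))
  }
  invisible(df)
}

#' Auditory spectrogram container
#'
#' @param values frequency x time non-negative matrix.
#' @param center_frequencies channel center frequencies in Hz.
#' @param frame_rate frames per second of the time axis.
#' @return object of class `auditory_spectrogram`.
#' @export
auditory_spectrogram <- function(values, center_frequencies, frame_rate) {
  values <- as.matrix(values)
  if (nrow(values) != length(center_frequencies))
    stop_invalid("one center frequency per channel required")
  if (min(values) < 0) stop_invalid("spectrogram values must be non-negative")
  structure(list(values = values, center_frequencies = center_frequencies,
                 frame_rate = frame_rate),
            class = "auditory_spectrogram")
}

#' @export
print.auditory_spectrogram <- function(x, ...) {
  cat(sprintf(
    "<auditory_spectrogram> %d channels (%.0f-%.0f Hz) x %d frames @ %g Hz\n",
    nrow(x$values), min(x$center_frequencies), max(x$center_frequencies),
    ncol(x$values), x$frame_rate))
  invisible(x)
}

# Epoch container: token x feature x lag array plus per-token metadata.
new_epoch_set <- function(epochs, meta, lag_ms, fs, feature_labels,
                          feature_kind = c("electrode", "frequency")) {
  feature_kind <- match.arg(feature_kind)
  stopifnot(dim(epochs)[1] == nrow(meta), dim(epochs)[3] == length(lag_ms))
  structure(list(epochs = epochs, meta = meta, lag_ms = lag_ms, fs = fs,
                 feature_labels = feature_labels,
                 feature_kind = feature_kind),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d tokens x %d %ss x %d lags (%g..%g ms)\n",
              dim(x$epochs)[1], dim(x$epochs)[2], x$feature_kind,
              dim(x$epochs)[3], min(x$lag_ms), max(x$lag_ms)))
  invisible(x)
}

#' Subset an epoch set by token index
#' @param epochs an `epoch_set`.
#' @param idx integer or logical token index.
#' @return an `epoch_set` with the selected tokens.
#' @export
subset_epochs <- function(epochs, idx) {
  new_epoch_set(epochs$epochs[idx, , , drop = FALSE],
                epochs$meta[idx, , drop = FALSE],
                epochs$lag_ms, epochs$fs, epochs$feature_labels,
                epochs$feature_kind)
}

# PRP container: category x electrode x lag averages with per-category counts.
new_prp_set <- function(values, counts, lag_ms, electrodes, subject = NA) {
  stopifnot(dim(values)[1] == length(counts),
            dim(values)[3] == length(lag_ms))
  structure(list(values = values, counts = counts,
                 categories = dimnames(values)[[1]],
                 electrodes = electrodes, lag_ms = lag_ms, subject = subject),
            class = "prp_set")
}

#' @export
print.prp_set <- function(x, ...) {
  cat(sprintf(
    "<prp_set> %d categories x %d electrodes x %d lags; %d epochs averaged\n",
    length(x$categories), length(x$electrodes), length(x$lag_ms),
    sum(x$counts)))
  invisible(x)
}

new_avg_spectrogram_set <- function(values, counts, lag_ms,
                                    center_frequencies) {
  stopifnot(dim(values)[1] == length(counts),
            dim(values)[3] == length(lag_ms))
  structure(list(values = values, counts = counts,
                 categories = dimnames(values)[[1]],
                 center_frequencies = center_frequencies, lag_ms = lag_ms),
            class = "avg_spectrogram_set")
}

#' @export
print.avg_spectrogram_set <- function(x, ...) {
  cat(sprintf(
    "<avg_spectrogram_set> %d categories x %d channels x %d lags\n",
    length(x$categories), length(x$center_frequencies), length(x$lag_ms)))
  invisible(x)
}

new_distance_series <- function(values, lag_ms, categories, space) {
  for (l in seq_len(dim(values)[3])) {
    d <- values[, , l]
    if (max(abs(d - t(d))) > 1e-8 || any(diag(d) != 0) || min(d) < -1e-12)
      stop_invalid("distance matrices must be symmetric, non-negative, ",
                   "with zero diagonal")
  }
  structure(list(values = values, lag_ms = lag_ms, categories = categories,
                 space = space),
            class = "distance_series")
}

#' @export
print.distance_series <- function(x, ...) {
  cat(sprintf("<distance_series> [%s] %d categories, %d lags\n",
              x$space, length(x$categories), length(x$lag_ms)))
  invisible(x)
}

new_cross_sim <- function(values, lag_a, lag_b, axes, mask = NULL,
                          boot = NULL, statistic = "covariance") {
  structure(list(values = values, lag_a = lag_a, lag_b = lag_b, axes = axes,
                 mask = mask, boot = boot, statistic = statistic),
            class = "cross_sim")
}

#' @export
print.cross_sim <- function(x, ...) {
  cat(sprintf("<cross_sim> %s, %s x %s, %d x %d lags%s\n", x$statistic,
              x$axes[1], x$axes[2], length(x$lag_a), length(x$lag_b),
              if (!is.null(x$mask))
                sprintf(" (%d significant cells)", sum(x$mask, na.rm = TRUE))
              else ""))
  invisible(x)
}
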