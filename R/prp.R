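# PRP core: epoch extraction by phoneme onset, category averaging (the PRP
# and the matched average auditory spectrogram), rare-category filtering and
# baseline significance testing.

# Shared epoching over a feature x time matrix at rate fs.
epochs_from_matrix <- function(values, fs, alignment, window = c(-100, 600),
                               lag_step_ms = 1, feature_labels = NULL,
                               feature_kind = "electrode") {
  step <- as.integer(round(lag_step_ms * fs / 1000))
  if (step < 1L) stop_invalid("lag_step_ms below the sample interval")
  lags <- seq(as.integer(round(window[1] * fs / 1000)),
              as.integer(round(window[2] * fs / 1000)), by = step)
  lag_ms <- lags / fs * 1000
  n_t <- ncol(values)
  onsets <- vapply(alignment$onset, onset_sample, integer(1), fs = fs)
  ok <- onsets + min(lags) >= 1L & onsets + max(lags) <= n_t
  if (!all(ok))
    message(sum(!ok), " token(s) outside the recording span dropped")
  alignment <- alignment[ok, , drop = FALSE]
  onsets <- onsets[ok]
  n <- nrow(alignment)
  if (n == 0L) warning("no tokens to epoch: empty epoch set")
  ep <- array(0, dim = c(n, nrow(values), length(lags)))
  for (i in seq_len(n))
    ep[i, , ] <- values[, onsets[i] + lags, drop = FALSE]
  meta <- as.data.frame(alignment)
  meta$onset_sample <- onsets
  rownames(meta) <- NULL
  new_epoch_set(ep, meta, lag_ms, fs,
                feature_labels %||% rownames(values), feature_kind)
}

#' Extract phoneme-aligned EEG epochs
#'
#' Epoch sample at lag tau is `r(e, T_kn + tau)`; token order is preserved.
#' Tokens whose window falls outside the recording are dropped with a log
#' message.
#'
#' @param rec an [eeg_recording()] (filtered, z-scored, resampled).
#' @param alignment a [phoneme_alignment()].
#' @param window lag window in ms, default `c(-100, 600)`.
#' @param lag_step_ms lag-grid step in ms (>= one sample interval).
#' @return an `epoch_set`.
#' @export
extract_epochs <- function(rec, alignment, window = c(-100, 600),
                           lag_step_ms = 1000 / rec$fs) {
  epochs_from_matrix(rec$values, rec$fs, alignment, window, lag_step_ms,
                     rec$electrode_labels, "electrode")
}

#' Extract phoneme-aligned auditory-spectrogram epochs
#'
#' Same conventions as [extract_epochs()], on the spectrogram frame grid.
#'
#' @param spec an [auditory_spectrogram()].
#' @param alignment a [phoneme_alignment()].
#' @param window lag window in ms.
#' @param lag_step_ms lag-grid step in ms.
#' @return an `epoch_set` with frequency features.
#' @export
extract_spectrogram_epochs <- function(spec, alignment,
                                       window = c(-100, 600),
                                       lag_step_ms = 1000 / spec$frame_rate) {
  epochs_from_matrix(spec$values, spec$frame_rate, alignment, window,
                     lag_step_ms,
                     sprintf("%.0fHz", spec$center_frequencies), "frequency")
}

category_means <- function(epochs, keep = NULL, min_count = 1L) {
  n <- dim(epochs$epochs)[1]
  keep <- keep %||% rep(TRUE, n)
  labs <- epochs$meta$label[keep]
  cats <- sort(unique(labs))
  dims <- dim(epochs$epochs)[2:3]
  flat <- matrix(epochs$epochs[keep, , , drop = FALSE],
                 nrow = sum(keep))       # tokens x (feature*lag)
  sums <- rowsum(flat, labs)
  counts <- as.vector(table(factor(labs, levels = cats)))
  vals <- array(sums / counts, dim = c(length(cats), dims),
                dimnames = list(cats, NULL, NULL))
  drop_k <- counts < min_count
  if (any(drop_k)) {
    message("dropping empty/undersized categories: ",
            paste(cats[drop_k], collapse = ", "))
    vals <- vals[!drop_k, , , drop = FALSE]
    counts <- counts[!drop_k]
    cats <- cats[!drop_k]
  }
  list(values = vals, counts = counts, categories = cats)
}

#' Compute phoneme-related potentials
#'
#' `PRP(k, e, tau)` is the arithmetic mean over the kept epochs of category
#' `k` of the epoched response at electrode `e` and lag `tau`; `N_k` is the
#' number of averaged epochs. Categories with no kept epochs are excluded
#' with a message.
#'
#' @param epochs an `epoch_set` from [extract_epochs()].
#' @param mask optional `rejection_mask` aligned to the epochs.
#' @param subject optional subject id carried in the result.
#' @return a `prp_set`.
#' @export
compute_prp <- function(epochs, mask = NULL, subject = NA) {
  keep <- if (is.null(mask)) rep(TRUE, dim(epochs$epochs)[1]) else mask$keep
  if (length(keep) != dim(epochs$epochs)[1])
    stop_invalid("mask is not aligned to the epochs")
  cm <- category_means(epochs, keep)
  dimnames(cm$values)[[2]] <- epochs$feature_labels
  new_prp_set(cm$values, cm$counts, epochs$lag_ms, epochs$feature_labels,
              subject)
}

#' Drop phoneme categories rarer than a frequency floor
#'
#' @param prp a `prp_set` (or `avg_spectrogram_set`).
#' @param floor minimum `N_k / sum(N)` to retain (default 0.0001,
#'   i.e. 0.01%).
#' @return the filtered object.
#' @export
filter_rare_categories <- function(prp, floor = 1e-4) {
  frac <- prp$counts / sum(prp$counts)
  keep <- frac >= floor
  if (!any(keep)) stop_invalid("frequency floor removed every category")
  if (all(keep)) return(prp)
  prp$values <- prp$values[keep, , , drop = FALSE]
  prp$counts <- prp$counts[keep]
  prp$categories <- prp$categories[keep]
  prp
}

#' Compute average auditory spectrograms per phoneme category
#'
#' `Sbar(k, f, tau)` is the mean over the (kept) instances of category `k`
#' of `s(f, T_kn + tau)`, with the same window and category conventions as
#' [compute_prp()]. Accumulates streaming sums, so long sessions never
#' materialize a token x frequency x lag array.
#'
#' @param spec an [auditory_spectrogram()].
#' @param alignment a [phoneme_alignment()].
#' @param window lag window in ms.
#' @param mask optional logical keep vector aligned to the alignment rows
#'   that fall inside the spectrogram span.
#' @param lag_step_ms lag-grid step in ms.
#' @return an `avg_spectrogram_set`.
#' @export
compute_avg_spectrograms <- function(spec, alignment, window = c(-100, 600),
                                     mask = NULL,
                                     lag_step_ms = 1000 / spec$frame_rate) {
  fs <- spec$frame_rate
  step <- as.integer(round(lag_step_ms * fs / 1000))
  lags <- seq(as.integer(round(window[1] * fs / 1000)),
              as.integer(round(window[2] * fs / 1000)), by = step)
  lag_ms <- lags / fs * 1000
  onsets <- vapply(alignment$onset, onset_sample, integer(1), fs = fs)
  ok <- onsets + min(lags) >= 1L & onsets + max(lags) <= ncol(spec$values)
  if (!all(ok))
    message(sum(!ok), " token(s) outside the spectrogram span dropped")
  alignment <- alignment[ok, , drop = FALSE]
  onsets <- onsets[ok]
  keep <- mask %||% rep(TRUE, nrow(alignment))
  if (length(keep) != nrow(alignment))
    stop_invalid("mask is not aligned to the in-span tokens")
  labs <- alignment$label[keep]
  onsets <- onsets[keep]
  cats <- sort(unique(labs))
  nf <- nrow(spec$values)
  sums <- lapply(cats, function(k) matrix(0, nf, length(lags)))
  names(sums) <- cats
  counts <- setNames(integer(length(cats)), cats)
  for (i in seq_along(onsets)) {
    k <- labs[i]
    sums[[k]] <- sums[[k]] + spec$values[, onsets[i] + lags, drop = FALSE]
    counts[[k]] <- counts[[k]] + 1L
  }
  vals <- array(0, dim = c(length(cats), nf, length(lags)),
                dimnames = list(cats, NULL, NULL))
  for (j in seq_along(cats)) vals[j, , ] <- sums[[j]] / counts[[j]]
  new_avg_spectrogram_set(vals, as.integer(counts), lag_ms,
                          spec$center_frequencies)
}

#' Baseline significance of the grand-average PRP
#'
#' Per lag, a two-tailed paired t test across subjects of the subject-mean
#' PRP (token-count-weighted mean over categories) against each subject's
#' pre-onset baseline mean, Benjamini-Hochberg corrected at level `q`;
#' contiguous runs of significant lags are reported as windows.
#'
#' @param prps list of `prp_set`, one per subject (>= 2 subjects).
#' @param electrode electrode label, or `"mean"` for the electrode average.
#' @param q FDR level (default 0.01).
#' @param baseline baseline window in ms, default `c(-100, 0)`.
#' @return list with `lag_ms`, `t`, `p`, `sig` (logical mask) and `windows`
#'   (data.frame of significant lag ranges).
#' @export
baseline_significance <- function(prps, electrode = "Cz", q = 0.01,
                                  baseline = c(-100, 0)) {
  if (length(prps) < 2L) stop_invalid("need PRPs from at least 2 subjects")
  fraction_check(q, "q")
  lag_ms <- prps[[1]]$lag_ms
  series <- vapply(prps, function(p) {
    k <- dim(p$values)[1]
    v <- if (identical(electrode, "mean")) {
      apply(p$values, c(1, 3), mean)           # category x lag
    } else {
      ei <- match(electrode, p$electrodes)
      if (is.na(ei)) stop_invalid("electrode not found: ", electrode)
      matrix(p$values[, ei, , drop = FALSE], k, length(p$lag_ms))
    }
    colSums(v * p$counts) / sum(p$counts)      # token-weighted category mean
  }, numeric(length(lag_ms)))                  # lag x subject
  bl <- colMeans(series[lag_ms >= baseline[1] & lag_ms <= baseline[2], ,
                        drop = FALSE])
  diffs <- sweep(series, 2L, bl)               # lag x subject
  tp <- apply(diffs, 1L, function(d) {
    if (sd(d) == 0) return(c(0, 1))
    ht <- t.test(d)
    c(ht$statistic, ht$p.value)
  })
  sig <- bh_fdr(tp[2, ], q)
  runs <- rle(sig)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  windows <- data.frame(from_ms = lag_ms[starts[runs$values]],
                        to_ms = lag_ms[ends[runs$values]])
  list(lag_ms = lag_ms, t = tp[1, ], p = tp[2, ], sig = sig,
       windows = windows, q = q)
}
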