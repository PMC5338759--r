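# Speaker-resolved representational analysis: quadrant distance matrices,
# the speaker index, the per-phoneme speaker-encoding (SE) index, and the
# speaker-dependent neural-acoustic correlation map.

speaker_features <- function(set, window) {
  sel <- set$lag_ms >= window[1] & set$lag_ms <= window[2]
  matrix(set$values[, , sel, drop = FALSE], nrow = dim(set$values)[1])
}

#' Speaker-resolved pairwise phoneme distance matrix
#'
#' Euclidean distances among all 2K phoneme-by-speaker items (speaker 1
#' categories first). The diagonal K x K quadrants are the within-speaker
#' distances d_WS1, d_WS2; the off-diagonal quadrants are the
#' between-speaker distances (d_BS1(i, j) = distance between phoneme i of
#' speaker 1 and phoneme j of speaker 2).
#'
#' @param set_a,set_b per-speaker `prp_set`s (or `avg_spectrogram_set`s)
#'   over the same K categories.
#' @param window lag window in ms whose feature x lag vectors are
#'   concatenated (a single lag may be given as `c(l, l)`).
#' @return object of class `speaker_distance_matrix`.
#' @export
speaker_distance_matrix <- function(set_a, set_b, window = c(0, 400)) {
  if (!identical(set_a$categories, set_b$categories))
    stop_invalid("category sets/ordering differ between speakers")
  k <- length(set_a$categories)
  feats <- rbind(speaker_features(set_a, window),
                 speaker_features(set_b, window))
  m <- as.matrix(dist(feats))
  dimnames(m) <- NULL
  structure(list(values = m, k = k, categories = set_a$categories,
                 window = window),
            class = "speaker_distance_matrix")
}

ws1 <- function(m) m$values[seq_len(m$k), seq_len(m$k)]
ws2 <- function(m) m$values[m$k + seq_len(m$k), m$k + seq_len(m$k)]
bs1 <- function(m) m$values[seq_len(m$k), m$k + seq_len(m$k)]

#' @export
print.speaker_distance_matrix <- function(x, ...) {
  cat(sprintf("<speaker_distance_matrix> 2 x %d items, window %g..%g ms\n",
              x$k, x$window[1], x$window[2]))
  invisible(x)
}

#' Speaker index of a speaker distance matrix
#'
#' Mean within-speaker distance (off-diagonal entries of the two diagonal
#' quadrants) minus mean between-speaker distance over the matching
#' phoneme pairs (off-diagonal entries of the between-speaker quadrant;
#' the same-phoneme diagonal is excluded so the index is exactly zero
#' when the two speakers' representations are identical). The index turns
#' increasingly *negative* as speaker separation grows (between-speaker
#' distances exceed within-speaker ones), so its magnitude carries the
#' effect.
#'
#' @param m a [speaker_distance_matrix()].
#' @return scalar index.
#' @export
speaker_index <- function(m) {
  w1 <- ws1(m); w2 <- ws2(m); b <- bs1(m)
  within <- c(lower_tri_vec(w1), lower_tri_vec(w2))
  between <- b[row(b) != col(b)]   # covers d_BS1 and d_BS2, i != j
  mean(within) - mean(between)
}

#' Speaker-dependent encoding (SE) index per phoneme
#'
#' For phoneme i, SE(i) contrasts its between-speaker distances to the other
#' phonemes with the corresponding within-speaker distances:
#' `SE(i) = mean over j != i of ((d_BS1(i,j) + d_BS2(i,j)) -
#' (d_WS1(i,j) + d_WS2(i,j))) / 2`. SE is identically zero when the two
#' speakers' representations coincide, and grows with the planted speaker
#' separation; it is not constrained to be non-negative.
#'
#' @param set_a,set_b per-speaker feature sets (as in
#'   [speaker_distance_matrix()]), or pass a precomputed matrix via `m`.
#' @param window lag window in ms.
#' @param m optional [speaker_distance_matrix()] (overrides the sets).
#' @return named numeric vector (class `se_vector`) with attribute `space`.
#' @export
se_index <- function(set_a = NULL, set_b = NULL, window = c(0, 400),
                     m = NULL) {
  if (is.null(m)) m <- speaker_distance_matrix(set_a, set_b, window)
  k <- m$k
  if (k < 2L) stop_invalid("SE needs at least 2 phoneme categories")
  w1 <- ws1(m); w2 <- ws2(m); b <- bs1(m)
  se <- vapply(seq_len(k), function(i) {
    j <- setdiff(seq_len(k), i)
    mean(((b[i, j] + b[j, i]) - (w1[i, j] + w2[i, j])) / 2)
  }, numeric(1))
  names(se) <- m$categories
  structure(se, class = "se_vector",
            space = if (is.null(set_a)) "unknown" else
              if (inherits(set_a, "prp_set")) "neural" else "acoustic")
}

# Speaker-contrast pattern at one lag: strict-upper-triangle vectorization
# of P(i,j) = mean between-speaker minus mean within-speaker distance for
# the phoneme pair (i, j). The same-phoneme diagonal d(i_1, i_2) is
# excluded: being a norm of an estimate difference it is positive under
# pure noise in every space, which would inject a spurious common
# component into every lag pair.
speaker_pattern <- function(m) {
  w1 <- ws1(m); w2 <- ws2(m); b <- bs1(m)
  p <- (b + t(b)) / 2 - (w1 + w2) / 2
  p[upper.tri(p, diag = FALSE)]
}

#' Speaker-dependent neural-acoustic correlation map
#'
#' At each (neural lag, acoustic lag) pair, the Pearson correlation between
#' the speaker-contrast patterns (between- minus within-speaker distance per
#' phoneme pair) of the two spaces, with a BH-FDR mask at level `q`.
#' Before distances are taken, each speaker's category means are centered
#' across categories at that lag: a speaker-global offset (for example the
#' smeared response to *neighbouring* tokens of the same speaker, or a
#' global pitch offset in the acoustic space) shifts every category equally
#' and carries no category-specific speaker information, but would
#' otherwise bleed into the between-speaker distances at every lag.
#' Constant patterns yield NA cells, flagged and excluded from the
#' correction.
#'
#' @param neural_a,neural_b per-speaker `prp_set`s.
#' @param acoustic_a,acoustic_b per-speaker `avg_spectrogram_set`s.
#' @param q FDR level (default 0.05).
#' @param lag_step_ms lag-grid step for both axes.
#' @return a `cross_sim` with correlation values, axes
#'   `c("neural", "acoustic")` and the FDR mask.
#' @export
speaker_neural_acoustic_map <- function(neural_a, neural_b, acoustic_a,
                                        acoustic_b, q = 0.05,
                                        lag_step_ms = 10) {
  fraction_check(q, "q")
  center_categories <- function(set) {
    k <- dim(set$values)[1]
    for (l in seq_len(dim(set$values)[3])) {
      m <- matrix(set$values[, , l], k)
      set$values[, , l] <- m - rep(colMeans(m), each = k)
    }
    set
  }
  pat_series <- function(sa, sb) {
    sa <- center_categories(sa)
    sb <- center_categories(sb)
    lag_sel <- seq(1L, length(sa$lag_ms),
                   by = max(1L, round(lag_step_ms /
                                        diff(sa$lag_ms[1:2]))))
    pats <- vapply(lag_sel, function(l) {
      lag <- sa$lag_ms[l]
      speaker_pattern(speaker_distance_matrix(sa, sb, c(lag, lag)))
    }, numeric(length(sa$categories) * (length(sa$categories) - 1) / 2))
    list(lag_ms = sa$lag_ms[lag_sel], pats = t(pats))   # lags x pairs
  }
  pn <- pat_series(neural_a, neural_b)
  pa <- pat_series(acoustic_a, acoustic_b)
  sd_n <- apply(pn$pats, 1L, sd)
  sd_a <- apply(pa$pats, 1L, sd)
  zn <- pn$pats - rowMeans(pn$pats)
  za <- pa$pats - rowMeans(pa$pats)
  r <- tcrossprod(zn / sqrt(rowSums(zn^2)), za / sqrt(rowSums(za^2)))
  r[sd_n == 0, ] <- NA
  r[, sd_a == 0] <- NA
  np <- ncol(pn$pats)
  tt <- r * sqrt((np - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tt), df = np - 2)
  mask <- matrix(FALSE, nrow(r), ncol(r))
  ok <- !is.na(p)
  if (any(ok)) mask[ok] <- bh_fdr(p[ok], q)
  new_cross_sim(r, pn$lag_ms, pa$lag_ms, axes = c("neural", "acoustic"),
                mask = mask, statistic = "pearson r",
                boot = list(q = q, p = p, n_pairs = np))
}

#' Correlation between neural and acoustic SE vectors
#'
#' @param se_neural,se_acoustic `se_vector`s over the same categories in
#'   the same order.
#' @return list with `r`, `p`, `n`.
#' @export
se_correlation <- function(se_neural, se_acoustic) {
  if (!identical(names(se_neural), names(se_acoustic)))
    stop_invalid("category orderings differ")
  pearson_with_p(as.numeric(se_neural), as.numeric(se_acoustic))
}
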