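# Time-resolved representational analysis: pairwise phoneme distance
# matrices per lag, m - D similarity, lag x lag covariance maps with
# bootstrap significance, UPGMA clustering, non-metric MDS and silhouette.

#' Per-lag pairwise phoneme distance matrices
#'
#' At each lag, the Euclidean distance between category feature vectors
#' (electrodes for a `prp_set`, frequency channels for an
#' `avg_spectrogram_set`). All electrodes enter the neural distance by
#' default; `electrodes` restricts the feature axis, e.g. to the
#' electrodes showing significant manner distinctions.
#'
#' @param featureset a `prp_set` or `avg_spectrogram_set`.
#' @param electrodes optional electrode labels (or indices) to retain.
#' @return a `distance_series` (category x category x lag).
#' @export
pairwise_distance_series <- function(featureset, electrodes = NULL) {
  if (!is.null(electrodes)) {
    idx <- if (is.character(electrodes))
      match(electrodes, featureset$electrodes) else electrodes
    if (anyNA(idx)) stop_invalid("unknown electrode label")
    featureset$values <- featureset$values[, idx, , drop = FALSE]
  }
  vals <- featureset$values
  k <- dim(vals)[1]
  if (k < 2L) stop_invalid("need at least 2 categories")
  nl <- dim(vals)[3]
  space <- if (inherits(featureset, "prp_set")) "neural" else "acoustic"
  out <- array(0, dim = c(k, k, nl),
               dimnames = list(featureset$categories, featureset$categories,
                               NULL))
  for (l in seq_len(nl))
    out[, , l] <- as.matrix(dist(vals[, , l, drop = TRUE]))
  new_distance_series(out, featureset$lag_ms, featureset$categories, space)
}

#' Similarity transform m - D
#'
#' `m` is the mean of the matrix entries (including the zero diagonal by
#' default, so closest pairs get the largest similarity and the mean of the
#' result is zero when `m_mode = "all"`).
#'
#' @param d a distance matrix, or a `distance_series`.
#' @param m_mode `"all"` (mean of all entries) or `"lower"` (strict lower
#'   triangle only).
#' @return object of the same shape with entries `m - D`.
#' @export
similarity_matrix <- function(d, m_mode = c("all", "lower")) {
  m_mode <- match.arg(m_mode)
  mfun <- function(x) if (m_mode == "all") mean(x) else
    mean(lower_tri_vec(x))
  if (inherits(d, "distance_series")) {
    out <- d$values
    for (l in seq_len(dim(out)[3])) out[, , l] <- mfun(out[, , l]) -
        out[, , l]
    structure(list(values = out, lag_ms = d$lag_ms,
                   categories = d$categories, space = d$space,
                   m_mode = m_mode),
              class = "similarity_series")
  } else {
    mfun(d) - d
  }
}

# Lower-triangle vectorization of every lag of a distance series:
# lags x pairs matrix.
series_lower_tri <- function(series) {
  nl <- dim(series$values)[3]
  t(vapply(seq_len(nl), function(l) lower_tri_vec(series$values[, , l]),
           numeric(sum(lower.tri(series$values[, , 1])))))
}

#' Lag x lag covariance between two distance series
#'
#' `value(tau_a, tau_b)` is the covariance between the vectorized strict
#' lower triangles of `A(tau_a)` and `B(tau_b)` (the lower triangle avoids
#' double-counting the symmetric matrix). Covariance is shift-invariant, so
#' running it on distances or on m - D similarities gives identical values.
#'
#' @param series_a,series_b `distance_series` over the same categories in
#'   the same order.
#' @return a `cross_sim` with `lag_a` from `series_a` and `lag_b` from
#'   `series_b`.
#' @export
cross_covariance <- function(series_a, series_b) {
  if (!identical(series_a$categories, series_b$categories))
    stop_invalid("category sets/ordering differ between the two series")
  xa <- series_lower_tri(series_a)
  xb <- series_lower_tri(series_b)
  p <- ncol(xa)
  xa <- xa - rowMeans(xa)
  xb <- xb - rowMeans(xb)
  v <- tcrossprod(xa, xb) / (p - 1)
  new_cross_sim(v, series_a$lag_ms, series_b$lag_ms,
                axes = c(series_a$space, series_b$space))
}

# Internal: category-mean array (K x F x L) from an epoch set for the given
# token index multiset (bootstrap resample), categories fixed.
resampled_means <- function(flat, labs, cats, idx) {
  sums <- rowsum(flat[idx, , drop = FALSE], labs[idx])
  counts <- as.vector(table(factor(labs[idx], levels = cats)))
  sums / counts
}

#' Bootstrap significance of a lag x lag covariance map
#'
#' Tokens are resampled with replacement within each phoneme category
#' (keeping every category populated); the covariance map is recomputed for
#' each replicate. Per cell, a t statistic (bootstrap mean over bootstrap
#' standard deviation, df = n - 1) yields a two-sided p-value against zero
#' covariance, corrected by Benjamini-Hochberg at level `q`.
#'
#' @param epochs_a,epochs_b `epoch_set`s over the same tokens (e.g. neural
#'   and acoustic epochs of one session).
#' @param n number of bootstrap resamples (default 20; >= 2).
#' @param q FDR level (default 1e-4).
#' @param seed integer seed for the resampling.
#' @return a `cross_sim` with the observed covariance in `values`, the FDR
#'   mask in `mask`, and bootstrap details in `boot`.
#' @export
bootstrap_significance <- function(epochs_a, epochs_b, n = 20, q = 1e-4,
                                   seed = 1) {
  if (n < 2L) stop_invalid("need at least 2 bootstrap resamples")
  if (n < 5L) warning("very few bootstrap resamples: low power")
  fraction_check(q, "q")
  if (!identical(epochs_a$meta$label, epochs_b$meta$label))
    stop_invalid("epoch sets do not cover the same tokens")
  labs <- epochs_a$meta$label
  cats <- sort(unique(labs))
  k <- length(cats)
  if (k < 2L) stop_invalid("need at least 2 categories")
  nt <- length(labs)
  dim_a <- dim(epochs_a$epochs)[2:3]
  dim_b <- dim(epochs_b$epochs)[2:3]
  flat_a <- matrix(epochs_a$epochs, nrow = nt)
  flat_b <- matrix(epochs_b$epochs, nrow = nt)

  series_of <- function(mean_a, mean_b) {
    sa <- new_distance_series(dist_array(mean_a, k, dim_a), epochs_a$lag_ms,
                              cats, "a")
    sb <- new_distance_series(dist_array(mean_b, k, dim_b), epochs_b$lag_ms,
                              cats, "b")
    cross_covariance(sa, sb)$values
  }
  dist_array <- function(m, k, dims) {
    arr <- array(m, dim = c(k, dims))
    out <- array(0, dim = c(k, k, dims[2]),
                 dimnames = list(cats, cats, NULL))
    for (l in seq_len(dims[2]))
      out[, , l] <- as.matrix(dist(arr[, , l, drop = TRUE]))
    out
  }

  observed <- series_of(resampled_means(flat_a, labs, cats, seq_len(nt)),
                        resampled_means(flat_b, labs, cats, seq_len(nt)))
  by_cat <- split(seq_len(nt), labs)
  reps <- with_seed(seed, {
    lapply(seq_len(n), function(b) {
      idx <- unlist(lapply(by_cat, function(ix)
        ix[sample.int(length(ix), length(ix), replace = TRUE)]),
        use.names = FALSE)
      series_of(resampled_means(flat_a, labs, cats, idx),
                resampled_means(flat_b, labs, cats, idx))
    })
  })
  arr <- simplify2array(reps)                      # La x Lb x n
  bmean <- apply(arr, c(1, 2), mean)
  bsd <- apply(arr, c(1, 2), sd)
  tt <- bmean / bsd
  tt[bsd == 0] <- ifelse(bmean[bsd == 0] == 0, 0, Inf)
  p <- 2 * pt(-abs(tt), df = n - 1)
  mask <- matrix(bh_fdr(as.vector(p), q), nrow(p), ncol(p))
  new_cross_sim(observed, epochs_a$lag_ms, epochs_b$lag_ms,
                axes = c("a", "b"), mask = mask,
                boot = list(n = n, q = q, seed = seed, t = tt, p = p))
}

#' UPGMA clustering of category responses
#'
#' Average-linkage (UPGMA) hierarchical clustering on Euclidean distances
#' between the concatenated feature x lag vectors within the window
#' (default 0-400 ms, the span of the significant PRP components).
#'
#' @param featureset a `prp_set` or `avg_spectrogram_set` (>= 2 categories).
#' @param window lag window in ms.
#' @return list with `hclust`, `phylo` (ultrametric [ape::as.phylo] tree),
#'   `newick` string and the `dist` object.
#' @export
upgma_cluster <- function(featureset, window = c(0, 400)) {
  vals <- featureset$values
  if (dim(vals)[1] < 2L) stop_invalid("need at least 2 categories")
  sel <- featureset$lag_ms >= window[1] & featureset$lag_ms <= window[2]
  feat <- matrix(vals[, , sel, drop = FALSE], nrow = dim(vals)[1])
  rownames(feat) <- featureset$categories
  d <- dist(feat)
  hc <- hclust(d, method = "average")
  phylo <- ape::as.phylo(hc)
  list(hclust = hc, phylo = phylo,
       newick = ape::write.tree(phylo), dist = d)
}

#' Non-metric MDS embedding of a distance matrix
#'
#' Kruskal's stress-1 non-metric scaling with seeded random restarts from
#' jittered classical-scaling starts; the best-stress configuration is kept,
#' centered at zero, with the sign fixed so the first category is
#' non-negative on each dimension. When classical scaling already
#' reproduces the distances (stress ~ 0) it is returned directly.
#'
#' @param d symmetric distance matrix (or `dist`).
#' @param dims embedding dimension (1, 2 or 3).
#' @param n_restarts random restarts (default 8).
#' @param seed integer seed.
#' @return matrix of coordinates (categories x dims) with attribute
#'   `stress` (Kruskal stress-1, fraction).
#' @export
mds_embed <- function(d, dims = 1, n_restarts = 8, seed = 1) {
  dm <- as.matrix(d)
  k <- nrow(dm)
  if (!dims %in% 1:3) stop_invalid("`dims` must be 1, 2 or 3")
  if (dims > k - 1L) stop_invalid("`dims` exceeds categories - 1")
  finish <- function(y, stress) {
    y <- matrix(y, k, dims)
    y <- sweep(y, 2L, colMeans(y))
    for (j in seq_len(dims)) if (y[1, j] < 0) y[, j] <- -y[, j]
    rownames(y) <- rownames(dm)
    attr(y, "stress") <- stress
    y
  }
  if (all(dm == 0)) return(finish(matrix(0, k, dims), 0))
  off <- dm[lower.tri(dm)]
  if (any(off <= 0)) {   # isoMDS rejects zero distances between items
    eps <- min(off[off > 0], na.rm = TRUE) * 1e-6
    dm[dm <= 0] <- eps
    diag(dm) <- 0
  }
  init <- cmdscale(dm, k = dims)
  if (ncol(init) < dims)
    init <- cbind(init, matrix(0, k, dims - ncol(init)))
  stress1 <- function(y) {
    dy <- as.matrix(dist(y))[lower.tri(dm)]
    fit <- stats::isoreg(dm[lower.tri(dm)], dy)
    sqrt(sum((dy[order(dm[lower.tri(dm)])] - fit$yf)^2) /
           max(sum(dy^2), .Machine$double.eps))
  }
  if (stress1(init) < 1e-8) return(finish(init, 0))
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      y0 <- if (r == 1L) init else
        init + rnorm(length(init)) * 0.05 * max(abs(init))
      fit <- tryCatch(
        MASS::isoMDS(dm, y = y0, k = dims, trace = FALSE),
        error = function(e) NULL)
      if (!is.null(fit) &&
          (is.null(best) || fit$stress < best$stress)) best <<- fit
    }
  })
  if (is.null(best)) return(finish(init, stress1(init)))
  finish(best$points, best$stress / 100)   # isoMDS reports percent
}

#' One-dimensional MDS trajectory of a distance series
#'
#' Embeds each lag's distance matrix independently; lags flagged in
#' `zero_mask` (e.g. no electrode significant) emit all-zero coordinates.
#'
#' @param series a `distance_series`.
#' @param dims embedding dimension per lag.
#' @param zero_mask optional logical vector over lags.
#' @param n_restarts,seed passed to [mds_embed()].
#' @return array categories x dims x lags.
#' @export
mds_trajectory <- function(series, dims = 1, zero_mask = NULL,
                           n_restarts = 4, seed = 1) {
  nl <- dim(series$values)[3]
  k <- length(series$categories)
  zero_mask <- zero_mask %||% rep(FALSE, nl)
  if (length(zero_mask) != nl)
    stop_invalid("`zero_mask` must have one entry per lag")
  out <- array(0, dim = c(k, dims, nl),
               dimnames = list(series$categories, NULL, NULL))
  for (l in seq_len(nl)) {
    if (zero_mask[l]) next
    out[, , l] <- mds_embed(series$values[, , l], dims = dims,
                            n_restarts = n_restarts, seed = seed + l)
  }
  out
}

#' Silhouette index of a labelled configuration
#'
#' Mean over items of `(b - a) / max(a, b)` with `a` the mean distance to
#' the item's own label and `b` the smallest mean distance to another
#' label. Items in singleton clusters contribute 0 (the usual convention).
#'
#' @param x distance matrix (or `dist`), or an items x features matrix from
#'   which Euclidean distances are computed.
#' @param labels cluster labels, one per item; >= 2 distinct labels, not
#'   all singletons.
#' @return mean silhouette width (scalar in \[-1, 1\]).
#' @export
silhouette_index <- function(x, labels) {
  dm <- if (inherits(x, "dist")) as.matrix(x)
        else if (is.matrix(x) && isSymmetric(unname(x)) &&
                 all(diag(x) == 0) && nrow(x) == length(labels)) x
        else as.matrix(dist(x))
  labels <- as.character(labels)
  n <- nrow(dm)
  if (length(labels) != n) stop_invalid("one label per item required")
  if (length(unique(labels)) < 2L) stop_invalid("need >= 2 distinct labels")
  if (all(table(labels) == 1L))
    stop_invalid("silhouette undefined when every cluster is a singleton")
  s <- vapply(seq_len(n), function(i) {
    own <- labels == labels[i]
    if (sum(own) == 1L) return(0)
    a <- mean(dm[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(g) mean(dm[i, labels == g]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}
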