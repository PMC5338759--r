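# Manner-of-articulation group statistics: F time courses, per-electrode
# maps, effect-size accumulation, BH-FDR, the regularized least-squares
# manner classifier and confusion-pattern comparison.

#' Benjamini-Hochberg FDR mask
#'
#' Step-up procedure at level `q`.
#'
#' @param pvals p-values in \[0, 1\].
#' @param q FDR level in (0, 1).
#' @return logical vector: TRUE where the hypothesis is rejected.
#' @export
bh_fdr <- function(pvals, q) {
  if (any(!is.finite(pvals)) || any(pvals < 0 | pvals > 1))
    stop_invalid("p-values must lie in [0, 1]")
  fraction_check(q, "q")
  p.adjust(pvals, method = "BH") <= q
}

#' Unit matrix for manner F statistics
#'
#' Stacks per-subject, per-category PRP values at one analysis electrode
#' into a units x lags matrix (units = category x subject), the observation
#' unit of the grand-average F analysis.
#'
#' @param prps a `prp_set` or list of them (one per subject).
#' @param electrode electrode label (default `"FCz"`).
#' @return list with `x` (units x lags), `category` and `subject` per unit.
#' @export
prp_unit_matrix <- function(prps, electrode = "FCz") {
  if (inherits(prps, "prp_set")) prps <- list(prps)
  rows <- list(); cats <- character(0); subj <- character(0)
  for (si in seq_along(prps)) {
    p <- prps[[si]]
    ei <- match(electrode, p$electrodes)
    if (is.na(ei)) stop_invalid("electrode not found: ", electrode)
    rows[[si]] <- p$values[, ei, ]
    cats <- c(cats, p$categories)
    subj <- c(subj, rep(as.character(si), length(p$categories)))
  }
  list(x = do.call(rbind, rows), category = cats, subject = subj,
       lag_ms = prps[[1]]$lag_ms)
}

#' Token-level unit matrix for manner F statistics
#'
#' One row per (kept) token: the epoched response at one electrode. The
#' token-level alternative to the category x subject units of
#' [prp_unit_matrix()].
#'
#' @param epochs an `epoch_set` from [extract_epochs()].
#' @param electrode electrode label (default `"FCz"`).
#' @return list with `x` (tokens x lags), `category` per token, `lag_ms`.
#' @export
epoch_unit_matrix <- function(epochs, electrode = "FCz") {
  ei <- match(electrode, epochs$feature_labels)
  if (is.na(ei)) stop_invalid("electrode not found: ", electrode)
  x <- matrix(epochs$epochs[, ei, , drop = FALSE],
              nrow = dim(epochs$epochs)[1])
  list(x = x, category = epochs$meta$label, lag_ms = epochs$lag_ms)
}

#' Unit matrix from average spectrograms (acoustic F input)
#'
#' Collapses the frequency axis (root-mean-square per lag) so acoustic and
#' neural F series share the same code path downstream.
#'
#' @param sets an `avg_spectrogram_set` or list of them.
#' @return list as in [prp_unit_matrix()].
#' @export
spectrogram_unit_matrix <- function(sets) {
  if (inherits(sets, "avg_spectrogram_set")) sets <- list(sets)
  rows <- list(); cats <- character(0); subj <- character(0)
  for (si in seq_along(sets)) {
    s <- sets[[si]]
    rows[[si]] <- apply(s$values, c(1, 3), function(v) sqrt(mean(v^2)))
    cats <- c(cats, s$categories)
    subj <- c(subj, rep(as.character(si), length(s$categories)))
  }
  list(x = do.call(rbind, rows), category = cats, subject = subj,
       lag_ms = sets[[1]]$lag_ms)
}

#' F-statistic time course for manner separability
#'
#' One-way ANOVA F at each lag over units grouped by manner of
#' articulation, with a BH-FDR significance mask. Neural ("response") and
#' acoustic ("stimulus") inputs share this code path.
#'
#' @param x units x lags matrix (see [prp_unit_matrix()]).
#' @param groups manner group per unit (>= 2 groups, each >= 2 units).
#' @param q FDR level for the mask (default 0.05).
#' @param lag_ms optional lag axis carried through.
#' @param source `"response"` or `"stimulus"` tag.
#' @return object of class `f_series`: list with `f`, `p`, `sig`, `df1`,
#'   `df2`, `lag_ms`, `source`, `exact_separation`.
#' @export
manner_f_series <- function(x, groups, q = 0.05, lag_ms = NULL,
                            source = "response") {
  res <- f_oneway_cols(as.matrix(x), groups)
  sig <- bh_fdr(res$p, q)
  structure(list(f = res$f, p = res$p, sig = sig, df1 = res$df1,
                 df2 = res$df2, lag_ms = lag_ms %||% seq_along(res$f),
                 source = source, q = q,
                 exact_separation = res$exact_separation),
            class = "f_series")
}

#' @export
print.f_series <- function(x, ...) {
  cat(sprintf("<f_series> [%s] %d lags, F(%d, %d), %d significant (q=%g)\n",
              x$source, length(x$f), x$df1, x$df2, sum(x$sig), x$q))
  invisible(x)
}

# Default PRP component windows (ms) around the four response events.
default_response_windows <- function(latencies = c(50, 120, 230, 400),
                                     half_width = 20) {
  w <- lapply(latencies, function(l) c(l - half_width, l + half_width))
  names(w) <- paste0("R", seq_along(latencies))
  w
}

#' Per-electrode F maps over response windows
#'
#' F computed independently per electrode, then averaged within each
#' response window (the scalp-map quantity).
#'
#' @param prps a `prp_set` or list of them (subjects).
#' @param partition named manner map, phoneme -> group.
#' @param windows named list of `c(from_ms, to_ms)` windows.
#' @return electrodes x windows matrix of mean F.
#' @export
per_electrode_f_maps <- function(prps, partition,
                                 windows = default_response_windows()) {
  if (inherits(prps, "prp_set")) prps <- list(prps)
  electrodes <- prps[[1]]$electrodes
  lag_ms <- prps[[1]]$lag_ms
  for (w in windows)
    if (w[1] < min(lag_ms) || w[2] > max(lag_ms))
      stop_invalid("window outside the lag range")
  out <- matrix(NA_real_, length(electrodes), length(windows),
                dimnames = list(electrodes, names(windows)))
  for (ei in seq_along(electrodes)) {
    um <- prp_unit_matrix(prps, electrodes[ei])
    res <- f_oneway_cols(um$x, partition[um$category])
    for (wi in seq_along(windows)) {
      sel <- lag_ms >= windows[[wi]][1] & lag_ms <= windows[[wi]][2]
      out[ei, wi] <- mean(res$f[sel])
    }
  }
  out
}

#' Effect size accumulated over subjects and recording time
#'
#' For each grid cell, subsamples subjects and truncates each session to an
#' initial duration, recomputes the peak manner F at the analysis
#' electrode, and averages over seeded repetitions. Grid values beyond the
#' available data are truncated with a warning.
#'
#' @param subjects list, one element per subject, each a list with
#'   `epochs` (an `epoch_set`) and optionally `mask`.
#' @param partition named manner map.
#' @param n_subjects_grid,duration_grid_min grids of cohort size and
#'   initial duration (minutes).
#' @param electrode analysis electrode (default `"FCz"`).
#' @param n_rep repetitions per cell.
#' @param seed integer seed.
#' @return matrix length(n_subjects_grid) x length(duration_grid_min) of
#'   mean peak F.
#' @export
effect_size_accumulation <- function(subjects, partition,
                                     n_subjects_grid, duration_grid_min,
                                     electrode = "FCz", n_rep = 3,
                                     seed = 1) {
  ns_avail <- length(subjects)
  if (any(n_subjects_grid > ns_avail)) {
    warning("subject grid truncated to the available ", ns_avail,
            " subjects")
    n_subjects_grid <- n_subjects_grid[n_subjects_grid <= ns_avail]
  }
  out <- matrix(NA_real_, length(n_subjects_grid),
                length(duration_grid_min),
                dimnames = list(paste0("n", n_subjects_grid),
                                paste0("min", duration_grid_min)))
  with_seed(seed, {
    for (i in seq_along(n_subjects_grid)) {
      for (j in seq_along(duration_grid_min)) {
        vals <- numeric(n_rep)
        for (r in seq_len(n_rep)) {
          pick <- sample.int(ns_avail, n_subjects_grid[i])
          prps <- lapply(subjects[pick], function(s) {
            keep_t <- s$epochs$meta$onset < duration_grid_min[j] * 60
            keep <- if (is.null(s$mask)) keep_t else keep_t & s$mask$keep
            compute_prp(subset_epochs(s$epochs, which(keep)))
          })
          um <- prp_unit_matrix(prps, electrode)
          grp <- partition[um$category]
          vals[r] <- if (min(table(grp)) < 2L) NA_real_
                     else max(f_oneway_cols(um$x, grp)$f, na.rm = TRUE)
        }
        out[i, j] <- mean(vals, na.rm = TRUE)
      }
    }
  })
  out
}

#' Flatten epochs for classification
#'
#' @param epochs an `epoch_set`.
#' @param window lag window in ms to retain.
#' @return tokens x (features * lags) matrix.
#' @export
flatten_epochs <- function(epochs, window = c(0, 400)) {
  sel <- epochs$lag_ms >= window[1] & epochs$lag_ms <= window[2]
  matrix(epochs$epochs[, , sel, drop = FALSE], nrow = dim(epochs$epochs)[1])
}

# Ridge solutions for a grid of penalties via the eigendecomposition of the
# Gram matrix (dual form): efficient when features outnumber observations,
# which is the norm for flattened electrode x lag epochs. Returns dual
# coefficients alpha with weights w = X' alpha.
ridge_dual_fit <- function(x, y, lambda) {
  k <- tcrossprod(x)
  eg <- eigen(k, symmetric = TRUE)
  qty <- crossprod(eg$vectors, y)
  lapply(lambda, function(l)
    eg$vectors %*% (qty / (pmax(eg$values, 0) + l)))
}

stratified_split <- function(labels, holdout, seed_offset = 0) {
  test <- integer(0)
  for (cl in unique(labels)) {
    ix <- which(labels == cl)
    n_test <- max(1L, round(length(ix) * holdout))
    test <- c(test, sample(ix, n_test))
  }
  sort(test)
}

#' Regularized least-squares manner classifier
#'
#' One-vs-rest ridge regression on flattened feature x lag epoch vectors;
#' the predicted class is the argmax score. The ridge penalty is selected on
#' an inner stratified split of the training data; performance is reported
#' on a stratified held-out split.
#'
#' @param x tokens x features matrix (see [flatten_epochs()]).
#' @param labels class label per token (>= 2 classes).
#' @param holdout held-out fraction (default 0.10).
#' @param seed integer seed for the splits.
#' @param lambda ridge penalty grid.
#' @return list with `model` (weights, column centers, class means,
#'   `lambda`), `confusion` (a `confusion_matrix`: counts, row = true), and
#'   `accuracy`.
#' @export
rls_classifier <- function(x, labels, holdout = 0.10, seed = 1,
                           lambda = 10^seq(-3, 3, length.out = 7)) {
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2L) stop_invalid("need >= 2 classes")
  fraction_check(holdout, "holdout")
  with_seed(seed, {
    test <- stratified_split(labels, holdout)
    train <- setdiff(seq_len(nrow(x)), test)
    if (!all(classes %in% labels[train]) || !all(classes %in% labels[test]))
      stop_invalid("every class must appear in both train and test splits")

    pick_lambda <- if (length(lambda) > 1L) {
      inner_test <- train[stratified_split(labels[train], 0.1)]
      inner_train <- setdiff(train, inner_test)
      acc <- vapply(fit_predict(x, labels, inner_train, inner_test, lambda,
                                classes),
                    function(pred) mean(pred == labels[inner_test]),
                    numeric(1))
      lambda[which.max(acc)]
    } else lambda

    fit <- fit_model(x, labels, train, pick_lambda, classes)
    pred <- predict_rls(fit, x[test, , drop = FALSE])
    cm <- table(true = factor(labels[test], classes),
                predicted = factor(pred, classes))
    cm <- unclass(as.matrix(cm))
    conf <- structure(list(counts = cm,
                           class_accuracy = diag(cm) / rowSums(cm),
                           classes = classes),
                      class = "confusion_matrix")
    list(model = fit, confusion = conf,
         accuracy = mean(pred == labels[test]),
         test_index = test)
  })
}

fit_model <- function(x, labels, train, lambda, classes) {
  xtr <- x[train, , drop = FALSE]
  centers <- colMeans(xtr)
  xtr <- sweep(xtr, 2L, centers)
  y <- outer(labels[train], classes, `==`) * 1
  ybar <- colMeans(y)
  alpha <- ridge_dual_fit(xtr, sweep(y, 2L, ybar), lambda)[[1]]
  list(alpha = alpha, xtr = xtr, centers = centers, intercept = ybar,
       classes = classes, lambda = lambda)
}

predict_rls <- function(fit, xnew) {
  sc <- tcrossprod(sweep(xnew, 2L, fit$centers), t(fit$alpha) %*% fit$xtr)
  sc <- sweep(sc, 2L, fit$intercept, `+`)
  fit$classes[max.col(sc, ties.method = "first")]
}

fit_predict <- function(x, labels, train, test, lambdas, classes) {
  centers <- colMeans(x[train, , drop = FALSE])
  xtr <- sweep(x[train, , drop = FALSE], 2L, centers)
  y <- outer(labels[train], classes, `==`) * 1
  ybar <- colMeans(y)
  alphas <- ridge_dual_fit(xtr, sweep(y, 2L, ybar), lambdas)
  kte <- tcrossprod(sweep(x[test, , drop = FALSE], 2L, centers), xtr)
  lapply(alphas, function(a) {
    sc <- sweep(kte %*% a, 2L, ybar, `+`)
    classes[max.col(sc, ties.method = "first")]
  })
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("<confusion_matrix> rows = true class\n")
  print(x$counts)
  invisible(x)
}

#' Correlation of neural and acoustic confusion patterns
#'
#' Pearson correlation between the row-normalized confusion matrices
#' (all cells by default), with the usual t-transform p-value.
#'
#' @param neural,acoustic `confusion_matrix` objects over the same classes
#'   in the same order.
#' @param cells `"all"` (default) or `"offdiag"`.
#' @return list with `r`, `p`, `n` (cells compared).
#' @export
confusion_correlation <- function(neural, acoustic,
                                  cells = c("all", "offdiag")) {
  cells <- match.arg(cells)
  if (!identical(neural$classes, acoustic$classes))
    stop_invalid("class orderings differ")
  rn <- function(m) m / rowSums(m)
  a <- rn(neural$counts); b <- rn(acoustic$counts)
  if (cells == "offdiag") {
    keep <- row(a) != col(a)
    a <- a[keep]; b <- b[keep]
  }
  pearson_with_p(as.vector(a), as.vector(b))
}
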