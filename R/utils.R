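# Internal helpers shared across modules.

stop_invalid <- function(...) stop(..., call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Saves and restores the caller's RNG state so that seeded generators do not
#' perturb the global random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop_invalid("`seed` must be a single finite number")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Strict lower triangle of a square matrix, column-major order.
lower_tri_vec <- function(m) m[lower.tri(m, diag = FALSE)]

# Sample index of the first sample at or after time `t` seconds
# (1-based; sample i sits at time (i - 1) / fs).
onset_sample <- function(t, fs) as.integer(ceiling(t * fs - 1e-9)) + 1L

# Zero-phase FIR filtering by FFT convolution with a symmetric, odd-length
# kernel; output aligned to the input (group delay removed).
fft_conv_centered <- function(x, h) {
  n <- length(x)
  nh <- length(h)
  if (nh %% 2L != 1L) stop_invalid("FIR kernel must have odd length")
  m <- (nh - 1L) %/% 2L
  len <- nextn(n + nh - 1L, c(2, 3, 5))
  X <- fft(c(x, numeric(len - n)))
  H <- fft(c(h, numeric(len - nh)))
  y <- Re(fft(X * H, inverse = TRUE)) / len
  y[(m + 1L):(m + n)]
}

# Pearson correlation with the usual t-transform p-value.
pearson_with_p <- function(x, y) {
  if (length(x) != length(y)) stop_invalid("vectors must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop_invalid("need at least 3 paired observations")
  if (sd(x) == 0 || sd(y) == 0)
    stop_invalid("correlation undefined for constant input")
  r <- cor(x, y)
  tt <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  list(r = r, p = 2 * pt(-abs(tt), df = n - 2), n = n)
}

# One-way ANOVA F computed column-wise for a units x columns matrix.
# Returns F, dfs and upper-tail p per column; infinite F (zero within-group
# variance with non-zero between-group variance) is kept as +Inf.
f_oneway_cols <- function(x, groups) {
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2L)
    stop_invalid("need at least 2 groups")
  groups <- droplevels(groups)
  if (any(table(groups) < 2L))
    stop_invalid("every group needs at least 2 units")
  n <- nrow(x)
  k <- nlevels(groups)
  gsize <- as.vector(table(groups))
  gsum <- rowsum(x, groups)
  gmean <- gsum / gsize
  grand <- colMeans(x)
  ssb <- colSums(gsize * (sweep(gmean, 2L, grand))^2)
  sst <- colSums(sweep(x, 2L, grand)^2)
  ssw <- pmax(sst - ssb, 0)
  df1 <- k - 1L
  df2 <- n - k
  f <- (ssb / df1) / (ssw / df2)
  f[ssw == 0 & ssb > 0] <- Inf
  f[ssw == 0 & ssb == 0] <- NaN
  p <- pf(f, df1, df2, lower.tail = FALSE)
  p[is.infinite(f)] <- 0
  list(f = f, df1 = df1, df2 = df2, p = p,
       exact_separation = any(ssw == 0 & ssb > 0))
}

# Full-precision number formatting for text serialization ("%.17g" is
# round-trip exact for IEEE doubles).
format_full <- function(x) sprintf("%.17g", x)

fraction_check <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0 || x >= 1)
    stop_invalid(sprintf("`%s` must lie strictly between 0 and 1", name))
  invisible(x)
}
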