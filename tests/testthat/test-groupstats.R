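# Group statistics: BH-FDR against the step-up definition, F series
# against aov, per-electrode maps, effect-size accumulation, the RLS
# classifier and confusion-pattern correlation.

# brute-force step-up evaluation of the BH definition
bh_oracle <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- which(ps <= q * seq_len(m) / m)
  out <- rep(FALSE, m)
  if (length(k)) out[o[seq_len(max(k))]] <- TRUE
  out
}

test_that("BH-FDR matches the hand-applied step-up rule", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.5), 0.05), c(TRUE, TRUE, FALSE))
  expect_false(any(bh_fdr(rep(1, 10), 0.05)))
  expect_true(all(bh_fdr(rep(0, 10), 0.05)))
  expect_error(bh_fdr(c(0.5, 1.2), 0.05), "\\[0, 1\\]")
  expect_error(bh_fdr(c(0.5, 0.1), 1.5), "between 0 and 1")

  set.seed(31)
  for (i in 1:200) {
    p <- runif(sample(3:40, 1))^sample(1:3, 1)
    q <- runif(1, 0.01, 0.2)
    expect_identical(bh_fdr(p, q), bh_oracle(p, q))
  }
})

test_that("manner F series equals the aov oracle and handles boundaries", {
  set.seed(32)
  x <- matrix(rnorm(24 * 10), 24, 10)
  g <- rep(c("plosive", "fricative", "nasal", "vowel"), each = 6)
  fs <- manner_f_series(x, g, q = 0.05)
  for (l in c(1, 5, 10)) {
    ref <- anova(lm(x[, l] ~ g))
    expect_lt(abs(fs$f[l] - ref$`F value`[1]), 1e-10)
    expect_lt(abs(fs$p[l] - ref$`Pr(>F)`[1]), 1e-10)
  }
  expect_equal(fs$df1, 3)
  expect_equal(fs$df2, 20)

  # null data: F near 1 on average
  set.seed(33)
  xn <- matrix(rnorm(40 * 500), 40, 500)
  gn <- rep(letters[1:4], each = 10)
  fn <- manner_f_series(xn, gn)
  expect_gt(mean(fn$f), 0.8)
  expect_lt(mean(fn$f), 1.25)

  # exact separation: zero within-group variance -> +Inf with flag
  xb <- matrix(c(0, 0, 10, 10), 4, 1)
  fb <- manner_f_series(xb, c("a", "a", "b", "b"))
  expect_true(is.infinite(fb$f[1]))
  expect_true(fb$exact_separation)
  expect_true(fb$sig[1])

  expect_error(manner_f_series(x, rep("a", 24)), "2 groups")
  expect_error(manner_f_series(x, c("b", rep("a", 23))), "at least 2 units")

  # acoustic and neural inputs share the code path: same values in,
  # same F out regardless of the source tag
  fs2 <- manner_f_series(x, g, source = "stimulus")
  expect_identical(fs$f, fs2$f)
})

test_that("per-electrode F maps localize planted discriminability", {
  # categories differ only on electrodes 1-2
  set.seed(34)
  k <- 12
  lag_ms <- seq(0, 100, by = 10)
  cats <- sprintf("C%02d", seq_len(k))
  manner <- rep(c("plosive", "vowel"), each = 6)
  names(manner) <- cats
  prps <- lapply(1:4, function(s) {
    vals <- array(rnorm(k * 4 * length(lag_ms), sd = 0.2),
                  dim = c(k, 4, length(lag_ms)),
                  dimnames = list(cats, paste0("E", 1:4), NULL))
    vals[manner == "vowel", 1:2, ] <- vals[manner == "vowel", 1:2, ] + 2
    prpkit:::new_prp_set(vals, counts = rep(10L, k), lag_ms = lag_ms,
                         electrodes = paste0("E", 1:4), subject = s)
  })
  maps <- per_electrode_f_maps(prps, manner,
                               windows = list(all = c(0, 100)))
  expect_setequal(rownames(maps)[order(-maps[, 1])][1:2],
                  c("E1", "E2"))

  # one window spanning every lag equals the mean per-lag F
  um <- prp_unit_matrix(prps, "E1")
  f_all <- manner_f_series(um$x, manner[um$category])
  expect_lt(abs(maps["E1", "all"] - mean(f_all$f)), 1e-10)

  expect_error(per_electrode_f_maps(prps, manner,
                                    windows = list(bad = c(0, 500))),
               "outside")
})

test_that("effect size accumulates over subjects and time", {
  ks <- kernel_spec()
  subjects <- lapply(1:3, function(s) {
    sim <- small_session(duration = 60, n_utterances = 6, seed = 40 + s,
                         noise_snr = 0)
    rec <- preprocess_rec(sim$recording)
    al <- exclude_utterance_onset_tokens(sim$alignment, 500)
    list(epochs = extract_epochs(rec, al, c(-100, 600)))
  })
  partition <- manner_partition(phoneme_inventory())
  grid <- effect_size_accumulation(subjects, partition,
                                   n_subjects_grid = c(1, 3),
                                   duration_grid_min = c(0.5, 1),
                                   electrode = "FCz", n_rep = 2, seed = 9)
  expect_true(all(is.finite(grid)))
  # more subjects and more data should not reduce the peak F (on average,
  # at this SNR the full cell exceeds the smallest cell clearly)
  expect_gt(grid["n3", "min1"], grid["n1", "min0.5"] * 0.5)

  expect_warning(
    effect_size_accumulation(subjects, partition, n_subjects_grid = c(2, 9),
                             duration_grid_min = 1, n_rep = 1, seed = 2),
    "truncated")
})

test_that("RLS classifier separates separable classes and fails shuffled
           labels at chance", {
  set.seed(35)
  k <- 4
  n_per <- 60
  templates <- matrix(rnorm(k * 40), k, 40) * 3
  x <- templates[rep(1:k, each = n_per), ] + rnorm(k * n_per * 40, sd = 0.5)
  y <- rep(c("plosive", "fricative", "nasal", "vowel"), each = n_per)
  fit <- rls_classifier(x, y, holdout = 0.2, seed = 1)
  expect_gt(fit$accuracy, 0.9)
  expect_equal(unname(rowSums(fit$confusion$counts)),
               as.vector(table(y)[fit$confusion$classes]) * 0.2,
               tolerance = 0.2)

  # shuffled labels: accuracy within the binomial band around chance
  set.seed(36)
  accs <- vapply(1:5, function(i) {
    rls_classifier(x, sample(y), holdout = 0.2, seed = i)$accuracy
  }, numeric(1))
  n_test <- k * n_per * 0.2
  band <- 3 * sqrt(0.25 * 0.75 / n_test)
  expect_lt(abs(mean(accs) - 0.25), band)

  expect_error(rls_classifier(x, rep("a", nrow(x))), "2 classes")
})

test_that("duplicating every epoch with a doubled penalty reproduces the
           fit", {
  set.seed(37)
  x <- matrix(rnorm(40 * 12), 40, 12)
  y <- rep(c("a", "b"), each = 20)
  classes <- c("a", "b")
  f1 <- prpkit:::fit_model(x, y, seq_len(40), lambda = 1, classes = classes)
  f2 <- prpkit:::fit_model(rbind(x, x), c(y, y), seq_len(80), lambda = 2,
                           classes = classes)
  xnew <- matrix(rnorm(5 * 12), 5, 12)
  s1 <- prpkit:::predict_rls(f1, xnew)
  s2 <- prpkit:::predict_rls(f2, xnew)
  expect_identical(s1, s2)
  w1 <- t(f1$alpha) %*% f1$xtr
  w2 <- t(f2$alpha) %*% f2$xtr
  expect_lt(max(abs(w1 - w2)), 1e-8)
})

test_that("confusion correlation is a Pearson r with t-based p", {
  cm <- function(m) structure(list(counts = m,
                                   class_accuracy = diag(m) / rowSums(m),
                                   classes = rownames(m)),
                              class = "confusion_matrix")
  m1 <- matrix(c(30, 5, 2, 3, 25, 6, 1, 4, 28), 3, 3,
               dimnames = list(letters[1:3], letters[1:3]))
  expect_equal(confusion_correlation(cm(m1), cm(m1))$r, 1)

  set.seed(38)
  m2 <- matrix(rpois(9, 20) + 1, 3, 3,
               dimnames = list(letters[1:3], letters[1:3]))
  res <- confusion_correlation(cm(m1), cm(m2))
  rn <- function(m) m / rowSums(m)
  ref <- cor.test(as.vector(rn(m1)), as.vector(rn(m2)))
  expect_lt(abs(res$r - unname(ref$estimate)), 1e-12)
  expect_lt(abs(res$p - ref$p.value), 1e-12)

  m3 <- m2; rownames(m3) <- colnames(m3) <- c("x", "y", "z")
  expect_error(confusion_correlation(cm(m1), cm(m3)), "orderings differ")
})

test_that("token-level units give a valid F series", {
  sim <- small_session(duration = 30, n_utterances = 6, seed = 44,
                       noise_snr = 0)
  rec <- preprocess_rec(sim$recording)
  ep <- extract_epochs(rec, exclude_utterance_onset_tokens(sim$alignment),
                       c(-100, 600))
  um <- epoch_unit_matrix(ep, "FCz")
  partition <- manner_partition(sim$inventory)
  fs <- manner_f_series(um$x, partition[um$category], q = 0.05,
                        lag_ms = um$lag_ms)
  expect_equal(length(fs$f), length(ep$lag_ms))
  expect_true(all(fs$f >= 0))
  # strong manner structure at the most selective component
  expect_true(any(fs$sig[abs(um$lag_ms - 120) <= 20]))
  expect_error(epoch_unit_matrix(ep, "Oz"), "not found")
})
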