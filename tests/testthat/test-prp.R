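# PRP core: epoch alignment, category averaging against brute-force
# oracles, rare-category filtering, matched spectrogram averages and
# baseline significance.

# -- local fixtures ---------------------------------------------------------

new_epoch_set_small <- function(vals) {
  prpkit:::new_epoch_set(
    array(vals, dim = c(length(vals), 1, 1)),
    data.frame(label = rep("AA", length(vals)), onset = seq_along(vals),
               offset = 2, speaker = "sp1", utterance = 1L),
    lag_ms = 0, fs = 1000, feature_labels = "Cz")
}

fake_prp <- function(counts) {
  k <- length(counts)
  vals <- array(rnorm(k * 2 * 3), dim = c(k, 2, 3),
                dimnames = list(names(counts), c("Cz", "FCz"), NULL))
  prpkit:::new_prp_set(vals, counts = unname(counts), lag_ms = 1:3,
                       electrodes = c("Cz", "FCz"))
}


test_that("epoch extraction is an alignment identity", {
  fs <- 500
  # constant recording -> constant epochs
  rec <- eeg_recording(matrix(3, 2, 5 * fs), fs, c("FCz", "Cz"))
  al <- phoneme_alignment(c("AA", "S"), c(1, 2), c(1.2, 2.2),
                          c("sp1", "sp1"), c(1L, 1L))
  ep <- extract_epochs(rec, al, c(-100, 600))
  expect_true(all(ep$epochs == 3))
  expect_equal(dim(ep$epochs), c(2, 2, 351))
  expect_equal(ep$meta$label, c("AA", "S"))     # token order preserved

  # impulse at the onset sample appears at lag 0
  rec2 <- eeg_recording(matrix(0, 1, 5 * fs), fs, "Cz")
  onset <- 1.0
  idx <- as.integer(ceiling(onset * fs - 1e-9)) + 1L
  rec2$values[1, idx] <- 1
  ep2 <- extract_epochs(rec2, phoneme_alignment("T", onset, 1.1, "sp1", 1L),
                        c(-100, 600))
  expect_equal(which(ep2$epochs[1, 1, ] != 0),
               which(ep2$lag_ms == 0))

  # tokens whose window leaves the recording are dropped with a message
  al3 <- phoneme_alignment(c("AA", "IY"), c(0.05, 4.9), c(0.2, 5.0),
                          c("sp1", "sp1"), c(1L, 1L))
  expect_message(suppressWarnings(ep3 <- extract_epochs(rec, al3,
                                                        c(-100, 600))),
                 "dropped")
  expect_equal(dim(ep3$epochs)[1], 0)

  # empty alignment -> empty epoch set with warning
  empty <- phoneme_alignment(character(0), numeric(0), numeric(0),
                             character(0), integer(0))
  expect_warning(ep4 <- extract_epochs(rec, empty), "empty")
  expect_equal(dim(ep4$epochs)[1], 0)
})

test_that("compute_prp equals the brute-force loop oracle", {
  sim <- small_session(duration = 20, seed = 11, noise_snr = 5)
  rec <- preprocess_rec(sim$recording)
  al <- exclude_utterance_onset_tokens(sim$alignment, 500)
  ep <- extract_epochs(rec, al, c(-100, 600))
  mask <- reject_artifact_epochs(ep, 10)
  prp <- compute_prp(ep, mask)

  # independent oracle: explicit loop over kept tokens
  keep <- which(mask$keep)
  labs <- ep$meta$label[keep]
  for (k in unique(labs)) {
    ix <- keep[labs == k]
    acc <- 0
    for (i in ix) acc <- acc + ep$epochs[i, , ]
    expect_lt(max(abs(prp$values[k, , ] - acc / length(ix))), 1e-12)
    expect_equal(prp$counts[match(k, prp$categories)], length(ix))
  }
  # category partition: counts add up to the kept tokens
  expect_equal(sum(prp$counts), length(keep))

  # simple arithmetic: epochs [1, 3] average to 2
  ep2 <- new_epoch_set_small(c(1, 3))
  prp2 <- compute_prp(ep2)
  expect_equal(unname(prp2$values[1, 1, 1]), 2)

  # single kept epoch: PRP equals that epoch exactly
  m <- reject_artifact_epochs(ep2, Inf); m$keep <- c(TRUE, FALSE)
  expect_equal(unname(compute_prp(ep2, m)$values[1, 1, 1]), 1)
})

test_that("PRP averaging is linear over concatenated epoch sets", {
  sim <- small_session(duration = 16, seed = 12)
  rec <- preprocess_rec(sim$recording)
  ep <- extract_epochs(rec, sim$alignment, c(-100, 600))
  n <- dim(ep$epochs)[1]
  half <- seq_len(n %/% 2)
  p1 <- compute_prp(subset_epochs(ep, half))
  p2 <- compute_prp(subset_epochs(ep, setdiff(seq_len(n), half)))
  pall <- compute_prp(ep)
  for (k in pall$categories) {
    i1 <- match(k, p1$categories); i2 <- match(k, p2$categories)
    n1 <- if (is.na(i1)) 0 else p1$counts[i1]
    n2 <- if (is.na(i2)) 0 else p2$counts[i2]
    v1 <- if (is.na(i1)) 0 else p1$values[k, , ]
    v2 <- if (is.na(i2)) 0 else p2$values[k, , ]
    expect_lt(max(abs(pall$values[k, , ] -
                        (n1 * v1 + n2 * v2) / (n1 + n2))), 1e-12)
  }
})

test_that("rare-category filtering applies the frequency floor", {
  prp <- fake_prp(counts = c(A = 999L, B = 1L))
  expect_equal(filter_rare_categories(prp, 1e-4)$categories, c("A", "B"))

  prp2 <- fake_prp(counts = c(A = 99999L, B = 5L))
  expect_equal(filter_rare_categories(prp2, 1e-4)$categories, "A")

  expect_identical(filter_rare_categories(prp2, 0), prp2)
  expect_error(filter_rare_categories(prp2, 0.99999), "every category")
})

test_that("average spectrograms match excised segments and the oracle", {
  set.seed(13)
  vals <- matrix(abs(rnorm(16 * 3000)), 16, 3000)
  spec <- auditory_spectrogram(vals, exp(seq(log(80), log(8000),
                                             length.out = 16)), 1000)
  al <- phoneme_alignment(c("AA", "AA", "S"), c(0.5, 1.2, 1.9),
                          c(0.6, 1.3, 2.0), rep("sp1", 3), rep(1L, 3))
  avg <- compute_avg_spectrograms(spec, al, c(-100, 600))

  # oracle: direct excision at the onset samples
  lags <- -100:600
  seg_at <- function(t) vals[, (as.integer(ceiling(t * 1000 - 1e-9)) + 1L) +
                               lags]
  expect_lt(max(abs(avg$values["S", , ] - seg_at(1.9))), 1e-12)
  expect_lt(max(abs(avg$values["AA", , ] -
                      (seg_at(0.5) + seg_at(1.2)) / 2)), 1e-12)

  # two identical tokens average to either segment
  al2 <- phoneme_alignment(c("IY", "IY"), c(0.5, 0.5),
                           c(0.6, 0.6), c("sp1", "sp2"), c(1L, 2L))
  avg2 <- compute_avg_spectrograms(spec, al2, c(0, 100))
  expect_lt(max(abs(avg2$values["IY", , ] -
                      vals[, 501 + 0:100])), 1e-12)
})

test_that("planted vowel templates are recoverable from average
           spectrograms", {
  inv <- phoneme_inventory()
  pars <- filterbank_params(n_channels = 64)
  spk <- default_speakers()
  # many repetitions of one vowel, one speaker
  onsets <- seq(0.5, 14, by = 0.45)
  al <- phoneme_alignment(rep("AA", length(onsets)), onsets,
                          onsets + 0.25, "sp1", rep(1L, length(onsets)))
  wav <- gen_stimulus_audio(al, inv, spk, fs = 16000, seed = 21)
  spec <- compute_auditory_spectrogram(wav, pars)
  avg <- compute_avg_spectrograms(spec, al, c(0, 250))
  prof <- rowMeans(avg$values["AA", , ])
  peak_ch <- which.max(prof)
  # lateral inhibition shifts energy toward the rising (low-frequency)
  # skirt of the formant, so allow 2 channels around F1 = 730 Hz
  target <- which.min(abs(pars$center_frequencies - 730))
  expect_lte(abs(peak_ch - target), 2)
})

test_that("baseline significance recovers a planted component window", {
  lag_ms <- seq(-100, 600, by = 2)
  bump <- exp(-0.5 * ((lag_ms - 120) / 20)^2)
  set.seed(14)
  prps <- lapply(1:20, function(s) {
    vals <- array(rep(bump, each = 2) * 1 +
                    rnorm(2 * length(lag_ms), sd = 0.15),
                  dim = c(1, 2, length(lag_ms)),
                  dimnames = list("AA", c("Cz", "FCz"), NULL))
    prpkit:::new_prp_set(vals, counts = 50L, lag_ms = lag_ms,
                         electrodes = c("Cz", "FCz"), subject = s)
  })
  res <- baseline_significance(prps, electrode = "Cz", q = 0.01)
  covering <- res$windows$from_ms <= 110 & res$windows$to_ms >= 130
  expect_true(any(covering))
  # lags far from the bump are not significant
  expect_false(any(res$sig[lag_ms < -20]))

  # all-zero PRPs: nothing significant
  zeros <- lapply(prps, function(p) { p$values[] <- 0; p })
  expect_false(any(baseline_significance(zeros, "Cz")$sig))

  # constant equal to baseline: difference 0 -> nothing significant
  const <- lapply(prps, function(p) { p$values[] <- 2; p })
  expect_false(any(baseline_significance(const, "Cz")$sig))

  expect_error(baseline_significance(prps[1], "Cz"), "2 subjects")
})

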