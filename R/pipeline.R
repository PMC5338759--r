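# Umbrella pipeline: configuration object with the study's stage defaults
# and an end-to-end runner over a synthetic (or ingested) session.

#' Pipeline configuration
#'
#' All stage parameters with their standard defaults: 2-15 Hz zero-phase
#' band-pass, +/-10 z-unit epoch rejection, 500 ms utterance-onset
#' exclusion, 0.01% category frequency floor, -100..600 ms epochs, 0-400 ms
#' clustering window, bootstrap n = 20, and FDR levels q = 0.01 (baseline),
#' 0.05 (F mask, speaker map), 0.001 (MDS zeroing), 1e-4 (covariance
#' bootstrap). Serializes losslessly through JSON.
#'
#' @param duration,n_utterances,n_electrodes,audio_fs,eeg_fs,analysis_fs
#'   synthetic-session geometry and rates.
#' @param noise_snr,artifact_rate EEG noise level (dB) and artifacts/min.
#' @param filter_low,filter_high band-pass edges in Hz.
#' @param reject_threshold epoch rejection threshold in z-units.
#' @param onset_exclusion_ms utterance-onset exclusion window.
#' @param rare_floor category frequency floor (fraction).
#' @param window,cluster_window epoch and clustering windows in ms.
#' @param lag_step_ms lag grid step for the covariance/speaker maps.
#' @param bootstrap_n bootstrap resamples.
#' @param q_baseline,q_f,q_mds,q_boot,q_speaker FDR levels.
#' @param holdout classifier held-out fraction.
#' @param seed master seed.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(duration = 120, n_utterances = 24,
                            n_electrodes = 16, audio_fs = 16000,
                            eeg_fs = 2000, analysis_fs = 1000,
                            noise_snr = 10, artifact_rate = 2,
                            filter_low = 2, filter_high = 15,
                            reject_threshold = 10,
                            onset_exclusion_ms = 500, rare_floor = 1e-4,
                            window = c(-100, 600),
                            cluster_window = c(0, 400), lag_step_ms = 10,
                            bootstrap_n = 20, q_baseline = 0.01, q_f = 0.05,
                            q_mds = 0.001, q_boot = 1e-4, q_speaker = 0.05,
                            holdout = 0.1, seed = 1) {
  cfg <- as.list(environment())
  if (cfg$duration <= 0) stop_invalid("`duration` must be > 0")
  if (cfg$filter_low <= 0 || cfg$filter_low >= cfg$filter_high)
    stop_invalid("invalid filter band")
  for (nm in c("q_baseline", "q_f", "q_mds", "q_boot", "q_speaker",
               "holdout", "rare_floor"))
    if (nm != "rare_floor") fraction_check(cfg[[nm]], nm)
  if (cfg$rare_floor < 0 || cfg$rare_floor >= 1)
    stop_invalid("`rare_floor` must be in [0, 1)")
  if (cfg$bootstrap_n < 2) stop_invalid("`bootstrap_n` must be >= 2")
  if (cfg$window[1] >= cfg$window[2]) stop_invalid("invalid epoch window")
  structure(cfg, class = "pipeline_config")
}

#' Serialize / restore a pipeline configuration
#' @param config a [pipeline_config()].
#' @return JSON string.
#' @export
config_to_json <- function(config) {
  jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = I(17))
}

#' @rdname config_to_json
#' @param json JSON string from [config_to_json()].
#' @export
config_from_json <- function(json) {
  do.call(pipeline_config, jsonlite::fromJSON(json))
}

#' Run the full analysis pipeline on a synthetic session
#'
#' Stages: simulate -> auditory spectrogram -> preprocess (band-pass,
#' z-score, resample) -> epoch + reject -> PRP / average spectrograms ->
#' distance series + covariance maps (with bootstrap significance) -> UPGMA
#' -> manner F series -> RLS classifiers and confusion correlation ->
#' speaker analyses (SE indices, SE correlation, speaker map, silhouettes).
#' Any stage failure aborts with the stage named. Rerunning with the same
#' configuration reproduces the bundle exactly.
#'
#' @param config a [pipeline_config()].
#' @param verbose print per-stage progress messages.
#' @return a result bundle (list) with per-stage outputs and `provenance`.
#' @export
run_pipeline <- function(config = pipeline_config(), verbose = TRUE) {
  stage <- function(name, expr) {
    if (verbose) message("[", name, "] ...")
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  cfg <- config

  sim <- stage("simulate", simulate_session(
    duration = cfg$duration, n_utterances = cfg$n_utterances,
    n_electrodes = cfg$n_electrodes, audio_fs = cfg$audio_fs,
    eeg_fs = cfg$eeg_fs, noise_snr = cfg$noise_snr,
    artifact_rate = cfg$artifact_rate, seed = cfg$seed))

  spec <- stage("spectrogram", compute_auditory_spectrogram(
    sim$audio, filterbank_params(frame_rate = cfg$analysis_fs)))

  rec <- stage("preprocess", {
    r <- bandpass_filter(sim$recording, cfg$filter_low, cfg$filter_high)
    r <- zscore_channels(r)
    resample_recording(r, cfg$analysis_fs)
  })

  alignment <- stage("screen", exclude_utterance_onset_tokens(
    sim$alignment, cfg$onset_exclusion_ms))

  epochs <- stage("epoch", extract_epochs(rec, alignment, cfg$window))
  mask <- stage("reject", reject_artifact_epochs(epochs,
                                                 cfg$reject_threshold))
  kept <- subset_epochs(epochs, which(mask$keep))

  prp <- stage("prp", filter_rare_categories(
    compute_prp(epochs, mask), cfg$rare_floor))

  sspec <- stage("avg-spectrogram", {
    # token-level acoustic epochs only needed on the coarse analysis grid
    acoustic_epochs <- extract_spectrogram_epochs(
      spec, alignment, cfg$window, lag_step_ms = cfg$lag_step_ms)
    aligned <- align_epoch_sets(kept, acoustic_epochs)
    list(epochs = aligned$b, neural_epochs = aligned$a,
         set = compute_avg_spectrograms(spec, alignment, cfg$window,
                                        mask = NULL))
  })

  rsa <- stage("rsa", {
    dn <- pairwise_distance_series(prp)
    da <- pairwise_distance_series(sspec$set)
    boot <- bootstrap_significance(
      coarsen_epochs(sspec$neural_epochs, cfg$lag_step_ms),
      coarsen_epochs(sspec$epochs, cfg$lag_step_ms),
      n = cfg$bootstrap_n, q = cfg$q_boot, seed = cfg$seed + 7)
    list(neural = dn, acoustic = da, neural_acoustic = boot)
  })

  clustering <- stage("upgma", upgma_cluster(prp, cfg$cluster_window))

  fstats <- stage("fstat", {
    um <- prp_unit_matrix(prp, "FCz")
    partition <- manner_partition(sim$inventory)
    manner_f_series(um$x, partition[um$category], q = cfg$q_f,
                    lag_ms = um$lag_ms, source = "response")
  })

  classify <- stage("classify", {
    partition <- manner_partition(sim$inventory)
    xn <- flatten_epochs(kept, cfg$cluster_window)
    yn <- partition[kept$meta$label]
    neural <- rls_classifier(xn, yn, holdout = cfg$holdout,
                             seed = cfg$seed + 11)
    xa <- flatten_epochs(sspec$epochs, cfg$cluster_window)
    ya <- partition[sspec$epochs$meta$label]
    acoustic <- rls_classifier(xa, ya, holdout = cfg$holdout,
                               seed = cfg$seed + 11)
    list(neural = neural, acoustic = acoustic,
         confusion_r = confusion_correlation(neural$confusion,
                                             acoustic$confusion))
  })

  speaker <- stage("speaker", {
    ids <- sort(unique(kept$meta$speaker))
    prps_by <- lapply(ids, function(s)
      compute_prp(subset_epochs(kept, which(kept$meta$speaker == s))))
    common <- intersect(prps_by[[1]]$categories, prps_by[[2]]$categories)
    prps_by <- lapply(prps_by, subset_categories, common)
    specs_by <- lapply(ids, function(s) {
      al <- alignment[alignment$speaker == s, , drop = FALSE]
      class(al) <- c("phoneme_alignment", "data.frame")
      compute_avg_spectrograms(spec, al, cfg$window)
    })
    specs_by <- lapply(specs_by, subset_categories, common)
    se_n <- se_index(prps_by[[1]], prps_by[[2]], cfg$cluster_window)
    se_a <- se_index(specs_by[[1]], specs_by[[2]], cfg$cluster_window)
    manner <- manner_partition(sim$inventory)[common]
    map <- speaker_neural_acoustic_map(prps_by[[1]], prps_by[[2]],
                                       specs_by[[1]], specs_by[[2]],
                                       q = cfg$q_speaker,
                                       lag_step_ms = cfg$lag_step_ms)
    sil <- speaker_silhouettes(prps_by, manner, cfg$cluster_window)
    list(prps_by_speaker = prps_by, specs_by_speaker = specs_by,
         se_neural = se_n, se_acoustic = se_a,
         se_r = se_correlation(se_n, se_a), map = map,
         silhouettes = sil, manner = manner)
  })

  list(config = cfg, alignment = alignment, spectrogram = spec,
       recording = rec, epochs = kept, rejection = mask, prp = prp,
       avg_spectrograms = sspec$set, rsa = rsa, clustering = clustering,
       f_series = fstats, classification = classify, speaker = speaker,
       provenance = list(package = "prpkit",
                         version = as.character(
                           utils::packageVersion("prpkit")),
                         seed = cfg$seed,
                         config_json = as.character(config_to_json(cfg))))
}

# Keep every lag_step-th lag of an epoch set (coarse grid for the
# covariance bootstrap).
coarsen_epochs <- function(epochs, lag_step_ms) {
  step0 <- diff(epochs$lag_ms[1:2])
  by <- max(1L, as.integer(round(lag_step_ms / step0)))
  sel <- seq(1L, length(epochs$lag_ms), by = by)
  new_epoch_set(epochs$epochs[, , sel, drop = FALSE], epochs$meta,
                epochs$lag_ms[sel], epochs$fs, epochs$feature_labels,
                epochs$feature_kind)
}

token_key <- function(meta) {
  paste(meta$label, format(meta$onset, digits = 12))
}

# Restrict two epoch sets to their common tokens, in identical order.
align_epoch_sets <- function(a, b) {
  ka <- token_key(a$meta); kb <- token_key(b$meta)
  common <- intersect(ka, kb)
  list(a = subset_epochs(a, match(common, ka)),
       b = subset_epochs(b, match(common, kb)))
}

# Restrict a prp_set / avg_spectrogram_set to the given categories.
subset_categories <- function(set, categories) {
  idx <- match(categories, set$categories)
  set$values <- set$values[idx, , , drop = FALSE]
  set$counts <- set$counts[idx]
  set$categories <- categories
  set
}

# Manner (S1), speaker (S2) and within-vowel speaker (S3) silhouettes of
# the speaker-resolved PRP items.
speaker_silhouettes <- function(prps_by, manner, window) {
  f1 <- speaker_features(prps_by[[1]], window)
  f2 <- speaker_features(prps_by[[2]], window)
  feats <- rbind(f1, f2)
  cats <- prps_by[[1]]$categories
  manner_lab <- rep(manner[cats], 2L)
  speaker_lab <- rep(c("sp1", "sp2"), each = length(cats))
  vowels <- manner[cats] == "vowel"
  s3 <- if (sum(vowels) >= 2L)
    silhouette_index(rbind(f1[vowels, , drop = FALSE],
                           f2[vowels, , drop = FALSE]),
                     rep(c("sp1", "sp2"), each = sum(vowels)))
  else NA_real_
  c(S1_manner = silhouette_index(feats, manner_lab),
    S2_speaker = silhouette_index(feats, speaker_lab),
    S3_speaker_vowels = s3)
}
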