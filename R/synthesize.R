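# Synthetic-data module: phoneme sequences, stimulus audio rendered from
# per-category spectral templates, and forward-modelled EEG with known
# ground truth.

# Log-normal duration parameters per manner (seconds). Means chosen at
# plausible conversational-speech scale; vowels longest, plosives shortest.
.duration_mean <- c(plosive = 0.060, fricative = 0.090, nasal = 0.095,
                    vowel = 0.110)
.duration_sdlog <- 0.5

#' Generate a phoneme sequence for two alternating speakers
#'
#' Tokens tile each utterance without gaps or overlaps; utterances alternate
#' between the two speakers; category durations are log-normal with
#' manner-dependent means and category identities are drawn uniformly.
#'
#' @param inventory a [phoneme_inventory()].
#' @param total_duration total stimulus duration in seconds (> 0).
#' @param n_utterances number of equal-length utterances.
#' @param speakers list of two [speaker_profile()]s.
#' @param seed integer seed; identical seeds give identical alignments.
#' @return a [phoneme_alignment()].
#' @export
gen_phoneme_sequence <- function(inventory, total_duration, n_utterances = 10,
                                 speakers = default_speakers(), seed = 1) {
  if (!inherits(inventory, "phoneme_inventory") ||
      length(inventory$labels) == 0L)
    stop_invalid("`inventory` must be a non-empty phoneme inventory")
  if (!is.numeric(total_duration) || total_duration <= 0)
    stop_invalid("`total_duration` must be > 0")
  if (length(speakers) != 2L) stop_invalid("exactly two speakers required")
  utt_dur <- total_duration / n_utterances
  with_seed(seed, {
    rows <- vector("list", n_utterances)
    for (u in seq_len(n_utterances)) {
      t0 <- (u - 1) * utt_dur
      t_end <- u * utt_dur
      sp <- speakers[[if (u %% 2L == 1L) 1L else 2L]]$speaker_id
      lab <- character(0); on <- numeric(0); off <- numeric(0)
      t <- t0
      while (t < t_end - 1e-9) {
        k <- sample(inventory$labels, 1L)
        mn <- inventory$manner[[k]]
        mu <- log(.duration_mean[[mn]]) - .duration_sdlog^2 / 2
        d <- rlnorm(1L, mu, .duration_sdlog)
        lab <- c(lab, k); on <- c(on, t); off <- c(off, min(t + d, t_end))
        t <- t + d
      }
      # avoid a vanishing final sliver: merge into the previous token
      n <- length(lab)
      if (n > 1L && off[n] - on[n] < 0.015) {
        off[n - 1L] <- off[n]
        lab <- lab[-n]; on <- on[-n]; off <- off[-n]
      }
      rows[[u]] <- data.frame(label = lab, onset = on, offset = off,
                              speaker = sp, utterance = u,
                              stringsAsFactors = FALSE)
    }
    df <- do.call(rbind, rows)
    phoneme_alignment(df$label, df$onset, df$offset, df$speaker, df$utterance)
  })
}

# Spectral template envelope evaluated at frequencies f (Hz) for one
# phoneme profile under a speaker's formant scale.
profile_envelope <- function(profile, f, formant_scale = 1) {
  env <- numeric(length(f))
  for (i in seq_along(profile$cf)) {
    env <- env + profile$gain[i] *
      exp(-0.5 * ((f - profile$cf[i] * formant_scale) / profile$bw[i])^2)
  }
  env + 1e-3
}

max_profile_frequency <- function(inventory, speakers) {
  fs_max <- max(vapply(speakers, `[[`, numeric(1), "formant_scale"))
  max(vapply(inventory$profiles, function(p) max(p$cf), numeric(1))) * fs_max
}

# Render one token: voiced manners are harmonic complexes at the speaker's
# f0 shaped by the template; fricatives are template-shaped noise; plosives
# are a sudden broadband burst decaying into a low noise floor.
render_token <- function(n, fs, profile, manner, speaker) {
  if (n <= 0L) return(numeric(0))
  t <- (seq_len(n) - 1L) / fs
  if (manner %in% c("vowel", "nasal")) {
    f0 <- speaker$f0
    nh <- max(1L, floor((fs / 2 - 1) / f0))
    h <- seq_len(nh)
    w <- profile_envelope(profile, h * f0, speaker$formant_scale)
    ph <- runif(nh, 0, 2 * pi)
    x <- as.vector(cos(outer(t, 2 * pi * h * f0) +
                         matrix(ph, n, nh, byrow = TRUE)) %*% w)
  } else {
    x <- rnorm(n)
    spec <- fft(x)
    f <- (seq_len(n) - 1L) / n * fs
    f <- ifelse(f > fs / 2, fs - f, f)
    spec <- spec * profile_envelope(profile, f, speaker$formant_scale)
    x <- Re(fft(spec, inverse = TRUE)) / n
    if (manner == "plosive") {
      burst <- exp(-t / 0.015)
      x <- x * (burst + 0.02)
    }
  }
  r <- sqrt(mean(x^2))
  if (r > 0) x <- x / r * profile$level
  # raised-cosine on/off ramps for amplitude continuity (sudden plosive onset)
  ramp_on <- if (manner == "plosive") max(1L, round(0.0005 * fs))
             else min(n, round(0.005 * fs))
  ramp_off <- min(n, round(0.005 * fs))
  if (ramp_on > 1L) {
    w <- 0.5 * (1 - cos(pi * seq(0, 1, length.out = ramp_on)))
    x[seq_len(ramp_on)] <- x[seq_len(ramp_on)] * w
  }
  if (ramp_off > 1L) {
    w <- 0.5 * (1 + cos(pi * seq(0, 1, length.out = ramp_off)))
    x[(n - ramp_off + 1L):n] <- x[(n - ramp_off + 1L):n] * w
  }
  x
}

#' Render stimulus audio from a phoneme alignment
#'
#' Each token is synthesized from its category's spectral template scaled by
#' the speaker's formant scale and fundamental frequency: vowels and nasals
#' as harmonic complexes, fricatives as shaped noise, plosives as sudden
#' broadband bursts.
#'
#' @param alignment a [phoneme_alignment()].
#' @param inventory the [phoneme_inventory()] the alignment was drawn from.
#' @param speakers list of two [speaker_profile()]s.
#' @param fs audio sampling rate in Hz; must exceed twice the highest
#'   template frequency.
#' @param seed integer seed.
#' @return list with `samples` (numeric vector in \[-1, 1\]) and `fs`,
#'   of class `waveform`.
#' @export
gen_stimulus_audio <- function(alignment, inventory,
                               speakers = default_speakers(), fs = 16000,
                               seed = 1) {
  fmax <- max_profile_frequency(inventory, speakers)
  if (fs < 2 * fmax)
    stop_invalid(sprintf(
      "fs = %g Hz is below twice the highest template frequency (%g Hz)",
      fs, fmax))
  n_total <- if (nrow(alignment) == 0L) 0L
             else as.integer(ceiling(max(alignment$offset) * fs))
  x <- numeric(n_total)
  sp_by_id <- setNames(speakers, vapply(speakers, `[[`, "", "speaker_id"))
  with_seed(seed, {
    for (i in seq_len(nrow(alignment))) {
      i0 <- onset_sample(alignment$onset[i], fs)
      i1 <- min(n_total, onset_sample(alignment$offset[i], fs) - 1L)
      if (i1 < i0) next
      lab <- alignment$label[i]
      seg <- render_token(i1 - i0 + 1L, fs, inventory$profiles[[lab]],
                          inventory$manner[[lab]],
                          sp_by_id[[alignment$speaker[i]]])
      x[i0:i1] <- x[i0:i1] + seg
    }
  })
  peak <- max(abs(x), 1e-12)
  if (peak > 1) x <- x / peak
  structure(list(samples = x, fs = fs), class = "waveform")
}

#' Forward-model EEG from a phoneme alignment
#'
#' The recording is the superposition, over tokens, of the token's
#' category/speaker kernel placed at the token onset, plus 1/f background
#' noise at the stated SNR and sparse high-amplitude artifact transients.
#'
#' @param alignment a [phoneme_alignment()].
#' @param kernels a [kernel_spec()].
#' @param n_electrodes number of electrodes (>= 1).
#' @param fs EEG sampling rate in Hz.
#' @param noise_snr signal-to-noise ratio in dB (`Inf` disables noise).
#' @param artifact_rate expected artifacts per minute (>= 0; 0 disables).
#' @param seed integer seed.
#' @param inventory,speakers,montage generation context; defaults match
#'   [gen_phoneme_sequence()].
#' @return list with `recording` (an [eeg_recording()]) and `ground_truth`
#'   (class `ground_truth`, recording everything planted).
#' @export
gen_eeg <- function(alignment, kernels = kernel_spec(), n_electrodes = 16,
                    fs = 2000, noise_snr = 10, artifact_rate = 2, seed = 1,
                    inventory = phoneme_inventory(),
                    speakers = default_speakers(),
                    montage = default_montage(n_electrodes)) {
  if (n_electrodes < 1L) stop_invalid("`n_electrodes` must be >= 1")
  if (!is.numeric(artifact_rate) || artifact_rate < 0)
    stop_invalid("`artifact_rate` must be >= 0")
  if (!is.numeric(noise_snr) || is.na(noise_snr))
    stop_invalid("`noise_snr` must be numeric (dB) or Inf")
  if (nrow(alignment) == 0L) stop_invalid("empty alignment")

  amp <- kernel_amplitudes(kernels, inventory, speakers, montage)
  support_ms <- max(kernels$component_latencies) +
    4 * max(kernels$component_widths)
  sp_ids <- dimnames(amp)[[2]]
  nc <- length(kernels$component_latencies)
  kern <- vector("list", length(inventory$labels) * 2L)
  dim(kern) <- c(length(inventory$labels), 2L)
  for (ki in seq_along(inventory$labels))
    for (si in 1:2)
      kern[[ki, si]] <- kernel_waveform(
        kernels, matrix(amp[ki, si, , ], n_electrodes, nc), fs, support_ms)

  lk <- ncol(kern[[1, 1]])
  n <- as.integer(ceiling((max(alignment$offset) + support_ms / 1000 + 0.1) *
                            fs))
  rec <- matrix(0, n_electrodes, n)
  kidx <- match(alignment$label, inventory$labels)
  sidx <- match(alignment$speaker, sp_ids)
  for (i in seq_len(nrow(alignment))) {
    i0 <- onset_sample(alignment$onset[i], fs)
    cols <- i0:(i0 + lk - 1L)
    rec[, cols] <- rec[, cols] + kern[[kidx[i], sidx[i]]]
  }
  sig_var <- mean(rec^2)

  noise_sd <- 0
  artifact_times <- numeric(0)
  with_seed(seed, {
    if (is.finite(noise_snr)) {
      noise_sd <- sqrt(sig_var / 10^(noise_snr / 10))
      for (e in seq_len(n_electrodes))
        rec[e, ] <- rec[e, ] + noise_sd * pink_noise(n, fs)
    }
    if (artifact_rate > 0) {
      n_art <- rpois(1L, artifact_rate * n / fs / 60)
      if (n_art > 0) {
        artifact_times <- sort(runif(n_art, 0, n / fs - 0.25))
        amp_art <- 15 * max(sd(as.vector(rec)), 1e-12)
        w_art <- as.integer(round(0.2 * fs))
        # boxcar-windowed 8 Hz burst: sits inside the 2-15 Hz analysis
        # band, so its amplitude survives the downstream band-pass
        burst <- amp_art * sin(2 * pi * 8 * (seq_len(w_art) - 1L) / fs)
        for (ta in artifact_times) {
          j0 <- onset_sample(ta, fs)
          cols <- j0:(j0 + w_art - 1L)
          rec[, cols] <- rec[, cols] + rep(burst, each = n_electrodes)
        }
      }
    }
  })

  gt <- structure(list(
    kernel_spec = kernels, amplitudes = amp, montage = montage,
    categories = inventory$labels, manner = inventory$manner,
    speaker_ids = sp_ids, fs = fs, support_ms = support_ms,
    noise = list(snr_db = noise_snr, sd = noise_sd),
    artifact_times = artifact_times, artifact_width_s = 0.2,
    speaker_separation = kernels$speaker_separation, seed = seed),
    class = "ground_truth")
  list(recording = eeg_recording(rec, fs, montage$labels),
       ground_truth = gt)
}

# 1/f ("pink") noise via spectral shaping of white noise, unit variance.
pink_noise <- function(n, fs) {
  white <- rnorm(n)
  spec <- fft(white)
  f <- (seq_len(n) - 1L) / n * fs
  f <- pmin(f, fs - f)
  shape <- 1 / sqrt(pmax(f, 1))   # flat below 1 Hz, 1/f power above
  x <- Re(fft(spec * shape, inverse = TRUE)) / n
  as.vector(scale(x))
}

#' Noise-free forward predictions of the per-speaker PRPs
#'
#' Evaluates the planted kernels on a lag grid, giving the PRPs the
#' pipeline would recover with no noise and no overlap between neighbouring
#' tokens. One `prp_set` per speaker.
#'
#' @param ground_truth a `ground_truth` from [gen_eeg()].
#' @param fs_out lag-grid rate in Hz.
#' @param window lag window in ms, `c(from, to)`.
#' @return named list of two [prp_set][compute_prp] objects.
#' @export
ideal_prps <- function(ground_truth, fs_out = 1000, window = c(-100, 600)) {
  gt <- ground_truth
  lag_ms <- seq(window[1], window[2], by = 1000 / fs_out)
  k <- length(gt$categories)
  e <- length(gt$montage$labels)
  spec <- gt$kernel_spec
  comp <- vapply(seq_along(spec$component_latencies), function(ci) {
    v <- exp(-0.5 * ((lag_ms - spec$component_latencies[ci]) /
                       spec$component_widths[ci])^2)
    v[lag_ms < 0] <- 0   # kernels are causal: no pre-onset energy
    v
  }, numeric(length(lag_ms)))
  out <- list()
  for (si in 1:2) {
    vals <- array(0, dim = c(k, e, length(lag_ms)),
                  dimnames = list(gt$categories, gt$montage$labels, NULL))
    nc <- length(spec$component_latencies)
    for (ki in seq_len(k))
      vals[ki, , ] <- matrix(gt$amplitudes[ki, si, , ], e, nc) %*% t(comp)
    out[[gt$speaker_ids[si]]] <-
      new_prp_set(vals, counts = rep(1L, k), lag_ms = lag_ms,
                  electrodes = gt$montage$labels,
                  subject = paste0("ideal-", gt$speaker_ids[si]))
  }
  out
}

#' Simulate a complete synthetic session
#'
#' Convenience wrapper: sequence, audio and EEG from one seed, with the
#' sub-seeds derived deterministically.
#'
#' @param duration stimulus duration in seconds.
#' @param n_utterances utterance count.
#' @param n_electrodes EEG electrode count.
#' @param audio_fs,eeg_fs sampling rates.
#' @param noise_snr,artifact_rate EEG noise and artifact parameters.
#' @param kernels a [kernel_spec()].
#' @param seed integer seed.
#' @param render_audio set `FALSE` to skip the audio waveform (EEG-only use).
#' @return list with `alignment`, `audio`, `recording`, `ground_truth`,
#'   `inventory`, `speakers`.
#' @export
simulate_session <- function(duration = 120, n_utterances = 24,
                             n_electrodes = 16, audio_fs = 16000,
                             eeg_fs = 2000, noise_snr = 10,
                             artifact_rate = 2, kernels = kernel_spec(),
                             seed = 1, render_audio = TRUE) {
  inventory <- phoneme_inventory()
  speakers <- default_speakers()
  alignment <- gen_phoneme_sequence(inventory, duration, n_utterances,
                                    speakers, seed = seed)
  audio <- if (render_audio)
    gen_stimulus_audio(alignment, inventory, speakers, fs = audio_fs,
                       seed = seed + 1000L)
  else NULL
  ee <- gen_eeg(alignment, kernels, n_electrodes, fs = eeg_fs,
                noise_snr = noise_snr, artifact_rate = artifact_rate,
                seed = seed + 2000L, inventory = inventory,
                speakers = speakers)
  list(alignment = alignment, audio = audio, recording = ee$recording,
       ground_truth = ee$ground_truth, inventory = inventory,
       speakers = speakers)
}
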