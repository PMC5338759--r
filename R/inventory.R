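# Phoneme inventory, speaker profiles and the evoked-response kernel model
# used by the synthetic-data generator.

#' American English phoneme inventory
#'
#' A 30-category ARPAbet inventory covering the four manners of articulation
#' (plosive, fricative, nasal, vowel). Each phoneme carries a spectral
#' template: Gaussian bumps described by center frequencies, bandwidths and
#' relative gains, plus an overall rendering level. Vowel templates use
#' typical first/second formant values; fricatives peak at high frequencies;
#' plosives are broadband; nasals are low-frequency dominated and spectrally
#' suppressed.
#'
#' @return an object of class `phoneme_inventory`: a list with `labels`,
#'   `manner` (named character), and `profiles` (named list with fields
#'   `cf`, `bw`, `gain`, `level`).
#' @export
phoneme_inventory <- function() {
  v <- function(f1, f2) list(cf = c(f1, f2), bw = c(90, 140),
                             gain = c(1, 0.5), level = 1)
  p <- function(cf, bw) list(cf = cf, bw = bw, gain = 1, level = 0.9)
  f <- function(cf, bw, g = 0.8) list(cf = cf, bw = bw, gain = 1, level = g)
  n <- function(f1) list(cf = c(f1, 2200), bw = c(70, 300),
                         gain = c(1, 0.15), level = 0.5)
  profiles <- list(
    # vowels (12)
    IY = v(270, 2290), IH = v(390, 1990), EY = v(450, 2100),
    EH = v(530, 1840), AE = v(660, 1720), AA = v(730, 1090),
    AO = v(570, 840),  OW = v(490, 910),  UH = v(440, 1020),
    UW = v(300, 870),  AH = v(640, 1190), ER = v(490, 1350),
    # plosives (6)
    P = p(1500, 1800), B = p(1200, 1500), T = p(4000, 2500),
    D = p(3200, 2200), K = p(2200, 1800), G = p(1900, 1600),
    # fricatives (9)
    S = f(6000, 1400), Z = f(5600, 1400), SH = f(3300, 1200),
    ZH = f(3100, 1200), F = f(4800, 2500, 0.5), V = f(3800, 2200, 0.5),
    TH = f(5200, 2600, 0.45), DH = f(4200, 2400, 0.5),
    HH = f(1700, 1500, 0.5),
    # nasals (3)
    M = n(250), N = n(280), NG = n(320)
  )
  manner <- c(rep("vowel", 12), rep("plosive", 6), rep("fricative", 9),
              rep("nasal", 3))
  names(manner) <- names(profiles)
  stopifnot(all(vapply(profiles, function(q) all(q$cf > 0) && all(q$bw > 0) &&
                         all(q$gain >= 0) && q$level >= 0, logical(1))))
  structure(list(labels = names(profiles), manner = manner,
                 profiles = profiles),
            class = "phoneme_inventory")
}

#' Manner-of-articulation partition of an inventory
#'
#' @param inventory a [phoneme_inventory()].
#' @return named character vector, phoneme -> manner.
#' @export
manner_partition <- function(inventory) inventory$manner

# Scalar acoustic projection of a spectral template: gain-weighted mean
# log center frequency. Used to couple EEG kernel amplitudes to acoustics.
acoustic_scalar <- function(profile) {
  sum(profile$gain * log(profile$cf)) / sum(profile$gain)
}

inventory_acoustic_z <- function(inventory) {
  a <- vapply(inventory$profiles, acoustic_scalar, numeric(1))
  as.vector(scale(a))
}

#' Speaker profile
#'
#' @param speaker_id character id.
#' @param f0 fundamental frequency in Hz (> 0).
#' @param formant_scale unitless multiplier applied to template center
#'   frequencies (> 0); models vocal-tract length differences.
#' @param amplitude_map optional named numeric vector of per-phoneme EEG
#'   kernel gain modifiers.
#' @return object of class `speaker_profile`.
#' @export
speaker_profile <- function(speaker_id, f0, formant_scale = 1,
                            amplitude_map = NULL) {
  if (!is.numeric(f0) || f0 <= 0) stop_invalid("`f0` must be > 0")
  if (!is.numeric(formant_scale) || formant_scale <= 0)
    stop_invalid("`formant_scale` must be > 0")
  structure(list(speaker_id = as.character(speaker_id), f0 = f0,
                 formant_scale = formant_scale,
                 amplitude_map = amplitude_map),
            class = "speaker_profile")
}

#' Default pair of alternating speakers
#'
#' A male-like speaker (f0 = 110 Hz) and a female-like speaker (f0 = 220 Hz,
#' formants scaled up 15%).
#'
#' @return list of two [speaker_profile()] objects.
#' @export
default_speakers <- function() {
  list(speaker_profile("sp1", f0 = 110, formant_scale = 1),
       speaker_profile("sp2", f0 = 220, formant_scale = 1.15))
}

# 10-20 style electrode labels ordered so that small montages retain the
# electrodes the analyses single out (FCz, Cz, T7/T8).
.montage_labels <- c(
  "FCz", "Cz", "Fz", "C3", "C4", "T7", "T8", "Pz", "F3", "F4", "P3", "P4",
  "Fp1", "Fp2", "O1", "O2", "F7", "F8", "FC3", "FC4", "CP3", "CP4", "CPz",
  "P7", "P8", "POz", "Oz", "AF3", "AF4", "FT7", "FT8", "TP7", "TP8",
  "C1", "C2", "C5", "C6", "F1", "F2", "F5", "F6", "P1", "P2", "P5", "P6",
  "FC1", "FC2", "FC5", "FC6", "CP1", "CP2", "CP5", "CP6", "PO3", "PO4",
  "PO7", "PO8", "AF7", "AF8", "FPz", "PO9", "PO10")

#' Default EEG montage
#'
#' Electrode labels plus frontocentral topography weights used by the EEG
#' forward model (evoked activity strongest at FCz/Cz, weakest occipitally).
#'
#' @param n_electrodes number of electrodes (1..62).
#' @return list with `labels` and `weights`.
#' @export
default_montage <- function(n_electrodes = 16) {
  if (n_electrodes < 1 || n_electrodes > length(.montage_labels))
    stop_invalid("`n_electrodes` must be in 1..", length(.montage_labels))
  labels <- .montage_labels[seq_len(n_electrodes)]
  w <- vapply(labels, function(l) {
    if (l == "FCz") 1.0
    else if (l == "Cz") 0.9
    else if (grepl("^FC", l)) 0.85
    else if (grepl("^(FT|TP|T)", l)) 0.5
    else if (grepl("^CP", l)) 0.6
    else if (grepl("^C", l)) 0.75
    else if (grepl("^(Fp|AF|FP)", l)) 0.4
    else if (grepl("^F", l)) 0.65
    else if (grepl("^(PO|O)", l)) 0.3
    else if (grepl("^P", l)) 0.45
    else 0.3
  }, numeric(1))
  list(labels = labels, weights = unname(w))
}

#' Evoked-response kernel specification
#'
#' Describes the per-phoneme EEG response kernel planted by the forward
#' model: a sum of Gaussian-windowed components at fixed latencies. Component
#' amplitudes are modulated by manner of articulation (signed gains, so late
#' components can flip polarity between obstruents and sonorants), by a
#' continuous acoustic projection of each phoneme's spectral template
#' (`acoustic_coupling`, per component), and by speaker
#' (`speaker_separation` scales the targeted manner/component for speaker 2
#' relative to speaker 1).
#'
#' @param component_latencies component centers in ms, strictly increasing.
#' @param component_widths Gaussian sigma per component in ms, > 0.
#' @param manner_gains 4 x C signed gain matrix, rows plosive, fricative,
#'   nasal, vowel.
#' @param acoustic_coupling length-C coupling of amplitudes to the acoustic
#'   scalar (0 = category-independent component).
#' @param speaker_separation scalar >= 0; 0 makes the two speakers' kernels
#'   identical.
#' @param speaker_target list(manner=, component=) where the separation is
#'   injected (default: vowels on the 230-ms component).
#' @return object of class `kernel_spec`.
#' @export
kernel_spec <- function(component_latencies = c(50, 120, 230, 400),
                        component_widths = c(15, 20, 30, 40),
                        manner_gains = NULL,
                        acoustic_coupling = c(0.05, 0.5, 0.4, 0.3),
                        speaker_separation = 0.5,
                        speaker_target = list(manner = "vowel",
                                              component = 3L)) {
  nc <- length(component_latencies)
  if (nc < 1L || any(diff(component_latencies) <= 0))
    stop_invalid("component latencies must be strictly increasing")
  if (length(component_widths) != nc || any(component_widths <= 0))
    stop_invalid("component widths must be positive, one per component")
  if (is.null(manner_gains)) {
    manner_gains <- rbind(
      plosive   = c(1.30,  1.05, 0.45,  0.65),
      fricative = c(0.60,  0.60, 0.85,  0.45),
      nasal     = c(0.40, -0.80, 0.70, -0.60),
      vowel     = c(0.90, -0.80, 1.30, -0.60))[, seq_len(nc), drop = FALSE]
  }
  if (!is.matrix(manner_gains) || nrow(manner_gains) != 4L ||
      ncol(manner_gains) != nc)
    stop_invalid("`manner_gains` must be a 4 x n_components matrix")
  if (length(acoustic_coupling) != nc)
    stop_invalid("`acoustic_coupling` needs one entry per component")
  if (speaker_separation < 0)
    stop_invalid("`speaker_separation` must be >= 0")
  rownames(manner_gains) <- c("plosive", "fricative", "nasal", "vowel")
  structure(list(component_latencies = component_latencies,
                 component_widths = component_widths,
                 manner_gains = manner_gains,
                 acoustic_coupling = acoustic_coupling,
                 speaker_separation = speaker_separation,
                 speaker_target = speaker_target),
            class = "kernel_spec")
}

# Amplitude array [category, speaker, electrode, component] realized from a
# kernel spec for a given inventory / speaker pair / montage.
kernel_amplitudes <- function(spec, inventory, speakers, montage) {
  k <- length(inventory$labels)
  nc <- length(spec$component_latencies)
  e <- length(montage$labels)
  az <- inventory_acoustic_z(inventory)
  amp <- array(0, dim = c(k, 2L, e, nc),
               dimnames = list(inventory$labels,
                               vapply(speakers, `[[`, "", "speaker_id"),
                               montage$labels, NULL))
  for (ki in seq_len(k)) {
    g <- spec$manner_gains[inventory$manner[ki], ]
    base <- g * (1 + spec$acoustic_coupling * az[ki])
    for (si in 1:2) {
      sgain <- base
      tgt <- spec$speaker_target
      if (si == 2L && inventory$manner[ki] == tgt$manner)
        sgain[tgt$component] <- sgain[tgt$component] *
          (1 + spec$speaker_separation)
      am <- speakers[[si]]$amplitude_map
      if (!is.null(am) && inventory$labels[ki] %in% names(am))
        sgain <- sgain * am[[inventory$labels[ki]]]
      amp[ki, si, , ] <- outer(montage$weights, sgain)
    }
  }
  amp
}

# Kernel waveform (electrode x sample) for one category/speaker at a given
# sampling rate, supported on [0, support_ms].
kernel_waveform <- function(spec, amp_ke, fs, support_ms = 600) {
  t_ms <- seq(0, support_ms, by = 1000 / fs)
  nc <- length(spec$component_latencies)
  comp <- vapply(seq_len(nc), function(ci) {
    exp(-0.5 * ((t_ms - spec$component_latencies[ci]) /
                  spec$component_widths[ci])^2)
  }, numeric(length(t_ms)))            # samples x components
  amp_ke %*% t(comp)                    # electrodes x samples
}
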