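# Shared fixtures: small synthetic sessions and a preprocessing shortcut.
# Sizes are deliberately modest so the full suite runs quickly; the
# acceptance tests use larger sessions.

small_session <- function(duration = 20, n_utterances = 4, n_electrodes = 4,
                          eeg_fs = 500, noise_snr = 10, artifact_rate = 0,
                          kernels = kernel_spec(), seed = 1,
                          render_audio = FALSE, audio_fs = 16000) {
  simulate_session(duration = duration, n_utterances = n_utterances,
                   n_electrodes = n_electrodes, audio_fs = audio_fs,
                   eeg_fs = eeg_fs, noise_snr = noise_snr,
                   artifact_rate = artifact_rate, kernels = kernels,
                   seed = seed, render_audio = render_audio)
}

# band-pass + z-score (+ optional resample), the standard preprocessing
preprocess_rec <- function(rec, analysis_fs = rec$fs) {
  r <- bandpass_filter(rec, 2, 15)
  r <- zscore_channels(r)
  resample_recording(r, analysis_fs)
}

# session -> subject PRP (screening + rejection applied)
session_prp <- function(sim, window = c(-100, 600), subject = NA,
                        threshold = 10) {
  rec <- preprocess_rec(sim$recording)
  al <- exclude_utterance_onset_tokens(sim$alignment, 500)
  ep <- extract_epochs(rec, al, window)
  mask <- reject_artifact_epochs(ep, threshold)
  compute_prp(ep, mask, subject = subject)
}

expect_symmetric_zero_diag <- function(m, tol = 1e-10) {
  expect_lt(max(abs(m - t(m))), tol)
  expect_equal(unname(diag(m)), rep(0, nrow(m)))
}
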