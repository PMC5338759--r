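---
title: "Phoneme-related potentials from continuous speech: models and methods"
author: "prpkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phoneme-related potentials from continuous speech: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Event-related-potential methods traditionally require isolated,
non-overlapping stimuli. `prpkit` implements the alternative of treating
every phoneme instance in *continuous* speech as an event: the EEG is
epoched at forced-aligned phoneme onsets and averaged per phoneme category,
yielding the phoneme-related potential

$$\mathrm{PRP}(k, e, \tau) = \frac{1}{N_k} \sum_{n=1}^{N_k}
r(e,\, T_{kn} + \tau),$$

where $r(e, t)$ is the preprocessed response of electrode $e$, $T_{kn}$ the
onset of the $n$-th instance of category $k$, and $\tau$ the lag relative
to onset (window $-100..600$ ms). The matched stimulus representation is
the average auditory spectrogram $\bar S(k, f, \tau)$, computed with the
same epoching from a peripheral auditory model $s(f, t)$. All downstream
analyses — time-resolved distance matrices, lag-by-lag covariance maps,
manner-of-articulation F statistics, classifiers and speaker-encoding
indices — compare these two representations.

Because the original human recordings are not available, the package ships
a first-class synthetic-data module whose ground truth makes every stage
testable by parameter recovery.

## The synthetic session

`gen_phoneme_sequence()` tiles each utterance with tokens drawn uniformly
from a 30-category ARPAbet inventory; utterances alternate between two
speakers. Durations are log-normal per manner (means 60 ms plosives, 90 ms
fricatives, 95 ms nasals, 110 ms vowels; sdlog 0.5, i.e. a coefficient of
variation near one half, in line with the large spread of phone durations
in natural speech). Durations matter beyond realism: a token's duration
sets where its *neighbours'* responses fall inside its epoch, so
duration distributions that are both manner-dependent and broad make the
generator reproduce the context effects that continuous speech inflicts
on any event-locked average.

`gen_stimulus_audio()` renders each token from its category's spectral
template (Gaussian bumps at formant-like center frequencies): vowels and
nasals as harmonic complexes at the speaker's $f_0$ (110 vs 220 Hz by
default), fricatives as spectrally shaped noise, plosives as sudden
broadband bursts with a 15 ms decay. The second speaker's template
frequencies are scaled by 1.15, modelling a shorter vocal tract. Audio is
16 kHz mono.

`gen_eeg()` superposes, at every token onset, a causal response kernel: a
sum of Gaussian components at 50/120/230/400 ms (sigma 15/20/30/40 ms).
Component amplitudes factor into

* a signed manner gain (4 x 4 matrix). The defaults make the average
  response largest at the first component, the manner *contrast* largest at
  the second, and flip polarity between obstruents and sonorants on
  components 2 and 4 — so the fourth component is invisible in the grand
  average but strong in the F statistic, and the top split of a UPGMA tree
  is obstruent/sonorant. The four components' contrast variances are kept
  within a factor of ~3 of each other; if one component dwarfs the others,
  its filtered tails bias the neighbouring components' apparent peak
  latencies (see *Known biases* below).
* a continuous coupling to each category's acoustic template (the
  gain-weighted mean log center frequency, standardized). This is what
  makes neural phoneme distances mirror acoustic phoneme distances. The
  first component's coupling is kept small (0.05): early evoked activity
  is dominated by sound onset rather than category identity.
* a frontocentral electrode topography (FCz strongest).
* a speaker factor: speaker 2's gain on the 230-ms component of vowels is
  scaled by `1 + speaker_separation` (default 0.5). Setting the separation
  to 0 makes the two speakers' kernels identical — the null used by the
  speaker-index tests.

Background noise is 1/f with a configurable SNR (dB, total power relative
to the clean superposition). Artifacts are 200-ms boxcar-windowed 8 Hz
bursts with amplitude 15 standard deviations, Poisson-placed at a
configurable rate; the 8 Hz carrier sits inside the 2–15 Hz analysis band
so the planted amplitude survives filtering and the ±10 rejection rule is
genuinely exercised. Everything planted is recorded in a serializable
`ground_truth` object, and `ideal_prps()` returns the overlap-free forward
predictions used by exactness tests.

What the generator does **not** emulate: intelligible speech,
coarticulation (token categories are i.i.d.), realistic head-model lead
fields, non-stationary noise, or eye-blink topographies. Passing recovery
tests therefore demonstrates the correctness of the analysis chain, not
the physiological claims themselves.

## The peripheral auditory model

`compute_auditory_spectrogram()` chains: (1) a cochlear filterbank of 128
gammatone filters (Slaney second-order-section implementation) equally
spaced in log frequency over 80 Hz–8 kHz — on the log axis a gammatone's
upper skirt falls more steeply than its lower skirt, matching the
asymmetric cochlear description; (2) a hair-cell stage: sign-preserving
cube-root compression followed by a second-order 2 kHz low-pass; (3)
lateral inhibition: the first difference along the channel axis,
half-wave rectified; (4) the per-band envelope: frame means at 1 kHz
(rectify-then-smooth; 1-ms frames put acoustic and EEG lags on one grid).

Edge handling for the spectral derivative replicates channel 1 (it is
differenced against itself), so a spectrally flat input maps to zero in
*every* channel while the channel count is preserved. The whole chain is
fused in compiled code and streamed channel-by-channel, so hour-long audio
never materializes a full band matrix; the staged R functions
(`cochlear_filterbank()` etc.) expose the identical arithmetic for tests.

## Preprocessing

The band-pass (2–15 Hz, the band where the PRP's power concentrates,
peaking near the syllabic rate) is a zero-phase symmetric FIR applied by
centered FFT convolution. It is built as the cascade of a *sharp*
high-pass at 2 Hz (1 Hz transition; >40 dB at 1 Hz, removes DC and drift)
and a *gentle* low-pass at 15 Hz (transition `high/2`). The gentle upper
edge matters: a sharp 15 Hz cutoff rings with a ~67 ms period — precisely
the spacing of the two early response components — and measurably shifts
recovered component latencies; the relaxed transition still leaves >50 dB
attenuation one octave above the passband.

Channels are z-scored (constant channels dropped with a warning),
decimated to the 1 kHz analysis grid, epoched over −100..600 ms with the
onset mapped to the first sample at or after $T_{kn}$ (half-open token
intervals), and epochs with any sample beyond ±10 z-units are rejected.
Tokens within 500 ms of their utterance onset are excluded before
epoching; categories holding <0.01% of all phones are dropped after
averaging.

## Statistics

* **F time courses** (`manner_f_series()`): one-way ANOVA F per lag;
  the default observation unit is the per-subject, per-category PRP value
  at one electrode (FCz), matching a grand-average analysis; token-level
  matrices can be passed instead. The acoustic ("stimulus") series uses
  the identical code path with RMS-over-frequency category values.
  Masks are Benjamini–Hochberg at q = 0.05.
* **Distance series and covariance maps**: Euclidean distances between
  category vectors per lag; covariance of strict lower triangles across
  lag pairs (covariance is shift-invariant, so using distances or their
  m − D similarity transform gives identical maps; m averages all matrix
  entries including the zero diagonal). Significance is by stratified
  token bootstrap (resampling with replacement within category, keeping
  every category populated): per cell, t = bootstrap mean / bootstrap sd
  with df = n − 1, two-sided, BH at q = 1e-4. A percentile p-value cannot
  resolve q = 1e-4 from n = 20 resamples (its floor is ~2/(n+1) ≈ 0.1),
  so the t approximation is the only form under which this q is
  attainable; its null calibration is verified by simulation in the test
  suite.
* **Clustering and embedding**: UPGMA via average-linkage `hclust` (ties
  resolved by its deterministic internal rule), exported to ultrametric
  `ape` trees/Newick; non-metric MDS by `MASS::isoMDS` (Kruskal stress-1)
  with seeded jittered classical starts, best of 8 kept, centered, sign
  fixed by the first category. Lags with no significant electrode emit
  all-zero coordinates in trajectory mode. Classical scaling is used
  directly when it already attains ~zero stress (isoMDS rejects some
  degenerate exact configurations). Zero off-diagonal distances are
  nudged by a relative 1e-6 before isoMDS.
* **Classifier**: one-vs-rest ridge ("regularized least squares") on
  flattened feature-by-lag epochs, solved in the dual (Gram) form since
  features far outnumber epochs; penalty chosen on an inner stratified
  split, accuracy reported on a 10% stratified holdout. Confusion
  patterns are compared by Pearson correlation of row-normalized
  matrices (all 16 cells by default; off-diagonal-only available).
* **Speaker encoding**: the 2K x 2K speaker-resolved distance matrix has
  within-speaker diagonal quadrants and between-speaker off-diagonal
  quadrants. `speaker_index()` = mean within − mean between over matched
  off-diagonal pairs (the same-phoneme diagonal is excluded so identity
  gives exactly zero). The per-phoneme SE index is

  $$SE(i) = \frac{1}{K-1}\sum_{j \ne i}
  \frac{(d_{BS1}(i,j) + d_{BS2}(i,j)) - (d_{WS1}(i,j) + d_{WS2}(i,j))}{2},$$

  zero under speaker identity and increasing with separation; it is not
  constrained to be non-negative. The speaker-dependent neural-acoustic
  map correlates, per lag pair, the between-minus-within contrast over
  strict-upper-triangle phoneme pairs; the same-phoneme diagonal is
  excluded there because, being a norm of an estimate difference, it is
  positive under pure noise in both spaces and would make every lag pair
  appear correlated. For the same reason each speaker's category means
  are centered across categories per lag before distances are taken: a
  speaker-global offset (the smeared response to neighbouring same-speaker
  tokens, or a global pitch offset acoustically) carries no
  category-specific speaker information but would otherwise bleed into
  the between-speaker distances at every lag.

## Numerical and design choices

* Times are seconds externally, sample indices internally; token
  intervals are half-open; the onset sample is the first at or after the
  onset time.
* Exactness under speaker identity is tested on `ideal_prps()`: with
  contiguous tokens, neighbouring-kernel overlap leaks into
  pipeline-estimated PRPs, so the full pipeline is only *approximately*
  symmetric across speakers even without noise.
* Delimited text formats write `%.17g`, which round-trips IEEE doubles
  exactly; ground truth serializes to JSON at 17 significant digits.
* EEG I/O is delimited text (+ JSON header); alignments read/write Praat
  TextGrid (labels `PHONE|speaker|utterance`) and TSV; audio is 16-bit
  PCM WAV.

### Known biases (and why they are expected)

Continuous speech means overlapping responses. Two visible consequences in
synthetic recoveries: (1) component latencies recovered from F-statistic
local maxima carry a few milliseconds of systematic bias, because
neighbouring tokens' average responses are time-locked to the current
token through its manner-dependent *duration*; (2) distance structure at
negative neural lags can correlate with the acoustics of *preceding*
phonemes. Both effects mirror phenomena the method exhibits on real
speech and are part of what the recovery tolerances absorb.

### Problem sizes in the test suite

The suite favours many modest sessions over few large ones: module tests
use 10–20 s sessions at 250–500 Hz with 2–6 electrodes; recovery tests use
cohorts of 12 synthetic subjects x 90 s (component latencies) and 20
seeded runs of 150 s sessions with 16 electrodes (speaker effects); the
averaging oracle runs one five-minute session at the full 128-channel,
1 kHz analysis resolution; null calibration uses 200 reduced-size
simulations. These sizes were chosen once, as the smallest at which the
planted effects are comfortably powered.

## Limitations

* Unequal category counts leave a small genuine covariance between any
  two distance maps (rarer categories have noisier means, hence larger
  expected distances in every space). The null-calibration tests
  therefore use balanced category counts; applied studies should keep
  this nuisance in mind when categories are heavily imbalanced.
* The forward model is linear and stationary; no refractoriness or
  adaptation across repeated phonemes.
* Acoustic rendering is template-based; formant transitions and
  coarticulation are absent, so acoustic category structure is somewhat
  cleaner than in natural speech.
* The package analyses one subject-session at a time; group analyses
  operate on lists of per-subject results (no mixed-effects modelling).
* EDF ingestion is out of scope; EEG exchange is via the delimited text
  format.
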