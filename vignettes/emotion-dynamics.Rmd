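---
title: "Linking EEG emotion dynamics to cognitive load: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking EEG emotion dynamics to cognitive load: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(emodyn)
```

## The scientific question

Emotion dynamics research asks not what someone feels but *how fast their
feelings change*. `emodyn` implements a complete EEG pipeline for one
specific hypothesis from multimedia-learning research: **learners under
higher cognitive load undergo slower emotional changes**. The pipeline
turns multichannel EEG into two per-participant scalars — a rate of
emotional change and an index of cognitive load — and fits the linear
relation between them across participants:

    ZCR_EC = alpha * CLI + beta

A negative slope `alpha` means emotional activity slows as load rises.

The emulated study design is a two-condition between-subjects experiment
(a "grayscale" and a "color" learning-material condition, 19 participants
each), 5-minute recordings from 15 electrodes of the 10/20 system at
125 Hz. Because the original recordings are not required, the package
ships a synthetic-cohort generator with known ground truth, so every stage
— and the headline sign — can be tested end to end.

## The pipeline, stage by stage

**Preprocessing** (`preprocess_recording()`, `epoch_signal()`). Band-stop
at mains (default 50 ± 2 Hz), FIR high-pass at 1 Hz, FIR low-pass at
50 Hz, then common-average re-referencing. All filters are windowed-sinc
(Hamming) designs applied forward–backward, i.e. zero-phase; filter orders
target roughly 40 dB of stop-band attenuation given each transition width.
Internally the cascade is combined into a single symmetric kernel and
applied by FFT convolution with odd-reflection edge padding, and channels
are mean-centred first so DC is removed exactly rather than to within
design ripple. Signals are cut into non-overlapping 4-s epochs
(half-open sample intervals; a trailing partial epoch is dropped). ICA
artifact removal is deliberately not implemented in-package: the
synthetic data are artifact-free, and for real data an external ICA
cleanup can be injected through the `artifact_remover` hook of
`preprocess_recording()`, which runs between filtering and
re-referencing.

**Spectral features** (`emd()`, `hilbert_spectrum()`, `band_powers()`).
Band powers use the Hilbert–Huang transform rather than Fourier methods:
empirical mode decomposition with cubic-spline envelopes (Cauchy-type SD
stopping criterion < 0.2, at most 10 sifts per IMF and 12 IMFs; extrema
mirrored at the boundaries so 4-s epochs do not suffer end swings), then
per-IMF analytic-signal amplitude and instantaneous frequency (phase
unwrapping, centred differences, negative frequencies clipped into the
lowest bin), binned at 0.1 Hz resolution. Powers are averaged within the
five rhythms — delta 0–3.9, theta 3.9–7.8, alpha 7.8–13.7, beta
13.7–29.3, gamma 29.3–46.9 Hz — giving 5 × 15 = 75 features per epoch.
Whether the feature vector should be per epoch or averaged per recording
is ambiguous in the source design; both are emitted
(`band_feature_matrix(per_epoch = )`).

**Wavelet features** (`wavelet_packet()`, `wavelet_entropy()`). A 5-level
periodised Daubechies-10 wavelet-packet decomposition yields 32 uniform
leaves of fs/64 ≈ 1.95 Hz; leaves are sequency-ordered so contiguous leaf
indices map to the rhythm table above (delta = leaves 1–2, …, gamma =
16–24; the beta/gamma boundary is taken as 15|16 so the ranges are
disjoint, consistent with the frequency edges). Energy ratios
`R_i = E_i / E_total` and the wavelet entropy `We = -sum R_i ln R_i`
follow; since the rhythms cover only 0–46.9 Hz of the analysed band,
`sum(R) <= 1`. The choice of a 5-level tree is forced by the 32-leaf
geometry; db10 is used as the mother wavelet. No wavelet-packet
implementation existed in the target environment, so the transform is
implemented here and checked against orthonormality and Parseval
identities in the tests.

**Complexity features** (`approximate_entropy()` and friends,
`sliding_feature_series()`). Four estimators, all validated against
brute-force direct-count oracles: ApEn (Pincus: self-matches included,
`Phi^m` means over `n - m + 1` templates), SampEn (Richman–Moorman:
self-matches excluded, pairs counted over the first `n - m` templates,
`-ln(A/B)`), permutation entropy (ordinal patterns, stride 1, ties by
order of appearance, bits) and state-space correlation entropy. For
SSCEn the pieces of the delay embedding are stacked and the correlation
matrix between all pairs of pieces is formed; the reading in which the
matrix is only `D x D` would leave three numbers to histogram for
`D = 3`, which cannot support a K-bin histogram, so the Gram matrix
between pieces is used. The series is mean-centred before embedding so
that, together with range-relative bins and the SD-relative ApEn/SampEn
tolerance (`r = F * sd`), every estimator is invariant under positive
affine transforms of the input — a property the tests enforce. Defaults
`m = 2`, `F = 0.2`, `D = 3`, `K = 16` are the canonical literature
choices; windows are 5 s (about one cycle of emotional change),
non-overlapping. Degenerate inputs: a constant series gets a tolerance
floor `r >= 1e-12` (ApEn 0 rather than 0/0), and an undefined SampEn
(no matches at length `m + 1`) raises a typed error instead of returning
a silently large value.

One practical caveat the tests make visible: at 5-s windows (625
samples), ApEn operates near its finite-sample ceiling for broadband
signals, so its dynamic range across conditions is small even when its
group difference is highly significant; PEn and SSCEn carry most of the
within-recording dynamics.

**Trajectory** (`cfs_select()`, `isomap_embed()`). Windowed features from
the seven emotion-related channels (Fp1, F7, T7, Cz, T8, P8, O2) are
pooled across participants and ranked by correlation-based feature
selection: greedy forward search on the merit
`k r̄_cf / sqrt(k + k(k-1) r̄_ff)` with Pearson correlations and the
condition label coded 0/1. "Subject-independent" is operationalised as a
leave-one-subject-out screen: a feature must keep the sign of its pooled
label correlation in at least 80% of the leave-one-out replicates. (A
per-subject within-subject correlation is not computable here because the
label is constant within a subject; the LOSO variant is this package's
definition.) The top 15 features then go through Isomap **per subject**:
symmetric k-NN graph (k = 10 by default; incremented with a message if
disconnected), all-pairs Dijkstra geodesics, classical MDS of squared
geodesics, top coordinate scaled by the root eigenvalue. Each subject's
1-D emotion trajectory is zero-mean with an arbitrary sign (fixed so the
first nonzero value is positive); the downstream crossing count is
sign-invariant anyway. Per-subject embedding is used because pooled
embedding would entangle participants' time courses.

**Dynamics and the fit** (`zcr_ec()`, `cognitive_load_index()`,
`fit_modulation()`). The trajectory is quantified by a zero-crossing
count: binomial high-pass filters of order k (`L_k`, equal to the
(k−1)-th backward difference; k = 1 is the identity), binarisation at 0
(with `>=` mapping to 1), and the count of symbol changes. The reported
statistic is k = 1 — the plain zero-crossing count the method's prose
describes — with orders up to M = 4 stored. The cognitive load index is
the engagement ratio beta/(theta + alpha) with band-specific channel
subsets (eight frontal/temporal/occipital sites for alpha, eight
frontal/central sites for beta, all 15 for theta), per 4-s epoch, averaged
per subject; epochs with non-positive denominators are excluded with a
message. Both scalars enter an ordinary least-squares fit across
participants; `raw_signal_zcr()` provides the raw-signal counterpart
(crossing counts of the zero-meaned emotion channels themselves), whose
slope against CLI is expected *positive* — faster raw oscillation under
load — while the trajectory slope is expected *negative*.

**Group statistics** (`one_way_anova()`, `stats_report()`). One-way
between-subjects ANOVA per feature with partial eta squared
`SS_b / (SS_b + SS_w)`, plus a Shapiro–Wilk normality screen that is
reported but never gates anything. Degrees of freedom are always computed
from the data supplied. (A side observation: published effect sizes of
the form ηp² with F at df (1, 37) reproduce exactly under
ηp² = F/(F + 36), i.e. with 36 within-group degrees of freedom; the
package never hard-codes either choice.)

## The synthetic cohort: what it emulates and what it does not

`generate_cohort()` encodes the study conditions:

* Two conditions, 19 participants each; 125 Hz; the 15-channel montage.
* Per-condition rhythm mix (`band_gains`, relative powers): the grayscale
  condition gets the beta-rich, broadband mix (beta 1.3, gamma 0.9
  against theta 0.6/alpha 0.7), the color condition the alpha-dominated
  mix (alpha 1.3, theta 1.1, beta 0.5, gamma 0.35). Grayscale therefore
  has the higher engagement index beta/(theta+alpha) *and* the higher
  signal complexity — the directions reported for the emulated study —
  and the generator derives its ground truth from these gains rather
  than storing it.
* A latent emotion state per participant: a smooth stationary Gaussian
  process with squared-exponential covariance, whose correlation length
  is set by the Rice formula so its expected sign-change rate equals
  `emotion_rate` (3/min for grayscale, 8/min for color). A rougher
  autoregressive state was tried first and rejected: its sign changes are
  fast jitter that 5-s window averaging erases, so the configured rate
  would be invisible to the feature pipeline. Smoothness, not just the
  nominal rate, is what makes the rate recoverable.
* The state modulates the **alpha-rhythm amplitude** on the seven emotion
  channels (`exp(depth * state)`, depth 1.0). This choice is deliberate:
  every complexity estimator in the pipeline is scale-invariant, so a
  whole-channel amplitude modulation would be invisible downstream.
  Modulating the alpha-to-broadband mix moves windowed complexity
  through its steepest operating range, mimicking alpha waxing/waning
  with emotional state.
* Between-subject dispersion: lognormal jitter (SD 0.1) on band gains and
  noise scales, per participant, with derived seeds `seed + index`. The
  emulated study reports no within-condition dispersion for CLI or
  ZCR_EC, so this knob is a free modelling choice, fixed once.
* Units are arbitrary; channels are z-scored, as the pipeline is
  scale-covariant apart from SD-relative entropy tolerances.

Not emulated: ocular/muscle artifacts, volume conduction and channel
correlation structure, non-stationary drifts, individual alpha-peak
variation. Passing tests therefore demonstrate that the *method* recovers
the constructed effect directions under realistic noise levels — not that
real recordings would show them.

## Problem sizes and numerical choices

End-to-end checks run the full study design (38 participants) at 60-s
recordings over 30 replicate cohorts — a size at which the slope's sign,
not its magnitude, is the stable quantity. The published magnitudes of
`alpha` depend on the original recordings and are not desk-reproducible;
the reproducible claims are the signs (trajectory slope negative,
raw-signal slope positive) and the group ordering of the complexity
measures, and those are what the tests assert. Tolerances: EMD
reconstruction 1e-8 relative; Hilbert energy conservation 1e-6; Parseval
1e-6; entropy oracles 1e-9; band-gain recovery 15% relative; latent-rate
recovery 20% relative.

## Known limitations

* EMD uses a fixed sifting budget; on pathological inputs an IMF may
  violate the extrema/zero-crossing balance slightly.
* The Gram-matrix reading of SSCEn is a documented interpretation of an
  ambiguous published definition (see above).
* CFS ranks features greedily; it does not revisit earlier choices.
* Isomap embeddings of very short window series (a dozen points) are
  noisy; the crossing count inherits that noise, which is why stability
  is assessed across replicate cohorts rather than within one.
* File I/O is CSV/JSON only; EDF input is out of scope for this build.
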