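# emodyn

EEG analysis pipeline linking **emotion dynamics** to **cognitive load**
during multimedia learning, built for a two-condition between-subjects
design (19 participants per condition, 15-channel 10/20 montage, 125 Hz).

The question the pipeline answers: *do learners under higher cognitive
load undergo slower emotional changes?* Each participant's multichannel
EEG is reduced to two scalars and their relation is fitted across
participants:

- **ZCR_EC** — the rate of emotional change: sliding-window complexity
  features (approximate, permutation and state-space correlation entropy)
  over seven emotion-related channels (Fp1, F7, T7, Cz, T8, P8, O2) are
  ranked by correlation-based feature selection (CFS), embedded per
  subject with Isomap into a one-dimensional emotion trajectory, and
  quantified by a zero-crossing-rate statistic (binomial high-pass
  filters `L_k`, binarisation at zero, symbol-change count).
- **CLI** — the engagement index of cognitive load,
  `beta / (theta + alpha)`, from Hilbert–Huang band powers of 4-s epochs
  over band-specific channel subsets.

The headline model is the least-squares fit

    ZCR_EC = alpha * CLI + beta

where `alpha < 0` means emotional activity slows as load rises. A
synthetic-EEG cohort generator with known ground truth (per-condition
rhythm mixes, a smooth latent emotion state with a calibrated sign-change
rate) stands in for the study's recordings, so the whole chain is
testable offline.

## Worked example

```r
library(emodyn)
cfg <- default_pipeline_config(seed = 1, cohort = list(duration = 60))
res <- run_pipeline(cfg, out_dir = "results/run1")
res$fit_trajectory
res$fit_raw
res$report[, c("feature", "F", "df1", "df2", "p", "eta_p2")]
```

which prints (numbers from this exact call):

```
<modulation_fit> ZCR_EC = -10.6304 * CLI + 5.4702  (se(alpha) = 3.2141, n = 38)
<modulation_fit> ZCR_EC = 3960.2899 * CLI + 1457.6808  (se(alpha) = 154.1650, n = 38)
  feature        F df1 df2            p    eta_p2
1    apen 174.4179   1  36 2.275861e-15 0.8289119
2     pen 348.6220   1  36 4.205040e-20 0.9064016
3   sscen 119.3593   1  36 5.546277e-13 0.7682791
```

Reading: across the 38 synthetic participants the emotion-trajectory
crossing rate *falls* with cognitive load (negative slope — the grayscale
high-load group, mean CLI 0.209, shows slower emotional change than the
color low-load group, mean CLI 0.068), while the raw-signal crossing rate
*rises* with load (positive slope — more violent raw oscillation). The
high-load group also shows significantly higher complexity on all three
entropy features. These are the three effect directions the pipeline is
designed to recover; slope magnitudes depend on the recordings analysed.

The same stages can be driven step by step from the numbered scripts in
`analysis/` (`01_simulate.R`, `02_pipeline.R`, `03_seed_stability.R`),
each of which writes its tables under `results/`.

## Package layout

- `R/` — the pipeline: synthetic cohorts (`generate_cohort`),
  preprocessing (`preprocess_recording`, `epoch_signal`), Hilbert–Huang
  band powers (`emd`, `hilbert_spectrum`, `band_powers`), wavelet-packet
  rhythm energies and entropy (`wavelet_packet`, `wavelet_entropy`),
  complexity estimators (`approximate_entropy`, `sample_entropy`,
  `permutation_entropy`, `state_space_correlation_entropy`), trajectory
  construction (`cfs_select`, `isomap_embed`), dynamics (`zcr_ec`,
  `cognitive_load_index`, `fit_modulation`), group statistics
  (`one_way_anova`, `stats_report`) and the end-to-end driver
  (`analyze_cohort`, `run_pipeline`).
- `src/` — C++ kernels for EMD sifting and entropy template counting.
- `vignettes/emotion-dynamics.Rmd` — the methods vignette: models,
  parameter choices, generator design, numerical decisions, limitations.
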