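# The cohort study behind the end-to-end checks is expensive, so it is run
# once per test session and cached; several test files read from it.
cohort_study_env <- new.env(parent = emptyenv())

cohort_study <- function(n_seeds = 30, duration = 60) {
  key <- sprintf("study_%d_%d", n_seeds, duration)
  if (!is.null(cohort_study_env[[key]])) return(cohort_study_env[[key]])
  out <- vector("list", n_seeds)
  for (s in seq_len(n_seeds)) {
    cfg <- default_pipeline_config(seed = s, cohort = list(duration = duration))
    res <- analyze_cohort(cfg)
    out[[s]] <- list(alpha_traj = res$fit_trajectory$alpha,
                     alpha_raw = res$fit_raw$alpha,
                     subjects = res$subjects,
                     report = res$report,
                     ground_truth_sign = res$ground_truth$true_modulation_sign)
  }
  cohort_study_env[[key]] <- out
  out
}
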