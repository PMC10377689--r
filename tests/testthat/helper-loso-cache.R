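# Heavy leave-one-subject-out runs shared by several acceptance checks.
# Computed lazily once per test session and cached.

.loso_cache <- new.env(parent = emptyenv())

study_spec <- function(seed, class_contrast = 0.8) {
  cohort_spec(n_subjects = 6, trials_per_class = 20,
              class_contrast = class_contrast, snr = 5, subject_sigma = 0.3,
              seed = seed)
}

study_train_cfg <- function(seed) {
  training_config(max_epochs = 60, seed = seed)
}

loso_study_runs <- function() {
  if (!is.null(.loso_cache$runs)) {
    return(.loso_cache$runs)
  }
  seeds <- c(11L, 22L, 33L)
  runs <- lapply(seeds, function(s) {
    cohort <- generate_cohort(study_spec(s))
    tc <- study_train_cfg(s)
    list(
      seed = s,
      msaenet = run_loso(cohort, msaenet_config(input_size = 12),
                         train_cfg = tc, return_features = TRUE),
      withoutloss = run_loso(cohort,
                             msaenet_config(input_size = 12,
                                            variant = "withoutloss"),
                             train_cfg = tc, return_features = TRUE),
      rawdata = run_loso(cohort,
                         msaenet_config(input_size = 12,
                                        variant = "rawdata"),
                         train_cfg = tc))
  })
  .loso_cache$runs <- runs
  runs
}

# Mean within-class Euclidean scatter of the test-set fused features,
# pooled over LOSO folds.
fused_within_class_scatter <- function(run) {
  dists <- unlist(lapply(run$features, function(f) {
    unlist(lapply(unique(f$truth), function(cl) {
      Z <- f$fused[f$truth == cl, , drop = FALSE]
      ctr <- colMeans(Z)
      sqrt(rowSums(sweep(Z, 2, ctr)^2))
    }))
  }))
  mean(dists)
}
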