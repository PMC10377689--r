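test_that("cohort spec validates its invariants", {
  expect_s3_class(cohort_spec(), "cohort_spec")
  expect_error(cohort_spec(n_subjects = 1), "n_subjects")
  expect_error(cohort_spec(trials_per_class = 0), "trials_per_class")
  expect_error(cohort_spec(mu_freq = 25, beta_freq = 20), "mu_freq")
  expect_error(cohort_spec(beta_freq = 40, fs = 64), "beta_freq|fs")
  expect_error(cohort_spec(snr = 0), "snr")
  expect_error(cohort_spec(subject_sigma = -1), "subject_sigma")
})

test_that("subject generation is deterministic and balanced", {
  spec <- cohort_spec(n_subjects = 2, trials_per_class = 20, seed = 9)
  a <- generate_subject(spec, 0)
  b <- generate_subject(spec, 0)
  expect_identical(a$X, b$X)
  expect_identical(a$y, b$y)
  expect_equal(dim(a$X)[1], 40)
  expect_equal(as.vector(table(a$y)), c(20, 20))
  expect_equal(a$subject_id, 0L)
  # different seed: same label layout, different signal
  spec2 <- cohort_spec(n_subjects = 2, trials_per_class = 20, seed = 10)
  c2 <- generate_subject(spec2, 0)
  expect_identical(a$y, c2$y)
  expect_false(identical(a$X, c2$X))
  expect_error(generate_subject(spec, 5), "subject_index")
})

test_that("cohort entries carry distinct subject ids", {
  spec <- cohort_spec(n_subjects = 3, trials_per_class = 3, seed = 2)
  cohort <- generate_cohort(spec)
  expect_length(cohort, 3)
  expect_equal(vapply(cohort, function(tr) tr$subject_id, 0L), 0:2)
})

test_that("class covariance contrast grows with class_contrast", {
  dist_for <- function(contrast) {
    spec <- cohort_spec(n_subjects = 2, trials_per_class = 50,
                        class_contrast = contrast, subject_sigma = 0,
                        seed = 4)
    tr <- generate_subject(spec, 0)
    norm(class_covariance(tr, 0) - class_covariance(tr, 1), "F")
  }
  d <- vapply(c(0, 0.4, 0.8), dist_for, 0)
  expect_lt(d[1], d[2])
  expect_lt(d[2], d[3])
})

test_that("with zero subject variability, subjects share covariance structure", {
  spec <- cohort_spec(n_subjects = 2, trials_per_class = 100,
                      subject_sigma = 0, seed = 6)
  cohort <- generate_cohort(spec)
  s1 <- cohort[[1]]
  s2 <- cohort[[2]]
  # noise floor: split subject 1 in half and compare halves
  half <- subset_trials(s1, seq(1, 200, by = 2))
  other <- subset_trials(s1, seq(2, 200, by = 2))
  for (cl in 0:1) {
    floor_d <- norm(class_covariance(half, cl) - class_covariance(other, cl),
                    "F")
    cross_d <- norm(class_covariance(s1, cl) - class_covariance(s2, cl), "F")
    expect_lt(cross_d, 3 * floor_d + 1e-3)
  }
})

test_that("forced separability: within-subject CSP read-out is near perfect", {
  spec <- cohort_spec(n_subjects = 2, trials_per_class = 60,
                      class_contrast = 0.8, snr = 10, subject_sigma = 0,
                      seed = 12)
  tr <- generate_subject(spec, 0)
  idx <- seq_len(120)
  train <- subset_trials(tr, idx[idx %% 2 == 1])
  test <- subset_trials(tr, idx[idx %% 2 == 0])
  expect_gt(csp_linear_accuracy(train, test), 95)
})

test_that("cross-subject transfer degrades with subject_sigma", {
  acc_for <- function(sigma, seed) {
    spec <- cohort_spec(n_subjects = 2, trials_per_class = 30,
                        subject_sigma = sigma, seed = seed)
    cohort <- generate_cohort(spec)
    csp_linear_accuracy(cohort[[1]], cohort[[2]])
  }
  accs <- vapply(c(0, 0.5, 1), function(sg) {
    mean(vapply(1:3, function(s) acc_for(sg, 20 + s), 0))
  }, 0)
  expect_true(accs[1] >= accs[2] - 1e-9)
  expect_true(accs[2] >= accs[3] - 1e-9)
})
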