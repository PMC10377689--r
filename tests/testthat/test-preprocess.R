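test_that("band-pass keeps the band and rejects out-of-band tones", {
  # geometric band center of 8-30 Hz
  mid <- sine_trials(15.49)
  out <- bandpass_trials(mid, bandpass_spec())
  expect_gte(rms(out$X[1, 1, ]) / rms(mid$X[1, 1, ]), 0.95)
  low <- sine_trials(4)
  out_low <- bandpass_trials(low, bandpass_spec())
  expect_lte(rms(out_low$X[1, 1, ]) / rms(low$X[1, 1, ]), 0.05)
  zeros <- epoched_trials(array(0, c(1, 2, 500)), 0L, 250)
  expect_equal(max(abs(bandpass_trials(zeros)$X)), 0)
  expect_error(bandpass_trials(sine_trials(10, fs = 50),
                               bandpass_spec(8, 30)), "fs/2")
})

test_that("filtering is idempotent in the pass band", {
  tr <- sine_trials(15.49)
  once <- bandpass_trials(tr)
  twice <- bandpass_trials(once)
  expect_lt(abs(rms(twice$X[1, 1, ]) - rms(once$X[1, 1, ])),
            0.1 * rms(once$X[1, 1, ]))
})

test_that("filtered white noise concentrates its power in the band", {
  set.seed(8)
  fs <- 250
  tr <- epoched_trials(array(rnorm(2 * 2 * fs * 60), c(2, 2, fs * 60)),
                       c(0L, 1L), fs)
  out <- bandpass_trials(tr)
  x <- out$X[1, 1, ]
  spec <- Mod(fft(x))^2
  freq <- (seq_along(spec) - 1) * fs / length(spec)
  half <- freq <= fs / 2
  inband <- half & freq >= 6 & freq <= 32
  expect_gte(sum(spec[inband]) / sum(spec[half]), 0.9)
})

test_that("resampling preserves duration, length and DC", {
  tr512 <- epoched_trials(array(rnorm(2 * 2 * 2048), c(2, 2, 2048)),
                          c(0L, 1L), 512)
  out <- resample_trials(tr512, 250)
  expect_equal(dim(out$X)[3], 1000)
  expect_equal(out$fs, 250)
  tr1k <- epoched_trials(array(rnorm(1 * 2 * 4000), c(1, 2, 4000)), 0L, 1000)
  expect_equal(dim(resample_trials(tr1k, 250)$X)[3], 1000)
  const <- epoched_trials(array(3.7, c(1, 2, 2048)), 0L, 512)
  cr <- resample_trials(const, 250)
  expect_lt(max(abs(cr$X - 3.7)) / 3.7, 1e-6)
  expect_error(resample_trials(const, 1024), "upsampling")
  expect_identical(resample_trials(const, 512), const)
})

test_that("resample and window extraction commute up to boundary samples", {
  set.seed(3)
  tr <- epoched_trials(array(rnorm(1 * 2 * 2048), c(1, 2, 2048)), 0L, 512)
  a <- extract_window(resample_trials(tr, 256), 1, 3)
  b <- resample_trials(extract_window(tr, 1, 3), 256)
  expect_equal(dim(a$X), dim(b$X))
  mid <- 50:460  # away from the resampling edges
  expect_lt(max(abs(a$X[1, 1, mid] - b$X[1, 1, mid])),
            0.05 * rms(tr$X[1, 1, ]))
})

test_that("channel selection reorders, rejects unknowns and duplicates", {
  tr <- tiny_trials(C = 4, channel_names = c("C3", "Cz", "C4", "Pz"))
  sel <- select_channels(tr, c("C4", "C3"))
  expect_equal(sel$channel_names, c("C4", "C3"))
  expect_identical(sel$X[, 1, ], tr$X[, 3, ])
  expect_identical(select_channels(tr, tr$channel_names)$X, tr$X)
  expect_error(select_channels(tr, c("C3", "XX")), "XX")
  expect_error(select_channels(tr, c("C3", "C3")), "duplicate")
})

test_that("window extraction follows the half-open sample convention", {
  tr <- tiny_trials(N = 2, C = 2, Tn = 1500, fs = 250)
  w <- extract_window(tr, 3, 6)
  expect_equal(dim(w$X)[3], 750)
  expect_identical(w$X[1, 1, 1], tr$X[1, 1, 751])
  tr4 <- tiny_trials(N = 1, C = 2, Tn = 1000, fs = 250)
  expect_identical(extract_window(tr4, 0, 4)$X, tr4$X)
  expect_error(extract_window(tr4, 0, 4.5), "exceeds")
})

test_that("presets compose the full chain with the documented geometry", {
  set.seed(4)
  # 22-channel 250 Hz 6 s fixture -> 20 motor channels x 750 samples
  tr <- epoched_trials(array(rnorm(2 * 22 * 1500), c(2, 22, 1500)),
                       c(0L, 1L), 250, channel_names = montage22())
  out <- apply_preset(tr, dataset_preset("bciiv2a"))
  expect_equal(dim(out$X)[2], 20)
  expect_equal(dim(out$X)[3], 750)
  # 15-channel 512 Hz 4 s fixture -> 15 x 1000
  tr2 <- epoched_trials(array(rnorm(2 * 15 * 2048), c(2, 15, 2048)),
                        c(0L, 1L), 512)
  out2 <- apply_preset(tr2, dataset_preset("smrbci"))
  expect_equal(dim(out2$X)[2:3], c(15, 1000))
  # custom full-window preset only filters
  tr3 <- tiny_trials(N = 2, C = 2, Tn = 1000, fs = 250)
  pre <- dataset_preset("custom", target_fs = 250, window = c(0, 4))
  out3 <- apply_preset(tr3, pre)
  expect_equal(dim(out3$X), dim(tr3$X))
  expect_false(identical(out3$X, tr3$X))
})

test_that("the 20-channel motor list resolves its duplicated electrode", {
  ch <- midecode:::motor20_channels()
  expect_length(ch, 20)
  expect_false(anyDuplicated(ch) > 0)
  expect_true("CP2" %in% ch)
  ch2 <- midecode:::motor20_channels("POz")
  expect_true("POz" %in% ch2)
  expect_length(ch2, 20)
})
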