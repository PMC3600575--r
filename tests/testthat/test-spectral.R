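test_that("power concentrates at the stimulus frequency", {
  ep <- sine_epochs(10, sfreq = 128, n_sec = 3, n_trials = 2)
  spec <- morlet_spec(c(5, 10, 20), cycles = 5, sfreq = 128)
  pw <- morlet_power(ep, spec)
  interior <- which(!pw$edge[, 1] & !pw$edge[, 2] & !pw$edge[, 3])
  expect_gt(length(interior), 50)
  expect_true(all(pw$values[1, interior, 2, 1] >
                    pw$values[1, interior, 1, 1]))
  expect_true(all(pw$values[1, interior, 2, 1] >
                    pw$values[1, interior, 3, 1]))
})

test_that("all-zero epochs give all-zero power and power is nonnegative", {
  ep <- eeg_epochs(array(0, c(2, 256, 3)), 128, c(0, 2000))
  pw <- morlet_power(ep, morlet_spec(c(8, 12), 5, 128))
  expect_equal(max(abs(pw$values)), 0)
  set.seed(2)
  ep2 <- eeg_epochs(array(rnorm(2 * 256 * 3), c(2, 256, 3)), 128, c(0, 2000))
  expect_true(all(morlet_power(ep2, morlet_spec(c(8, 12), 5, 128))$values >= 0))
})

test_that("FFT and direct-path convolution match a brute-force time-domain oracle", {
  set.seed(7)
  sfreq <- 128
  # long epoch exercises the FFT path, short one the matrix path
  for (T_ in c(1024, 256)) {
    x <- rnorm(T_)
    ep <- eeg_epochs(array(x, c(1, T_, 1)), sfreq,
                     c(0, 1000 * T_ / sfreq))
    k <- morlet_kernel(10, 5, sfreq)
    pw <- morlet_power(ep, morlet_spec(10, 5, sfreq))
    oracle <- Mod(direct_morlet(x, k$kernel))^2
    expect_lt(max(abs(pw$values[1, , 1, 1] - oracle)) / max(oracle), 1e-8)
  }
})

test_that("power is sign-invariant and scales quadratically with the signal", {
  set.seed(8)
  x <- array(rnorm(2 * 256 * 2), c(2, 256, 2))
  spec <- morlet_spec(c(8, 10), 5, 128)
  p1 <- morlet_power(eeg_epochs(x, 128, c(0, 2000)), spec)
  p2 <- morlet_power(eeg_epochs(-x, 128, c(0, 2000)), spec)
  expect_equal(p1$values, p2$values, tolerance = 1e-12)
  x3 <- x; x3[1, , ] <- 3 * x3[1, , ]
  p3 <- morlet_power(eeg_epochs(x3, 128, c(0, 2000)), spec)
  expect_equal(p3$values[1, , , ], 9 * p1$values[1, , , ], tolerance = 1e-10)
  expect_equal(p3$values[2, , , ], p1$values[2, , , ], tolerance = 1e-12)
  # band collapse commutes with channel scaling before baseline subtraction
  zeroM <- matrix(0, 2, 256)
  b1 <- band_collapse(p1, c(8, 10), baseline_trials = zeroM)
  b3 <- band_collapse(p3, c(8, 10), baseline_trials = zeroM)
  expect_equal(b3$values[1, , ], 9 * b1$values[1, , ], tolerance = 1e-10)
})

test_that("a unit sinusoid at a grid frequency has stable positive power across interior latencies", {
  ep <- sine_epochs(10, sfreq = 128, n_sec = 4, n_trials = 1)
  pw <- morlet_power(ep, morlet_spec(10, 5, 128))
  sig <- morlet_kernel(10, 5, 128)$sigma_ms
  interior <- which(pw$times > 3 * sig & pw$times < 4000 - 3 * sig)
  p <- pw$values[1, interior, 1, 1]
  expect_true(all(p > 0))
  expect_lt((max(p) - min(p)) / mean(p), 0.01)
})

test_that("band collapse takes the in-band max and subtracts the baseline mean", {
  set.seed(9)
  ep <- eeg_epochs(array(rnorm(2 * 256 * 6), c(2, 256, 6)), 128, c(0, 2000))
  pw <- morlet_power(ep, morlet_spec(c(8, 9, 10, 11, 12), 5, 128))
  # single-frequency band equals that frequency's power minus baseline
  b1 <- band_collapse(pw, c(10, 10))
  M <- rowMeans(pw$values[, , 3, , drop = FALSE], dims = 2)
  expect_equal(b1$values, pw$values[, , 3, ] - array(M, c(2, 256, 6)),
               tolerance = 1e-12)
  # after subtraction the baseline-trial mean is ~0 per channel/latency
  b <- band_collapse(pw, c(8, 12), baseline_trials = 1:4)
  resid <- rowMeans(b$values[, , 1:4, drop = FALSE], dims = 2)
  expect_lt(max(abs(resid)), 1e-12)
  # brute-force the max over frequencies at one point
  expect_equal(b$values[2, 100, 5] + b$baseline_mean[2, 100],
               max(pw$values[2, 100, , 5]), tolerance = 1e-12)
  expect_error(band_collapse(pw, c(50, 60)), "no grid frequency")
})

test_that("the default band table matches the standard EEG intervals", {
  b <- eeg_bands()
  expect_equal(b$band, c("theta", "alpha", "beta1", "beta2", "gamma"))
  expect_equal(b$lo, c(5, 8, 16, 23, 31))
  expect_equal(b$hi, c(7, 12, 22, 30, 40))
})

test_that("band definitions load from YAML", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c("bands:", "  alpha: [8, 12]", "  beta1: [16, 22]"), path)
  cfg <- read_band_config(path)
  expect_equal(cfg$band, c("alpha", "beta1"))
  expect_equal(cfg$lo, c(8, 16))
  expect_equal(cfg$hi, c(12, 22))
})

test_that("subject aggregation concatenates trials and keeps retrievable provenance", {
  b1 <- tiny_band(D = 3, T_ = 8, N = 100, seed = 21)
  b2 <- tiny_band(D = 3, T_ = 8, N = 110, seed = 22)
  agg <- aggregate_subjects(list(b1, b2))
  expect_equal(dim(agg$values)[3], 210)
  # single dataset aggregation is the identity
  expect_identical(aggregate_subjects(list(b1)), b1)
  # trial k of input j is retrievable by provenance
  for (probe in list(c(1, 7), c(2, 103))) {
    rows <- which(agg$trials$source_dataset == probe[1] &
                    agg$trials$source_trial == probe[2])
    src <- if (probe[1] == 1) b1 else b2
    expect_equal(agg$values[, , rows], src$values[, , probe[2]])
  }
  b3 <- tiny_band(D = 4, T_ = 8, N = 10, seed = 23)
  expect_error(aggregate_subjects(list(b1, b3)), "axes differ")
})

test_that("spectral preconditions are enforced", {
  expect_error(morlet_spec(c(10, 70), 5, 128), "Nyquist")
  expect_error(morlet_spec(c(0, 10), 5, 128), "positive")
  expect_error(morlet_spec(10, 0.5, 128), "cycles")
  short <- eeg_epochs(array(rnorm(26), c(1, 26, 1)), 128, c(0, 203.125))
  expect_error(morlet_power(short, morlet_spec(8, 5, 128)), "shorter")
})

test_that("restricting output latencies changes nothing numerically", {
  set.seed(12)
  ep <- eeg_epochs(array(rnorm(2 * 256 * 3), c(2, 256, 3)), 128, c(0, 2000))
  spec <- morlet_spec(c(8, 12), 5, 128)
  full <- morlet_power(ep, spec)
  res <- morlet_power(ep, spec, latency_range = c(500, 900))
  sel <- which(full$times >= 500 - 1e-9 & full$times < 900 - 1e-9)
  expect_equal(res$values, full$values[, sel, , , drop = FALSE],
               tolerance = 1e-12)
  expect_equal(res$times, full$times[sel])
})
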