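test_that("every feature matches its brute-force oracle on random epochs", {
  # exact-arithmetic oracles: agreement to 1e-6 relative
  for (s in 1:50) {
    ep <- random_epoch(s)
    got <- extract_features(ep)
    want <- oracle_features(ep)
    expect_identical(names(got), names(want))
    expect_equal(got, want, tolerance = 1e-6)
  }
})

test_that("the periodogram matches a direct DFT and satisfies Parseval", {
  for (s in 1:5) {
    ep <- random_epoch(s, n = 600L, fs = 400)
    sp <- periodogram(ep)
    nfft <- 4L * 2L^ceiling(log2(600L))
    bins <- c(1L, 7L, 33L, 150L, length(sp$freqs))
    expect_equal(sp$power[bins], o_psd_bins(ep$samples, 400, nfft, bins),
                 tolerance = 1e-9)
    df <- sp$freqs[2L] - sp$freqs[1L]
    expect_equal(sum(sp$power) * df, mean(ep$samples^2), tolerance = 1e-9)
  }
})

test_that("scale invariance and scaling laws hold across the bank", {
  ep <- random_epoch(99)
  c_ <- 7.3
  sc <- ep; sc$samples <- c_ * ep$samples
  f1 <- extract_features(ep); f2 <- extract_features(sc)
  invariant <- c("mean_local_skew_15ms", "temporal_kurtosis",
                 grep("^lambda_", names(f1), value = TRUE),
                 "fd_kurtosis_higuchi", "fd_kurtosis_katz", "haar_kurtosis")
  expect_equal(f2[invariant], f1[invariant], tolerance = 1e-9)
  expect_equal(f2[["amplitude_change_50ms"]],
               c_ * f1[["amplitude_change_50ms"]], tolerance = 1e-9)
  expect_equal(f2[["amplitude_variance"]],
               c_^4 * f1[["amplitude_variance"]], tolerance = 1e-9)
  # sign flip leaves the windowed net-change features unchanged
  fl <- ep; fl$samples <- -ep$samples
  f3 <- extract_features(fl)
  dv <- grep("^deriv_sum_", names(f1), value = TRUE)
  expect_equal(f3[dv], f1[dv], tolerance = 1e-12)
})

test_that("closed-form examples: ramp, sine and Gaussian noise", {
  fs <- 2000
  ramp <- eeg_epoch(2 * (seq_len(3000) - 1) / fs * 1000, fs = fs)  # 2 uV/ms
  # 50 ms window = 100 samples spanning 99 steps of 1 uV each
  expect_equal(amplitude_change(ramp, 0.05), 99, tolerance = 1e-12)

  sine <- eeg_epoch(sin(2 * pi * 10 * (seq_len(3000) - 1) / fs), fs = fs)
  expect_equal(temporal_kurtosis(sine), 1.5, tolerance = 0.01)

  set.seed(4)
  gauss <- eeg_epoch(rnorm(30000), fs = fs, event_offset = 0.5)
  expect_equal(temporal_kurtosis(gauss), 3, tolerance = 0.2)

  const <- eeg_epoch(rep(4.2, 3000), fs = fs)
  expect_equal(amplitude_change(const, 0.05), 0)
  expect_equal(mean_local_skewness(const), 0)
  expect_equal(temporal_kurtosis(const), 0)
  expect_equal(derivative_sum(const, 0.05), 0)
})

test_that("constant epochs yield an all-zero vector under the degenerate conventions", {
  const <- eeg_epoch(rep(4.2, 3000), fs = 2000)
  fv <- suppressWarnings(extract_features(const))
  expect_length(fv, 31L)
  expect_true(all(is.finite(fv)))
  expect_true(all(fv == 0))
})

test_that("band power localises a pure tone in its band", {
  fs <- 2000
  a <- 3
  ep <- eeg_epoch(a * sin(2 * pi * 10 * (seq_len(3000) - 1) / fs), fs = fs)
  sp <- periodogram(ep)
  total <- sum(sp$power) * (sp$freqs[2] - sp$freqs[1])
  expect_equal(total, a^2 / 2, tolerance = 1e-3)
  alpha <- band_power(sp, "alpha")
  expect_gt(alpha / total, 0.95)          # sinc sidelobes carry the rest
  expect_lt(band_power(sp, "gamma") / total, 0.01)
  expect_lt(power_below_0p5hz(sp) / total, 0.01)
  # disjoint EEG bands never exceed the total
  bands <- feature_bands()[c("delta", "theta", "alpha", "beta", "gamma")]
  expect_lte(sum(vapply(bands, band_power, numeric(1), spec = sp)), total)
})

test_that("band power equals the analytic integral on a boxcar spectrum", {
  sp <- eeg_spectrum(freqs = seq(0, 100, by = 0.25),
                     power = rep(2, 401))           # flat 2 uV^2/Hz
  expect_equal(band_power(sp, c(10, 20)), 2 * 10, tolerance = 1e-12)
  expect_warning(v <- band_power(sp, c(10.05, 10.20)), "no bins")
  expect_equal(v, 0)
})

test_that("spectral fit recovers an exact power law with zero error", {
  f <- seq(0.5, 100, by = 0.5)
  sp <- eeg_spectrum(f, 5 * f^(-2))
  fit <- spectral_fit(sp, c(2, 70))
  expect_equal(fit[["lambda"]], -2, tolerance = 1e-10)
  expect_lt(fit[["fit_error"]], 1e-10)
  expect_equal(fit[["C"]], log10(5), tolerance = 1e-10)
  # white spectrum -> flat fit
  spw <- eeg_spectrum(f, rep(3, length(f)))
  expect_equal(spectral_fit(spw, c(2, 70))[["lambda"]], 0, tolerance = 1e-10)
  # planted residuals: RMSE equals the planted norm
  resid <- rep(c(0.1, -0.1), length.out = length(f))
  spr <- eeg_spectrum(f, 10^(log10(5) - 2 * log10(f) + resid))
  idx <- f >= 2 & f < 70
  planted <- sqrt(mean((resid[idx] - mean(resid[idx] * 0))^2))
  fitr <- spectral_fit(spr, c(2, 70))
  expect_equal(fitr[["fit_error"]], planted, tolerance = 0.02)
  expect_warning(out <- spectral_fit(sp, c(0.01, 0.6)), "<3 usable")
  expect_equal(unname(out), c(0, 0, 0))
})

test_that("fractal estimators behave on known processes", {
  # Katz FD of any straight segment is exactly 1
  expect_equal(katz_fd(seq(0, 5, length.out = 200)), 1, tolerance = 1e-12)
  expect_equal(katz_fd(rep(2, 50)), 1)
  # Higuchi FD of white noise approaches 2
  set.seed(8)
  fds <- replicate(20, higuchi_fd(rnorm(200), k_max = 8L))
  expect_true(all(abs(fds - 2) < 0.15))
  # and of a smooth low-frequency curve stays near 1
  t <- seq(0, 1, length.out = 200)
  expect_lt(higuchi_fd(sin(2 * pi * t)), 1.1)
})

test_that("fd kurtosis pipes the windowed FD series through the moment formula", {
  ep <- random_epoch(5)
  expect_equal(fd_kurtosis(ep, "higuchi"),
               o_fd_kurtosis(ep$samples, ep$fs, "higuchi"), tolerance = 1e-9)
  expect_equal(fd_kurtosis(ep, "katz"),
               o_fd_kurtosis(ep$samples, ep$fs, "katz"), tolerance = 1e-9)
  short <- eeg_epoch(rnorm(300), fs = 2000, event_offset = 0.1)
  expect_error(fd_kurtosis(short, "katz"), "4 FD windows")
})

test_that("Haar details match the direct transform and flag spikes", {
  x <- rnorm(16)
  d <- haar_details(x)
  lvl1 <- (x[seq(1, 15, 2)] - x[seq(2, 16, 2)]) / sqrt(2)
  expect_equal(d[1:8], lvl1, tolerance = 1e-12)
  expect_length(d, 15L)
  # orthonormal transform preserves energy (details + final approximation)
  approx_last <- sum(x) / sqrt(16)
  expect_equal(sum(d^2) + approx_last^2, sum(x^2), tolerance = 1e-9)

  spike <- eeg_epoch(c(rep(0, 1499), 150, rep(0, 1500)) + rnorm(3000, sd = 1),
                     fs = 2000)
  expect_gt(haar_kurtosis(spike), 3)
})

test_that("feature extraction is deterministic and artefacts move the bank", {
  spec <- sim_spec()
  ep <- gen_clean_epoch(spec, seed = 21)
  expect_identical(extract_features(ep), extract_features(ep))
  art <- inject_artefact(ep, "movement_burst", spec = spec, seed = 22)
  f_clean <- extract_features(ep)
  f_art <- extract_features(art)
  rel <- abs(f_art - f_clean) / pmax(abs(f_clean), 1e-12)
  expect_gte(sum(rel > 0.10), 5L)
})

test_that("the shipped manifest file matches the in-code ordering", {
  path <- system.file("extdata", "feature_manifest_v1.txt",
                      package = "neonartefact")
  expect_true(nzchar(path))
  expect_identical(readLines(path), as.vector(feature_manifest()))
})
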