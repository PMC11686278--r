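test_that("denoise preserves DC, removes spikes, attenuates high frequency", {
  fs <- 1000
  const <- rep(3.7, 2000)
  expect_equal(denoise(const, fs), const, tolerance = 1e-8)

  spiked <- rep(1, 2000); spiked[1000] <- 50
  out <- denoise(spiked, fs, median_window = 5)
  expect_equal(out, rep(1, 2000), tolerance = 1e-6)

  # 0.1 Hz preserved within 5%, 100 Hz attenuated >= 20 dB (3 Hz cutoff)
  t <- seq(0, 40 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * 0.1 * t) + sin(2 * pi * 100 * t)
  y <- denoise(x, fs, lowpass_cutoff = 3)
  mid <- seq(5 * fs, 35 * fs)  # avoid filter edges
  amp_at <- function(sig, f) {
    b <- cbind(sin(2 * pi * f * t[mid]), cos(2 * pi * f * t[mid]))
    sqrt(sum(stats::coef(stats::lm.fit(b, sig[mid]))^2))
  }
  expect_lt(abs(amp_at(y, 0.1) - 1), 0.05)
  expect_lt(amp_at(y, 100), 10^(-20 / 20))

  expect_error(denoise(const, fs, median_window = 4), "odd")
  expect_error(denoise(const, fs, lowpass_cutoff = 600), "fs/2")
})

test_that("trim_start applies assay-specific exclusions and clips epochs", {
  mk <- function(dur, fs = 10, assay = "DID") {
    n <- dur * fs
    structure(list(time_s = (seq_len(n) - 1) / fs, f465 = rnorm(n),
                   f405 = rnorm(n), fs = fs, assay = assay,
                   licks = c(100, 1500),
                   epoch_schedule = epoch_schedule("W1", 0, dur)),
              class = "photometry_session")
  }
  s <- trim_start(mk(3600))
  expect_equal(range(s$time_s), c(1000, 3600 - 0.1))
  expect_equal(s$licks, 1500)
  expect_equal(s$epoch_schedule$start_s, 1000)

  epm <- trim_start(mk(500, assay = "EPM"))
  expect_equal(epm$time_s[1], 150)
  expect_length(epm$time_s, 350 * 10)

  expect_identical(trim_start(mk(3600), exclusion_override = 0)$time_s,
                   mk(3600)$time_s)
  expect_error(trim_start(mk(900)), "exclusion")
})

test_that("downsample_mean is the block mean with trailing drop", {
  expect_equal(downsample_mean(1:100, 100), 50.5)
  expect_identical(downsample_mean(1:7, 1), 1:7)
  expect_length(downsample_mean(rnorm(250), 100), 2)
  # commutes with direct block means on random input
  set.seed(42)
  x <- rnorm(1000)
  direct <- vapply(1:10, function(k) mean(x[((k - 1) * 100 + 1):(k * 100)]),
                   numeric(1))
  expect_equal(downsample_mean(x, 100), direct)
  expect_error(downsample_mean(x, 0), "factor")
})

test_that("motion correction recovers the linear fit and kills shared motion", {
  x405 <- rnorm(500, 50, 2)
  mc <- motion_correct(2 * x405 + 3, x405)
  expect_equal(mc$fit$slope, 2, tolerance = 1e-9)
  expect_equal(mc$fit$intercept, 3, tolerance = 1e-9)
  expect_equal(max(abs(mc$corrected)), 0, tolerance = 1e-9)

  # orthogonal regressor: slope 0, corrected = centered signal
  f465 <- c(1, -1, 1, -1)
  f405 <- c(1, 1, -1, -1)
  mc2 <- motion_correct(f465, f405)
  expect_equal(mc2$fit$slope, 0)
  expect_equal(mc2$corrected, f465 - mean(f465))

  expect_error(motion_correct(rnorm(10), rep(1, 10)), "constant")

  # simulated shared motion: correlation with ground truth collapses
  sim <- simulate_photometry(photometry_sim_params(
    duration_s = 120, fs = 100, motion_amp = 2, noise_sd = 0.5,
    transient_rate = 4, seed = 21))
  f465d <- downsample_mean(sim$session$f465, 10)
  f405d <- downsample_mean(sim$session$f405, 10)
  md <- downsample_mean(sim$truth$motion_trace, 10)
  expect_gt(abs(cor(f465d, md)), 0.5)
  corrected <- motion_correct(f465d, f405d)$corrected
  expect_lt(abs(cor(corrected, md)), 0.05)
})

test_that("zscore_trace meets its contract and is affine-invariant", {
  expect_equal(zscore_trace(c(1, 2, 3)), c(-1, 0, 1))
  set.seed(7)
  x <- rnorm(200, 5, 3)
  z <- zscore_trace(x)
  expect_lt(abs(mean(z)), 1e-9)
  expect_lt(abs(sd(z) - 1), 1e-9)
  expect_equal(zscore_trace(2.5 * x + 17), z)
  expect_error(zscore_trace(rep(1, 10)), "variance")
})

test_that("full preprocessing meets the z contract and round-trips transient times", {
  sim <- simulate_photometry(photometry_sim_params(
    duration_s = 120, fs = 101.725, transient_rate = 4,
    transient_amp_mean = 8, transient_amp_sd = 1, motion_amp = 0,
    noise_sd = 0.01, bleach_frac = 0, seed = 31))
  tr <- preprocess(sim$session, factor = 10, exclusion_override = 0)
  expect_lt(abs(mean(tr$z)), 1e-9)
  expect_lt(abs(sd(tr$z) - 1), 1e-9)
  expect_equal(tr$fs_eff, 101.725 / 10)
  expect_named(tr$provenance,
               c("denoise", "trim", "downsample", "motion_correct", "zscore"))

  # every resolvable true transient (no neighbor within the 1 s separation
  # limit, full window inside the trace) is detected at the processed
  # trace's own local argmax (within 1 effective sample of it), with total
  # onset-to-peak latency bounded by the filter + block-averaging shift
  ev <- detect_transients(tr, k_mad = 3)
  tt_all <- sim$truth$transient_times
  gaps <- diff(c(-Inf, tt_all, Inf))
  resolvable <- gaps[-length(gaps)] > 1.5 & gaps[-1] > 1.5 &
    tt_all > 1 & tt_all < max(tr$time_s) - 1
  expect_gt(sum(resolvable), 2)
  for (tt in tt_all[resolvable]) {
    near <- which(tr$time_s >= tt - 0.2 & tr$time_s <= tt + 0.6)
    oracle_peak <- tr$time_s[near[which.max(tr$z[near])]]
    expect_lt(min(abs(ev$time - oracle_peak)), 1 / tr$fs_eff + 1e-9)
    expect_lt(min(abs(ev$time - tt)), 0.3)
  }

  # determinism and degenerate-config reduction
  expect_identical(preprocess(sim$session, factor = 10,
                              exclusion_override = 0), tr)
  plain <- preprocess(sim$session, median_window = 3, lowpass_cutoff = 3,
                      factor = 1, exclusion_override = 0)
  expect_length(plain$z, length(sim$session$f465))
})

test_that("motion-fit residual is uncorrelated with the regressor", {
  sim <- simulate_photometry(photometry_sim_params(
    duration_s = 60, fs = 100, motion_amp = 1, noise_sd = 0.5, seed = 5))
  f465d <- downsample_mean(sim$session$f465, 10)
  f405d <- downsample_mean(sim$session$f405, 10)
  mc <- motion_correct(f465d, f405d)
  expect_lt(abs(cor(mc$corrected, f405d)), 1e-9)
  expect_lt(abs(mean(mc$corrected)), 1e-9)
})
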