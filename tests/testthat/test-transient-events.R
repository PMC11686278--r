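test_that("segment_epochs positions the four 30-min analysis epochs", {
  sched <- epoch_schedule(c("W1", "EtOH", "W2"), c(0, 3600, 10800),
                          c(3600, 10800, 12600))
  ep <- segment_epochs(sched)
  expect_equal(ep$label, c("W1", "EtOH1", "EtOH2", "W2"))
  expect_equal(ep$start_s, c(1800, 3600, 9000, 10800))
  expect_equal(ep$end_s, c(3600, 5400, 10800, 12600))

  # EtOH access exactly 60 min: the two EtOH epochs abut without overlap
  ep2 <- segment_epochs(epoch_schedule(c("W1", "EtOH", "W2"),
                                       c(0, 1800, 5400),
                                       c(1800, 5400, 7200)))
  expect_equal(ep2$end_s[ep2$label == "EtOH1"],
               ep2$start_s[ep2$label == "EtOH2"])

  expect_error(segment_epochs(epoch_schedule(c("W1", "EtOH", "W2"),
                                             c(0, 1200, 4800),
                                             c(1200, 4800, 6600))),
               "W1 access")
})

test_that("detect_transients finds inserted peaks with correct amplitude", {
  set.seed(1)
  z <- rnorm(3000, 0, 0.1)
  z[1500:1509] <- z[1500:1509] + 5 * exp(-(0:9) / 3)
  ev <- detect_transients(make_trace(z), k_mad = 8)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$amplitude, 5, tolerance = 0.2)
  expect_equal(ev$time, 1499 / 10, tolerance = 0.15)

  # shift invariance: adding a constant changes nothing
  ev2 <- detect_transients(make_trace(z + 42), k_mad = 8)
  expect_equal(ev, ev2)

  expect_error(detect_transients(make_trace(numeric(0))), "empty")
})

test_that("pure noise at an extreme threshold yields no events", {
  hits <- vapply(1:200, function(seed) {
    set.seed(seed)
    nrow(detect_transients(make_trace(rnorm(2000)), k_mad = 8))
  }, numeric(1))
  expect_gte(mean(hits == 0), 0.95)
})

test_that("detector sensitivity and FDR on ground-truthed simulations", {
  # amplitudes >= 5x the raw sensor noise sd, run through the full
  # preprocessing pipeline as in a real session
  hits <- 0; misses <- 0; false_pos <- 0; n_det <- 0
  for (seed in 1:3) {
    sim <- simulate_photometry(photometry_sim_params(
      duration_s = 600, fs = 101.725, transient_rate = 6,
      transient_amp_mean = 6, transient_amp_sd = 1, noise_sd = 1,
      motion_amp = 0, seed = seed))
    tr <- preprocess(sim$session, factor = 10, exclusion_override = 0)
    ev <- detect_transients(tr, k_mad = 3.5)
    tt <- sim$truth$transient_times
    gaps <- diff(c(-Inf, tt, Inf))
    resolvable <- gaps[-length(gaps)] > 1.5 & gaps[-1] > 1.5 &
      tt < 599
    matched <- vapply(tt[resolvable],
                      function(x) any(abs(ev$time - x) <= 0.5), logical(1))
    hits <- hits + sum(matched)
    misses <- misses + sum(!matched)
    false_pos <- false_pos +
      sum(vapply(ev$time, function(et) all(abs(tt - et) > 0.5),
                 logical(1)))
    n_det <- n_det + nrow(ev)
  }
  expect_gte(hits / (hits + misses), 0.95)
  expect_lte(false_pos / n_det, 0.05)
})

test_that("amplitude binning and reference normalization follow the rules", {
  ev <- function(a) data.frame(time = seq(10, by = 10,
                                          length.out = length(a)),
                               amplitude = a)
  ref <- ev(c(1.2, 1.7, 3.4))
  d <- amplitude_distribution(ref, c(0, 1800), ref, c(0, 1800),
                              bin_width = 1)
  expect_equal(d$count[d$bin_left == 1], 2)
  expect_equal(d$count[d$bin_left == 3], 1)
  expect_equal(sum(d$count), 3)
  expect_equal(sum(d$normalized), 1, tolerance = 1e-9)  # self-normalization

  # added large events: total > 1 and peak moves right
  extra <- ev(c(1.2, 1.7, 3.4, rep(6.3, 10)))
  d2 <- amplitude_distribution(extra, c(0, 1800), ref, c(0, 1800),
                               bin_width = 1)
  expect_gt(sum(d2$normalized), 1)
  expect_gt(summarize_distribution(d2)$peak_amplitude,
            summarize_distribution(d)$peak_amplitude)

  expect_error(amplitude_distribution(ref, c(0, 10), ev(numeric(0)),
                                      c(0, 10)), "no events")
})

test_that("distribution summary: trapezoid AUC, lower-tie peak, linearity", {
  d <- data.frame(bin_center = c(0.5, 1.5, 2.5), normalized = c(0, 1, 0))
  s <- summarize_distribution(d)
  expect_equal(s$auc, 1.0)
  expect_equal(s$peak_amplitude, 1.5)

  # tie broken toward the lower amplitude
  tie <- data.frame(bin_center = c(0.5, 1.5), normalized = c(0.4, 0.4))
  expect_equal(summarize_distribution(tie)$peak_amplitude, 0.5)

  # scaling scales AUC, leaves the peak
  d3 <- transform(d, normalized = normalized * 3)
  expect_equal(summarize_distribution(d3)$auc, 3 * s$auc)
  expect_equal(summarize_distribution(d3)$peak_amplitude, s$peak_amplitude)

  # rectangle-rule oracle agrees within one bin of mass
  set.seed(3)
  y <- runif(20)
  dd <- data.frame(bin_center = seq(0.25, by = 0.5, length.out = 20),
                   normalized = y)
  expect_lt(abs(summarize_distribution(dd)$auc - sum(y * 0.5)),
            max(y) * 0.5)
})

test_that("rate and amplitude manipulations dissociate AUC and peak", {
  set.seed(9)
  mk_ev <- function(n, amp_mean) {
    data.frame(time = sort(runif(n, 0, 1800)),
               amplitude = rlnorm(n, log(amp_mean) - 0.02, 0.2))
  }
  w1 <- mk_ev(150, 3)
  rate_up <- mk_ev(300, 3)     # doubled rate, same amplitudes
  amp_up <- mk_ev(150, 5)      # same rate, +2 z amplitude

  iv <- c(0, 1800)
  d_ref <- amplitude_distribution(w1, iv, w1, iv)
  d_rate <- amplitude_distribution(rate_up, iv, w1, iv)
  d_amp <- amplitude_distribution(amp_up, iv, w1, iv)

  s_ref <- summarize_distribution(d_ref)
  s_rate <- summarize_distribution(d_rate)
  s_amp <- summarize_distribution(d_amp)

  # rate-only: AUC rises above the reference's ~1, peak stays (within a bin)
  expect_gt(s_rate$auc, s_ref$auc * 1.5)
  expect_lte(abs(s_rate$peak_amplitude - s_ref$peak_amplitude), 0.5)
  # amplitude-only: peak shifts right by ~2 z (within a bin)
  expect_lte(abs((s_amp$peak_amplitude - s_ref$peak_amplitude) - 2), 0.5)
})

test_that("event counts are additive over disjoint epochs", {
  set.seed(13)
  ev <- data.frame(time = sort(runif(200, 0, 100)),
                   amplitude = runif(200, 0.2, 9.5))
  ref <- ev
  whole <- amplitude_distribution(ev, c(0, 100), ref, c(0, 100))
  a <- amplitude_distribution(ev, c(0, 40), ref, c(0, 100))
  b <- amplitude_distribution(ev, c(40, 100), ref, c(0, 100))
  expect_equal(a$count + b$count, whole$count)
})
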