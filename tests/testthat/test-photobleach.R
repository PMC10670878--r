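test_that("cFR anchors are exact and degenerate traces are rejected", {
  sim <- generate_photobleach_trace(photobleach_params(seed = 3L)) # noisy
  cfr <- compute_cfr(sim$trace)
  expect_identical(cfr$cfr[1], 1)
  expect_identical(cfr$cfr[2], 0)
  # no detectable bleach
  p0 <- quiet_frap_params(bleach_efficiency = 0, k = 0)
  sim0 <- generate_photobleach_trace(p0)
  expect_error(compute_cfr(sim0$trace), "no detectable bleach")
})

test_that("a trace frozen at its postbleach value keeps cFR at zero", {
  p <- quiet_frap_params(k = 0)
  sim <- generate_photobleach_trace(p)
  cfr <- compute_cfr(sim$trace)
  expect_equal(cfr$cfr[-1], rep(0, 30))
  # and a bleached trace identical to the reference keeps cFR at one
  tr <- sim$trace
  tr$bleached_fs <- tr$reference_cell
  tr$bleached_fs[2] <- 0 # need a bleach event to define the anchors
  cfr1 <- compute_cfr(tr)
  expect_equal(cfr1$cfr[-(1:2)], rep(1, 29))
})

test_that("noise-free cFR follows the finite-pool recovery closed form", {
  # the bleached molecules are destroyed, so recovery plateaus at
  # v_mc / (v_fs + v_mc), not at 1; oracle cross-checked by Euler stepping
  # in the generator tests
  p <- quiet_frap_params(k = 0.01)
  sim <- generate_photobleach_trace(p)
  cfr <- compute_cfr(sim$trace)
  P <- p$v_mc / (p$v_fs + p$v_mc)
  rate <- p$k * (1 / p$v_fs + 1 / p$v_mc)
  post <- cfr$time >= 0
  expect_lt(max(abs(cfr$cfr[post] - P * (1 - exp(-rate * cfr$time[post])))),
            1e-4)
})

test_that("acquisition-loss standard curve averages normalized distal traces", {
  p <- quiet_frap_params(k = 0, acq_loss = 0.99, bleach_target = "mother_cell")
  sim <- generate_photobleach_trace(p)
  loss <- fit_acquisition_loss(sim$trace)
  expect_equal(loss$retention, 0.99^(0:30) / 0.99^0, tolerance = 1e-12)
  expect_identical(loss$retention[1], 1)
  # explicit matrix input: mean of per-cell normalized curves
  m <- cbind(100 * 0.98^(0:5), 50 * 1.00^(0:5))
  lc <- fit_acquisition_loss(m)
  expect_equal(lc$retention, (0.98^(0:5) + 1) / 2)
  # nonpositive prebleach trace excluded with warning; all excluded errors
  m2 <- cbind(m, 0)
  expect_warning(lc2 <- fit_acquisition_loss(m2), "excluded")
  expect_equal(lc2$retention, lc$retention)
  expect_error(suppressWarnings(fit_acquisition_loss(cbind(0, 0))), "usable")
})

test_that("FLIP normalization anchors and no-transport flatness hold", {
  p <- quiet_frap_params(k = 0, acq_loss = 0.98, bleach_target = "mother_cell",
                         bleach_efficiency = 0.9)
  sim <- generate_photobleach_trace(p)
  loss <- fit_acquisition_loss(sim$trace)
  flip <- compute_flip(sim$trace, loss)
  expect_identical(flip$fs_norm[1], 1)
  expect_identical(flip$mc_norm[1], 1)
  expect_identical(flip$mc_norm[2], 0)
  # no exchange: corrected forespore signal stays at 1 at every frame
  expect_equal(flip$fs_norm, rep(1, 31), tolerance = 1e-9)
})

test_that("with transport the forespore signal drains toward the mother cell", {
  p <- quiet_frap_params(k = 0.05, acq_loss = 0.99,
                         bleach_target = "mother_cell", bleach_efficiency = 1)
  sim <- generate_photobleach_trace(p)
  flip <- compute_flip(sim$trace, fit_acquisition_loss(sim$trace))
  expect_lt(flip$fs_norm[31], 0.3)
  expect_true(all(diff(flip$fs_norm[-1]) <= 1e-9))
})

test_that("a unit retention curve makes correction a plain normalization", {
  p <- quiet_frap_params(k = 0.02, bleach_target = "mother_cell",
                         bleach_efficiency = 0.8)
  sim <- generate_photobleach_trace(p)
  ones <- data.frame(frame = sim$trace$frame, time = sim$trace$time,
                     retention = 1)
  flip <- compute_flip(sim$trace, ones)
  fs <- sim$trace$bleached_fs
  mc <- sim$trace$bleached_mc
  expect_equal(flip$fs_norm, fs / fs[1])
  expect_equal(flip$mc_norm, (mc - mc[2]) / (mc[1] - mc[2]))
  # mismatched grids and nonpositive retention are rejected
  expect_error(compute_flip(sim$trace, ones[-1, ]), "covers")
  bad <- ones; bad$retention[5] <- 0
  expect_error(compute_flip(sim$trace, bad), "positive")
})

test_that("curve averaging is pointwise with SD and refuses mixed grids", {
  s1 <- data.frame(time = 0:5, cfr = rep(0.4, 6))
  s2 <- data.frame(time = 0:5, cfr = rep(0.6, 6))
  av <- average_curves(list(s1, s2), "cfr")
  expect_equal(av$mean, rep(0.5, 6))
  expect_equal(av$sd, rep(stats::sd(c(0.4, 0.6)), 6))
  expect_equal(av$n, rep(2, 6))
  one <- average_curves(list(s1), "cfr")
  expect_equal(one$mean, s1$cfr)
  expect_equal(one$sd, rep(0, 6))
  s3 <- data.frame(time = seq(0, 10, 2), cfr = 0.1)
  expect_error(average_curves(list(s1, s3), "cfr"), "time grid")
})

test_that("averaged noisy recoveries track the closed form", {
  p0 <- quiet_frap_params(k = 0.03)
  reps <- lapply(1:50, function(s) {
    p <- photobleach_params(k = 0.03, noise_sd = 10, acq_loss = 1,
                            bleach_efficiency = 1, seed = s)
    compute_cfr(generate_photobleach_trace(p)$trace)
  })
  av <- average_curves(reps, "cfr")
  P <- p0$v_mc / (p0$v_fs + p0$v_mc)
  rate <- p0$k * (1 / p0$v_fs + 1 / p0$v_mc)
  post <- av$time > 0
  expected <- P * (1 - exp(-rate * av$time[post]))
  se <- av$sd[post] / sqrt(av$n[post])
  dev <- abs(av$mean[post] - expected) / se
  # Monte-Carlo check: ~95% of frames within 2 SE, none implausibly far
  expect_gte(mean(dev <= 2), 0.9)
  expect_true(all(dev <= 4.5))
})

test_that("exchange-rate recovery is exact without noise and bounded with it", {
  for (k in c(0.01, 0.1)) {
    p <- quiet_frap_params(k = k)
    cfr <- compute_cfr(generate_photobleach_trace(p)$trace)
    fit <- estimate_exchange_rate(cfr, p$v_fs, p$v_mc)
    expect_lt(abs(fit$k_hat - k) / k, 0.01)
    expect_true(fit$converged)
  }
  # flat curve: k pinned at zero
  p0 <- quiet_frap_params(k = 0)
  fit0 <- estimate_exchange_rate(compute_cfr(generate_photobleach_trace(p0)$trace),
                                 p0$v_fs, p0$v_mc)
  expect_lt(fit0$k_hat, 1e-4)
  short <- compute_cfr(generate_photobleach_trace(
    quiet_frap_params(k = 0.01, n_postbleach_frames = 3))$trace)
  expect_error(estimate_exchange_rate(short, 0.35, 3), "postbleach")
})

test_that("wild-type and channel-mutant cohorts separate by final-frame cFR", {
  final_cfr <- function(k, seeds) {
    vapply(seeds, function(s) {
      p <- photobleach_params(k = k, noise_sd = 10, acq_loss = 1,
                              bleach_efficiency = 1, seed = s)
      cfr <- compute_cfr(generate_photobleach_trace(p)$trace)
      cfr$cfr[nrow(cfr)]
    }, numeric(1))
  }
  wt <- final_cfr(0.03, 1:10)
  mut <- final_cfr(0, 11:20)
  expect_lte(stats::t.test(wt, mut)$p.value, 0.001)
})
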