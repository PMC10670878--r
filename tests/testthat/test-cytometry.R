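test_that("equal concentrations give a unit ratio and zero signal clips to zero", {
  sim <- generate_sporangium_image(quiet_image_params(
    reporter_conc_fs = 150, reporter_conc_mc = 150, seed = 2L))
  res <- seg_all(sim$stack)
  bg <- estimate_background(sim$stack, "reporter", threshold_absolute(100))
  rt <- concentration_ratio(res$seg, sim$stack, bg)
  expect_equal(rt$ratio, 1, tolerance = 1e-6)

  # forespore at background level: corrected mean clips to 0
  sim0 <- generate_sporangium_image(quiet_image_params(
    reporter_conc_fs = 0, reporter_conc_mc = 150, seed = 2L))
  res0 <- seg_all(sim0$stack)
  bg0 <- estimate_background(sim0$stack, "reporter", threshold_absolute(100))
  rt0 <- concentration_ratio(res0$seg, sim0$stack, bg0)
  expect_equal(rt0$ratio, 0)
  expect_true(rt0$ratio_defined)

  # zero mother-cell signal: undefined flag, not NaN
  simu <- generate_sporangium_image(quiet_image_params(
    reporter_conc_fs = 0, reporter_conc_mc = 0, seed = 2L))
  resu <- seg_all(simu$stack)
  bgu <- estimate_background(simu$stack, "reporter", threshold_absolute(100))
  rtu <- concentration_ratio(resu$seg, simu$stack, bgu)
  expect_false(rtu$ratio_defined)
  expect_true(is.na(rtu$ratio))
})

test_that("noise-free ratio estimates recover generator truth within 5%", {
  for (true_ratio in c(0.05, 0.25, 1.0)) {
    sim <- generate_sporangium_image(quiet_image_params(
      reporter_conc_fs = 200 * true_ratio, reporter_conc_mc = 200, seed = 7L))
    res <- seg_all(sim$stack)
    bg <- estimate_background(sim$stack, "reporter", threshold_absolute(100))
    rt <- concentration_ratio(res$seg, sim$stack, bg)
    expect_lt(abs(rt$ratio - true_ratio) / true_ratio, 0.05)
  }
})

test_that("volume mode uses the spherocylinder and spheroid models", {
  obj <- data.frame(extent_major = 40, extent_minor = 14,
                    semi_major = 8, semi_minor = 5)
  px <- 0.065
  L <- 40 * px; r <- 7 * px
  expect_equal(volume_estimate(obj, px, "spherocylinder"),
               pi * r^2 * (L - 2 * r) + 4 / 3 * pi * r^3)
  a <- 8 * px; b <- 5 * px
  expect_equal(volume_estimate(obj, px, "spheroid"), 4 / 3 * pi * a * b^2)
  sim <- generate_sporangium_image(quiet_image_params(seed = 2L))
  res <- seg_all(sim$stack)
  bg <- estimate_background(sim$stack, "reporter", threshold_absolute(100))
  rt <- concentration_ratio(res$seg, sim$stack, bg, volume_mode = TRUE)
  expect_gt(rt$fs_volume, 0)
  expect_gt(rt$mc_volume, rt$fs_volume)
})

test_that("depletion series are anchored at one and follow the decay", {
  p <- quiet_image_params(reporter_conc_fs = 100, reporter_conc_mc = 100,
                          seed = 5L)
  tl <- generate_timelapse(p, depletion_rate = 0.5, n_frames = 4)
  ser <- depletion_timecourse(tl$frames, threshold_absolute(300),
                              threshold_absolute(100))
  expect_length(ser, 1L)
  s <- ser[[1]]
  expect_identical(s$fs_norm[1], 1)
  expect_identical(s$mc_norm[1], 1)
  expect_equal(s$fs_norm, 0.5^(0:3), tolerance = 1e-3)
  expect_equal(s$mc_norm, rep(1, 4), tolerance = 1e-3)

  tl0 <- generate_timelapse(p, depletion_rate = 0, n_frames = 3)
  s0 <- depletion_timecourse(tl0$frames, threshold_absolute(300),
                             threshold_absolute(100))[[1]]
  expect_equal(s0$fs_norm, rep(1, 3), tolerance = 1e-6)
})

test_that("mother cell holds steady under noise while the forespore decays", {
  p <- sporangium_image_params(image_shape = c(96L, 96L), n_sporangia = 1L,
                               reporter_conc_fs = 200, reporter_conc_mc = 200,
                               poisson_noise = TRUE, background_sd = 2,
                               seed = 31L)
  tl <- generate_timelapse(p, depletion_rate = 0.3, n_frames = 5)
  ser <- depletion_timecourse(tl$frames, threshold_absolute(300),
                              threshold_absolute(100))
  s <- ser[[1]]
  expect_true(all(abs(s$mc_norm - 1) < 0.1))
  expect_equal(s$fs_norm, 0.7^(0:4), tolerance = 0.1)
})

test_that("BONCAT follows the corrected-mean over reference-median formula", {
  # constructed field: cell pixels at 100; background with mean 20, SD 5
  img <- matrix(0, 20, 20)
  fs <- matrix(FALSE, 20, 20); fs[2:4, 2:4] <- TRUE
  mc <- matrix(FALSE, 20, 20); mc[10:12, 10:12] <- TRUE
  bgm <- matrix(FALSE, 20, 20); bgm[16:20, 1] <- TRUE
  img[fs] <- 100; img[mc] <- 100
  img[16:20, 1] <- 20 + 5 * c(-1, -1, 0, 1, 1) # mean 20, sample SD 5 exactly
  m <- boncat_quantify(img, fs, mc, bgm, list(fs = 70, mc = 70))
  expect_equal(m$fs_value, (100 - 20 - 10) / 70)
  expect_equal(m$mc_value, 1)
  # below background + 2 SD clips to zero
  img[fs] <- 25
  m2 <- boncat_quantify(img, fs, mc, bgm, list(fs = 70, mc = 70))
  expect_identical(m2$fs_value, 0)
  # z-sections are sum-projected
  m3 <- boncat_quantify(list(img / 2, img / 2), fs, mc, bgm,
                        list(fs = 70, mc = 70))
  expect_equal(m3$mc_value, m2$mc_value)
  expect_error(boncat_quantify(img, fs, mc, bgm, list(fs = 0, mc = 70)),
               "reference")
  expect_error(boncat_quantify(img, fs, mc, fs, list(fs = 1, mc = 1)),
               "overlaps")
})

test_that("raising a cell's signal never lowers its BONCAT value", {
  img <- matrix(10, 20, 20)
  fs <- matrix(FALSE, 20, 20); fs[2:4, 2:4] <- TRUE
  mc <- matrix(FALSE, 20, 20); mc[10:12, 10:12] <- TRUE
  bgm <- matrix(FALSE, 20, 20); bgm[16:20, 16:20] <- TRUE
  vals <- vapply(seq(0, 200, by = 20), function(sig) {
    im <- img; im[fs] <- 10 + sig
    boncat_quantify(im, fs, mc, bgm, list(fs = 50, mc = 50))$fs_value
  }, numeric(1))
  expect_true(all(diff(vals) >= 0))
})

test_that("translation-arrest scenario zeroes the forespore BONCAT readout", {
  sim <- generate_sporangium_image(quiet_image_params(
    reporter_conc_fs = 0, reporter_conc_mc = 100, seed = 12L))
  bg <- estimate_background(sim$stack, "reporter", threshold_absolute(100))
  m <- boncat_quantify(get_channel(sim$stack, "reporter"),
                       sim$truth$fs_labels == 1, sim$truth$mc_labels == 1,
                       bg$mask, list(fs = 100, mc = 100))
  expect_equal(m$fs_value, 0)
  expect_equal(m$mc_value, 1, tolerance = 1e-6)
})

test_that("engulfment classification is exact on noise-free mixed truth", {
  p <- quiet_image_params(n_sporangia = 4L, image_shape = c(224L, 224L),
                          engulfed = c(TRUE, FALSE, TRUE, FALSE), seed = 21L)
  sim <- generate_sporangium_image(p)
  fs_objs <- sporoquant:::cell_objects_from_labels(sim$truth$fs_labels,
                                                   sim$stack)
  eng <- classify_engulfed(sim$stack, fs_objs)
  expect_identical(eng$engulfed, p$engulfed)
  # DAPI overlap excludes the non-engulfed forespores
  expect_identical(eng$dapi_overlap, !p$engulfed)
  st <- sim$stack
  st$channels$dapi <- NULL
  expect_error(classify_engulfed(st, fs_objs), "dapi")
})

test_that("phase-bright calls use a strict 0.1 AU boundary on engulfed spores", {
  base <- quiet_image_params(engulfed = TRUE, seed = 13L)
  score_at <- function(intensity) {
    p <- quiet_image_params(engulfed = TRUE, phase_intensity_fs = intensity,
                            seed = 13L)
    sim <- generate_sporangium_image(p)
    fs_objs <- sporoquant:::cell_objects_from_labels(sim$truth$fs_labels,
                                                     sim$stack)
    eng <- classify_engulfed(sim$stack, fs_objs)
    phase_bright_score(sim$stack, fs_objs, eng,
                       background_mask = sim$truth$fs_labels == 0 &
                         sim$truth$mc_labels == 0)
  }
  expect_true(score_at(0.15)$bright)
  expect_false(score_at(0.05)$bright)
  expect_false(score_at(0.1)$bright) # exactly at threshold: not bright
  # non-engulfed spores are never bright regardless of intensity
  p <- quiet_image_params(engulfed = FALSE, phase_intensity_fs = 0.5, seed = 13L)
  sim <- generate_sporangium_image(p)
  fs_objs <- sporoquant:::cell_objects_from_labels(sim$truth$fs_labels, sim$stack)
  eng <- classify_engulfed(sim$stack, fs_objs)
  ps <- phase_bright_score(sim$stack, fs_objs, eng,
                           background_mask = sim$truth$fs_labels == 0 &
                             sim$truth$mc_labels == 0)
  expect_false(ps$bright)
  expect_gt(ps$avg_phase, 0.1)
})
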