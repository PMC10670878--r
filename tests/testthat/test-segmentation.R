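test_that("uniform background segments to nothing", {
  st <- image_stack(list(membrane = matrix(5, 64, 64),
                         reporter = matrix(5, 64, 64)),
                    pixel_size = 0.065)
  parts <- segment_membrane(st, threshold_absolute(300), threshold_absolute(100))
  expect_equal(nrow(parts$forespores$objects), 0L)
  expect_equal(nrow(parts$whole_cells$objects), 0L)
})

test_that("single noise-free sporangium is recovered with sub-pixel accuracy", {
  sim <- generate_sporangium_image(quiet_image_params(seed = 3L))
  res <- seg_all(sim$stack)
  expect_equal(nrow(res$parts$forespores$objects), 1L)
  expect_equal(nrow(res$parts$whole_cells$objects), 1L)
  truth_c <- sporoquant:::mask_moments(sim$truth$fs_labels == 1)$centroid
  seg_c <- c(res$parts$forespores$objects$centroid_row,
             res$parts$forespores$objects$centroid_col)
  expect_lt(sqrt(sum((truth_c - seg_c)^2)), 1)
})

test_that("two separated sporangia give two objects each, ordered by position", {
  p <- quiet_image_params(n_sporangia = 2L, image_shape = c(96L, 192L),
                          centers = rbind(c(3.1, 3.1), c(3.1, 9.3)),
                          angles = c(0, 0))
  sim <- generate_sporangium_image(p)
  res <- seg_all(sim$stack)
  expect_equal(nrow(res$parts$forespores$objects), 2L)
  expect_equal(nrow(res$parts$whole_cells$objects), 2L)
  expect_equal(nrow(res$seg$pairs), 2L)
})

test_that("raising the high threshold never increases forespore count", {
  sim <- generate_sporangium_image(sporangium_image_params(seed = 8L,
                                                           n_sporangia = 3L))
  counts <- vapply(c(0.90, 0.95, 0.99, 0.995, 0.999), function(q) {
    parts <- segment_membrane(sim$stack, threshold_quantile(q),
                              threshold_absolute(1))
    nrow(parts$forespores$objects)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("threshold and channel errors are reported", {
  st <- image_stack(list(reporter = matrix(5, 32, 32)), pixel_size = 0.065)
  expect_error(segment_membrane(st), "membrane")
  sim <- generate_sporangium_image(quiet_image_params())
  expect_error(segment_membrane(sim$stack, threshold_absolute(100),
                                threshold_absolute(300)), "exceed")
})

test_that("mother cells are the whole-cell remainder after forespore subtraction", {
  sim <- generate_sporangium_image(quiet_image_params(seed = 4L))
  res <- seg_all(sim$stack)
  mc_mask <- res$seg$mother_cells$labels > 0
  fs_mask <- res$seg$forespores$labels > 0
  expect_false(any(mc_mask & fs_mask))
  truth_mc <- sim$truth$mc_labels > 0
  jaccard <- sum(mc_mask & truth_mc) / sum(mc_mask | truth_mc)
  expect_gte(jaccard, 0.8)
  # a whole cell entirely covered by a forespore yields no mother cell
  labs <- matrix(0L, 32, 32); labs[10:20, 10:20] <- 1L
  st <- image_stack(list(membrane = matrix(1, 32, 32)), pixel_size = 0.065)
  wc <- sporoquant:::cell_objects_from_labels(labs, st)
  fs <- sporoquant:::cell_objects_from_labels(labs, st)
  mc <- derive_mother_cells(wc, fs, st, min_area = 1)
  expect_equal(nrow(mc$objects), 0L)
  # with no overlapping forespore the mother cell equals the whole cell
  none <- sporoquant:::cell_objects_from_labels(matrix(0L, 32, 32), st)
  mc2 <- derive_mother_cells(wc, none, st, min_area = 1)
  expect_identical(mc2$labels, wc$labels)
})

test_that("pairing is one-to-one, strict, and breaks ties by angle then label", {
  sim <- generate_sporangium_image(quiet_image_params(seed = 6L))
  res <- seg_all(sim$stack)
  expect_equal(nrow(res$seg$pairs), 1L)
  # a distant forespore stays unmatched
  far <- seg_all(sim$stack, max_distance = 0.01)
  expect_equal(nrow(far$seg$pairs), 0L)
  expect_equal(far$seg$unmatched_forespores, 1L)

  # constructed tie: one forespore equidistant from two mother cells.
  # Enumerating both candidate assignments: both pass the filters, so the
  # smaller pair angle must win; with equal angles, the smaller label.
  fake_objs <- function(df) {
    structure(list(objects = df, labels = matrix(0L, 1, 1), pixel_size = 0.1),
              class = "cell_objects")
  }
  fs <- fake_objs(data.frame(label = 1L, centroid_row = 0, centroid_col = 0,
                             area = 10, orientation = 0))
  mc_df <- data.frame(
    label = c(1L, 2L),
    centroid_row = c(0, -10 * sin(20 * pi / 180)),
    centroid_col = c(-10, -10 * cos(20 * pi / 180)),
    area = 50,
    orientation = c(20, -20) # mc 1 off-axis by 20 deg, mc 2 aligned
  )
  seg <- pair_sporangia(fs, fake_objs(mc_df), max_distance = 3, max_angle = 45)
  expect_equal(nrow(seg$pairs), 1L)
  expect_equal(seg$pairs$mc_label, 2L) # smaller angle wins over smaller label
  mc_df$orientation <- c(0, -20) # both now aligned with their vectors
  seg2 <- pair_sporangia(fs, fake_objs(mc_df), max_distance = 3, max_angle = 45)
  expect_equal(seg2$pairs$mc_label, 1L) # equal angles: smaller label
})

test_that("noise-free random layouts are paired perfectly", {
  for (s in 1:8) {
    p <- sporangium_image_params(image_shape = c(192L, 192L), n_sporangia = 3L,
                                 poisson_noise = FALSE, background_sd = 0,
                                 seed = 100L + s)
    sim <- generate_sporangium_image(p)
    res <- seg_all(sim$stack)
    expect_equal(nrow(res$seg$pairs), 3L)
    # mask disjointness per pair
    for (i in seq_len(nrow(res$seg$pairs))) {
      fs_m <- object_mask(res$seg$forespores, res$seg$pairs$fs_label[i])
      mc_m <- object_mask(res$seg$mother_cells, res$seg$pairs$mc_label[i])
      expect_false(any(fs_m & mc_m))
    }
    # every truth forespore centroid matched within 1 px
    for (i in seq_len(3)) {
      tc <- sporoquant:::mask_moments(sim$truth$fs_labels == i)$centroid
      d <- sqrt((res$seg$forespores$objects$centroid_row - tc[1])^2 +
                  (res$seg$forespores$objects$centroid_col - tc[2])^2)
      expect_lt(min(d), 1)
    }
    expect_equal(anyDuplicated(res$seg$pairs$mc_label), 0L)
    expect_equal(anyDuplicated(res$seg$pairs$fs_label), 0L)
  }
})
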