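# Shared fixture builders: small noise-free fields and a one-call
# segmentation wrapper used throughout the suite. Membrane intensities are
# 200 (mother-cell outline) and 400 (forespore double membrane), so
# absolute thresholds of 300 / 100 separate the two outline populations.

quiet_image_params <- function(...) {
  args <- list(...)
  defaults <- list(image_shape = c(96L, 96L), n_sporangia = 1L,
                   poisson_noise = FALSE, background_sd = 0, seed = 1L)
  defaults[names(args)] <- args
  do.call(sporangium_image_params, defaults)
}

seg_all <- function(stack, high = 300, low = 100, min_area = 20,
                    max_distance = 3, max_angle = 30) {
  parts <- segment_membrane(stack, threshold_absolute(high),
                            threshold_absolute(low), min_area)
  mc <- derive_mother_cells(parts$whole_cells, parts$forespores, stack,
                            min_area = min_area)
  list(seg = pair_sporangia(parts$forespores, mc, max_distance, max_angle),
       parts = parts)
}

quiet_frap_params <- function(...) {
  args <- list(...)
  defaults <- list(noise_sd = 0, acq_loss = 1, bleach_efficiency = 1,
                   seed = 1L)
  defaults[names(args)] <- args
  do.call(photobleach_params, defaults)
}
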