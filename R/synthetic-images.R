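#' Parameters for the synthetic sporangium image generator
#'
#' Describes a field of sporulating cells as imaged in the membrane (FM 4-64),
#' GFP reporter, MitoTracker, DAPI and phase-contrast channels. The mother
#' cell is rendered as a 2D spherocylinder (rectangle with semicircular caps)
#' and the forespore as an ellipse aligned with the cell axis and placed at
#' one pole, matching sporangium morphology with minimal parameters. The
#' forespore's double membrane appears in the membrane channel as an outline
#' brighter than the mother-cell outline by `fs_outline_multiplier` — unless
#' the forespore is fully engulfed, in which case the impermeable membrane
#' dye cannot reach it and its outline appears only in the permeable-dye
#' (mito) channel.
#'
#' @param image_shape Integer (rows, cols) in pixels.
#' @param pixel_size Micrometres per pixel.
#' @param n_sporangia Number of sporangia to place.
#' @param mc_length,mc_radius Mother-cell length and radius, um.
#' @param fs_semiaxes Forespore ellipse semi-axes (a along the cell axis,
#'   b across), um. Must satisfy `a < mc_length/2`, `b < mc_radius`.
#' @param fs_offset Distance of the forespore centre from the mother-cell
#'   centre along the axis, um. `NULL` places the forespore at the pole.
#' @param membrane_intensity_mc Mother-cell membrane outline intensity, AU.
#' @param fs_outline_multiplier Brightness boost of the forespore double
#'   membrane relative to the mother-cell outline; must be >= 1.
#' @param reporter_conc_fs,reporter_conc_mc Per-pixel expected reporter
#'   intensity inside the forespore / mother cell, AU.
#' @param phase_intensity_fs Forespore phase-contrast intensity, AU on the
#'   normalized phase scale (a mature phase-bright spore exceeds 0.1 AU).
#' @param engulfed Logical, scalar or one per sporangium.
#' @param background_mean,background_sd Camera background level and Gaussian
#'   read-noise SD, AU.
#' @param poisson_noise Apply Poisson shot noise to the fluorescence
#'   channels' expected counts.
#' @param centers Optional n x 2 matrix of sporangium centres (um, row/col
#'   order); random non-overlapping placement if `NULL`.
#' @param angles Optional orientation of each cell axis, degrees; random if
#'   `NULL`.
#' @param seed Integer seed; identical parameters and seed give bit-identical
#'   output.
#' @return An object of class `sporangium_image_params`.
#' @export
sporangium_image_params <- function(image_shape = c(192L, 192L),
                                    pixel_size = 0.065,
                                    n_sporangia = 4L,
                                    mc_length = 2.5,
                                    mc_radius = 0.45,
                                    fs_semiaxes = c(0.5, 0.35),
                                    fs_offset = NULL,
                                    membrane_intensity_mc = 200,
                                    fs_outline_multiplier = 2,
                                    reporter_conc_fs = 100,
                                    reporter_conc_mc = 100,
                                    phase_intensity_fs = 0.3,
                                    engulfed = FALSE,
                                    background_mean = 10,
                                    background_sd = 2,
                                    poisson_noise = TRUE,
                                    centers = NULL,
                                    angles = NULL,
                                    seed = 1L) {
  check_number(image_shape, "image_shape", min = 8, len = 2L)
  check_number(pixel_size, "pixel_size", min = 1e-6)
  check_number(n_sporangia, "n_sporangia", min = 0)
  check_number(mc_length, "mc_length", min = 1e-6)
  check_number(mc_radius, "mc_radius", min = 1e-6)
  check_number(fs_semiaxes, "fs_semiaxes", min = 1e-6, len = 2L)
  if (fs_semiaxes[1] >= mc_length / 2 || fs_semiaxes[2] >= mc_radius) {
    stop_param("forespore semi-axes must satisfy a < mc_length/2 and b < mc_radius")
  }
  if (mc_length <= 2 * mc_radius) {
    stop_param("mc_length must exceed the cell diameter 2*mc_radius")
  }
  if (is.null(fs_offset)) fs_offset <- mc_length / 2 - fs_semiaxes[1] - 0.05
  check_number(fs_offset, "fs_offset", min = 0)
  if (fs_offset + fs_semiaxes[1] > mc_length / 2) {
    stop_param("forespore (offset + a) extends beyond the mother-cell pole")
  }
  check_number(membrane_intensity_mc, "membrane_intensity_mc", min = 0)
  check_number(fs_outline_multiplier, "fs_outline_multiplier", min = 1)
  check_number(reporter_conc_fs, "reporter_conc_fs", min = 0)
  check_number(reporter_conc_mc, "reporter_conc_mc", min = 0)
  check_number(phase_intensity_fs, "phase_intensity_fs", min = 0)
  check_number(background_mean, "background_mean", min = 0)
  check_number(background_sd, "background_sd", min = 0)
  n <- as.integer(n_sporangia)
  engulfed <- rep_len(as.logical(engulfed), max(n, 1L))
  if (!is.null(centers)) {
    centers <- matrix(as.numeric(centers), ncol = 2)
    if (nrow(centers) != n) stop_param("`centers` must have one row per sporangium")
  }
  if (!is.null(angles)) {
    angles <- rep_len(as.numeric(angles), n)
  }
  structure(
    list(image_shape = as.integer(image_shape), pixel_size = pixel_size,
         n_sporangia = n, mc_length = mc_length, mc_radius = mc_radius,
         fs_semiaxes = as.numeric(fs_semiaxes), fs_offset = fs_offset,
         membrane_intensity_mc = membrane_intensity_mc,
         fs_outline_multiplier = fs_outline_multiplier,
         reporter_conc_fs = reporter_conc_fs,
         reporter_conc_mc = reporter_conc_mc,
         phase_intensity_fs = phase_intensity_fs,
         engulfed = engulfed, background_mean = background_mean,
         background_sd = background_sd, poisson_noise = poisson_noise,
         centers = centers, angles = angles, seed = as.integer(seed)),
    class = "sporangium_image_params"
  )
}

# Geometry of one sporangium, in pixel units. Returns logical masks on the
# full image grid: mother-cell body, forespore ellipse (clipped to the body
# so truth masks are always nested), and the nucleoid blobs.
render_sporangium_masks <- function(shape, center_px, angle_deg, L_px, R_px,
                                    a_px, b_px, off_px) {
  nr <- shape[1]; nc <- shape[2]
  theta <- angle_deg * pi / 180
  # direction of the cell axis in (row, col) space; rows grow downward
  d <- c(-sin(theta), cos(theta))
  h <- L_px / 2 - R_px # half-length of the cylindrical part
  row0 <- matrix(seq_len(nr) - 1, nr, nc)
  col0 <- matrix(seq_len(nc) - 1, nr, nc, byrow = TRUE)
  pr <- row0 - center_px[1]
  pc <- col0 - center_px[2]
  # distance to the axis segment
  t_ax <- pr * d[1] + pc * d[2]
  t_cl <- pmin(pmax(t_ax, -h), h)
  dist2 <- (pr - t_cl * d[1])^2 + (pc - t_cl * d[2])^2
  body <- dist2 <= R_px^2
  # forespore ellipse at +off along the axis
  fr <- pr - off_px * d[1]
  fc <- pc - off_px * d[2]
  t_f <- fr * d[1] + fc * d[2]
  s_f <- -fr * d[2] + fc * d[1]
  fs <- ((t_f / a_px)^2 + (s_f / b_px)^2) <= 1
  fs <- fs & body
  # mother-cell nucleoid: ellipse in the half away from the forespore
  ncen <- -0.35 * h
  t_n <- t_ax - ncen
  s_n <- -pr * d[2] + pc * d[1]
  nuc_mc <- ((t_n / (0.35 * L_px))^2 + (s_n / (0.6 * R_px))^2) <= 1
  nuc_mc <- nuc_mc & body & !fs
  # forespore nucleoid: half-size ellipse at the forespore centre
  nuc_fs <- ((t_f / (0.5 * a_px))^2 + (s_f / (0.5 * b_px))^2) <= 1
  nuc_fs <- nuc_fs & fs
  list(body = body, fs = fs, nuc_mc = nuc_mc, nuc_fs = nuc_fs)
}

# Random non-overlapping placement by rejection sampling on bounding circles.
place_sporangia <- function(params) {
  n <- params$n_sporangia
  shape_um <- params$image_shape * params$pixel_size
  rad <- params$mc_length / 2 + 2 * params$pixel_size
  if (!is.null(params$centers)) {
    centers <- params$centers
    if (n > 1) {
      dd <- as.matrix(stats::dist(centers))
      diag(dd) <- Inf
      bad <- which(dd < 2 * rad, arr.ind = TRUE)
      bad <- bad[bad[, 1] < bad[, 2], , drop = FALSE]
      if (nrow(bad) > 0) {
        stop_param("sporangia overlap beyond the packing limit: indices %s",
                   paste(apply(bad, 1, paste, collapse = "-"), collapse = ", "))
      }
    }
  } else {
    if (2 * rad > min(shape_um) - 2 * rad && n > 0) {
      stop_param("image too small to place a sporangium without clipping")
    }
    centers <- matrix(NA_real_, n, 2)
    for (i in seq_len(n)) {
      ok <- FALSE
      for (try in seq_len(400L)) {
        cand <- c(stats::runif(1, rad, shape_um[1] - rad),
                  stats::runif(1, rad, shape_um[2] - rad))
        if (i == 1 ||
            all(sqrt(rowSums(sweep(centers[seq_len(i - 1), , drop = FALSE],
                                   2, cand)^2)) >= 2 * rad)) {
          centers[i, ] <- cand
          ok <- TRUE
          break
        }
      }
      if (!ok) {
        stop_param("could not place sporangium %d without overlap (packing limit)", i)
      }
    }
  }
  angles <- params$angles %||% stats::runif(n, -90, 90)
  list(centers = centers, angles = angles)
}

# Apply the camera noise model: Poisson shot noise on expected counts of the
# fluorescence channels, then additive Gaussian read noise, clipped at zero.
apply_camera_noise <- function(expectation, poisson, read_sd) {
  x <- expectation
  if (poisson) x <- matrix(stats::rpois(length(x), x), nrow(x), ncol(x))
  if (read_sd > 0) x <- x + stats::rnorm(length(x), 0, read_sd)
  pmax(x, 0)
}

#' Generate a ground-truthed synthetic sporangium image
#'
#' Renders a field of sporangia into the five channels `membrane`,
#' `reporter`, `mito`, `dapi`, `phase` and returns the stack together with
#' exact per-cell truth masks and concentrations. Engulfed forespores are
#' absent from the membrane (impermeable-dye) channel but present in the
#' mito (permeable-dye) channel, and carry no DAPI signal; non-engulfed
#' forespores appear in both dye channels and contain a DAPI nucleoid.
#'
#' @param params A [sporangium_image_params()].
#' @return A list with elements `stack` ([image_stack()]) and `truth`
#'   (class `ground_truth`): label matrices `fs_labels`, `mc_labels`
#'   (disjoint), per-cell table `cells` (concentrations, true ratio,
#'   engulfed flag, centre, angle), and the generator parameters.
#' @export
generate_sporangium_image <- function(params) {
  stopifnot(inherits(params, "sporangium_image_params"))
  with_seed(params$seed, {
    layout <- place_sporangia(params)
    render_field(params, layout,
                 fs_conc = rep(params$reporter_conc_fs, max(params$n_sporangia, 1L)))
  })
}

# Shared renderer: one frame given a fixed layout and per-cell forespore
# reporter concentrations. Runs inside the caller's seeded stream.
render_field <- function(params, layout, fs_conc) {
  shape <- params$image_shape
  px <- params$pixel_size
  n <- params$n_sporangia
  zero <- matrix(0, shape[1], shape[2])
  membrane <- zero; reporter <- zero; mito <- zero; dapi <- zero; phase <- zero
  fs_labels <- matrix(0L, shape[1], shape[2])
  mc_labels <- matrix(0L, shape[1], shape[2])
  cells <- data.frame(label = integer(0), fs_conc = numeric(0),
                      mc_conc = numeric(0), true_ratio = numeric(0),
                      engulfed = logical(0),
                      center_row_um = numeric(0), center_col_um = numeric(0),
                      angle = numeric(0))
  for (i in seq_len(n)) {
    m <- render_sporangium_masks(
      shape,
      center_px = layout$centers[i, ] / px,
      angle_deg = layout$angles[i],
      L_px = params$mc_length / px, R_px = params$mc_radius / px,
      a_px = params$fs_semiaxes[1] / px, b_px = params$fs_semiaxes[2] / px,
      off_px = params$fs_offset / px
    )
    body_out <- mask_outline(m$body)
    fs_out <- mask_outline(m$fs)
    imc <- params$membrane_intensity_mc
    membrane <- membrane + body_out * imc
    if (!params$engulfed[i]) {
      # forespore double membrane: brighter outline, max where it meets the
      # mother-cell outline
      membrane[fs_out] <- pmax(membrane[fs_out],
                               imc * params$fs_outline_multiplier)
    }
    mito <- mito + body_out * imc
    mito[fs_out] <- pmax(mito[fs_out], imc)
    reporter <- reporter + (m$body & !m$fs) * params$reporter_conc_mc +
      m$fs * fs_conc[i]
    dapi <- dapi + m$nuc_mc * imc
    if (!params$engulfed[i]) dapi <- dapi + m$nuc_fs * imc
    phase <- phase + m$fs * params$phase_intensity_fs
    fs_labels[m$fs] <- i
    mc_labels[m$body & !m$fs] <- i
    cells <- rbind(cells, data.frame(
      label = i, fs_conc = fs_conc[i], mc_conc = params$reporter_conc_mc,
      true_ratio = if (params$reporter_conc_mc > 0)
        fs_conc[i] / params$reporter_conc_mc else NA_real_,
      engulfed = params$engulfed[i],
      center_row_um = layout$centers[i, 1], center_col_um = layout$centers[i, 2],
      angle = layout$angles[i]
    ))
  }
  bg <- params$background_mean
  channels <- list(
    membrane = apply_camera_noise(membrane + bg, params$poisson_noise,
                                  params$background_sd),
    reporter = apply_camera_noise(reporter + bg, params$poisson_noise,
                                  params$background_sd),
    mito = apply_camera_noise(mito + bg, params$poisson_noise,
                              params$background_sd),
    dapi = apply_camera_noise(dapi + bg, params$poisson_noise,
                              params$background_sd),
    phase = phase # phase-contrast scale; camera noise model is for photon counts
  )
  truth <- structure(
    list(fs_labels = fs_labels, mc_labels = mc_labels, cells = cells,
         params = params, layout = layout),
    class = "ground_truth"
  )
  list(stack = image_stack(channels, pixel_size = px), truth = truth)
}

#' Generate a ground-truthed depletion time-lapse
#'
#' Renders `n_frames` frames of a fixed field in which the expected forespore
#' reporter concentration decays geometrically by a factor
#' `(1 - depletion_rate)` per frame while the mother-cell expectation stays
#' constant — emulating reporter depletion from the forespore after the
#' sporulation division.
#'
#' @param params A [sporangium_image_params()].
#' @param depletion_rate Per-frame fractional loss in `[0, 1]`.
#' @param n_frames Number of frames (>= 2).
#' @param frame_interval Time between frames, minutes (metadata only).
#' @return A list with `frames` (list of [image_stack()]) and `truth`
#'   carrying the per-frame true forespore concentrations and the true
#'   ratio series (monotone nonincreasing).
#' @export
generate_timelapse <- function(params, depletion_rate, n_frames,
                               frame_interval = 5) {
  stopifnot(inherits(params, "sporangium_image_params"))
  check_number(depletion_rate, "depletion_rate", min = 0, max = 1)
  check_number(n_frames, "n_frames", min = 2)
  n_frames <- as.integer(n_frames)
  with_seed(params$seed, {
    layout <- place_sporangia(params)
    factor <- (1 - depletion_rate)^(seq_len(n_frames) - 1)
    frames <- vector("list", n_frames)
    truth0 <- NULL
    ratio_series <- matrix(NA_real_, n_frames, max(params$n_sporangia, 1L))
    for (f in seq_len(n_frames)) {
      fs_conc <- rep(params$reporter_conc_fs * factor[f],
                     max(params$n_sporangia, 1L))
      out <- render_field(params, layout, fs_conc)
      out$stack$frame_times <- (f - 1) * frame_interval * 60
      frames[[f]] <- out$stack
      if (f == 1L) truth0 <- out$truth
      if (params$n_sporangia > 0) {
        ratio_series[f, ] <- out$truth$cells$true_ratio
      }
    }
    truth0$ratio_series <- ratio_series
    truth0$fs_conc_series <- params$reporter_conc_fs * factor
    truth0$depletion_rate <- depletion_rate
    list(frames = frames, truth = truth0)
  })
}

#' Serialize ground truth to disk
#'
#' Writes the per-cell table and scalar truth as JSON and the label masks as
#' 16-bit TIFFs alongside.
#'
#' @param truth A `ground_truth` object.
#' @param path Base path; writes `<path>.json`, `<path>_fs_labels.tif`,
#'   `<path>_mc_labels.tif`.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  jsonlite::write_json(
    list(cells = truth$cells,
         ratio_series = truth$ratio_series,
         fs_conc_series = truth$fs_conc_series,
         depletion_rate = truth$depletion_rate),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, null = "null"
  )
  write_label_tiff(truth$fs_labels, paste0(path, "_fs_labels.tif"))
  write_label_tiff(truth$mc_labels, paste0(path, "_mc_labels.tif"))
  invisible(path)
}
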