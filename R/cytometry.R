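#' Estimate image background from the acellular region
#'
#' The complement of the dilated low-threshold membrane mask segments the
#' background; its mean and SD in the requested channel are returned.
#'
#' @param stack An [image_stack()].
#' @param channel Channel to measure.
#' @param low_level Threshold spec for the membrane channel (see
#'   [threshold_quantile()]).
#' @param dilate_px Dilation radius applied to the cell mask before taking
#'   the complement, px.
#' @return List with `mean`, `sd` (AU) and the logical background `mask`.
#' @export
estimate_background <- function(stack, channel = "reporter",
                                low_level = threshold_quantile(0.95),
                                dilate_px = 3L) {
  mem <- get_channel(stack, "membrane")
  ch <- get_channel(stack, channel)
  lo <- resolve_threshold(low_level, mem)
  cells <- fill_holes(mem > lo)
  if (any(cells)) cells <- binary_dilate(cells, 2L * as.integer(dilate_px) + 1L)
  bg_mask <- !cells
  if (!any(bg_mask)) stop_param("no background pixels left after dilation")
  list(mean = mean(ch[bg_mask]), sd = stats::sd(ch[bg_mask]), mask = bg_mask)
}

#' Cell volume from mask geometry
#'
#' Mother cells are modelled as spherocylinders,
#' `V = pi r^2 (L - 2r) + 4/3 pi r^3`, with `L` and `2r` taken from the
#' mask extents along its principal axes; forespores as prolate spheroids,
#' `V = 4/3 pi a b^2`, with semi-axes from the mask's equivalent ellipse.
#'
#' @param object One row of a `cell_objects` feature table.
#' @param pixel_size um/px.
#' @param model `"spherocylinder"` or `"spheroid"`.
#' @return Volume in um^3.
#' @export
volume_estimate <- function(object, pixel_size,
                            model = c("spherocylinder", "spheroid")) {
  model <- match.arg(model)
  if (model == "spherocylinder") {
    L <- object$extent_major * pixel_size
    r <- object$extent_minor / 2 * pixel_size
    if (L <= 2 * r) return(4 / 3 * pi * (L / 2)^3) # degenerate: sphere
    pi * r^2 * (L - 2 * r) + 4 / 3 * pi * r^3
  } else {
    a <- object$semi_major * pixel_size
    b <- object$semi_minor * pixel_size
    4 / 3 * pi * a * b^2
  }
}

#' Forespore/mother-cell concentration ratios
#'
#' For every paired sporangium, computes background-subtracted mean reporter
#' intensities over the forespore and mother-cell masks and their ratio.
#' The default concentration proxy is the per-pixel mean (intensity per unit
#' projected area); with `volume_mode = TRUE` the background-subtracted
#' integrated intensity is divided by the model volume
#' ([volume_estimate()]), which additionally corrects for axial-depth
#' differences between the two cells. Negative corrected means are clipped
#' to zero; a zero mother-cell concentration flags the ratio as undefined
#' rather than propagating `NaN`.
#'
#' @param seg A `segmented_sporangia` from [pair_sporangia()].
#' @param stack The originating [image_stack()].
#' @param background Background estimate from [estimate_background()] (or a
#'   list with `mean`).
#' @param channel Reporter channel name.
#' @param volume_mode Normalize integrated intensities by model volumes.
#' @return Data frame with one row per pair: `fs_label`, `mc_label`,
#'   `fs_mean`, `mc_mean` (background-subtracted AU), `fs_conc`, `mc_conc`,
#'   `fs_volume`, `mc_volume` (um^3), `ratio`, `ratio_defined`.
#' @export
concentration_ratio <- function(seg, stack, background,
                                channel = "reporter", volume_mode = FALSE) {
  stopifnot(inherits(seg, "segmented_sporangia"))
  ch <- get_channel(stack, channel)
  px <- stack$pixel_size
  bg <- background$mean
  out <- lapply(seq_len(nrow(seg$pairs)), function(i) {
    p <- seg$pairs[i, ]
    fs_mask <- object_mask(seg$forespores, p$fs_label)
    mc_mask <- object_mask(seg$mother_cells, p$mc_label)
    if (!any(fs_mask) || !any(mc_mask)) {
      stop_param("pair %d references an empty mask", i)
    }
    fs_obj <- seg$forespores$objects[seg$forespores$objects$label == p$fs_label, ]
    mc_obj <- seg$mother_cells$objects[seg$mother_cells$objects$label == p$mc_label, ]
    fs_mean <- max(0, mean(ch[fs_mask]) - bg)
    mc_mean <- max(0, mean(ch[mc_mask]) - bg)
    fs_vol <- volume_estimate(fs_obj, px, "spheroid")
    mc_vol <- volume_estimate(mc_obj, px, "spherocylinder")
    if (volume_mode) {
      fs_conc <- max(0, sum(ch[fs_mask]) - bg * sum(fs_mask)) / fs_vol
      mc_conc <- max(0, sum(ch[mc_mask]) - bg * sum(mc_mask)) / mc_vol
    } else {
      fs_conc <- fs_mean
      mc_conc <- mc_mean
    }
    defined <- mc_conc > 0
    data.frame(fs_label = p$fs_label, mc_label = p$mc_label,
               fs_mean = fs_mean, mc_mean = mc_mean,
               fs_conc = fs_conc, mc_conc = mc_conc,
               fs_volume = fs_vol, mc_volume = mc_vol,
               ratio = if (defined) fs_conc / mc_conc else NA_real_,
               ratio_defined = defined)
  })
  if (length(out)) do.call(rbind, out) else
    data.frame(fs_label = integer(0), mc_label = integer(0),
               fs_mean = numeric(0), mc_mean = numeric(0),
               fs_conc = numeric(0), mc_conc = numeric(0),
               fs_volume = numeric(0), mc_volume = numeric(0),
               ratio = numeric(0), ratio_defined = logical(0))
}

#' Reporter depletion time course of a tracked sporangium
#'
#' Segments and pairs every frame, links the sporangium across frames by
#' nearest forespore centroid (within `max_displacement` um/frame), and
#' returns background-subtracted mean reporter intensities for both cells,
#' each series scaled so its initial value is exactly 1. If the track is
#' lost in a frame the series is truncated there with a warning.
#'
#' @param frames List of [image_stack()]s (time-ordered).
#' @param high_level,low_level,min_area Segmentation parameters
#'   ([segment_membrane()]).
#' @param max_distance,max_angle Pairing limits ([pair_sporangia()]).
#' @param channel Reporter channel.
#' @param max_displacement Maximum frame-to-frame forespore centroid
#'   displacement, um.
#' @return A list of `depletion_series` data frames (one per sporangium
#'   tracked from frame 1) with columns `frame`, `fs_raw`, `mc_raw`
#'   (background-subtracted AU), `fs_norm`, `mc_norm`.
#' @export
depletion_timecourse <- function(frames,
                                 high_level = threshold_quantile(0.995),
                                 low_level = threshold_quantile(0.95),
                                 min_area = 20,
                                 max_distance = 3, max_angle = 30,
                                 channel = "reporter",
                                 max_displacement = 1) {
  if (length(frames) < 2L) stop_param("need at least 2 frames")
  per_frame <- lapply(frames, function(st) {
    seg2 <- segment_membrane(st, high_level, low_level, min_area)
    mc <- derive_mother_cells(seg2$whole_cells, seg2$forespores, st)
    seg <- pair_sporangia(seg2$forespores, mc, max_distance, max_angle)
    bg <- estimate_background(st, channel, low_level)
    list(seg = seg, bg = bg, stack = st)
  })
  first <- per_frame[[1]]
  n_tracks <- nrow(first$seg$pairs)
  out <- vector("list", n_tracks)
  for (tr in seq_len(n_tracks)) {
    fs_raw <- numeric(0)
    mc_raw <- numeric(0)
    # current forespore centroid in um
    pair <- first$seg$pairs[tr, ]
    cur <- NULL
    for (f in seq_along(per_frame)) {
      pf <- per_frame[[f]]
      fsub <- pf$seg$forespores$objects
      if (f == 1L) {
        idx <- which(fsub$label == pair$fs_label)
      } else {
        if (nrow(fsub) == 0) idx <- integer(0) else {
          d <- sqrt((fsub$centroid_row - cur[1])^2 +
                      (fsub$centroid_col - cur[2])^2) * pf$stack$pixel_size
          idx <- which(d <= max_displacement &
                         fsub$label %in% pf$seg$pairs$fs_label)
          if (length(idx) > 1) idx <- idx[which.min(d[idx])]
        }
      }
      if (length(idx) == 0) {
        warning(sprintf("track %d lost at frame %d; series truncated", tr, f))
        break
      }
      fl <- fsub$label[idx]
      ml <- pf$seg$pairs$mc_label[pf$seg$pairs$fs_label == fl]
      ch <- get_channel(pf$stack, channel)
      fs_mask <- object_mask(pf$seg$forespores, fl)
      mc_mask <- object_mask(pf$seg$mother_cells, ml)
      fs_raw <- c(fs_raw, max(0, mean(ch[fs_mask]) - pf$bg$mean))
      mc_raw <- c(mc_raw, max(0, mean(ch[mc_mask]) - pf$bg$mean))
      cur <- c(fsub$centroid_row[idx], fsub$centroid_col[idx])
    }
    if (length(fs_raw) == 0 || fs_raw[1] <= 0 || mc_raw[1] <= 0) {
      out[[tr]] <- NULL
      next
    }
    ser <- data.frame(frame = seq_along(fs_raw),
                      fs_raw = fs_raw, mc_raw = mc_raw,
                      fs_norm = fs_raw / fs_raw[1],
                      mc_norm = mc_raw / mc_raw[1])
    class(ser) <- c("depletion_series", "data.frame")
    out[[tr]] <- ser
  }
  out[!vapply(out, is.null, logical(1))]
}

#' BONCAT per-cell protein-synthesis quantification
#'
#' Optical sections are sum-projected; each cell's mean intensity over its
#' mask is corrected by subtracting the background mean plus two background
#' SDs (clipped at zero) and divided by the reference median of the
#' corresponding cell type.
#'
#' @param z_sections List of matrices (or a single matrix for a presummed
#'   projection).
#' @param fs_mask,mc_mask Logical cell masks.
#' @param background_mask Logical mask of an acellular region, disjoint
#'   from all cells.
#' @param reference_medians List with `fs` and `mc` reference medians (> 0).
#' @return List (class `boncat_measurement`) with `fs_value`, `mc_value`,
#'   `fs_corrected`, `mc_corrected`, `background_mean`, `background_sd`.
#' @export
boncat_quantify <- function(z_sections, fs_mask, mc_mask, background_mask,
                            reference_medians) {
  if (is.matrix(z_sections)) z_sections <- list(z_sections)
  proj <- Reduce(`+`, z_sections)
  if (any(background_mask & (fs_mask | mc_mask))) {
    stop_param("background region overlaps a cell mask")
  }
  if (!is.list(reference_medians) ||
      is.null(reference_medians$fs) || is.null(reference_medians$mc) ||
      reference_medians$fs <= 0 || reference_medians$mc <= 0) {
    stop_param("reference_medians must be a list with positive `fs` and `mc`")
  }
  bg_mean <- mean(proj[background_mask])
  bg_sd <- stats::sd(proj[background_mask])
  if (is.na(bg_sd)) bg_sd <- 0
  corr <- function(mask) max(0, mean(proj[mask]) - (bg_mean + 2 * bg_sd))
  fs_corr <- corr(fs_mask)
  mc_corr <- corr(mc_mask)
  structure(
    list(fs_value = fs_corr / reference_medians$fs,
         mc_value = mc_corr / reference_medians$mc,
         fs_corrected = fs_corr, mc_corrected = mc_corr,
         background_mean = bg_mean, background_sd = bg_sd),
    class = "boncat_measurement"
  )
}

#' Classify forespores as fully engulfed
#'
#' A forespore is engulfed when its membrane is stained by the permeable
#' dye but not the impermeable one: the (mito - membrane) difference image
#' shows outline signal above threshold. Forespores overlapped by a DAPI
#' object are excluded, since DAPI cannot enter fully engulfed spores.
#'
#' @param stack [image_stack()] with registered `membrane`, `mito` and
#'   `dapi` channels.
#' @param forespores `cell_objects` of forespore candidates (e.g. truth
#'   masks or high-threshold mito segmentation).
#' @param diff_threshold Outline-mean threshold on the clipped difference
#'   image; `NULL` uses `median + 3 * mad` of the difference image.
#' @param dapi_threshold Threshold for DAPI-positive objects; `NULL` uses
#'   `median + 5 * mad` of the DAPI channel.
#' @param dapi_min_area Minimum DAPI object area, px^2.
#' @return Data frame with `label`, `outline_diff` (AU), `dapi_overlap`,
#'   `engulfed`.
#' @export
classify_engulfed <- function(stack, forespores, diff_threshold = NULL,
                              dapi_threshold = NULL, dapi_min_area = 5) {
  for (nm in c("membrane", "mito", "dapi")) {
    if (!nm %in% names(stack$channels)) stop_param("stack has no '%s' channel", nm)
  }
  diffim <- pmax(get_channel(stack, "mito") - get_channel(stack, "membrane"), 0)
  if (is.null(diff_threshold)) {
    diff_threshold <- stats::median(diffim) + 3 * stats::mad(diffim)
  }
  dapi <- get_channel(stack, "dapi")
  if (is.null(dapi_threshold)) {
    dapi_threshold <- stats::median(dapi) + 5 * stats::mad(dapi)
  }
  dapi_mask <- dapi > dapi_threshold
  if (any(dapi_mask)) {
    lab <- EBImage::bwlabel(EBImage::Image(dapi_mask * 1))
    labm <- matrix(as.integer(EBImage::imageData(lab)), nrow(dapi), ncol(dapi))
    sizes <- tabulate(labm[labm > 0])
    keep <- which(sizes >= dapi_min_area)
    dapi_mask <- labm %in% keep & labm > 0
    dapi_mask <- matrix(dapi_mask, nrow(dapi), ncol(dapi))
  }
  objs <- forespores$objects
  out <- lapply(seq_len(nrow(objs)), function(i) {
    mask <- object_mask(forespores, objs$label[i])
    outline <- mask_outline(mask)
    sig <- mean(diffim[outline])
    overlap <- any(dapi_mask & mask)
    data.frame(label = objs$label[i], outline_diff = sig,
               dapi_overlap = overlap,
               engulfed = (sig > diff_threshold) && !overlap)
  })
  if (length(out)) do.call(rbind, out) else
    data.frame(label = integer(0), outline_diff = numeric(0),
               dapi_overlap = logical(0), engulfed = logical(0))
}

#' Phase-bright spore scoring
#'
#' For each engulfed forespore the average phase intensity over its mask is
#' computed with the average background phase intensity removed; a spore is
#' phase-bright when this exceeds the threshold (0.1 AU by default,
#' strictly: a value of exactly 0.1 is not bright). Only engulfed
#' forespores are scored as bright.
#'
#' @param stack [image_stack()] with a `phase` channel.
#' @param forespores `cell_objects` of forespores.
#' @param engulfed Data frame from [classify_engulfed()] (or a logical
#'   vector aligned with the forespore labels).
#' @param background_mask Logical acellular mask; `NULL` derives it from
#'   the membrane channel via [estimate_background()].
#' @param threshold Phase-bright threshold, AU.
#' @return Data frame with `label`, `engulfed`, `avg_phase`
#'   (background-subtracted AU), `bright`.
#' @export
phase_bright_score <- function(stack, forespores, engulfed,
                               background_mask = NULL, threshold = 0.1) {
  ph <- get_channel(stack, "phase")
  if (is.null(background_mask)) {
    background_mask <- estimate_background(stack, "phase")$mask
  }
  bg <- mean(ph[background_mask])
  if (is.data.frame(engulfed)) {
    eng <- engulfed$engulfed[match(forespores$objects$label, engulfed$label)]
  } else {
    eng <- rep_len(as.logical(engulfed), nrow(forespores$objects))
  }
  objs <- forespores$objects
  out <- lapply(seq_len(nrow(objs)), function(i) {
    mask <- object_mask(forespores, objs$label[i])
    avg <- mean(ph[mask]) - bg
    data.frame(label = objs$label[i], engulfed = eng[i], avg_phase = avg,
               bright = isTRUE(eng[i]) && (avg > threshold))
  })
  if (length(out)) do.call(rbind, out) else
    data.frame(label = integer(0), engulfed = logical(0),
               avg_phase = numeric(0), bright = logical(0))
}

#' Box-plot summary statistics used for ratio cohorts
#'
#' Median, the middle 75% of the data (boxes) and the middle 90%
#' (whiskers), plus n.
#'
#' @param x Numeric vector.
#' @return Named list of summary statistics.
#' @export
ratio_box_stats <- function(x) {
  x <- x[is.finite(x)]
  q <- stats::quantile(x, c(0.05, 0.125, 0.5, 0.875, 0.95), names = FALSE)
  list(n = length(x), median = q[3], box_low = q[2], box_high = q[4],
       whisker_low = q[1], whisker_high = q[5])
}
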