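#' Threshold specifications
#'
#' The membrane-channel thresholds can be given either as intensity
#' quantiles of the channel (robust across exposure settings) or as absolute
#' intensities in AU.
#'
#' @param q Quantile in `[0, 1]`.
#' @return A threshold spec understood by [segment_membrane()].
#' @export
threshold_quantile <- function(q) {
  check_number(q, "q", min = 0, max = 1)
  structure(list(kind = "quantile", value = q), class = "threshold_spec")
}

#' @rdname threshold_quantile
#' @param value Absolute intensity, AU.
#' @export
threshold_absolute <- function(value) {
  check_number(value, "value", min = 0)
  structure(list(kind = "absolute", value = value), class = "threshold_spec")
}

resolve_threshold <- function(spec, channel) {
  if (!inherits(spec, "threshold_spec")) {
    stop_param("thresholds must be built with threshold_quantile() or threshold_absolute()")
  }
  if (spec$kind == "quantile") {
    stats::quantile(channel, spec$value, names = FALSE)
  } else {
    spec$value
  }
}

# Build a cell_objects value from a label matrix: feature table + labels.
cell_objects_from_labels <- function(labels, stack, min_area = 0) {
  ids <- setdiff(sort(unique(as.vector(labels))), 0L)
  keep <- integer(0)
  rows <- list()
  relabelled <- matrix(0L, nrow(labels), ncol(labels))
  next_label <- 0L
  for (id in ids) {
    mask <- labels == id
    mom <- mask_moments(mask)
    if (mom$area < min_area) next
    next_label <- next_label + 1L
    relabelled[mask] <- next_label
    means <- vapply(stack$channels, function(ch) mean(ch[mask]), numeric(1))
    rows[[length(rows) + 1L]] <- data.frame(
      label = next_label,
      centroid_row = mom$centroid[1], centroid_col = mom$centroid[2],
      area = mom$area, orientation = mom$orientation,
      semi_major = mom$semi_major, semi_minor = mom$semi_minor,
      extent_major = mom$extent_major, extent_minor = mom$extent_minor,
      t(means)
    )
  }
  objects <- if (length(rows)) do.call(rbind, rows) else
    data.frame(label = integer(0), centroid_row = numeric(0),
               centroid_col = numeric(0), area = numeric(0),
               orientation = numeric(0), semi_major = numeric(0),
               semi_minor = numeric(0), extent_major = numeric(0),
               extent_minor = numeric(0))
  structure(list(objects = objects, labels = relabelled,
                 pixel_size = stack$pixel_size),
            class = "cell_objects")
}

#' @export
print.cell_objects <- function(x, ...) {
  cat(sprintf("cell_objects: %d objects\n", nrow(x$objects)))
  invisible(x)
}

#' Mask of one cell object
#'
#' @param objs A `cell_objects` value.
#' @param label Object label.
#' @return Logical matrix.
#' @export
object_mask <- function(objs, label) {
  objs$labels == label
}

#' Dual-threshold segmentation of the membrane channel
#'
#' Thresholding the membrane (FM 4-64) channel high isolates the bright
#' double membrane around each forespore; thresholding low gives the whole
#' sporangium outline. Connected components (8-connectivity) are hole-filled
#' and filtered by minimum area, yielding solid forespore and whole-cell
#' objects.
#'
#' @param stack An [image_stack()] with a `membrane` channel.
#' @param high_level,low_level Threshold specs ([threshold_quantile()] /
#'   [threshold_absolute()]); the resolved high threshold must exceed the
#'   low one.
#' @param min_area Minimum object area, px^2.
#' @return A list with `forespores` and `whole_cells`, both `cell_objects`.
#' @export
segment_membrane <- function(stack,
                             high_level = threshold_quantile(0.995),
                             low_level = threshold_quantile(0.95),
                             min_area = 20) {
  stopifnot(inherits(stack, "image_stack"))
  if (!"membrane" %in% names(stack$channels)) {
    stop_param("stack has no 'membrane' channel")
  }
  ch <- get_channel(stack, "membrane")
  hi <- resolve_threshold(high_level, ch)
  lo <- resolve_threshold(low_level, ch)
  if (hi <= lo) stop_param("high threshold (%g) must exceed low threshold (%g)", hi, lo)
  seg_at <- function(thr) {
    mask <- ch > thr
    if (!any(mask)) {
      return(cell_objects_from_labels(matrix(0L, nrow(ch), ncol(ch)), stack, min_area))
    }
    lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
    lab <- EBImage::fillHull(lab)
    cell_objects_from_labels(matrix(as.integer(EBImage::imageData(lab)),
                                    nrow(ch), ncol(ch)),
                             stack, min_area)
  }
  list(forespores = seg_at(hi), whole_cells = seg_at(lo))
}

#' Derive mother cells by subtracting forespores from whole cells
#'
#' Each forespore mask is dilated by one pixel before subtraction so that
#' shared membrane-outline pixels are not attributed to the mother cell;
#' whole cells left empty by the subtraction are dropped.
#'
#' @param whole_cells,forespores `cell_objects` from the same stack (see
#'   [segment_membrane()]).
#' @param stack The originating [image_stack()] (for per-channel means).
#' @param dilate_px Dilation radius applied to forespore masks, px.
#' @param min_area Minimum remaining mother-cell area, px^2.
#' @return Mother cells as `cell_objects`.
#' @export
derive_mother_cells <- function(whole_cells, forespores, stack,
                                dilate_px = 1L, min_area = 20) {
  fs_any <- forespores$labels > 0
  if (any(fs_any) && dilate_px > 0) {
    fs_any <- binary_dilate(fs_any, 2L * as.integer(dilate_px) + 1L)
  }
  mc_labels <- whole_cells$labels
  mc_labels[fs_any] <- 0L
  cell_objects_from_labels(mc_labels, stack, min_area)
}

#' Pair forespores with their mother cells
#'
#' Candidate mother cells are filtered first by Euclidean
#' centroid-to-centroid distance, then by the angle between the mother
#' cell's major axis and the centroid-to-centroid vector; both filters are
#' strict to reduce false matches. Matching is one-to-one: forespores are
#' processed in label order and each takes the nearest surviving candidate,
#' with ties broken by smaller pair angle, then smaller mother-cell label.
#'
#' @param forespores,mother_cells `cell_objects`.
#' @param max_distance Maximum pairing distance, um (default 3, about one
#'   sporangium length).
#' @param max_angle Maximum pairing angle, degrees (default 30).
#' @return An object of class `segmented_sporangia`: data frame `pairs`
#'   (`fs_label`, `mc_label`, `pair_distance` um, `pair_angle` deg) plus
#'   `unmatched_forespores`, `unmatched_mother_cells`, and the two
#'   `cell_objects` inputs.
#' @export
pair_sporangia <- function(forespores, mother_cells,
                           max_distance = 3, max_angle = 30) {
  check_number(max_distance, "max_distance", min = 0)
  check_number(max_angle, "max_angle", min = 0, max = 90)
  px <- forespores$pixel_size
  fs <- forespores$objects
  mc <- mother_cells$objects
  pairs <- data.frame(fs_label = integer(0), mc_label = integer(0),
                      pair_distance = numeric(0), pair_angle = numeric(0))
  used_mc <- integer(0)
  for (i in seq_len(nrow(fs))) {
    if (nrow(mc) == 0) break
    dr <- (fs$centroid_row[i] - mc$centroid_row) * px
    dc <- (fs$centroid_col[i] - mc$centroid_col) * px
    dist <- sqrt(dr^2 + dc^2)
    # angle between the mother-cell major axis and the vector to the
    # forespore, folded to [0, 90]
    vec_ang <- atan2(-dr, dc) * 180 / pi
    ang <- abs((vec_ang - mc$orientation) %% 180)
    ang <- pmin(ang, 180 - ang)
    ok <- which(dist <= max_distance & ang <= max_angle &
                  !(mc$label %in% used_mc))
    if (length(ok) == 0) next
    ord <- ok[order(dist[ok], ang[ok], mc$label[ok])]
    j <- ord[1]
    used_mc <- c(used_mc, mc$label[j])
    pairs <- rbind(pairs, data.frame(
      fs_label = fs$label[i], mc_label = mc$label[j],
      pair_distance = dist[j], pair_angle = ang[j]
    ))
  }
  structure(
    list(pairs = pairs,
         unmatched_forespores = setdiff(fs$label, pairs$fs_label),
         unmatched_mother_cells = setdiff(mc$label, pairs$mc_label),
         forespores = forespores, mother_cells = mother_cells),
    class = "segmented_sporangia"
  )
}

#' @export
print.segmented_sporangia <- function(x, ...) {
  cat(sprintf("segmented_sporangia: %d pairs (%d forespores / %d mother cells unmatched)\n",
              nrow(x$pairs), length(x$unmatched_forespores),
              length(x$unmatched_mother_cells)))
  invisible(x)
}

#' Write pairing results
#'
#' Writes the pairs table as CSV and the forespore / mother-cell label
#' images as 16-bit TIFFs.
#'
#' @param seg A `segmented_sporangia`.
#' @param prefix Output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_segmentation <- function(seg, prefix) {
  stopifnot(inherits(seg, "segmented_sporangia"))
  utils::write.csv(seg$pairs, paste0(prefix, "_pairs.csv"), row.names = FALSE)
  write_label_tiff(seg$forespores$labels, paste0(prefix, "_fs_labels.tif"))
  write_label_tiff(seg$mother_cells$labels, paste0(prefix, "_mc_labels.tif"))
  invisible(prefix)
}
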