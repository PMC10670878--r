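#' Multi-channel image stack
#'
#' Container for a registered set of single-plane fluorescence/phase channels
#' sharing one pixel grid, plus the physical pixel size. Time-lapse data are
#' represented as a list of `image_stack` objects with `frame_times` recorded
#' on each stack.
#'
#' @param channels Named list of numeric matrices (intensities in arbitrary
#'   units, AU). All matrices must share one shape; values must be finite and
#'   nonnegative.
#' @param pixel_size Physical pixel size in micrometres per pixel.
#' @param frame_times Optional numeric vector of acquisition times in seconds.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(channels, pixel_size, frame_times = NULL) {
  if (!is.list(channels) || is.null(names(channels)) ||
      any(!nzchar(names(channels)))) {
    stop_param("`channels` must be a named list of matrices")
  }
  dims <- lapply(channels, dim)
  if (length(unique(dims)) != 1L) {
    stop_param("all channels must share one shape")
  }
  for (nm in names(channels)) {
    ch <- channels[[nm]]
    if (!is.matrix(ch) || !is.numeric(ch) || any(!is.finite(ch)) || any(ch < 0)) {
      stop_param("channel '%s' must be a finite nonnegative numeric matrix", nm)
    }
  }
  check_number(pixel_size, "pixel_size", min = .Machine$double.eps)
  structure(
    list(channels = channels, pixel_size = pixel_size,
         frame_times = frame_times),
    class = "image_stack"
  )
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("image_stack: %d x %d px, %.3f um/px, channels: %s\n",
              d[1], d[2], x$pixel_size,
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

#' Get one channel of an image stack
#'
#' @param stack An [image_stack()].
#' @param name Channel name.
#' @return The channel matrix.
#' @export
get_channel <- function(stack, name) {
  stopifnot(inherits(stack, "image_stack"))
  if (!name %in% names(stack$channels)) {
    stop_param("channel '%s' not present (have: %s)", name,
               paste(names(stack$channels), collapse = ", "))
  }
  stack$channels[[name]]
}

#' Write an image stack as multi-page TIFF plus JSON sidecar
#'
#' Channels are written as one 32-bit float page each, in stack order; the
#' sidecar records channel order and pixel size so the file round-trips.
#'
#' @param stack An [image_stack()].
#' @param path Output TIFF path; the sidecar is written at `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  # TIFF pages are stored on [0, 1]; the sidecar records the AU scale so
  # intensities round-trip
  scale <- max(vapply(stack$channels, max, numeric(1)), 1)
  pages <- lapply(stack$channels, function(m) m / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  sidecar <- list(
    channels = as.list(names(stack$channels)),
    pixel_size = stack$pixel_size,
    intensity_scale = scale,
    frame_times = stack$frame_times
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read an image stack written by [write_image_stack()]
#'
#' @param path TIFF path with `<path>.json` sidecar alongside.
#' @return An [image_stack()].
#' @export
read_image_stack <- function(path) {
  sidecar_path <- paste0(path, ".json")
  if (!file.exists(sidecar_path)) {
    stop_param("channel-map sidecar '%s' not found", sidecar_path)
  }
  sidecar <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != length(sidecar$channels)) {
    stop_param("TIFF has %d pages but sidecar lists %d channels",
               length(pages), length(sidecar$channels))
  }
  scale <- sidecar$intensity_scale %||% 1
  pages <- lapply(pages, function(m) m * scale)
  names(pages) <- sidecar$channels
  ft <- sidecar$frame_times
  if (length(ft) == 0) ft <- NULL
  image_stack(pages, pixel_size = sidecar$pixel_size, frame_times = ft)
}

#' Write an integer label image as 16-bit TIFF
#'
#' @param labels Integer matrix of per-cell labels (0 = background).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_label_tiff <- function(labels, path) {
  if (max(labels) > 65535) stop_param("labels exceed 16-bit range")
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a label image written by [write_label_tiff()]
#'
#' @param path TIFF path.
#' @return Integer label matrix.
#' @export
read_label_tiff <- function(path) {
  m <- tiff::readTIFF(path)
  round(m * 65535)
}
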