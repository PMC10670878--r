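# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state. All generator randomness flows through a single stream.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(code)
}

stop_param <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

check_number <- function(x, name, min = -Inf, max = Inf, len = 1L) {
  if (!is.numeric(x) || length(x) != len || any(!is.finite(x))) {
    stop_param("`%s` must be %d finite numeric value(s)", name, len)
  }
  if (any(x < min) || any(x > max)) {
    stop_param("`%s` must lie in [%s, %s]", name, format(min), format(max))
  }
  invisible(x)
}

# Binary morphology on logical matrices via EBImage (3x3 box = 8-connected).
binary_erode <- function(mask, size = 3L) {
  m <- EBImage::erode(EBImage::Image(mask * 1), EBImage::makeBrush(size, "box"))
  EBImage::imageData(m) > 0.5
}

binary_dilate <- function(mask, size = 3L) {
  m <- EBImage::dilate(EBImage::Image(mask * 1), EBImage::makeBrush(size, "box"))
  EBImage::imageData(m) > 0.5
}

fill_holes <- function(mask) {
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  EBImage::imageData(EBImage::fillHull(lab)) > 0.5
}

# 1-pixel-wide boundary of a binary region
mask_outline <- function(mask) {
  mask & !binary_erode(mask)
}

# Image second-moment summaries used for CellObject features: centroid,
# area, orientation of the major axis in degrees within (-90, 90], and the
# equivalent-ellipse semi-axes (in pixels).
mask_moments <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  n <- nrow(idx)
  if (n == 0L) {
    return(list(area = 0, centroid = c(NA_real_, NA_real_)))
  }
  r <- idx[, 1] - 1 # 0-based coordinates
  c <- idx[, 2] - 1
  cr <- mean(r)
  cc <- mean(c)
  mrr <- mean((r - cr)^2)
  mcc <- mean((c - cc)^2)
  mrc <- mean((r - cr) * (c - cc))
  # orientation measured from the column (x) axis, as atan2 of the principal
  # eigenvector; image rows grow downward so flip the sign for math convention
  theta <- 0.5 * atan2(2 * mrc, mcc - mrr)
  ang <- -theta * 180 / pi
  if (ang <= -90) ang <- ang + 180
  if (ang > 90) ang <- ang - 180
  ev <- eigen(matrix(c(mrr, mrc, mrc, mcc), 2, 2), symmetric = TRUE)$values
  ev <- pmax(ev, 0)
  # extent along the principal axes
  ax <- cos(theta)
  ay <- sin(theta)
  proj_major <- (c - cc) * ax + (r - cr) * ay
  proj_minor <- -(c - cc) * ay + (r - cr) * ax
  list(
    area = n,
    centroid = c(cr, cc),
    orientation = ang,
    semi_major = 2 * sqrt(ev[1]),
    semi_minor = 2 * sqrt(ev[2]),
    extent_major = diff(range(proj_major)) + 1,
    extent_minor = diff(range(proj_minor)) + 1
  )
}

md5_of_file <- function(path) unname(tools::md5sum(path))

`%||%` <- function(a, b) if (is.null(a)) b else a
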