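# Fovea/disc-calibrated retinal frame, four clock-hour zones, posterior pole,
# and the 48-partition system (24 sectors of 15 degrees x inner/outer ring).
#
# Conventions used throughout:
#   * pixel coordinates are 1-based (x = column, y = row), continuous values
#     allowed for landmarks; images are H x W matrices/arrays with row = y.
#   * the clock angle theta of a pixel is measured clockwise from the
#     calibrated 12 o'clock direction, theta in [0, 360).
#   * partition indices are 0-based: index = ring * 24 + floor(theta / 15),
#     ring 0 inside the posterior-pole circle, ring 1 outside.

#' Zone labels in canonical order
#'
#' Fixed order used for confusion matrices and tie-breaking displays:
#' superior, right, inferior, left.
#'
#' @return Character vector of the four zone names.
#' @export
rd_zones <- function() c("superior", "right", "inferior", "left")

#' Build the fovea/disc-calibrated retinal frame
#'
#' The anatomical coordinate system is centered on the fovea and calibrated by
#' the horizontal line through the fovea and the optic disc center. The
#' posterior pole is the smallest fovea-centered circle containing the whole
#' disc, so its radius is `|disc_center - fovea| + disc_radius`.
#'
#' The rotation is the angle of the fovea-disc line relative to the image
#' x-axis, sign-normalized so the calibrated horizontal points toward
#' increasing image x (the fovea->disc direction is flipped for left eyes,
#' where the disc sits on the image-left of the fovea).
#'
#' @param fovea Numeric `c(x, y)` fovea position in pixels.
#' @param disc Either a `disc_geometry` object (see
#'   [extract_disc_geometry()]) or a list with `center = c(x, y)` and
#'   `radius`.
#' @param laterality `"OD"` (right eye) or `"OS"` (left eye).
#' @param canvas Integer `c(height, width)` of the image grid.
#' @return An object of class `rd_frame`: fovea, disc_center, disc_radius,
#'   rotation (degrees), laterality, posterior_pole_radius, canvas.
#' @export
fit_frame <- function(fovea, disc, laterality = c("OD", "OS"), canvas) {
  laterality <- match.arg(laterality)
  stopifnot(length(fovea) == 2, length(canvas) == 2)
  dc <- disc$center
  dr <- disc$radius
  stopifnot(length(dc) == 2, is.numeric(dr), dr > 0)
  d <- c(dc[1] - fovea[1], dc[2] - fovea[2])
  if (sqrt(sum(d^2)) < .Machine$double.eps^0.5) {
    stop("fovea and disc center coincide; frame undefined")
  }
  # normalize so the calibrated horizontal points toward increasing image-x
  if (d[1] < 0) d <- -d
  rotation <- atan2(d[2], d[1]) * 180 / pi
  structure(list(
    fovea = as.numeric(fovea),
    disc_center = as.numeric(dc),
    disc_radius = as.numeric(dr),
    rotation = rotation,
    laterality = laterality,
    posterior_pole_radius = sqrt(sum((dc - fovea)^2)) + dr,
    canvas = as.integer(canvas)
  ), class = "rd_frame")
}

#' @export
print.rd_frame <- function(x, ...) {
  cat(sprintf(
    "rd_frame: fovea (%.1f, %.1f), disc (%.1f, %.1f) r=%.1f, rot=%.2f deg, %s, pole r=%.1f, canvas %dx%d\n",
    x$fovea[1], x$fovea[2], x$disc_center[1], x$disc_center[2],
    x$disc_radius, x$rotation, x$laterality, x$posterior_pole_radius,
    x$canvas[1], x$canvas[2]
  ))
  invisible(x)
}

#' Clock angle of pixels in the calibrated frame
#'
#' Angle in degrees measured clockwise from calibrated 12 o'clock
#' (1 clock hour = 30 degrees), after compensating the frame rotation.
#'
#' @param frame An `rd_frame`.
#' @param x,y Numeric vectors of pixel coordinates.
#' @return Numeric vector of angles in `[0, 360)`.
#' @export
clock_angle <- function(frame, x, y) {
  vx <- x - frame$fovea[1]
  vy <- y - frame$fovea[2]
  th <- frame$rotation * pi / 180
  # rotate by -rotation in image coords (y axis points down)
  rx <- cos(th) * vx + sin(th) * vy
  ry <- -sin(th) * vx + cos(th) * vy
  ang <- atan2(rx, -ry) * 180 / pi
  ang %% 360
}

zone_of_angle <- function(theta) {
  theta <- theta %% 360
  out <- character(length(theta))
  out[theta >= 300 | theta < 60] <- "superior"
  out[theta >= 60 & theta < 120] <- "right"
  out[theta >= 120 & theta < 240] <- "inferior"
  out[theta >= 240 & theta < 300] <- "left"
  out
}

#' Four-zone label of a pixel
#'
#' Clock-hour zones around the fovea: superior 10-2 o'clock, right 2-4,
#' inferior 4-8, left 8-10. Intervals are half-open; a boundary angle belongs
#' to the clockwise-later zone (e.g. exactly 2 o'clock is "right").
#'
#' @inheritParams clock_angle
#' @return Character vector of zone labels.
#' @export
zone_of_point <- function(frame, x, y) {
  if (any(x == frame$fovea[1] & y == frame$fovea[2])) {
    stop("zone undefined at the fovea itself")
  }
  zone_of_angle(clock_angle(frame, x, y))
}

#' Posterior-pole mask
#'
#' Binary raster of pixels within `posterior_pole_radius` of the fovea.
#'
#' @param frame An `rd_frame`.
#' @return Integer 0/1 matrix of size `frame$canvas`.
#' @export
posterior_pole_mask <- function(frame) {
  h <- frame$canvas[1]; w <- frame$canvas[2]
  dx <- matrix(rep((1:w) - frame$fovea[1], each = h), h, w)
  dy <- matrix(rep((1:h) - frame$fovea[2], times = w), h, w)
  m <- (dx^2 + dy^2) <= frame$posterior_pole_radius^2
  storage.mode(m) <- "integer"
  m
}

#' 48-partition index of a pixel
#'
#' `index = ring * 24 + floor(theta / 15)`, 0-based; ring 0 inside the
#' posterior-pole circle (distance <= radius), ring 1 outside.
#'
#' @inheritParams clock_angle
#' @return Integer vector of partition indices in 0..47.
#' @export
partition_index <- function(frame, x, y) {
  if (any(x == frame$fovea[1] & y == frame$fovea[2])) {
    stop("partition undefined at the fovea itself")
  }
  theta <- clock_angle(frame, x, y)
  sector <- pmin(floor(theta / 15), 23L)
  d2 <- (x - frame$fovea[1])^2 + (y - frame$fovea[2])^2
  ring <- as.integer(d2 > frame$posterior_pole_radius^2)
  as.integer(ring * 24L + sector)
}

#' Partition counting rule
#'
#' A partition bit is set when strictly more than `min_pixels` lesion pixels
#' fall into it. `min_pixels` is defined on a reference grid of side
#' `resolution`; when a mask is evaluated on a different (square) canvas the
#' threshold is scaled by `(canvas / resolution)^2` so the rule is
#' resolution-consistent. The printed default is 50 pixels at 512.
#'
#' @param min_pixels Count threshold (strict `>`), default 50.
#' @param resolution Reference grid side in pixels, default 512. Use `NA` to
#'   apply `min_pixels` unscaled on any canvas.
#' @return An object of class `rd_partition_rule`.
#' @export
partition_rule <- function(min_pixels = 50, resolution = 512) {
  stopifnot(min_pixels >= 0)
  structure(list(min_pixels = min_pixels, resolution = resolution),
            class = "rd_partition_rule")
}

effective_min_pixels <- function(rule, canvas) {
  if (is.na(rule$resolution)) return(rule$min_pixels)
  rule$min_pixels * (max(canvas) / rule$resolution)^2
}

mask_pixels <- function(mask, frame) {
  idx <- which(mask != 0, arr.ind = TRUE)
  if (nrow(idx) == 0) return(idx)
  keep <- !(idx[, 2] == frame$fovea[1] & idx[, 1] == frame$fovea[2])
  idx[keep, , drop = FALSE]
}

#' 48-partition vector of a lesion mask
#'
#' Counts lesion pixels per partition and sets bit `i` (1-based position
#' `i + 1`) when the count strictly exceeds the rule threshold.
#'
#' @param mask Binary H x W matrix aligned with `frame$canvas`.
#' @param frame An `rd_frame`.
#' @param rule An `rd_partition_rule`.
#' @return Integer vector of length 48 with values in {0, 1}; attribute
#'   `counts` carries the raw per-partition pixel counts.
#' @export
partition_vector <- function(mask, frame, rule = partition_rule()) {
  stopifnot(all(dim(mask) == frame$canvas))
  counts <- integer(48)
  px <- mask_pixels(mask, frame)
  if (nrow(px) > 0) {
    pid <- partition_index(frame, px[, 2], px[, 1])
    tab <- tabulate(pid + 1L, nbins = 48L)
    counts <- tab
  }
  bits <- as.integer(counts > effective_min_pixels(rule, frame$canvas))
  attr(bits, "counts") <- counts
  bits
}

#' Primary zone of a lesion mask
#'
#' The zone containing the largest number of lesion pixels. Ties are resolved
#' by the fixed order superior > inferior > right > left.
#'
#' @inheritParams partition_vector
#' @return A single zone label, or `NA_character_` for an empty mask
#'   ("no lesion").
#' @export
primary_zone <- function(mask, frame) {
  px <- mask_pixels(mask, frame)
  if (nrow(px) == 0) return(NA_character_)
  z <- zone_of_point(frame, px[, 2], px[, 1])
  order_pref <- c("superior", "inferior", "right", "left")
  cnt <- vapply(order_pref, function(zz) sum(z == zz), integer(1))
  order_pref[which.max(cnt)]
}

#' Posterior-pole involvement of a lesion mask
#'
#' TRUE when the lesion pixel count inside the posterior-pole circle strictly
#' exceeds the rule threshold (same counting rule as the partitions).
#'
#' @inheritParams partition_vector
#' @return Logical flag.
#' @export
posterior_involved <- function(mask, frame, rule = partition_rule()) {
  stopifnot(all(dim(mask) == frame$canvas))
  px <- mask_pixels(mask, frame)
  if (nrow(px) == 0) return(FALSE)
  d2 <- (px[, 2] - frame$fovea[1])^2 + (px[, 1] - frame$fovea[2])^2
  inside <- sum(d2 <= frame$posterior_pole_radius^2)
  inside > effective_min_pixels(rule, frame$canvas)
}

#' Serialize a partition vector as a bit-string
#'
#' @param bits Integer vector of length 48.
#' @return Single string of 48 characters `"0"`/`"1"`.
#' @export
partition_bitstring <- function(bits) {
  stopifnot(length(bits) == 48)
  paste(as.integer(bits), collapse = "")
}
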