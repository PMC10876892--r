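# Preoperative postural guidance from the anatomical localization: supine
# for superior-zone RD, sitting for inferior, lateral decubitus toward the
# affected side for the right/left zones, and supine plus urgent referral
# whenever the posterior pole is involved.

#' Postural advice for a localized detachment
#'
#' Zone-to-posture map: superior -> supine, inferior -> sitting, right ->
#' right lateral, left -> left lateral. Posterior-pole involvement overrides
#' the zone rule: posture is forced to supine and an urgent referral is
#' flagged. Zone names are image-space clock positions; the eye's laterality
#' is recorded in the advice so the convention can be audited.
#'
#' @param primary Primary zone label (one of [rd_zones()]).
#' @param posterior Logical: posterior pole involved?
#' @param laterality `"OD"` or `"OS"`.
#' @return An object of class `rd_posture_advice`: `posture`,
#'   `urgent_referral`, `basis`.
#' @export
posture_for <- function(primary, posterior = FALSE,
                        laterality = c("OD", "OS")) {
  laterality <- match.arg(laterality)
  if (is.na(primary) || !primary %in% rd_zones()) {
    stop("primary zone undefined: no lesion to advise on")
  }
  posture <- switch(primary,
    superior = "supine",
    inferior = "sitting",
    right = "right_lateral",
    left = "left_lateral"
  )
  urgent <- isTRUE(posterior)
  if (urgent) posture <- "supine"
  structure(list(posture = posture, urgent_referral = urgent,
                 basis = list(primary_zone = primary,
                              posterior_involved = urgent,
                              laterality = laterality)),
            class = "rd_posture_advice")
}

#' @export
print.rd_posture_advice <- function(x, ...) {
  cat(sprintf("posture: %s%s (zone %s, %s)\n", x$posture,
              if (x$urgent_referral) " + URGENT REFERRAL" else "",
              x$basis$primary_zone, x$basis$laterality))
  invisible(x)
}

#' Structured guidance record for one image
#'
#' Combines classification, localization and posture into one serializable
#' record. Non-RD images (or empty masks) yield a "no lesion" record without
#' postural advice.
#'
#' @param id Image identifier.
#' @param localization Output of [localize_rd()].
#' @param frame The `rd_frame` used (provides laterality).
#' @param provenance Optional list (model phase, thresholds, landmark
#'   source, ...) stored verbatim.
#' @return A list of class `rd_guidance_record`.
#' @export
guidance_record <- function(id, localization, frame, provenance = list()) {
  loc <- localization
  if (is.null(loc$probability) || is.null(loc$partitions)) {
    stop("incomplete localization output")
  }
  has_lesion <- isTRUE(loc$is_rd) && !is.na(loc$primary_zone)
  advice <- if (has_lesion) {
    posture_for(loc$primary_zone, loc$posterior, frame$laterality)
  } else NULL
  structure(list(
    id = id,
    probability = loc$probability,
    is_rd = isTRUE(loc$is_rd),
    partitions = partition_bitstring(loc$partitions),
    primary_zone = if (has_lesion) loc$primary_zone else NA_character_,
    posterior_involved = isTRUE(loc$posterior) && has_lesion,
    posture = if (has_lesion) advice$posture else "none",
    urgent_referral = if (has_lesion) advice$urgent_referral else FALSE,
    laterality = frame$laterality,
    provenance = provenance
  ), class = "rd_guidance_record")
}

#' Write guidance records as JSON lines
#'
#' @param records List of `rd_guidance_record`.
#' @param path Output path (one JSON object per line).
#' @return `path`, invisibly.
#' @export
write_guidance_records <- function(records, path) {
  lines <- vapply(records, function(r) {
    jsonlite::toJSON(unclass(r), auto_unbox = TRUE, digits = NA)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read guidance records from JSON lines
#'
#' @param path File written by [write_guidance_records()].
#' @return List of `rd_guidance_record`.
#' @export
read_guidance_records <- function(path) {
  lapply(readLines(path), function(l) {
    r <- jsonlite::fromJSON(l, simplifyVector = TRUE)
    if (length(r$provenance) == 0) r$provenance <- list()
    structure(r, class = "rd_guidance_record")
  })
}

#' Render a four-zone overlay image
#'
#' The base image dimmed, zones tinted around the fovea, the posterior-pole
#' circle and the lesion contour marked; intended for human-readable reports.
#'
#' @param sample An `rd_sample` (or list with `image`, `frame`).
#' @param mask Optional lesion mask to outline (defaults to the truth mask).
#' @return H x W x 3 array in `[0, 1]`.
#' @export
render_zone_overlay <- function(sample, mask = NULL) {
  img <- sample$image * 0.6
  fr <- sample$frame
  h <- dim(img)[1]; w <- dim(img)[2]
  xs <- matrix(rep(1:w, each = h), h, w)
  ys <- matrix(rep(1:h, times = w), h, w)
  zone <- matrix(zone_of_angle(clock_angle(fr, xs, ys)), h, w)
  tint <- list(superior = c(0.15, 0, 0), right = c(0, 0.15, 0),
               inferior = c(0, 0, 0.15), left = c(0.12, 0.12, 0))
  for (z in rd_zones()) {
    sel <- zone == z
    for (ch in 1:3) img[, , ch][sel] <- img[, , ch][sel] + tint[[z]][ch]
  }
  d <- sqrt((xs - fr$fovea[1])^2 + (ys - fr$fovea[2])^2)
  ring <- abs(d - fr$posterior_pole_radius) <= 1
  for (ch in 1:3) img[, , ch][ring] <- c(1, 1, 1)[ch]
  if (is.null(mask)) mask <- sample$truth_mask
  if (!is.null(mask) && any(mask != 0)) {
    m <- mask != 0
    er <- m
    er[-1, ] <- er[-1, ] & m[-h, ]; er[-h, ] <- er[-h, ] & m[-1, ]
    er[, -1] <- er[, -1] & m[, -w]; er[, -w] <- er[, -w] & m[, -1]
    edge <- m & !er
    img[, , 1][edge] <- 0; img[, , 2][edge] <- 1; img[, , 3][edge] <- 0
  }
  pmin(pmax(img, 0), 1)
}
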