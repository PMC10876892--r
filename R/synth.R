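# Seeded synthetic ultra-widefield-like fundus generator. The emulated scene:
# a circular fundus field on a square canvas (four information-free corners),
# an optic disc nasal to the fovea (image-right for OD, image-left for OS),
# and, for RD cases, a bright wedge-shaped lesion with sinusoidal radial
# corrugation. Lesion geometry is exact by construction, so every downstream
# stage can be evaluated against a perfect ground truth.

ALLOWED_CANVAS <- c(128L, 256L, 512L, 1024L)

#' Configuration for the synthetic fundus generator
#'
#' @param canvas_px Square canvas side, one of 128/256/512/1024 (default 512).
#' @param laterality `"OD"` (disc on image-right of the fovea) or `"OS"`.
#' @param rd_probability Probability that a sample carries a detachment
#'   (default 0.10, emulating an RD prevalence of roughly 2,400 in 24,000).
#' @param lesion_sector_span Pair of clock angles in degrees (clockwise from
#'   12 o'clock) delimiting the lesion wedge in the final image, or `NULL` to
#'   randomize per sample (random center, width 60-150 degrees).
#' @param lesion_radial_band Pair of fractions of the fundus radius, default
#'   `c(0.25, 0.95)`.
#' @param shallow If TRUE the lesion/background contrast is scaled by 0.3,
#'   emulating low-contrast shallow detachments.
#' @param corrugation_period_px Radial period of the corrugation ridges in
#'   pixels; default `canvas_px / 24`.
#' @param corrugation_amplitude Relative amplitude of the sinusoidal intensity
#'   modulation, default 0.5.
#' @param artifact_level Intensity in `[0, 1]` of bright distractor arcs near
#'   the fundus rim (0 disables them; for robustness experiments only).
#' @param fundus_radius_fraction Fundus field radius as a fraction of the
#'   canvas, default 0.48.
#' @param disc_offset_fraction Horizontal fovea-to-disc offset fraction,
#'   default 0.22.
#' @param disc_radius_fraction Disc radius fraction, default 0.04.
#' @param seed RNG seed for this sample.
#' @return An object of class `rd_synth_config`.
#' @export
synth_config <- function(canvas_px = 512, laterality = c("OD", "OS"),
                         rd_probability = 0.10, lesion_sector_span = NULL,
                         lesion_radial_band = c(0.25, 0.95), shallow = FALSE,
                         corrugation_period_px = NULL,
                         corrugation_amplitude = 0.5, artifact_level = 0,
                         fundus_radius_fraction = 0.48,
                         disc_offset_fraction = 0.22,
                         disc_radius_fraction = 0.04, seed = 1L) {
  laterality <- match.arg(laterality)
  if (!(canvas_px %in% ALLOWED_CANVAS)) {
    stop("canvas_px must be one of ", paste(ALLOWED_CANVAS, collapse = "/"))
  }
  stopifnot(rd_probability >= 0, rd_probability <= 1)
  if (!is.null(lesion_sector_span)) {
    stopifnot(length(lesion_sector_span) == 2)
    if ((lesion_sector_span[2] - lesion_sector_span[1]) %% 360 == 0) {
      stop("degenerate lesion sector span")
    }
  }
  stopifnot(length(lesion_radial_band) == 2,
            lesion_radial_band[1] < lesion_radial_band[2])
  if (is.null(corrugation_period_px)) corrugation_period_px <- canvas_px / 24
  structure(list(
    canvas_px = as.integer(canvas_px), laterality = laterality,
    rd_probability = rd_probability, lesion_sector_span = lesion_sector_span,
    lesion_radial_band = lesion_radial_band, shallow = isTRUE(shallow),
    corrugation_period_px = corrugation_period_px,
    corrugation_amplitude = corrugation_amplitude,
    artifact_level = artifact_level,
    fundus_radius_fraction = fundus_radius_fraction,
    disc_offset_fraction = disc_offset_fraction,
    disc_radius_fraction = disc_radius_fraction,
    seed = as.integer(seed)
  ), class = "rd_synth_config")
}

# angular membership of theta in the clockwise span (a, b), wrap-aware
in_clock_span <- function(theta, span) {
  a <- span[1] %% 360; b <- span[2] %% 360
  if (a < b) theta >= a & theta < b else theta >= a | theta < b
}

mirror_span <- function(span) c((360 - span[2]) %% 360, (360 - span[1]) %% 360)

#' Generate one synthetic fundus sample
#'
#' Deterministic for a fixed config (bit-identical across runs). The image is
#' built in a canonical disc-on-the-right layout and flipped horizontally for
#' OS, so an OD sample and an OS sample with the same seed and mirrored
#' lesion span are exact mirror images.
#'
#' @param config An `rd_synth_config`.
#' @return An object of class `rd_sample` with fields `image` (H x W x 3 in
#'   `[0,1]`), `truth_mask` (0/1 matrix, empty iff `is_rd` is FALSE), `fovea`,
#'   `disc_center`, `disc_radius`, `laterality`, `is_rd`, `truth_partitions`
#'   (48-length 0/1 vector), `truth_primary_zone`, `truth_posterior` and
#'   `frame`.
#' @export
generate_fundus <- function(config = synth_config()) {
  stopifnot(inherits(config, "rd_synth_config"))
  set.seed(config$seed)
  S <- config$canvas_px
  fov <- c((S + 1) / 2, (S + 1) / 2)
  fundus_r <- config$fundus_radius_fraction * S
  disc_c <- fov + c(config$disc_offset_fraction * S, 0)
  disc_r <- config$disc_radius_fraction * S

  # RD status is decided by the first uniform draw of the sample's RNG
  # stream (a documented contract: dataset-level RD counts can be derived
  # from per-sample seeds without rendering)
  is_rd <- stats::runif(1) < config$rd_probability

  xs <- matrix(rep(1:S, each = S), S, S)   # x = column index
  ys <- matrix(rep(1:S, times = S), S, S)  # y = row index
  dx <- xs - fov[1]; dy <- ys - fov[2]
  r <- sqrt(dx^2 + dy^2)
  inside <- r <= fundus_r

  # base fundus coloring: reddish-orange with radial vignette and grain
  vign <- 1 - 0.35 * (r / fundus_r)^2
  grain <- matrix(stats::rnorm(S * S, 0, 0.015), S, S)
  base <- list(R = 0.75, G = 0.38, B = 0.16)
  img <- array(0, dim = c(S, S, 3))
  img[, , 1] <- (base$R * vign + grain) * inside
  img[, , 2] <- (base$G * vign + grain) * inside
  img[, , 3] <- (base$B * vign + grain) * inside

  # fovea: slightly darker dip
  fov_dip <- exp(-(r / (0.035 * S))^2) * 0.12
  for (ch in 1:3) img[, , ch] <- img[, , ch] - fov_dip * inside

  # lesion geometry (all draws in canonical layout)
  truth_mask <- matrix(0L, S, S)
  if (is_rd) {
    span_final <- config$lesion_sector_span
    if (is.null(span_final)) {
      ctr <- stats::runif(1, 0, 360)
      wid <- stats::runif(1, 60, 150)
      span_final <- c((ctr - wid / 2) %% 360, (ctr + wid / 2) %% 360)
    }
    span_canon <- if (config$laterality == "OS") mirror_span(span_final) else span_final
    theta <- (atan2(dx, -dy) * 180 / pi) %% 360  # canonical frame rotation 0
    band <- config$lesion_radial_band * fundus_r
    wedge <- inside & in_clock_span(theta, span_canon) & r >= band[1] & r <= band[2]
    truth_mask[wedge] <- 1L

    lift <- 0.28 * if (config$shallow) 0.3 else 1
    corr <- 1 + config$corrugation_amplitude *
      sin(2 * pi * r / config$corrugation_period_px)
    lesion_gain <- lift * corr * wedge
    img[, , 1] <- img[, , 1] + 0.65 * lesion_gain
    img[, , 2] <- img[, , 2] + 1.00 * lesion_gain
    img[, , 3] <- img[, , 3] + 0.90 * lesion_gain
  }

  # optic disc: bright yellowish circle, drawn on top of any lesion
  dd <- sqrt((xs - disc_c[1])^2 + (ys - disc_c[2])^2)
  disc_m <- dd <= disc_r
  disc_col <- c(0.98, 0.87, 0.55)
  for (ch in 1:3) {
    img[, , ch] <- ifelse(disc_m, disc_col[ch], img[, , ch])
  }

  # optional distractor arcs near the rim (camera-pad-like artifacts)
  if (config$artifact_level > 0) {
    for (k in 1:2) {
      a0 <- stats::runif(1, 0, 360); wid <- stats::runif(1, 20, 60)
      theta_a <- (atan2(dx, -dy) * 180 / pi) %% 360
      ring <- inside & r >= 0.90 * fundus_r & r <= 0.99 * fundus_r &
        in_clock_span(theta_a, c(a0, (a0 + wid) %% 360))
      add <- 0.4 * config$artifact_level * ring
      for (ch in 1:3) img[, , ch] <- img[, , ch] + add
    }
  }

  img <- pmin(pmax(img, 0), 1)
  for (ch in 1:3) img[, , ch] <- img[, , ch] * inside

  # mirror for left eyes: canonical layout has the disc on the image-right
  if (config$laterality == "OS") {
    img <- img[, S:1, , drop = FALSE]
    truth_mask <- truth_mask[, S:1, drop = FALSE]
    disc_c[1] <- (S + 1) - disc_c[1]
  }

  frame <- fit_frame(fov, list(center = disc_c, radius = disc_r),
                     config$laterality, canvas = c(S, S))
  bits <- partition_vector(truth_mask, frame)
  structure(list(
    image = img, truth_mask = truth_mask, fovea = fov, disc_center = disc_c,
    disc_radius = disc_r, laterality = config$laterality, is_rd = is_rd,
    truth_partitions = as.integer(bits),
    truth_primary_zone = primary_zone(truth_mask, frame),
    truth_posterior = posterior_involved(truth_mask, frame),
    frame = frame, config = config
  ), class = "rd_sample")
}

#' @export
print.rd_sample <- function(x, ...) {
  cat(sprintf("rd_sample %dpx %s %s%s\n", dim(x$image)[1], x$laterality,
              if (x$is_rd) "RD" else "non-RD",
              if (x$is_rd) sprintf(" (primary zone %s)", x$truth_primary_zone) else ""))
  invisible(x)
}

#' Generate a seeded collection of synthetic samples
#'
#' Per-sample seeds are derived deterministically from the master seed;
#' laterality is drawn 50/50 and RD status per `rd_probability` of the
#' template.
#'
#' @param n Number of samples (>= 1).
#' @param config_template An `rd_synth_config`; its `seed` and `laterality`
#'   are overridden per sample.
#' @param seed Master seed.
#' @param shallow_fraction Fraction of RD lesions drawn as low-contrast
#'   shallow detachments (default 0: all lesions use the template's
#'   `shallow` flag).
#' @return List of `rd_sample` objects, named `img000001`...
#' @export
generate_dataset <- function(n, config_template = synth_config(), seed = 1L,
                             shallow_fraction = 0) {
  stopifnot(n >= 1, shallow_fraction >= 0, shallow_fraction <= 1)
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, n)
  lats <- ifelse(stats::runif(n) < 0.5, "OD", "OS")
  shallow <- stats::runif(n) < shallow_fraction
  out <- vector("list", n)
  for (i in seq_len(n)) {
    cfg <- config_template
    cfg$seed <- seeds[i]
    cfg$laterality <- lats[i]
    if (shallow[i]) cfg$shallow <- TRUE
    out[[i]] <- generate_fundus(cfg)
    out[[i]]$id <- sprintf("img%06d", i)
  }
  names(out) <- vapply(out, `[[`, character(1), "id")
  out
}

#' Split a dataset into train and test sets
#'
#' Disjoint and exhaustive; membership is a seeded shuffle and the train size
#' is `floor(n * train_fraction)`.
#'
#' @param samples List of samples.
#' @param train_fraction Fraction in (0, 1), default 0.8.
#' @param seed Shuffle seed.
#' @return List with elements `train` and `test`.
#' @export
split_dataset <- function(samples, train_fraction = 0.8, seed = 1L) {
  n <- length(samples)
  if (n < 2) stop("need at least 2 samples to split")
  stopifnot(train_fraction > 0, train_fraction < 1)
  set.seed(seed)
  perm <- sample.int(n)
  ntr <- floor(n * train_fraction)
  list(train = samples[perm[seq_len(ntr)]],
       test = samples[perm[setdiff(seq_len(n), seq_len(ntr))]])
}

#' Write a dataset to disk
#'
#' Images as PPM, truth masks as PGM, one JSON sidecar per image
#' (`fovea`, `disc_center`, `disc_radius`, `laterality`, `is_rd`; 0-based
#' pixel coordinates), and a `manifest.csv` (id, path, split, label).
#'
#' @param samples List of `rd_sample`.
#' @param dir Output directory (created if needed).
#' @param split Optional character vector of split names per sample.
#' @return The manifest data.frame, invisibly.
#' @export
write_dataset <- function(samples, dir, split = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ids <- names(samples)
  if (is.null(split)) split <- rep("all", length(samples))
  rows <- vector("list", length(samples))
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    img_path <- file.path(dir, paste0(ids[i], ".ppm"))
    write_pnm(s$image, img_path)
    write_pnm(s$truth_mask * 1.0, file.path(dir, paste0(ids[i], "_mask.pgm")))
    write_sidecar(s, file.path(dir, paste0(ids[i], ".json")))
    rows[[i]] <- data.frame(id = ids[i], path = img_path, split = split[i],
                            label = as.integer(s$is_rd))
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

write_sidecar <- function(sample, path) {
  jsonlite::write_json(list(
    fovea = sample$fovea - 1,              # 0-based on disk
    disc_center = sample$disc_center - 1,
    disc_radius = sample$disc_radius,
    laterality = sample$laterality,
    is_rd = sample$is_rd
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
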