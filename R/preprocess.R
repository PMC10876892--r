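# Input conditioning: a region-of-interest template that erases the four
# information-free corners of an ultra-widefield capture, and contrast-limited
# adaptive histogram equalization (CLAHE) applied to the luminance channel.

#' Build an analytic region-of-interest template
#'
#' The retained region is the centered fundus disc; everything else
#' (including the four corners) is zeroed. The reference handcrafted template
#' of real captures is approximated by this analytic disc; a user-supplied
#' raster can be wrapped with [roi_template_from_mask()] instead.
#'
#' @param canvas_px Square canvas side (>= 32).
#' @param fundus_radius_fraction Disc radius as a fraction of the canvas,
#'   in (0, 0.5]; default 0.48.
#' @return An object of class `rd_roi_template` with fields `mask`
#'   (0/1 matrix) and `provenance = "generated"`.
#' @export
build_roi_template <- function(canvas_px, fundus_radius_fraction = 0.48) {
  stopifnot(canvas_px >= 32)
  if (fundus_radius_fraction <= 0 || fundus_radius_fraction > 0.5) {
    stop("fundus_radius_fraction must be in (0, 0.5]")
  }
  S <- as.integer(canvas_px)
  ctr <- (S + 1) / 2
  xs <- matrix(rep(1:S, each = S), S, S)
  ys <- matrix(rep(1:S, times = S), S, S)
  m <- (xs - ctr)^2 + (ys - ctr)^2 <= (fundus_radius_fraction * S)^2
  storage.mode(m) <- "integer"
  structure(list(mask = m, provenance = "generated"),
            class = "rd_roi_template")
}

#' Wrap a user-supplied ROI mask
#'
#' @param mask Binary matrix (nonzero = retained).
#' @return An `rd_roi_template` with `provenance = "handcrafted"`.
#' @export
roi_template_from_mask <- function(mask) {
  m <- (mask != 0) * 1L
  structure(list(mask = m, provenance = "handcrafted"),
            class = "rd_roi_template")
}

#' Apply an ROI template to an image
#'
#' Pixels where the template is 0 are set to 0 in all channels; the rest are
#' unchanged. Applying the template twice equals applying it once.
#'
#' @param image Numeric matrix or H x W x C array.
#' @param template An `rd_roi_template` with matching spatial size.
#' @return Masked image of the same shape.
#' @export
apply_roi_template <- function(image, template) {
  m <- template$mask
  d <- dim(image)
  if (!all(d[1:2] == dim(m))) stop("image and ROI template shapes differ")
  if (length(d) == 2) return(image * m)
  out <- image
  for (ch in seq_len(d[3])) out[, , ch] <- out[, , ch] * m
  out
}

#' Contrast-limited adaptive histogram equalization
#'
#' CLAHE on the luminance channel (Rec. 601 weights) with chroma offsets
#' preserved: each color channel is shifted by the luminance change and
#' clamped to `[0, 1]`. Tile histograms (256 bins) are clipped at
#' `clip_limit` times the uniform bin height, the excess is redistributed
#' uniformly, and per-pixel mappings are bilinearly blended between the four
#' neighboring tile mappings. Applied deterministically to every input.
#'
#' @param image Numeric matrix or H x W x 3 array with values in `[0, 1]`.
#' @param clip_limit Histogram clip factor (> 0), default 2.
#' @param tile_grid Integer `c(rows, cols)` of the tile grid, default 8 x 8.
#' @return Enhanced image, same shape and value domain as the input.
#' @export
clahe_enhance <- function(image, clip_limit = 2, tile_grid = c(8, 8)) {
  stopifnot(length(image) > 0, clip_limit > 0, all(tile_grid >= 1))
  rgb <- length(dim(image)) == 3
  if (rgb) {
    y <- 0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
  } else {
    y <- image
  }
  y2 <- clahe_gray(pmin(pmax(y, 0), 1), clip_limit, tile_grid)
  if (!rgb) return(y2)
  out <- image
  dy <- y2 - y
  for (ch in 1:3) out[, , ch] <- pmin(pmax(image[, , ch] + dy, 0), 1)
  out
}

clahe_gray <- function(y, clip_limit, tile_grid, nbins = 256L) {
  h <- nrow(y); w <- ncol(y)
  tr <- min(tile_grid[1], h); tc <- min(tile_grid[2], w)
  bin <- pmin(pmax(floor(y * nbins) + 1L, 1L), nbins)

  row_edges <- round(seq(0, h, length.out = tr + 1))
  col_edges <- round(seq(0, w, length.out = tc + 1))
  # per-tile clipped-CDF mappings: M[tile_row, tile_col, bin] in [0, 1]
  M <- array(0, dim = c(tr, tc, nbins))
  for (i in seq_len(tr)) {
    for (j in seq_len(tc)) {
      rows <- (row_edges[i] + 1):row_edges[i + 1]
      cols <- (col_edges[j] + 1):col_edges[j + 1]
      b <- bin[rows, cols]
      hist <- tabulate(b, nbins = nbins)
      npix <- length(b)
      clip <- max(1, clip_limit * npix / nbins)
      excess <- sum(pmax(hist - clip, 0))
      hist <- pmin(hist, clip) + excess / nbins
      M[i, j, ] <- cumsum(hist) / npix
    }
  }

  rc <- (row_edges[-1] + row_edges[-(tr + 1)] + 1) / 2  # tile centers
  cc <- (col_edges[-1] + col_edges[-(tc + 1)] + 1) / 2
  ri <- findInterval(seq_len(h), rc)                # 0..tr
  ci <- findInterval(seq_len(w), cc)
  i0 <- pmin(pmax(ri, 1L), tr); i1 <- pmin(ri + 1L, tr)
  j0 <- pmin(pmax(ci, 1L), tc); j1 <- pmin(ci + 1L, tc)
  wy <- ifelse(ri < 1 | ri >= tr, 0,
               (seq_len(h) - rc[i0]) / pmax(rc[pmin(i1, tr)] - rc[i0], 1e-12))
  wx <- ifelse(ci < 1 | ci >= tc, 0,
               (seq_len(w) - cc[j0]) / pmax(cc[pmin(j1, tc)] - cc[j0], 1e-12))
  wy <- pmin(pmax(wy, 0), 1); wx <- pmin(pmax(wx, 0), 1)

  I0 <- matrix(i0, h, w); I1 <- matrix(i1, h, w)
  J0 <- matrix(j0, h, w, byrow = TRUE); J1 <- matrix(j1, h, w, byrow = TRUE)
  WY <- matrix(wy, h, w); WX <- matrix(wx, h, w, byrow = TRUE)
  look <- function(I, J) {
    idx <- (bin - 1L) * (tr * tc) + (J - 1L) * tr + I
    matrix(M[idx], h, w)
  }
  (1 - WY) * ((1 - WX) * look(I0, J0) + WX * look(I0, J1)) +
    WY * ((1 - WX) * look(I1, J0) + WX * look(I1, J1))
}

#' Standard preprocessing chain
#'
#' ROI masking followed by CLAHE, the fixed input conditioning of the
#' classifier.
#'
#' @param image H x W x 3 image in `[0, 1]`.
#' @param template An `rd_roi_template` (built for the canvas if missing).
#' @param clip_limit,tile_grid CLAHE parameters.
#' @return Preprocessed image.
#' @export
preprocess_image <- function(image, template = NULL, clip_limit = 2,
                             tile_grid = c(8, 8)) {
  if (is.null(template)) template <- build_roi_template(dim(image)[1])
  x <- apply_roi_template(image, template)
  x <- clahe_enhance(x, clip_limit, tile_grid)
  apply_roi_template(x, template)
}
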