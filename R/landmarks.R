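# Landmarks of the anatomical frame: the fovea (manually annotated, read
# from a JSON sidecar) and the optic disc (segmented by a small
# encoder-decoder network with skip connections, reduced to center+radius).
# Sidecar disc parameters, when present, act as the oracle fallback so the
# zoning geometry can be evaluated independently of the segmentation model.

#' Build an untrained disc segmentation network
#'
#' A 2-level encoder-decoder with skip connections (channel concatenation)
#' and a per-pixel single-logit head, trained with weighted pixel-wise
#' cross-entropy.
#'
#' @param resolution Input side length (must be divisible by 4), default 128.
#' @param seed Initialization seed.
#' @return An object of class `rd_disc_net`.
#' @export
build_disc_net <- function(resolution = 128, seed = 1L) {
  stopifnot(resolution %% 4 == 0)
  set.seed(seed)
  params <- list(
    enc0 = conv_init(3, 3, 3, 8),
    down1 = conv_init(3, 3, 8, 16),
    down2 = conv_init(3, 3, 16, 32),
    up1 = conv_init(3, 3, 32 + 16, 16),
    up2 = conv_init(3, 3, 16 + 8, 8),
    out = conv_init(1, 1, 8, 1)
  )
  structure(list(params = params, resolution = resolution, trained = FALSE,
                 seed = seed),
            class = "rd_disc_net")
}

cat_channels <- function(a, b) {
  array(c(a, b), dim = c(dim(a)[1], dim(a)[2], dim(a)[3] + dim(b)[3]))
}

disc_net_forward <- function(net, x, keep = FALSE) {
  p <- net$params
  z0 <- conv_fwd(x, p$enc0, 1); a0 <- lrelu_fwd(z0)
  z1 <- conv_fwd(a0, p$down1, 2); a1 <- lrelu_fwd(z1)
  z2 <- conv_fwd(a1, p$down2, 2); a2 <- lrelu_fwd(z2)
  u1 <- .upsample2x_forward(a2)
  c1 <- cat_channels(u1, a1)
  z3 <- conv_fwd(c1, p$up1, 1); a3 <- lrelu_fwd(z3)
  u2 <- .upsample2x_forward(a3)
  c2 <- cat_channels(u2, a0)
  z4 <- conv_fwd(c2, p$up2, 1); a4 <- lrelu_fwd(z4)
  z5 <- conv_fwd(a4, p$out, 1, pad = 0L)
  logits <- z5[, , 1]
  if (!keep) return(list(logits = logits))
  list(logits = logits,
       cache = list(x = x, z0 = z0, a0 = a0, z1 = z1, a1 = a1, z2 = z2,
                    a2 = a2, u1 = u1, c1 = c1, z3 = z3, a3 = a3, u2 = u2,
                    c2 = c2, z4 = z4, a4 = a4))
}

disc_net_backward <- function(net, fw, dlogits) {
  p <- net$params; cc <- fw$cache
  g <- list()
  dz5 <- array(dlogits, dim = c(dim(dlogits), 1))
  r5 <- conv_bwd(cc$a4, p$out, dz5, 1, pad = 0L); g$out <- list(w = r5$dw, b = r5$db)
  dz4 <- lrelu_bwd(cc$z4, r5$dx)
  r4 <- conv_bwd(cc$c2, p$up2, dz4, 1); g$up2 <- list(w = r4$dw, b = r4$db)
  c2s <- dim(cc$u2)[3]
  du2 <- r4$dx[, , seq_len(c2s), drop = FALSE]
  da0_skip <- r4$dx[, , -seq_len(c2s), drop = FALSE]
  da3 <- .upsample2x_backward(du2)
  dz3 <- lrelu_bwd(cc$z3, da3)
  r3 <- conv_bwd(cc$c1, p$up1, dz3, 1); g$up1 <- list(w = r3$dw, b = r3$db)
  c1s <- dim(cc$u1)[3]
  du1 <- r3$dx[, , seq_len(c1s), drop = FALSE]
  da1_skip <- r3$dx[, , -seq_len(c1s), drop = FALSE]
  da2 <- .upsample2x_backward(du1)
  dz2 <- lrelu_bwd(cc$z2, da2)
  r2 <- conv_bwd(cc$a1, p$down2, dz2, 2); g$down2 <- list(w = r2$dw, b = r2$db)
  da1 <- r2$dx + da1_skip
  dz1 <- lrelu_bwd(cc$z1, da1)
  r1 <- conv_bwd(cc$a0, p$down1, dz1, 2); g$down1 <- list(w = r1$dw, b = r1$db)
  da0 <- r1$dx + da0_skip
  dz0 <- lrelu_bwd(cc$z0, da0)
  r0 <- conv_bwd(cc$x, p$enc0, dz0, 1); g$enc0 <- list(w = r0$dw, b = r0$db)
  g
}

disc_truth_mask <- function(sample, resolution) {
  S <- dim(sample$image)[1]
  sc <- resolution / S
  ctr <- (sample$disc_center - 0.5) * sc + 0.5
  r <- sample$disc_radius * sc
  xs <- matrix(rep(1:resolution, each = resolution), resolution, resolution)
  ys <- matrix(rep(1:resolution, times = resolution), resolution, resolution)
  ((xs - ctr[1])^2 + (ys - ctr[2])^2 <= r^2) * 1
}

#' Train the disc segmentation network
#'
#' Weighted pixel-wise cross-entropy (positives up-weighted, the disc covers
#' well under 1% of the canvas), momentum SGD; disc positions of the
#' synthetic samples are the supervision.
#'
#' @param samples List of `rd_sample` objects.
#' @param net An `rd_disc_net` (built at the sample resolution if missing).
#' @param epochs Training epochs, default 8.
#' @param lr Learning rate, default 0.05.
#' @param pos_weight Positive-pixel loss weight; `NULL` (default) balances
#'   the classes per image (`0.5 / class fraction`), which is essential for
#'   the tiny disc (well under 1% of pixels).
#' @param seed Shuffle seed.
#' @return The trained network with a `training_log`.
#' @export
train_disc_net <- function(samples, net = NULL, epochs = 8, lr = 0.05,
                           pos_weight = NULL, seed = 1L) {
  stopifnot(length(samples) >= 1)
  S <- dim(samples[[1]]$image)[1]
  if (is.null(net)) net <- build_disc_net(S, seed = seed)
  res <- net$resolution
  xs <- lapply(samples, function(s) {
    img <- s$image
    if (dim(img)[1] != res) img <- bilinear_resize(img, res, res)
    img
  })
  ts <- lapply(samples, disc_truth_mask, resolution = res)
  set.seed(seed + 10L)
  mom <- NULL
  log <- list()
  npix <- res * res
  for (ep in seq_len(epochs)) {
    ord <- sample.int(length(xs))
    losses <- numeric(0)
    for (i in ord) {
      fw <- disc_net_forward(net, xs[[i]], keep = TRUE)
      pr <- sigmoid(fw$logits)
      t <- ts[[i]]
      if (is.null(pos_weight)) {
        pf <- max(mean(t), 1e-4)
        w <- ifelse(t == 1, 0.5 / pf, 0.5 / (1 - pf))
      } else {
        w <- ifelse(t == 1, pos_weight, 1)
      }
      eps <- 1e-7
      losses <- c(losses, mean(-w * (t * log(pr + eps) +
                                       (1 - t) * log(1 - pr + eps))))
      dlog <- w * (pr - t) / npix
      g <- disc_net_backward(net, fw, dlog)
      st <- sgd_step(net$params, g, mom, lr)
      net$params <- st$p; mom <- st$v
    }
    log[[ep]] <- data.frame(epoch = ep, loss = mean(losses))
  }
  net$trained <- TRUE
  net$training_log <- do.call(rbind, log)
  net
}

#' Segment the optic disc in an image
#'
#' @param image H x W x 3 image in `[0, 1]`.
#' @param net A trained `rd_disc_net`.
#' @return Binary 0/1 matrix at the image's resolution.
#' @export
segment_disc <- function(image, net) {
  if (!isTRUE(net$trained)) stop("disc segmentation network is untrained")
  S <- dim(image)[1]
  x <- image
  if (S != net$resolution) x <- bilinear_resize(x, net$resolution, net$resolution)
  pr <- sigmoid(disc_net_forward(net, x)$logits)
  if (S != net$resolution) pr <- bilinear_resize(pr, S, S)
  m <- (pr >= 0.5) * 1L
  storage.mode(m) <- "integer"
  m
}

#' Reduce a disc mask to center + radius geometry
#'
#' Keeps the largest 4-connected component; the center is its centroid and
#' the radius the equivalent-circle radius `sqrt(area / pi)` (robust to
#' ragged mask borders).
#'
#' @param mask Binary matrix.
#' @return An object of class `rd_disc_geometry`: `center = c(x, y)`,
#'   `radius`, `mask` (largest component only).
#' @export
extract_disc_geometry <- function(mask) {
  m <- mask != 0
  if (!any(m)) stop("no disc: empty segmentation mask")
  lab <- .ccl_label(matrix(as.integer(m), nrow(mask), ncol(mask)))
  sizes <- tabulate(lab[lab > 0])
  keep <- which.max(sizes)
  comp <- (lab == keep) * 1L
  idx <- which(comp == 1L, arr.ind = TRUE)
  structure(list(center = c(mean(idx[, 2]), mean(idx[, 1])),
                 radius = sqrt(nrow(idx) / pi),
                 mask = comp),
            class = "rd_disc_geometry")
}

#' Read a landmark sidecar
#'
#' Sidecars store 0-based pixel coordinates; positions are returned 1-based
#' to match the in-memory convention. An absent fovea marks a Macula-OFF
#' image, which is excluded from anatomical evaluation.
#'
#' @param sidecar Path to a JSON sidecar, or an already-parsed list.
#' @return List with `fovea` (`position`, `present`), `disc` (an
#'   `rd_disc_geometry` without mask, or NULL), `laterality`, `is_rd`.
#' @export
read_landmarks <- function(sidecar) {
  rec <- if (is.character(sidecar)) jsonlite::read_json(sidecar,
                                                        simplifyVector = TRUE)
         else sidecar
  if (!is.list(rec)) stop("malformed landmark sidecar")
  fov_present <- !is.null(rec$fovea) && length(rec$fovea) == 2 &&
    !any(is.na(unlist(rec$fovea)))
  fovea <- list(
    position = if (fov_present) as.numeric(unlist(rec$fovea)) + 1 else c(NA, NA),
    present = fov_present
  )
  disc <- NULL
  if (!is.null(rec$disc_center) && !is.null(rec$disc_radius)) {
    disc <- structure(list(center = as.numeric(unlist(rec$disc_center)) + 1,
                           radius = as.numeric(rec$disc_radius), mask = NULL),
                      class = "rd_disc_geometry")
  }
  list(fovea = fovea, disc = disc,
       laterality = rec$laterality %||% NA_character_,
       is_rd = isTRUE(rec$is_rd))
}

#' Build the anatomical frame from landmarks with fallback hierarchy
#'
#' Disc source preference: sidecar disc (oracle) over the segmented disc;
#' the active source is recorded for provenance. Macula-OFF inputs (absent
#' fovea) are rejected and must not reach the anatomy stage.
#'
#' @param landmarks Result of [read_landmarks()].
#' @param canvas Integer `c(h, w)`.
#' @param image Optional image, needed when falling back to segmentation.
#' @param net Optional trained `rd_disc_net`.
#' @return An `rd_frame` with attribute `disc_source`
#'   (`"sidecar"`/`"segmented"`).
#' @export
landmark_frame <- function(landmarks, canvas, image = NULL, net = NULL) {
  if (!landmarks$fovea$present) {
    stop("Macula-OFF image (no fovea annotation): excluded from anatomical evaluation")
  }
  disc <- landmarks$disc
  source <- "sidecar"
  if (is.null(disc)) {
    if (is.null(image) || is.null(net)) {
      stop("no sidecar disc and no segmentation model available")
    }
    disc <- extract_disc_geometry(segment_disc(image, net))
    source <- "segmented"
  }
  fr <- fit_frame(landmarks$fovea$position, disc,
                  if (is.na(landmarks$laterality)) "OD" else landmarks$laterality,
                  canvas)
  attr(fr, "disc_source") <- source
  fr
}
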