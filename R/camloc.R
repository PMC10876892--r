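# Lesion localization from the trained classifier: Grad-CAM on stage-4
# feature maps, per-image min-max normalization to [0, 1], bilinear
# resampling to the original grid, ROI re-masking, and thresholding into a
# binary pseudo-mask (default probability threshold 0.5).

#' Grad-CAM activation map for the RD class
#'
#' `map = ReLU(sum_k w_k A_k)` where `A_k` are the stage-4 feature maps and
#' `w_k` the spatially pooled gradients of the pre-sigmoid RD score with
#' respect to `A_k`.
#'
#' @param model An `rd_backbone` (or a toy model of class `rd_toy_model`, a
#'   list with `features(image)` returning an H x W x C array and a `head_w`
#'   vector so that `logit = sum(head_w * gap(A)) + head_b`).
#' @param image Preprocessed image at the model's input resolution.
#' @return Non-negative low-resolution activation map (matrix) with
#'   attribute `source_resolution`.
#' @export
grad_cam_map <- function(model, image) UseMethod("grad_cam_map")

#' @export
grad_cam_map.rd_backbone <- function(model, image) {
  fw <- forward_backbone(model, image)
  cam_from_features(fw$stage4, grad_wrt_features(effective_head(model),
                                                 fw$stage4))
}

# head weights on the raw (unstandardized) GAP features
effective_head <- function(model) {
  sd_ <- sqrt(model$feat_stats$var + 1e-5)
  list(w = model$params$head$w / sd_, b = model$params$head$b)
}

#' @export
grad_cam_map.rd_toy_model <- function(model, image) {
  A <- model$features(image)
  head <- list(w = model$head_w, b = model$head_b %||% 0)
  cam_from_features(A, grad_wrt_features(head, A))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# d logit / d A for a GAP + linear head: constant head_w[c] / (H*W)
grad_wrt_features <- function(head, A) {
  gap_bwd(A, head$w)
}

#' Combine feature maps and their gradients into a class activation map
#'
#' @param A H x W x C feature array.
#' @param dA Gradient of the class score with respect to `A`, same shape.
#' @return `ReLU(sum_k mean(dA_k) * A_k)` as a matrix with attribute
#'   `source_resolution`.
#' @export
cam_from_features <- function(A, dA) {
  stopifnot(all(dim(A) == dim(dA)))
  w <- apply(dA, 3, mean)
  m <- matrix(0, dim(A)[1], dim(A)[2])
  for (k in seq_along(w)) m <- m + w[k] * A[, , k]
  m <- pmax(m, 0)
  attr(m, "source_resolution") <- dim(A)[1]
  m
}

#' Min-max normalize an activation map to a probability map
#'
#' Linear rescale to `[0, 1]` over the ROI support (whole map if no ROI is
#' given). A constant map normalizes to all zeros (no lesion claimed), and
#' values outside the ROI support are forced to 0. Idempotent.
#'
#' @param raw Non-negative activation map (matrix).
#' @param roi Optional 0/1 support matrix matching `raw`.
#' @return Probability map in `[0, 1]`.
#' @export
normalize_map <- function(raw, roi = NULL) {
  m <- raw
  sup <- if (is.null(roi)) rep(TRUE, length(m)) else as.logical(roi != 0)
  v <- m[sup]
  if (length(v) == 0 || max(v) - min(v) < .Machine$double.eps) {
    out <- matrix(0, nrow(m), ncol(m))
  } else {
    out <- (m - min(v)) / (max(v) - min(v))
    out <- pmin(pmax(out, 0), 1)
  }
  out[!sup] <- 0
  attr(out, "source_resolution") <- attr(raw, "source_resolution") %||% nrow(raw)
  out
}

#' Resample a probability map to the original image size
#'
#' Bilinear interpolation (half-pixel centers); the `[0, 1]` range is
#' preserved and the ROI is re-applied after resampling when given.
#'
#' @param map Probability map matrix.
#' @param target_size Target side length in pixels (>= source side).
#' @param roi Optional `rd_roi_template` (or 0/1 matrix) at the target size.
#' @return `target_size` x `target_size` probability map.
#' @export
upsample_to_image <- function(map, target_size, roi = NULL) {
  if (target_size <= 0) stop("target size must be positive")
  if (target_size < nrow(map)) stop("target size below the source resolution")
  out <- if (target_size == nrow(map) && target_size == ncol(map)) {
    map + 0  # drop attributes copy
  } else {
    bilinear_resize(map, target_size, target_size)
  }
  out <- pmin(pmax(out, 0), 1)
  if (!is.null(roi)) {
    rm_ <- if (inherits(roi, "rd_roi_template")) roi$mask else roi
    out <- out * (rm_ != 0)
  }
  attr(out, "source_resolution") <- attr(map, "source_resolution") %||% nrow(map)
  out
}

#' Threshold a probability map into a binary pseudo-mask
#'
#' `mask = (map >= threshold)`, intersected with the ROI support when given;
#' monotone in the threshold (a higher threshold yields a subset).
#'
#' @param map Probability map in `[0, 1]`.
#' @param threshold Threshold in `[0, 1]`, default 0.5.
#' @param roi Optional `rd_roi_template` (or 0/1 matrix) matching `map`.
#' @return Integer 0/1 matrix with attribute `threshold_used`.
#' @export
pseudo_mask <- function(map, threshold = 0.5, roi = NULL) {
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
  m <- (map >= threshold) * 1L
  if (!is.null(roi)) {
    rm_ <- if (inherits(roi, "rd_roi_template")) roi$mask else roi
    m <- m * (rm_ != 0)
  }
  storage.mode(m) <- "integer"
  attr(m, "threshold_used") <- threshold
  m
}

#' Full localization chain for one sample
#'
#' Preprocess -> classify -> Grad-CAM -> normalize -> resample to the canvas
#' -> ROI re-mask -> pseudo-mask -> 48-partition vector, primary zone and
#' posterior-pole involvement.
#'
#' @param model A trained `rd_backbone`.
#' @param sample An `rd_sample` (or a list with `image` and `frame`).
#' @param rule An `rd_partition_rule`.
#' @param threshold Pseudo-mask probability threshold, default 0.5.
#' @return List: `probability`, `is_rd`, `prob_map` (canvas-sized),
#'   `mask`, `partitions`, `primary_zone`, `posterior`.
#' @export
localize_rd <- function(model, sample, rule = partition_rule(),
                        threshold = 0.5) {
  S <- dim(sample$image)[1]
  res <- model$input_resolution
  roi_S <- build_roi_template(S)
  img <- sample$image
  if (S != res) img <- bilinear_resize(img, res, res)
  img <- preprocess_image(img, build_roi_template(res))
  fw <- forward_backbone(model, img)
  raw <- cam_from_features(fw$stage4,
                           grad_wrt_features(effective_head(model), fw$stage4))
  pm <- normalize_map(raw)
  pm <- upsample_to_image(pm, S, roi_S)
  mask <- pseudo_mask(pm, threshold, roi_S)
  list(
    probability = fw$prob,
    is_rd = fw$prob >= model$config$decision_threshold,
    prob_map = pm,
    mask = mask,
    partitions = partition_vector(mask, sample$frame, rule),
    primary_zone = primary_zone(mask, sample$frame),
    posterior = posterior_involved(mask, sample$frame, rule)
  )
}

#' Centroid of a binary mask
#'
#' @param mask 0/1 matrix.
#' @return `c(x, y)` centroid of the nonzero pixels, or `c(NA, NA)` if empty.
#' @export
mask_centroid <- function(mask) {
  idx <- which(mask != 0, arr.ind = TRUE)
  if (nrow(idx) == 0) return(c(NA_real_, NA_real_))
  c(mean(idx[, 2]), mean(idx[, 1]))
}

#' Bounding box of a binary mask
#'
#' @param mask 0/1 matrix.
#' @return `c(xmin, xmax, ymin, ymax)` or NAs if empty.
#' @export
mask_bbox <- function(mask) {
  idx <- which(mask != 0, arr.ind = TRUE)
  if (nrow(idx) == 0) return(rep(NA_real_, 4))
  c(min(idx[, 2]), max(idx[, 2]), min(idx[, 1]), max(idx[, 1]))
}
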