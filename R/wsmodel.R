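# Weakly-supervised RD classifier: a 4-stage residual-style convolutional
# backbone (desk-scale widths; the reference design is a ResNet-101) trained
# in two phases. Phase 1: plain classifier, focal loss (alpha 0.65, gamma
# 1.15), lr 0.01. Phase 2: channel attention modulation modules (AMM) are
# inserted between every two consecutive stages and the network is fine-tuned
# at lr 0.001 so that minor-but-relevant channels survive into the stage-4
# activation maps used for localization.

#' Training configuration
#'
#' Defaults follow the reference protocol: focal loss alpha 0.65 / gamma
#' 1.15, pretrain lr 0.01, fine-tune lr 0.001, decision threshold 0.5. The
#' desk-scale default input resolution is 128.
#'
#' @param input_resolution One of 128/256/512/1024.
#' @param lr_pretrain,lr_finetune Learning rates of the two phases.
#' @param focal_alpha Positive-class weight in (0, 1).
#' @param focal_gamma Focusing exponent (>= 0).
#' @param epochs_pretrain,epochs_finetune Epoch counts.
#' @param batch_size Mini-batch size.
#' @param backbone_depth `"tiny"` (desk scale) or `"wide"` (doubled widths).
#' @param weight_decay L2 penalty on convolution and head weights (not
#'   biases), default 5e-4; concentrates the activation maps on the
#'   discriminative channels.
#' @param amm_reduction Channel-attention bottleneck reduction ratio (>= 1).
#' @param amm_lambda Modulation strength lambda (>= 0, 0 = identity).
#' @param decision_threshold Image-level RD decision threshold.
#' @param seed RNG seed controlling initialization and shuffling.
#' @return An object of class `rd_train_config`.
#' @export
train_config <- function(input_resolution = 128, lr_pretrain = 0.01,
                         lr_finetune = 0.001, focal_alpha = 0.65,
                         focal_gamma = 1.15, epochs_pretrain = 10,
                         epochs_finetune = 2, batch_size = 16,
                         backbone_depth = c("tiny", "wide"),
                         weight_decay = 5e-4,
                         amm_reduction = 4, amm_lambda = 1,
                         decision_threshold = 0.5, seed = 1L) {
  backbone_depth <- match.arg(backbone_depth)
  stopifnot(input_resolution %in% c(128, 256, 512, 1024),
            lr_pretrain > 0, lr_finetune > 0,
            focal_alpha > 0, focal_alpha < 1, focal_gamma >= 0,
            weight_decay >= 0, amm_reduction >= 1, amm_lambda >= 0)
  structure(as.list(environment()), class = "rd_train_config")
}

#' Focal loss for the true-class probability
#'
#' `loss = -w * (1 - p)^gamma * log(p)` with `w = alpha` for the positive
#' class and `1 - alpha` for the negative class. At `gamma = 0` this is
#' weighted cross-entropy.
#'
#' @param p Probability assigned to the true class, in (0, 1). Vectorized.
#' @param alpha Positive-class weight, default 0.65.
#' @param gamma Focusing exponent, default 1.15.
#' @param positive Logical (vectorized): is the true class the positive one?
#' @return Non-negative loss values.
#' @export
focal_loss <- function(p, alpha = 0.65, gamma = 1.15, positive = TRUE) {
  if (any(p <= 0 | p >= 1)) stop("p must lie strictly inside (0, 1)")
  w <- ifelse(positive, alpha, 1 - alpha)
  -w * (1 - p)^gamma * log(p)
}

# d loss / d logit for a single-logit sigmoid head; pp = P(positive)
focal_grad_logit <- function(pp, y, alpha, gamma) {
  if (y == 1) {
    alpha * gamma * pp * (1 - pp)^gamma * log(pp) - alpha * (1 - pp)^(gamma + 1)
  } else {
    (1 - alpha) * pp^(gamma + 1) -
      (1 - alpha) * gamma * (1 - pp) * pp^gamma * log(1 - pp)
  }
}

## ---- attention modulation module -------------------------------------------

#' AMM hyper-parameters
#'
#' @param reduction_ratio Bottleneck factor of the channel attention (>= 1).
#' @param lambda Modulation strength; 0 disables modulation (identity).
#' @return An object of class `rd_amm_params`.
#' @export
amm_params <- function(reduction_ratio = 4, lambda = 1) {
  stopifnot(reduction_ratio >= 1, lambda >= 0)
  structure(list(reduction_ratio = reduction_ratio, lambda = lambda),
            class = "rd_amm_params")
}

# Identity-flavored init: each bottleneck unit pools a contiguous channel
# group, and the expansion reproduces the (normalized) group energy, so the
# initial attention is monotone in channel energy and recalibration starts
# from a meaningful ranking.
amm_init <- function(C, reduction = 4, lambda = 1, gain = 0.5) {
  Cmid <- max(1L, floor(C / reduction))
  grp <- ceiling(seq_len(C) * Cmid / C)
  W1 <- matrix(stats::rnorm(Cmid * C, 0, 0.01), Cmid, C)
  W2 <- matrix(stats::rnorm(C * Cmid, 0, 0.01), C, Cmid)
  for (m in seq_len(Cmid)) {
    idx <- which(grp == m)
    W1[m, idx] <- W1[m, idx] + 1 / length(idx)
    W2[idx, m] <- W2[idx, m] + gain
  }
  list(W1 = W1, b1 = numeric(Cmid), W2 = W2, b2 = rep(-gain, C),
       lambda = lambda, reduction = reduction)
}

amm_fwd <- function(x, p) {
  d <- dim(x)
  e <- gap_fwd(x)
  s <- mean(e) + 1e-8
  ehat <- e / s
  z1 <- as.numeric(p$W1 %*% ehat + p$b1)
  h <- pmax(z1, 0)
  z2 <- as.numeric(p$W2 %*% h + p$b2)
  a <- sigmoid(z2)
  rk <- rank(a, ties.method = "first")
  atil <- 0.5 * (a + (1 - rk / d[3]))
  f <- 1 + p$lambda * atil
  y <- sweep(x, 3, f, "*")
  list(y = y, cache = list(e = e, s = s, ehat = ehat, z1 = z1, h = h,
                           a = a, atil = atil, f = f))
}

amm_bwd <- function(x, cache, p, dy) {
  d <- dim(x)
  dx <- sweep(dy, 3, cache$f, "*")
  df <- vapply(seq_len(d[3]), function(c) sum(dy[, , c] * x[, , c]),
               numeric(1))
  da <- 0.5 * p$lambda * df               # rank term treated as constant
  dz2 <- da * cache$a * (1 - cache$a)
  dW2 <- outer(dz2, cache$h)
  db2 <- dz2
  dh <- as.numeric(t(p$W2) %*% dz2)
  dz1 <- dh * (cache$z1 > 0)
  dW1 <- outer(dz1, cache$ehat)
  db1 <- dz1
  dehat <- as.numeric(t(p$W1) %*% dz1)
  de <- dehat / cache$s - sum(dehat * cache$ehat) / (cache$s * d[3])
  dx <- dx + gap_bwd(x, de)
  list(dx = dx, g = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2))
}

#' Apply attention modulation to a feature tensor
#'
#' Computes per-channel attention `a` (global average pool -> bottleneck ->
#' sigmoid), recalibrates it by blending with its inverted rank,
#' `a~ = (a + (1 - rank(a)/C)) / 2`, and returns `x * (1 + lambda * a~)`
#' per channel. Recalibration lifts minor (low-attention) channels so they
#' keep contributing to downstream activation maps; `lambda = 0` is the
#' identity.
#'
#' @param features H x W x C numeric array (a stage output).
#' @param params An `rd_amm_params`.
#' @param weights Optional module weights (as produced by the internal
#'   initializer); a fresh deterministic initialization from `seed` is used
#'   when omitted, as for an untrained module.
#' @param seed Seed for the fresh initialization.
#' @return Modulated array of the same shape, with attributes `attention`
#'   (a), `recalibrated` (a~) and `factor` (1 + lambda * a~).
#' @export
amm_modulate <- function(features, params = amm_params(), weights = NULL,
                         seed = 1L) {
  d <- dim(features)
  if (is.null(d) || length(d) != 3 || any(d == 0)) {
    stop("features must be a non-empty H x W x C array")
  }
  if (is.null(weights)) {
    set.seed(seed)
    weights <- amm_init(d[3], params$reduction_ratio, params$lambda)
  }
  weights$lambda <- params$lambda
  r <- amm_fwd(features, weights)
  structure(r$y, attention = r$cache$a, recalibrated = r$cache$atil,
            factor = r$cache$f)
}

#' Normalized per-channel importance of a feature tensor
#'
#' Mean absolute activation per channel, normalized to sum to one; the
#' dispersion (standard deviation) of this distribution quantifies how
#' concentrated the feature importance is across channels.
#'
#' @param features H x W x C numeric array.
#' @return Numeric vector of length C summing to 1.
#' @export
channel_importance <- function(features) {
  e <- apply(abs(features), 3, mean)
  e / (sum(e) + 1e-12)
}

## ---- backbone ---------------------------------------------------------------

backbone_widths <- function(depth) {
  w <- c(stem = 8L, s1 = 16L, s2 = 24L, s3 = 32L, s4 = 32L)
  if (depth == "wide") w <- w * 2L
  w
}

#' Build an untrained 4-stage backbone
#'
#' Stem plus four stages (stride 2,2,2,1,1), ReLU activations, global average
#' pooling and a single-logit head. AMM insertion points sit between every
#' two consecutive stages (after stages 1-3); stage-4 feature maps are the
#' Grad-CAM source.
#'
#' @param config An `rd_train_config`.
#' @return An object of class `rd_backbone` (untrained, no AMMs).
#' @export
build_backbone <- function(config = train_config()) {
  set.seed(config$seed)
  wd <- backbone_widths(config$backbone_depth)
  params <- list(
    stem = conv_init(3, 3, 3, wd["stem"]),
    s1 = conv_init(3, 3, wd["stem"], wd["s1"]),
    s2 = conv_init(3, 3, wd["s1"], wd["s2"]),
    s3 = conv_init(3, 3, wd["s2"], wd["s3"]),
    s4 = conv_init(3, 3, wd["s3"], wd["s4"]),
    head = list(w = stats::rnorm(wd["s4"], 0, 0.05), b = 0),
    amm1 = NULL, amm2 = NULL, amm3 = NULL
  )
  structure(list(params = params, widths = wd,
                 input_resolution = config$input_resolution,
                 # BatchNorm-style running statistics of the GAP feature
                 # vector: the head reads standardized features, which keeps
                 # the logit linear in the stage-4 maps (Grad-CAM stays
                 # exact) while making the head trainable at the reference
                 # learning rates. Constants in the backward pass; frozen at
                 # inference.
                 feat_stats = list(mu = numeric(wd[["s4"]]),
                                   var = rep(1, wd[["s4"]])),
                 config = config, phase = "untrained"),
            class = "rd_backbone")
}

#' @export
print.rd_backbone <- function(x, ...) {
  cat(sprintf("rd_backbone (%s, %dpx, widths %s, AMM %s)\n", x$phase,
              x$input_resolution, paste(x$widths, collapse = "/"),
              if (is.null(x$params$amm1)) "absent" else
                sprintf("lambda=%g", x$params$amm1$lambda)))
  invisible(x)
}

#' Insert attention modulation modules between stages
#'
#' Three AMMs are added after stages 1-3. With `lambda = 0` the modulated
#' network reproduces the plain classifier's outputs exactly.
#'
#' @param model An `rd_backbone`.
#' @param params An `rd_amm_params`.
#' @return The model with freshly initialized AMMs.
#' @export
insert_amm <- function(model, params = amm_params()) {
  set.seed(model$config$seed + 1000L)
  wd <- model$widths
  model$params$amm1 <- amm_init(wd[["s1"]], params$reduction_ratio, params$lambda)
  model$params$amm2 <- amm_init(wd[["s2"]], params$reduction_ratio, params$lambda)
  model$params$amm3 <- amm_init(wd[["s3"]], params$reduction_ratio, params$lambda)
  model
}

forward_backbone <- function(model, x, keep = FALSE) {
  p <- model$params
  cache <- list(x = x)
  z0 <- conv_fwd(x, p$stem, 2); a0 <- relu_fwd(z0)
  z1 <- conv_fwd(a0, p$s1, 2); a1 <- relu_fwd(z1)
  if (!is.null(p$amm1)) { r <- amm_fwd(a1, p$amm1); m1 <- r$y; cache$amm1 <- r$cache } else m1 <- a1
  z2 <- conv_fwd(m1, p$s2, 2); a2 <- relu_fwd(z2)
  if (!is.null(p$amm2)) { r <- amm_fwd(a2, p$amm2); m2 <- r$y; cache$amm2 <- r$cache } else m2 <- a2
  z3 <- conv_fwd(m2, p$s3, 1); a3 <- relu_fwd(z3)
  if (!is.null(p$amm3)) { r <- amm_fwd(a3, p$amm3); m3 <- r$y; cache$amm3 <- r$cache } else m3 <- a3
  z4 <- conv_fwd(m3, p$s4, 1); a4 <- relu_fwd(z4)
  g <- gap_fwd(a4)
  sd_ <- sqrt(model$feat_stats$var + 1e-5)
  ghat <- (g - model$feat_stats$mu) / sd_
  logit <- sum(p$head$w * ghat) + p$head$b
  if (keep) {
    cache <- c(cache, list(z0 = z0, a0 = a0, z1 = z1, a1 = a1, m1 = m1,
                           z2 = z2, a2 = a2, m2 = m2, z3 = z3, a3 = a3,
                           m3 = m3, z4 = z4, a4 = a4, g = g, ghat = ghat,
                           sd = sd_))
  }
  list(logit = logit, prob = sigmoid(logit), stage4 = a4, g = g,
       cache = cache)
}

# full backward from d(logit); returns parameter gradients and d(stage4)
backward_backbone <- function(model, fw, dlogit) {
  p <- model$params; cc <- fw$cache
  g <- list()
  g$head <- list(w = cc$ghat * dlogit, b = dlogit)
  dg <- p$head$w / cc$sd * dlogit
  da4 <- gap_bwd(cc$a4, dg)
  dz4 <- relu_bwd(cc$z4, da4)
  r4 <- conv_bwd(cc$m3, p$s4, dz4, 1); g$s4 <- list(w = r4$dw, b = r4$db)
  dm3 <- r4$dx
  if (!is.null(p$amm3)) {
    r <- amm_bwd(cc$a3, cc$amm3, p$amm3, dm3); da3 <- r$dx; g$amm3 <- r$g
  } else da3 <- dm3
  dz3 <- relu_bwd(cc$z3, da3)
  r3 <- conv_bwd(cc$m2, p$s3, dz3, 1); g$s3 <- list(w = r3$dw, b = r3$db)
  dm2 <- r3$dx
  if (!is.null(p$amm2)) {
    r <- amm_bwd(cc$a2, cc$amm2, p$amm2, dm2); da2 <- r$dx; g$amm2 <- r$g
  } else da2 <- dm2
  dz2 <- relu_bwd(cc$z2, da2)
  r2 <- conv_bwd(cc$m1, p$s2, dz2, 2); g$s2 <- list(w = r2$dw, b = r2$db)
  dm1 <- r2$dx
  if (!is.null(p$amm1)) {
    r <- amm_bwd(cc$a1, cc$amm1, p$amm1, dm1); da1 <- r$dx; g$amm1 <- r$g
  } else da1 <- dm1
  dz1 <- relu_bwd(cc$z1, da1)
  r1 <- conv_bwd(cc$a0, p$s1, dz1, 2); g$s1 <- list(w = r1$dw, b = r1$db)
  dz0 <- relu_bwd(cc$z0, r1$dx)
  r0 <- conv_bwd(cc$x, p$stem, dz0, 2); g$stem <- list(w = r0$dw, b = r0$db)
  g
}

## ---- training ---------------------------------------------------------------

prepare_inputs <- function(samples, resolution, preprocess = TRUE) {
  template <- build_roi_template(resolution)
  xs <- lapply(samples, function(s) {
    img <- if (inherits(s, "rd_sample")) s$image else s
    if (dim(img)[1] != resolution) {
      img <- bilinear_resize(img, resolution, resolution)
    }
    if (preprocess) preprocess_image(img, template) else img
  })
  ys <- vapply(samples, function(s) {
    if (inherits(s, "rd_sample")) as.integer(s$is_rd) else NA_integer_
  }, integer(1))
  list(xs = xs, ys = ys)
}

train_loop <- function(model, xs, ys, config, lr, epochs, phase) {
  n <- length(xs)
  mom <- NULL
  log <- list()
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    losses <- numeric(0); correct <- 0
    for (b0 in seq(1, n, by = config$batch_size)) {
      idx <- ord[b0:min(b0 + config$batch_size - 1, n)]
      acc <- NULL
      for (i in idx) {
        fw <- forward_backbone(model, xs[[i]], keep = TRUE)
        # update running feature statistics (cumulative early, EMA later)
        nseen <- model$feat_stats$n %||% 0
        rate <- max(0.02, 1 / (nseen + 1))
        model$feat_stats$mu <- (1 - rate) * model$feat_stats$mu + rate * fw$g
        model$feat_stats$var <- (1 - rate) * model$feat_stats$var +
          rate * (fw$g - model$feat_stats$mu)^2
        model$feat_stats$n <- nseen + 1
        pp <- min(max(fw$prob, 1e-7), 1 - 1e-7)
        ptrue <- if (ys[i] == 1) pp else 1 - pp
        losses <- c(losses, focal_loss(ptrue, config$focal_alpha,
                                       config$focal_gamma, ys[i] == 1))
        correct <- correct + as.integer((pp >= config$decision_threshold) == (ys[i] == 1))
        dlogit <- focal_grad_logit(pp, ys[i], config$focal_alpha,
                                   config$focal_gamma)
        acc <- grad_accumulate(acc, backward_backbone(model, fw, dlogit))
      }
      acc <- grad_scale(acc, 1 / length(idx))
      acc <- add_weight_decay(acc, model$params, config$weight_decay %||% 0)
      st <- sgd_step(model$params, acc, mom, lr)
      model$params <- st$p; mom <- st$v
    }
    log[[ep]] <- data.frame(phase = phase, epoch = ep, loss = mean(losses),
                            accuracy = correct / n)
  }
  model$training_log <- rbind(model$training_log, do.call(rbind, log))
  model
}

#' Train the plain RD classifier (phase 1)
#'
#' No AMM active; focal loss at the configured alpha/gamma, momentum SGD at
#' `lr_pretrain`. Fully seeded and deterministic on one device.
#'
#' @param train_set List of `rd_sample` objects (images are ROI-masked,
#'   CLAHE-enhanced and resized to the configured resolution internally).
#' @param config An `rd_train_config`.
#' @return A trained `rd_backbone` with a `training_log` data.frame.
#' @export
train_classifier <- function(train_set, config = train_config()) {
  if (length(train_set) == 0) stop("empty training set")
  prep <- prepare_inputs(train_set, config$input_resolution)
  if (length(unique(prep$ys)) < 2) {
    stop("training set must contain both RD and non-RD images")
  }
  model <- build_backbone(config)
  set.seed(config$seed + 1L)
  model <- train_loop(model, prep$xs, prep$ys, config, config$lr_pretrain,
                      config$epochs_pretrain, "pretrain")
  model$phase <- "pretrained"
  model
}

#' Fine-tune with attention modulation modules (phase 2)
#'
#' Inserts AMMs between every two consecutive stages (unless already present)
#' and fine-tunes all parameters at `lr_finetune`.
#'
#' @param model A pretrained `rd_backbone`.
#' @param train_set List of `rd_sample` objects.
#' @param config An `rd_train_config`.
#' @return The fine-tuned model.
#' @export
finetune_with_amm <- function(model, train_set, config = model$config) {
  if (!inherits(model, "rd_backbone")) stop("model lacks AMM insertion points")
  if (is.null(model$params$amm1)) {
    model <- insert_amm(model, amm_params(config$amm_reduction,
                                          config$amm_lambda))
  }
  prep <- prepare_inputs(train_set, config$input_resolution)
  set.seed(config$seed + 2L)
  model <- train_loop(model, prep$xs, prep$ys, config, config$lr_finetune,
                      config$epochs_finetune, "finetune")
  model$phase <- "amm-finetuned"
  model
}

#' Classify a preprocessed image as RD / non-RD
#'
#' @param model A trained `rd_backbone`.
#' @param image H x W x 3 image at the model's input resolution, already
#'   preprocessed (see [preprocess_image()]).
#' @param threshold Decision threshold; the boundary case `prob == threshold`
#'   is called RD (>= convention).
#' @return List with `probability` in `[0, 1]` and logical `is_rd`.
#' @export
classify_rd <- function(model, image, threshold = 0.5) {
  if (dim(image)[1] != model$input_resolution ||
      dim(image)[2] != model$input_resolution) {
    stop("image resolution does not match the model's input resolution")
  }
  fw <- forward_backbone(model, image)
  list(probability = fw$prob, is_rd = fw$prob >= threshold)
}
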