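# Thin R layer over the compiled conv/upsample kernels: parameter
# initialization, forward/backward passes, and SGD with momentum. Tensors are
# H x W x C arrays; conv weights are kh x kw x cin x cout arrays flattened to
# (kh*kw*cin) x cout matrices at the C++ boundary.

conv_init <- function(kh, kw, cin, cout) {
  fan_in <- kh * kw * cin
  list(w = array(stats::rnorm(kh * kw * cin * cout, 0, sqrt(2 / fan_in)),
                 dim = c(kh, kw, cin, cout)),
       b = numeric(cout))
}

wmat <- function(p) {
  d <- dim(p$w)
  matrix(p$w, d[1] * d[2] * d[3], d[4])
}

conv_fwd <- function(x, p, stride = 1L, pad = 1L) {
  d <- dim(p$w)
  .conv2d_forward(x, wmat(p), p$b, d[1], d[2], as.integer(stride),
                  as.integer(pad))
}

conv_bwd <- function(x, p, dy, stride = 1L, pad = 1L) {
  d <- dim(p$w)
  g <- .conv2d_backward(x, wmat(p), dy, d[1], d[2], as.integer(stride),
                        as.integer(pad))
  g$dw <- array(g$dw, dim = d)
  g
}

relu_fwd <- function(x) pmax(x, 0)
relu_bwd <- function(x, dy) dy * (x > 0)

# leaky variant (used in the dense segmenter, where the heavily one-sided
# background gradient can otherwise kill units permanently)
lrelu_fwd <- function(x) pmax(x, 0.01 * x)
lrelu_bwd <- function(x, dy) dy * ifelse(x > 0, 1, 0.01)

gap_fwd <- function(x) apply(x, 3, mean)
gap_bwd <- function(x, dg) {
  d <- dim(x)
  sweep(array(1 / (d[1] * d[2]), dim = d), 3, dg, "*")
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# momentum SGD over a nested parameter/gradient structure (named lists of
# numeric arrays with matching shapes; gradients are matched to parameters
# by name, so partial/ordered-differently gradient lists are fine)
sgd_step <- function(params, grads, state, lr, momentum = 0.9) {
  walk <- function(p, g, v) {
    if (is.list(p)) {
      out_p <- p
      out_v <- if (is.null(v)) stats::setNames(vector("list", length(p)),
                                               names(p)) else v
      for (nm in names(p)) {
        if (is.null(g[[nm]]) || is.null(p[[nm]])) next
        r <- walk(p[[nm]], g[[nm]], out_v[[nm]])
        out_p[[nm]] <- r$p; out_v[[nm]] <- r$v
      }
      list(p = out_p, v = out_v)
    } else {
      vv <- if (is.null(v)) g * 0 else v
      vv <- momentum * vv + g
      list(p = p - lr * vv, v = vv)
    }
  }
  walk(params, grads, state)
}

grad_accumulate <- function(acc, g) {
  if (is.null(acc)) return(g)
  walk <- function(a, b) {
    if (is.list(a)) {
      for (i in seq_along(a)) a[[i]] <- walk(a[[i]], b[[i]])
      a
    } else a + b
  }
  walk(acc, g)
}

# add L2 gradient wd * p to weight leaves (names "w", "W1", "W2"); biases
# and running statistics are not decayed
add_weight_decay <- function(g, p, wd) {
  if (wd == 0) return(g)
  walk <- function(gg, pp) {
    if (is.list(gg)) {
      for (nm in names(gg)) {
        if (is.null(gg[[nm]]) || is.null(pp[[nm]])) next
        gg[[nm]] <- if (is.list(gg[[nm]])) walk(gg[[nm]], pp[[nm]])
                    else if (nm %in% c("w", "W1", "W2")) gg[[nm]] + wd * pp[[nm]]
                    else gg[[nm]]
      }
    }
    gg
  }
  walk(g, p)
}

grad_scale <- function(g, s) {
  walk <- function(a) {
    if (is.list(a)) {
      for (i in seq_along(a)) a[[i]] <- walk(a[[i]])
      a
    } else a * s
  }
  walk(g)
}

#' Bilinear resize of a matrix or multi-channel array
#'
#' Half-pixel-center convention: target pixel `t` (1-based) samples source
#' coordinate `(t - 0.5) * S / T + 0.5`, clamped to the border.
#'
#' @param x Numeric matrix or H x W x C array.
#' @param out_h,out_w Target size.
#' @return Resized matrix/array.
#' @export
bilinear_resize <- function(x, out_h, out_w) {
  rgb <- length(dim(x)) == 3
  h <- dim(x)[1]; w <- dim(x)[2]
  sy <- (seq_len(out_h) - 0.5) * h / out_h + 0.5
  sx <- (seq_len(out_w) - 0.5) * w / out_w + 0.5
  y0 <- pmin(pmax(floor(sy), 1), h); y1 <- pmin(y0 + 1, h)
  x0 <- pmin(pmax(floor(sx), 1), w); x1 <- pmin(x0 + 1, w)
  wy <- pmin(pmax(sy - y0, 0), 1); wx <- pmin(pmax(sx - x0, 0), 1)
  one <- function(m) {
    a <- m[y0, x0, drop = FALSE]; b <- m[y0, x1, drop = FALSE]
    c_ <- m[y1, x0, drop = FALSE]; d <- m[y1, x1, drop = FALSE]
    WY <- matrix(wy, out_h, out_w); WX <- matrix(wx, out_h, out_w, byrow = TRUE)
    (1 - WY) * ((1 - WX) * a + WX * b) + WY * ((1 - WX) * c_ + WX * d)
  }
  if (!rgb) return(one(x))
  out <- array(0, dim = c(out_h, out_w, dim(x)[3]))
  for (ch in seq_len(dim(x)[3])) out[, , ch] <- one(x[, , ch])
  out
}
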