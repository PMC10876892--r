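# Independent brute-force oracles for the zoning geometry, written as plain
# per-pixel loops with their own angle arithmetic (kept deliberately separate
# from the package's vectorized implementations).

oracle_clock_angle <- function(frame, x, y) {
  th <- frame$rotation * pi / 180
  vx <- x - frame$fovea[1]; vy <- y - frame$fovea[2]
  rx <- cos(th) * vx + sin(th) * vy
  ry <- -sin(th) * vx + cos(th) * vy
  # clockwise from 12 o'clock, via the trigonometric angle in a y-up frame
  ang <- atan2(-ry, rx) * 180 / pi       # counterclockwise from +x, y up
  (90 - ang) %% 360
}

oracle_zone <- function(theta) {
  if (theta >= 300 || theta < 60) "superior"
  else if (theta < 120) "right"
  else if (theta < 240) "inferior"
  else "left"
}

oracle_partition_counts <- function(mask, frame) {
  counts <- integer(48)
  for (yy in seq_len(nrow(mask))) {
    for (xx in seq_len(ncol(mask))) {
      if (mask[yy, xx] == 0) next
      if (xx == frame$fovea[1] && yy == frame$fovea[2]) next
      th <- oracle_clock_angle(frame, xx, yy)
      sec <- min(floor(th / 15), 23)
      d <- sqrt((xx - frame$fovea[1])^2 + (yy - frame$fovea[2])^2)
      ring <- if (d > frame$posterior_pole_radius) 1 else 0
      counts[ring * 24 + sec + 1] <- counts[ring * 24 + sec + 1] + 1L
    }
  }
  counts
}

oracle_zone_counts <- function(mask, frame) {
  counts <- c(superior = 0L, right = 0L, inferior = 0L, left = 0L)
  for (yy in seq_len(nrow(mask))) {
    for (xx in seq_len(ncol(mask))) {
      if (mask[yy, xx] == 0) next
      if (xx == frame$fovea[1] && yy == frame$fovea[2]) next
      z <- oracle_zone(oracle_clock_angle(frame, xx, yy))
      counts[z] <- counts[z] + 1L
    }
  }
  counts
}

oracle_posterior_count <- function(mask, frame) {
  n <- 0L
  for (yy in seq_len(nrow(mask))) {
    for (xx in seq_len(ncol(mask))) {
      if (mask[yy, xx] == 0) next
      d <- sqrt((xx - frame$fovea[1])^2 + (yy - frame$fovea[2])^2)
      if (d <= frame$posterior_pole_radius) n <- n + 1L
    }
  }
  n
}

# standard test frame on a square canvas: fovea at the center, disc on the
# image-right (OD), zero rotation
test_frame <- function(S = 128, disc_dx = 0.22 * S, disc_r = 0.04 * S) {
  ctr <- (S + 1) / 2
  fit_frame(c(ctr, ctr), list(center = c(ctr + disc_dx, ctr), radius = disc_r),
            "OD", canvas = c(S, S))
}

# random blob mask: k disc-shaped blobs of random radius
random_blob_mask <- function(S, k = 3, seed = 1) {
  set.seed(seed)
  m <- matrix(0L, S, S)
  xs <- matrix(rep(1:S, each = S), S, S)
  ys <- matrix(rep(1:S, times = S), S, S)
  for (i in seq_len(k)) {
    cx <- runif(1, 1, S); cy <- runif(1, 1, S); r <- runif(1, 3, S / 6)
    m[(xs - cx)^2 + (ys - cy)^2 <= r^2] <- 1L
  }
  m
}

# a point at clock angle theta (deg) and radius r from the fovea of a
# zero-rotation frame
point_at <- function(frame, theta, r) {
  th <- theta * pi / 180
  c(frame$fovea[1] + r * sin(th), frame$fovea[2] - r * cos(th))
}

# closed-form Wilson oracle written independently of the package version
oracle_wilson <- function(k, n, level = 0.95) {
  z <- qnorm(1 - (1 - level) / 2)
  phat <- k / n
  a <- (phat + z * z / (2 * n)) / (1 + z * z / n)
  b <- (z / (1 + z * z / n)) * sqrt(phat * (1 - phat) / n + z * z / (4 * n * n))
  c(a - b, a + b)
}

# contingency-table kappa oracle via explicit loops
oracle_kappa <- function(a, b) {
  lv <- sort(unique(c(a, b)))
  n <- length(a)
  tab <- matrix(0, length(lv), length(lv))
  for (i in seq_len(n)) {
    tab[match(a[i], lv), match(b[i], lv)] <- tab[match(a[i], lv), match(b[i], lv)] + 1
  }
  po <- sum(diag(tab)) / n
  pe <- 0
  for (i in seq_along(lv)) pe <- pe + sum(tab[i, ]) * sum(tab[, i]) / n^2
  (po - pe) / (1 - pe)
}

# independent bilinear resize oracle (explicit double loop, same half-pixel
# convention stated in the docs)
oracle_bilinear <- function(m, oh, ow) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0, oh, ow)
  for (i in seq_len(oh)) {
    for (j in seq_len(ow)) {
      sy <- (i - 0.5) * h / oh + 0.5
      sx <- (j - 0.5) * w / ow + 0.5
      y0 <- min(max(floor(sy), 1), h); y1 <- min(y0 + 1, h)
      x0 <- min(max(floor(sx), 1), w); x1 <- min(x0 + 1, w)
      wy <- min(max(sy - y0, 0), 1); wx <- min(max(sx - x0, 0), 1)
      out[i, j] <- (1 - wy) * ((1 - wx) * m[y0, x0] + wx * m[y0, x1]) +
        wy * ((1 - wx) * m[y1, x0] + wx * m[y1, x1])
    }
  }
  out
}

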