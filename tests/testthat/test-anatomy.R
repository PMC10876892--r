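test_that("fit_frame builds the calibrated frame", {
  fr <- fit_frame(c(256, 256), list(center = c(320, 256), radius = 20),
                  "OD", c(512, 512))
  expect_equal(fr$rotation, 0)
  expect_equal(fr$posterior_pole_radius, 84)  # |64| + 20

  # disc 45 degrees below-right: rotation +45, and a pixel at image-angle 45
  # from the fovea sits at calibrated 3 o'clock
  fr45 <- fit_frame(c(256, 256), list(center = c(320, 320), radius = 20),
                    "OD", c(512, 512))
  expect_equal(fr45$rotation, 45)
  expect_equal(clock_angle(fr45, 256 + 50, 256 + 50), 90)
  expect_equal(zone_of_point(fr45, 256 + 50, 256 + 50), "right")

  # OS mirrored disc position: rotation is normalized toward increasing x
  frod <- fit_frame(c(256, 256), list(center = c(320, 256), radius = 20),
                    "OD", c(512, 512))
  fros <- fit_frame(c(256, 256), list(center = c(192, 256), radius = 20),
                    "OS", c(512, 512))
  expect_equal(fros$rotation, frod$rotation)
  # mirrored pixel swaps left/right, preserves superior/inferior
  for (th in c(10, 80, 170, 250)) {
    p <- point_at(frod, th, 40)
    pm <- c(512 + 1 - p[1], p[2])
    z <- zone_of_point(frod, p[1], p[2])
    zm <- zone_of_point(fros, pm[1], pm[2])
    swap <- c(superior = "superior", inferior = "inferior",
              left = "right", right = "left")
    expect_equal(zm, unname(swap[z]))
  }

  expect_error(fit_frame(c(10, 10), list(center = c(10, 10), radius = 5),
                         "OD", c(64, 64)), "coincide")
})

test_that("zone_of_point follows the clock-hour designations", {
  fr <- test_frame(128)
  r <- 30
  expect_equal(zone_of_point(fr, point_at(fr, 0, r)[1], point_at(fr, 0, r)[2]),
               "superior")
  for (th in c(90, 180, 270)) {
    expect_equal(zone_of_angle(th),
                 c(`90` = "right", `180` = "inferior", `270` = "left")[[as.character(th)]])
    p <- point_at(fr, th, r)
    expect_equal(zone_of_point(fr, p[1], p[2]), zone_of_angle(th))
  }
  # half-open boundaries: exactly 2 o'clock (60 deg) belongs to "right"
  expect_equal(zone_of_angle(60), "right")
  expect_equal(zone_of_angle(120), "inferior")
  expect_equal(zone_of_angle(240), "left")
  expect_equal(zone_of_angle(300), "superior")
  expect_error(zone_of_point(fr, fr$fovea[1], fr$fovea[2]), "fovea")
})

test_that("posterior pole mask matches its radius", {
  fr <- test_frame(128)
  m <- posterior_pole_mask(fr)
  # the disc is fully inside by construction
  xs <- matrix(rep(1:128, each = 128), 128, 128)
  ys <- matrix(rep(1:128, times = 128), 128, 128)
  disc <- (xs - fr$disc_center[1])^2 + (ys - fr$disc_center[2])^2 <=
    fr$disc_radius^2
  expect_true(all(m[disc] == 1))
  # area close to pi r^2
  r <- fr$posterior_pole_radius
  expect_lt(abs(sum(m) - pi * r^2), 4 * r)
  # a pixel at distance > r is outside
  p <- point_at(fr, 90, r + 1.5)
  expect_equal(m[round(p[2]), round(p[1])], 0L)
})

test_that("partition_index follows ring * 24 + sector", {
  fr <- test_frame(128)
  rin <- fr$posterior_pole_radius * 0.5
  rout <- fr$posterior_pole_radius + 10
  p <- point_at(fr, 7, rin)
  expect_equal(partition_index(fr, p[1], p[2]), 0L)
  p <- point_at(fr, 350, rout)
  expect_equal(partition_index(fr, p[1], p[2]), 47L)
  # rotating a point clockwise by 15 deg increments the sector mod 24
  # (mid-sector angles, away from the floating-point boundary)
  for (th in seq(0, 345, by = 15) + 7) {
    i1 <- partition_index(fr, point_at(fr, th, rin)[1], point_at(fr, th, rin)[2])
    i2 <- partition_index(fr, point_at(fr, th + 15, rin)[1],
                          point_at(fr, th + 15, rin)[2])
    expect_equal(i2, (i1 + 1L) %% 24L)
  }
})

test_that("partition_vector applies the strict > min_pixels rule", {
  S <- 128
  fr <- test_frame(S)
  rule <- partition_rule(min_pixels = 50, resolution = S)  # threshold 50 as-is
  # pixels of partition 5 (outer loop over the grid, via the package index)
  xs <- matrix(rep(1:S, each = S), S, S)
  ys <- matrix(rep(1:S, times = S), S, S)
  pid <- matrix(partition_index(fr, as.numeric(xs), as.numeric(ys)), S, S)
  cand <- which(pid == 5L)
  expect_gt(length(cand), 51)
  m50 <- matrix(0L, S, S); m50[cand[1:50]] <- 1L
  m51 <- matrix(0L, S, S); m51[cand[1:51]] <- 1L
  expect_equal(sum(partition_vector(m50, fr, rule)), 0L)
  v51 <- partition_vector(m51, fr, rule)
  expect_equal(which(v51 == 1L), 6L)  # 1-based position of index 5
  # threshold scaling: same 51 pixels with the reference-512 rule (threshold
  # 50 * (128/512)^2 = 3.125) also fires
  expect_equal(which(partition_vector(m51, fr, partition_rule()) == 1L), 6L)
})

test_that("partition_vector, primary_zone, posterior_involved match the brute-force oracle", {
  S <- 128
  fr <- test_frame(S)
  rule <- partition_rule(min_pixels = 3, resolution = NA)
  for (seed in 1:20) {
    m <- random_blob_mask(S, k = 3, seed = seed)
    counts <- oracle_partition_counts(m, fr)
    bits <- partition_vector(m, fr, rule)
    expect_equal(attr(bits, "counts"), counts)
    expect_equal(as.integer(bits), as.integer(counts > 3))
    zc <- oracle_zone_counts(m, fr)
    pref <- c("superior", "inferior", "right", "left")
    expect_equal(primary_zone(m, fr), pref[which.max(zc[pref])])
    expect_equal(posterior_involved(m, fr, rule),
                 oracle_posterior_count(m, fr) > 3)
  }
})

test_that("partitions tile the canvas exhaustively and compose the zones", {
  S <- 128
  fr <- test_frame(S)
  xs <- as.numeric(matrix(rep(1:S, each = S), S, S))
  ys <- as.numeric(matrix(rep(1:S, times = S), S, S))
  keep <- !(xs == fr$fovea[1] & ys == fr$fovea[2])
  pid <- partition_index(fr, xs[keep], ys[keep])
  expect_true(all(pid >= 0 & pid <= 47))
  # inner ring = posterior pole circle
  d2 <- (xs[keep] - fr$fovea[1])^2 + (ys[keep] - fr$fovea[2])^2
  expect_equal(pid < 24, d2 <= fr$posterior_pole_radius^2)
  # zone = union of its sectors (superior: sectors 20..23 and 0..3, etc.)
  sec <- pid %% 24
  zone_from_sector <- ifelse(sec >= 20 | sec < 4, "superior",
                        ifelse(sec < 8, "right",
                          ifelse(sec < 16, "inferior", "left")))
  expect_equal(zone_from_sector, zone_of_point(fr, xs[keep], ys[keep]))
})

test_that("rotation by multiples of 15 degrees permutes sectors cyclically", {
  fr <- test_frame(128)
  set.seed(42)
  n <- 400
  th <- runif(n, 0, 360); rr <- runif(n, 2, 60)
  px <- fr$fovea[1] + rr * sin(th * pi / 180)
  py <- fr$fovea[2] - rr * cos(th * pi / 180)
  base <- partition_index(fr, px, py)
  for (k in c(1, 5, 23)) {
    phi <- (th + 15 * k) * pi / 180
    qx <- fr$fovea[1] + rr * sin(phi)
    qy <- fr$fovea[2] - rr * cos(phi)
    rot <- partition_index(fr, qx, qy)
    expect_equal(rot %/% 24, base %/% 24)                 # ring preserved
    expect_equal(rot %% 24, (base %% 24 + k) %% 24)       # cyclic shift
  }
})

test_that("horizontal mirror about the fovea swaps left/right zones", {
  S <- 128
  fr <- test_frame(S)
  for (seed in 1:5) {
    m <- random_blob_mask(S, k = 2, seed = seed)
    mm <- m[, S:1]
    zc <- oracle_zone_counts(m, fr)
    zcm <- oracle_zone_counts(mm, fr)
    expect_equal(unname(zcm["left"]), unname(zc["right"]))
    expect_equal(unname(zcm["right"]), unname(zc["left"]))
    expect_equal(unname(zcm["superior"]), unname(zc["superior"]))
    expect_equal(unname(zcm["inferior"]), unname(zc["inferior"]))
  }
})

test_that("primary_zone handles ties, rotation and empty masks", {
  S <- 128
  fr <- test_frame(S)
  rule <- partition_rule(3, NA)
  # 100 px superior vs 40 px right
  m <- matrix(0L, S, S)
  sup <- point_at(fr, 0, 30); rgt <- point_at(fr, 90, 30)
  xs <- matrix(rep(1:S, each = S), S, S); ys <- matrix(rep(1:S, times = S), S, S)
  sup_px <- which((xs - sup[1])^2 + (ys - sup[2])^2 <= 49)
  rgt_px <- which((xs - rgt[1])^2 + (ys - rgt[2])^2 <= 49)
  m[sup_px[1:100]] <- 1L; m[rgt_px[1:40]] <- 1L
  expect_equal(primary_zone(m, fr), "superior")
  # superior/inferior tie resolves to superior
  m2 <- matrix(0L, S, S)
  inf <- point_at(fr, 180, 30)
  inf_px <- which((xs - inf[1])^2 + (ys - inf[2])^2 <= 49)
  m2[sup_px[1:60]] <- 1L; m2[inf_px[1:60]] <- 1L
  expect_equal(primary_zone(m2, fr), "superior")
  # rotated copies rotate the primary zone
  for (k in 0:3) {
    mk <- matrix(0L, S, S)
    ctr <- point_at(fr, 90 * k, 30)
    mk[(xs - ctr[1])^2 + (ys - ctr[2])^2 <= 64] <- 1L
    expect_equal(primary_zone(mk, fr), rd_zones()[k + 1])
  }
  expect_equal(primary_zone(matrix(0L, S, S), fr), NA_character_)
})
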