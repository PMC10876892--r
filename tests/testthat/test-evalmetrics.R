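test_that("precision/recall/F1 match hand computations and printed pairs", {
  r <- precision_recall_f1(binary_counts(tp = 3, fp = 1, fn = 2, tn = 10))
  expect_equal(r$precision$value, 0.75)
  expect_equal(r$recall$value, 0.6)
  expect_equal(r$f1$value, 2 * 0.75 * 0.6 / 1.35)

  # perfect detector
  rp <- precision_recall_f1(binary_counts(5, 0, 0, 7))
  expect_equal(rp$precision$value, 1)
  expect_equal(rp$recall$value, 1)
  expect_equal(rp$f1$value, 1)

  # the published weakly-supervised operating point: F1 from its 4-dp
  # rounded precision/recall pair
  f1 <- 2 * 0.8642 * 0.8327 / (0.8642 + 0.8327)
  expect_lt(abs(f1 - 0.8481), 0.001)

  expect_error(precision_recall_f1(binary_counts(0, 0, 3, 5)), "denominator")
  # CI ordering
  expect_lte(r$precision$ci_low, r$precision$value)
  expect_gte(r$precision$ci_high, r$precision$value)
  expect_lte(r$f1$ci_low, r$f1$value)
})

test_that("wilson_ci matches the closed form and its edge cases", {
  expect_equal(wilson_ci(100, 100)[2], 1.0)
  expect_equal(wilson_ci(0, 100)[1], 0.0)
  for (kn in list(c(83, 100), c(1, 7), c(250, 1000))) {
    expect_equal(wilson_ci(kn[1], kn[2]), oracle_wilson(kn[1], kn[2]),
                 tolerance = 1e-10)
  }
  expect_error(wilson_ci(1, 0), "trials")
})

test_that("sens/spec/acc match hand computation and swap symmetrically", {
  r <- sens_spec_acc(binary_counts(tp = 80, fp = 10, fn = 20, tn = 90))
  expect_equal(r$sensitivity$value, 0.8)
  expect_equal(r$specificity$value, 0.9)
  expect_equal(r$accuracy$value, 0.85)
  # swapping the positive-class convention swaps sensitivity and specificity
  rs <- sens_spec_acc(binary_counts(tp = 90, fp = 20, fn = 10, tn = 80))
  expect_equal(rs$sensitivity$value, r$specificity$value)
  expect_equal(rs$specificity$value, r$sensitivity$value)
  expect_equal(rs$accuracy$value, r$accuracy$value)
  rp <- sens_spec_acc(binary_counts(5, 0, 0, 5))
  expect_equal(rp$sensitivity$value, 1)
  expect_equal(rp$specificity$value, 1)
  expect_equal(rp$accuracy$value, 1)
  expect_error(sens_spec_acc(binary_counts(0, 0, 0, 9)), "absent")
})

test_that("cohen_kappa agrees with the contingency oracle", {
  z <- rd_zones()
  expect_equal(cohen_kappa(z, z)$value, 1)
  # the classic 2x2 at chance: {(S,S),(S,I),(I,S),(I,I)}
  expect_equal(cohen_kappa(c("S", "S", "I", "I"), c("S", "I", "S", "I"))$value,
               0)
  set.seed(33)
  for (rep in 1:20) {
    a <- sample(z, 50, replace = TRUE)
    b <- sample(z, 50, replace = TRUE)
    if (sum(a == b) == 50) next
    expect_equal(cohen_kappa(a, b)$value, oracle_kappa(a, b),
                 tolerance = 1e-12)
    # relabeling invariance
    perm <- setNames(sample(z), z)
    expect_equal(cohen_kappa(unname(perm[a]), unname(perm[b]))$value,
                 cohen_kappa(a, b)$value, tolerance = 1e-12)
  }
  expect_error(cohen_kappa(z, z[1:3]), "length")
  expect_error(cohen_kappa(c("S", "S"), c("S", "S")), "degenerate")
})

test_that("confusion4 tallies truth rows and prediction columns", {
  z <- rd_zones()
  r <- confusion4(z, z)
  expect_equal(diag(r$matrix), setNames(rep(1L, 4), z))
  expect_equal(r$accuracy$value, 1)
  truth <- rep(z, c(3, 3, 2, 2))
  pred <- truth; pred[1] <- "inferior"
  r2 <- confusion4(truth, pred)
  expect_equal(r2$accuracy$value, 0.9)
  expect_equal(unname(rowSums(r2$matrix)), c(3L, 3L, 2L, 2L))
  expect_equal(unname(colSums(r2$matrix)),
               vapply(z, function(v) sum(pred == v), integer(1), USE.NAMES = FALSE))
  expect_error(confusion4(c("superior", "nasal"), c("superior", "left")),
               "unknown")
})

test_that("iou covers identity, disjointness and the half-field case", {
  a <- matrix(0L, 10, 10); a[3:6, 3:6] <- 1L
  expect_equal(iou(a, a), 1)
  b <- matrix(0L, 10, 10); b[8:9, 8:9] <- 1L
  expect_equal(iou(a, b), 0)
  left <- matrix(0L, 10, 10); left[, 1:5] <- 1L
  full <- matrix(1L, 10, 10)
  expect_equal(iou(left, full), 0.5)
  expect_equal(iou(matrix(0L, 4, 4), matrix(0L, 4, 4)), 1)  # both empty
  expect_error(iou(a, matrix(0L, 4, 4)), "shapes")
})

test_that("average precision follows the step rule", {
  # perfect ordering
  expect_equal(ap_from_pr(c(1, 1, 1), c(0.2, 0.6, 1)), 1)
  # the three-threshold toy: 0.5*1.0 + 0.25*0.8 + 0.25*0.6
  expect_equal(ap_from_pr(c(1.0, 0.8, 0.6), c(0.5, 0.75, 1.0)), 0.85)
})

test_that("pr_curve_ap is stable under grid refinement and monotone maps", {
  set.seed(44)
  fr <- test_frame(128)
  rule <- partition_rule(3, NA)
  maps <- list(); truths <- list(); frames <- list()
  for (i in 1:4) {
    truth_mask <- random_blob_mask(128, k = 2, seed = 100 + i)
    # a plausible probability map: smoothed truth plus noise
    base <- truth_mask * runif(1, 0.6, 0.9)
    noise <- matrix(runif(128 * 128, 0, 0.45), 128, 128)
    maps[[i]] <- pmin(pmax(base + noise * (1 - truth_mask), 0), 1)
    truths[[i]] <- as.integer(partition_vector(truth_mask, fr, rule))
    frames[[i]] <- fr
  }
  pr1 <- pr_curve_ap(maps, frames, truths, rule,
                     thresholds = seq(0, 1, length.out = 101))
  pr2 <- pr_curve_ap(maps, frames, truths, rule,
                     thresholds = seq(0, 1, length.out = 1001))
  expect_lt(abs(attr(pr1, "ap") - attr(pr2, "ap")), 0.01)
  # AP is invariant under strictly monotone transforms of the maps
  maps_sq <- lapply(maps, function(m) m^2)
  pr3 <- pr_curve_ap(maps_sq, frames, truths, rule,
                     thresholds = sort(unique(c(seq(0, 1, length.out = 101)^2,
                                                1))))
  expect_lt(abs(attr(pr3, "ap") - attr(pr1, "ap")), 0.02)
  expect_error(pr_curve_ap(maps, frames,
                           lapply(truths, function(x) x * 0L), rule),
               "no positive")
})

test_that("evaluate_localization pools decisions exactly", {
  # constructed fixture: 2 images x 48 partitions with known flips
  t1 <- integer(48); t1[1:30] <- 1L
  t2 <- integer(48); t2[1:20] <- 1L     # 50 true positives overall
  p1 <- t1; p1[29:30] <- 0L             # 2 false negatives
  p2 <- t2; p2[17:20] <- 0L; p2[21:24] <- 1L  # 4 FN + 4 FP
  preds <- list(a = list(partitions = p1, posterior = TRUE,
                         primary_zone = "superior"),
                b = list(partitions = p2, posterior = FALSE,
                         primary_zone = "left"))
  truths <- list(a = list(partitions = t1, posterior = TRUE,
                          primary_zone = "superior"),
                 b = list(partitions = t2, posterior = TRUE,
                          primary_zone = "inferior"))
  rep <- evaluate_localization(preds, truths)
  cnt <- rep$partition$counts
  expect_equal(cnt$tp, 44); expect_equal(cnt$fp, 4); expect_equal(cnt$fn, 6)
  expect_equal(cnt$tn, 96 - 44 - 4 - 6)
  expect_equal(rep$partition$precision$value, 44 / 48)
  expect_equal(rep$partition$recall$value, 44 / 50)
  # pooling consistency: counts equal the sum of per-image counts
  per_img_tp <- sum(p1 == 1 & t1 == 1) + sum(p2 == 1 & t2 == 1)
  expect_equal(cnt$tp, per_img_tp)
  expect_equal(rep$n_partition_decisions, 96)

  # identical predictions give all-ones metrics and kappa 1
  same <- evaluate_localization(truths, truths)
  expect_equal(same$partition$precision$value, 1)
  expect_equal(same$partition$recall$value, 1)
  expect_equal(same$partition$f1$value, 1)
  expect_error(evaluate_localization(preds, truths[1]), "identifiers")
})

test_that("eval reports serialize to JSON", {
  t1 <- integer(48); t1[5:10] <- 1L
  truths <- list(a = list(partitions = t1, posterior = TRUE,
                          primary_zone = "superior"),
                 b = list(partitions = integer(48), posterior = FALSE,
                          primary_zone = "inferior"))
  rep <- evaluate_localization(truths, truths)
  path <- withr::local_tempfile(fileext = ".json")
  write_eval_report(rep, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$partition$precision$value, 1)
  expect_equal(back$n_images, 2)
})
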