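# Evaluation statistics: pooled partition-level precision/recall/F1 with
# Wilson 95% CIs, posterior-pole sensitivity/specificity/accuracy,
# precision-recall curve with step-rule average precision, unweighted
# Cohen's kappa with asymptotic CI, the 4x4 zone confusion matrix, and mask
# intersection-over-union.

#' Binary decision counts
#'
#' @param tp,fp,fn,tn Non-negative counts.
#' @return An object of class `rd_binary_counts`.
#' @export
binary_counts <- function(tp, fp, fn, tn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0, tn >= 0)
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn),
            class = "rd_binary_counts")
}

metric_with_ci <- function(value, lo, hi) {
  structure(list(value = value, ci_low = lo, ci_high = hi),
            class = "rd_metric")
}

#' @export
print.rd_metric <- function(x, ...) {
  cat(sprintf("%.4f (95%%CI: %.4f-%.4f)\n", x$value, x$ci_low, x$ci_high))
  invisible(x)
}

#' Wilson score interval for a binomial proportion
#'
#' @param successes Number of successes `k` (0 <= k <= n).
#' @param trials Number of trials `n` (> 0).
#' @param level Confidence level, default 0.95.
#' @return `c(low, high)`, contained in `[0, 1]`.
#' @export
wilson_ci <- function(successes, trials, level = 0.95) {
  if (trials <= 0) stop("wilson_ci needs trials > 0")
  stopifnot(successes >= 0, successes <= trials)
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- successes / trials
  den <- 1 + z^2 / trials
  ctr <- (p + z^2 / (2 * trials)) / den
  hw <- z * sqrt(p * (1 - p) / trials + z^2 / (4 * trials^2)) / den
  c(max(0, ctr - hw), min(1, ctr + hw))
}

f1_of <- function(p, r) if (p + r == 0) 0 else 2 * p * r / (p + r)

#' Precision, recall and F1 with 95% CIs
#'
#' `precision = tp/(tp+fp)`, `recall = tp/(tp+fn)`,
#' `F1 = 2*Precision*Recall/(Precision+Recall)`. CIs: Wilson score on the
#' two proportions; the F1 interval propagates the Wilson bounds through the
#' harmonic mean (a documented approximation).
#'
#' @param counts An `rd_binary_counts` with `tp+fp > 0` and `tp+fn > 0`.
#' @return List with `precision`, `recall`, `f1` (`rd_metric` each) and the
#'   input `counts`.
#' @export
precision_recall_f1 <- function(counts) {
  with(counts, {
    if (tp + fp == 0 || tp + fn == 0) {
      stop("precision/recall undefined: zero denominator")
    }
    p <- tp / (tp + fp); r <- tp / (tp + fn)
    pci <- wilson_ci(tp, tp + fp); rci <- wilson_ci(tp, tp + fn)
    list(precision = metric_with_ci(p, pci[1], pci[2]),
         recall = metric_with_ci(r, rci[1], rci[2]),
         f1 = metric_with_ci(f1_of(p, r), f1_of(pci[1], rci[1]),
                             f1_of(pci[2], rci[2])),
         counts = counts)
  })
}

#' Sensitivity, specificity and accuracy with 95% CIs
#'
#' @param counts An `rd_binary_counts` with both classes present.
#' @return List with `sensitivity`, `specificity`, `accuracy` (`rd_metric`).
#' @export
sens_spec_acc <- function(counts) {
  with(counts, {
    if (tp + fn == 0 || tn + fp == 0) {
      stop("sensitivity/specificity undefined: a class is absent")
    }
    sens <- tp / (tp + fn); spec <- tn / (tn + fp)
    total <- tp + fp + fn + tn
    acc <- (tp + tn) / total
    sci <- wilson_ci(tp, tp + fn); pci <- wilson_ci(tn, tn + fp)
    aci <- wilson_ci(tp + tn, total)
    list(sensitivity = metric_with_ci(sens, sci[1], sci[2]),
         specificity = metric_with_ci(spec, pci[1], pci[2]),
         accuracy = metric_with_ci(acc, aci[1], aci[2]),
         counts = counts)
  })
}

#' Unweighted Cohen's kappa with 95% CI
#'
#' `kappa = (p_o - p_e) / (1 - p_e)` with chance agreement from the marginal
#' products; CI by the standard asymptotic variance
#' `p_o (1 - p_o) / (n (1 - p_e)^2)`.
#'
#' @param labels_a,labels_b Equal-length label sequences (length >= 2).
#' @param level Confidence level, default 0.95.
#' @return An `rd_metric`.
#' @export
cohen_kappa <- function(labels_a, labels_b, level = 0.95) {
  if (length(labels_a) != length(labels_b)) stop("label sequences differ in length")
  n <- length(labels_a)
  stopifnot(n >= 2)
  lev <- sort(unique(c(labels_a, labels_b)))
  ta <- factor(labels_a, levels = lev); tb <- factor(labels_b, levels = lev)
  tab <- table(ta, tb)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (1 - pe < .Machine$double.eps) {
    stop("degenerate marginals: chance agreement is 1, kappa undefined")
  }
  k <- (po - pe) / (1 - pe)
  z <- stats::qnorm(1 - (1 - level) / 2)
  se <- sqrt(po * (1 - po) / (n * (1 - pe)^2))
  metric_with_ci(k, k - z * se, k + z * se)
}

#' Four-zone confusion matrix and accuracy
#'
#' Rows are truth, columns prediction, fixed zone order superior, right,
#' inferior, left.
#'
#' @param truth,pred Equal-length zone label vectors.
#' @return List with `matrix` (4x4) and `accuracy` (`rd_metric`).
#' @export
confusion4 <- function(truth, pred) {
  if (length(truth) != length(pred)) stop("length mismatch")
  zl <- rd_zones()
  if (!all(c(truth, pred) %in% zl)) stop("unknown zone label")
  m <- table(factor(truth, levels = zl), factor(pred, levels = zl))
  m <- matrix(as.integer(m), 4, 4, dimnames = list(truth = zl, pred = zl))
  n <- length(truth)
  ci <- wilson_ci(sum(diag(m)), n)
  list(matrix = m, accuracy = metric_with_ci(sum(diag(m)) / n, ci[1], ci[2]))
}

#' Intersection-over-union of two binary masks
#'
#' Defined as 1 when both masks are empty.
#'
#' @param mask_a,mask_b Binary matrices of equal shape.
#' @return Scalar in `[0, 1]`.
#' @export
iou <- function(mask_a, mask_b) {
  if (!all(dim(mask_a) == dim(mask_b))) stop("mask shapes differ")
  a <- mask_a != 0; b <- mask_b != 0
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}

#' Average precision from precision-recall points (step rule)
#'
#' Points are sorted by recall; the precision envelope (maximum precision at
#' recall >= r) is integrated stepwise from recall 0.
#'
#' @param precision,recall Equal-length numeric vectors.
#' @return Scalar AP.
#' @export
ap_from_pr <- function(precision, recall) {
  stopifnot(length(precision) == length(recall))
  o <- order(recall, -precision)
  r <- recall[o]; p <- precision[o]
  # precision envelope from the right
  penv <- rev(cummax(rev(p)))
  keep <- !duplicated(r, fromLast = TRUE)
  r <- r[keep]; penv <- penv[keep]
  sum(diff(c(0, r)) * penv)
}

#' Precision-recall curve and average precision over partition decisions
#'
#' For each threshold the pseudo-masks and 48-partition vectors are
#' recomputed from the probability maps and the decisions pooled over all
#' images (micro-averaging).
#'
#' @param maps List of canvas-sized probability maps.
#' @param frames List of `rd_frame` objects (one per image).
#' @param truth_bits List of 48-length truth vectors.
#' @param rule An `rd_partition_rule`.
#' @param thresholds Threshold grid, default 101 points over `[0, 1]`.
#' @return data.frame (threshold, precision, recall) with attribute `ap`.
#' @export
pr_curve_ap <- function(maps, frames, truth_bits, rule = partition_rule(),
                        thresholds = seq(0, 1, length.out = 101)) {
  stopifnot(length(maps) == length(frames), length(maps) == length(truth_bits))
  truth <- unlist(truth_bits)
  if (sum(truth) == 0) stop("no positive partitions in the truth")
  res <- lapply(thresholds, function(tau) {
    pred <- unlist(lapply(seq_along(maps), function(i) {
      partition_vector(pseudo_mask(maps[[i]], tau), frames[[i]], rule)
    }))
    tp <- sum(pred == 1 & truth == 1)
    fp <- sum(pred == 1 & truth == 0)
    fn <- sum(pred == 0 & truth == 1)
    c(precision = if (tp + fp == 0) 1 else tp / (tp + fp),
      recall = tp / (tp + fn))
  })
  df <- data.frame(threshold = thresholds,
                   precision = vapply(res, `[[`, numeric(1), "precision"),
                   recall = vapply(res, `[[`, numeric(1), "recall"))
  attr(df, "ap") <- ap_from_pr(df$precision, df$recall)
  df
}

#' Pool localization outputs into a full evaluation report
#'
#' Pools the 48 decisions per image for the partition metrics, per-image
#' posterior-pole flags for sensitivity/specificity/accuracy, and per-image
#' primary zones for kappa and the confusion matrix. Images where either the
#' truth or the prediction has no primary zone (empty mask) are excluded
#' from the zone agreement (and counted in `n_zone_dropped`).
#'
#' @param predictions Named list per image: `partitions` (48 bits),
#'   `posterior` (flag), `primary_zone` (zone label or NA).
#' @param truths Same structure (an `rd_sample` also works: its
#'   `truth_partitions`, `truth_posterior`, `truth_primary_zone` are used).
#' @param rule The `rd_partition_rule` used to produce the inputs (recorded).
#' @return An object of class `rd_eval_report`.
#' @export
evaluate_localization <- function(predictions, truths,
                                  rule = partition_rule()) {
  if (!identical(names(predictions), names(truths))) {
    stop("prediction and truth image identifiers do not match")
  }
  get_truth <- function(t) {
    if (inherits(t, "rd_sample")) {
      list(partitions = t$truth_partitions, posterior = t$truth_posterior,
           primary_zone = t$truth_primary_zone)
    } else t
  }
  truths <- lapply(truths, get_truth)
  pb <- unlist(lapply(predictions, `[[`, "partitions"))
  tb <- unlist(lapply(truths, `[[`, "partitions"))
  counts <- binary_counts(sum(pb == 1 & tb == 1), sum(pb == 1 & tb == 0),
                          sum(pb == 0 & tb == 1), sum(pb == 0 & tb == 0))
  part <- precision_recall_f1(counts)

  pf <- vapply(predictions, function(p) isTRUE(p$posterior), logical(1))
  tf <- vapply(truths, function(t) isTRUE(t$posterior), logical(1))
  post <- NULL
  if (any(tf) && any(!tf)) {
    post <- sens_spec_acc(binary_counts(sum(pf & tf), sum(pf & !tf),
                                        sum(!pf & tf), sum(!pf & !tf)))
  }

  pz <- vapply(predictions, function(p) p$primary_zone %||% NA_character_,
               character(1))
  tz <- vapply(truths, function(t) t$primary_zone %||% NA_character_,
               character(1))
  ok <- !is.na(pz) & !is.na(tz)
  zone <- NULL; kappa <- NULL
  if (sum(ok) >= 2) {
    zone <- confusion4(tz[ok], pz[ok])
    kappa <- cohen_kappa(tz[ok], pz[ok])
  }
  structure(list(
    partition = part, posterior = post, zone = zone, kappa = kappa,
    n_images = length(predictions), n_partition_decisions = length(pb),
    n_zone_dropped = sum(!ok), rule = rule
  ), class = "rd_eval_report")
}

#' @export
print.rd_eval_report <- function(x, ...) {
  cat(sprintf("rd_eval_report: %d images, %d partition decisions\n",
              x$n_images, x$n_partition_decisions))
  cat("  partition precision: "); print(x$partition$precision)
  cat("  partition recall:    "); print(x$partition$recall)
  cat("  partition F1:        "); print(x$partition$f1)
  if (!is.null(x$posterior)) {
    cat("  posterior sens:      "); print(x$posterior$sensitivity)
    cat("  posterior spec:      "); print(x$posterior$specificity)
    cat("  posterior acc:       "); print(x$posterior$accuracy)
  }
  if (!is.null(x$kappa)) { cat("  four-zone kappa:     "); print(x$kappa) }
  if (!is.null(x$zone)) { cat("  four-zone accuracy:  "); print(x$zone$accuracy) }
  invisible(x)
}

#' Serialize an evaluation report to JSON
#'
#' @param report An `rd_eval_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path) {
  as_m <- function(m) if (is.null(m)) NULL else
    list(value = m$value, ci_low = m$ci_low, ci_high = m$ci_high)
  out <- list(
    n_images = report$n_images,
    n_partition_decisions = report$n_partition_decisions,
    partition = list(precision = as_m(report$partition$precision),
                     recall = as_m(report$partition$recall),
                     f1 = as_m(report$partition$f1)),
    posterior = if (is.null(report$posterior)) NULL else
      list(sensitivity = as_m(report$posterior$sensitivity),
           specificity = as_m(report$posterior$specificity),
           accuracy = as_m(report$posterior$accuracy)),
    kappa = as_m(report$kappa),
    zone_accuracy = if (is.null(report$zone)) NULL else as_m(report$zone$accuracy),
    confusion = if (is.null(report$zone)) NULL else report$zone$matrix
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
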