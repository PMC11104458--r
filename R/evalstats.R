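#' Area under the ROC curve
#'
#' The Mann-Whitney pair-counting statistic: the probability that a
#' random positive scores above a random negative, with ties counted
#' one half (computed via average ranks).
#'
#' @param scores Numeric scores, higher = more positive.
#' @param labels 0/1 (or logical) class labels.
#' @return AUC in \[0, 1\].
#' @examples
#' roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  if (length(scores) != length(labels)) stop("scores and labels differ in length")
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("degenerate data: both classes must be present")
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n0 * n1)
}

#' Confusion counts at a threshold
#'
#' @param scores Numeric scores.
#' @param labels 0/1 labels.
#' @param threshold Scores `>= threshold` are predicted positive.
#' @return List with integer fields `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_counts <- function(scores, labels, threshold = 0.5) {
  labels <- as.integer(as.logical(labels))
  pred <- as.integer(scores >= threshold)
  list(tp = sum(pred == 1L & labels == 1L),
       fp = sum(pred == 1L & labels == 0L),
       fn = sum(pred == 0L & labels == 1L),
       tn = sum(pred == 0L & labels == 0L))
}

#' Precision, recall and F1 at a threshold
#'
#' Precision is reported as 0 (with a warning) when there are no
#' predicted positives.
#'
#' @inheritParams confusion_counts
#' @return List with `precision`, `recall`, `f1` and the `counts`.
#' @export
pr_f1 <- function(scores, labels, threshold = 0.5) {
  if (threshold < 0 || threshold > 1) stop("threshold must lie in [0, 1]")
  cc <- confusion_counts(scores, labels, threshold)
  prf <- prf_from_counts(cc$tp, cc$fp, cc$fn)
  c(prf, list(counts = cc))
}

prf_from_counts <- function(tp, fp, fn) {
  if (tp + fp == 0L) {
    warning("no predicted positives; precision reported as 0")
    precision <- 0
  } else precision <- tp / (tp + fp)
  recall <- if (tp + fn == 0L) 0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  list(precision = precision, recall = recall, f1 = f1)
}

#' Micro-averaged precision/recall/F1
#'
#' Pools TP/FP/FN across labels before computing the metrics (never the
#' mean of per-label F1 scores).
#'
#' @param counts A list of per-label confusion counts (each as returned
#'   by [confusion_counts()]).
#' @return List with `precision`, `recall`, `f1`.
#' @examples
#' micro_f1(list(list(tp = 1, fp = 1, fn = 0, tn = 0),
#'               list(tp = 1, fp = 0, fn = 1, tn = 0)))
#' @export
micro_f1 <- function(counts) {
  tp <- sum(vapply(counts, `[[`, 0, "tp"))
  fp <- sum(vapply(counts, `[[`, 0, "fp"))
  fn <- sum(vapply(counts, `[[`, 0, "fn"))
  prf_from_counts(tp, fp, fn)
}

#' G-mean optimal operating point
#'
#' Scans every candidate threshold (the unique scores) and returns the
#' one maximizing the geometric mean of sensitivity and specificity;
#' ties break to the lowest threshold.
#'
#' @param scores Numeric scores.
#' @param labels 0/1 labels.
#' @return List with `threshold`, `sensitivity`, `specificity`, `gmean`.
#' @export
gmean_cutoff <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("degenerate data: both classes must be present")
  cand <- sort(unique(scores))
  best <- NULL
  for (thr in cand) {
    sens <- sum(scores >= thr & labels == 1L) / n1
    spec <- sum(scores < thr & labels == 0L) / n0
    gm <- sqrt(sens * spec)
    if (is.null(best) || gm > best$gmean + 1e-15)
      best <- list(threshold = thr, sensitivity = sens,
                   specificity = spec, gmean = gm)
  }
  best
}

#' Diagnostic odds ratio with Wald confidence interval
#'
#' DOR = (TP * TN) / (FP * FN). When any cell is zero the
#' Haldane-Anscombe correction adds 0.5 to all four cells. The CI is
#' log-normal Wald.
#'
#' @param counts Confusion counts ([confusion_counts()] output or a
#'   list with tp/fp/fn/tn).
#' @param level Confidence level.
#' @return List with `dor`, `lower`, `upper`, `corrected`.
#' @examples
#' diagnostic_odds_ratio(list(tp = 9, fp = 1, fn = 1, tn = 9))$dor
#' @export
diagnostic_odds_ratio <- function(counts, level = 0.95) {
  a <- counts$tp; b <- counts$fp; c <- counts$fn; d <- counts$tn
  if (a + b + c + d == 0) stop("empty confusion table")
  corrected <- any(c(a, b, c, d) == 0)
  if (corrected) { a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5 }
  dor <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  z <- stats::qnorm(1 - (1 - level) / 2)
  list(dor = dor, lower = exp(log(dor) - z * se),
       upper = exp(log(dor) + z * se), corrected = corrected)
}

#' Percentile bootstrap confidence interval for any record-level metric
#'
#' Resamples records (rows) with replacement `B` times, recomputes the
#' metric on each resample, and reports the percentile interval around
#' the full-sample point estimate.
#'
#' @param metric_fn Function `(data) -> scalar`, where `data` is a
#'   data frame of records.
#' @param data Data frame; rows are resampled.
#' @param B Bootstrap replicates (>= 100).
#' @param level Confidence level.
#' @param seed Seed for reproducibility.
#' @return Object of class `metric_ci`: `point`, `lower`, `upper`,
#'   `B`, `level`, `replicates`.
#' @export
bootstrap_ci <- function(metric_fn, data, B = 1000, level = 0.95, seed = 1L) {
  if (B < 100) stop("B must be >= 100")
  data <- as.data.frame(data)
  point <- metric_fn(data)
  reps <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      metric_fn(data[sample.int(nrow(data), replace = TRUE), , drop = FALSE])
    }, 0)
  })
  qs <- stats::quantile(reps, c((1 - level) / 2, 1 - (1 - level) / 2),
                        na.rm = TRUE, names = FALSE)
  structure(list(point = point, lower = qs[1], upper = qs[2],
                 B = B, level = level, replicates = reps),
            class = "metric_ci")
}

#' @export
print.metric_ci <- function(x, ...) {
  cat(sprintf("%.4f [%.0f%% CI, %.4f-%.4f] (B = %d)\n",
              x$point, 100 * x$level, x$lower, x$upper, x$B))
  invisible(x)
}

#' Paired bootstrap p-value for a metric difference
#'
#' Both models are scored on identical records; records are resampled
#' jointly. The two-sided p-value is twice the fraction of resamples in
#' which the metric difference changes sign relative to the observed
#' difference, capped at 1.
#'
#' @param metric_fn Function `(scores, labels) -> scalar`.
#' @param scores_a,scores_b Score vectors from the two models.
#' @param labels Shared 0/1 labels.
#' @param B Bootstrap replicates (>= 100).
#' @param seed Seed.
#' @return Two-sided p-value.
#' @export
paired_bootstrap_pvalue <- function(metric_fn, scores_a, scores_b, labels,
                                    B = 1000, seed = 1L) {
  if (B < 100) stop("B must be >= 100")
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(labels))
    stop("both models must be scored on identical records")
  d0 <- metric_fn(scores_a, labels) - metric_fn(scores_b, labels)
  if (d0 == 0) return(1)
  flips <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      idx <- sample.int(length(labels), replace = TRUE)
      db <- tryCatch(
        metric_fn(scores_a[idx], labels[idx]) -
          metric_fn(scores_b[idx], labels[idx]),
        error = function(e) NA_real_)
      as.numeric(!is.na(db) && db * sign(d0) <= 0)
    }, 0)
  })
  min(1, 2 * mean(flips))
}

#' Metric with bootstrap CI per population subgroup
#'
#' Default age stratification uses half-open bins \[0, 45), \[45, 75),
#' \[75, Inf) (young/middle/old); `"sex"` stratifies on the `is_male`
#' metadata column; any other vector/factor is used as-is. Groups where
#' the metric is undefined (e.g. single-class) are reported as `NA`
#' rather than erroring.
#'
#' @param scores,labels Scores and 0/1 labels.
#' @param metadata Data frame with one row per record (needs `age` or
#'   `is_male` for the built-in groupings).
#' @param grouping `"age"`, `"sex"`, or a vector/factor of group ids.
#' @param metric_fn Function `(scores, labels) -> scalar`, default AUC.
#' @param B,level,seed Bootstrap settings.
#' @return Data frame: group, n, point, lower, upper.
#' @export
subgroup_metrics <- function(scores, labels, metadata, grouping = "age",
                             metric_fn = roc_auc, B = 1000, level = 0.95,
                             seed = 1L) {
  n <- length(scores)
  g <- if (is.character(grouping) && length(grouping) == 1L) {
    if (grouping == "age") {
      cut(metadata$age, c(0, 45, 75, Inf), right = FALSE,
          labels = c("young (<45)", "middle (45-74)", "old (>=75)"))
    } else if (grouping == "sex") {
      factor(ifelse(metadata$is_male == 1, "male", "female"))
    } else stop("unknown grouping: ", grouping)
  } else factor(grouping)
  if (length(g) != n) stop("grouping must cover all records")
  out <- lapply(levels(g), function(lv) {
    idx <- which(g == lv)
    row <- data.frame(group = lv, n = length(idx), point = NA_real_,
                      lower = NA_real_, upper = NA_real_)
    if (length(idx) == 0L) return(row)
    ci <- tryCatch({
      d <- data.frame(s = scores[idx], y = labels[idx])
      bootstrap_ci(function(dd) tryCatch(metric_fn(dd$s, dd$y),
                                         error = function(e) NA_real_),
                   d, B = B, level = level, seed = seed)
    }, error = function(e) NULL)
    if (!is.null(ci) && is.finite(ci$point)) {
      row$point <- ci$point; row$lower <- ci$lower; row$upper <- ci$upper
    }
    row
  })
  do.call(rbind, out)
}
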