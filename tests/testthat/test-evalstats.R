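# independent AUC oracles: exhaustive pair counting and trapezoidal
# integration of the empirical ROC curve
auc_pairs <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}
auc_trapezoid <- function(scores, labels) {
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  tpr <- vapply(thr, function(t) mean(scores[labels == 1] >= t), 0)
  fpr <- vapply(thr, function(t) mean(scores[labels == 0] >= t), 0)
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

test_that("AUC equals the pair-counting and trapezoid estimators", {
  expect_identical(roc_auc(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1)), 1)
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  set.seed(1)
  for (k in 1:20) {
    n <- sample(10:60, 1)
    s <- round(runif(n), 2)          # rounding forces ties
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) next
    a <- roc_auc(s, y)
    expect_equal(a, auc_pairs(s, y), tolerance = 1e-12)
    expect_equal(a, auc_trapezoid(s, y), tolerance = 1e-12)
    expect_equal(roc_auc(s, 1 - y), 1 - a, tolerance = 1e-12)
  }
  expect_error(roc_auc(1:3, c(1, 1, 1)), "degenerate")
})

test_that("AUC agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(2)
  s <- runif(80); y <- rbinom(80, 1, 0.5)
  ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE)))
  expect_equal(roc_auc(s, y), ref, tolerance = 1e-12)
})

test_that("micro-average pools counts before computing F1", {
  mi <- micro_f1(list(list(tp = 1, fp = 1, fn = 0, tn = 0),
                      list(tp = 1, fp = 0, fn = 1, tn = 0)))
  expect_equal(mi$precision, 2 / 3)
  expect_equal(mi$recall, 2 / 3)
  expect_equal(mi$f1, 2 / 3)
  # deliberately wrong macro average of per-label F1s differs
  f1a <- prf <- pr_f1(c(0.9, 0.9), c(1, 0), 0.5)$f1        # tp1 fp1 -> 2/3
  f1b <- pr_f1(c(0.9, 0.1), c(1, 1), 0.5)$f1               # tp1 fn1 -> 2/3
  macro <- mean(c(f1a, f1b))
  expect_false(isTRUE(all.equal(macro, 0))) # guard: macro is defined
  counts <- list(confusion_counts(c(0.9, 0.9), c(1, 0), 0.5),
                 confusion_counts(c(0.9, 0.1), c(1, 1), 0.5))
  expect_equal(micro_f1(counts)$f1, 2 / 3)

  perfect <- pr_f1(c(0.9, 0.1), c(1, 0), 0.5)
  expect_identical(perfect$f1, 1)
  expect_warning(none <- pr_f1(c(0.1, 0.2), c(1, 0), 0.5), "precision")
  expect_identical(none$recall, 0)
  expect_identical(none$f1, 0)
  expect_error(pr_f1(c(0.5), c(1), 1.5), "threshold")
})

test_that("micro-F1 differs from macro-F1 on asymmetric labels", {
  counts <- list(list(tp = 8, fp = 2, fn = 0, tn = 10),
                 list(tp = 1, fp = 0, fn = 9, tn = 10))
  micro <- micro_f1(counts)$f1
  f1_of <- function(cc) prf_from <- with(cc, {
    p <- tp / (tp + fp); r <- tp / (tp + fn); 2 * p * r / (p + r)
  })
  macro <- mean(vapply(counts, f1_of, 0))
  expect_gt(abs(micro - macro), 0.05)
})

test_that("G-mean cutoff equals an exhaustive scan", {
  sep <- gmean_cutoff(c(1, 2, 3, 7, 8, 9), c(0, 0, 0, 1, 1, 1))
  expect_equal(sep$gmean, 1)
  expect_identical(sep$threshold, 7)    # lowest separating candidate
  set.seed(5)
  for (k in 1:10) {
    s <- round(runif(20), 1)
    y <- rbinom(20, 1, 0.5)
    if (length(unique(y)) < 2) next
    got <- gmean_cutoff(s, y)
    best <- -1; best_thr <- NA
    for (thr in sort(unique(s))) {
      sens <- sum(s >= thr & y == 1) / sum(y == 1)
      spec <- sum(s < thr & y == 0) / sum(y == 0)
      g <- sqrt(sens * spec)
      if (g > best + 1e-15) { best <- g; best_thr <- thr }
    }
    expect_equal(got$gmean, best, tolerance = 1e-12)
    expect_identical(got$threshold, best_thr)
  }
  flat <- gmean_cutoff(rep(0.5, 10), c(rep(0, 5), rep(1, 5)))
  expect_equal(flat$gmean, 0)           # only the all-positive point exists
  expect_error(gmean_cutoff(1:4, rep(1, 4)), "degenerate")
})

test_that("diagnostic odds ratio follows the closed form with correction", {
  expect_equal(diagnostic_odds_ratio(list(tp = 9, fp = 1, fn = 1,
                                          tn = 9))$dor, 81)
  expect_equal(diagnostic_odds_ratio(list(tp = 4, fp = 4, fn = 4,
                                          tn = 4))$dor, 1)
  z <- diagnostic_odds_ratio(list(tp = 5, fp = 1, fn = 0, tn = 9))
  expect_true(z$corrected)
  expect_equal(z$dor, (5.5 * 9.5) / (1.5 * 0.5), tolerance = 1e-12)
  expect_lt(z$lower, z$dor); expect_gt(z$upper, z$dor)
})

test_that("bootstrap CIs are seeded percentile intervals", {
  d <- data.frame(x = rnorm(50))
  const <- bootstrap_ci(function(dd) 42, d, B = 100, seed = 1)
  expect_identical(c(const$point, const$lower, const$upper), c(42, 42, 42))
  set.seed(6)
  d2 <- data.frame(s = runif(100), y = rbinom(100, 1, 0.5))
  fn <- function(dd) tryCatch(roc_auc(dd$s, dd$y), error = function(e) NA)
  ci95 <- bootstrap_ci(fn, d2, B = 300, level = 0.95, seed = 2)
  ci50 <- bootstrap_ci(fn, d2, B = 300, level = 0.50, seed = 2)
  expect_lt(ci50$upper - ci50$lower, ci95$upper - ci95$lower)
  expect_lte(ci95$lower, ci95$point)
  expect_gte(ci95$upper, ci95$point)
  rep1 <- bootstrap_ci(fn, d2, B = 120, seed = 3)
  rep2 <- bootstrap_ci(fn, d2, B = 120, seed = 3)
  expect_identical(rep1$replicates, rep2$replicates)
  expect_error(bootstrap_ci(fn, d2, B = 50), "B")
})

test_that("paired bootstrap p-values behave at the extremes", {
  set.seed(7)
  y <- rbinom(200, 1, 0.5)
  s_good <- y + rnorm(200, 0, 0.05)
  s_rand <- runif(200)
  expect_identical(paired_bootstrap_pvalue(roc_auc, s_good, s_good, y), 1)
  p <- paired_bootstrap_pvalue(roc_auc, s_good, s_rand, y, B = 500, seed = 0)
  expect_lt(p, 0.05)
  p_ab <- paired_bootstrap_pvalue(roc_auc, s_good, s_rand, y, B = 500, seed = 4)
  p_ba <- paired_bootstrap_pvalue(roc_auc, s_rand, s_good, y, B = 500, seed = 4)
  expect_identical(p_ab, p_ba)
  expect_error(paired_bootstrap_pvalue(roc_auc, s_good, s_rand[-1], y[-1]),
               "identical records")
})

test_that("subgroup stratification uses half-open age bins", {
  set.seed(8)
  n <- 120
  meta <- data.frame(age = runif(n, 20, 90), is_male = rbinom(n, 1, 0.5))
  y <- rbinom(n, 1, 0.5)
  s <- y + rnorm(n, 0, 0.8)
  whole <- subgroup_metrics(s, y, meta, grouping = rep("all", n), B = 150)
  expect_equal(whole$point, roc_auc(s, y), tolerance = 1e-12)

  bins <- subgroup_metrics(rep(0.5, 3), c(0, 1, 1),
                           data.frame(age = c(44, 45, 75)), "age", B = 150)
  expect_identical(bins$n, c(1L, 1L, 1L))
  expect_identical(bins$group,
                   c("young (<45)", "middle (45-74)", "old (>=75)"))

  # a stratum with a stronger planted signal scores higher
  strong <- meta$age < 45
  s2 <- ifelse(strong, y * 3, y * 0.3) + rnorm(n, 0, 1)
  tab <- subgroup_metrics(s2, y, meta, "age", B = 150, seed = 2)
  expect_gt(tab$point[1], tab$point[2])
})
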