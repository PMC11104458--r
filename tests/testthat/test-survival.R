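# hand-rolled product-limit estimator used as the independent oracle
km_oracle <- function(time, event) {
  ut <- sort(unique(time[event == 1]))
  s <- 1; out <- numeric(length(ut))
  for (k in seq_along(ut)) {
    at_risk <- sum(time >= ut[k])
    d <- sum(time == ut[k] & event == 1)
    s <- s * (1 - d / at_risk)
    out[k] <- s
  }
  data.frame(time = ut, surv = out)
}

# Breslow partial log-likelihood for a single covariate with distinct
# event times (no ties, so it equals Efron), used for the grid search
cox_pll <- function(beta, time, event, x) {
  s <- 0
  for (i in which(event == 1)) {
    risk <- which(time >= time[i])
    s <- s + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  s
}

test_that("KM estimator matches the hand product-limit", {
  km <- km_estimate(data.frame(time = c(1, 2, 3, 4, 5),
                               event = c(1, 1, 0, 1, 0)))
  expect_equal(km$surv[km$time == 1], 0.8)
  expect_equal(km$surv[km$time == 2], 0.6)
  expect_equal(km$surv[km$time == 4], 0.3)

  none <- km_estimate(data.frame(time = 1:4, event = rep(0, 4)))
  expect_true(all(none$surv == 1))

  first <- km_estimate(data.frame(time = rep(0.01, 3), event = rep(1, 3)))
  expect_equal(min(first$surv), 0)

  set.seed(1)
  for (k in 1:10) {
    n <- sample(4:10, 1)
    d <- data.frame(time = round(runif(n, 0, 5), 1),
                    event = rbinom(n, 1, 0.7))
    if (sum(d$event) == 0) next
    km2 <- km_estimate(d)
    oracle <- km_oracle(d$time, d$event)
    got <- km2[km2$n_event > 0, ]
    expect_equal(got$surv, oracle$surv[match(got$time, oracle$time)],
                 tolerance = 1e-12)
  }
  expect_error(km_estimate(data.frame(time = -1, event = 1)), "negative")
})

test_that("cumulative event curves are scale-invariant step functions", {
  flat <- cumulative_events(data.frame(time = 1:5, event = rep(0, 5)))
  expect_identical(flat$cum_event_frac, 0)

  d <- data.frame(time = c(1, 1, 2, 4, 6, 7), event = c(1, 0, 1, 1, 0, 0))
  ce <- cumulative_events(d)
  expect_equal(max(ce$cum_event_frac), sum(d$event) / nrow(d))
  expect_true(all(diff(ce$cum_event_frac) >= 0))
  doubled <- cumulative_events(rbind(d, d))
  expect_identical(ce, doubled)
})

test_that("terminal cumulative event fraction reproduces a 3.34% cohort", {
  # 5196 events among 155,435 subjects
  d <- data.frame(time = c(runif(5196, 0, 7), rep(7, 155435 - 5196)),
                  event = c(rep(1, 5196), rep(0, 155435 - 5196)))
  ce <- cumulative_events(d)
  expect_equal(max(ce$cum_event_frac), 0.0334, tolerance = 0.002)
})

test_that("Cox fit matches a partial-likelihood grid search", {
  d <- data.frame(time = c(1, 2, 3, 4, 5, 6),
                  event = c(1, 1, 1, 1, 0, 1),
                  x = c(1, 1, 0, 1, 0, 0))
  f <- cox_fit(d, "x")
  grid <- seq(-3, 3, by = 1e-4)
  ll <- vapply(grid, cox_pll, 0, time = d$time, event = d$event, x = d$x)
  expect_lt(abs(f$table$beta - grid[which.max(ll)]), 1e-3)
  expect_equal(f$table$hr, exp(f$table$beta))
  expect_equal(f$table$lower, exp(f$table$beta - 1.96 * f$table$se))

  expect_error(cox_fit(data.frame(time = 1:3, event = rep(0, 3),
                                  x = c(1, 0, 1)), "x"), "events")
  expect_error(cox_fit(data.frame(time = 1:3, event = c(1, 0, 1),
                                  x = rep(2, 3)), "x"), "degenerate")
})

test_that("complementing a binary flag inverts its hazard ratio", {
  set.seed(2)
  n <- 400
  x <- rbinom(n, 1, 0.4)
  sv <- simulate_survival(cbind(x = x), c(x = log(2)), 0.1, seed = 3)
  d <- cbind(sv, x = x)
  hr <- cox_fit(d, "x")$table$hr
  d$x <- 1 - d$x
  expect_equal(cox_fit(d, "x")$table$hr, 1 / hr, tolerance = 1e-6)
})

test_that("null covariates show no association at large n", {
  set.seed(4)
  n <- 50000
  x <- rbinom(n, 1, 0.3)
  sv <- simulate_survival(cbind(x = x), c(x = 0), 1, admin_years = 100,
                          dropout = 0, seed = 5)
  f <- cox_fit(cbind(sv, x = x), "x")
  expect_lt(abs(f$table$beta), 0.05)
})

test_that("hazard-ratio tables cover the requested covariates", {
  set.seed(6)
  n <- 2000
  X <- cbind(age = rnorm(n, 54, 17) - 54, is_male = rbinom(n, 1, 0.4),
             hypertension = rbinom(n, 1, 0.32))
  cf <- c(age = 0.03, is_male = 0.3, hypertension = 0.5)
  sv <- simulate_survival(X, cf, 0.02, seed = 7)
  d <- cbind(sv, as.data.frame(X))
  uni <- hazard_ratios(d, c("is_male", "hypertension"), mode = "univariate")
  expect_identical(nrow(uni), 2L)
  adj <- hazard_ratios(d, c("is_male", "hypertension"), mode = "adjusted")
  expect_identical(nrow(adj), 2L)
  # adjusted with an empty adjustment set degenerates to univariate
  a0 <- hazard_ratios(d, "hypertension", mode = "adjusted",
                      adjustment = character(0))
  u0 <- hazard_ratios(d, "hypertension", mode = "univariate")
  expect_equal(a0$hr, u0$hr, tolerance = 1e-12)
  # the univariate estimate for a single fitted covariate equals cox_fit
  expect_equal(u0$hr, cox_fit(d, "hypertension")$table$hr)
})

test_that("Efron and Breslow tie handling differ only with ties", {
  d <- data.frame(time = c(1, 1, 1, 1, 2, 2, 3, 4),
                  event = c(1, 1, 1, 0, 1, 1, 1, 0),
                  x = c(1, 1, 0, 1, 1, 0, 0, 0))
  be <- cox_fit(d, "x", ties = "efron")$table$beta
  bb <- cox_fit(d, "x", ties = "breslow")$table$beta
  expect_false(isTRUE(all.equal(be, bb)))
  d2 <- data.frame(time = 1:6, event = c(1, 1, 0, 1, 1, 0),
                   x = c(1, 0, 1, 1, 0, 0))
  expect_equal(cox_fit(d2, "x", ties = "efron")$table$beta,
               cox_fit(d2, "x", ties = "breslow")$table$beta,
               tolerance = 1e-12)
})

test_that("G-mean binarization feeds predicted phenotypes into Cox models", {
  set.seed(8)
  n <- 3000
  truth <- rbinom(n, 1, 0.32)
  prob <- plogis(qlogis(0.3) + 2.5 * truth + rnorm(n, 0, 1))
  bz <- binarize_at_gmean(prob, prob, truth)
  expect_true(bz$threshold > 0 && bz$threshold < 1)
  sv <- simulate_survival(cbind(x = truth), c(x = log(1.7)), 0.05, seed = 9)
  d <- cbind(sv, pred = bz$flags)
  hr <- cox_fit(d, "pred")$table$hr
  expect_gt(hr, 1.2)   # predicted phenotype carries the planted risk signal
})
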