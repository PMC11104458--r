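#' Kaplan-Meier survival curves
#'
#' Product-limit estimator per group; censored subjects leave the risk
#' set without a step. Backed by [survival::survfit()].
#'
#' @param data Data frame with columns `time` (years, >= 0) and `event`
#'   (0/1).
#' @param group Optional column name or vector defining groups.
#' @return Object of class `km_curve`: a data frame with columns
#'   `group`, `time`, `n_risk`, `n_event`, `surv`.
#' @examples
#' km_estimate(data.frame(time = 1:5, event = c(1, 1, 0, 1, 0)))
#' @export
km_estimate <- function(data, group = NULL) {
  data <- as.data.frame(data)
  if (nrow(data) == 0L) stop("empty data")
  if (any(data$time < 0)) stop("negative survival times")
  g <- if (is.null(group)) factor(rep("all", nrow(data)))
  else if (is.character(group) && length(group) == 1L) factor(data[[group]])
  else factor(group)
  out <- lapply(levels(g), function(lv) {
    d <- data[g == lv, , drop = FALSE]
    if (nrow(d) == 0L) stop("empty group: ", lv)
    fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = d)
    data.frame(group = lv, time = fit$time, n_risk = fit$n.risk,
               n_event = fit$n.event, surv = fit$surv)
  })
  structure(do.call(rbind, out), class = c("km_curve", "data.frame"))
}

#' Cumulative event fraction over follow-up
#'
#' Non-decreasing step curve of the fraction of the cohort with an
#' observed event by each time; the terminal value is
#' total events / n.
#'
#' @param data Data frame with `time` and `event` columns.
#' @return Data frame with columns `time` and `cum_event_frac`,
#'   starting at (0, 0).
#' @export
cumulative_events <- function(data) {
  data <- as.data.frame(data)
  if (nrow(data) == 0L) stop("empty data")
  n <- nrow(data)
  et <- sort(data$time[data$event == 1])
  if (length(et) == 0L)
    return(data.frame(time = 0, cum_event_frac = 0))
  ut <- unique(et)
  data.frame(time = c(0, ut),
             cum_event_frac = c(0, cumsum(as.numeric(table(et))) / n))
}

#' Cox proportional-hazards fit
#'
#' Maximizes the partial likelihood via [survival::coxph()] (Efron tie
#' correction by default, Breslow optional) and reports per-covariate
#' log hazard ratios, Wald standard errors, hazard ratios with 95% Wald
#' confidence intervals, z statistics and p-values.
#'
#' @param data Data frame with `time`, `event` and covariate columns.
#' @param covariates Character vector of covariate column names.
#' @param ties `"efron"` or `"breslow"`.
#' @return Object of class `cox_fit`: `table` (data frame with columns
#'   covariate, beta, se, hr, lower, upper, z, p), `loglik`, `n`,
#'   `events`, `iter`.
#' @examples
#' d <- data.frame(time = c(1, 2, 3, 4, 5, 6),
#'                 event = c(1, 1, 1, 1, 0, 1),
#'                 x = c(1, 1, 0, 1, 0, 0))
#' cox_fit(d, "x")$table$hr
#' @export
cox_fit <- function(data, covariates, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  data <- as.data.frame(data)
  if (!all(c("time", "event") %in% names(data)))
    stop("data must have 'time' and 'event' columns")
  missing_cov <- setdiff(covariates, names(data))
  if (length(missing_cov))
    stop("missing covariate column(s): ", paste(missing_cov, collapse = ", "))
  if (sum(data$event) < 1) stop("no events in the data")
  for (v in covariates) {
    if (any(is.na(data[[v]]))) stop("missing values in covariate ", v)
    if (stats::var(data[[v]]) == 0)
      stop("degenerate covariate (constant): ", v)
  }
  fml <- stats::as.formula(paste(
    "survival::Surv(time, event) ~",
    paste(sprintf("`%s`", covariates), collapse = " + ")))
  fit <- survival::coxph(fml, data = data, ties = ties)
  s <- summary(fit)
  beta <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  tab <- data.frame(covariate = covariates, beta = unname(beta),
                    se = unname(se), hr = unname(exp(beta)),
                    lower = unname(exp(beta - 1.96 * se)),
                    upper = unname(exp(beta + 1.96 * se)),
                    z = unname(beta / se),
                    p = unname(2 * stats::pnorm(-abs(beta / se))))
  structure(list(table = tab, loglik = fit$loglik[2], n = s$n,
                 events = s$nevent, iter = fit$iter, ties = ties),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox proportional-hazards fit (%s ties): n = %d, events = %d\n",
              x$ties, x$n, x$events))
  tab <- x$table
  tab$`HR (95% CI)` <- sprintf("%.2f (%.2f-%.2f)", tab$hr, tab$lower, tab$upper)
  print(tab[c("covariate", "beta", "se", "HR (95% CI)", "p")], row.names = FALSE)
  invisible(x)
}

#' Univariate and adjusted hazard-ratio tables
#'
#' Univariate mode fits one Cox model per requested covariate; adjusted
#' mode fits a single joint model over the requested covariates plus the
#' adjustment set (default: age, sex, the six abnormalities and
#' hypertension, intersected with the available columns) and reports the
#' rows for the requested covariates.
#'
#' @param data Data frame with `time`, `event` and covariate columns.
#' @param covariates Covariates to report.
#' @param mode `"univariate"` or `"adjusted"`.
#' @param adjustment Adjustment covariates for the joint model.
#' @param ties Tie handling, see [cox_fit()].
#' @return Data frame: covariate, hr, lower, upper, p, n, events.
#' @export
hazard_ratios <- function(data, covariates,
                          mode = c("univariate", "adjusted"),
                          adjustment = intersect(
                            c("age", "is_male", ECG_ABNORMALITIES,
                              "hypertension"), names(data)),
                          ties = "efron") {
  mode <- match.arg(mode)
  data <- as.data.frame(data)
  if (mode == "univariate") {
    rows <- lapply(covariates, function(v) {
      f <- cox_fit(data, v, ties = ties)
      cbind(f$table[1, c("covariate", "hr", "lower", "upper", "p")],
            n = f$n, events = f$events)
    })
    out <- do.call(rbind, rows)
  } else {
    all_cov <- union(covariates, setdiff(adjustment, c("time", "event")))
    f <- cox_fit(data, all_cov, ties = ties)
    keep <- f$table$covariate %in% covariates
    out <- cbind(f$table[keep, c("covariate", "hr", "lower", "upper", "p")],
                 n = f$n, events = f$events)
  }
  rownames(out) <- NULL
  out
}

#' Binarize predicted probabilities at the G-mean operating point
#'
#' Model-predicted phenotype probabilities are converted to 0/1 flags at
#' the threshold maximizing the G-mean on a labelled calibration set,
#' the operating point used before predicted phenotypes enter survival
#' models.
#'
#' @param probabilities Predicted probabilities for the cohort.
#' @param calibration_scores,calibration_labels Scores and labels used
#'   to locate the operating point (defaults: the cohort itself).
#' @return List with `flags` (0/1 vector) and `threshold`.
#' @export
binarize_at_gmean <- function(probabilities, calibration_scores = probabilities,
                              calibration_labels) {
  op <- gmean_cutoff(calibration_scores, calibration_labels)
  list(flags = as.integer(probabilities >= op$threshold),
       threshold = op$threshold)
}
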