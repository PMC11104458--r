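#' Planted-lead saliency benchmark
#'
#' Generates a binary classification task with known interpretability
#' ground truth: every record is a synthetic 12-lead ECG, and positive
#' records additionally carry a windowed sinusoidal transient planted
#' in one lead (default V1) at a random onset. A model trained on this
#' task should (a) separate the classes and (b) place its saliency mass
#' on the planted lead inside the planted window.
#'
#' @param n_train,n_test Record counts for the two splits.
#' @param input_length Samples per record (T).
#' @param fs Sampling rate, Hz.
#' @param lead Planted lead name.
#' @param amplitude,frequency Transient amplitude (mV) and frequency (Hz).
#' @param window_s Transient window length, s.
#' @param snr_db Background noise level of the base records.
#' @param seed Seed; the benchmark is fully deterministic.
#' @return List with `x_train`, `y_train`, `x_test`, `y_test` (arrays
#'   n x 12 x T and 0/1 vectors), `windows` (per-record data frame with
#'   t0/t1, `NA` for negatives; rows `1:n_train` then the test split)
#'   and the planted `lead`.
#' @export
planted_lead_benchmark <- function(n_train = 500, n_test = 200,
                                   input_length = 1024, fs = 400,
                                   lead = "V1", amplitude = 0.4,
                                   frequency = 30, window_s = 0.8,
                                   snr_db = 20, seed = 0L) {
  n <- n_train + n_test
  duration <- input_length / fs
  if (duration < window_s + 0.2)
    stop("records too short for the planted window")
  with_seed(seed, {
    x <- array(0, c(n, 12L, input_length))
    y <- stats::rbinom(n, 1L, 0.5)
    t0 <- rep(NA_real_, n)
    for (i in seq_len(n)) {
      hr <- min(max(stats::rnorm(1, 72, 5), 62), 95)
      rec <- synth_ecg(rhythm_spec(heart_rate = hr), beat_model(),
                       fs = fs, duration = duration,
                       snr_db = snr_db, exam_id = i)
      if (y[i] == 1L) {
        t0[i] <- stats::runif(1, 0.1, duration - window_s - 0.1)
        rec <- plant_signal(rec, planted_saliency(
          lead, t0[i], t0[i] + window_s,
          amplitude = amplitude, frequency = frequency))
      }
      sig <- rec$signal
      if (ncol(sig) > input_length) sig <- sig[, seq_len(input_length)]
      x[i, , ] <- sig
    }
    tr <- seq_len(n_train)
    list(x_train = x[tr, , , drop = FALSE], y_train = y[tr],
         x_test = x[-tr, , , drop = FALSE], y_test = y[-tr],
         windows = data.frame(t0 = t0, t1 = t0 + window_s),
         lead = lead, fs = fs)
  })
}

#' Hazard-ratio recovery benchmark
#'
#' Simulates a cohort with one or more planted binary risk indicators
#' whose true hazard ratios are known, tunes the exponential baseline
#' hazard to a target overall event fraction, and fits a Cox model to
#' check that the planted values are recovered. In `"adjusted"` mode
#' the cohort carries age (normal, mean 54, sd 17, centred), male sex
#' (prevalence 0.4) and hypertension (0.32) as nuisance covariates with
#' small nonzero coefficients, and the joint model is fitted;
#' `"univariate"` mode simulates a single binary covariate and fits it
#' alone.
#'
#' @param planted_hr Named vector of true hazard ratios for the planted
#'   indicator(s).
#' @param prevalence Named prevalences matching `planted_hr`.
#' @param mode `"adjusted"` or `"univariate"` (univariate requires a
#'   single planted indicator).
#' @param n Cohort size.
#' @param event_rate Target overall event fraction over the follow-up.
#' @param admin_years,dropout Censoring model, see [simulate_survival()].
#' @param nuisance Coefficients for age/sex/hypertension in adjusted mode.
#' @param seed Seed (covariate and survival streams are derived from it).
#' @return List with `hr` (named recovered hazard ratios), `fit` (the
#'   [cox_fit()]), `lambda0` and `events`.
#' @export
cox_recovery_benchmark <- function(planted_hr, prevalence,
                                   mode = c("adjusted", "univariate"),
                                   n = 20000, event_rate = 0.033,
                                   admin_years = 7, dropout = 0.1,
                                   nuisance = c(age = 0.02, is_male = 0.25,
                                                hypertension = 0.40),
                                   seed = 0L) {
  mode <- match.arg(mode)
  if (is.null(names(planted_hr)) ||
      !identical(sort(names(planted_hr)), sort(names(prevalence))))
    stop("planted_hr and prevalence must share names")
  if (mode == "univariate" && length(planted_hr) != 1L)
    stop("univariate mode takes a single planted indicator")
  X <- with_seed(split_seed(seed, 101L), {
    base <- if (mode == "adjusted")
      cbind(age = stats::rnorm(n, 54, 17) - 54,
            is_male = stats::rbinom(n, 1, 0.4),
            hypertension = stats::rbinom(n, 1, 0.32))
    else NULL
    planted <- vapply(names(planted_hr),
                      function(v) stats::rbinom(n, 1, prevalence[[v]]),
                      numeric(n))
    cbind(base, planted)
  })
  coefs <- c(if (mode == "adjusted") nuisance[colnames(X)[1:3]],
             log(planted_hr))
  names(coefs) <- colnames(X)
  lambda0 <- tune_baseline_hazard(event_rate, drop(X %*% coefs),
                                  admin_years, dropout)
  sv <- simulate_survival(X, coefs, lambda0, admin_years, dropout,
                          seed = split_seed(seed, 202L))
  d <- cbind(sv, as.data.frame(X))
  fit <- cox_fit(d, colnames(X))
  hr <- fit$table$hr[match(names(planted_hr), fit$table$covariate)]
  names(hr) <- names(planted_hr)
  list(hr = hr, fit = fit, lambda0 = lambda0, events = fit$events)
}
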