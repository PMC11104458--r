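#' Cohort simulation specification
#'
#' Population-level parameters for the synthetic cohort: sample size,
#' abnormality prevalences, demographic mix, age distribution and the
#' proportional-hazards survival model. Defaults emulate the population
#' structure of a large primary-care ECG cohort: 60.26% female, 31.66%
#' hypertensive, age 53.64 +/- 17.42 years, and a 3.34% mortality rate
#' over 7 follow-up years.
#'
#' @param n_subjects Number of subjects.
#' @param prevalence Named prevalences for the six abnormalities. SB, ST
#'   and AF are treated as mutually exclusive rhythms (their prevalences
#'   must sum to at most 1); conduction labels are independent.
#' @param female_fraction,hypertension_fraction Demographic fractions.
#' @param age_mean,age_sd,age_range Truncated-normal age model (years).
#' @param coefs Named log-hazard-ratio coefficients for the survival
#'   model. Age enters centred at `age_mean`. Defaults take the printed
#'   adjusted hazard ratios for the abnormality cohorts where available.
#' @param target_event_rate Overall event fraction the baseline hazard is
#'   tuned to (see [tune_baseline_hazard()]).
#' @param admin_years Administrative censoring horizon, years.
#' @param dropout Fraction of subjects subject to uniform dropout.
#' @param seed Global seed; per-subject streams are derived by a counter
#'   split so any subset regenerates identically.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 1000,
                        prevalence = c("1dAVb" = 0.014, RBBB = 0.027,
                                       LBBB = 0.017, SB = 0.016,
                                       AF = 0.018, ST = 0.022),
                        female_fraction = 0.6026,
                        hypertension_fraction = 0.3166,
                        age_mean = 53.64, age_sd = 17.42,
                        age_range = c(18, 95),
                        coefs = c(age = 0.085, is_male = 0.35,
                                  hypertension = log(1.67),
                                  "1dAVb" = log(1.93), RBBB = 0.30,
                                  LBBB = log(3.30), SB = 0.10,
                                  AF = log(2.22), ST = log(2.24)),
                        target_event_rate = 0.0334,
                        admin_years = 7, dropout = 0.1,
                        seed = 1L) {
  if (n_subjects < 1) stop("n_subjects must be >= 1")
  if (!all(ECG_ABNORMALITIES %in% names(prevalence)))
    stop("prevalence must name all six abnormalities")
  prevalence <- prevalence[ECG_ABNORMALITIES]
  if (any(prevalence < 0 | prevalence > 1))
    stop("prevalences must lie in [0, 1]")
  if (sum(prevalence[c("SB", "AF", "ST")]) > 1)
    stop("spec validation: exclusive rhythm prevalences (SB, AF, ST) sum to > 1")
  for (f in c(female_fraction, hypertension_fraction, dropout))
    if (f < 0 || f > 1) stop("fractions must lie in [0, 1]")
  if (target_event_rate <= 0 || target_event_rate >= 1)
    stop("target_event_rate must lie in (0, 1)")
  structure(list(n_subjects = as.integer(n_subjects), prevalence = prevalence,
                 female_fraction = female_fraction,
                 hypertension_fraction = hypertension_fraction,
                 age_mean = age_mean, age_sd = age_sd, age_range = age_range,
                 coefs = coefs, target_event_rate = target_event_rate,
                 admin_years = admin_years, dropout = dropout,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Expected event fraction under the simulation model
#'
#' Closed-form expectation of the observed event fraction for exponential
#' event times with per-subject rate `lambda0 * exp(lp)`, administrative
#' censoring at `admin_years` and a `dropout` fraction censored uniformly
#' on (0, admin_years).
#'
#' @param lambda0 Baseline hazard, events/year.
#' @param lp Vector of linear predictors.
#' @param admin_years Censoring horizon.
#' @param dropout Uniform-dropout fraction.
#' @return Expected event fraction.
#' @export
expected_event_rate <- function(lambda0, lp, admin_years = 7, dropout = 0.1) {
  r <- lambda0 * exp(lp)
  a <- admin_years
  p_admin <- 1 - exp(-r * a)
  # uniform censor U(0, a): P(event) = 1 - (1 - exp(-r a)) / (r a)
  p_drop <- 1 - p_admin / (r * a)
  mean((1 - dropout) * p_admin + dropout * p_drop)
}

#' Tune the baseline hazard to a target event fraction
#'
#' Solves for `lambda0` such that [expected_event_rate()] equals
#' `target` for the given linear predictors.
#'
#' @param target Target event fraction in (0, 1).
#' @param lp Vector of linear predictors.
#' @param admin_years,dropout As in [expected_event_rate()].
#' @return Baseline hazard `lambda0` (events/year).
#' @export
tune_baseline_hazard <- function(target, lp, admin_years = 7, dropout = 0.1) {
  f <- function(loglam)
    expected_event_rate(exp(loglam), lp, admin_years, dropout) - target
  exp(stats::uniroot(f, c(-20, 5), tol = 1e-10)$root)
}

#' Simulate proportional-hazards survival times
#'
#' Event times are exponential with hazard `lambda0 * exp(x' beta)`;
#' censoring is the minimum of administrative follow-up and (for a
#' `dropout` fraction of subjects) a uniform dropout time.
#'
#' @param covariates Numeric matrix, n x p.
#' @param coefs Length-p vector of log hazard ratios.
#' @param lambda0 Baseline hazard, events/year (> 0).
#' @param admin_years Administrative censoring horizon, years.
#' @param dropout Fraction of subjects with uniform dropout.
#' @param seed Optional seed (caller's RNG state restored).
#' @return `data.frame(time, event)` with `time` in years.
#' @examples
#' x <- matrix(rbinom(200, 1, 0.3))
#' simulate_survival(x, log(2), 0.05, seed = 1)[1:3, ]
#' @export
simulate_survival <- function(covariates, coefs, lambda0, admin_years = 7,
                              dropout = 0.1, seed = NULL) {
  covariates <- as.matrix(covariates)
  if (ncol(covariates) != length(coefs))
    stop("covariate columns (", ncol(covariates), ") do not match coefficients (",
         length(coefs), ")")
  if (!all(is.finite(coefs))) stop("coefficients must be finite")
  if (!is.numeric(lambda0) || lambda0 <= 0) stop("lambda0 must be positive")
  with_seed(seed, {
    n <- nrow(covariates)
    rate <- lambda0 * exp(drop(covariates %*% coefs))
    t_event <- stats::rexp(n) / rate
    censor <- rep(admin_years, n)
    if (dropout > 0) {
      drops <- stats::runif(n) < dropout
      u <- stats::runif(n, 0, admin_years)
      censor[drops] <- pmin(censor[drops], u[drops])
    }
    data.frame(time = pmin(t_event, censor),
               event = as.integer(t_event <= censor))
  })
}

#' Simulate a cohort of subjects with 12-lead ECGs
#'
#' Draws demographics and abnormality phenotypes at the spec's
#' prevalences, generates each subject's ECG from a rhythm/beat model
#' carrying their phenotype, and attaches proportional-hazards survival
#' outcomes. Sex is expressed in the tracings as a T-wave amplitude scale
#' and a heart-rate offset; hypertension as a raised V1 R-wave amplitude
#' and a widened DII P wave. Deterministic given `spec$seed`; subject
#' `i`'s tracing is generated from a counter-derived stream so subsets
#' regenerate identically.
#'
#' @param spec A [cohort_spec()].
#' @param ecg Generate tracings (set `FALSE` for metadata/survival only)?
#' @param fs,duration Sampling rate and record length for the tracings.
#' @param snr_db,wander Noise settings passed to [synth_ecg()].
#' @return `list(subjects = data.frame, records = list of ecg_record)`.
#'   The metadata columns are exam_id, age, is_male, hypertension, the six
#'   abnormality flags, follow_up_years and death.
#' @examples
#' coh <- simulate_cohort(cohort_spec(n_subjects = 5, seed = 7),
#'                        fs = 200, duration = 4)
#' coh$subjects$age
#' @export
simulate_cohort <- function(spec, ecg = TRUE, fs = 400, duration = 10.24,
                            snr_db = 20, wander = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_subjects
  meta <- with_seed(split_seed(spec$seed, 0L), {
    age <- stats::rnorm(n, spec$age_mean, spec$age_sd)
    age <- pmin(pmax(age, spec$age_range[1]), spec$age_range[2])
    is_male <- as.integer(stats::runif(n) >= spec$female_fraction)
    hyp <- as.integer(stats::runif(n) < spec$hypertension_fraction)
    pv <- spec$prevalence
    u <- stats::runif(n)
    rhythm_lab <- rep("none", n)
    rhythm_lab[u < pv["SB"]] <- "SB"
    rhythm_lab[u >= pv["SB"] & u < pv["SB"] + pv["AF"]] <- "AF"
    rhythm_lab[u >= pv["SB"] + pv["AF"] &
                 u < pv["SB"] + pv["AF"] + pv["ST"]] <- "ST"
    flags <- data.frame(
      "1dAVb" = as.integer(stats::runif(n) < pv["1dAVb"]),
      RBBB = as.integer(stats::runif(n) < pv["RBBB"]),
      LBBB = as.integer(stats::runif(n) < pv["LBBB"]),
      SB = as.integer(rhythm_lab == "SB"),
      AF = as.integer(rhythm_lab == "AF"),
      ST = as.integer(rhythm_lab == "ST"),
      check.names = FALSE)
    hr_base <- pmin(pmax(stats::rnorm(n, 72, 5), 62), 98)
    data.frame(exam_id = seq_len(n), age = age, is_male = is_male,
               hypertension = hyp, flags, hr_base = hr_base,
               check.names = FALSE)
  })
  X <- cbind(age = meta$age - spec$age_mean,
             is_male = meta$is_male, hypertension = meta$hypertension,
             as.matrix(meta[ECG_ABNORMALITIES]))
  beta <- spec$coefs[colnames(X)]
  lp <- drop(X %*% beta)
  lambda0 <- tune_baseline_hazard(spec$target_event_rate, lp,
                                  spec$admin_years, spec$dropout)
  surv <- simulate_survival(X, beta, lambda0, spec$admin_years, spec$dropout,
                            seed = split_seed(spec$seed, 1L))
  meta$follow_up_years <- surv$time
  meta$death <- surv$event
  records <- NULL
  if (ecg) {
    records <- vector("list", n)
    for (i in seq_len(n)) {
      records[[i]] <- with_seed(split_seed(spec$seed, 1L + i), {
        rhythm <- rhythm_spec(heart_rate = meta$hr_base[i] -
                                if (meta$is_male[i]) 4 else 0)
        beats <- beat_model()
        if (meta$is_male[i])
          beats$lead_mixing[, "T"] <- beats$lead_mixing[, "T"] * 1.2
        if (meta$hypertension[i]) {
          beats$lead_mixing["V1", "R"] <- beats$lead_mixing["V1", "R"] * 1.3
          beats$p_width_dii <- 1.5
        }
        for (lab in ECG_ABNORMALITIES) {
          if (meta[[lab]][i] == 1L) {
            mod <- apply_abnormality(rhythm, beats, lab)
            rhythm <- mod$rhythm; beats <- mod$beats
          }
        }
        synth_ecg(rhythm, beats, fs = fs, duration = duration,
                  snr_db = snr_db, wander = wander, exam_id = meta$exam_id[i])
      })
    }
  }
  meta$hr_base <- NULL
  list(subjects = meta, records = records, lambda0 = lambda0)
}
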