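test_that("beat train honours rate, length and determinism", {
  rec <- synth_ecg(rhythm_spec(heart_rate = 60, rr_cv = 0), beat_model(),
                   fs = 200, duration = 10, seed = 1, snr_db = Inf,
                   wander = FALSE)
  expect_length(cardiolens:::find_r_peaks(rec$signal["DII", ], 200), 10L)

  rec2 <- synth_ecg(rhythm_spec(), beat_model(), fs = 400, duration = 10.24,
                    seed = 2)
  expect_identical(dim(rec2$signal), c(12L, 4096L))

  rec3 <- synth_ecg(rhythm_spec(), beat_model(), fs = 400, duration = 10.24,
                    seed = 2)
  expect_identical(rec2$signal, rec3$signal)
})

test_that("generator rejects invalid arguments", {
  expect_error(synth_ecg(rhythm_spec(), beat_model(), fs = 50, duration = 10),
               "fs")
  expect_error(synth_ecg(rhythm_spec(), beat_model(), duration = -1),
               "duration")
  expect_error(synth_ecg(rhythm_spec(heart_rate = 30), beat_model(),
                         duration = 2), "2 beats")
  # label/parameter inconsistency is a spec-validation error
  bad <- rhythm_spec(heart_rate = 80, labels = "SB")
  expect_error(synth_ecg(bad, beat_model(), duration = 10), "inconsistent")
})

test_that("P-wave suppression leaves the inter-beat baseline flat", {
  rhythm <- rhythm_spec(p_present = FALSE, pr_interval = 0.16)
  rec <- synth_ecg(rhythm, beat_model(), fs = 400, duration = 10, seed = 4,
                   snr_db = Inf, wander = FALSE)
  m <- measure_ecg(rec)
  expect_false(m$p_present)
  # AF-style irregularity: injected CV is well above sinus variability
  af <- apply_abnormality(rhythm_spec(), beat_model(), "AF")
  expect_false(af$rhythm$p_present)
  expect_gte(af$rhythm$rr_cv, 0.15)
  expect_true(af$rhythm$fib_wave[2] >= 4 && af$rhythm$fib_wave[2] <= 9)
})

test_that("abnormality injectors move parameters into textbook ranges", {
  set.seed(11)
  av <- apply_abnormality(rhythm_spec(), beat_model(), "1dAVb")
  expect_gt(av$rhythm$pr_interval, 0.2)
  rec <- synth_ecg(av$rhythm, av$beats, fs = 400, duration = 10, seed = 1,
                   snr_db = Inf, wander = FALSE)
  expect_gt(measure_ecg(rec)$pr_interval, 0.2)

  lb <- apply_abnormality(rhythm_spec(), beat_model(), "LBBB")
  expect_gte(lb$rhythm$qrs_duration, 0.12)

  sb <- apply_abnormality(rhythm_spec(), beat_model(), "SB")
  expect_lt(sb$rhythm$heart_rate, 60)
  expect_error(apply_abnormality(sb$rhythm, sb$beats, "ST"),
               "mutually exclusive")
  expect_error(apply_abnormality(rhythm_spec(), beat_model(), "XYZ"),
               "unknown")
})

test_that("rule-based measurer recovers every injected abnormality", {
  for (lab in c(ECG_ABNORMALITIES, "none")) {
    for (rep in 1:3) {
      if (lab == "none") {
        rhythm <- rhythm_spec(); beats <- beat_model()
      } else {
        set.seed(1000 + rep)
        mod <- apply_abnormality(rhythm_spec(), beat_model(), lab)
        rhythm <- mod$rhythm; beats <- mod$beats
      }
      rec <- synth_ecg(rhythm, beats, fs = 400, duration = 12, seed = rep,
                       snr_db = Inf, wander = FALSE)
      got <- classify_rhythm(measure_ecg(rec))
      want <- if (lab == "none") character(0) else lab
      expect_identical(sort(got), sort(want),
                       label = paste("label", lab, "rep", rep))
    }
  }
})

test_that("planted transients are local, additive and order-independent", {
  rec <- ecg_record(matrix(0, 12, 1200), fs = 400)
  p1 <- planted_saliency("V1", 1, 2, amplitude = 0.5, frequency = 25)
  out <- plant_signal(rec, p1)
  touched <- which(out$signal != 0, arr.ind = TRUE)
  expect_identical(unique(touched[, 1]), match("V1", ECG_LEADS))
  expect_true(all(touched[, 2] >= 1 * 400 & touched[, 2] <= 2 * 400 + 1))

  expect_identical(plant_signal(rec, planted_saliency("V2", 0.5, 1,
                                                      amplitude = 0))$signal,
                   rec$signal)

  p2 <- planted_saliency("DII", 0.2, 0.8, amplitude = 0.3, frequency = 12)
  ab <- plant_signal(plant_signal(rec, p1), p2)
  ba <- plant_signal(plant_signal(rec, p2), p1)
  expect_equal(ab$signal, ba$signal, tolerance = 1e-12)

  expect_error(plant_signal(rec, planted_saliency("V1", 2.5, 4)), "window")
})

test_that("cohort draws match the requested population structure", {
  spec <- cohort_spec(n_subjects = 1000, seed = 5)
  coh <- simulate_cohort(spec, ecg = FALSE)
  expect_equal(mean(coh$subjects$is_male == 0), 0.6026, tolerance = 0.05 / 0.6)
  expect_true(all(coh$subjects$age > 0))
  expect_true(all(coh$subjects$follow_up_years >= 0 &
                    coh$subjects$follow_up_years <= 7))

  coh2 <- simulate_cohort(cohort_spec(n_subjects = 1000, seed = 5),
                          ecg = FALSE)
  expect_identical(coh$subjects, coh2$subjects)

  pv <- c("1dAVb" = 0.1, RBBB = 0, LBBB = 0, SB = 0, AF = 0, ST = 0)
  coh3 <- simulate_cohort(cohort_spec(n_subjects = 12, prevalence = pv,
                                      seed = 2),
                          fs = 200, duration = 6, snr_db = Inf, wander = FALSE)
  expect_true(all(coh3$subjects$AF == 0))
  p_found <- vapply(coh3$records, function(r) measure_ecg(r)$p_present, TRUE)
  expect_true(all(p_found))

  expect_error(cohort_spec(prevalence = c("1dAVb" = 0, RBBB = 0, LBBB = 0,
                                          SB = 0.6, AF = 0.3, ST = 0.3)),
               "spec validation")
})

test_that("subject ECG streams regenerate identically from the seed", {
  spec <- cohort_spec(n_subjects = 6, seed = 9)
  coh <- simulate_cohort(spec, fs = 200, duration = 4)
  # regenerating the full cohort reproduces subject 4's tracing exactly
  coh2 <- simulate_cohort(spec, fs = 200, duration = 4)
  expect_identical(coh$records[[4]]$signal, coh2$records[[4]]$signal)
})

test_that("survival generator satisfies the proportional-hazards model", {
  # null: no covariate effect, (almost) fully observed events
  n <- 50000
  set.seed(21)
  X <- cbind(x = rbinom(n, 1, 0.3))
  sv <- simulate_survival(X, c(x = 0), lambda0 = 1, admin_years = 100,
                          dropout = 0, seed = 1)
  f <- cox_fit(cbind(sv, x = X[, 1]), "x")
  expect_lt(abs(f$table$beta), 0.05)

  # planted log-HR of ln 2 is recovered
  sv2 <- simulate_survival(X, c(x = log(2)), lambda0 = 1, admin_years = 100,
                           dropout = 0, seed = 2)
  f2 <- cox_fit(cbind(sv2, x = X[, 1]), "x")
  expect_gt(f2$table$hr, 1.9)
  expect_lt(f2$table$hr, 2.1)

  # doubling the baseline hazard halves the mean event time
  sv_a <- simulate_survival(X, c(x = 0), lambda0 = 0.5, admin_years = Inf,
                            dropout = 0, seed = 3)
  sv_b <- simulate_survival(X, c(x = 0), lambda0 = 1.0, admin_years = Inf,
                            dropout = 0, seed = 3)
  expect_equal(mean(sv_b$time) / mean(sv_a$time), 0.5, tolerance = 0.02)

  expect_error(simulate_survival(X, c(0, 0), 1), "do not match")
  expect_error(simulate_survival(X, c(x = 0), -1), "lambda0")
})

test_that("baseline-hazard tuning hits the target event fraction", {
  set.seed(31)
  lp <- rnorm(20000, 0, 0.5)
  lam <- tune_baseline_hazard(0.0334, lp)
  expect_equal(expected_event_rate(lam, lp), 0.0334, tolerance = 1e-6)
  sv <- simulate_survival(matrix(lp), c(1), lam, seed = 4)
  expect_equal(mean(sv$event), 0.0334, tolerance = 0.15)
})
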