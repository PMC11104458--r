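#' Gaussian-wave beat morphology model
#'
#' Parameterizes one cardiac cycle as a sum of Gaussian deflections
#' (P, Q, R, S, T, U), each with an amplitude (mV, referenced to lead DII),
#' a centre offset relative to the R peak (s) and a width (s), plus a
#' 12 x 6 lead-mixing table of per-lead amplitude scale factors. The Q, R
#' and S waves are scaled in time by the rhythm's QRS duration, so bundle
#' branch block morphologies widen coherently.
#'
#' @param amplitude Named vector of wave amplitudes in mV (names P,Q,R,S,T,U).
#' @param center Named vector of wave centres relative to the R peak, s.
#'   The P centre is ignored: P placement is derived from the rhythm's PR
#'   interval at synthesis time.
#' @param width Named vector of Gaussian standard deviations, s.
#' @param lead_mixing 12 x 6 matrix (leads x waves) of amplitude scales.
#' @param p_width_dii Width multiplier applied to the P wave in lead DII
#'   only (used to express hypertension-linked P-wave widening).
#' @return An object of class `beat_model`.
#' @examples
#' b <- beat_model()
#' b$amplitude["R"]
#' @export
beat_model <- function(amplitude = c(P = 0.15, Q = -0.08, R = 1.0,
                                     S = -0.15, T = 0.30, U = 0.05),
                       center = c(P = -0.16, Q = -0.02, R = 0,
                                  S = 0.02, T = 0.30, U = 0.45),
                       width = c(P = 0.025, Q = 0.0125, R = 0.018,
                                 S = 0.0125, T = 0.05, U = 0.025),
                       lead_mixing = default_lead_mixing(),
                       p_width_dii = 1) {
  waves <- c("P", "Q", "R", "S", "T", "U")
  stopifnot(all(waves %in% names(amplitude)), all(waves %in% names(center)),
            all(waves %in% names(width)))
  if (any(width[waves] <= 0)) stop("wave widths must be positive")
  if (amplitude["U"] < 0 || amplitude["U"] > 0.1 * abs(amplitude["R"]))
    stop("U-wave amplitude must be nonnegative and small (<= 0.1 * R amplitude)")
  lead_mixing <- as.matrix(lead_mixing)
  if (!identical(dim(lead_mixing), c(12L, 6L)))
    stop("lead_mixing must be a 12 x 6 matrix (leads x waves)")
  dimnames(lead_mixing) <- list(ECG_LEADS, waves)
  structure(list(amplitude = amplitude[waves], center = center[waves],
                 width = width[waves], lead_mixing = lead_mixing,
                 p_width_dii = p_width_dii),
            class = "beat_model")
}

# Plausible relative projections of each wave onto the 12 leads:
# DII is the reference; AVR is inverted; V1 has an rS complex with a
# shallow negative T; amplitudes grow across the precordial leads.
default_lead_mixing <- function() {
  m <- rbind(
    DI   = c(0.60, 0.40, 0.70, 0.40, 0.60, 0.50),
    DII  = c(1.00, 1.00, 1.00, 1.00, 1.00, 1.00),
    DIII = c(0.50, 0.60, 0.50, 0.70, 0.40, 0.40),
    AVR  = c(-0.80, -0.70, -0.90, -0.70, -0.80, -0.50),
    AVL  = c(0.30, 0.30, 0.40, 0.30, 0.30, 0.20),
    AVF  = c(0.70, 0.80, 0.80, 0.90, 0.70, 0.60),
    V1   = c(0.25, 0.20, 0.25, 1.60, -0.30, 0.30),
    V2   = c(0.30, 0.30, 0.50, 1.40, 0.50, 0.40),
    V3   = c(0.35, 0.40, 0.80, 1.10, 0.70, 0.50),
    V4   = c(0.40, 0.50, 1.20, 0.80, 0.80, 0.50),
    V5   = c(0.45, 0.60, 1.10, 0.50, 0.70, 0.50),
    V6   = c(0.50, 0.60, 0.90, 0.30, 0.60, 0.40))
  colnames(m) <- c("P", "Q", "R", "S", "T", "U")
  m
}

#' Rhythm specification
#'
#' Heart-rate and interval parameters for a synthetic tracing, together
#' with the abnormality labels the parameters encode. Consistency between
#' labels and parameters is enforced by [apply_abnormality()] and checked
#' again by [synth_ecg()].
#'
#' @param heart_rate Beats per minute.
#' @param rr_cv Coefficient of variation of RR intervals (dimensionless).
#' @param pr_interval PR interval (P onset to QRS onset), s.
#' @param qrs_duration QRS duration, s.
#' @param p_present Logical; P waves synthesized?
#' @param fib_wave `NULL`, or `c(amplitude, frequency)` in mV / Hz for a
#'   fibrillatory baseline oscillation.
#' @param labels Character subset of [ECG_ABNORMALITIES].
#' @return An object of class `rhythm_spec`.
#' @examples
#' rhythm_spec(heart_rate = 60)
#' @export
rhythm_spec <- function(heart_rate = 75, rr_cv = 0.03, pr_interval = 0.16,
                        qrs_duration = 0.09, p_present = TRUE,
                        fib_wave = NULL, labels = character(0)) {
  if (heart_rate <= 0) stop("heart_rate must be positive")
  if (rr_cv < 0) stop("rr_cv must be nonnegative")
  if (p_present && pr_interval <= 0) stop("pr_interval must be positive when P waves are present")
  if (qrs_duration <= 0) stop("qrs_duration must be positive")
  if (!is.null(fib_wave) && (length(fib_wave) != 2L || any(fib_wave <= 0)))
    stop("fib_wave must be NULL or c(amplitude, frequency), both positive")
  bad <- setdiff(labels, ECG_ABNORMALITIES)
  if (length(bad)) stop("unknown abnormality label(s): ", paste(bad, collapse = ", "))
  structure(list(heart_rate = heart_rate, rr_cv = rr_cv,
                 pr_interval = pr_interval, qrs_duration = qrs_duration,
                 p_present = p_present, fib_wave = fib_wave,
                 labels = labels),
            class = "rhythm_spec")
}

# label/parameter consistency used by synth_ecg(); textbook thresholds
check_rhythm_labels <- function(rhythm) {
  lab <- rhythm$labels
  err <- function(...) stop("rhythm spec inconsistent with its labels: ", ...)
  if ("SB" %in% lab && rhythm$heart_rate >= 60) err("SB requires heart_rate < 60")
  if ("ST" %in% lab && rhythm$heart_rate <= 100) err("ST requires heart_rate > 100")
  if ("1dAVb" %in% lab && rhythm$pr_interval <= 0.2) err("1dAVb requires pr_interval > 0.2 s")
  if (any(c("RBBB", "LBBB") %in% lab) && rhythm$qrs_duration < 0.12)
    err("bundle branch block requires qrs_duration >= 0.12 s")
  if ("AF" %in% lab) {
    if (rhythm$p_present) err("AF requires absent P waves")
    if (rhythm$rr_cv < 0.15) err("AF requires rr_cv >= 0.15")
    if (is.null(rhythm$fib_wave)) err("AF requires a fibrillatory wave")
  }
  invisible(TRUE)
}

#' Inject an abnormality into a rhythm/beat specification
#'
#' Modifies a `rhythm_spec` + `beat_model` pair so that the generated
#' tracing carries one of the six supported abnormalities. Parameter
#' values are sampled within textbook ranges: 1dAVb prolongs PR into
#' \[0.21, 0.36\] s; RBBB/LBBB widen the QRS into \[0.12, 0.16\] s with
#' opposite V1/V6 morphologies (RBBB: dominant V1 R wave and deep V6 S;
#' LBBB: deep V1 S and dominant V6 R); SB draws heart rate in \[40, 55\]
#' bpm and ST in \[101, 150\] bpm; AF removes P waves, makes RR intervals
#' irregular (CV in \[0.15, 0.30\]) and adds a 4-9 Hz fibrillatory wave.
#'
#' @param rhythm A [rhythm_spec()].
#' @param beats A [beat_model()].
#' @param label One of [ECG_ABNORMALITIES].
#' @return `list(rhythm =, beats =)` with the label appended.
#' @examples
#' mod <- apply_abnormality(rhythm_spec(), beat_model(), "SB")
#' mod$rhythm$heart_rate
#' @export
apply_abnormality <- function(rhythm, beats, label) {
  stopifnot(inherits(rhythm, "rhythm_spec"), inherits(beats, "beat_model"))
  if (!is.character(label) || length(label) != 1L || !label %in% ECG_ABNORMALITIES)
    stop("unknown abnormality label: ", paste(label, collapse = ", "))
  if (label %in% c("SB", "ST") &&
      any(c("SB", "ST") %in% rhythm$labels))
    stop("SB and ST are mutually exclusive rhythm labels")
  mix <- beats$lead_mixing
  if (label == "1dAVb") {
    rhythm$pr_interval <- stats::runif(1, 0.21, 0.36)
  } else if (label == "RBBB") {
    rhythm$qrs_duration <- max(rhythm$qrs_duration, stats::runif(1, 0.12, 0.16))
    mix["V1", "R"] <- 1.30; mix["V1", "S"] <- 0.40
    mix["V6", "R"] <- 0.60; mix["V6", "S"] <- 1.30
  } else if (label == "LBBB") {
    rhythm$qrs_duration <- max(rhythm$qrs_duration, stats::runif(1, 0.12, 0.16))
    mix["V1", "R"] <- 0.10; mix["V1", "S"] <- 1.90
    mix["V6", "R"] <- 1.40; mix["V6", "S"] <- 0.10
  } else if (label == "SB") {
    rhythm$heart_rate <- stats::runif(1, 40, 55)
  } else if (label == "ST") {
    rhythm$heart_rate <- stats::runif(1, 101, 150)
  } else if (label == "AF") {
    rhythm$p_present <- FALSE
    rhythm$rr_cv <- max(rhythm$rr_cv, stats::runif(1, 0.15, 0.30))
    rhythm$fib_wave <- c(stats::runif(1, 0.05, 0.10), stats::runif(1, 4, 9))
  }
  beats$lead_mixing <- mix
  rhythm$labels <- union(rhythm$labels, label)
  list(rhythm = rhythm, beats = beats)
}
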