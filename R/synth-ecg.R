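# Beat geometry conventions shared by the generator and the rule-based
# measurer: Q/R/S centres and widths scale with qrs_duration relative to
# a 90 ms reference; the designed QRS onset is mu_Q - 2*sigma_Q (scaled)
# and the P wave is placed so that (QRS onset - P onset at 2 sigma)
# equals the rhythm's PR interval.
QRS_REF <- 0.09

# evaluate seeded code without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# derive a per-subject stream from one global seed (counter split),
# keeping results in 32-bit integer range
split_seed <- function(seed, counter) {
  as.integer((as.double(seed) * 48271 + counter * 16807) %% 2147483647)
}

#' Synthesize a 12-lead ECG tracing
#'
#' Builds a beat train as a sum of Gaussian waves per lead, with RR
#' intervals drawn at the rhythm's mean rate and coefficient of
#' variation, optional fibrillatory oscillation (AF), pink baseline
#' wander and white noise at a configurable signal-to-noise ratio.
#' Deterministic given `seed`.
#'
#' @param rhythm A [rhythm_spec()].
#' @param beats A [beat_model()].
#' @param fs Sampling rate in Hz (supported range 100-1000).
#' @param duration Record length in seconds; must cover at least 2 beats.
#' @param seed Optional integer seed; the caller's RNG state is restored.
#' @param snr_db Signal-to-noise ratio of the additive white noise in dB;
#'   `Inf` disables it.
#' @param wander Add low-frequency baseline wander?
#' @param exam_id Integer id for the returned record.
#' @return An [ecg_record()].
#' @examples
#' rec <- synth_ecg(rhythm_spec(heart_rate = 60, rr_cv = 0), beat_model(),
#'                  fs = 200, duration = 10, seed = 1)
#' @export
synth_ecg <- function(rhythm, beats, fs = 400, duration = 10.24, seed = NULL,
                      snr_db = 20, wander = TRUE, exam_id = 1L) {
  stopifnot(inherits(rhythm, "rhythm_spec"), inherits(beats, "beat_model"))
  if (duration <= 0) stop("duration must be positive")
  if (fs < 100 || fs > 1000) stop("fs must lie in [100, 1000] Hz")
  if (duration < 2 * 60 / rhythm$heart_rate)
    stop("duration must cover at least 2 beats at the given heart rate")
  check_rhythm_labels(rhythm)
  with_seed(seed, {
    Tn <- round(fs * duration)
    tt <- (seq_len(Tn) - 1) / fs
    rr_mean <- 60 / rhythm$heart_rate
    r_times <- numeric(0)
    t <- 0.5 * rr_mean
    while (t < duration) {
      r_times <- c(r_times, t)
      step <- if (rhythm$rr_cv > 0)
        rr_mean * max(0.35, stats::rnorm(1, 1, rhythm$rr_cv)) else rr_mean
      t <- t + step
    }
    scale <- rhythm$qrs_duration / QRS_REF
    amp <- beats$amplitude; ctr <- beats$center; wid <- beats$width
    qrs_onset <- (ctr["Q"] - 2 * wid["Q"]) * scale
    p_center <- qrs_onset - rhythm$pr_interval + 2 * wid["P"]
    sig <- matrix(0, 12L, Tn)
    waves <- c("P", "Q", "R", "S", "T", "U")
    for (l in seq_len(12L)) {
      x <- numeric(Tn)
      for (w in waves) {
        if (w == "P" && !rhythm$p_present) next
        a <- amp[[w]] * beats$lead_mixing[l, w]
        if (a == 0) next
        if (w %in% c("Q", "R", "S")) {
          mu <- ctr[[w]] * scale; sg <- wid[[w]] * scale
        } else if (w == "P") {
          mu <- p_center
          sg <- wid[[w]] * if (ECG_LEADS[l] == "DII") beats$p_width_dii else 1
        } else {
          mu <- ctr[[w]]; sg <- wid[[w]]
        }
        for (rt in r_times) {
          c0 <- rt + mu
          i0 <- max(1L, floor((c0 - 4.5 * sg) * fs) + 1L)
          i1 <- min(Tn, ceiling((c0 + 4.5 * sg) * fs) + 1L)
          if (i0 > i1) next
          idx <- i0:i1
          x[idx] <- x[idx] + a * exp(-(tt[idx] - c0)^2 / (2 * sg^2))
        }
      }
      sig[l, ] <- x
    }
    if (!is.null(rhythm$fib_wave)) {
      phi <- stats::runif(1, 0, 2 * pi)
      fib <- rhythm$fib_wave[1] * sin(2 * pi * rhythm$fib_wave[2] * tt + phi)
      sig <- sig + abs(beats$lead_mixing[, "P"]) %o% fib
    }
    if (wander) {
      for (l in seq_len(12L)) {
        f <- stats::runif(3, 0.05, 0.4)
        ph <- stats::runif(3, 0, 2 * pi)
        a <- 0.015 / sqrt(f / 0.1)   # pink-ish: more power at lower frequency
        for (k in 1:3) sig[l, ] <- sig[l, ] + a[k] * sin(2 * pi * f[k] * tt + ph[k])
      }
    }
    if (is.finite(snr_db)) {
      nsd <- sqrt(mean(sig^2) / 10^(snr_db / 10))
      sig <- sig + matrix(stats::rnorm(length(sig), 0, nsd), 12L)
    }
    ecg_record(sig, fs, exam_id)
  })
}

#' Planted saliency ground truth
#'
#' Describes a windowed sinusoidal transient added to one lead of a
#' record: the ground truth against which the saliency procedure is
#' validated.
#'
#' @param lead Lead name or index (1-12).
#' @param t0,t1 Window start/end in seconds, `0 <= t0 < t1`.
#' @param amplitude Transient amplitude, mV.
#' @param frequency Transient frequency, Hz.
#' @param taper Cosine-taper fraction applied at each window edge.
#' @return An object of class `planted_saliency`.
#' @export
planted_saliency <- function(lead, t0, t1, amplitude = 0.4, frequency = 30,
                             taper = 0.2) {
  if (is.character(lead)) lead <- match(lead, ECG_LEADS)
  if (is.na(lead) || lead < 1 || lead > 12) stop("invalid lead")
  if (!(t0 >= 0 && t0 < t1)) stop("window must satisfy 0 <= t0 < t1")
  if (taper < 0 || taper > 0.5) stop("taper fraction must lie in [0, 0.5]")
  structure(list(lead = as.integer(lead), t0 = t0, t1 = t1,
                 amplitude = amplitude, frequency = frequency, taper = taper),
            class = "planted_saliency")
}

#' Plant a windowed transient into one ECG lead
#'
#' Adds a cosine-tapered sinusoid to a single lead over a time window,
#' leaving every other sample untouched. Disjoint plants are additive and
#' order-independent.
#'
#' @param record An [ecg_record()].
#' @param planted A [planted_saliency()].
#' @return The modified [ecg_record()].
#' @examples
#' rec <- ecg_record(matrix(0, 12, 1200), fs = 400)
#' out <- plant_signal(rec, planted_saliency("V1", 1, 2))
#' range(which(out$signal["V1", ] != 0)) / 400
#' @export
plant_signal <- function(record, planted) {
  stopifnot(inherits(record, "ecg_record"), inherits(planted, "planted_saliency"))
  dur <- ncol(record$signal) / record$fs
  if (planted$t1 > dur + 1e-9) stop("planted window exceeds record duration")
  fs <- record$fs
  i0 <- floor(planted$t0 * fs) + 1L
  i1 <- ceiling(planted$t1 * fs)
  i1 <- min(i1, ncol(record$signal))
  if (i0 > i1) stop("planted window contains no samples")
  u <- (seq(i0, i1) - 1) / fs - planted$t0
  w <- planted$t1 - planted$t0
  env <- rep(1, length(u))
  p <- planted$taper
  if (p > 0) {
    fr <- u / w
    left <- fr < p
    right <- fr > 1 - p
    env[left] <- 0.5 * (1 - cos(pi * fr[left] / p))
    env[right] <- 0.5 * (1 - cos(pi * (1 - fr[right]) / p))
  }
  record$signal[planted$lead, i0:i1] <- record$signal[planted$lead, i0:i1] +
    planted$amplitude * env * sin(2 * pi * planted$frequency * u)
  record
}
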