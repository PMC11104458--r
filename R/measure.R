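#' Rule-based ECG interval measurement
#'
#' A deliberately simple, deterministic measurer used to validate the
#' generator: threshold R-peak detection on lead DII, RR statistics,
#' QRS onset/offset by walking outward from the R peak until the signal
#' falls below 5% of the R amplitude, P-wave search in a fixed window
#' before the QRS onset, and the PR interval from the two onsets.
#' Designed for noise-free synthetic records; it is scaffolding, not a
#' clinical delineator.
#'
#' @param record An [ecg_record()].
#' @return List with `r_peaks` (sample indices), `heart_rate` (bpm),
#'   `rr_cv`, `qrs_width` (s), `pr_interval` (s or `NA`), `p_present`
#'   (logical) and `v1_positive` (dominant QRS polarity in V1).
#' @examples
#' rec <- synth_ecg(rhythm_spec(heart_rate = 60, rr_cv = 0), beat_model(),
#'                  fs = 400, duration = 10, snr_db = Inf, wander = FALSE)
#' measure_ecg(rec)$heart_rate
#' @export
measure_ecg <- function(record) {
  stopifnot(inherits(record, "ecg_record"))
  s <- record$signal["DII", ]
  fs <- record$fs
  r <- find_r_peaks(s, fs)
  if (length(r) < 2L) stop("fewer than two R peaks detected")
  rr <- diff(r) / fs
  hr <- 60 / mean(rr)
  rr_cv <- if (length(rr) >= 3L) stats::sd(rr) / mean(rr) else 0
  # measure morphology on a mid-record beat with full neighbourhood.
  # QRS boundaries are slope-based: the QRS flanks are an order of
  # magnitude steeper than T waves or fibrillatory oscillation, so the
  # outermost steep-slope excursion around the R peak delimits the
  # complex robustly even when adjacent waves merge at high rates.
  mid <- r[ceiling(length(r) / 2)]
  d <- diff(s) * fs
  w <- max(1L, mid - round(0.1 * fs)):min(length(d), mid + round(0.1 * fs))
  dthr <- 0.25 * max(abs(d[w]))
  i <- mid - 1L
  while (i > 1L && abs(d[i]) < dthr) i <- i - 1L   # climb onto the left flank
  while (i > 1L && abs(d[i]) >= dthr) i <- i - 1L  # and exit it
  onset <- i + 1L
  j <- mid
  while (j < length(d) && abs(d[j]) < dthr) j <- j + 1L
  while (j < length(d) && abs(d[j]) >= dthr) j <- j + 1L
  offset <- j
  qrs_width <- (offset - onset) / fs
  # P search window before the QRS onset
  w0 <- max(1L, onset - round(0.32 * fs))
  w1 <- max(1L, onset - round(0.02 * fs))
  p_present <- FALSE
  pr <- NA_real_
  if (w1 > w0) {
    win <- s[w0:w1]
    pk <- which.max(abs(win))
    if (abs(win[pk]) >= 0.06) {
      p_present <- TRUE
      j <- pk
      while (j > 1L && abs(win[j - 1L]) >= 0.03) j <- j - 1L
      pr <- (onset - (w0 + j - 1L)) / fs
    }
  }
  v1 <- record$signal["V1", onset:offset]
  list(r_peaks = r, heart_rate = hr, rr_cv = rr_cv, qrs_width = qrs_width,
       pr_interval = pr, p_present = p_present,
       v1_positive = max(v1) >= -min(v1))
}

# threshold peak finder: local maxima above half the global maximum,
# with a 0.2 s refractory window
find_r_peaks <- function(s, fs) {
  thr <- 0.5 * max(s)
  n <- length(s)
  cand <- which(s > thr &
                  s >= c(-Inf, s[-n]) &
                  s >= c(s[-1], -Inf))
  if (!length(cand)) return(integer(0))
  keep <- cand[1]
  for (k in cand[-1]) {
    if (k - keep[length(keep)] > 0.2 * fs) keep <- c(keep, k)
    else if (s[k] > s[keep[length(keep)]]) keep[length(keep)] <- k
  }
  keep
}

#' Classify rhythm abnormalities from measurements
#'
#' Maps [measure_ecg()] output to the six supported labels using
#' thresholds calibrated to the generator's beat geometry (the
#' measurement-domain equivalents of the textbook rules PR > 200 ms,
#' QRS >= 120 ms, rate < 60 / > 100 bpm, irregular RR without P waves).
#'
#' @param meas Output of [measure_ecg()].
#' @return Character vector of recovered labels (possibly empty).
#' @export
classify_rhythm <- function(meas) {
  labs <- character(0)
  af <- meas$rr_cv > 0.07
  if (af) labs <- c(labs, "AF")
  if (!af && meas$heart_rate < 59) labs <- c(labs, "SB")
  if (!af && meas$heart_rate > 99) labs <- c(labs, "ST")
  # PR is not assessable at tachycardic rates with this simple
  # delineator (the preceding T wave merges into the P window)
  if (!af && meas$heart_rate <= 99 &&
      !is.na(meas$pr_interval) && meas$pr_interval > 0.2)
    labs <- c(labs, "1dAVb")
  if (meas$qrs_width > 0.098)
    labs <- c(labs, if (meas$v1_positive) "RBBB" else "LBBB")
  labs
}
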