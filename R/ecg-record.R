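#' Standard 12-lead order
#'
#' The fixed lead order used throughout the package: limb leads DI, DII,
#' DIII, augmented leads AVR, AVL, AVF, then precordial leads V1-V6.
#' All signal matrices are stored with one row per lead in this order.
#'
#' @format Character vector of length 12.
#' @export
ECG_LEADS <- c("DI", "DII", "DIII", "AVR", "AVL", "AVF",
               "V1", "V2", "V3", "V4", "V5", "V6")

#' The six supported rhythm/conduction abnormalities
#'
#' First-degree atrioventricular block (1dAVb), right and left bundle
#' branch block (RBBB/LBBB), sinus bradycardia (SB), atrial fibrillation
#' (AF) and sinus tachycardia (ST).
#'
#' @format Character vector of length 6.
#' @export
ECG_ABNORMALITIES <- c("1dAVb", "RBBB", "LBBB", "SB", "AF", "ST")

#' Construct an ECG record
#'
#' A single multichannel ECG tracing: a 12 x T matrix of lead voltages in
#' millivolt together with its sampling rate. Rows must follow the fixed
#' lead order [ECG_LEADS].
#'
#' @param signal Numeric matrix, 12 rows (leads) by T columns (samples), mV.
#' @param fs Sampling rate in Hz.
#' @param exam_id Integer identifier.
#' @return An object of class `ecg_record` with fields `exam_id`, `signal`,
#'   `fs` and `lead_names`.
#' @examples
#' rec <- ecg_record(matrix(0, 12, 400), fs = 400)
#' dim(rec$signal)
#' @export
ecg_record <- function(signal, fs, exam_id = 1L) {
  signal <- as.matrix(signal)
  if (nrow(signal) != 12L)
    stop("an ECG record must have exactly 12 lead rows, got ", nrow(signal))
  if (!all(is.finite(signal)))
    stop("ECG samples must all be finite")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("'fs' must be a positive sampling rate in Hz")
  rownames(signal) <- ECG_LEADS
  structure(
    list(exam_id = as.integer(exam_id), signal = signal, fs = fs,
         lead_names = ECG_LEADS),
    class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record #%d> 12 x %d samples @ %g Hz (%.2f s), range [%.2f, %.2f] mV\n",
              x$exam_id, ncol(x$signal), x$fs, ncol(x$signal) / x$fs,
              min(x$signal), max(x$signal)))
  invisible(x)
}

#' Plot an ECG record
#'
#' Stacked per-lead traces, optionally overlaid with a saliency heatmap.
#'
#' @param x An `ecg_record`.
#' @param leads Leads to draw (names or indices); default all 12.
#' @param heatmap Optional `ecg_heatmap` (see [explain()]) to overlay as
#'   colour intensity under each trace.
#' @param threshold Heatmap values below this are not drawn (display only).
#' @param ... Unused.
#' @export
plot.ecg_record <- function(x, leads = ECG_LEADS, heatmap = NULL,
                            threshold = 0, ...) {
  if (is.numeric(leads)) leads <- ECG_LEADS[leads]
  leads <- match.arg(leads, ECG_LEADS, several.ok = TRUE)
  tt <- seq_len(ncol(x$signal)) / x$fs
  sep <- 2 * max(0.5, stats::quantile(abs(x$signal), 0.999))
  n <- length(leads)
  graphics::plot(NULL, xlim = range(tt), ylim = c(-sep / 2, (n - 0.5) * sep),
                 xlab = "time (s)", ylab = "", yaxt = "n")
  graphics::axis(2, at = (rev(seq_len(n)) - 1) * sep, labels = leads, las = 1)
  for (i in seq_along(leads)) {
    l <- leads[i]
    off <- (n - i) * sep
    if (!is.null(heatmap)) {
      h <- heatmap$values[l, ]
      hot <- which(h > threshold)
      if (length(hot))
        graphics::points(tt[hot], x$signal[l, hot] + off, pch = 16, cex = 0.4,
                         col = grDevices::rgb(1, 0, 0, pmin(1, h[hot])))
    }
    graphics::lines(tt, x$signal[l, ] + off, lwd = 0.6)
  }
  invisible(x)
}
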