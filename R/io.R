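#' Write a dataset bundle
#'
#' Persists tracings and subject metadata as a plain-text bundle:
#' `tracings.csv.gz` (one row per exam: exam_id then the lead-major
#' flattened 12 x T signal in mV), `meta.csv` (the subject table) and
#' `manifest.json` (counts, T, fs, lead order and md5 content hashes).
#'
#' @param records List of [ecg_record()].
#' @param subjects Metadata data frame with an `exam_id` column.
#' @param path Directory to create/write into.
#' @return The manifest, invisibly.
#' @export
write_dataset <- function(records, subjects, path) {
  if (length(records) == 0L) stop("empty record list")
  ids <- vapply(records, function(r) r$exam_id, 0L)
  if (anyDuplicated(ids)) stop("duplicate exam_id in records")
  if (!setequal(ids, subjects$exam_id))
    stop("exam_id sets in records and metadata differ")
  fs <- unique(vapply(records, function(r) r$fs, 0))
  Tn <- unique(vapply(records, function(r) ncol(r$signal), 0L))
  if (length(fs) != 1L || length(Tn) != 1L)
    stop("all records must share one sampling rate and length")
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  mat <- t(vapply(records, function(r) as.numeric(t(r$signal)),
                  numeric(12L * Tn)))
  tr_path <- file.path(path, "tracings.csv.gz")
  con <- gzfile(tr_path, "w")
  utils::write.csv(data.frame(exam_id = ids, mat), con, row.names = FALSE)
  close(con)
  meta_path <- file.path(path, "meta.csv")
  utils::write.csv(subjects, meta_path, row.names = FALSE)
  manifest <- list(n = length(records), T = Tn, fs = fs,
                   lead_order = ECG_LEADS,
                   hashes = list(
                     tracings = unname(tools::md5sum(tr_path)),
                     meta = unname(tools::md5sum(meta_path))))
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Read a dataset bundle
#'
#' Validates the manifest (content hashes, lead order, required
#' metadata columns) and reconstructs the records. Optionally resamples
#' tracings to a new rate by linear interpolation and pads/truncates to
#' a fixed length (padding with zeros).
#'
#' @param path Bundle directory from [write_dataset()].
#' @param fs_out Optional target sampling rate, Hz.
#' @param length_out Optional target length in samples.
#' @return `list(records =, subjects =, manifest =)`.
#' @export
read_dataset <- function(path, fs_out = NULL, length_out = NULL) {
  man_path <- file.path(path, "manifest.json")
  if (!file.exists(man_path)) stop("format error: missing manifest.json")
  manifest <- jsonlite::read_json(man_path, simplifyVector = TRUE)
  for (key in c("n", "T", "fs", "lead_order", "hashes"))
    if (is.null(manifest[[key]]))
      stop("format error: manifest key missing: ", key)
  if (!identical(as.character(manifest$lead_order), ECG_LEADS))
    stop("format error: lead_order does not match the 12-lead convention")
  tr_path <- file.path(path, "tracings.csv.gz")
  meta_path <- file.path(path, "meta.csv")
  for (f in c(tr_path, meta_path))
    if (!file.exists(f)) stop("format error: missing file ", basename(f))
  if (!identical(unname(tools::md5sum(tr_path)), manifest$hashes$tracings) ||
      !identical(unname(tools::md5sum(meta_path)), manifest$hashes$meta))
    stop("format error: content hash mismatch (bundle modified?)")
  subjects <- utils::read.csv(meta_path, check.names = FALSE)
  required <- c("exam_id")
  miss <- setdiff(required, names(subjects))
  if (length(miss))
    stop("format error: missing metadata column(s): ",
         paste(miss, collapse = ", "))
  raw <- utils::read.csv(gzfile(tr_path), check.names = FALSE)
  Tn <- manifest$T
  fs <- manifest$fs
  records <- vector("list", nrow(raw))
  for (i in seq_len(nrow(raw))) {
    sig <- matrix(as.numeric(raw[i, -1]), nrow = 12L, byrow = TRUE)
    if (!is.null(fs_out) && fs_out != fs) {
      new_T <- round(Tn * fs_out / fs)
      t_old <- (seq_len(Tn) - 1) / fs
      t_new <- (seq_len(new_T) - 1) / fs_out
      sig <- t(apply(sig, 1, function(row)
        stats::approx(t_old, row, xout = t_new, rule = 2)$y))
    }
    if (!is.null(length_out)) {
      cur <- ncol(sig)
      if (cur >= length_out) sig <- sig[, seq_len(length_out)]
      else sig <- cbind(sig, matrix(0, 12L, length_out - cur))
    }
    records[[i]] <- ecg_record(sig, if (is.null(fs_out)) fs else fs_out,
                               raw$exam_id[i])
  }
  if (!setequal(raw$exam_id, subjects$exam_id))
    stop("format error: exam_id sets in tracings and metadata differ")
  list(records = records, subjects = subjects, manifest = manifest)
}

#' Export heatmaps
#'
#' Writes one CSV per record (`heatmap_<id>.csv`, columns lead, sample,
#' value) or a single RDS file holding the list.
#'
#' @param heatmaps List of `ecg_heatmap` objects.
#' @param ids Vector of exam ids aligned with `heatmaps`.
#' @param path Output directory (csv) or file (rds).
#' @param format `"csv"` or `"rds"`.
#' @return Invisibly, the written file paths.
#' @export
export_heatmaps <- function(heatmaps, ids, path, format = c("csv", "rds")) {
  format <- match.arg(format)
  if (length(heatmaps) != length(ids))
    stop("heatmaps and ids are misaligned")
  if (format == "rds") {
    names(heatmaps) <- as.character(ids)
    saveRDS(heatmaps, path)
    return(invisible(path))
  }
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  files <- character(length(ids))
  for (i in seq_along(ids)) {
    v <- heatmaps[[i]]$values
    df <- data.frame(lead = rep(rownames(v), each = ncol(v)),
                     sample = rep(seq_len(ncol(v)), nrow(v)),
                     value = as.numeric(t(v)))
    files[i] <- file.path(path, sprintf("heatmap_%s.csv", ids[i]))
    utils::write.csv(df, files[i], row.names = FALSE)
  }
  invisible(files)
}

#' Import heatmaps written by [export_heatmaps()]
#'
#' @param path Directory of per-record CSVs or an RDS file.
#' @return Named list of heatmap value matrices (or `ecg_heatmap`
#'   objects for RDS input).
#' @export
import_heatmaps <- function(path) {
  if (file.exists(path) && !dir.exists(path)) return(readRDS(path))
  files <- list.files(path, pattern = "^heatmap_.*\\.csv$", full.names = TRUE)
  if (!length(files)) stop("no heatmap CSVs found under ", path)
  out <- lapply(files, function(f) {
    df <- utils::read.csv(f)
    leads <- unique(df$lead)
    v <- matrix(df$value, nrow = length(leads), byrow = TRUE,
                dimnames = list(leads, NULL))
    v
  })
  names(out) <- sub("^heatmap_(.*)\\.csv$", "\\1", basename(files))
  out
}
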