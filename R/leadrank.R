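#' Records with confident predictions
#'
#' Indices of records whose predicted probability is strictly greater
#' than the confidence threshold (default 0.8).
#'
#' @param probabilities Numeric vector of probabilities in \[0, 1\].
#' @param tau Threshold in \[0, 1\].
#' @return Integer vector of record indices (possibly empty).
#' @examples
#' confident_subset(c(0.79, 0.80, 0.81))
#' @export
confident_subset <- function(probabilities, tau = 0.8) {
  if (!is.numeric(tau) || length(tau) != 1L || tau < 0 || tau > 1)
    stop("tau must lie in [0, 1]")
  if (any(probabilities < 0 | probabilities > 1, na.rm = TRUE))
    stop("probabilities must lie in [0, 1]")
  which(probabilities > tau)
}

#' Total heatmap mass per lead
#'
#' Sums the heatmap values over time within each lead.
#'
#' @param heatmap An `ecg_heatmap` from [explain()] (or a bare L x T
#'   matrix with lead rownames).
#' @return Named nonnegative vector, one entry per lead.
#' @export
lead_mass <- function(heatmap) {
  v <- if (inherits(heatmap, "ecg_heatmap")) heatmap$values else as.matrix(heatmap)
  rowSums(v)
}

#' Dominant lead of a recording
#'
#' The lead with the largest heatmap mass. Ties break to the lowest
#' lead index in the fixed lead order; an all-zero mass vector has no
#' dominant lead and returns `NA` (such records are excluded from
#' distributions).
#'
#' @param mass Named nonnegative vector from [lead_mass()].
#' @return Lead name, or `NA_character_`.
#' @export
dominant_lead <- function(mass) {
  if (any(mass < 0)) stop("lead mass must be nonnegative")
  if (all(mass == 0)) return(NA_character_)
  nm <- names(mass)
  if (is.null(nm)) nm <- paste0("L", seq_along(mass))
  nm[which.max(mass)]
}

#' Distribution of dominant leads over a dataset
#'
#' For every record predicted with probability strictly above `tau` for
#' the chosen label, computes the saliency heatmap, its per-lead mass
#' and the dominant lead, then tabulates occurrences and percentages
#' across the leads. Dispersion is estimated by resampling the confident
#' records with replacement `B` times and recomputing the counts.
#'
#' @param model A fitted [ecgnet()].
#' @param x Dataset (n x L x T array or list of [ecg_record()]).
#' @param label Label index or name.
#' @param tau Confidence threshold (strictly-greater comparison).
#' @param B Bootstrap replicates.
#' @param seed Seed for the bootstrap.
#' @return An object of class `dominant_lead_distribution`: a data frame
#'   with columns lead, count, percent, boot_mean, boot_sd, plus fields
#'   `n_confident`, `label`, `B`.
#' @export
dominant_distribution <- function(model, x, label = 1L, tau = 0.8,
                                  B = 1000, seed = 1L) {
  stopifnot(inherits(model, "ecgnet"))
  cfg <- model$config
  lab <- resolve_label(cfg, label)
  probs <- predict(model, x)[, lab]
  if (length(probs) == 0L) stop("dataset is empty")
  conf <- confident_subset(probs, tau)
  if (length(conf) == 0L)
    stop("empty distribution: no record has probability > ", tau,
         " for label ", cfg$labels[lab])
  doms <- character(length(conf))
  for (j in seq_along(conf)) {
    rec <- if (is.list(x)) x[conf[j]] else x[conf[j], , , drop = FALSE]
    hm <- explain(model, rec, label = lab)
    doms[j] <- dominant_lead(lead_mass(hm))
  }
  defined <- !is.na(doms)
  doms <- doms[defined]
  leads <- lead_names_of(cfg)
  counts <- table(factor(doms, levels = leads))
  boot <- with_seed(seed, {
    replicate(B, {
      res <- doms[sample.int(length(doms), replace = TRUE)]
      as.numeric(table(factor(res, levels = leads)))
    })
  })
  out <- data.frame(lead = leads, count = as.numeric(counts),
                    percent = 100 * as.numeric(counts) / sum(counts),
                    boot_mean = rowMeans(boot),
                    boot_sd = apply(boot, 1, stats::sd))
  structure(out, class = c("dominant_lead_distribution", "data.frame"),
            n_confident = sum(defined), label = cfg$labels[lab], B = B)
}

#' @export
print.dominant_lead_distribution <- function(x, ...) {
  cat(sprintf("Dominant-lead distribution for label '%s' (%d confident records, B = %d)\n",
              attr(x, "label"), attr(x, "n_confident"), attr(x, "B")))
  df <- as.data.frame(x)
  df$percent <- sprintf("%.1f%%", df$percent)
  df$occurrences <- sprintf("%.1f +/- %.1f", df$boot_mean, df$boot_sd)
  print(df[c("lead", "count", "percent", "occurrences")], row.names = FALSE)
  invisible(x)
}

#' Select a reduced lead subset from a dominant-lead distribution
#'
#' Leads whose dominant-lead percentage is strictly above the threshold
#' (default 10%), ordered by descending percentage.
#'
#' @param dist A [dominant_distribution()] result.
#' @param threshold Percentage threshold.
#' @return Character vector of lead names (warns when empty).
#' @export
select_lead_subset <- function(dist, threshold = 10) {
  df <- as.data.frame(dist)
  sel <- df[df$percent > threshold, , drop = FALSE]
  if (nrow(sel) == 0L) {
    warning("no lead exceeds ", threshold, "% of dominant-lead occurrences")
    return(character(0))
  }
  sel$lead[order(sel$percent, decreasing = TRUE)]
}

#' Train a reduced-lead model
#'
#' Builds a fresh network with one isolated encoder per selected lead
#' and trains it from scratch on those leads only (retraining, not
#' zero-masking of the 12-lead model). With all 12 leads the
#' architecture is identical to the standard model.
#'
#' @param x 12-lead dataset (n x 12 x T array or list of records).
#' @param y Labels as in [ecgnet()].
#' @param subset Character vector of lead names (subset of [ECG_LEADS]).
#' @param config Optional template [ecgnet_config()]; its width/depth
#'   settings are reused with `n_leads = length(subset)`.
#' @param ... Passed on to [ecgnet()] (epochs, seed, ...).
#' @return A fitted `ecgnet` whose config records the lead subset.
#' @export
reduced_lead_train <- function(x, y, subset, config = NULL, ...) {
  if (length(subset) < 1L) stop("lead subset must be nonempty")
  bad <- setdiff(subset, ECG_LEADS)
  if (length(bad)) stop("unknown lead name(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(subset)) stop("lead subset must be unique")
  if (is.array(x) && length(dim(x)) == 3L) {
    if (dim(x)[2] != 12L) stop("reduced_lead_train expects 12-lead input")
    x <- x[, match(subset, ECG_LEADS), , drop = FALSE]
    Tn <- dim(x)[3]
  } else {
    Tn <- ncol(x[[1]]$signal)
  }
  if (is.null(config)) {
    cfg <- ecgnet_config(n_leads = length(subset), input_length = Tn,
                         lead_names = subset)
  } else {
    cfg <- config
    cfg$n_leads <- length(subset)
    cfg$lead_names <- subset
  }
  ecgnet(x, y, config = cfg, ...)
}

#' Zero-mask leads outside a subset
#'
#' Ablation alternative to [reduced_lead_train()]: keeps the 12-lead
#' model but silences all leads outside `subset` (zero after the
#' model's per-lead standardization, i.e. each masked lead is pinned at
#' its training mean). Measures the fitted model's reliance on the
#' masked leads rather than the leads' information content.
#'
#' @param x n x 12 x T array or list of [ecg_record()].
#' @param subset Lead names to keep.
#' @param model Optional `ecgnet`; when given, masked leads are set to
#'   the model's stored per-lead training mean instead of raw zero.
#' @return The masked n x 12 x T array.
#' @export
mask_leads <- function(x, subset, model = NULL) {
  bad <- setdiff(subset, ECG_LEADS)
  if (length(bad)) stop("unknown lead name(s): ", paste(bad, collapse = ", "))
  if (is.list(x) && !inherits(x, "ecg_record")) {
    Tn <- ncol(x[[1]]$signal)
    arr <- array(0, c(length(x), 12L, Tn))
    for (i in seq_along(x)) arr[i, , ] <- x[[i]]$signal
    x <- arr
  }
  drop_leads <- which(!ECG_LEADS %in% subset)
  for (l in drop_leads)
    x[, l, ] <- if (is.null(model)) 0 else model$norm$mean[l]
  x
}
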