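#' Gradient of a label's logit with respect to the feature matrix
#'
#' Backpropagates the chosen label's pre-sigmoid logit through the
#' integration trunk only, yielding one gradient value per entry of the
#' concatenated per-lead feature matrix.
#'
#' @param model A fitted [ecgnet()].
#' @param x A single record (as in [encode_isolated()]).
#' @param label Label index or name.
#' @param target `"logit"` (default) or `"prob"`; the probability target
#'   rescales the gradient by `p(1-p)`, which leaves the normalized
#'   heatmap of [explain()] unchanged.
#' @return Matrix (L*C) x T/2 of gradients, with the `block_map`
#'   attribute of the feature matrix.
#' @export
feature_gradients <- function(model, x, label = 1L, target = c("logit", "prob")) {
  stopifnot(inherits(model, "ecgnet"))
  target <- match.arg(target)
  cfg <- model$config
  lab <- resolve_label(cfg, label)
  if (is.matrix(x)) x <- array(x, c(1L, nrow(x), ncol(x)))
  x <- as_input_array(x, cfg)
  if (dim(x)[1] != 1L) stop("feature_gradients takes a single record")
  x <- standardize_input(x, model$norm)
  ef <- encoder_forward(model$params, cfg, x)
  tf <- trunk_forward(model$params, cfg, ef$F, keep_cache = TRUE)
  dlog <- matrix(0, cfg$n_labels, 1)
  dlog[lab, 1] <- 1
  if (target == "prob") {
    p <- 1 / (1 + exp(-tf$logits[lab, 1]))
    dlog[lab, 1] <- p * (1 - p)
  }
  tb <- trunk_backward(model$params, cfg, tf, dlog, param_grads = FALSE)
  G <- matrix(tb$dF, dim(tb$dF)[1], dim(tb$dF)[2])
  attr(G, "block_map") <- rep(seq_len(cfg$n_leads), each = cfg$enc_channels)
  attr(G, "logit") <- tf$logits[lab, 1]
  G
}

resolve_label <- function(cfg, label) {
  if (is.character(label)) {
    lab <- match(label, cfg$labels)
    if (is.na(lab)) stop("unknown label: ", label)
  } else lab <- as.integer(label)
  if (lab < 1L || lab > cfg$n_labels) stop("label index out of range: ", lab)
  lab
}

#' Per-channel kernel weights from averaged gradients
#'
#' One scalar per feature-matrix channel: the arithmetic mean of that
#' channel's gradient over the temporal axis (per recording; no batch
#' averaging).
#'
#' @param grad Gradient matrix from [feature_gradients()].
#' @return Numeric vector, one weight per channel.
#' @export
kernel_weights <- function(grad) {
  grad <- as.matrix(grad)
  if (ncol(grad) == 0L) stop("empty temporal axis")
  if (!all(is.finite(grad))) stop("gradients must be finite")
  rowMeans(grad)
}

#' Weighted, ReLU-filtered class activation map per lead
#'
#' Within each lead's channel block, sums the kernel-weighted feature
#' activations over channels, then applies a ReLU so only positively
#' contributing time points survive.
#'
#' @param features Feature matrix from [encode_isolated()] (must carry a
#'   `block_map` attribute).
#' @param alpha Kernel weights from [kernel_weights()].
#' @return Matrix L x T/2, nonnegative.
#' @export
lead_cam <- function(features, alpha) {
  block_map <- attr(features, "block_map")
  if (is.null(block_map)) stop("features must carry a block_map attribute")
  if (length(alpha) != nrow(features))
    stop("block_map/weight mismatch: ", length(alpha), " weights for ",
         nrow(features), " channels")
  L <- max(block_map)
  raw <- matrix(0, L, ncol(features))
  weighted <- features * alpha
  for (l in seq_len(L))
    raw[l, ] <- colSums(weighted[block_map == l, , drop = FALSE])
  raw * (raw > 0)
}

#' Upsample a raw map to the input's temporal resolution
#'
#' The feature matrix lives at half the input resolution, so alignment
#' is a magnification by exactly 2. Linear interpolation (endpoints
#' preserved) by default; `"nearest"` gives bit-exact block heatmaps.
#'
#' @param raw L x T/2 matrix.
#' @param T Target temporal length (must equal `2 * ncol(raw)`).
#' @param method `"linear"` or `"nearest"`.
#' @return L x T matrix, nonnegative if the input is.
#' @export
align_heatmap <- function(raw, T, method = c("linear", "nearest")) {
  method <- match.arg(method)
  raw <- as.matrix(raw)
  T2 <- ncol(raw)
  if (T != 2L * T2)
    stop("alignment factor must be exactly 2: got T = ", T, " for T/2 = ", T2)
  xout <- seq(1, T2, length.out = T)
  out <- matrix(0, nrow(raw), T)
  for (l in seq_len(nrow(raw))) {
    out[l, ] <- if (T2 == 1L) rep(raw[l, 1L], T)
    else if (method == "linear") stats::approx(seq_len(T2), raw[l, ], xout = xout)$y
    else raw[l, pmin(T2, round(xout))]
  }
  rownames(out) <- rownames(raw)
  out
}

#' Explain a prediction with a per-lead saliency heatmap
#'
#' The full fine-grained interpretation pipeline: logit gradients with
#' respect to the concatenated feature matrix, temporal averaging into
#' per-channel kernel weights, ReLU-filtered weighted sums within each
#' lead's channel block, x2 upsampling to the input resolution, and
#' normalization by the global maximum across all leads (so lead masses
#' are comparable across leads; all-zero maps stay zero).
#'
#' @param model A fitted [ecgnet()].
#' @param x A single record (as in [encode_isolated()]).
#' @param label Label index or name; defaults to the argmax-probability
#'   label of the prediction.
#' @param normalize `"global"` (one shared scale across leads, default)
#'   or `"per_lead"`.
#' @param target,method Passed to [feature_gradients()] / [align_heatmap()].
#' @param ... Unused.
#' @return An object of class `ecg_heatmap`: `values` (L x T in \[0,1\],
#'   rows named by lead), `label`, `probability`.
#' @export
explain <- function(model, x, label = NULL, ...) UseMethod("explain")

#' @rdname explain
#' @export
explain.ecgnet <- function(model, x, label = NULL,
                           normalize = c("global", "per_lead"),
                           target = "logit", method = "linear", ...) {
  normalize <- match.arg(normalize)
  cfg <- model$config
  probs <- predict(model, x)
  if (nrow(probs) != 1L) stop("explain takes a single record")
  if (is.null(label)) label <- which.max(probs[1, ])
  lab <- resolve_label(cfg, label)
  Fm <- encode_isolated(model, x)
  G <- feature_gradients(model, x, lab, target = target)
  alpha <- kernel_weights(G)
  raw <- lead_cam(Fm, alpha)
  hm <- align_heatmap(raw, cfg$input_length, method = method)
  if (normalize == "global") {
    mx <- max(hm)
    if (mx > 0) hm <- hm / mx
  } else {
    for (l in seq_len(nrow(hm))) {
      mx <- max(hm[l, ])
      if (mx > 0) hm[l, ] <- hm[l, ] / mx
    }
  }
  rownames(hm) <- lead_names_of(cfg)
  structure(list(values = hm, label = cfg$labels[lab],
                 probability = unname(probs[1, lab])),
            class = "ecg_heatmap")
}

lead_names_of <- function(cfg) {
  if (!is.null(cfg$lead_names)) cfg$lead_names
  else if (cfg$n_leads == 12L) ECG_LEADS
  else paste0("L", seq_len(cfg$n_leads))
}

#' @export
print.ecg_heatmap <- function(x, ...) {
  m <- rowSums(x$values)
  cat(sprintf("<ecg_heatmap> label %s (p = %.3f), %d x %d, dominant lead %s\n",
              x$label, x$probability, nrow(x$values), ncol(x$values),
              names(which.max(m))))
  invisible(x)
}
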