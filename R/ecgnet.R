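#' Configuration of the isolation-integration network
#'
#' The network has two stages. (1) Isolation: each lead is processed by
#' its own small convolutional encoder (architecture shared, parameters
#' NOT shared), with a single stride-2 layer so the concatenated feature
#' matrix has exactly half the input's temporal length. (2) Integration:
#' the per-lead channel blocks are stacked into an (L*C) x T/2 feature
#' matrix and passed through a residual convolutional trunk with
#' stride-`pool` average pooling, a global average pool and a linear
#' head.
#'
#' @param n_leads Number of input leads L (default 12).
#' @param input_length Temporal length T of the input (must be even).
#' @param enc_channels Channels C produced by each per-lead encoder.
#' @param enc_kernel Encoder kernel size (odd).
#' @param trunk_blocks Number of residual blocks.
#' @param trunk_channels Trunk channel width.
#' @param trunk_kernel Trunk kernel size (odd).
#' @param pool Average-pooling stride after each residual block.
#' @param n_labels Number of output labels (sigmoid per label).
#' @param labels Optional label names.
#' @param lead_names Optional lead names (defaults to the standard
#'   12-lead order when `n_leads == 12`).
#' @param seed Seed for deterministic parameter initialization.
#' @return An object of class `ecgnet_config`.
#' @examples
#' cfg <- ecgnet_config(n_leads = 2, input_length = 64, n_labels = 1)
#' @export
ecgnet_config <- function(n_leads = 12, input_length = 4096,
                          enc_channels = 8, enc_kernel = 17,
                          trunk_blocks = 4, trunk_channels = 16,
                          trunk_kernel = 9, pool = 4,
                          n_labels = 1, labels = NULL, lead_names = NULL,
                          seed = 1L) {
  if (input_length %% 2L != 0L)
    stop("input_length must be even (the encoder downsamples by exactly 2)")
  if (enc_kernel %% 2L == 0L || trunk_kernel %% 2L == 0L)
    stop("kernel sizes must be odd")
  if (n_labels < 1) stop("n_labels must be >= 1")
  if (n_leads < 1) stop("n_leads must be >= 1")
  if (is.null(labels)) labels <- paste0("label", seq_len(n_labels))
  if (length(labels) != n_labels) stop("labels must have length n_labels")
  if (is.null(lead_names) && n_leads == 12) lead_names <- ECG_LEADS
  if (!is.null(lead_names) && length(lead_names) != n_leads)
    stop("lead_names must have length n_leads")
  structure(list(n_leads = as.integer(n_leads),
                 input_length = as.integer(input_length),
                 enc_channels = as.integer(enc_channels),
                 enc_kernel = as.integer(enc_kernel),
                 trunk_blocks = as.integer(trunk_blocks),
                 trunk_channels = as.integer(trunk_channels),
                 trunk_kernel = as.integer(trunk_kernel),
                 pool = as.integer(pool),
                 n_labels = as.integer(n_labels), labels = labels,
                 lead_names = lead_names,
                 seed = as.integer(seed)),
            class = "ecgnet_config")
}

# accept a list of ecg_record, a single record, or an n x L x T array
as_input_array <- function(x, cfg, lead_subset = NULL) {
  leads <- lead_subset
  if (inherits(x, "ecg_record")) x <- list(x)
  if (is.list(x)) {
    n <- length(x)
    if (is.null(leads)) leads <- cfg$lead_names
    if (is.null(leads))
      stop("lead names required to extract a lead subset from records")
    arr <- array(0, c(n, length(leads), cfg$input_length))
    for (i in seq_len(n)) {
      s <- x[[i]]$signal[leads, , drop = FALSE]
      Tn <- ncol(s)
      if (Tn >= cfg$input_length) {
        arr[i, , ] <- s[, seq_len(cfg$input_length)]
      } else {
        arr[i, , seq_len(Tn)] <- s   # zero-pad shorter tracings
      }
    }
    x <- arr
  }
  if (length(dim(x)) != 3L) stop("input must be an n x L x T array or list of ecg_record")
  if (dim(x)[2] != cfg$n_leads)
    stop("input has ", dim(x)[2], " leads but the model expects ", cfg$n_leads)
  if (dim(x)[3] != cfg$input_length)
    stop("input length ", dim(x)[3], " does not match the model's ", cfg$input_length)
  x
}

standardize_input <- function(x, norm) {
  for (l in seq_len(dim(x)[2]))
    x[, l, ] <- (x[, l, ] - norm$mean[l]) / norm$sd[l]
  x
}

bce_loss <- function(logits, y, w_pos) {
  p <- 1 / (1 + exp(-logits))
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -mean(w_pos * y * log(p) + (1 - y) * log(1 - p))
}

#' Fit the isolation-integration ECG network
#'
#' Trains the network of [ecgnet_config()] with binary cross-entropy
#' loss (positive-class weighting `n_neg/n_pos` capped at 20), the Adam
#' optimizer, an internal validation split and early stopping on
#' validation loss; the returned model carries the parameters of the
#' best validation epoch. Inputs are standardized per lead to zero mean
#' and unit variance using training-set statistics, which are stored
#' with the model. Deterministic given `seed` (single-threaded BLAS
#' assumed for bit reproducibility).
#'
#' @param x Training inputs: n x L x T array or list of [ecg_record()].
#' @param y Labels: vector or n x n_labels matrix of 0/1.
#' @param config An [ecgnet_config()] (a default is built from the data
#'   dimensions when omitted).
#' @param epochs Maximum training epochs.
#' @param batch_size Minibatch size.
#' @param lr Adam learning rate.
#' @param val_frac Fraction held out for validation, in (0, 1).
#' @param patience Early-stopping patience (epochs without improvement).
#' @param seed Seed for the split, shuffling and initialization.
#' @param verbose Print per-epoch losses?
#' @return An object of class `ecgnet`: fields `config`, `params`,
#'   `norm` (standardization statistics), `history` (per-epoch train and
#'   validation loss) and `best_epoch`.
#' @seealso [predict.ecgnet()], [explain()], [encode_isolated()]
#' @export
ecgnet <- function(x, y, config = NULL, epochs = 20, batch_size = 32,
                   lr = 1e-3, val_frac = 0.2, patience = 5,
                   seed = 1L, verbose = FALSE) {
  if (is.null(config)) {
    d <- if (is.list(x) && !inherits(x, "ecg_record"))
      c(length(x), 12L, ncol(x[[1]]$signal)) else dim(x)
    config <- ecgnet_config(n_leads = d[2], input_length = d[3], seed = seed)
  }
  stopifnot(inherits(config, "ecgnet_config"))
  if (val_frac <= 0 || val_frac >= 1) stop("val_frac must lie in (0, 1)")
  if (patience < 1) stop("patience must be >= 1")
  x <- as_input_array(x, config)
  y <- as.matrix(y) * 1
  if (nrow(y) != dim(x)[1]) stop("x and y disagree on n")
  if (ncol(y) != config$n_labels) stop("y must have n_labels columns")
  npos <- colSums(y); nneg <- nrow(y) - npos
  if (any(npos == 0) || any(nneg == 0))
    stop("degenerate data: every label needs both classes present")
  w_pos <- pmin(nneg / npos, 20)
  norm <- list(mean = apply(x, 2, mean), sd = pmax(apply(x, 2, stats::sd), 1e-8))
  x <- standardize_input(x, norm)
  n <- dim(x)[1]
  with_seed(seed, {
    params <- init_ecgnet_params(config)
    idx <- sample(n)
    n_val <- max(1L, round(val_frac * n))
    val_idx <- idx[seq_len(n_val)]
    tr_idx <- idx[-seq_len(n_val)]
    state <- list(m = NULL, v = NULL)
    history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                          val_loss = numeric(0))
    best <- Inf; best_params <- params; best_epoch <- 0L; wait <- 0L
    step <- 0L
    wrow <- matrix(w_pos, config$n_labels, 1)
    for (ep in seq_len(epochs)) {
      ord <- sample(tr_idx)
      tl <- 0; nb <- 0L
      for (start in seq(1L, length(ord), by = batch_size)) {
        bidx <- ord[start:min(start + batch_size - 1L, length(ord))]
        xb <- x[bidx, , , drop = FALSE]
        yb <- t(y[bidx, , drop = FALSE])          # n_labels x nb
        ef <- encoder_forward(params, config, xb, keep_cache = TRUE)
        tf <- trunk_forward(params, config, ef$F, keep_cache = TRUE)
        p <- 1 / (1 + exp(-tf$logits))
        # d(weighted BCE)/dlogit, averaged over batch and labels
        dlog <- (p * (1 - yb) - wrow[, rep(1, length(bidx)), drop = FALSE] *
                   yb * (1 - p)) / (length(bidx) * config$n_labels)
        tb <- trunk_backward(params, config, tf, dlog, param_grads = TRUE)
        eg <- encoder_backward(params, config, ef$cache, tb$dF)
        grads <- list(enc = eg, trunk = tb$grads$trunk, head = tb$grads$head)
        step <- step + 1L
        up <- adam_step(params, grads, state, lr, step)
        params <- up$params; state <- up$state
        tl <- tl + bce_loss(tf$logits, yb, wrow[, rep(1, length(bidx))])
        nb <- nb + 1L
      }
      vl <- local({
        xv <- x[val_idx, , , drop = FALSE]
        yv <- t(y[val_idx, , drop = FALSE])
        ef <- encoder_forward(params, config, xv)
        tf <- trunk_forward(params, config, ef$F)
        bce_loss(tf$logits, yv, wrow[, rep(1, length(val_idx))])
      })
      history <- rbind(history, data.frame(epoch = ep, train_loss = tl / nb,
                                           val_loss = vl))
      if (verbose)
        message(sprintf("epoch %2d  train %.4f  val %.4f", ep, tl / nb, vl))
      if (vl < best) {
        best <- vl; best_params <- params; best_epoch <- ep; wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= patience) break
      }
    }
    structure(list(config = config, params = best_params, norm = norm,
                   history = history, best_epoch = best_epoch,
                   val_loss = best),
              class = "ecgnet")
  })
}

# an untrained model (random deterministic initialization); used by the
# architectural tests and as the starting point of ecgnet()
build_ecgnet <- function(config, norm = NULL) {
  stopifnot(inherits(config, "ecgnet_config"))
  if (is.null(norm))
    norm <- list(mean = numeric(config$n_leads), sd = rep(1, config$n_leads))
  structure(list(config = config, params = init_ecgnet_params(config),
                 norm = norm, history = NULL, best_epoch = 0L,
                 val_loss = NA_real_),
            class = "ecgnet")
}

#' Predict label probabilities
#'
#' Deterministic forward pass (no stochastic layers); batch order is
#' preserved and repeated calls give identical outputs.
#'
#' @param object A fitted [ecgnet()].
#' @param x Inputs as in [ecgnet()].
#' @param type `"prob"` for sigmoid probabilities, `"logit"` for
#'   pre-sigmoid scores.
#' @param batch_size Internal chunk size.
#' @param ... Unused.
#' @return n x n_labels matrix with label column names.
#' @export
predict.ecgnet <- function(object, x, type = c("prob", "logit"),
                           batch_size = 64, ...) {
  type <- match.arg(type)
  x <- as_input_array(x, object$config)
  x <- standardize_input(x, object$norm)
  n <- dim(x)[1]
  out <- matrix(NA_real_, n, object$config$n_labels,
                dimnames = list(NULL, object$config$labels))
  for (start in seq(1L, n, by = batch_size)) {
    bidx <- start:min(start + batch_size - 1L, n)
    ef <- encoder_forward(object$params, object$config, x[bidx, , , drop = FALSE])
    tf <- trunk_forward(object$params, object$config, ef$F)
    out[bidx, ] <- t(tf$logits)
  }
  if (type == "prob") 1 / (1 + exp(-out)) else out
}

#' Concatenated per-lead feature matrix
#'
#' Runs only the isolated encoders: the returned matrix stacks each
#' lead's channel block, and block `j` depends exclusively on lead `j`'s
#' samples (the isolation property). Temporal length is exactly T/2.
#'
#' @param model An `ecgnet` (trained or freshly built).
#' @param x One [ecg_record()] or a 1 x L x T / L x T input.
#' @return Matrix (L*C) x T/2 of class `feature_matrix` with attribute
#'   `block_map` (lead index per row).
#' @export
encode_isolated <- function(model, x) {
  stopifnot(inherits(model, "ecgnet"))
  cfg <- model$config
  if (is.matrix(x)) {
    if (nrow(x) != cfg$n_leads) stop("wrong lead count: ", nrow(x))
    x <- array(x, c(1L, nrow(x), ncol(x)))
  }
  x <- as_input_array(x, cfg)
  if (dim(x)[1] != 1L) stop("encode_isolated takes a single record")
  x <- standardize_input(x, model$norm)
  F <- encoder_forward(model$params, cfg, x)$F
  Fm <- matrix(F, dim(F)[1], dim(F)[2])
  attr(Fm, "block_map") <- rep(seq_len(cfg$n_leads), each = cfg$enc_channels)
  class(Fm) <- c("feature_matrix", class(Fm))
  Fm
}

#' @export
print.ecgnet <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<ecgnet> %d-lead isolation-integration network\n", cfg$n_leads))
  cat(sprintf("  encoders: %d x conv(k=%d, C=%d, downsample 2) -> feature matrix %d x %d\n",
              cfg$n_leads, cfg$enc_kernel, cfg$enc_channels,
              cfg$n_leads * cfg$enc_channels, cfg$input_length %/% 2L))
  cat(sprintf("  trunk: %d residual blocks (C=%d, k=%d, pool %d), linear head -> %d label(s)\n",
              cfg$trunk_blocks, cfg$trunk_channels, cfg$trunk_kernel,
              cfg$pool, cfg$n_labels))
  if (!is.null(x$history))
    cat(sprintf("  trained %d epoch(s); best val loss %.4f at epoch %d\n",
                nrow(x$history), x$val_loss, x$best_epoch))
  else cat("  untrained (random initialization)\n")
  invisible(x)
}

#' @export
summary.ecgnet <- function(object, ...) {
  n_par <- sum(rapply(object$params, length, how = "unlist"))
  cat(sprintf("Isolation-integration ECG network: %s parameters\n",
              format(n_par, big.mark = ",")))
  print(object)
  if (!is.null(object$history)) {
    cat("\nTraining history:\n")
    print(object$history, row.names = FALSE)
  }
  invisible(object)
}

#' @export
coef.ecgnet <- function(object, ...) {
  w <- object$params$head$Wh
  rownames(w) <- object$config$labels
  list(head_weights = w, head_bias = object$params$head$bh)
}

#' Plot training history
#' @param x A fitted `ecgnet`.
#' @param ... Unused.
#' @export
plot.ecgnet <- function(x, ...) {
  if (is.null(x$history)) stop("model has no training history")
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "b",
                    pch = 16, lty = 1, xlab = "epoch", ylab = "loss",
                    col = c("grey40", "firebrick"))
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("grey40", "firebrick"), bty = "n")
  graphics::abline(v = x$best_epoch, lty = 3)
  invisible(x)
}
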