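# full from-scratch re-derivation of the saliency pipeline used as the
# independent oracle: finite-difference gradients through the trunk,
# explicit per-block sums, manual interpolation and normalization
explain_oracle <- function(model, x, label, eps = 1e-3) {
  cfg <- model$config
  xs <- cardiolens:::standardize_input(array(x, c(1, dim(x))), model$norm)
  F0 <- cardiolens:::encoder_forward(model$params, cfg, xs)$F
  C <- dim(F0)[1]; T2 <- dim(F0)[2]
  logit_of <- function(F) cardiolens:::trunk_forward(model$params, cfg,
                                                     F)$logits[label, 1]
  fd <- matrix(0, C, T2)
  for (c in seq_len(C)) for (t in seq_len(T2)) {
    Fp <- F0; Fp[c, t, 1] <- Fp[c, t, 1] + eps
    Fm <- F0; Fm[c, t, 1] <- Fm[c, t, 1] - eps
    fd[c, t] <- (logit_of(Fp) - logit_of(Fm)) / (2 * eps)
  }
  alpha <- numeric(C)
  for (c in seq_len(C)) alpha[c] <- sum(fd[c, ]) / T2
  block <- rep(seq_len(cfg$n_leads), each = cfg$enc_channels)
  raw <- matrix(0, cfg$n_leads, T2)
  for (l in seq_len(cfg$n_leads)) for (t in seq_len(T2)) {
    s <- 0
    for (c in which(block == l)) s <- s + alpha[c] * F0[c, t, 1]
    raw[l, t] <- max(0, s)
  }
  Tn <- cfg$input_length
  up <- matrix(0, cfg$n_leads, Tn)
  xout <- seq(1, T2, length.out = Tn)
  for (l in seq_len(cfg$n_leads)) {
    for (k in seq_len(Tn)) {
      lo <- floor(xout[k]); hi <- ceiling(xout[k]); w <- xout[k] - lo
      up[l, k] <- (1 - w) * raw[l, lo] + w * raw[l, hi]
    }
  }
  if (max(up) > 0) up <- up / max(up)
  up
}

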