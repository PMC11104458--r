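# Internal layers of the isolation-integration network. All activations
# travel as 3-d arrays (channels, time, batch) matching the arma::cube
# layout of the compiled conv1d kernels in src/conv1d.cpp.

relu <- function(x) x * (x > 0)

as_cube <- function(x, C, T, n) { dim(x) <- c(C, T, n); x }

he_init <- function(nrow, ncol, fan_in) {
  matrix(stats::rnorm(nrow * ncol, 0, sqrt(2 / fan_in)), nrow, ncol)
}

init_ecgnet_params <- function(cfg) {
  with_seed(cfg$seed, {
    k <- cfg$enc_kernel; C <- cfg$enc_channels
    enc <- lapply(seq_len(cfg$n_leads), function(l) {
      list(W1 = he_init(C, k, k), b1 = numeric(C),
           W2 = he_init(C, C * k, C * k), b2 = numeric(C))
    })
    kt <- cfg$trunk_kernel; Ct <- cfg$trunk_channels
    cin <- cfg$n_leads * C
    trunk <- vector("list", cfg$trunk_blocks)
    for (b in seq_len(cfg$trunk_blocks)) {
      trunk[[b]] <- list(
        Wa = he_init(Ct, cin * kt, cin * kt), ba = numeric(Ct),
        Wb = he_init(Ct, Ct * kt, Ct * kt), bb = numeric(Ct),
        Ws = if (cin != Ct) he_init(Ct, cin, cin) else NULL)
      cin <- Ct
    }
    head <- list(Wh = he_init(cfg$n_labels, Ct, Ct),
                 bh = numeric(cfg$n_labels))
    list(enc = enc, trunk = trunk, head = head)
  })
}

# per-lead isolated encoders: lead j's channel block depends on lead j only
encoder_forward <- function(params, cfg, X, keep_cache = FALSE) {
  n <- dim(X)[1]; L <- cfg$n_leads; Tn <- dim(X)[3]
  C <- cfg$enc_channels; k <- cfg$enc_kernel
  T2 <- Tn %/% 2L
  F <- array(0, c(L * C, T2, n))
  cache <- if (keep_cache) vector("list", L) else NULL
  for (l in seq_len(L)) {
    x1 <- as_cube(t(X[, l, , drop = TRUE]), 1L, Tn, n)
    if (n == 1L) x1 <- as_cube(X[1, l, ], 1L, Tn, 1L)
    a1 <- relu(.conv1d_fwd(x1, params$enc[[l]]$W1, params$enc[[l]]$b1, k, 1L))
    a2 <- relu(.conv1d_fwd(a1, params$enc[[l]]$W2, params$enc[[l]]$b2, k, 2L))
    F[((l - 1L) * C + 1L):(l * C), , ] <- a2
    if (keep_cache) cache[[l]] <- list(x1 = x1, a1 = a1, a2 = a2)
  }
  list(F = F, cache = cache)
}

encoder_backward <- function(params, cfg, cache, dF) {
  L <- cfg$n_leads; C <- cfg$enc_channels; k <- cfg$enc_kernel
  grads <- vector("list", L)
  for (l in seq_len(L)) {
    cc <- cache[[l]]
    dA2 <- dF[((l - 1L) * C + 1L):(l * C), , , drop = FALSE]
    dim(dA2) <- dim(cc$a2)
    dA2 <- dA2 * (cc$a2 > 0)
    g2 <- .conv1d_bwd_wb(cc$a1, dA2, k, 2L)
    dA1 <- .conv1d_bwd_input(dA2, params$enc[[l]]$W2, dim(cc$a1)[2], k, 2L)
    dA1 <- dA1 * (cc$a1 > 0)
    g1 <- .conv1d_bwd_wb(cc$x1, dA1, k, 1L)
    grads[[l]] <- list(W1 = g1$dW, b1 = as.numeric(g1$db),
                       W2 = g2$dW, b2 = as.numeric(g2$db))
  }
  grads
}

# residual trunk: conv-relu-conv + skip (1x1 projection on channel
# change), relu, then non-overlapping average pooling
trunk_forward <- function(params, cfg, F, keep_cache = FALSE) {
  kt <- cfg$trunk_kernel
  Z <- F
  cache <- if (keep_cache) vector("list", cfg$trunk_blocks) else NULL
  for (b in seq_len(cfg$trunk_blocks)) {
    pb <- params$trunk[[b]]
    A <- relu(.conv1d_fwd(Z, pb$Wa, pb$ba, kt, 1L))
    Bz <- .conv1d_fwd(A, pb$Wb, pb$bb, kt, 1L)
    S <- if (is.null(pb$Ws)) Z else .conv1d_fwd(Z, pb$Ws, numeric(nrow(pb$Ws)), 1L, 1L)
    Zo <- relu(Bz + S)
    P <- .avgpool_fwd(Zo, cfg$pool)
    if (keep_cache) cache[[b]] <- list(Zin = Z, A = A, Zo = Zo)
    Z <- P
  }
  g <- apply(Z, c(1, 3), mean)
  if (is.null(dim(g))) g <- matrix(g, nrow = dim(Z)[1])
  logits <- params$head$Wh %*% g + params$head$bh
  list(logits = logits, g = g, Ztop = Z, cache = cache)
}

# backpropagate d(loss)/d(logits) through the trunk; returns dF and,
# optionally, parameter gradients
trunk_backward <- function(params, cfg, fwd, dlogits, param_grads = TRUE) {
  kt <- cfg$trunk_kernel
  g <- fwd$g
  dWh <- dlogits %*% t(g)
  dbh <- rowSums(dlogits)
  dg <- t(params$head$Wh) %*% dlogits
  Ztop <- fwd$Ztop
  Tz <- dim(Ztop)[2]; n <- dim(Ztop)[3]; Cz <- dim(Ztop)[1]
  dZ <- aperm(array(dg / Tz, c(Cz, n, Tz)), c(1, 3, 2))
  tg <- if (param_grads) vector("list", cfg$trunk_blocks) else NULL
  for (b in rev(seq_len(cfg$trunk_blocks))) {
    pb <- params$trunk[[b]]
    cc <- fwd$cache[[b]]
    dZo <- .avgpool_bwd(dZ, dim(cc$Zo)[2], cfg$pool)
    dpre <- dZo * (cc$Zo > 0)
    gb <- if (param_grads) .conv1d_bwd_wb(cc$A, dpre, kt, 1L)
    dA <- .conv1d_bwd_input(dpre, pb$Wb, dim(cc$A)[2], kt, 1L) * (cc$A > 0)
    ga <- if (param_grads) .conv1d_bwd_wb(cc$Zin, dA, kt, 1L)
    dZ <- .conv1d_bwd_input(dA, pb$Wa, dim(cc$Zin)[2], kt, 1L)
    if (is.null(pb$Ws)) {
      dZ <- dZ + dpre
      gs <- NULL
    } else {
      if (param_grads) gs <- .conv1d_bwd_wb(cc$Zin, dpre, 1L, 1L)
      dZ <- dZ + .conv1d_bwd_input(dpre, pb$Ws, dim(cc$Zin)[2], 1L, 1L)
    }
    if (param_grads)
      tg[[b]] <- list(Wa = ga$dW, ba = as.numeric(ga$db),
                      Wb = gb$dW, bb = as.numeric(gb$db),
                      Ws = if (!is.null(pb$Ws)) gs$dW else NULL)
  }
  list(dF = dZ,
       grads = if (param_grads)
         list(trunk = tg, head = list(Wh = dWh, bh = dbh)) else NULL)
}

# Adam update over the nested parameter list
adam_step <- function(params, grads, state, lr, t, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  walk <- function(p, g, m, v) {
    if (is.null(p) || is.null(g)) return(list(p = p, m = m, v = v))
    if (is.list(p)) {
      out_p <- p
      out_m <- if (is.null(m)) vector("list", length(p)) else m
      out_v <- if (is.null(v)) vector("list", length(p)) else v
      for (i in seq_along(p)) {
        r <- walk(p[[i]], g[[i]], out_m[[i]], out_v[[i]])
        out_p[[i]] <- r$p
        out_m[[i]] <- r$m
        out_v[[i]] <- r$v
      }
      return(list(p = out_p, m = out_m, v = out_v))
    }
    if (is.null(m)) { m <- p * 0; v <- p * 0 }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mh <- m / (1 - beta1^t)
    vh <- v / (1 - beta2^t)
    list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
  }
  r <- walk(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v))
}
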