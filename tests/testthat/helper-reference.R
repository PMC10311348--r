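# Independent pure-R reference implementation of the forward pass, written
# directly from the layer equations with explicit loops. Used as an oracle
# for the compiled engine on tiny configurations; deliberately slow and
# structured differently from the C++ code.

ref_softmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

ref_layernorm <- function(X, g, b, eps = 1e-5) {
  t(apply(X, 1, function(r) {
    mu <- mean(r)
    s <- sqrt(mean((r - mu)^2) + eps)
    g * (r - mu) / s + b
  }))
}

ref_mha <- function(Xq, Xkv, WQ, WK, WV, WO, H, mask) {
  w <- ncol(WQ); dh <- w / H
  Q <- Xq %*% WQ; K <- Xkv %*% WK; V <- Xkv %*% WV
  heads <- matrix(0, nrow(Xq), w)
  for (h in seq_len(H)) {
    cols <- ((h - 1) * dh + 1):(h * dh)
    S <- Q[, cols, drop = FALSE] %*% t(K[, cols, drop = FALSE]) / sqrt(dh)
    S <- S + mask
    A <- t(apply(S, 1, ref_softmax))
    heads[, cols] <- A %*% V[, cols, drop = FALSE]
  }
  heads %*% WO
}

ref_ff <- function(X, W1, b1, W2, b2) {
  H <- pmax(sweep(X %*% W1, 2, b1, "+"), 0)
  sweep(H %*% W2, 2, b2, "+")
}

ref_ws <- function(dS, N) {
  WS <- matrix(0, dS, N + 1)
  for (k in 0:(dS / 2 - 1)) {
    for (i in 1:(N + 1)) {
      WS[2 * k + 1, i] <- sin(i / 10000^(2 * k / dS))
      WS[2 * k + 2, i] <- cos(i / 10000^(2 * k / dS))
    }
  }
  WS
}

# full teacher-forced forward; tokens 1..21, labels_in 1..9 (BOS first)
ref_forward <- function(tokens, n_real, group, labels_in, params, cfg) {
  N <- cfg$N; d <- cfg$d; dS <- cfg$dS; dm <- d + dS; H <- cfg$H
  neg <- -1e30
  E <- t(params$WP)
  for (i in seq_len(N)) E[i, ] <- E[i, ] + params$Wa[, tokens[i]]
  enc_mask <- matrix(0, N, N)
  if (n_real < N) enc_mask[, (n_real + 1):N] <- neg
  for (l in seq_len(cfg$L_enc)) {
    pre <- sprintf("e%d_", l)
    g <- function(s) params[[paste0(pre, s)]]
    A <- ref_mha(E, E, g("WQ"), g("WK"), g("WV"), g("WO"), H, enc_mask)
    E <- ref_layernorm(E + A, g("ln1_g"), g("ln1_b"))
    E <- ref_layernorm(E + ref_ff(E, g("W1"), g("b1"), g("W2"), g("b2")),
                       g("ln2_g"), g("ln2_b"))
  }
  WS <- ref_ws(dS, N)
  M <- rbind(E, params$WG[, group])
  M <- cbind(M, t(WS))
  D <- matrix(0, N + 1, dm)
  for (i in seq_len(N + 1)) {
    D[i, ] <- c(params$Wy[, labels_in[i]], WS[, i])
  }
  self_mask <- matrix(0, N + 1, N + 1)
  for (i in seq_len(N + 1)) {
    for (j in seq_len(N + 1)) if (j > i || j > n_real + 1) self_mask[i, j] <- neg
  }
  cross_mask <- matrix(0, N + 1, N + 1)
  if (n_real < N) cross_mask[, (n_real + 1):N] <- neg
  for (l in seq_len(cfg$L_dec)) {
    pre <- sprintf("d%d_", l)
    g <- function(s) params[[paste0(pre, s)]]
    A <- ref_mha(D, D, g("sWQ"), g("sWK"), g("sWV"), g("sWO"), H, self_mask)
    D <- ref_layernorm(D + A, g("ln1_g"), g("ln1_b"))
    A <- ref_mha(D, M, g("cWQ"), g("cWK"), g("cWV"), g("cWO"), H, cross_mask)
    D <- ref_layernorm(D + A, g("ln2_g"), g("ln2_b"))
    D <- ref_layernorm(D + ref_ff(D, g("W1"), g("b1"), g("W2"), g("b2")),
                       g("ln3_g"), g("ln3_b"))
  }
  probs <- matrix(0, N, 8)
  for (k in seq_len(N)) {
    ck <- numeric(21); ck[tokens[k]] <- 1
    z <- c(D[k, ], ck)
    probs[k, ] <- ref_softmax(as.numeric(z %*% params$WO_out))
  }
  probs
}
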