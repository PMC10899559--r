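# Minimal dense/attention neural-network core with analytic gradients.
#
# Layouts:
#   sequence batches are arrays X[n, t, k] (sequence, token, feature) with a
#   logical mask[n, t] marking valid tokens. All attention arithmetic is
#   vectorised over the sequence dimension n and loops only over the (small,
#   <= 7) token and head dimensions, which keeps pure-R training fast.
#
# Parameters live in a flat named list of numeric arrays; gradients are a
# parallel list. All backward passes are verified against central finite
# differences in the test suite.

nn_linear <- function(X2, W, b) sweep(X2 %*% W, 2, b, "+")

nn_linear_bwd <- function(dY, X2, W) {
  list(dX = dY %*% t(W), dW = t(X2) %*% dY, db = colSums(dY))
}

nn_layernorm_fwd <- function(X2, g, b, eps = 1e-5) {
  mu <- rowMeans(X2)
  xc <- X2 - mu
  v <- rowMeans(xc * xc)
  istd <- 1 / sqrt(v + eps)
  xhat <- xc * istd
  Y <- sweep(sweep(xhat, 2, g, "*"), 2, b, "+")
  list(Y = Y, xhat = xhat, istd = istd)
}

nn_layernorm_bwd <- function(dY, cache, g) {
  xhat <- cache$xhat
  istd <- cache$istd
  dg <- colSums(dY * xhat)
  db <- colSums(dY)
  dxhat <- sweep(dY, 2, g, "*")
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dX <- istd * (dxhat - m1 - xhat * m2)
  list(dX = dX, dg = dg, db = db)
}

# Masked multi-head self-attention on X[n, t, d]. Keys at masked positions
# receive exactly zero weight (their exponentials are hard-zeroed); rows of
# fully-masked sequences are zeroed rather than NaN.
nn_attention_fwd <- function(X, mask, W, H) {
  dm <- dim(X)
  N <- dm[1]; T <- dm[2]; d <- dm[3]
  dh <- d %/% H
  X2 <- X; dim(X2) <- c(N * T, d)
  Q <- nn_linear(X2, W$Wq, W$bq); dim(Q) <- c(N, T, dh, H)
  K <- nn_linear(X2, W$Wk, W$bk); dim(K) <- c(N, T, dh, H)
  V <- nn_linear(X2, W$Wv, W$bv); dim(V) <- c(N, T, dh, H)
  scl <- 1 / sqrt(dh)
  A <- array(0, c(N, T, T, H))
  any_valid <- rowSums(mask) > 0
  for (h in seq_len(H)) {
    S <- array(-Inf, c(N, T, T))
    for (i in seq_len(T)) for (j in seq_len(T)) {
      s <- rowSums(Q[, i, , h, drop = FALSE] * K[, j, , h, drop = FALSE]) * scl
      s[!mask[, j]] <- -Inf
      S[, i, j] <- s
    }
    for (i in seq_len(T)) {
      Si <- S[, i, , drop = FALSE]; dim(Si) <- c(N, T)
      mx <- do.call(pmax, c(lapply(seq_len(T), function(j) Si[, j]), list(-Inf)))
      E <- exp(Si - mx)              # masked keys: exp(-Inf) == 0 exactly
      E[!is.finite(E)] <- 0          # fully-masked rows give NaN; zero them
      den <- rowSums(E)
      Ai <- E / ifelse(den > 0, den, 1)
      Ai[den == 0, ] <- 0
      A[, i, , h] <- Ai
    }
  }
  O <- array(0, c(N, T, dh, H))
  for (h in seq_len(H)) for (i in seq_len(T)) {
    acc <- matrix(0, N, dh)
    for (j in seq_len(T)) {
      Vj <- V[, j, , h]; dim(Vj) <- c(N, dh)
      acc <- acc + A[, i, j, h] * Vj
    }
    O[, i, , h] <- acc
  }
  O2 <- O; dim(O2) <- c(N * T, dh * H)
  Y2 <- nn_linear(O2, W$Wo, W$bo)
  Y <- Y2; dim(Y) <- c(N, T, d)
  Y[!any_valid, , ] <- 0
  list(Y = Y, A = A, Q = Q, K = K, V = V, O2 = O2, X2 = X2,
       any_valid = any_valid)
}

nn_attention_bwd <- function(dY, cache, mask, W, H) {
  A <- cache$A; Q <- cache$Q; K <- cache$K; V <- cache$V
  N <- dim(A)[1]; T <- dim(A)[2]
  dh <- dim(Q)[3]; d <- dh * H
  dY[!cache$any_valid, , ] <- 0
  dY2 <- dY; dim(dY2) <- c(N * T, d)
  lo <- nn_linear_bwd(dY2, cache$O2, W$Wo)
  dO <- lo$dX; dim(dO) <- c(N, T, dh, H)
  dQ <- array(0, dim(Q)); dK <- array(0, dim(K)); dV <- array(0, dim(V))
  scl <- 1 / sqrt(dh)
  for (h in seq_len(H)) {
    dA <- array(0, c(N, T, T))
    for (i in seq_len(T)) {
      dOi <- dO[, i, , h]; dim(dOi) <- c(N, dh)
      for (j in seq_len(T)) {
        Vj <- V[, j, , h]; dim(Vj) <- c(N, dh)
        dA[, i, j] <- rowSums(dOi * Vj)
        dV[, j, , h] <- dV[, j, , h] + A[, i, j, h] * dOi
      }
    }
    # softmax backward per (n, i) row over keys j
    for (i in seq_len(T)) {
      Ai <- A[, i, , h]; dim(Ai) <- c(N, T)
      dAi <- dA[, i, ]; dim(dAi) <- c(N, T)
      s <- rowSums(dAi * Ai)
      dS <- Ai * (dAi - s)
      for (j in seq_len(T)) {
        Kj <- K[, j, , h]; dim(Kj) <- c(N, dh)
        dQ[, i, , h] <- dQ[, i, , h] + dS[, j] * Kj * scl
        Qi <- Q[, i, , h]; dim(Qi) <- c(N, dh)
        dK[, j, , h] <- dK[, j, , h] + dS[, j] * Qi * scl
      }
    }
  }
  dQ2 <- dQ; dim(dQ2) <- c(N * T, d)
  dK2 <- dK; dim(dK2) <- c(N * T, d)
  dV2 <- dV; dim(dV2) <- c(N * T, d)
  lq <- nn_linear_bwd(dQ2, cache$X2, W$Wq)
  lk <- nn_linear_bwd(dK2, cache$X2, W$Wk)
  lv <- nn_linear_bwd(dV2, cache$X2, W$Wv)
  dX2 <- lq$dX + lk$dX + lv$dX
  dX <- dX2; dim(dX) <- c(N, T, d)
  list(dX = dX,
       grads = list(Wq = lq$dW, bq = lq$db, Wk = lk$dW, bk = lk$db,
                    Wv = lv$dW, bv = lv$db, Wo = lo$dW, bo = lo$db))
}

# One pre-norm transformer block: x + Attn(LN1(x)), then x + FFN(LN2(x)).
nn_block_fwd <- function(X, mask, par, H) {
  dm <- dim(X); N <- dm[1]; T <- dm[2]; d <- dm[3]
  X2 <- X; dim(X2) <- c(N * T, d)
  ln1 <- nn_layernorm_fwd(X2, par$ln1.g, par$ln1.b)
  Xn <- ln1$Y; dim(Xn) <- c(N, T, d)
  att <- nn_attention_fwd(Xn, mask, par, H)
  H1 <- X + att$Y
  H12 <- H1; dim(H12) <- c(N * T, d)
  ln2 <- nn_layernorm_fwd(H12, par$ln2.g, par$ln2.b)
  Z1 <- nn_linear(ln2$Y, par$W1, par$b1)
  R <- pmax(Z1, 0)
  Z2 <- nn_linear(R, par$W2, par$b2)
  F2 <- Z2; dim(F2) <- c(N, T, d)
  Y <- H1 + F2
  list(Y = Y, cache = list(X2 = X2, ln1 = ln1, att = att, H12 = H12,
                           ln2 = ln2, Z1 = Z1, R = R))
}

nn_block_bwd <- function(dY, cache, mask, par, H) {
  dm <- dim(dY); N <- dm[1]; T <- dm[2]; d <- dm[3]
  dY2 <- dY; dim(dY2) <- c(N * T, d)
  l2b <- nn_linear_bwd(dY2, cache$R, par$W2)
  dR <- l2b$dX
  dZ1 <- dR * (cache$Z1 > 0)
  l1b <- nn_linear_bwd(dZ1, cache$ln2$Y, par$W1)
  lnb2 <- nn_layernorm_bwd(l1b$dX, cache$ln2, par$ln2.g)
  dH12 <- dY2 + lnb2$dX
  dH1 <- dH12; dim(dH1) <- c(N, T, d)
  ab <- nn_attention_bwd(dH1, cache$att, mask, par, H)
  dXn2 <- ab$dX; dim(dXn2) <- c(N * T, d)
  lnb1 <- nn_layernorm_bwd(dXn2, cache$ln1, par$ln1.g)
  dX <- dH1
  dX2 <- lnb1$dX; dim(dX2) <- c(N, T, d)
  dX <- dX + dX2
  grads <- c(ab$grads,
             list(ln1.g = lnb1$dg, ln1.b = lnb1$db,
                  ln2.g = lnb2$dg, ln2.b = lnb2$db,
                  W1 = l1b$dW, b1 = l1b$db, W2 = l2b$dW, b2 = l2b$db))
  list(dX = dX, grads = grads)
}

# Stack of blocks. Returns last-layer attention for explanation.
nn_encoder_fwd <- function(X, mask, pars, H) {
  caches <- vector("list", length(pars))
  for (l in seq_along(pars)) {
    out <- nn_block_fwd(X, mask, pars[[l]], H)
    X <- out$Y
    caches[[l]] <- out$cache
  }
  list(Y = X, caches = caches, attn_last = caches[[length(pars)]]$att$A)
}

nn_encoder_bwd <- function(dY, caches, mask, pars, H) {
  grads <- vector("list", length(pars))
  for (l in rev(seq_along(pars))) {
    out <- nn_block_bwd(dY, caches[[l]], mask, pars[[l]], H)
    dY <- out$dX
    grads[[l]] <- out$grads
  }
  list(dX = dY, grads = grads)
}

nn_init_block <- function(d, dff, sd = 0.05) {
  list(ln1.g = rep(1, d), ln1.b = rep(0, d),
       Wq = matrix(rnorm(d * d, 0, sd), d, d), bq = rep(0, d),
       Wk = matrix(rnorm(d * d, 0, sd), d, d), bk = rep(0, d),
       Wv = matrix(rnorm(d * d, 0, sd), d, d), bv = rep(0, d),
       Wo = matrix(rnorm(d * d, 0, sd), d, d), bo = rep(0, d),
       ln2.g = rep(1, d), ln2.b = rep(0, d),
       W1 = matrix(rnorm(d * dff, 0, sd), d, dff), b1 = rep(0, dff),
       W2 = matrix(rnorm(dff * d, 0, sd), dff, d), b2 = rep(0, d))
}

# ---- flat parameter plumbing -------------------------------------------

flatten_params <- function(x, prefix = "") {
  if (is.list(x) && !is.null(names(x)) && !is.numeric(x)) {
    out <- list()
    for (nm in names(x)) {
      out <- c(out, flatten_params(x[[nm]], paste0(prefix, nm, ".")))
    }
    out
  } else if (is.list(x)) {
    out <- list()
    for (i in seq_along(x)) {
      out <- c(out, flatten_params(x[[i]], paste0(prefix, i, ".")))
    }
    out
  } else {
    setNames(list(x), sub("\\.$", "", prefix))
  }
}

adam_init <- function(par_flat) {
  list(m = lapply(par_flat, function(p) p * 0),
       v = lapply(par_flat, function(p) p * 0), t = 0L)
}

adam_step <- function(par_flat, grad_flat, state, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(par_flat)) {
    g <- grad_flat[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    par_flat[[nm]] <- par_flat[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(par = par_flat, state = state)
}
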