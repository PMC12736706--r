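# Compact 1D Siamese convolutional network for pairwise re-identification,
# implemented directly in base R (im2col convolutions, Adam, binary
# cross-entropy). Two weight-shared branches
#   conv(16, kernel 7) -> ReLU -> maxpool(2) -> conv(32, kernel 5) -> ReLU
#   -> global average pool -> dense(64)
# are merged by the absolute embedding difference followed by a sigmoid
# unit. Sized for CPU training on desk-scale pair sets.

siamese_dims <- function(L, k1 = 7L, c1 = 16L, k2 = 5L, c2 = 32L, emb = 64L) {
  n1 <- L - k1 + 1L
  n1p <- n1 %/% 2L
  n2 <- n1p - k2 + 1L
  if (n2 < 1L) stop("input length too short for the network")
  list(L = L, k1 = k1, c1 = c1, k2 = k2, c2 = c2, emb = emb,
       n1 = n1, n1p = n1p, n2 = n2)
}

siamese_init <- function(dims) {
  he <- function(nr, nc, fan_in) matrix(stats::rnorm(nr * nc, 0, sqrt(2 / fan_in)), nr, nc)
  list(W1 = he(dims$k1, dims$c1, dims$k1),
       b1 = numeric(dims$c1),
       W2 = he(dims$k2 * dims$c1, dims$c2, dims$k2 * dims$c1),
       b2 = numeric(dims$c2),
       W3 = he(dims$c2, dims$emb, dims$c2),
       b3 = numeric(dims$emb),
       w4 = matrix(stats::rnorm(dims$emb, 0, sqrt(1 / dims$emb)), dims$emb, 1),
       b4 = 0)
}

im2col <- function(X, k, n_out) {
  B <- nrow(X)
  E <- matrix(0, B * n_out, k)
  for (t in seq_len(k)) {
    E[, t] <- as.vector(t(X[, t:(t + n_out - 1), drop = FALSE]))
  }
  E
}

siamese_branch <- function(par, dims, X, keep_cache = FALSE) {
  B <- nrow(X)
  E1 <- im2col(X, dims$k1, dims$n1)
  Z1 <- sweep(E1 %*% par$W1, 2, par$b1, "+")
  A1 <- pmax(Z1, 0)
  base <- rep((seq_len(B) - 1L) * dims$n1, each = dims$n1p)
  podd <- base + rep(seq.int(1L, 2L * dims$n1p, by = 2L), B)
  peven <- podd + 1L
  Ao <- A1[podd, , drop = FALSE]
  Ae <- A1[peven, , drop = FALSE]
  P <- pmax(Ao, Ae)
  E2 <- matrix(0, B * dims$n2, dims$k2 * dims$c1)
  base2 <- rep((seq_len(B) - 1L) * dims$n1p, each = dims$n2)
  rowsel <- vector("list", dims$k2)
  for (t in seq_len(dims$k2)) {
    rowsel[[t]] <- base2 + rep(t:(t + dims$n2 - 1L), B)
    E2[, ((t - 1L) * dims$c1 + 1L):(t * dims$c1)] <- P[rowsel[[t]], , drop = FALSE]
  }
  Z2 <- sweep(E2 %*% par$W2, 2, par$b2, "+")
  A2 <- pmax(Z2, 0)
  grp <- rep(seq_len(B), each = dims$n2)
  G <- rowsum(A2, grp) / dims$n2
  E <- sweep(G %*% par$W3, 2, par$b3, "+")
  out <- list(E = E)
  if (keep_cache) {
    out$cache <- list(E1 = E1, Z1pos = Z1 > 0, podd = podd, peven = peven,
                      mask_odd = Ao >= Ae, E2 = E2, Z2pos = Z2 > 0, G = G,
                      rowsel = rowsel, B = B)
  }
  out
}

siamese_branch_backward <- function(par, dims, cache, dE, grads) {
  B <- cache$B
  grads$W3 <- grads$W3 + t(cache$G) %*% dE
  grads$b3 <- grads$b3 + colSums(dE)
  dG <- dE %*% t(par$W3)
  dA2 <- dG[rep(seq_len(B), each = dims$n2), , drop = FALSE] / dims$n2
  dZ2 <- dA2 * cache$Z2pos
  grads$W2 <- grads$W2 + t(cache$E2) %*% dZ2
  grads$b2 <- grads$b2 + colSums(dZ2)
  dE2 <- dZ2 %*% t(par$W2)
  dP <- matrix(0, B * dims$n1p, dims$c1)
  for (t in seq_len(dims$k2)) {
    cols <- ((t - 1L) * dims$c1 + 1L):(t * dims$c1)
    sel <- cache$rowsel[[t]]
    dP[sel, ] <- dP[sel, ] + dE2[, cols, drop = FALSE]
  }
  dA1 <- matrix(0, B * dims$n1, dims$c1)
  dA1[cache$podd, ] <- dP * cache$mask_odd
  dA1[cache$peven, ] <- dP * (1 - cache$mask_odd)
  dZ1 <- dA1 * cache$Z1pos
  grads$W1 <- grads$W1 + t(cache$E1) %*% dZ1
  grads$b1 <- grads$b1 + colSums(dZ1)
  grads
}

siamese_forward_pair <- function(par, dims, X1, X2) {
  b1 <- siamese_branch(par, dims, X1)
  b2 <- siamese_branch(par, dims, X2)
  D <- abs(b1$E - b2$E)
  logit <- as.numeric(D %*% par$w4) + par$b4
  1 / (1 + exp(-logit))
}

zero_like <- function(par) lapply(par, function(p) p * 0)

#' Train the 1D Siamese re-identification network
#'
#' @param X1,X2 Matrices (pairs x L) of standardised cycle templates.
#' @param y Binary labels (1 = same user).
#' @param config List: `epochs` (<= 50), `lr` (1e-3), `batch` (64),
#'   `val_frac` (0.2), `patience` (5).
#' @param seed Integer seed; a fixed seed with single-threaded BLAS
#'   reproduces training.
#' @return List with fitted parameters, dims and training history.
#' @keywords internal
siamese_train <- function(X1, X2, y, config = list(), seed = 1) {
  stopifnot(nrow(X1) == nrow(X2), nrow(X1) == length(y))
  dims <- siamese_dims(ncol(X1))
  epochs <- config$epochs %||% 50
  lr <- config$lr %||% 1e-3
  batch <- config$batch %||% 64
  val_frac <- config$val_frac %||% 0.2
  patience <- config$patience %||% 5
  n <- nrow(X1)

  with_seed(seed, {
    par <- siamese_init(dims)
    n_val <- max(0L, min(n - 2L, round(val_frac * n)))
    val_idx <- if (n_val > 0) sample.int(n, n_val) else integer(0)
    tr_idx <- setdiff(seq_len(n), val_idx)
    mstate <- zero_like(par); vstate <- zero_like(par)
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8; step <- 0
    best_val <- Inf; best_par <- par; bad <- 0
    history <- numeric(0)

    bce <- function(p, yy) {
      p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
      -mean(yy * log(p) + (1 - yy) * log(1 - p))
    }

    for (ep in seq_len(epochs)) {
      ord <- sample(tr_idx)
      for (b0 in seq.int(1L, length(ord), by = batch)) {
        sel <- ord[b0:min(b0 + batch - 1L, length(ord))]
        Bn <- length(sel)
        f1 <- siamese_branch(par, dims, X1[sel, , drop = FALSE], keep_cache = TRUE)
        f2 <- siamese_branch(par, dims, X2[sel, , drop = FALSE], keep_cache = TRUE)
        D <- abs(f1$E - f2$E)
        logit <- as.numeric(D %*% par$w4) + par$b4
        p <- 1 / (1 + exp(-logit))
        dlogit <- (p - y[sel]) / Bn
        grads <- zero_like(par)
        grads$w4 <- t(D) %*% dlogit
        grads$b4 <- sum(dlogit)
        dD <- outer(dlogit, as.numeric(par$w4))
        sgn <- sign(f1$E - f2$E)
        grads <- siamese_branch_backward(par, dims, f1$cache, dD * sgn, grads)
        grads <- siamese_branch_backward(par, dims, f2$cache, -dD * sgn, grads)
        step <- step + 1
        for (nm in names(par)) {
          mstate[[nm]] <- beta1 * mstate[[nm]] + (1 - beta1) * grads[[nm]]
          vstate[[nm]] <- beta2 * vstate[[nm]] + (1 - beta2) * grads[[nm]]^2
          mhat <- mstate[[nm]] / (1 - beta1^step)
          vhat <- vstate[[nm]] / (1 - beta2^step)
          par[[nm]] <- par[[nm]] - lr * mhat / (sqrt(vhat) + eps)
        }
      }
      val_loss <- if (length(val_idx)) {
        bce(siamese_forward_pair(par, dims, X1[val_idx, , drop = FALSE],
                                 X2[val_idx, , drop = FALSE]), y[val_idx])
      } else {
        bce(siamese_forward_pair(par, dims, X1[tr_idx, , drop = FALSE],
                                 X2[tr_idx, , drop = FALSE]), y[tr_idx])
      }
      history <- c(history, val_loss)
      if (val_loss < best_val - 1e-6) {
        best_val <- val_loss; best_par <- par; bad <- 0
      } else {
        bad <- bad + 1
        if (bad >= patience) break
      }
    }
    list(par = best_par, dims = dims, history = history, val_loss = best_val)
  })
}

siamese_predict <- function(fit, X1, X2, chunk = 256L) {
  n <- nrow(X1)
  out <- numeric(n)
  for (b0 in seq.int(1L, n, by = chunk)) {
    sel <- b0:min(b0 + chunk - 1L, n)
    out[sel] <- siamese_forward_pair(fit$par, fit$dims,
                                     X1[sel, , drop = FALSE],
                                     X2[sel, , drop = FALSE])
  }
  out
}
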