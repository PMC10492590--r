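# 1-D convolutional network engine in base-R matrix algebra.
#
# Layout: conv(k1, F1) -> ReLU -> maxpool(p1) -> conv(k2, F2) -> ReLU ->
# maxpool(p2) -> flatten -> dense(D) -> ReLU -> dense(1) -> sigmoid.
# Convolutions are evaluated via im2col so each layer is a single BLAS
# matrix product; training uses Adam on the mean binary cross-entropy with
# early stopping on a validation set. Windows arrive as arrays
# (batch, length, channels).

#' 1-D CNN architecture description
#'
#' Two convolution blocks (ReLU + max pooling) followed by one dense ReLU
#' layer and a sigmoid output. All sizes are configurable; the defaults
#' (32 filters of kernel 7, 64 filters of kernel 5, pooling 2, 64 dense
#' units) are this package's own.
#'
#' @param filters Integer vector of length 2: filters per conv block.
#' @param kernels Integer vector of length 2: kernel sizes.
#' @param pool Integer vector of length 2: max-pool widths.
#' @param dense_units Units in the dense layer.
#' @return An object of class `mash_cnn_arch`.
#' @export
cnn_architecture <- function(filters = c(32L, 64L), kernels = c(7L, 5L),
                             pool = c(2L, 2L), dense_units = 64L) {
  stopifnot(length(filters) == 2L, length(kernels) == 2L, length(pool) == 2L)
  structure(list(filters = as.integer(filters), kernels = as.integer(kernels),
                 pool = as.integer(pool), dense_units = as.integer(dense_units)),
            class = "mash_cnn_arch")
}

im2col <- function(X, k) {
  n <- dim(X)[1L]; L <- dim(X)[2L]; C <- dim(X)[3L]
  Lout <- L - k + 1L
  M <- matrix(0, n * Lout, k * C)
  for (j in seq_len(k)) {
    M[, ((j - 1L) * C + 1L):(j * C)] <-
      matrix(X[, j:(j + Lout - 1L), , drop = FALSE], n * Lout, C)
  }
  M
}

col2im_add <- function(dM, n, L, C, k) {
  Lout <- L - k + 1L
  dX <- array(0, c(n, L, C))
  for (j in seq_len(k)) {
    dX[, j:(j + Lout - 1L), ] <- dX[, j:(j + Lout - 1L), ] +
      array(dM[, ((j - 1L) * C + 1L):(j * C)], c(n, Lout, C))
  }
  dX
}

maxpool_fwd <- function(X, p) {
  n <- dim(X)[1L]; L <- dim(X)[2L]; Fc <- dim(X)[3L]
  Lp <- L %/% p
  Xt <- X[, seq_len(Lp * p), , drop = FALSE]
  dim(Xt) <- c(n, p, Lp, Fc)
  Y <- array(Xt[, 1L, , ], c(n, Lp, Fc))
  arg <- array(1L, c(n, Lp, Fc))
  if (p > 1L) {
    for (q in 2:p) {
      cur <- array(Xt[, q, , ], c(n, Lp, Fc))
      upd <- cur > Y
      Y[upd] <- cur[upd]
      arg[upd] <- q
    }
  }
  list(Y = Y, arg = arg, L = L, p = p)
}

maxpool_bwd <- function(dY, pool) {
  n <- dim(dY)[1L]; Lp <- dim(dY)[2L]; Fc <- dim(dY)[3L]
  dXt <- array(0, c(n, pool$p, Lp, Fc))
  for (q in seq_len(pool$p)) {
    mask <- pool$arg == q
    tmp <- array(0, c(n, Lp, Fc))
    tmp[mask] <- dY[mask]
    dXt[, q, , ] <- tmp
  }
  dim(dXt) <- c(n, pool$p * Lp, Fc)
  if (pool$p * Lp < pool$L) {
    dX <- array(0, c(n, pool$L, Fc))
    dX[, seq_len(pool$p * Lp), ] <- dXt
    dXt <- dX
  }
  dXt
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

cnn_dims <- function(arch, window_len, n_channels) {
  L1 <- window_len - arch$kernels[1L] + 1L
  Lp1 <- L1 %/% arch$pool[1L]
  L2 <- Lp1 - arch$kernels[2L] + 1L
  Lp2 <- L2 %/% arch$pool[2L]
  if (Lp2 < 1L) abort("window too short for this architecture")
  list(L1 = L1, Lp1 = Lp1, L2 = L2, Lp2 = Lp2,
       flat = Lp2 * arch$filters[2L])
}

cnn_init <- function(arch, window_len, n_channels) {
  d <- cnn_dims(arch, window_len, n_channels)
  he <- function(nr, nc, fan) matrix(rnorm(nr * nc, 0, sqrt(2 / fan)), nr, nc)
  k <- arch$kernels; f <- arch$filters
  list(
    W1 = he(k[1L] * n_channels, f[1L], k[1L] * n_channels),
    b1 = rep(0, f[1L]),
    W2 = he(k[2L] * f[1L], f[2L], k[2L] * f[1L]),
    b2 = rep(0, f[2L]),
    Wd = he(d$flat, arch$dense_units, d$flat),
    bd = rep(0, arch$dense_units),
    Wo = he(arch$dense_units, 1L, arch$dense_units),
    bo = 0
  )
}

cnn_forward <- function(params, arch, X, keep_cache = TRUE) {
  n <- dim(X)[1L]; L <- dim(X)[2L]; C <- dim(X)[3L]
  k <- arch$kernels; p <- arch$pool; f <- arch$filters
  M1 <- im2col(X, k[1L])
  Z1 <- sweep(M1 %*% params$W1, 2L, params$b1, "+")
  A1 <- array(relu(Z1), c(n, L - k[1L] + 1L, f[1L]))
  P1 <- maxpool_fwd(A1, p[1L])
  M2 <- im2col(P1$Y, k[2L])
  Z2 <- sweep(M2 %*% params$W2, 2L, params$b2, "+")
  A2 <- array(relu(Z2), c(n, dim(P1$Y)[2L] - k[2L] + 1L, f[2L]))
  P2 <- maxpool_fwd(A2, p[2L])
  flat <- P2$Y
  dim(flat) <- c(n, prod(dim(P2$Y)[2:3]))
  H <- relu(sweep(flat %*% params$Wd, 2L, params$bd, "+"))
  logit <- drop(H %*% params$Wo) + params$bo
  prob <- 1 / (1 + exp(-logit))
  if (!keep_cache) return(list(prob = prob))
  list(prob = prob, M1 = M1, Z1 = Z1, P1 = P1, M2 = M2, Z2 = Z2, P2 = P2,
       flat = flat, H = H, n = n, L = L, C = C)
}

cnn_backward <- function(params, arch, cache, y) {
  n <- cache$n
  k <- arch$kernels; f <- arch$filters
  dlogit <- (cache$prob - y) / n                       # d(mean BCE)/dlogit
  dWo <- t(cache$H) %*% dlogit
  dbo <- sum(dlogit)
  dH <- dlogit %*% t(params$Wo)
  dH[cache$H <= 0] <- 0
  dWd <- t(cache$flat) %*% dH
  dbd <- colSums(dH)
  dflat <- dH %*% t(params$Wd)
  dP2 <- array(dflat, c(n, dim(cache$P2$Y)[2L], f[2L]))
  dA2 <- maxpool_bwd(dP2, cache$P2)
  dZ2 <- matrix(dA2, nrow = n * dim(dA2)[2L])
  dZ2[cache$Z2 <= 0] <- 0
  dW2 <- t(cache$M2) %*% dZ2
  db2 <- colSums(dZ2)
  dM2 <- dZ2 %*% t(params$W2)
  dP1 <- col2im_add(dM2, n, dim(cache$P1$Y)[2L], f[1L], k[2L])
  dA1 <- maxpool_bwd(dP1, cache$P1)
  dZ1 <- matrix(dA1, nrow = n * dim(dA1)[2L])
  dZ1[cache$Z1 <= 0] <- 0
  dW1 <- t(cache$M1) %*% dZ1
  db1 <- colSums(dZ1)
  list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2, Wd = dWd, bd = dbd,
       Wo = dWo, bo = dbo)
}

bce_loss <- function(prob, y, eps = 1e-12) {
  p <- pmin(pmax(prob, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# Mini-batch training loop with best-validation-loss checkpointing.
cnn_fit <- function(X, y, Xval, yval, arch, epochs = 6L, batch = 128L,
                    lr = 1e-3, patience = 2L) {
  n <- dim(X)[1L]
  params <- cnn_init(arch, dim(X)[2L], dim(X)[3L])
  state <- adam_init(params)
  best <- list(loss = Inf, params = params)
  history <- tibble(epoch = integer(), train_loss = double(),
                    val_loss = double())
  stall <- 0L
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    tr_loss <- 0
    nb <- 0L
    for (start in seq(1L, n, by = batch)) {
      id <- ord[start:min(start + batch - 1L, n)]
      cache <- cnn_forward(params, arch, X[id, , , drop = FALSE])
      grads <- cnn_backward(params, arch, cache, y[id])
      upd <- adam_step(params, grads, state, lr = lr)
      params <- upd$params
      state <- upd$state
      tr_loss <- tr_loss + bce_loss(cache$prob, y[id])
      nb <- nb + 1L
    }
    val_loss <- bce_loss(
      cnn_predict_array(params, arch, Xval)$prob, yval)
    history <- add_row(history, epoch = ep, train_loss = tr_loss / nb,
                       val_loss = val_loss)
    if (val_loss < best$loss - 1e-5) {
      best <- list(loss = val_loss, params = params)
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= patience) break
    }
  }
  list(params = best$params, history = history)
}

cnn_predict_array <- function(params, arch, X, batch = 4096L) {
  n <- dim(X)[1L]
  prob <- numeric(n)
  for (start in seq(1L, n, by = batch)) {
    id <- start:min(start + batch - 1L, n)
    prob[id] <- cnn_forward(params, arch, X[id, , , drop = FALSE],
                            keep_cache = FALSE)$prob
  }
  list(prob = prob)
}
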