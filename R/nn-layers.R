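## Low-level network layers. Activations are stored as arrays with
## dimensions (H, W, N, C): channel last so a (H*W*N) x C matrix view is a
## free reshape, which keeps every layer a BLAS matrix product.

SELU_LAMBDA <- 1.0507009873554805
SELU_ALPHA <- 1.6732632423543772

seluForward <- function(x) {
  y <- x
  neg <- x <= 0
  y[neg] <- SELU_ALPHA * (exp(x[neg]) - 1)
  list(out = SELU_LAMBDA * y, cache = x)
}

seluBackward <- function(dY, cache) {
  d <- array(SELU_LAMBDA, dim = dim(cache))
  neg <- cache <= 0
  d[neg] <- SELU_LAMBDA * SELU_ALPHA * exp(cache[neg])
  dY * d
}

sigmoid <- function(x) 1 / (1 + exp(-x))

## 3x3 same-padding convolution, computed as nine shifted matrix products.
convForward <- function(X, Wk, b) {
  d <- dim(X); H <- d[1]; W <- d[2]; N <- d[3]; Cin <- d[4]
  Cout <- dim(Wk)[4]
  Xp <- array(0, c(H + 2L, W + 2L, N, Cin))
  Xp[2:(H + 1L), 2:(W + 1L), , ] <- X
  M <- H * W * N
  Y <- matrix(rep(b, each = M), M, Cout)
  for (di in 0:2) for (dj in 0:2) {
    Xo <- Xp[(1L + di):(H + di), (1L + dj):(W + dj), , , drop = FALSE]
    dim(Xo) <- c(M, Cin)
    Wo <- matrix(Wk[di + 1L, dj + 1L, , ], Cin, Cout)
    Y <- Y + Xo %*% Wo
  }
  dim(Y) <- c(H, W, N, Cout)
  list(out = Y, cache = list(Xp = Xp, dims = d))
}

convBackward <- function(dY, Wk, cache) {
  d <- cache$dims; H <- d[1]; W <- d[2]; N <- d[3]; Cin <- d[4]
  Cout <- dim(Wk)[4]
  M <- H * W * N
  dYm <- dY; dim(dYm) <- c(M, Cout)
  dW <- array(0, dim(Wk))
  dXp <- array(0, dim(cache$Xp))
  for (di in 0:2) for (dj in 0:2) {
    Xo <- cache$Xp[(1L + di):(H + di), (1L + dj):(W + dj), , , drop = FALSE]
    dim(Xo) <- c(M, Cin)
    dW[di + 1L, dj + 1L, , ] <- crossprod(Xo, dYm)
    dXo <- dYm %*% t(matrix(Wk[di + 1L, dj + 1L, , ], Cin, Cout))
    dim(dXo) <- c(H, W, N, Cin)
    dXp[(1L + di):(H + di), (1L + dj):(W + dj), , ] <-
      dXp[(1L + di):(H + di), (1L + dj):(W + dj), , , drop = FALSE] + dXo
  }
  list(dX = dXp[2:(H + 1L), 2:(W + 1L), , , drop = FALSE],
       dW = dW, db = colSums(dYm))
}

## Batch normalisation over (H, W, N) per channel. In training mode the
## batch statistics are used and the running statistics updated (momentum
## 0.1); in evaluation mode the running statistics are used.
bnForward <- function(X, gamma, beta, rmean, rvar, training,
                      momentum = 0.1, eps = 1e-5) {
  d <- dim(X); M <- prod(d[1:3]); C <- d[4]
  Xm <- X; dim(Xm) <- c(M, C)
  if (training) {
    mu <- colMeans(Xm)
    v <- colMeans(Xm^2) - mu^2
    v <- pmax(v, 0)
    rmean <- (1 - momentum) * rmean + momentum * mu
    rvar <- (1 - momentum) * rvar + momentum * v
  } else {
    mu <- rmean; v <- rvar
  }
  invstd <- 1 / sqrt(v + eps)
  xhat <- (Xm - rep(mu, each = M)) * rep(invstd, each = M)
  out <- xhat * rep(gamma, each = M) + rep(beta, each = M)
  dim(out) <- d
  list(out = out, rmean = rmean, rvar = rvar,
       cache = list(xhat = xhat, invstd = invstd, dims = d,
                    training = training))
}

bnBackward <- function(dY, gamma, cache) {
  d <- cache$dims; M <- prod(d[1:3]); C <- d[4]
  dYm <- dY; dim(dYm) <- c(M, C)
  xhat <- cache$xhat
  dgamma <- colSums(dYm * xhat)
  dbeta <- colSums(dYm)
  dxhat <- dYm * rep(gamma, each = M)
  if (cache$training) {
    dX <- rep(cache$invstd / M, each = M) *
      (M * dxhat - rep(colSums(dxhat), each = M) -
         xhat * rep(dgamma, each = M))
  } else {
    dX <- dxhat * rep(cache$invstd, each = M)
  }
  dim(dX) <- d
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

## Squeeze-and-excitation channel attention: global average pool, bottleneck
## of ratio r with ReLU, sigmoid gate, channel-wise rescale. The sigmoid
## keeps every weight strictly inside (0, 1).
seForward <- function(X, W1, b1, W2, b2) {
  d <- dim(X); HW <- d[1] * d[2]; N <- d[3]; C <- d[4]
  Xm <- X; dim(Xm) <- c(HW, N * C)
  S <- matrix(colMeans(Xm), N, C)
  Z1 <- S %*% W1 + rep(b1, each = N)
  H1 <- pmax(Z1, 0)
  Wt <- sigmoid(H1 %*% W2 + rep(b2, each = N))
  out <- Xm * rep(as.vector(Wt), each = HW)
  dim(out) <- d
  list(out = out, cache = list(Xm = Xm, S = S, Z1 = Z1, H1 = H1, Wt = Wt,
                               dims = d))
}

seBackward <- function(dY, W1, W2, cache) {
  d <- cache$dims; HW <- d[1] * d[2]; N <- d[3]; C <- d[4]
  dYm <- dY; dim(dYm) <- c(HW, N * C)
  wvec <- rep(as.vector(cache$Wt), each = HW)
  dXm <- dYm * wvec
  dWt <- matrix(colSums(dYm * cache$Xm), N, C)
  dZ2 <- dWt * cache$Wt * (1 - cache$Wt)
  dW2 <- crossprod(cache$H1, dZ2)
  db2 <- colSums(dZ2)
  dH1 <- tcrossprod(dZ2, W2)
  dZ1 <- dH1 * (cache$Z1 > 0)
  dW1 <- crossprod(cache$S, dZ1)
  db1 <- colSums(dZ1)
  dS <- tcrossprod(dZ1, W1)
  dXm <- dXm + rep(as.vector(dS) / HW, each = HW)
  dim(dXm) <- d
  list(dX = dXm, dW1 = dW1, db1 = db1, dW2 = dW2, db2 = db2)
}

## 2x2 average pooling (both spatial dimensions must be even).
poolForward <- function(X) {
  d <- dim(X); H <- d[1]; W <- d[2]
  ri <- seq(1L, H, 2L); ci <- seq(1L, W, 2L)
  Y <- (X[ri, ci, , , drop = FALSE] + X[ri + 1L, ci, , , drop = FALSE] +
        X[ri, ci + 1L, , , drop = FALSE] +
        X[ri + 1L, ci + 1L, , , drop = FALSE]) / 4
  list(out = Y, cache = d)
}

poolBackward <- function(dY, cache) {
  d <- cache
  dX <- array(0, d)
  ri <- seq(1L, d[1], 2L); ci <- seq(1L, d[2], 2L)
  q <- dY / 4
  dX[ri, ci, , ] <- q
  dX[ri + 1L, ci, , ] <- q
  dX[ri, ci + 1L, , ] <- q
  dX[ri + 1L, ci + 1L, , ] <- q
  dX
}

## CNN -> recurrent bridge: scalogram columns are time steps. The height
## axis is collapsed by average pooling, giving per-step features of size C.
bridgeForward <- function(X) {
  d <- dim(X); Hf <- d[1]; Tn <- d[2]; N <- d[3]; C <- d[4]
  xs <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    sl <- X[, t, , , drop = FALSE]
    dim(sl) <- c(Hf, N * C)
    xs[[t]] <- matrix(colMeans(sl), N, C)
  }
  list(out = xs, cache = d)
}

bridgeBackward <- function(dxs, cache) {
  d <- cache; Hf <- d[1]
  dX <- array(0, d)
  for (t in seq_along(dxs))
    dX[, t, , ] <- rep(as.vector(dxs[[t]]) / Hf, each = Hf)
  dX
}
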