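#' Mean absolute error loss
#'
#' The training criterion; identical to the MAE reported by
#' [computeMetrics()] when given the same vectors.
#'
#' @param yTrue,yPred numeric vectors or matrices of equal shape.
#' @return mean of `|yPred - yTrue|`.
#' @export
maeLoss <- function(yTrue, yPred) mean(abs(yPred - yTrue))

adamInit <- function(params, leaves) {
  list(m = lapply(leaves, function(p) getLeaf(params, p) * 0),
       v = lapply(leaves, function(p) getLeaf(params, p) * 0),
       t = 0L)
}

adamStep <- function(params, grads, state, leaves, lr = 0.001,
                     beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (i in seq_along(leaves)) {
    g <- getLeaf(grads, leaves[[i]])
    state$m[[i]] <- beta1 * state$m[[i]] + (1 - beta1) * g
    state$v[[i]] <- beta2 * state$v[[i]] + (1 - beta2) * g^2
    upd <- lr * (state$m[[i]] / bc1) / (sqrt(state$v[[i]] / bc2) + eps)
    params <- setLeaf(params, leaves[[i]],
                      getLeaf(params, leaves[[i]]) - upd)
  }
  list(params = params, state = state)
}

## Core optimisation loop. X: (H, W, N, C); Y: N x 2 raw mmHg labels.
## Labels are standardised internally (per-output mean/sd of the training
## labels); the statistics are stored on the returned model so predictBP()
## reports mmHg.
fitNetwork <- function(model, X, Y, epochs = 20L, batchSize = 32L,
                       lr = 0.001, seed = 1L, shuffle = TRUE,
                       verbose = FALSE) {
  cfg <- model@config
  params <- model@params
  N <- dim(X)[3]
  center <- colMeans(Y)
  scale <- pmax(apply(Y, 2, stats::sd), 1e-8)
  if (any(!is.finite(scale)) || nrow(Y) < 2L) {
    center <- c(0, 0); scale <- c(1, 1)
  }
  Ys <- sweep(sweep(Y, 2, center, "-"), 2, scale, "/")
  leaves <- trainableLeaves(params)
  opt <- adamInit(params, leaves)
  history <- numeric(epochs)
  withr::with_seed(as.integer(seed), {
    for (ep in seq_len(epochs)) {
      ord <- if (shuffle) sample.int(N) else seq_len(N)
      epochLoss <- 0; nb <- 0L
      for (s in seq(1L, N, by = batchSize)) {
        idx <- ord[s:min(N, s + batchSize - 1L)]
        Xb <- X[, , idx, , drop = FALSE]
        Yb <- Ys[idx, , drop = FALSE]
        fw <- nnForward(params, cfg, Xb, training = TRUE)
        params <- fw$params
        resid <- fw$pred - Yb
        loss <- mean(abs(resid))
        if (!is.finite(loss))
          stop("divergence error: non-finite training loss at epoch ", ep,
               " (try a lower learning rate)")
        dPred <- sign(resid) / length(resid)
        grads <- nnBackward(params, cfg, fw$cache, dPred)
        st <- adamStep(params, grads, opt, leaves, lr = lr)
        params <- st$params; opt <- st$state
        epochLoss <- epochLoss + loss; nb <- nb + 1L
      }
      history[ep] <- epochLoss / nb
      if (verbose)
        message(sprintf("epoch %d/%d: MAE (std units) %.4f", ep, epochs,
                        history[ep]))
    }
  })
  model@params <- params
  model@labelCenter <- as.numeric(center)
  model@labelScale <- as.numeric(scale)
  model@trained <- TRUE
  list(model = model, history = history)
}
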