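#' Architecture configuration for the attention CNN + BiLSTM regressor
#'
#' The network is `[conv 3x3 -> batch-norm -> SELU -> channel attention ->
#' 2x2 average pool] x convBlocks`; the resulting feature map is read as a
#' sequence along its time (width) axis with the height collapsed by
#' average pooling, fed to a two-layer bidirectional LSTM, and finished by
#' two dense layers emitting (SBP, DBP). The self-normalising SELU
#' activation follows each convolution and the first dense layer; channel
#' attention is squeeze-and-excitation with a sigmoid gate.
#'
#' Depths and widths are deliberately compact (tens of thousands of
#' parameters) so the full pipeline trains in minutes on one CPU core;
#' every size is configurable.
#'
#' @param variant `"single"` (one 3-channel scalogram image),
#'   `"four_branch"` (four weight-independent conv stacks whose per-step
#'   features are spliced before the recurrent stage), or `"fused12"`
#'   (one 12-channel fused tensor).
#' @param convBlocks number of conv blocks.
#' @param convChannels output channels per block (length `convBlocks`).
#' @param kernel spatial kernel size (only 3 is implemented).
#' @param attentionReduction squeeze-and-excitation bottleneck ratio.
#' @param lstmLayers number of BiLSTM layers (fixed at 2).
#' @param lstmHidden hidden units per LSTM direction.
#' @param fcSizes sizes of the two dense head layers; the last entry is the
#'   output count and must be 2 (SBP, DBP).
#' @return a validated list of class `mwppgModelConfig`.
#' @export
modelConfig <- function(variant = c("fused12", "single", "four_branch"),
                        convBlocks = 3L, convChannels = c(8L, 16L, 32L),
                        kernel = 3L, attentionReduction = 8L,
                        lstmLayers = 2L, lstmHidden = 32L,
                        fcSizes = c(32L, 2L)) {
  variant <- match.arg(variant)
  cfg <- list(variant = variant, convBlocks = as.integer(convBlocks),
              convChannels = as.integer(convChannels),
              kernel = as.integer(kernel),
              attentionReduction = as.integer(attentionReduction),
              lstmLayers = as.integer(lstmLayers),
              lstmHidden = as.integer(lstmHidden),
              fcSizes = as.integer(fcSizes), outputs = 2L)
  if (length(cfg$convChannels) != cfg$convBlocks)
    stop("configuration error: convChannels must have convBlocks entries")
  if (cfg$kernel != 3L)
    stop("configuration error: only kernel = 3 is implemented")
  if (cfg$lstmLayers != 2L)
    stop("configuration error: lstmLayers is fixed at 2")
  if (length(cfg$fcSizes) != 2L || cfg$fcSizes[2] != 2L)
    stop("configuration error: fcSizes must be two layers ending in 2 outputs")
  if (cfg$attentionReduction < 1L)
    stop("configuration error: attentionReduction must be >= 1")
  class(cfg) <- "mwppgModelConfig"
  cfg
}

expectedInChannels <- function(variant)
  switch(variant, single = 3L, fused12 = 12L, four_branch = 12L)

initConvStack <- function(cfg, inC) {
  blocks <- vector("list", cfg$convBlocks)
  cin <- inC
  for (b in seq_len(cfg$convBlocks)) {
    cout <- cfg$convChannels[b]
    cr <- max(1L, cout %/% cfg$attentionReduction)
    blocks[[b]] <- list(
      W = array(stats::rnorm(9 * cin * cout, 0, sqrt(2 / (9 * cin))),
                c(3L, 3L, cin, cout)),
      b = numeric(cout),
      gamma = rep(1, cout), beta = numeric(cout),
      rmean = numeric(cout), rvar = rep(1, cout),
      seW1 = matrix(stats::rnorm(cout * cr, 0, sqrt(2 / cout)), cout, cr),
      seb1 = numeric(cr),
      seW2 = matrix(stats::rnorm(cr * cout, 0, sqrt(2 / cr)), cr, cout),
      seb2 = numeric(cout)
    )
    cin <- cout
  }
  blocks
}

initLstmDir <- function(inD, hid) {
  s <- 1 / sqrt(hid)
  b <- numeric(4L * hid)
  b[(hid + 1L):(2L * hid)] <- 1  # forget-gate bias
  list(Wx = matrix(stats::runif(inD * 4 * hid, -s, s), inD, 4L * hid),
       Wh = matrix(stats::runif(hid * 4 * hid, -s, s), hid, 4L * hid),
       b = b)
}

#' Build an untrained blood-pressure regressor
#'
#' @param cfg an `mwppgModelConfig` from [modelConfig()].
#' @param inChannels input depth: 3 for `"single"`, 12 for `"fused12"` and
#'   `"four_branch"` (four 3-channel branches).
#' @param imgSize input image size `c(H, W)`; both must be divisible by
#'   `2^convBlocks`.
#' @param seed seed for the weight initialisation.
#' @return an untrained [BPModel-class].
#' @export
buildModel <- function(cfg, inChannels, imgSize = c(32, 32), seed = 1L) {
  stopifnot(inherits(cfg, "mwppgModelConfig"))
  if (inChannels != expectedInChannels(cfg$variant))
    stop(sprintf(
      "configuration error: variant '%s' expects %d input channels, got %d",
      cfg$variant, expectedInChannels(cfg$variant), inChannels))
  if (length(imgSize) == 1L) imgSize <- rep(imgSize, 2L)
  if (any(imgSize %% 2^cfg$convBlocks != 0))
    stop("configuration error: imgSize must be divisible by 2^convBlocks")
  cfg$imgSize <- as.integer(imgSize)
  withr::with_seed(as.integer(seed), {
    hid <- cfg$lstmHidden
    lastC <- cfg$convChannels[cfg$convBlocks]
    if (cfg$variant == "four_branch") {
      branches <- lapply(1:4, function(k) initConvStack(cfg, 3L))
      seqIn <- 4L * lastC
      convPart <- list(branches = branches)
    } else {
      convPart <- list(blocks = initConvStack(cfg, inChannels))
      seqIn <- lastC
    }
    params <- c(convPart, list(
      lstm1f = initLstmDir(seqIn, hid), lstm1b = initLstmDir(seqIn, hid),
      lstm2f = initLstmDir(2L * hid, hid), lstm2b = initLstmDir(2L * hid, hid),
      fc = list(
        W1 = matrix(stats::rnorm(2 * hid * cfg$fcSizes[1], 0,
                                 sqrt(1 / (2 * hid))), 2L * hid, cfg$fcSizes[1]),
        b1 = numeric(cfg$fcSizes[1]),
        W2 = matrix(stats::rnorm(prod(cfg$fcSizes), 0,
                                 sqrt(1 / cfg$fcSizes[1])),
                    cfg$fcSizes[1], cfg$fcSizes[2]),
        b2 = numeric(cfg$fcSizes[2])
      )
    ))
    new("BPModel", config = cfg, params = params)
  })
}

## Forward through one conv stack. `attnOff` forces the attention weights
## to 1 (used to verify the gating layer is live).
convStackForward <- function(blocks, X, training, attnOff = FALSE) {
  caches <- vector("list", length(blocks))
  A <- X
  for (b in seq_along(blocks)) {
    p <- blocks[[b]]
    cv <- convForward(A, p$W, p$b)
    bn <- bnForward(cv$out, p$gamma, p$beta, p$rmean, p$rvar, training)
    blocks[[b]]$rmean <- bn$rmean
    blocks[[b]]$rvar <- bn$rvar
    ac <- seluForward(bn$out)
    if (attnOff) {
      se <- list(out = ac$out, cache = NULL)
    } else {
      se <- seForward(ac$out, p$seW1, p$seb1, p$seW2, p$seb2)
    }
    pl <- poolForward(se$out)
    caches[[b]] <- list(cv = cv$cache, bn = bn$cache, ac = ac$cache,
                        se = se$cache, pl = pl$cache)
    A <- pl$out
  }
  list(out = A, caches = caches, blocks = blocks)
}

convStackBackward <- function(blocks, caches, dA) {
  grads <- vector("list", length(blocks))
  for (b in rev(seq_along(blocks))) {
    p <- blocks[[b]]; K <- caches[[b]]
    dA <- poolBackward(dA, K$pl)
    se <- seBackward(dA, p$seW1, p$seW2, K$se)
    dA <- seluBackward(se$dX, K$ac)
    bn <- bnBackward(dA, p$gamma, K$bn)
    cv <- convBackward(bn$dX, p$W, K$cv)
    dA <- cv$dX
    grads[[b]] <- list(W = cv$dW, b = cv$db, gamma = bn$dgamma,
                       beta = bn$dbeta, seW1 = se$dW1, seb1 = se$db1,
                       seW2 = se$dW2, seb2 = se$db2)
  }
  list(dX = dA, grads = grads)
}

## Full forward pass. X is (H, W, N, C). Returns predictions (N x 2,
## standardised units), caches for the backward pass, and params with
## updated batch-norm running statistics when training.
nnForward <- function(params, cfg, X, training = FALSE, attnOff = FALSE) {
  if (cfg$variant == "four_branch") {
    bridges <- vector("list", 4); stacks <- vector("list", 4)
    xsList <- vector("list", 4)
    for (k in 1:4) {
      st <- convStackForward(params$branches[[k]],
                             X[, , , (3L * k - 2L):(3L * k), drop = FALSE],
                             training, attnOff)
      params$branches[[k]] <- st$blocks
      br <- bridgeForward(st$out)
      stacks[[k]] <- st; bridges[[k]] <- br; xsList[[k]] <- br$out
    }
    Tn <- length(xsList[[1]])
    xs <- lapply(seq_len(Tn), function(t)
      do.call(cbind, lapply(xsList, `[[`, t)))
    convCache <- list(stacks = stacks, bridges = bridges)
  } else {
    st <- convStackForward(params$blocks, X, training, attnOff)
    params$blocks <- st$blocks
    br <- bridgeForward(st$out)
    xs <- br$out
    convCache <- list(stacks = list(st), bridges = list(br))
  }
  l1 <- biLstmForward(xs, params$lstm1f, params$lstm1b)
  l2 <- biLstmForward(l1$out, params$lstm2f, params$lstm2b)
  Tn <- length(xs); hid <- cfg$lstmHidden
  final <- cbind(l2$out[[Tn]][, 1:hid, drop = FALSE],
                 l2$out[[1L]][, hid + 1:hid, drop = FALSE])
  Z1 <- final %*% params$fc$W1 + rep(params$fc$b1, each = nrow(final))
  A1 <- seluForward(Z1)
  pred <- A1$out %*% params$fc$W2 + rep(params$fc$b2, each = nrow(final))
  list(pred = pred, params = params,
       cache = list(conv = convCache, l1 = l1, l2 = l2, xs = xs,
                    final = final, Z1 = Z1, A1 = A1, Tn = Tn))
}

nnBackward <- function(params, cfg, cache, dPred) {
  N <- nrow(dPred); hid <- cfg$lstmHidden; Tn <- cache$Tn
  fc <- params$fc
  dW2 <- crossprod(cache$A1$out, dPred)
  db2 <- colSums(dPred)
  dA1 <- tcrossprod(dPred, fc$W2)
  dZ1 <- seluBackward(dA1, cache$A1$cache)
  dW1 <- crossprod(cache$final, dZ1)
  db1 <- colSums(dZ1)
  dFinal <- tcrossprod(dZ1, fc$W1)
  dOut2 <- lapply(seq_len(Tn), function(t) matrix(0, N, 2L * hid))
  dOut2[[Tn]][, 1:hid] <- dFinal[, 1:hid, drop = FALSE]
  dOut2[[1L]][, hid + 1:hid] <- dOut2[[1L]][, hid + 1:hid, drop = FALSE] +
    dFinal[, hid + 1:hid, drop = FALSE]
  g2 <- biLstmBackward(dOut2, cache$l2$cache, params$lstm2f, params$lstm2b)
  g1 <- biLstmBackward(g2$dxs, cache$l1$cache, params$lstm1f, params$lstm1b)
  grads <- list(
    lstm1f = g1$gf, lstm1b = g1$gb, lstm2f = g2$gf, lstm2b = g2$gb,
    fc = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2)
  )
  if (cfg$variant == "four_branch") {
    lastC <- cfg$convChannels[cfg$convBlocks]
    grads$branches <- vector("list", 4)
    for (k in 1:4) {
      dxsK <- lapply(g1$dxs, function(m)
        m[, (lastC * (k - 1L) + 1L):(lastC * k), drop = FALSE])
      dF <- bridgeBackward(dxsK, cache$conv$bridges[[k]]$cache)
      bk <- convStackBackward(params$branches[[k]],
                              cache$conv$stacks[[k]]$caches, dF)
      grads$branches[[k]] <- bk$grads
    }
  } else {
    dF <- bridgeBackward(g1$dxs, cache$conv$bridges[[1]]$cache)
    bk <- convStackBackward(params$blocks, cache$conv$stacks[[1]]$caches, dF)
    grads$blocks <- bk$grads
  }
  grads
}

#' Apply squeeze-and-excitation channel attention to a feature map
#'
#' Standalone form of the attention layer: importance scores are computed
#' from globally pooled channel statistics and applied multiplicatively to
#' re-weight the feature map. Weights are strictly inside (0, 1) and the
#' spatial shape is unchanged.
#'
#' @param features array `H x W x N x C` (or `H x W x C` for one sample).
#' @param reduction bottleneck ratio (clipped so the bottleneck is >= 1).
#' @param seed seed for the (untrained) bottleneck weights.
#' @return list with `out` (re-weighted features, same shape) and `weights`
#'   (the per-sample, per-channel gate values).
#' @export
channelAttention <- function(features, reduction = 8, seed = 1L) {
  single <- length(dim(features)) == 3L
  if (single) dim(features) <- c(dim(features)[1:2], 1L, dim(features)[3])
  C <- dim(features)[4]
  cr <- max(1L, C %/% as.integer(reduction))
  withr::with_seed(as.integer(seed), {
    W1 <- matrix(stats::rnorm(C * cr, 0, sqrt(2 / C)), C, cr)
    W2 <- matrix(stats::rnorm(cr * C, 0, sqrt(2 / cr)), cr, C)
  })
  res <- seForward(features, W1, numeric(cr), W2, numeric(C))
  out <- res$out
  if (single) dim(out) <- dim(out)[c(1, 2, 4)]
  list(out = out, weights = res$cache$Wt)
}

trainableLeaves <- function(params, prefix = character()) {
  out <- list()
  for (nm in names(params)) {
    x <- params[[nm]]
    if (is.list(x)) {
      out <- c(out, trainableLeaves(x, c(prefix, nm)))
    } else if (is.numeric(x) && !nm %in% c("rmean", "rvar")) {
      out[[length(out) + 1L]] <- c(prefix, nm)
    }
  }
  out
}

getLeaf <- function(params, path) {
  for (p in path) params <- params[[p]]
  params
}

setLeaf <- function(params, path, value) {
  if (length(path) == 1L) {
    params[[path]] <- value
  } else {
    params[[path[1]]] <- setLeaf(params[[path[1]]], path[-1], value)
  }
  params
}

#' Number of trainable parameters of a model
#'
#' @param model a [BPModel-class].
#' @return integer count (batch-norm running statistics excluded).
#' @export
countParameters <- function(model) {
  stopifnot(is(model, "BPModel"))
  sum(vapply(trainableLeaves(model@params), function(p)
    length(getLeaf(model@params, p)), numeric(1)))
}

#' Predict blood pressure for a batch of inputs
#'
#' Runs the network in evaluation mode (batch-norm running statistics,
#' attention active) and maps the standardised outputs back to mmHg using
#' the label statistics learned at training time. Deterministic for fixed
#' weights.
#'
#' @param model a [BPModel-class].
#' @param X input array `H x W x N x C` (or `H x W x C` for one sample);
#'   `C` must match the model variant.
#' @param batchSize forward-pass chunk size.
#' @return matrix `N x 2` with columns `sbp`, `dbp` in mmHg.
#' @export
predictBP <- function(model, X, batchSize = 256L) {
  stopifnot(is(model, "BPModel"))
  if (length(dim(X)) == 3L) dim(X) <- c(dim(X)[1:2], 1L, dim(X)[3])
  d <- dim(X)
  if (d[4] != expectedInChannels(model@config$variant))
    stop(sprintf("input error: variant '%s' expects %d channels, got %d",
                 model@config$variant,
                 expectedInChannels(model@config$variant), d[4]))
  if (!identical(d[1:2], as.integer(model@config$imgSize)))
    stop("input error: image size does not match the built model")
  N <- d[3]
  preds <- matrix(0, N, 2)
  for (s in seq(1L, N, by = batchSize)) {
    e <- min(N, s + batchSize - 1L)
    fw <- nnForward(model@params, model@config,
                    X[, , s:e, , drop = FALSE], training = FALSE)
    preds[s:e, ] <- fw$pred
  }
  preds <- sweep(sweep(preds, 2, model@labelScale, "*"), 2,
                 model@labelCenter, "+")
  colnames(preds) <- c("sbp", "dbp")
  preds
}
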