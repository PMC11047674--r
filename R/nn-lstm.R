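## LSTM with the standard gate layout (input, forget, cell, output) and a
## bidirectional wrapper. Inputs are lists of T matrices (N x in).

lstmForward <- function(xs, Wx, Wh, b) {
  Tn <- length(xs); N <- nrow(xs[[1]]); hid <- nrow(Wh)
  h <- matrix(0, N, hid); cc <- matrix(0, N, hid)
  hs <- vector("list", Tn); cache <- vector("list", Tn)
  i1 <- 1:hid; i2 <- hid + i1; i3 <- 2L * hid + i1; i4 <- 3L * hid + i1
  for (t in seq_len(Tn)) {
    G <- xs[[t]] %*% Wx + h %*% Wh + rep(b, each = N)
    ig <- sigmoid(G[, i1, drop = FALSE])
    fg <- sigmoid(G[, i2, drop = FALSE])
    gg <- tanh(G[, i3, drop = FALSE])
    og <- sigmoid(G[, i4, drop = FALSE])
    cNew <- fg * cc + ig * gg
    tc <- tanh(cNew)
    hNew <- og * tc
    cache[[t]] <- list(x = xs[[t]], hprev = h, cprev = cc,
                       i = ig, f = fg, g = gg, o = og, tc = tc)
    h <- hNew; cc <- cNew
    hs[[t]] <- h
  }
  list(hs = hs, cache = cache)
}

lstmBackward <- function(dhs, cache, Wx, Wh) {
  Tn <- length(cache)
  N <- nrow(cache[[1]]$x); hid <- nrow(Wh)
  dWx <- matrix(0, nrow(Wx), ncol(Wx))
  dWh <- matrix(0, hid, ncol(Wh))
  db <- numeric(length = 4L * hid)
  dh <- matrix(0, N, hid); dc <- matrix(0, N, hid)
  dxs <- vector("list", Tn)
  for (t in rev(seq_len(Tn))) {
    K <- cache[[t]]
    dh <- dh + dhs[[t]]
    do_ <- dh * K$tc
    dcc <- dc + dh * K$o * (1 - K$tc^2)
    di <- dcc * K$g
    df <- dcc * K$cprev
    dg <- dcc * K$i
    dc <- dcc * K$f
    dG <- cbind(di * K$i * (1 - K$i), df * K$f * (1 - K$f),
                dg * (1 - K$g^2), do_ * K$o * (1 - K$o))
    dWx <- dWx + crossprod(K$x, dG)
    dWh <- dWh + crossprod(K$hprev, dG)
    db <- db + colSums(dG)
    dxs[[t]] <- tcrossprod(dG, Wx)
    dh <- tcrossprod(dG, Wh)
  }
  list(dxs = dxs, dWx = dWx, dWh = dWh, db = db)
}

## Bidirectional layer: forward pass over t = 1..T and a second pass over
## the reversed sequence; per-step output is the concatenation, aligned to
## the original time axis.
biLstmForward <- function(xs, pf, pb) {
  Tn <- length(xs)
  fw <- lstmForward(xs, pf$Wx, pf$Wh, pf$b)
  bw <- lstmForward(rev(xs), pb$Wx, pb$Wh, pb$b)
  out <- vector("list", Tn)
  for (t in seq_len(Tn))
    out[[t]] <- cbind(fw$hs[[t]], bw$hs[[Tn + 1L - t]])
  list(out = out, cache = list(fw = fw$cache, bw = bw$cache, Tn = Tn,
                               hid = nrow(pf$Wh)))
}

biLstmBackward <- function(douts, cache, pf, pb) {
  Tn <- cache$Tn; hid <- cache$hid
  dhf <- vector("list", Tn); dhb <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    dhf[[t]] <- douts[[t]][, 1:hid, drop = FALSE]
    dhb[[Tn + 1L - t]] <- douts[[t]][, hid + 1:hid, drop = FALSE]
  }
  gf <- lstmBackward(dhf, cache$fw, pf$Wx, pf$Wh)
  gb <- lstmBackward(dhb, cache$bw, pb$Wx, pb$Wh)
  dxs <- vector("list", Tn)
  for (t in seq_len(Tn))
    dxs[[t]] <- gf$dxs[[t]] + gb$dxs[[Tn + 1L - t]]
  list(dxs = dxs,
       gf = list(Wx = gf$dWx, Wh = gf$dWh, b = gf$db),
       gb = list(Wx = gb$dWx, Wh = gb$dWh, b = gb$db))
}
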