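## 256-level viridis lookup table (perceptually uniform, fixed for
## reproducibility of cached tensors).
viridisLUT <- local({
  lut <- NULL
  function() {
    if (is.null(lut))
      lut <<- t(grDevices::col2rgb(
        grDevices::hcl.colors(256, "viridis"))) / 255
    lut
  }
})

#' Bilinear resize of a matrix
#'
#' Pixel-center convention: output pixel i samples source coordinate
#' `(i - 0.5) * nrow(m) / H + 0.5`, clamped to the source grid. Recorded
#' here so cached tensors are bit-reproducible.
#'
#' @param m numeric matrix.
#' @param H,W output dimensions.
#' @return `H x W` matrix.
#' @export
resizeBilinear <- function(m, H, W) {
  S <- nrow(m); Tm <- ncol(m)
  sx <- pmin(pmax((seq_len(H) - 0.5) * S / H + 0.5, 1), S)
  sy <- pmin(pmax((seq_len(W) - 0.5) * Tm / W + 0.5, 1), Tm)
  i0 <- pmin(floor(sx), S - 1L); i0[S == 1] <- 1L
  j0 <- pmin(floor(sy), Tm - 1L); j0[Tm == 1] <- 1L
  i1 <- pmin(i0 + 1L, S); j1 <- pmin(j0 + 1L, Tm)
  fx <- sx - i0; fy <- sy - j0
  outer(1 - fx, 1 - fy) * m[i0, j0, drop = FALSE] +
    outer(fx, 1 - fy) * m[i1, j0, drop = FALSE] +
    outer(1 - fx, fy) * m[i0, j1, drop = FALSE] +
    outer(fx, fy) * m[i1, j1, drop = FALSE]
}

#' Render a scalogram as a fixed-size RGB image
#'
#' Magnitudes are min-max normalised per window to `[0, 1]`, resized with
#' bilinear interpolation to `size`, then mapped through a fixed 256-level
#' viridis colormap to three channels. Deterministic; an all-equal
#' scalogram maps to a uniform image at the colormap origin.
#'
#' @param s a [Scalogram-class].
#' @param size `c(H, W)` output image size in pixels.
#' @return numeric array `H x W x 3` with values in `[0, 1]`.
#' @export
scalogramToRGB <- function(s, size = c(64, 64)) {
  stopifnot(is(s, "Scalogram"), length(size) == 2L)
  m <- s@magnitudes
  rng <- range(m)
  v <- if (rng[2] > rng[1]) (m - rng[1]) / (rng[2] - rng[1]) else
    matrix(0, nrow(m), ncol(m))
  v <- resizeBilinear(v, size[1], size[2])
  v <- pmin(pmax(v, 0), 1)
  lut <- viridisLUT()
  idx <- pmin(floor(v * 256) + 1L, 256L)
  array(lut[idx, ], dim = c(size[1], size[2], 3L))
}

#' Fuse the four per-wavelength RGB images into a 12-channel tensor
#'
#' Depth-concatenates the RGB planes of the four images in Channel 1..4
#' order: depth blocks `1:3` hold Channel 1, `4:6` Channel 2, `7:9`
#' Channel 3 and `10:12` Channel 4. The stacking is lossless:
#' [channelBlock()] recovers each input image exactly.
#'
#' @param images list of exactly four `H x W x 3` arrays in `[0, 1]`,
#'   ordered Channel 1..4.
#' @return a [FusedTensor-class] of dimension `H x W x 12`.
#' @export
fuseChannels <- function(images) {
  if (!is.list(images) || length(images) != 4L)
    stop("arity error: exactly four RGB images are required")
  dims <- lapply(images, dim)
  for (k in 1:4) {
    d <- dims[[k]]
    if (length(d) != 3L || d[3] != 3L)
      stop("each image must be an H x W x 3 array (image ", k, ")")
  }
  if (!all(vapply(dims, function(d) identical(d[1:2], dims[[1]][1:2]),
                  logical(1))))
    stop("shape error: all four images must share the same height and width")
  d <- dims[[1]]
  new("FusedTensor",
      pixels = array(unlist(images), dim = c(d[1], d[2], 12L)))
}
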