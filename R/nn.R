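## Minimal convolutional network toolkit used by the codec, the diffusion
## noise predictor and the metal segmentation network. Tensors are plain R
## arrays dim (H, W, C); forward/backward conv kernels live in src/conv.cpp;
## optimization is Adam. Everything is seeded through R's RNG.

.actF <- function(z, act) {
  switch(act,
         linear  = z,
         relu    = pmax(z, 0),
         lrelu   = { y <- z; neg <- z < 0; y[neg] <- 0.2 * z[neg]; y },
         tanh    = tanh(z),
         sigmoid = 1 / (1 + exp(-z)),
         stop("unknown activation ", act))
}

.actG <- function(z, y, act) {
  # derivative wrt pre-activation, given z (pre) and y = actF(z)
  switch(act,
         linear  = 1,
         relu    = (z > 0) * 1,
         lrelu   = { g <- rep(1, length(z)); g[z < 0] <- 0.2
                     dim(g) <- dim(z); g },
         tanh    = 1 - y^2,
         sigmoid = y * (1 - y),
         stop("unknown activation ", act))
}

nnConv <- function(cin, cout, k = 3L, stride = 1L, act = "lrelu") {
  sdw <- sqrt(2 / (k * k * cin))
  list(type = "conv",
       w = array(rnorm(k * k * cin * cout, 0, sdw), c(k, k, cin, cout)),
       b = numeric(cout), k = as.integer(k), cin = as.integer(cin),
       cout = as.integer(cout), stride = as.integer(stride),
       pad = as.integer((k - 1) / 2), act = act)
}

.outSize <- function(n, k, stride, pad) (n + 2L * pad - k) %/% stride + 1L

nnConvF <- function(l, x, extraBias = NULL) {
  d <- dim(x)
  cols <- cpp_im2col(x, d[1], d[2], l$cin, l$k, l$stride, l$pad)
  zm <- cols %*% matrix(l$w, l$k * l$k * l$cin, l$cout)
  zm <- sweep(zm, 2L, l$b, `+`)
  if (!is.null(extraBias)) zm <- sweep(zm, 2L, extraBias, `+`)
  ho <- .outSize(d[1], l$k, l$stride, l$pad)
  wo <- .outSize(d[2], l$k, l$stride, l$pad)
  z <- array(zm, c(ho, wo, l$cout))
  y <- .actF(z, l$act)
  dim(y) <- dim(z)
  list(y = y, cache = list(dimIn = d, cols = cols, z = z, y = y))
}

nnConvB <- function(l, cache, gy) {
  gz <- gy * .actG(cache$z, cache$y, l$act)
  dz <- dim(cache$z)
  gzm <- matrix(gz, dz[1] * dz[2], dz[3])
  wm <- matrix(l$w, l$k * l$k * l$cin, l$cout)
  gw <- array(crossprod(cache$cols, gzm), dim(l$w))
  gb <- colSums(gzm)
  gcols <- gzm %*% t(wm)
  d <- cache$dimIn
  gx <- cpp_col2im(gcols, d[1], d[2], l$cin, l$k, l$stride, l$pad)
  list(gx = gx, gw = gw, gb = gb,
       gBias = gb)  # same reduction serves any extra per-channel bias
}

nnDense <- function(nin, nout, act = "linear") {
  list(type = "dense", w = matrix(rnorm(nin * nout, 0, sqrt(2 / nin)),
                                  nout, nin),
       b = numeric(nout), act = act)
}

nnDenseF <- function(l, x) {
  z <- drop(l$w %*% x) + l$b
  y <- .actF(z, l$act)
  list(y = y, cache = list(x = x, z = z, y = y))
}

nnDenseB <- function(l, cache, gy) {
  gz <- gy * .actG(cache$z, cache$y, l$act)
  list(gx = drop(crossprod(l$w, gz)), gw = outer(gz, cache$x), gb = gz)
}

nnUpsampleF <- function(x) {
  d <- dim(x)
  idx <- rep(seq_len(d[1]), each = 2)
  jdx <- rep(seq_len(d[2]), each = 2)
  y <- x[idx, jdx, , drop = FALSE]
  dim(y) <- c(2L * d[1], 2L * d[2], d[3])
  y
}

nnUpsampleB <- function(gy, dIn) {
  g <- array(0, dIn)
  for (dh in 0:1) for (dw in 0:1) {
    g <- g + gy[seq(1 + dh, 2 * dIn[1], by = 2),
                seq(1 + dw, 2 * dIn[2], by = 2), , drop = FALSE]
  }
  g
}

## Adam over a named list of parameter arrays.
adamInit <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adamStep <- function(params, grads, state, lr = 2e-4, beta1 = 0.9,
                     beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

## Flatten/restore network parameters to a named list for the optimizer.
.layerParams <- function(net) {
  out <- list()
  for (nm in names(net$layers)) {
    l <- net$layers[[nm]]
    out[[paste0(nm, ".w")]] <- l$w
    out[[paste0(nm, ".b")]] <- l$b
  }
  out
}

.setLayerParams <- function(net, params) {
  for (nm in names(net$layers)) {
    net$layers[[nm]]$w <- params[[paste0(nm, ".w")]]
    net$layers[[nm]]$b <- params[[paste0(nm, ".b")]]
  }
  net
}

#' Fixed random perceptual feature extractor
#'
#' A seeded, frozen multi-scale convolutional stack used for the
#' LPIPS-style perceptual term: layer-wise normalized feature distances
#' with unit channel weights. The extractor is deterministic for a given
#' seed and is never trained, which preserves all algebraic identities of
#' the perceptual loss (zero iff inputs identical) without external
#' pretrained weights.
#'
#' @param seed integer seed fixing the random filters.
#' @param channels channels per layer.
#' @return An object of class \code{"perceptualExtractor"}.
#' @export
perceptualExtractor <- function(seed = 7L, channels = c(8L, 8L)) {
  old <- .Random.seed_save()
  set.seed(seed)
  layers <- list()
  cin <- 1L
  for (i in seq_along(channels)) {
    layers[[paste0("p", i)]] <- nnConv(cin, channels[i], 3L, 2L, "lrelu")
    cin <- channels[i]
  }
  .Random.seed_restore(old)
  structure(list(layers = layers, seed = seed), class = "perceptualExtractor")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed",
                                                       envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}

.perceptForward <- function(fe, x) {
  caches <- list()
  feats <- list()
  h <- x
  for (nm in names(fe$layers)) {
    r <- nnConvF(fe$layers[[nm]], h)
    caches[[nm]] <- r$cache
    feats[[nm]] <- r$y
    h <- r$y
  }
  list(feats = feats, caches = caches)
}

#' Perceptual distance between two images
#'
#' Mean squared distance between the frozen extractor's features of the two
#' inputs, averaged per layer (unit channel weights).
#'
#' @param fe a \code{\link{perceptualExtractor}}.
#' @param a,b images as matrices or (H, W, 1) arrays on the same grid.
#' @param grad if TRUE also return the gradient with respect to \code{a}.
#' @return the scalar distance, or a list \code{(value, grad)}.
#' @export
perceptualDistance <- function(fe, a, b, grad = FALSE) {
  if (is.matrix(a)) dim(a) <- c(dim(a), 1L)
  if (is.matrix(b)) dim(b) <- c(dim(b), 1L)
  fa <- .perceptForward(fe, a)
  fb <- .perceptForward(fe, b)
  val <- 0
  gys <- list()
  for (nm in names(fa$feats)) {
    dd <- fa$feats[[nm]] - fb$feats[[nm]]
    val <- val + mean(dd^2)
    gys[[nm]] <- 2 * dd / length(dd)
  }
  if (!grad) return(val)
  # backprop the sum of layer losses through the extractor to input a
  g <- NULL
  nms <- names(fe$layers)
  for (i in rev(seq_along(nms))) {
    nm <- nms[i]
    gy <- gys[[nm]]
    if (!is.null(g)) gy <- gy + g
    g <- nnConvB(fe$layers[[nm]], fa$caches[[nm]], gy)$gx
  }
  list(value = val, grad = g)
}
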