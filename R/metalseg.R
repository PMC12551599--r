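## Metal segmentation: dataset synthesis (phantom-derived artifact maps
## overlaid on metal-free slices), adaptive-threshold pseudo-labels, a
## compact U-net trained with Dice + BCE, and thresholded inference.

#' Synthesize a metal-segmentation training set
#'
#' For each output sample an artifact map (corrupted minus clean) from a
#' phantom pair is rotated by a seeded random angle and overlaid onto a
#' metal-free slice; the identically rotated metal mask is the label.
#'
#' @param pairs list of \code{"phantomPair"} objects.
#' @param cleanSlices list of metal-free \linkS4class{CTImage}s.
#' @param nOut number of samples to emit.
#' @param seed integer seed; the emitted manifest is fully determined by it.
#' @return list of samples, each \code{list(input, label, source, pair,
#'   slice, rotationDeg)}.
#' @export
synthesizeSegDataset <- function(pairs, cleanSlices, nOut, seed = 1L) {
  if (length(pairs) == 0L || length(cleanSlices) == 0L)
    stop("need at least one phantom pair and one clean slice")
  if (nOut == 0L) return(list())
  set.seed(seed)
  pairIdx <- sample.int(length(pairs), nOut, replace = TRUE)
  sliceIdx <- sample.int(length(cleanSlices), nOut, replace = TRUE)
  rots <- runif(nOut, 0, 360)
  lapply(seq_len(nOut), function(k) {
    p <- pairs[[pairIdx[k]]]
    amap <- extractArtifactMap(p$corrupted, p$clean)
    ov <- overlayArtifact(amap, cleanSlices[[sliceIdx[k]]],
                          metalMask = p$metalMask, rotationDeg = rots[k])
    list(input = ov$image, label = ov$mask, source = "phantom_derived",
         pair = pairIdx[k], slice = sliceIdx[k], rotationDeg = rots[k])
  })
}

#' Pseudo-label metal by adaptive thresholding and morphology
#'
#' Locally adaptive thresholding followed by retention of the
#' brightest components, morphological closing and hole filling; the
#' heuristic labelling route for slices without ground truth.
#'
#' @param image \linkS4class{CTImage} or matrix.
#' @param blockSize adaptive-threshold window half-width (pixels).
#' @param offset additive offset of the local threshold, as a fraction of
#'   the image's robust maximum.
#' @param brightFrac keep components whose mean intensity exceeds this
#'   fraction of the robust maximum.
#' @param closeRadius radius of the closing brush (pixels).
#' @return binary matrix (possibly empty).
#' @export
pseudoLabel <- function(image, blockSize = 7L, offset = 0.35,
                        brightFrac = 0.55, closeRadius = 2L) {
  v <- if (is(image, "CTImage")) image@values else image
  stopifnot(all(is.finite(v)))
  hi <- stats::quantile(v, 0.999, names = FALSE)
  if (hi <= 0) return(matrix(FALSE, nrow(v), ncol(v)))
  eb <- EBImage::Image(v / hi)
  th <- EBImage::thresh(eb, w = blockSize, h = blockSize, offset = offset)
  m <- EBImage::imageData(th) > 0.5
  if (!any(m)) return(m)
  lab <- EBImage::bwlabel(EBImage::Image(m * 1))
  ld <- EBImage::imageData(lab)
  keep <- vapply(seq_len(max(ld)), function(k)
    mean(v[ld == k]) >= brightFrac * hi, logical(1))
  m <- matrix(ld %in% which(keep), nrow(v), ncol(v))
  if (any(m) && closeRadius > 0) {
    br <- EBImage::makeBrush(2L * closeRadius + 1L, shape = "disc")
    m <- EBImage::imageData(EBImage::closing(EBImage::Image(m * 1), br)) > 0.5
  }
  if (any(m))
    m <- EBImage::imageData(EBImage::fillHull(EBImage::Image(m * 1))) > 0.5
  matrix(m, nrow(v), ncol(v))
}

#' Compound segmentation loss (Dice + BCE)
#'
#' @param pred soft prediction in [0, 1].
#' @param label binary ground truth of the same shape.
#' @return list of class \code{"segLossParts"}: \code{dice} (1 - Dice
#'   overlap), \code{bce} (mean binary cross-entropy), \code{total}.
#' @export
segLoss <- function(pred, label) {
  if (!identical(dim(pred), dim(label)) &&
      !identical(length(pred), length(label)))
    stop("prediction and label shapes differ")
  if (any(pred < 0 | pred > 1)) stop("predictions must lie in [0, 1]")
  g <- as.numeric(label)
  p <- as.numeric(pred)
  sm <- 1e-7
  dice <- 1 - 2 * sum(p * g) / (sum(p) + sum(g) + sm)
  pc <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  bce <- mean(-g * log(pc) - (1 - g) * log(1 - pc))
  structure(list(dice = dice, bce = bce, total = dice + bce),
            class = "segLossParts")
}

#' Dice overlap coefficient of two binary masks
#'
#' @param a,b binary masks.
#' @return Dice coefficient in [0, 1] (1 when both masks are empty).
#' @export
diceCoef <- function(a, b) {
  a <- as.logical(a); b <- as.logical(b)
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}

#' Create an untrained metal-segmentation network
#'
#' A compact two-scale U-net: strided encoder, bottleneck, nearest-neighbour
#' upsampling with a skip concatenation, sigmoid output.
#'
#' @param channels base channel width.
#' @param seed integer seed for initialization.
#' @return object of class \code{"segNet"}.
#' @export
segNet <- function(channels = 12L, seed = 1L) {
  set.seed(seed)
  c1 <- channels; c2 <- 2L * channels
  layers <- list(
    s1 = nnConv(1L, c1, 3L, 1L, "lrelu"),
    s2 = nnConv(c1, c2, 3L, 2L, "lrelu"),
    s3 = nnConv(c2, c2, 3L, 1L, "lrelu"),
    s4 = nnConv(c1 + c2, c1, 3L, 1L, "lrelu"),
    s5 = nnConv(c1, 1L, 3L, 1L, "linear"))
  structure(list(layers = layers, channels = as.integer(channels),
                 normScale = 0.05, trained = FALSE, seed = seed),
            class = "segNet")
}

.segForward <- function(net, x) {
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L)
  L <- net$layers
  r1 <- nnConvF(L$s1, x)
  r2 <- nnConvF(L$s2, r1$y)
  r3 <- nnConvF(L$s3, r2$y)
  up <- nnUpsampleF(r3$y)
  cat1 <- array(c(r1$y, up), c(dim(r1$y)[1], dim(r1$y)[2],
                               dim(r1$y)[3] + dim(up)[3]))
  r4 <- nnConvF(L$s4, cat1)
  r5 <- nnConvF(L$s5, r4$y)
  prob <- 1 / (1 + exp(-r5$y[, , 1]))
  list(prob = prob, z = r5$y[, , 1],
       caches = list(c1 = r1$cache, c2 = r2$cache, c3 = r3$cache,
                     c4 = r4$cache, c5 = r5$cache, dimUp = dim(r3$y),
                     nSkip = dim(r1$y)[3]))
}

.segBackward <- function(net, fwd, gz) {
  L <- net$layers
  gz5 <- array(gz, c(dim(gz), 1L))
  g5 <- nnConvB(L$s5, fwd$caches$c5, gz5)
  g4 <- nnConvB(L$s4, fwd$caches$c4, g5$gx)
  nSkip <- fwd$caches$nSkip
  gSkip <- g4$gx[, , seq_len(nSkip), drop = FALSE]
  gUp <- g4$gx[, , -seq_len(nSkip), drop = FALSE]
  g3 <- nnConvB(L$s3, fwd$caches$c3, nnUpsampleB(gUp, fwd$caches$dimUp))
  g2 <- nnConvB(L$s2, fwd$caches$c2, g3$gx)
  g1 <- nnConvB(L$s1, fwd$caches$c1, g2$gx + gSkip)
  list("s1.w" = g1$gw, "s1.b" = g1$gb, "s2.w" = g2$gw, "s2.b" = g2$gb,
       "s3.w" = g3$gw, "s3.b" = g3$gb, "s4.w" = g4$gw, "s4.b" = g4$gb,
       "s5.w" = g5$gw, "s5.b" = g5$gb)
}

.segGradLogit <- function(prob, label) {
  g <- as.numeric(label)
  p <- as.numeric(prob)
  n <- length(p)
  sm <- 1e-7
  A <- sum(p * g); B <- sum(p) + sum(g) + sm
  # d(1 - 2A/B)/dp_i = -2 (g_i B - A) / B^2 ; chain through sigmoid
  gDice <- -2 * (g * B - A) / B^2
  gBce <- (p - g) / n            # bce gradient wrt logit directly
  gz <- gDice * p * (1 - p) + gBce
  matrix(gz, nrow(prob), ncol(prob))
}

#' Train the metal-segmentation network
#'
#' Adam on Dice + BCE over synthesized samples. Inputs are scaled by the
#' fixed normalization constant stored in the network (attenuation window),
#' the same scaling applied at inference.
#'
#' @param net a \code{\link{segNet}}.
#' @param samples list from \code{\link{synthesizeSegDataset}}.
#' @param epochs training epochs.
#' @param lr learning rate.
#' @param seed integer seed (shuffling and crop placement).
#' @param cropSize train on seeded random square crops of this side
#'   (biased toward metal-containing windows); 0 trains on full slices.
#'   Inference is always full-slice (the network is fully convolutional).
#' @param verbose print epoch losses.
#' @return the trained network (with \code{lossHistory}).
#' @export
trainSegNet <- function(net, samples, epochs = 8L, lr = 1e-3, seed = 1L,
                        cropSize = 32L, verbose = FALSE) {
  stopifnot(length(samples) > 0)
  xs <- lapply(samples, function(s) s$input@values / net$normScale)
  ys <- lapply(samples, function(s) s$label * 1)
  params <- .layerParams(net)
  st <- adamInit(params)
  set.seed(seed)
  hist <- numeric(0)
  for (ep in seq_len(epochs)) {
    ord <- sample(length(xs))
    epLoss <- 0
    for (i in ord) {
      x <- xs[[i]]; y <- ys[[i]]
      if (cropSize > 0 && cropSize < nrow(x)) {
        n <- nrow(x)
        met <- which(y > 0)
        if (length(met) && runif(1) < 0.7) {
          # centre the crop near a metal pixel
          p <- met[sample.int(length(met), 1L)]
          pr <- (p - 1L) %% n + 1L
          pc <- (p - 1L) %/% n + 1L
          r0 <- min(max(pr - cropSize %/% 2L, 1L), n - cropSize + 1L)
          c0 <- min(max(pc - cropSize %/% 2L, 1L), n - cropSize + 1L)
        } else {
          r0 <- sample.int(n - cropSize + 1L, 1L)
          c0 <- sample.int(n - cropSize + 1L, 1L)
        }
        x <- x[r0:(r0 + cropSize - 1L), c0:(c0 + cropSize - 1L)]
        y <- y[r0:(r0 + cropSize - 1L), c0:(c0 + cropSize - 1L)]
      }
      net <- .setLayerParams(net, params)
      fwd <- .segForward(net, x)
      l <- segLoss(fwd$prob, y)
      gz <- .segGradLogit(fwd$prob, y)
      grads <- .segBackward(net, fwd, gz)
      up <- adamStep(params, grads, st, lr)
      params <- up$params; st <- up$state
      epLoss <- epLoss + l$total
    }
    hist <- c(hist, epLoss / length(xs))
    if (verbose) message(sprintf("epoch %d loss %.4f", ep, tail(hist, 1)))
  }
  net <- .setLayerParams(net, params)
  net$trained <- TRUE
  net$lossHistory <- hist
  net
}

#' Segment metal in a slice
#'
#' Thresholds the trained network's soft output at 0.5 and removes
#' components smaller than \code{minComponent} pixels.
#'
#' @param image \linkS4class{CTImage} or matrix (attenuation units).
#' @param net trained \code{\link{segNet}}.
#' @param minComponent minimum connected-component size kept (pixels).
#' @return binary matrix.
#' @export
segmentMetal <- function(image, net, minComponent = 4L) {
  if (!isTRUE(net$trained)) stop("segmentation network is not trained")
  v <- if (is(image, "CTImage")) image@values else image
  fwd <- .segForward(net, v / net$normScale)
  m <- fwd$prob > 0.5
  if (any(m) && minComponent > 1L) {
    ld <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(m * 1)))
    sizes <- tabulate(ld[ld > 0])
    keep <- which(sizes >= minComponent)
    m <- matrix(ld %in% keep, nrow(v), ncol(v))
  }
  m
}
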