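## Vector-quantized autoencoder (VQ-VAE with online dead-code refresh).
## Maps windowed attenuation slices to a compact quantized latent grid and
## back; trained with reconstruction MSE + codebook + commitment + an
## LPIPS-style perceptual term:
##   L = MSE(f, f0) + ||sg[E(f0)] - z_q||^2 + beta ||E(f0) - sg[z_q]||^2
##       + lambda_p * perceptual(f, f0)

#' Create an untrained vector-quantized codec
#'
#' Desk-scale architecture: a strided convolutional encoder with
#' \code{downsample}-fold spatial reduction to a \code{latentDim}-channel
#' latent grid, a nearest-neighbour vector quantizer with \code{nCodes}
#' code vectors, and a mirrored decoder. Image intensities are linearly
#' mapped from the attenuation \code{window} (mm^-1) to [-1, 1] (values
#' above the window, i.e. metal, extend beyond 1 up to \code{clampMax})
#' before encoding.
#'
#' @param imageSize input side length (must be divisible by
#'   \code{downsample}).
#' @param latentDim latent embedding dimension D.
#' @param nCodes number of codebook vectors K.
#' @param channels encoder channel widths for the two strided stages.
#' @param window attenuation window (mm^-1) mapped to [-1, 1].
#' @param clampMax upper clamp of windowed intensities.
#' @param beta commitment loss weight.
#' @param lambdaP perceptual loss weight.
#' @param seed integer seed for weight initialization.
#' @return An object of class \code{"vqCodec"}.
#' @examples
#' cdc <- vqCodec(64, seed = 1)
#' @export
vqCodec <- function(imageSize = 64L, latentDim = 4L, nCodes = 64L,
                    channels = c(16L, 32L), window = c(0, 0.05),
                    clampMax = 3, beta = 0.25, lambdaP = 0.01, seed = 1L) {
  if (imageSize %% 4L != 0L)
    stop("image side must be divisible by the downsample factor 4; ",
         "pad the image to ", 4L * ceiling(imageSize / 4), " pixels")
  set.seed(seed)
  layers <- list(
    e1 = nnConv(1L, channels[1], 3L, 2L, "lrelu"),
    e2 = nnConv(channels[1], channels[2], 3L, 2L, "lrelu"),
    e3 = nnConv(channels[2], latentDim, 3L, 1L, "linear"),
    d1 = nnConv(latentDim, channels[2], 3L, 1L, "lrelu"),
    d2 = nnConv(channels[2], channels[2], 3L, 1L, "lrelu"),
    d3 = nnConv(channels[2], channels[1], 3L, 1L, "lrelu"),
    d4 = nnConv(channels[1], 1L, 3L, 1L, "linear"))
  codebook <- list(K = as.integer(nCodes), D = as.integer(latentDim),
                   vectors = matrix(rnorm(nCodes * latentDim, 0, 0.5),
                                    nCodes, latentDim),
                   usage = numeric(nCodes))
  structure(list(layers = layers, codebook = codebook,
                 imageSize = as.integer(imageSize),
                 latentDim = as.integer(latentDim), downsample = 4L,
                 window = window, clampMax = clampMax, beta = beta,
                 lambdaP = lambdaP,
                 perceptual = perceptualExtractor(seed + 1000L),
                 trained = FALSE, seed = seed),
            class = "vqCodec")
}

#' Map attenuation values to the codec's normalized intensity scale
#'
#' @param codec a \code{\link{vqCodec}}.
#' @param values numeric matrix/array of attenuation (mm^-1).
#' @return windowed values in [-1, clampMax].
#' @export
windowNormalize <- function(codec, values) {
  w <- codec$window
  v <- 2 * (values - w[1]) / (w[2] - w[1]) - 1
  pmin(pmax(v, -1), codec$clampMax)
}

#' @rdname windowNormalize
#' @export
windowDenormalize <- function(codec, values) {
  w <- codec$window
  (values + 1) / 2 * (w[2] - w[1]) + w[1]
}

.encForward <- function(codec, xn) {
  if (is.matrix(xn)) dim(xn) <- c(dim(xn), 1L)
  r1 <- nnConvF(codec$layers$e1, xn)
  r2 <- nnConvF(codec$layers$e2, r1$y)
  r3 <- nnConvF(codec$layers$e3, r2$y)
  list(z = r3$y, caches = list(e1 = r1$cache, e2 = r2$cache, e3 = r3$cache))
}

.decForward <- function(codec, zq) {
  r1 <- nnConvF(codec$layers$d1, zq)
  r2 <- nnConvF(codec$layers$d2, r1$y)
  u1 <- nnUpsampleF(r2$y)
  r3 <- nnConvF(codec$layers$d3, u1)
  u2 <- nnUpsampleF(r3$y)
  r4 <- nnConvF(codec$layers$d4, u2)
  list(out = r4$y,
       caches = list(d1 = r1$cache, d2 = r2$cache, d3 = r3$cache,
                     d4 = r4$cache, dimU1 = dim(r2$y), dimU2 = dim(r3$y)))
}

#' Nearest-neighbour vector quantization
#'
#' Assigns each latent location to its nearest codebook vector (Euclidean).
#' Quantizing an already-quantized grid returns identical indices.
#'
#' @param codebook the codec's codebook list.
#' @param z latent grid (h, w, D).
#' @return list with \code{indices} (h x w) and \code{zq} (h, w, D).
#' @export
quantizeLatent <- function(codebook, z) {
  d <- dim(z)
  flat <- matrix(z, d[1] * d[2], d[3])
  # ||z - c||^2 = ||z||^2 - 2 z.c + ||c||^2; argmin over codes
  cross <- flat %*% t(codebook$vectors)
  cn <- rowSums(codebook$vectors^2)
  idx <- max.col(2 * cross - matrix(cn, nrow(flat), codebook$K,
                                    byrow = TRUE), ties.method = "first")
  zq <- codebook$vectors[idx, , drop = FALSE]
  dim(idx) <- d[1:2]
  zqArr <- array(zq, d)
  list(indices = idx, zq = zqArr)
}

#' Encode an image to its latent code
#'
#' @param codec a \code{\link{vqCodec}}.
#' @param image a \linkS4class{CTImage} or numeric matrix (attenuation,
#'   mm^-1) whose side is divisible by the downsample factor.
#' @return list of class \code{"latentCode"}: \code{grid} (continuous
#'   encoder output), \code{indices}, \code{quantized}.
#' @export
encodeImage <- function(codec, image) {
  v <- if (is(image, "CTImage")) image@values else image
  if (nrow(v) %% codec$downsample != 0L)
    stop("image side must be divisible by ", codec$downsample,
         "; pad to ", codec$downsample * ceiling(nrow(v) / codec$downsample))
  xn <- windowNormalize(codec, v)
  enc <- .encForward(codec, xn)
  q <- quantizeLatent(codec$codebook, enc$z)
  structure(list(grid = enc$z, indices = q$indices, quantized = q$zq),
            class = "latentCode")
}

#' Decode a latent grid back to an image
#'
#' Accepts either the continuous encoder output or the quantized grid.
#'
#' @param codec a \code{\link{vqCodec}}.
#' @param latent a \code{"latentCode"} (its quantized grid is used) or a
#'   raw (h, w, D) array.
#' @param pixelSize pixel size of the output image (mm).
#' @return A \linkS4class{CTImage} in attenuation units.
#' @export
decodeLatent <- function(codec, latent, pixelSize = 3) {
  z <- if (inherits(latent, "latentCode")) latent$quantized else latent
  out <- .decForward(codec, z)$out
  ctImage(windowDenormalize(codec, out[, , 1]), pixelSize)
}

#' Composite codec loss
#'
#' The four-part vector-quantization training loss: reconstruction MSE,
#' codebook term \eqn{\|sg[E] - z_q\|^2}, commitment term
#' \eqn{\beta\|E - sg[z_q]\|^2}, and the perceptual feature distance with
#' weight \code{lambdaP}. Stop-gradients affect derivatives only, never
#' values, so \code{codebook + commit = (1 + beta) * ||E - z_q||^2}.
#'
#' @param f reconstructed image (windowed units, matrix).
#' @param f0 original image (windowed units, matrix).
#' @param z continuous encoder output (h, w, D).
#' @param zq quantized latent (h, w, D).
#' @param beta commitment weight (>= 0).
#' @param lambdaP perceptual weight (>= 0).
#' @param fe perceptual extractor (NULL to skip the term).
#' @return list of class \code{"codecLossParts"} with \code{recon},
#'   \code{codebook}, \code{commit}, \code{perceptual}, \code{total}.
#' @export
codecLoss <- function(f, f0, z, zq, beta = 0.25, lambdaP = 0.01,
                      fe = NULL) {
  if (beta < 0 || lambdaP < 0) stop("loss weights must be nonnegative")
  recon <- mean((f - f0)^2)
  qdiff <- mean((z - zq)^2)
  perc <- if (!is.null(fe)) perceptualDistance(fe, f, f0) else 0
  parts <- list(recon = recon, codebook = qdiff, commit = beta * qdiff,
                perceptual = perc,
                total = recon + qdiff + beta * qdiff + lambdaP * perc)
  class(parts) <- "codecLossParts"
  parts
}

#' Gradients of the codec loss with stop-gradient routing
#'
#' Computes the analytic gradients of \code{\link{codecLoss}} with respect
#' to the encoder output and the codebook vectors under the standard
#' stop-gradient convention: the codebook term moves only the codebook, the
#' commitment term only the encoder, and the reconstruction gradient
#' reaches the encoder by the straight-through copy.
#'
#' @param z continuous encoder output (h, w, D).
#' @param zq quantized latent (h, w, D).
#' @param indices code assignment matrix (h x w).
#' @param K number of codes.
#' @param beta commitment weight.
#' @param gRecon gradient of downstream loss wrt zq (straight-through
#'   input; 0 if absent).
#' @return list with \code{gEncoder} (h, w, D) and \code{gCodebook} (K x D).
#' @export
codecLossGrads <- function(z, zq, indices, K, beta = 0.25, gRecon = 0) {
  nl <- length(z)
  diffFlat <- matrix(z - zq, ncol = dim(z)[3])
  # commitment: d/dE beta * mean((E - sg[zq])^2)
  gEnc <- array(2 * beta * (z - zq) / nl, dim(z))
  if (!identical(gRecon, 0)) gEnc <- gEnc + gRecon  # straight-through
  # codebook: d/dc mean((sg[E] - zq)^2); accumulate -2(E - c)/n per use
  gCb <- matrix(0, K, dim(z)[3])
  idx <- as.vector(indices)
  acc <- rowsum(-2 * diffFlat / nl, idx)
  gCb[as.integer(rownames(acc)), ] <- acc
  list(gEncoder = gEnc, gCodebook = gCb)
}

#' Re-anchor rarely used codebook vectors
#'
#' Codes whose decayed usage falls below \code{threshold} are moved to
#' cluster centres of the recent encoder outputs that were not assigned to
#' any healthy code, the online clustering mechanism that keeps the
#' codebook alive. Deterministic under a fixed RNG state.
#'
#' @param codebook the codec codebook list.
#' @param recentFeatures matrix (n x D) of recent encoder outputs.
#' @param threshold usage count below which a code is considered dead.
#' @return the updated codebook.
#' @export
refreshDeadCodes <- function(codebook, recentFeatures, threshold = 1) {
  stopifnot(nrow(recentFeatures) > 0)
  dead <- which(codebook$usage < threshold)
  if (length(dead) == 0L) return(codebook)
  nc <- min(length(dead), nrow(recentFeatures))
  cl <- suppressWarnings(
    kmeans(recentFeatures, centers = nc, nstart = 1, iter.max = 20))
  codebook$vectors[dead[seq_len(nc)], ] <- cl$centers
  codebook$usage[dead[seq_len(nc)]] <- threshold
  codebook
}

.codecStep <- function(codec, xn) {
  # forward
  enc <- .encForward(codec, xn)
  q <- quantizeLatent(codec$codebook, enc$z)
  dec <- .decForward(codec, q$zq)
  f <- dec$out[, , 1]
  loss <- codecLoss(f, xn, enc$z, q$zq, codec$beta, codec$lambdaP,
                    codec$perceptual)
  # backward: reconstruction + perceptual wrt f
  gf <- 2 * (f - xn) / length(f)
  if (codec$lambdaP > 0) {
    pd <- perceptualDistance(codec$perceptual, f, xn, grad = TRUE)
    gf <- gf + codec$lambdaP * pd$grad[, , 1]
  }
  gOut <- array(gf, c(dim(f), 1L))
  L <- codec$layers
  g4 <- nnConvB(L$d4, dec$caches$d4, gOut)
  gU2 <- nnUpsampleB(g4$gx, dec$caches$dimU2)
  g3 <- nnConvB(L$d3, dec$caches$d3, gU2)
  gU1 <- nnUpsampleB(g3$gx, dec$caches$dimU1)
  g2 <- nnConvB(L$d2, dec$caches$d2, gU1)
  g1 <- nnConvB(L$d1, dec$caches$d1, g2$gx)
  lg <- codecLossGrads(enc$z, q$zq, q$indices, codec$codebook$K,
                       codec$beta, gRecon = g1$gx)
  ge3 <- nnConvB(L$e3, enc$caches$e3, lg$gEncoder)
  ge2 <- nnConvB(L$e2, enc$caches$e2, ge3$gx)
  ge1 <- nnConvB(L$e1, enc$caches$e1, ge2$gx)
  grads <- list("e1.w" = ge1$gw, "e1.b" = ge1$gb,
                "e2.w" = ge2$gw, "e2.b" = ge2$gb,
                "e3.w" = ge3$gw, "e3.b" = ge3$gb,
                "d1.w" = g1$gw, "d1.b" = g1$gb,
                "d2.w" = g2$gw, "d2.b" = g2$gb,
                "d3.w" = g3$gw, "d3.b" = g3$gb,
                "d4.w" = g4$gw, "d4.b" = g4$gb)
  list(loss = loss, grads = grads, gCodebook = lg$gCodebook,
       indices = q$indices, z = enc$z)
}

#' Train the vector-quantized codec
#'
#' Adam on the composite loss over a set of attenuation slices, with usage
#' tracking, usage decay and periodic dead-code refresh.
#'
#' @param codec a \code{\link{vqCodec}}.
#' @param images list of \linkS4class{CTImage}s or matrices.
#' @param epochs training epochs.
#' @param lr learning rate.
#' @param seed integer seed (shuffling).
#' @param refreshEvery refresh dead codes every this many steps (0 off).
#' @param verbose print epoch losses.
#' @return the trained codec (with \code{lossHistory}).
#' @export
trainCodec <- function(codec, images, epochs = 20, lr = 2e-4, seed = 1L,
                       refreshEvery = 200L, verbose = FALSE) {
  xs <- lapply(images, function(im)
    windowNormalize(codec, if (is(im, "CTImage")) im@values else im))
  params <- c(.layerParams(codec), list(codebook = codec$codebook$vectors))
  st <- adamInit(params)
  set.seed(seed)
  hist <- numeric(0)
  step <- 0L
  buffer <- NULL
  for (ep in seq_len(epochs)) {
    ord <- sample(length(xs))
    epLoss <- 0
    for (i in ord) {
      step <- step + 1L
      codec <- .setLayerParams(codec, params)
      codec$codebook$vectors <- params$codebook
      r <- .codecStep(codec, xs[[i]])
      grads <- c(r$grads, list(codebook = r$gCodebook))
      up <- adamStep(params, grads, st, lr)
      params <- up$params; st <- up$state
      epLoss <- epLoss + r$loss$total
      # usage bookkeeping (decayed counts) and feature buffer
      used <- tabulate(as.vector(r$indices), nbins = codec$codebook$K)
      codec$codebook$usage <- 0.99 * codec$codebook$usage + used
      flat <- matrix(r$z, ncol = codec$latentDim)
      buffer <- rbind(if (!is.null(buffer) && nrow(buffer) > 512)
        buffer[sample(nrow(buffer), 256), ] else buffer, flat)
      if (refreshEvery > 0 && step %% refreshEvery == 0L) {
        codec$codebook$vectors <- params$codebook
        codec$codebook <- refreshDeadCodes(codec$codebook, buffer,
                                           threshold = 1)
        params$codebook <- codec$codebook$vectors
      }
    }
    hist <- c(hist, epLoss / length(xs))
    if (verbose) message(sprintf("epoch %d loss %.5f", ep, tail(hist, 1)))
  }
  codec <- .setLayerParams(codec, params)
  codec$codebook$vectors <- params$codebook
  codec$trained <- TRUE
  codec$lossHistory <- hist
  codec
}
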