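## Full MAR workflow orchestration and the evaluation/ablation harness.

#' Pipeline configuration
#'
#' Collects geometry, model handles and MAR parameters for
#' \code{\link{runMar}}. Learned methods require the corresponding trained
#' models.
#'
#' @param geom a \linkS4class{FanBeamGeometry}.
#' @param n,pixelSize reconstruction grid.
#' @param codec trained \code{\link{vqCodec}} (learned methods).
#' @param ldm trained \code{\link{epsNet}} (learned methods).
#' @param sched \linkS4class{DiffusionSchedule}.
#' @param seg trained \code{\link{segNet}} (NULL: threshold segmentation).
#' @param latentStats latent normalization stats from LDM training.
#' @param traceMargin trace dilation (detector pixels).
#' @param inpaint \code{"harmonic"} or \code{"linear"}.
#' @param eps NMAR prior-projection clamp (NULL = automatic).
#' @param metalThreshold image-domain metal threshold (mm^-1) used when no
#'   segmentation network is supplied.
#' @param reinsert reinsert original metal pixels into the final image.
#' @param secondary apply secondary artifact correction (needs ldm).
#' @param startFraction secondary-correction re-noising fraction.
#' @param ddimSteps DDIM steps for the prior.
#' @param seed seed registry base for all stochastic stages.
#' @return list of class \code{"pipelineConfig"}.
#' @export
pipelineConfig <- function(geom = defaultGeometry(), n = 64L, pixelSize = 3,
                           codec = NULL, ldm = NULL, sched = NULL,
                           seg = NULL, latentStats = NULL,
                           traceMargin = 1L,
                           inpaint = c("harmonic", "linear"), eps = NULL,
                           metalThreshold = 0.09, reinsert = TRUE,
                           secondary = FALSE, startFraction = 0.2,
                           ddimSteps = 5L, seed = 1L) {
  structure(list(geom = geom, n = as.integer(n), pixelSize = pixelSize,
                 codec = codec, ldm = ldm, sched = sched, seg = seg,
                 latentStats = latentStats, traceMargin = traceMargin,
                 inpaint = match.arg(inpaint), eps = eps,
                 metalThreshold = metalThreshold, reinsert = reinsert,
                 secondary = secondary, startFraction = startFraction,
                 ddimSteps = ddimSteps, seed = seed),
            class = "pipelineConfig")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run a metal-artifact-reduction method on a sinogram
#'
#' Executes the selected workflow and returns the final image together
#' with every intermediate (FBP, prior, mask, trace, corrected sinogram)
#' for audit.
#'
#' \describe{
#'   \item{corrupted}{plain FBP of the input (passthrough).}
#'   \item{limar}{linear sinogram interpolation in the metal trace.}
#'   \item{nmar_threshold}{NMAR with the threshold prior.}
#'   \item{ldm_only}{the diffusion prior image itself.}
#'   \item{ldmnmar}{NMAR with the diffusion prior.}
#'   \item{ldmnmar_secondary}{ldmnmar followed by diffusion-based secondary
#'     artifact correction.}
#' }
#'
#' @param sino measured \linkS4class{Sinogram}.
#' @param config a \code{\link{pipelineConfig}}.
#' @param method method selector (see Details).
#' @param metalMask optional known metal mask (overrides segmentation).
#' @param prior optional prior image override (e.g. an oracle clean image).
#' @return list of class \code{"marResult"}: \code{image} plus
#'   intermediates.
#' @export
runMar <- function(sino, config,
                   method = c("corrupted", "limar", "nmar_threshold",
                              "ldm_only", "ldmnmar", "ldmnmar_secondary"),
                   metalMask = NULL, prior = NULL) {
  method <- match.arg(method)
  n <- config$n; px <- config$pixelSize
  fbp <- .stage("fbp", fbpReconstruct(sino, n, px))
  if (method == "corrupted")
    return(structure(list(image = fbp, method = method, fbp = fbp),
                     class = "marResult"))
  needsLdm <- method %in% c("ldm_only", "ldmnmar", "ldmnmar_secondary")
  if (needsLdm && (is.null(config$codec) || is.null(config$ldm) ||
                   is.null(config$sched)))
    stop("method '", method, "' needs trained codec/ldm checkpoints in the ",
         "pipeline config")
  # metal segmentation (image domain)
  if (is.null(metalMask)) {
    metalMask <- .stage("segment_metal",
      if (!is.null(config$seg)) segmentMetal(fbp, config$seg)
      else fbp@values >= config$metalThreshold)
  }
  trace <- .stage("metal_trace",
    computeMetalTrace(metalMask, config$geom, px, config$traceMargin))
  if (method == "limar") {
    out <- .stage("limar", fbpReconstruct(limar(sino, trace), n, px))
    if (config$reinsert) out <- reinsertMetal(out, metalMask, fbp)
    return(structure(list(image = out, method = method, fbp = fbp,
                          metalMask = metalMask, trace = trace),
                     class = "marResult"))
  }
  if (is.null(prior)) {
    prior <- .stage("prior",
      if (method == "nmar_threshold")
        buildThresholdPrior(fbp, softValue = 0.0222)
      else ldmPrior(fbp, config$codec, config$ldm, config$sched,
                    nSteps = config$ddimSteps, seed = config$seed,
                    latentStats = config$latentStats))
  }
  if (method == "ldm_only") {
    out <- prior
    if (config$reinsert) out <- reinsertMetal(out, metalMask, fbp)
    return(structure(list(image = out, method = method, fbp = fbp,
                          metalMask = metalMask, prior = prior),
                     class = "marResult"))
  }
  corrSino <- .stage("nmar", nmarCorrect(sino, prior, trace,
                                         eps = config$eps,
                                         inpaint = config$inpaint))
  out <- .stage("fbp_corrected", fbpReconstruct(corrSino, n, px))
  if (method == "ldmnmar_secondary" || (config$secondary && needsLdm)) {
    out <- .stage("secondary_correct",
      secondaryCorrect(out, config$codec, config$ldm, config$sched,
                       startFraction = config$startFraction,
                       seed = config$seed + 1L,
                       latentStats = config$latentStats))
  }
  if (config$reinsert) out <- reinsertMetal(out, metalMask, fbp)
  structure(list(image = out, method = method, fbp = fbp,
                 metalMask = metalMask, trace = trace, prior = prior,
                 correctedSino = corrSino),
            class = "marResult")
}

#' Root-mean-square error between two images
#'
#' @param a,b \linkS4class{CTImage}s (or matrices) on the same grid.
#' @param mask optional logical matrix restricting the evaluation (e.g.
#'   excluding metal pixels).
#' @return scalar RMSE.
#' @export
imageRMSE <- function(a, b, mask = NULL) {
  va <- if (is(a, "CTImage")) a@values else a
  vb <- if (is(b, "CTImage")) b@values else b
  if (!identical(dim(va), dim(vb))) stop("image grids differ")
  d <- (va - vb)^2
  if (!is.null(mask)) d <- d[mask]
  sqrt(mean(d))
}

#' Peak signal-to-noise ratio
#'
#' \eqn{20 \log_{10}(\mathrm{max\_val} / \mathrm{RMSE})} in dB; identical
#' images give \code{Inf}.
#'
#' @param a,b images.
#' @param maxVal reference dynamic range (default: the 0.05 mm^-1
#'   normalization window width).
#' @param mask optional evaluation mask.
#' @return PSNR in dB.
#' @export
imagePSNR <- function(a, b, maxVal = 0.05, mask = NULL) {
  r <- imageRMSE(a, b, mask)
  if (r == 0) return(Inf)
  20 * log10(maxVal / r)
}

.gaussKernel1d <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

.sepFilter <- function(m, k) {
  r <- (length(k) - 1) / 2
  one <- function(mm) {
    n <- nrow(mm)
    out <- matrix(0, n, ncol(mm))
    for (d in seq(-r, r)) {
      src <- pmin(pmax(seq_len(n) + d, 1), n)   # replicate boundary
      out <- out + k[d + r + 1] * mm[src, ]
    }
    out
  }
  t(one(t(one(m))))
}

#' Structural similarity index (mean SSIM)
#'
#' Standard SSIM with a Gaussian window (sigma 1.5) and constants
#' \eqn{C_1 = (0.01 L)^2}, \eqn{C_2 = (0.03 L)^2} for dynamic range L.
#'
#' @param a,b images.
#' @param L dynamic range (default 0.05 mm^-1, the normalization window).
#' @param sigma Gaussian window sigma (pixels).
#' @param mask optional evaluation mask applied to the SSIM map.
#' @return mean SSIM in [-1, 1].
#' @export
imageSSIM <- function(a, b, L = 0.05, sigma = 1.5, mask = NULL) {
  va <- if (is(a, "CTImage")) a@values else a
  vb <- if (is(b, "CTImage")) b@values else b
  if (!identical(dim(va), dim(vb))) stop("image grids differ")
  k <- .gaussKernel1d(sigma)
  C1 <- (0.01 * L)^2; C2 <- (0.03 * L)^2
  mua <- .sepFilter(va, k); mub <- .sepFilter(vb, k)
  saa <- .sepFilter(va * va, k) - mua^2
  sbb <- .sepFilter(vb * vb, k) - mub^2
  sab <- .sepFilter(va * vb, k) - mua * mub
  ssim <- ((2 * mua * mub + C1) * (2 * sab + C2)) /
    ((mua^2 + mub^2 + C1) * (saa + sbb + C2))
  if (!is.null(mask)) ssim <- ssim[mask]
  mean(ssim)
}

#' Standard deviation inside a region of interest
#'
#' The flat-region noise/streak metric: the standard deviation of pixel
#' values inside the ROI.
#'
#' @param image \linkS4class{CTImage} or matrix.
#' @param roi logical matrix, nonempty.
#' @return scalar standard deviation.
#' @export
roiStd <- function(image, roi) {
  v <- if (is(image, "CTImage")) image@values else image
  if (!any(roi)) stop("ROI is empty")
  sd(v[roi])
}

#' Soft-tissue ROI between the dental arch
#'
#' Automatically derives the evaluation ROI as the largest disc centred at
#' the midpoint of the metal inserts (or the arch centre) that fits inside
#' the soft-tissue region of the phantom's label map.
#'
#' @param phantom output of \code{\link{makeDentalPhantom}} (or the
#'   \code{phantom} element of a pair).
#' @return logical ROI matrix.
#' @export
archROI <- function(phantom) {
  lab <- phantom$map@labels
  n <- nrow(lab)
  if (any(phantom$metalMask)) {
    cc <- which(phantom$metalMask, arr.ind = TRUE)
    ctr <- colMeans(cc)
  } else {
    px <- phantom$map@pixelSize
    sp <- phantom$spec
    ctr <- c((n + 1) / 2 - (sp$archCenter[2] + sp$archRadius * 0.4) / px,
             (n + 1) / 2 + sp$archCenter[1] / px)
  }
  d2 <- (row(lab) - ctr[1])^2 + (col(lab) - ctr[2])^2
  soft <- lab == 2L
  # largest disc fully inside soft tissue; if the centroid itself is not
  # in soft tissue (e.g. it falls on the arch), recentre on the nearest
  # soft pixel first
  if (!soft[round(ctr[1]), round(ctr[2])]) {
    cand <- which(soft, arr.ind = TRUE)
    k <- which.min((cand[, 1] - ctr[1])^2 + (cand[, 2] - ctr[2])^2)
    ctr <- cand[k, ]
    d2 <- (row(lab) - ctr[1])^2 + (col(lab) - ctr[2])^2
  }
  rmax <- 1
  for (r in 2:floor(n / 2)) {
    if (all(soft[d2 <= r^2])) rmax <- r else break
  }
  # the ROI is always restricted to soft tissue
  d2 <= max(rmax, 3)^2 & soft
}

#' Evaluate a method over a simulation suite
#'
#' Runs one MAR method on every pair of the suite and computes per-slice
#' and aggregate RMSE, PSNR, SSIM (against the clean reference, metal
#' pixels excluded and included) and the ROI standard deviation.
#'
#' @param suite output of \code{\link{simulationSuite}}.
#' @param config a \code{\link{pipelineConfig}}.
#' @param method method selector (see \code{\link{runMar}}).
#' @param useKnownMask use the simulation's true metal mask instead of
#'   segmentation (oracle masking).
#' @param oraclePrior use the clean image as NMAR prior (oracle prior).
#' @return list of class \code{"evalReport"}: \code{perSlice} data.frame
#'   and \code{aggregate} named vector (mean and sd per metric).
#' @export
evaluateMethod <- function(suite, config, method, useKnownMask = TRUE,
                           oraclePrior = FALSE) {
  rows <- lapply(seq_along(suite$pairs), function(i) {
    p <- suite$pairs[[i]]
    res <- runMar(p$corruptedSino, config, method,
                  metalMask = if (useKnownMask) p$metalMask else NULL,
                  prior = if (oraclePrior) p$clean else NULL)
    roi <- archROI(p$phantom)
    nm <- !p$metalMask
    data.frame(pair = i, seed = p$seed,
               rmse = imageRMSE(res$image, p$clean, nm),
               rmseAll = imageRMSE(res$image, p$clean),
               psnr = imagePSNR(res$image, p$clean, mask = nm),
               ssim = imageSSIM(res$image, p$clean, mask = nm),
               roiStd = roiStd(res$image, roi))
  })
  perSlice <- do.call(rbind, rows)
  agg <- c(vapply(c("rmse", "rmseAll", "psnr", "ssim", "roiStd"),
                  function(m) mean(perSlice[[m]]), numeric(1)),
           vapply(c("rmse", "rmseAll", "psnr", "ssim", "roiStd"),
                  function(m) sd(perSlice[[m]]), numeric(1)))
  names(agg) <- c("rmse", "rmseAll", "psnr", "ssim", "roiStd",
                  "rmse_sd", "rmseAll_sd", "psnr_sd", "ssim_sd",
                  "roiStd_sd")
  structure(list(method = method, perSlice = perSlice, aggregate = agg,
                 seedManifest = suite$manifest, useKnownMask = useKnownMask,
                 oraclePrior = oraclePrior),
            class = "evalReport")
}

#' Run the ablation/comparison harness
#'
#' Evaluates several methods over the same suite (same slices and seeds)
#' and returns one aggregate row per method; per-method failures are
#' recorded and do not stop the run.
#'
#' @param suite simulation suite.
#' @param methods character vector of method selectors; the special values
#'   \code{"nmar_oracle"} (NMAR with the clean image as prior) and
#'   \code{"limar_oracle"} are also accepted.
#' @param config pipeline configuration.
#' @param useKnownMask oracle metal masks (default TRUE).
#' @return list with \code{table} (data.frame, one row per method),
#'   \code{reports}, and \code{errors}.
#' @export
runAblation <- function(suite, methods, config, useKnownMask = TRUE) {
  reports <- list()
  errors <- list()
  for (m in methods) {
    r <- tryCatch({
      if (m == "nmar_oracle")
        evaluateMethod(suite, config, "nmar_threshold",
                       useKnownMask = useKnownMask, oraclePrior = TRUE)
      else evaluateMethod(suite, config, m, useKnownMask = useKnownMask)
    }, error = function(e) e)
    if (inherits(r, "error")) errors[[m]] <- conditionMessage(r)
    else reports[[m]] <- r
  }
  tab <- do.call(rbind, lapply(names(reports), function(m)
    data.frame(method = m, t(reports[[m]]$aggregate))))
  list(table = tab, reports = reports, errors = errors)
}
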