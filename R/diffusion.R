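## Conditional latent DDPM: forward noising, epsilon-prediction training,
## deterministic DDIM sampling with the corrupted-image latent as condition,
## the changing-condition ablation schedule, and the secondary artifact
## correction that reuses the trained model from a partially noised start.

#' Construct a diffusion noise schedule
#'
#' Linear variance schedule beta_t from \code{betaStart} to \code{betaEnd}
#' over \code{nSteps} steps (desk-scale default 200 steps).
#'
#' @param nSteps total steps T.
#' @param betaStart,betaEnd first/last per-step variance.
#' @return A \linkS4class{DiffusionSchedule}.
#' @examples
#' sch <- diffusionSchedule(200)
#' @export
diffusionSchedule <- function(nSteps = 200L, betaStart = 1e-4,
                              betaEnd = 2e-2) {
  betas <- seq(betaStart, betaEnd, length.out = nSteps)
  alphas <- 1 - betas
  new("DiffusionSchedule", nSteps = as.integer(nSteps), betas = betas,
      alphas = alphas, alphaBars = cumprod(alphas))
}

#' Cumulative signal fraction at a step
#'
#' \eqn{\bar\alpha_t} with the convention \eqn{\bar\alpha_0 = 1} (no noise).
#'
#' @param sched a \linkS4class{DiffusionSchedule}.
#' @param t step in [0, T].
#' @return scalar \eqn{\bar\alpha_t}.
#' @export
alphaBarAt <- function(sched, t) {
  if (t < 0 || t > sched@nSteps) stop("t out of range [0, T]")
  if (t == 0) 1 else sched@alphaBars[t]
}

#' Closed-form forward diffusion
#'
#' Samples the forward-process marginal
#' \eqn{x_t = \sqrt{\bar\alpha_t} x_0 + \sqrt{1-\bar\alpha_t}\,\epsilon}.
#' At t = 0 this returns \code{x0} exactly.
#'
#' @param x0 clean latent grid (array).
#' @param t step in [0, T].
#' @param sched a \linkS4class{DiffusionSchedule}.
#' @param noise noise array of the same shape as \code{x0}.
#' @return the noised latent.
#' @export
forwardDiffuse <- function(x0, t, sched, noise) {
  ab <- alphaBarAt(sched, t)
  out <- sqrt(ab) * x0 + sqrt(1 - ab) * noise
  dim(out) <- dim(x0)
  out
}

#' Condition policy for conditional sampling
#'
#' \code{constant} supplies the corrupted-image latent at every step;
#' \code{weighted} implements the changing-condition ablation
#' \eqn{((T - t)\,\mathrm{Corrupted} - t)/T}: fully corrupted-guided at the
#' first step (t = 0) and pure -1 at the last (t = T).
#'
#' @param corruptedLatent the condition grid y (array).
#' @param mode \code{"constant"} or \code{"weighted"}.
#' @param tMax the T used by the weighted schedule.
#' @return object of class \code{"conditionPolicy"}.
#' @export
conditionPolicy <- function(corruptedLatent, mode = c("constant", "weighted"),
                            tMax = 200L) {
  mode <- match.arg(mode)
  structure(list(y = corruptedLatent, mode = mode, tMax = tMax),
            class = "conditionPolicy")
}

#' Condition grid at a given step
#'
#' @param policy a \code{\link{conditionPolicy}}.
#' @param t step in [0, T].
#' @return the condition grid for step t.
#' @export
conditionAt <- function(policy, t) {
  if (t > policy$tMax || t < 0) stop("t out of range [0, T]")
  if (policy$mode == "constant") return(policy$y)
  Tm <- policy$tMax
  out <- ((Tm - t) * policy$y - t) / Tm
  dim(out) <- dim(policy$y)
  out
}

#' Create an untrained noise-prediction network
#'
#' A compact convolutional epsilon-estimator for latent grids: the noisy
#' latent and the condition latent are concatenated channel-wise at every
#' step, a cosine time embedding enters as a learned per-channel bias after
#' the first convolution.
#'
#' @param latentDim latent channels D.
#' @param channels hidden channels.
#' @param embDim time embedding dimension.
#' @param seed integer seed for initialization.
#' @return object of class \code{"epsNet"}.
#' @export
epsNet <- function(latentDim = 4L, channels = 48L, embDim = 16L, seed = 1L) {
  set.seed(seed)
  layers <- list(
    c1 = nnConv(2L * latentDim, channels, 3L, 1L, "lrelu"),
    c2 = nnConv(channels, channels, 3L, 1L, "lrelu"),
    c3 = nnConv(channels, channels, 3L, 1L, "lrelu"),
    c4 = nnConv(channels, latentDim, 3L, 1L, "linear"),
    t1 = nnDense(embDim, channels, "lrelu"),
    t2 = nnDense(channels, channels, "linear"))
  structure(list(layers = layers, latentDim = as.integer(latentDim),
                 channels = as.integer(channels), embDim = as.integer(embDim),
                 trained = FALSE, seed = seed),
            class = "epsNet")
}

.timeEmbedding <- function(t, dim, tMax) {
  half <- dim / 2
  freqs <- exp(seq(0, log(tMax), length.out = half))
  ang <- pi * t / tMax * freqs
  c(cos(ang), sin(ang))
}

.epsForward <- function(model, xt, cond, t, tMax) {
  x <- array(c(xt, cond), c(dim(xt)[1], dim(xt)[2],
                            dim(xt)[3] + dim(cond)[3]))
  emb <- .timeEmbedding(t, model$embDim, tMax)
  L <- model$layers
  t1 <- nnDenseF(L$t1, emb)
  t2 <- nnDenseF(L$t2, t1$y)
  r1 <- nnConvF(L$c1, x, extraBias = t2$y)
  r2 <- nnConvF(L$c2, r1$y)
  r3 <- nnConvF(L$c3, r2$y)
  r4 <- nnConvF(L$c4, r3$y)
  list(eps = r4$y,
       caches = list(x = x, emb = emb, t1 = t1$cache, t2 = t2$cache,
                     c1 = r1$cache, c2 = r2$cache, c3 = r3$cache,
                     c4 = r4$cache))
}

#' Predict noise with a trained or user-supplied model
#'
#' @param model an \code{\link{epsNet}} or a function
#'   \code{function(xt, cond, t)} (e.g. an analytic test predictor).
#' @param xt noisy latent.
#' @param cond condition grid.
#' @param t step.
#' @param tMax schedule length for the time embedding.
#' @return predicted noise grid.
#' @export
predictNoise <- function(model, xt, cond, t, tMax = 200L) {
  if (is.function(model)) return(model(xt, cond, t))
  .epsForward(model, xt, cond, t, tMax)$eps
}

#' Diffusion training loss (epsilon prediction)
#'
#' Draws noise, forms \eqn{x_t}, and returns the mean squared error between
#' the drawn and the predicted noise,
#' \eqn{\|\epsilon - \epsilon_\theta(x_t, y, t)\|^2} (mean over elements).
#' Optionally adds a perceptual term on decoded \eqn{\hat x_0} estimates.
#'
#' @param x0 clean latent.
#' @param y condition latent.
#' @param t step in [1, T].
#' @param sched schedule.
#' @param model predictor (see \code{\link{predictNoise}}).
#' @param noise optional fixed noise (drawn from the RNG when NULL).
#' @param codec optional \code{\link{vqCodec}} enabling the perceptual term.
#' @param lambdaP perceptual weight.
#' @return scalar loss.
#' @export
diffusionLoss <- function(x0, y, t, sched, model, noise = NULL,
                          codec = NULL, lambdaP = 0.01) {
  if (is.null(noise)) noise <- array(rnorm(length(x0)), dim(x0))
  xt <- forwardDiffuse(x0, t, sched, noise)
  eps <- predictNoise(model, xt, y, t, sched@nSteps)
  loss <- mean((noise - eps)^2)
  if (!is.null(codec) && lambdaP > 0) {
    ab <- alphaBarAt(sched, t)
    x0hat <- (xt - sqrt(1 - ab) * eps) / sqrt(ab)
    fa <- .decForward(codec, x0hat)$out[, , 1]
    fb <- .decForward(codec, x0)$out[, , 1]
    loss <- loss + lambdaP * perceptualDistance(codec$perceptual, fa, fb)
  }
  loss
}

#' Deterministic DDIM sampling
#'
#' Runs the DDIM update over a uniformly spaced subset of the schedule,
#' supplying the condition to the model at every step. With \code{eta = 0}
#' the trajectory is a deterministic function of the initial noise.
#'
#' @param model predictor (\code{\link{epsNet}} or function).
#' @param policy a \code{\link{conditionPolicy}}.
#' @param sched a \linkS4class{DiffusionSchedule}.
#' @param nSteps number of sampling steps (1..T); default 5.
#' @param eta stochasticity parameter (0 = deterministic).
#' @param seed integer seed for the initial noise (and eta > 0 noise).
#' @param xT optional fixed initial latent (overrides the seeded draw).
#' @param shape latent shape when drawing the initial noise.
#' @param tStart start the trajectory at this step instead of T (used by
#'   secondary correction); \code{xT} is then the partially noised latent.
#' @return the sampled latent grid.
#' @export
ddimSample <- function(model, policy, sched, nSteps = 5L, eta = 0,
                       seed = 1L, xT = NULL, shape = NULL,
                       tStart = NULL) {
  if (nSteps < 1) stop("nSteps must be >= 1")
  Tm <- if (is.null(tStart)) sched@nSteps else as.integer(tStart)
  if (Tm < 1) stop("tStart must be >= 1")
  if (is.null(xT)) {
    if (is.null(shape)) shape <- dim(policy$y)
    set.seed(seed)
    xT <- array(rnorm(prod(shape)), shape)
  } else if (eta > 0) set.seed(seed)
  ts <- unique(round(seq(Tm, 0, length.out = nSteps + 1L)))
  x <- xT
  for (i in seq_len(length(ts) - 1L)) {
    t <- ts[i]; tp <- ts[i + 1L]
    abT <- alphaBarAt(sched, t)
    abP <- alphaBarAt(sched, tp)
    eps <- predictNoise(model, x, conditionAt(policy, t), t, sched@nSteps)
    x0hat <- (x - sqrt(1 - abT) * eps) / sqrt(abT)
    sig <- 0
    if (eta > 0 && tp > 0) {
      sig <- eta * sqrt((1 - abP) / (1 - abT)) * sqrt(1 - abT / abP)
    }
    dirCoef <- sqrt(pmax(1 - abP - sig^2, 0))
    x <- sqrt(abP) * x0hat + dirCoef * eps
    if (sig > 0) x <- x + sig * array(rnorm(length(x)), dim(x))
    dim(x) <- dim(xT)
  }
  x
}

.epsBackward <- function(model, fwd, gEps) {
  L <- model$layers
  g4 <- nnConvB(L$c4, fwd$caches$c4, gEps)
  g3 <- nnConvB(L$c3, fwd$caches$c3, g4$gx)
  g2 <- nnConvB(L$c2, fwd$caches$c2, g3$gx)
  g1 <- nnConvB(L$c1, fwd$caches$c1, g2$gx)
  gt2 <- nnDenseB(L$t2, fwd$caches$t2, g1$gBias)
  gt1 <- nnDenseB(L$t1, fwd$caches$t1, gt2$gx)
  list("c1.w" = g1$gw, "c1.b" = g1$gb, "c2.w" = g2$gw, "c2.b" = g2$gb,
       "c3.w" = g3$gw, "c3.b" = g3$gb, "c4.w" = g4$gw, "c4.b" = g4$gb,
       "t1.w" = gt1$gw, "t1.b" = gt1$gb, "t2.w" = gt2$gw, "t2.b" = gt2$gb)
}

#' Train the conditional latent diffusion model
#'
#' Adam on the epsilon-prediction objective over paired latents
#' (clean target, corrupted condition), with t drawn uniformly per sample.
#'
#' @param model an \code{\link{epsNet}}.
#' @param x0s list of clean latent grids.
#' @param ys list of matching condition grids.
#' @param sched schedule.
#' @param steps optimization steps.
#' @param lr learning rate.
#' @param batch batch size.
#' @param seed integer seed.
#' @param verbose print running loss.
#' @return the trained model (with \code{lossHistory}).
#' @export
trainDiffusion <- function(model, x0s, ys, sched, steps = 2000L, lr = 2e-3,
                           batch = 8L, seed = 1L, verbose = FALSE) {
  stopifnot(length(x0s) == length(ys), length(x0s) > 0)
  params <- .layerParams(model)
  st <- adamInit(params)
  set.seed(seed)
  hist <- numeric(0)
  run <- NA_real_
  for (s in seq_len(steps)) {
    model <- .setLayerParams(model, params)
    grads <- NULL
    lsum <- 0
    for (bi in seq_len(batch)) {
      i <- sample.int(length(x0s), 1L)
      t <- sample.int(sched@nSteps, 1L)
      noise <- array(rnorm(length(x0s[[i]])), dim(x0s[[i]]))
      xt <- forwardDiffuse(x0s[[i]], t, sched, noise)
      fwd <- .epsForward(model, xt, ys[[i]], t, sched@nSteps)
      gEps <- 2 * (fwd$eps - noise) / length(noise)
      gb <- .epsBackward(model, fwd, gEps)
      grads <- if (is.null(grads)) gb else
        Map(`+`, grads, gb)
      lsum <- lsum + mean((noise - fwd$eps)^2)
    }
    grads <- lapply(grads, function(g) g / batch)
    up <- adamStep(params, grads, st, lr)
    params <- up$params; st <- up$state
    run <- if (is.na(run)) lsum / batch else 0.98 * run + 0.02 * lsum / batch
    if (s %% 100L == 0L) {
      hist <- c(hist, run)
      if (verbose) message(sprintf("step %d loss %.4f", s, run))
    }
  }
  model <- .setLayerParams(model, params)
  model$trained <- TRUE
  model$lossHistory <- hist
  model
}

#' Synthesize an artifact-reduced prior image with the latent diffusion model
#'
#' Encodes the corrupted image, runs conditional DDIM sampling from noise
#' with the corrupted latent as constant condition, and decodes the result.
#'
#' @param corrupted corrupted \linkS4class{CTImage}.
#' @param codec trained \code{\link{vqCodec}}.
#' @param model trained \code{\link{epsNet}}.
#' @param sched schedule.
#' @param nSteps DDIM steps (default 5).
#' @param seed integer seed.
#' @param latentStats optional per-channel latent normalization (list with
#'   \code{mean}, \code{sd}) as stored in trained checkpoints.
#' @return A \linkS4class{CTImage} prior with attribute
#'   \code{provenance = "ldm_prior"}.
#' @export
ldmPrior <- function(corrupted, codec, model, sched, nSteps = 5L,
                     seed = 1L, latentStats = NULL) {
  if (!isTRUE(model$trained)) stop("the noise predictor is not trained")
  y <- encodeImage(codec, corrupted)$grid
  if (!is.null(latentStats)) y <- .latNorm(y, latentStats)
  pol <- conditionPolicy(y, "constant", tMax = sched@nSteps)
  z <- ddimSample(model, pol, sched, nSteps = nSteps, seed = seed)
  if (!is.null(latentStats)) z <- .latDenorm(z, latentStats)
  out <- decodeLatent(codec, z, pixelSize = corrupted@pixelSize)
  out@values <- pmax(out@values, 0)
  attr(out, "provenance") <- "ldm_prior"
  out
}

.latNorm <- function(z, stats) {
  for (c in seq_len(dim(z)[3])) z[, , c] <- (z[, , c] - stats$mean[c]) /
      stats$sd[c]
  z
}

.latDenorm <- function(z, stats) {
  for (c in seq_len(dim(z)[3])) z[, , c] <- z[, , c] * stats$sd[c] +
      stats$mean[c]
  z
}

#' Secondary artifact correction by reusing the trained model
#'
#' Encodes the initial (already MAR-corrected) image, noises it to the
#' schedule level at \code{startFraction} of the trajectory, and runs the
#' remaining DDIM steps with the initial image's latent as condition before
#' decoding, suppressing residual interpolation streaks. As
#' \code{startFraction} approaches 0 the output approaches the codec round
#' trip of the input.
#'
#' @param initial \linkS4class{CTImage} to refine.
#' @param codec trained \code{\link{vqCodec}}.
#' @param model trained \code{\link{epsNet}}.
#' @param sched schedule.
#' @param startFraction fraction [0, 1] of the trajectory to re-noise to;
#'   0 performs no noising and no steps (the exact codec round trip).
#' @param nSteps DDIM steps for the partial trajectory (default
#'   \code{ceiling(5 * startFraction)}).
#' @param seed integer seed.
#' @param latentStats optional latent normalization stats.
#' @param mode \code{"partial"} (default: start from the noised initial
#'   latent) or \code{"full"} (full trajectory from pure noise with the
#'   initial image as condition).
#' @return A refined \linkS4class{CTImage}.
#' @export
secondaryCorrect <- function(initial, codec, model, sched,
                             startFraction = 0.2, nSteps = NULL, seed = 1L,
                             latentStats = NULL,
                             mode = c("partial", "full")) {
  mode <- match.arg(mode)
  if (!isTRUE(model$trained)) stop("the noise predictor is not trained")
  if (startFraction < 0 || startFraction > 1)
    stop("startFraction must be in [0, 1]")
  z0 <- encodeImage(codec, initial)$grid
  if (startFraction == 0) {
    zc <- if (!is.null(latentStats)) .latDenorm(.latNorm(z0, latentStats),
                                                latentStats) else z0
    out <- decodeLatent(codec, zc, pixelSize = initial@pixelSize)
    out@values <- pmax(out@values, 0)
    return(out)
  }
  if (!is.null(latentStats)) z0 <- .latNorm(z0, latentStats)
  pol <- conditionPolicy(z0, "constant", tMax = sched@nSteps)
  if (mode == "full") {
    z <- ddimSample(model, pol, sched, nSteps = if (is.null(nSteps)) 5L
                    else nSteps, seed = seed)
  } else {
    tStart <- max(1L, round(startFraction * sched@nSteps))
    if (is.null(nSteps)) nSteps <- max(1L, ceiling(5 * startFraction))
    set.seed(seed)
    noise <- array(rnorm(length(z0)), dim(z0))
    xt <- forwardDiffuse(z0, tStart, sched, noise)
    z <- ddimSample(model, pol, sched, nSteps = nSteps, seed = seed,
                    xT = xt, tStart = tStart)
  }
  if (!is.null(latentStats)) z <- .latDenorm(z, latentStats)
  out <- decodeLatent(codec, z, pixelSize = initial@pixelSize)
  out@values <- pmax(out@values, 0)
  out
}
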