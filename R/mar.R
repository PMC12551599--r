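## Classical projection-domain MAR: metal trace, LIMAR, threshold prior,
## and the normalize -> inpaint -> denormalize NMAR procedure that accepts
## any prior image (threshold-based, learned, or an oracle clean image).

#' Compute the projection-domain metal trace
#'
#' Forward projects a binary metal mask and flags every sinogram entry whose
#' ray intersects metal, optionally dilated along the detector axis to
#' absorb projector edge effects.
#'
#' @param metalMask binary matrix (image grid) of metal pixels.
#' @param geom a \linkS4class{FanBeamGeometry}.
#' @param pixelSize image pixel size (mm).
#' @param margin dilation margin in detector pixels (default 1).
#' @return logical matrix \code{[n_angles x n_detectors]} with attributes
#'   \code{provenance = "projected_mask"} and \code{margin}.
#' @examples
#' g <- defaultGeometry(90)
#' m <- matrix(FALSE, 64, 64); m[30:32, 30:32] <- TRUE
#' tr <- computeMetalTrace(m, g, 3)
#' @export
computeMetalTrace <- function(metalMask, geom, pixelSize, margin = 1L) {
  stopifnot(is.matrix(metalMask))
  mm <- matrix(as.numeric(metalMask), nrow(metalMask), ncol(metalMask))
  fp <- sinoValues(forwardProject(ctImage(mm, pixelSize), geom))
  trace <- fp > 1e-9
  if (margin > 0) {
    tr <- trace
    for (d in seq_len(margin)) {
      nc <- ncol(trace)
      tr[, seq_len(nc - d)] <- tr[, seq_len(nc - d)] | trace[, seq_len(nc - d) + d]
      tr[, seq_len(nc - d) + d] <- tr[, seq_len(nc - d) + d] | trace[, seq_len(nc - d)]
    }
    trace <- tr
  }
  structure(trace, provenance = "projected_mask", margin = margin)
}

.interpRow <- function(row, traced) {
  # linear interpolation along the detector axis; constant extension when a
  # traced run touches the row edge
  keep <- which(!traced)
  if (length(keep) == 0L) return(NULL)
  if (length(keep) == 1L) { row[traced] <- row[keep]; return(row) }
  filled <- approx(keep, row[keep], xout = which(traced), rule = 2)$y
  row[traced] <- filled
  row
}

#' Linear-interpolation MAR (LIMAR)
#'
#' Replaces each traced run in every detector row by linear interpolation
#' between the nearest untraced neighbours; traced runs touching the row
#' edge are filled by constant extension of the single available neighbour.
#' Untraced entries are returned unchanged (bit-identical).
#'
#' @param sino a \linkS4class{Sinogram}.
#' @param trace logical matrix matching the sinogram shape.
#' @return A corrected \linkS4class{Sinogram}.
#' @examples
#' g <- defaultGeometry(4); v <- matrix(4, 4, 96); v[, 96] <- 8
#' tr <- matrix(FALSE, 4, 96); tr[, 50:60] <- TRUE
#' out <- limar(sinogram(v, g), tr)
#' @export
limar <- function(sino, trace) {
  stopifnot(is(sino, "Sinogram"))
  v <- sino@values
  if (!identical(dim(trace), dim(v)))
    stop("trace shape does not match the sinogram")
  if (!any(trace)) return(sino)
  fullRows <- which(apply(trace, 1L, all))
  for (i in seq_len(nrow(v))) {
    if (i %in% fullRows) next
    if (any(trace[i, ])) v[i, ] <- .interpRow(v[i, ], trace[i, ])
  }
  if (length(fullRows)) {
    warning("fully traced view(s) ", paste(fullRows, collapse = ", "),
            ": falling back to nearest untraced view")
    okRows <- setdiff(seq_len(nrow(v)), fullRows)
    if (length(okRows) == 0L) stop("every view is fully traced")
    for (i in fullRows) v[i, ] <- v[okRows[which.min(abs(okRows - i))], ]
  }
  sinogram(v, sino@geometry)
}

#' Build a threshold-based prior image
#'
#' The classical NMAR prior: air pixels (below \code{tSoft}) become 0, soft
#' tissue (between the thresholds) becomes the homogeneous \code{softValue},
#' and bone and denser pixels (at or above \code{tBone}) keep their original
#' values; optionally Gaussian-smoothed.
#'
#' @param image a \linkS4class{CTImage} (typically the corrupted FBP).
#' @param tSoft air/soft-tissue threshold (mm^-1).
#' @param tBone soft-tissue/bone threshold (mm^-1); must exceed \code{tSoft}.
#' @param softValue homogeneous soft-tissue value (mm^-1).
#' @param sigma Gaussian smoothing sigma in pixels (0 disables).
#' @return A \linkS4class{CTImage} with attribute
#'   \code{provenance = "threshold_prior"}.
#' @export
buildThresholdPrior <- function(image, tSoft = 0.010, tBone = 0.032,
                                softValue = 0.0222, sigma = 0) {
  stopifnot(is(image, "CTImage"))
  if (tSoft >= tBone) stop("need tSoft < tBone")
  v <- image@values
  out <- v
  out[v < tSoft] <- 0
  out[v >= tSoft & v < tBone] <- softValue
  if (sigma > 0) out <- .gaussBlur(out, sigma)
  res <- ctImage(out, image@pixelSize)
  attr(res, "provenance") <- "threshold_prior"
  res
}

.gaussBlur <- function(m, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  pad <- function(x, side) x  # zero boundary handled by normalization below
  sep <- function(mm) {
    n <- nrow(mm); p <- ncol(mm)
    out <- matrix(0, n, p)
    wgt <- matrix(0, n, p)
    for (d in seq(-r, r)) {
      w <- k[d + r + 1]
      src <- seq_len(n) + d
      ok <- src >= 1 & src <= n
      out[ok, ] <- out[ok, ] + w * mm[src[ok], ]
      wgt[ok, ] <- wgt[ok, ] + w
    }
    out / wgt
  }
  t(sep(t(sep(m))))
}

#' Inpaint traced sinogram entries
#'
#' Fills the traced region either harmonically (solving the Laplace
#' equation on the view-by-detector grid with Dirichlet data from untraced
#' neighbours; smooth across views) or by per-row linear interpolation.
#'
#' @param values sinogram-shaped numeric matrix.
#' @param trace logical matrix of entries to fill.
#' @param method \code{"harmonic"} (default) or \code{"linear"}.
#' @return matrix with traced entries replaced; untraced entries untouched.
#' @export
inpaintTrace <- function(values, trace, method = c("harmonic", "linear")) {
  method <- match.arg(method)
  if (!any(trace)) return(values)
  if (method == "harmonic") {
    out <- cpp_harmonic_inpaint(values, matrix(as.integer(trace),
                                               nrow(trace), ncol(trace)))
    out[!trace] <- values[!trace]
    return(out)
  }
  g0 <- fanBeamGeometry(2, 3, ncol(values), 1, nrow(values))
  sinoValues(limar(sinogram(values, g0), trace))
}

#' Normalized MAR (NMAR) correction
#'
#' Divides the measured sinogram by the forward projection of a prior image
#' (clamped away from zero), inpaints the metal trace in the normalized
#' domain, and multiplies the prior projection back. Entries outside the
#' trace are returned bit-identical to the input.
#'
#' @param sino measured \linkS4class{Sinogram}.
#' @param prior prior image (\linkS4class{CTImage}), nonnegative.
#' @param trace logical matrix of traced entries.
#' @param eps clamp for the prior projection; default
#'   \code{1e-4 * median(positive prior projection values)}. Must be > 0.
#' @param inpaint \code{"harmonic"} or \code{"linear"} trace completion.
#' @return A corrected \linkS4class{Sinogram}.
#' @examples
#' g <- defaultGeometry(90)
#' pair <- makePhantomPair(dentalPhantomSpec(), g, seed = 2)
#' tr <- computeMetalTrace(pair$metalMask, g, 3)
#' nm <- nmarCorrect(pair$corruptedSino, pair$clean, tr)
#' @export
nmarCorrect <- function(sino, prior, trace, eps = NULL,
                        inpaint = c("harmonic", "linear")) {
  stopifnot(is(sino, "Sinogram"), is(prior, "CTImage"))
  inpaint <- match.arg(inpaint)
  v <- sino@values
  if (!identical(dim(trace), dim(v)))
    stop("trace shape does not match the sinogram")
  pv <- pmax(prior@values, 0)
  q <- sinoValues(forwardProject(ctImage(pv, prior@pixelSize),
                                 sino@geometry))
  if (is.null(eps)) {
    pos <- q[q > 0]
    eps <- if (length(pos)) 1e-4 * median(pos) else 1e-6
  }
  if (eps <= 0) stop("eps must be > 0")
  q <- pmax(q, eps)
  norm <- v / q
  filled <- inpaintTrace(norm, trace, method = inpaint)
  out <- filled * q
  out[!trace] <- v[!trace]
  sinogram(out, sino@geometry)
}

#' Reinsert metal pixels into a corrected image
#'
#' @param corrected corrected \linkS4class{CTImage}.
#' @param metalMask binary matrix of metal pixels.
#' @param original image supplying the metal values.
#' @return A \linkS4class{CTImage} equal to \code{corrected} outside the
#'   mask and to \code{original} inside it.
#' @export
reinsertMetal <- function(corrected, metalMask, original) {
  if (!identical(dim(corrected@values), dim(original@values)))
    stop("images must share the grid")
  v <- corrected@values
  v[metalMask] <- original@values[metalMask]
  ctImage(v, corrected@pixelSize)
}
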