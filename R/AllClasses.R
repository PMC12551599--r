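#' Fan-beam acquisition geometry
#'
#' Describes a 2D fan-beam geometry with a flat (equidistant) detector:
#' source-to-isocenter and source-to-detector distances, the detector
#' sampling, an optional lateral detector offset, and the set of view angles.
#'
#' @slot sid source-to-isocenter distance (mm).
#' @slot sdd source-to-detector distance (mm).
#' @slot nDet number of detector elements.
#' @slot pitch detector element spacing (mm, at the detector).
#' @slot offset lateral shift of the detector centre (mm, default 0).
#' @slot angles view angles (radians, counter-clockwise, strictly increasing).
#' @slot arcDeg angular coverage of the scan (degrees).
#'
#' @exportClass FanBeamGeometry
setClass("FanBeamGeometry",
  representation(sid = "numeric", sdd = "numeric", nDet = "integer",
                 pitch = "numeric", offset = "numeric", angles = "numeric",
                 arcDeg = "numeric"))

setValidity("FanBeamGeometry", function(object) {
  msg <- NULL
  if (!(object@sdd > object@sid && object@sid > 0))
    msg <- c(msg, "need sdd > sid > 0")
  if (object@pitch <= 0) msg <- c(msg, "detector pitch must be > 0")
  if (object@nDet < 2L) msg <- c(msg, "need at least 2 detector elements")
  if (length(object@angles) < 1L || is.unsorted(object@angles, strictly = TRUE))
    msg <- c(msg, "angles must be strictly increasing")
  if (length(object@angles) > 1L) {
    span <- diff(range(object@angles))
    arc <- object@arcDeg * pi / 180
    # angles sample [0, arc) so the span is arc minus one angular step
    step <- arc / length(object@angles)
    if (abs(span + step - arc) > 1e-6 && abs(span - arc) > 1e-6)
      msg <- c(msg, "angles do not span arcDeg")
  }
  if (is.null(msg)) TRUE else msg
})

#' Square 2D attenuation image
#'
#' A square grid of linear attenuation coefficients (mm^-1) with a physical
#' pixel size; the grid centre is at the isocenter.
#'
#' @slot values square numeric matrix of attenuation values (mm^-1).
#' @slot pixelSize pixel edge length (mm).
#'
#' @exportClass CTImage
setClass("CTImage",
  representation(values = "matrix", pixelSize = "numeric"))

setValidity("CTImage", function(object) {
  msg <- NULL
  if (nrow(object@values) != ncol(object@values))
    msg <- c(msg, "image grid must be square")
  if (!all(is.finite(object@values))) msg <- c(msg, "values must be finite")
  if (object@pixelSize <= 0) msg <- c(msg, "pixelSize must be > 0")
  if (is.null(msg)) TRUE else msg
})

#' Fan-beam sinogram
#'
#' Line integrals (dimensionless, mm^-1 * mm) arranged as
#' \code{[n_angles x n_detectors]}, tied to the \linkS4class{FanBeamGeometry}
#' they were measured in.
#'
#' @slot values numeric matrix of line integrals, one row per view.
#' @slot geometry the \linkS4class{FanBeamGeometry}.
#'
#' @exportClass Sinogram
setClass("Sinogram",
  representation(values = "matrix", geometry = "FanBeamGeometry"))

setValidity("Sinogram", function(object) {
  msg <- NULL
  if (!all(is.finite(object@values))) msg <- c(msg, "values must be finite")
  if (nrow(object@values) != length(object@geometry@angles))
    msg <- c(msg, "rows must match the number of view angles")
  if (ncol(object@values) != object@geometry@nDet)
    msg <- c(msg, "columns must match the number of detector elements")
  if (is.null(msg)) TRUE else msg
})

#' Labelled material map with energy-dependent attenuation
#'
#' A square label grid (air, soft tissue, bone-equivalent, metal) plus a
#' table of linear attenuation coefficients per material on a diagnostic
#' energy grid.
#'
#' @slot labels integer matrix of material codes (indices into the mu table).
#' @slot materials character vector of material names, one per mu row.
#' @slot energies energy grid (keV), strictly increasing.
#' @slot mu matrix [materials x energies] of attenuation (mm^-1).
#' @slot pixelSize pixel edge length (mm).
#'
#' @exportClass MaterialMap
setClass("MaterialMap",
  representation(labels = "matrix", materials = "character",
                 energies = "numeric", mu = "matrix", pixelSize = "numeric"))

setValidity("MaterialMap", function(object) {
  msg <- NULL
  if (nrow(object@labels) != ncol(object@labels))
    msg <- c(msg, "label grid must be square")
  if (is.unsorted(object@energies, strictly = TRUE))
    msg <- c(msg, "energies must be strictly increasing")
  if (nrow(object@mu) != length(object@materials) ||
      ncol(object@mu) != length(object@energies))
    msg <- c(msg, "mu must be [materials x energies]")
  if (any(object@mu < 0)) msg <- c(msg, "mu must be >= 0")
  if (any(apply(object@mu, 1L, function(r) any(diff(r) > 1e-12))))
    msg <- c(msg, "mu must be non-increasing in energy for each material")
  lr <- range(object@labels)
  if (lr[1] < 1L || lr[2] > length(object@materials))
    msg <- c(msg, "labels must index the material table")
  if (object@pixelSize <= 0) msg <- c(msg, "pixelSize must be > 0")
  if (is.null(msg)) TRUE else msg
})

#' X-ray spectrum
#'
#' A discretized polychromatic spectrum: relative photon fluence per energy
#' bin, normalized to sum to one.
#'
#' @slot energies energy grid (keV), strictly increasing.
#' @slot weights relative fluence per bin, nonnegative, summing to 1.
#'
#' @exportClass XraySpectrum
setClass("XraySpectrum",
  representation(energies = "numeric", weights = "numeric"))

setValidity("XraySpectrum", function(object) {
  msg <- NULL
  if (length(object@energies) != length(object@weights))
    msg <- c(msg, "energies and weights must have equal length")
  if (is.unsorted(object@energies, strictly = TRUE))
    msg <- c(msg, "energies must be strictly increasing")
  if (any(object@weights < 0)) msg <- c(msg, "weights must be >= 0")
  if (abs(sum(object@weights) - 1) > 1e-8)
    msg <- c(msg, "weights must sum to 1")
  if (is.null(msg)) TRUE else msg
})

#' Diffusion noise schedule
#'
#' Per-step noise variances beta_t of the forward Markov chain and their
#' derived quantities alpha_t = 1 - beta_t and the cumulative products
#' alpha_bar_t, which govern the closed-form forward marginal
#' x_t = sqrt(alpha_bar_t) x_0 + sqrt(1 - alpha_bar_t) eps.
#'
#' @slot nSteps total number of steps T.
#' @slot betas beta_t in (0,1), length T.
#' @slot alphas 1 - beta_t.
#' @slot alphaBars cumulative products of alphas, strictly decreasing.
#'
#' @exportClass DiffusionSchedule
setClass("DiffusionSchedule",
  representation(nSteps = "integer", betas = "numeric", alphas = "numeric",
                 alphaBars = "numeric"))

setValidity("DiffusionSchedule", function(object) {
  msg <- NULL
  if (length(object@betas) != object@nSteps)
    msg <- c(msg, "betas must have length nSteps")
  if (any(object@betas <= 0) || any(object@betas >= 1))
    msg <- c(msg, "betas must lie in (0,1)")
  if (any(diff(object@alphaBars) >= 0))
    msg <- c(msg, "alphaBars must be strictly decreasing")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "FanBeamGeometry", function(object) {
  cat(sprintf(
    "FanBeamGeometry: SID %.1f mm, SDD %.1f mm, %d det @ %.3f mm (offset %.2f), %d views / %.0f deg\n",
    object@sid, object@sdd, object@nDet, object@pitch, object@offset,
    length(object@angles), object@arcDeg))
})

setMethod("show", "CTImage", function(object) {
  v <- object@values
  cat(sprintf("CTImage: %d x %d px @ %.3f mm, range [%.4g, %.4g] mm^-1\n",
              nrow(v), ncol(v), object@pixelSize, min(v), max(v)))
})

setMethod("show", "Sinogram", function(object) {
  cat(sprintf("Sinogram: %d views x %d detectors, range [%.4g, %.4g]\n",
              nrow(object@values), ncol(object@values),
              min(object@values), max(object@values)))
})

setMethod("show", "MaterialMap", function(object) {
  cat(sprintf("MaterialMap: %d x %d px @ %.3f mm, materials: %s\n",
              nrow(object@labels), ncol(object@labels), object@pixelSize,
              paste(object@materials, collapse = ", ")))
})

setMethod("show", "XraySpectrum", function(object) {
  cat(sprintf("XraySpectrum: %d bins, %.0f-%.0f keV, mean %.1f keV\n",
              length(object@energies), min(object@energies),
              max(object@energies),
              sum(object@energies * object@weights)))
})

setMethod("show", "DiffusionSchedule", function(object) {
  cat(sprintf("DiffusionSchedule: T = %d, beta in [%.2g, %.2g], alpha_bar_T = %.3g\n",
              object@nSteps, min(object@betas), max(object@betas),
              object@alphaBars[object@nSteps]))
})
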