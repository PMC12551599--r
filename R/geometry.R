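#' Construct a fan-beam geometry
#'
#' @param sid source-to-isocenter distance (mm).
#' @param sdd source-to-detector distance (mm); must exceed \code{sid}.
#' @param nDet number of detector elements.
#' @param pitch detector element spacing at the detector (mm).
#' @param nViews number of equally spaced view angles.
#' @param arcDeg angular coverage in degrees (default 360). Views sample
#'   \code{[0, arc)} so a full scan does not duplicate the 0/360 view.
#' @param offset lateral detector offset (mm, default 0).
#'
#' @return A \linkS4class{FanBeamGeometry}.
#' @examples
#' g <- fanBeamGeometry(400, 800, nDet = 96, pitch = 6, nViews = 180)
#' g
#' @export
fanBeamGeometry <- function(sid, sdd, nDet, pitch, nViews, arcDeg = 360,
                            offset = 0) {
  arc <- arcDeg * pi / 180
  angles <- seq(0, arc, length.out = nViews + 1L)[seq_len(nViews)]
  new("FanBeamGeometry", sid = as.numeric(sid), sdd = as.numeric(sdd),
      nDet = as.integer(nDet), pitch = as.numeric(pitch),
      offset = as.numeric(offset), angles = angles,
      arcDeg = as.numeric(arcDeg))
}

#' Construct a CT attenuation image
#'
#' @param values square numeric matrix of attenuation coefficients (mm^-1).
#' @param pixelSize pixel edge length (mm).
#' @return A \linkS4class{CTImage}.
#' @examples
#' img <- ctImage(matrix(0.02, 64, 64), pixelSize = 3)
#' @export
ctImage <- function(values, pixelSize) {
  new("CTImage", values = unname(as.matrix(values)),
      pixelSize = as.numeric(pixelSize))
}

#' Construct a sinogram
#'
#' @param values matrix of line integrals, \code{[n_angles x n_detectors]}.
#' @param geometry the \linkS4class{FanBeamGeometry} the data belong to.
#' @return A \linkS4class{Sinogram}.
#' @export
sinogram <- function(values, geometry) {
  new("Sinogram", values = unname(as.matrix(values)), geometry = geometry)
}

#' @rdname accessors
#' @param object a package object.
#' @export
setGeneric("imageValues", function(object) standardGeneric("imageValues"))

#' @rdname accessors
#' @export
setGeneric("sinoValues", function(object) standardGeneric("sinoValues"))

#' @rdname accessors
#' @export
setGeneric("pixelSize", function(object) standardGeneric("pixelSize"))

#' @rdname accessors
#' @export
setGeneric("geometry", function(object) standardGeneric("geometry"))

#' @rdname accessors
#' @export
setGeneric("viewAngles", function(object) standardGeneric("viewAngles"))

#' Accessors for the core containers
#'
#' \code{imageValues} returns the pixel matrix of a \linkS4class{CTImage},
#' \code{sinoValues} the view-by-detector matrix of a \linkS4class{Sinogram},
#' \code{pixelSize} the physical pixel size (mm), \code{geometry} the
#' attached \linkS4class{FanBeamGeometry}, and \code{viewAngles} the view
#' angles in radians.
#'
#' @name accessors
#' @aliases imageValues sinoValues pixelSize geometry viewAngles
NULL

setMethod("imageValues", "CTImage", function(object) object@values)
setMethod("pixelSize", "CTImage", function(object) object@pixelSize)
setMethod("pixelSize", "MaterialMap", function(object) object@pixelSize)
setMethod("sinoValues", "Sinogram", function(object) object@values)
setMethod("geometry", "Sinogram", function(object) object@geometry)
setMethod("viewAngles", "FanBeamGeometry", function(object) object@angles)

#' Radius of the reconstructible field of view
#'
#' The radius (mm) of the isocentric disc covered by every fan, limited by
#' the detector half-width (reduced by any lateral offset).
#'
#' @param geom a \linkS4class{FanBeamGeometry}.
#' @return FOV radius in mm.
#' @export
fovRadius <- function(geom) {
  halfWidth <- (geom@nDet - 1) / 2 * geom@pitch - abs(geom@offset)
  geom@sid * sin(atan2(halfWidth, geom@sdd))
}

.checkFov <- function(img, geom) {
  # the image support (inscribed disc of the grid) must fit in the FOV
  supp <- nrow(img@values) / 2 * img@pixelSize
  fov <- fovRadius(geom)
  if (fov < supp * 0.999)
    stop(sprintf(
      "field of view (radius %.1f mm) smaller than image support (%.1f mm)",
      fov, supp))
  invisible(TRUE)
}

#' Fan-beam forward projection
#'
#' Computes line integrals of a 2D attenuation image along every
#' source-to-detector-element ray, by Joseph-style sampling with bilinear
#' interpolation at steps of half a pixel. The operation is linear in the
#' image.
#'
#' @param image a \linkS4class{CTImage}.
#' @param geom a \linkS4class{FanBeamGeometry}; the image support must fit
#'   inside the field of view.
#' @return A \linkS4class{Sinogram}.
#' @examples
#' g <- fanBeamGeometry(400, 800, 96, 6, 90)
#' disc <- discPhantom(64, 3, radius = 40, mu = 0.02)
#' s <- forwardProject(disc, g)
#' @export
forwardProject <- function(image, geom) {
  stopifnot(is(image, "CTImage"), is(geom, "FanBeamGeometry"))
  .checkFov(image, geom)
  v <- cpp_forward_project(image@values, image@pixelSize, geom@sid, geom@sdd,
                           geom@nDet, geom@pitch, geom@offset, geom@angles)
  sinogram(v, geom)
}

#' Unfiltered backprojection (adjoint of the forward projector)
#'
#' The exact matrix transpose of \code{\link{forwardProject}} (ray-driven
#' splatting of sinogram values into the image grid). Useful for adjoint
#' consistency checks and iterative schemes; not a reconstruction by itself.
#'
#' @param sino a \linkS4class{Sinogram}.
#' @param n image grid side length (pixels).
#' @param pixelSize pixel size of the output grid (mm).
#' @return A \linkS4class{CTImage}.
#' @export
backProject <- function(sino, n, pixelSize) {
  stopifnot(is(sino, "Sinogram"))
  g <- sino@geometry
  v <- cpp_back_project(sino@values, pixelSize, g@sid, g@sdd, g@nDet,
                        g@pitch, g@offset, g@angles, as.integer(n))
  ctImage(v, pixelSize)
}

.rampKernel <- function(nPad, ds) {
  # discrete band-limited ramp (spatial domain), wrapped for FFT use
  h <- numeric(nPad)
  h[1] <- 1 / (4 * ds^2)
  idx <- seq_len(nPad - 1)
  half <- idx[idx <= nPad / 2]
  for (m in half) {
    val <- if (m %% 2 == 1) -1 / (pi^2 * m^2 * ds^2) else 0
    h[1 + m] <- val
    h[nPad + 1 - m] <- val
  }
  h
}

.parkerWeights <- function(angles, gamma, arc) {
  # Parker-style short-scan weights; gamma = fan angle per detector column
  nAng <- length(angles)
  gm <- (arc - pi) / 2
  w <- matrix(1, nAng, length(gamma))
  b <- angles - angles[1]
  for (ia in seq_len(nAng)) {
    bi <- b[ia]
    g <- gamma
    w1 <- bi / (2 * (gm - g))
    w2 <- (arc - bi) / (2 * (gm + g))
    row <- rep(1, length(g))
    sel1 <- bi < 2 * (gm - g)
    row[sel1] <- sin(pi / 2 * pmax(w1[sel1], 0))^2
    sel2 <- bi > pi - 2 * g
    row[sel2] <- sin(pi / 2 * pmax(w2[sel2], 0))^2
    w[ia, ] <- row
  }
  w
}

#' Filtered backprojection reconstruction
#'
#' Fan-beam filtered backprojection for a flat detector: cosine weighting,
#' ramp filtering in isocenter-rescaled detector coordinates (zero-padded to
#' the next power of two), and pixel-driven backprojection with inverse
#' square distance weighting. Short scans (arc < 360 degrees) are handled
#' with Parker-style weighting.
#'
#' @param sino a \linkS4class{Sinogram}.
#' @param n output grid side length (pixels).
#' @param pixelSize output pixel size (mm).
#' @param filter \code{"ramp"} (default) or \code{"cosine"} (ramp with
#'   cosine apodization).
#' @return A \linkS4class{CTImage} of attenuation coefficients.
#' @examples
#' g <- fanBeamGeometry(400, 800, 96, 6, 180)
#' p <- discPhantom(64, 3, radius = 40, mu = 0.02)
#' rec <- fbpReconstruct(forwardProject(p, g), 64, 3)
#' @export
fbpReconstruct <- function(sino, n, pixelSize, filter = c("ramp", "cosine")) {
  stopifnot(is(sino, "Sinogram"))
  supported <- c("ramp", "cosine")
  if (!is.character(filter) || !filter[1] %in% supported)
    stop("unsupported filter '", filter[1], "'; supported filters: ",
         paste(supported, collapse = ", "))
  filter <- filter[1]
  g <- sino@geometry
  nDet <- g@nDet
  mag <- g@sid / g@sdd
  ds <- g@pitch * mag
  s <- ((seq_len(nDet) - 1) - (nDet - 1) / 2) * ds + g@offset * mag
  # cosine (fan) weighting in rescaled flat-detector coordinates
  cw <- g@sid / sqrt(g@sid^2 + s^2)
  p <- sweep(sino@values, 2L, cw, `*`)
  arc <- g@arcDeg * pi / 180
  fullScan <- arc >= 2 * pi - 1e-9
  if (!fullScan) {
    gamma <- atan2(s, g@sid)
    p <- p * .parkerWeights(g@angles, gamma, arc)
  }
  nPad <- 2^ceiling(log2(2 * nDet))
  H <- Re(fft(.rampKernel(nPad, ds)))
  if (filter == "cosine") {
    f <- c(seq(0, nPad / 2), seq(nPad / 2 - 1, 1)) / nPad
    H <- H * cos(pi * f / (2 * max(f)))
  }
  pp <- matrix(0, nrow(p), nPad)
  pp[, seq_len(nDet)] <- p
  ftp <- t(mvfft(t(pp)))
  filt <- Re(t(mvfft(t(ftp * matrix(H, nrow(p), nPad, byrow = TRUE)),
                     inverse = TRUE))) / nPad
  q <- filt[, seq_len(nDet), drop = FALSE] * ds
  dBeta <- arc / length(g@angles)
  scale <- if (fullScan) 0.5 * dBeta else dBeta
  img <- cpp_fbp_backproject(q * scale, pixelSize, as.integer(n), g@sid,
                             s[1], ds, g@angles)
  ctImage(img, pixelSize)
}

#' Analytic disc phantom
#'
#' A centred (or shifted) homogeneous disc, the standard analytic test
#' object: its fan-beam projection along a ray at distance \eqn{s} from the
#' centre is the chord length \eqn{2\mu\sqrt{r^2 - s^2}}.
#'
#' @param n grid side length (pixels).
#' @param pixelSize pixel size (mm).
#' @param radius disc radius (mm).
#' @param mu attenuation inside the disc (mm^-1).
#' @param center disc centre (mm, length-2, default c(0, 0)).
#' @param supersample edge anti-aliasing factor (1 = hard binary edge).
#' @return A \linkS4class{CTImage}.
#' @export
discPhantom <- function(n, pixelSize, radius, mu, center = c(0, 0),
                        supersample = 4L) {
  ax <- (seq_len(n) - (n + 1) / 2) * pixelSize
  x <- matrix(ax, n, n, byrow = TRUE)
  y <- matrix(rev(ax), n, n)
  d <- sqrt((x - center[1])^2 + (y - center[2])^2)
  v <- ifelse(d <= radius, mu, 0)
  if (supersample > 1L) {
    # partial-volume weighting for pixels straddling the rim
    edge <- which(abs(d - radius) <= pixelSize)
    off <- (seq_len(supersample) - (supersample + 1) / 2) / supersample *
      pixelSize
    for (idx in edge) {
      xs <- x[idx] + off
      ys <- y[idx] + off
      inside <- outer(ys - center[2], xs - center[1],
                      function(a, b) a^2 + b^2 <= radius^2)
      v[idx] <- mu * mean(inside)
    }
  }
  ctImage(v, pixelSize)
}
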