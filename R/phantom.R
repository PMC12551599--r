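## Synthetic dental phantom + polychromatic acquisition physics.
## Materials follow a two-term attenuation model (photoelectric ~ E^-3 plus
## Compton ~ Klein-Nishina); coefficients are chosen for correct ordering and
## energy dependence of water-equivalent soft tissue, a Teflon-like bone
## surrogate and titanium, not for dosimetric accuracy.

.kleinNishina <- function(E) {
  a <- E / 511
  t1 <- (1 + a) / a^2 * (2 * (1 + a) / (1 + 2 * a) - log(1 + 2 * a) / a)
  t2 <- log(1 + 2 * a) / (2 * a)
  t3 <- -(1 + 3 * a) / (1 + 2 * a)^2
  t1 + t2 + t3
}

.muModel <- function(E, photo60, compton60) {
  kn <- .kleinNishina(E) / .kleinNishina(60)
  photo60 * (60 / E)^3 + compton60 * kn
}

#' Material attenuation table for the dental phantom
#'
#' Linear attenuation coefficients (mm^-1) on a diagnostic energy grid for
#' air, water-equivalent soft tissue, a Teflon-like bone surrogate and
#' titanium, from a photoelectric + Compton two-term model.
#'
#' @param energies energy grid in keV (default 20 equally spaced bins,
#'   25-95 keV).
#' @return list with \code{materials}, \code{energies} and the
#'   \code{[material x energy]} matrix \code{mu}.
#' @export
materialTable <- function(energies = seq(25, 95, length.out = 20)) {
  pars <- rbind(
    air         = c(0,     0),
    soft_tissue = c(0.0030, 0.0176),
    bone        = c(0.0140, 0.0310),
    metal       = c(0.3000, 0.0600))
  mu <- t(vapply(rownames(pars),
                 function(m) .muModel(energies, pars[m, 1], pars[m, 2]),
                 numeric(length(energies))))
  list(materials = rownames(pars), energies = energies, mu = mu)
}

#' Bremsstrahlung-like X-ray spectrum
#'
#' A discretized tube spectrum: Kramers-shaped fluence with a soft
#' filtration factor suppressing the lowest energies, normalized to unit
#' total weight.
#'
#' @param kvp tube potential (kVp); photons occupy (Emin, kvp).
#' @param nBins number of energy bins.
#' @param eMin lowest bin energy (keV).
#' @param filtration strength of the low-energy suppression (unitless
#'   exponent scale; 0 disables).
#' @return An \linkS4class{XraySpectrum}.
#' @examples
#' sp <- makeSpectrum(95, nBins = 12)
#' @export
makeSpectrum <- function(kvp = 95, nBins = 12, eMin = 15, filtration = 0.15) {
  E <- seq(eMin, kvp - 2, length.out = nBins)
  w <- (kvp - E) * exp(-filtration * (60 / E)^3)
  w <- w / sum(w)
  new("XraySpectrum", energies = E, weights = w)
}

#' Monoenergetic spectrum
#'
#' @param energy the single energy (keV).
#' @return An \linkS4class{XraySpectrum} with one bin of weight 1.
#' @export
monoSpectrum <- function(energy = 60) {
  new("XraySpectrum", energies = energy, weights = 1)
}

#' Parameters of the synthetic dental phantom
#'
#' A PMMA-like head section with a dental arch of bone-equivalent (Teflon
#' surrogate) teeth, optional titanium inserts seated inside teeth, a throat
#' air pocket, and a seeded low-frequency soft-tissue texture field
#' emulating clay-mixture variability.
#'
#' @param n grid side (pixels).
#' @param pixelSize pixel size (mm).
#' @param headRadii semi-axes of the soft-tissue ellipse (mm).
#' @param archRadius radius of the dental arch (mm).
#' @param archSpanDeg angular span of the arch (degrees).
#' @param archCenter arch centre (mm, relative to isocenter).
#' @param nTeeth number of bone-equivalent teeth.
#' @param toothRadius tooth disc radius (mm).
#' @param nMetal number of titanium inserts (0 to nTeeth).
#' @param metalRadius insert radius (mm); must be < toothRadius.
#' @param metalShape \code{"cylinder"} or \code{"screw"} (cylinder head plus
#'   a narrow shaft).
#' @param throatRadius radius of the posterior air pocket (mm, 0 disables).
#' @param textureAmp relative amplitude of the soft-tissue texture field.
#' @param jitter random positional jitter applied to teeth (mm).
#' @return A list of class \code{"phantomSpec"}.
#' @export
dentalPhantomSpec <- function(n = 64, pixelSize = 3, headRadii = c(82, 74),
                              archRadius = 52, archSpanDeg = 150,
                              archCenter = c(0, -8), nTeeth = 8,
                              toothRadius = 8, nMetal = 3, metalRadius = 5,
                              metalShape = c("cylinder", "screw"),
                              throatRadius = 12, textureAmp = 0.06,
                              jitter = 1.5) {
  metalShape <- match.arg(metalShape)
  if (metalRadius >= toothRadius)
    stop("metal insert must fit inside its tooth socket")
  if (nMetal > nTeeth) stop("more metal inserts than teeth")
  structure(list(n = n, pixelSize = pixelSize, headRadii = headRadii,
                 archRadius = archRadius, archSpanDeg = archSpanDeg,
                 archCenter = archCenter, nTeeth = nTeeth,
                 toothRadius = toothRadius, nMetal = nMetal,
                 metalRadius = metalRadius, metalShape = metalShape,
                 throatRadius = throatRadius, textureAmp = textureAmp,
                 jitter = jitter),
            class = "phantomSpec")
}

.gridXY <- function(n, px) {
  ax <- (seq_len(n) - (n + 1) / 2) * px
  list(x = matrix(ax, n, n, byrow = TRUE), y = matrix(rev(ax), n, n))
}

.lowFreqField <- function(n, nKnots = 5) {
  # smooth random field in [-1, 1] from a coarse Gaussian-bump expansion
  coarse <- matrix(rnorm(nKnots^2), nKnots, nKnots)
  ax <- seq(0, 1, length.out = n)
  knots <- seq(0, 1, length.out = nKnots)
  basis <- outer(ax, knots, function(a, k) exp(-((a - k) / 0.18)^2))
  f <- basis %*% coarse %*% t(basis)
  f / max(abs(f), 1e-12)
}

#' Generate a synthetic dental phantom
#'
#' Builds the labelled material map for one phantom realization: teeth are
#' placed along the arch (with seeded jitter), titanium inserts are seated
#' inside randomly chosen teeth, and a seeded low-frequency texture field
#' for the soft tissue is drawn. Deterministic for a fixed seed.
#'
#' @param spec a \code{\link{dentalPhantomSpec}}.
#' @param seed integer RNG seed.
#' @return A list with \code{map} (\linkS4class{MaterialMap}),
#'   \code{metalMask} (binary matrix), \code{texture} (matrix in [-1,1]),
#'   \code{spec} and \code{seed}.
#' @examples
#' ph <- makeDentalPhantom(dentalPhantomSpec(nMetal = 2), seed = 1)
#' table(ph$map@labels)
#' @export
makeDentalPhantom <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "phantomSpec"))
  set.seed(seed)
  n <- spec$n; px <- spec$pixelSize
  g <- .gridXY(n, px)
  tab <- materialTable()
  lab <- matrix(1L, n, n)                       # air
  inHead <- (g$x / spec$headRadii[1])^2 + (g$y / spec$headRadii[2])^2 <= 1
  lab[inHead] <- 2L                             # soft tissue
  # teeth along the anterior arch (arch opens posteriorly, +y = anterior)
  span <- spec$archSpanDeg * pi / 180
  th <- seq(pi / 2 - span / 2, pi / 2 + span / 2, length.out = spec$nTeeth)
  cx <- spec$archCenter[1] + spec$archRadius * cos(th) +
    rnorm(spec$nTeeth, 0, spec$jitter)
  cy <- spec$archCenter[2] + spec$archRadius * sin(th) +
    rnorm(spec$nTeeth, 0, spec$jitter)
  lim <- sqrt((cx / spec$headRadii[1])^2 + (cy / spec$headRadii[2])^2)
  if (any(lim + (spec$toothRadius / min(spec$headRadii)) > 1))
    stop("tooth insert overlaps the phantom boundary")
  for (k in seq_len(spec$nTeeth))
    lab[(g$x - cx[k])^2 + (g$y - cy[k])^2 <= spec$toothRadius^2] <- 3L
  metalMask <- matrix(FALSE, n, n)
  if (spec$nMetal > 0) {
    # spread inserts across the arch (one per contiguous block of teeth) so
    # rod pairs span a soft-tissue dark-band region between the arch halves
    edges <- round(seq(0, spec$nTeeth, length.out = spec$nMetal + 1))
    pick <- vapply(seq_len(spec$nMetal), function(b)
      sample(seq(edges[b] + 1L, edges[b + 1L]), 1L), integer(1))
    for (k in pick) {
      sel <- (g$x - cx[k])^2 + (g$y - cy[k])^2 <= spec$metalRadius^2
      if (spec$metalShape == "screw") {
        # narrow shaft pointing inward toward the arch centre
        dirx <- spec$archCenter[1] - cx[k]; diry <- spec$archCenter[2] - cy[k]
        nn <- sqrt(dirx^2 + diry^2); dirx <- dirx / nn; diry <- diry / nn
        relx <- g$x - cx[k]; rely <- g$y - cy[k]
        along <- relx * dirx + rely * diry
        across <- -relx * diry + rely * dirx
        sel <- sel | (along > 0 & along <= spec$toothRadius * 0.9 &
                        abs(across) <= spec$metalRadius * 0.45)
      }
      sel <- sel & lab == 3L                    # seat inside the bone socket
      metalMask[sel] <- TRUE
    }
    lab[metalMask] <- 4L
  }
  if (spec$throatRadius > 0) {
    ty <- spec$archCenter[2] - spec$archRadius * 0.45
    sel <- (g$x)^2 + (g$y - ty)^2 <= spec$throatRadius^2
    lab[sel & lab == 2L] <- 1L
  }
  texture <- .lowFreqField(n)
  map <- new("MaterialMap", labels = lab, materials = tab$materials,
             energies = tab$energies, mu = tab$mu, pixelSize = px)
  list(map = map, metalMask = metalMask, texture = texture, spec = spec,
       seed = seed)
}

#' Replace metal by bone-equivalent material
#'
#' The "no-metal" phantom variant: metal labels become bone labels,
#' mirroring a physical phantom whose metal inserts are swapped for
#' bone-surrogate pieces.
#'
#' @param phantom output of \code{\link{makeDentalPhantom}}.
#' @return The phantom list with metal removed (mask retained for reference).
#' @export
removeMetal <- function(phantom) {
  lab <- phantom$map@labels
  lab[lab == 4L] <- 3L
  phantom$map@labels <- lab
  phantom$noMetal <- TRUE
  phantom
}

#' Attenuation image of a material map at one energy
#'
#' @param map a \linkS4class{MaterialMap}.
#' @param energy energy in keV (interpolated on the map's grid).
#' @param texture optional soft-tissue texture field in [-1,1].
#' @param textureAmp relative texture amplitude.
#' @return A \linkS4class{CTImage}.
#' @export
muImage <- function(map, energy, texture = NULL, textureAmp = 0) {
  muE <- vapply(seq_along(map@materials), function(m)
    approx(map@energies, map@mu[m, ], xout = energy, rule = 2)$y, numeric(1))
  v <- matrix(muE[map@labels], nrow(map@labels), ncol(map@labels))
  if (!is.null(texture) && textureAmp > 0) {
    soft <- map@labels == 2L
    v[soft] <- v[soft] * (1 + textureAmp * texture[soft])
  }
  ctImage(v, map@pixelSize)
}

#' Polychromatic projection simulation
#'
#' Simulates fan-beam projections of a material map under a polychromatic
#' spectrum with Poisson photon noise: the detected fraction per ray is
#' \eqn{\sum_E w(E) \exp(-\int \mu(E))}, counts are Poisson with mean
#' \code{photonsPerRay} times that fraction (floored at one photon before
#' the log, emulating photon starvation), and the sinogram is
#' \eqn{-\ln(\mathrm{counts}/\mathrm{blank})}. With a single-bin spectrum
#' and \code{photonsPerRay = Inf} this reduces exactly to
#' \code{\link{forwardProject}} of the monoenergetic attenuation map.
#'
#' @param map a \linkS4class{MaterialMap}.
#' @param spectrum an \linkS4class{XraySpectrum}.
#' @param geom a \linkS4class{FanBeamGeometry}.
#' @param photonsPerRay blank-scan photons per detector element
#'   (\code{Inf} disables noise).
#' @param seed integer RNG seed for the Poisson draw.
#' @param texture,textureAmp optional soft-tissue texture (see
#'   \code{\link{muImage}}).
#' @return A \linkS4class{Sinogram}.
#' @export
simulatePolychromatic <- function(map, spectrum, geom, photonsPerRay = 8e3,
                                  seed = 1L, texture = NULL,
                                  textureAmp = 0) {
  stopifnot(is(map, "MaterialMap"), is(spectrum, "XraySpectrum"))
  if (sum(spectrum@weights) <= 0) stop("spectrum has zero total weight")
  if (photonsPerRay <= 0) stop("photonsPerRay must be > 0")
  detected <- NULL
  for (k in seq_along(spectrum@energies)) {
    wk <- spectrum@weights[k]
    if (wk == 0) next
    L <- sinoValues(forwardProject(
      muImage(map, spectrum@energies[k], texture, textureAmp), geom))
    term <- wk * exp(-L)
    detected <- if (is.null(detected)) term else detected + term
  }
  if (is.finite(photonsPerRay)) {
    set.seed(seed)
    counts <- matrix(rpois(length(detected), photonsPerRay * detected),
                     nrow(detected), ncol(detected))
    counts <- pmax(counts, 1)                  # photon starvation floor
    vals <- -log(counts / photonsPerRay)
  } else {
    vals <- -log(detected)
  }
  sinogram(vals, geom)
}

#' Generate one paired clean/corrupted phantom slice
#'
#' The corrupted member is the polychromatic, noisy acquisition of the
#' phantom with metal; the clean member is the monoenergetic, noise-free
#' reconstruction of the same phantom with metal replaced by bone
#' equivalent. Both share the texture field, grid and seed, so they differ
#' only through metal physics.
#'
#' @param spec a \code{\link{dentalPhantomSpec}}.
#' @param geom a \linkS4class{FanBeamGeometry}.
#' @param spectrum spectrum for the corrupted acquisition.
#' @param photonsPerRay blank photons per ray for the corrupted acquisition.
#' @param seed integer seed controlling phantom and noise.
#' @param refEnergy reference energy (keV) of the clean reconstruction;
#'   the default 54 keV is the effective energy of the default 95 kVp
#'   spectrum (the energy whose soft-tissue attenuation matches the
#'   polychromatic reconstruction plateau), so clean and corrupted share a
#'   common soft-tissue baseline.
#' @return A list of class \code{"phantomPair"}: \code{clean},
#'   \code{corrupted} (\linkS4class{CTImage}), \code{corruptedSino}
#'   (\linkS4class{Sinogram}), \code{metalMask} (binary matrix),
#'   \code{phantom}, \code{seed}.
#' @export
makePhantomPair <- function(spec, geom, spectrum = makeSpectrum(),
                            photonsPerRay = 8e3, seed = 1L,
                            refEnergy = 54) {
  ph <- makeDentalPhantom(spec, seed = seed)
  n <- spec$n; px <- spec$pixelSize
  corruptedSino <- simulatePolychromatic(ph$map, spectrum, geom,
                                         photonsPerRay, seed = seed + 1L,
                                         texture = ph$texture,
                                         textureAmp = spec$textureAmp)
  corrupted <- fbpReconstruct(corruptedSino, n, px)
  phClean <- removeMetal(ph)
  cleanSino <- simulatePolychromatic(phClean$map, monoSpectrum(refEnergy),
                                     geom, Inf, texture = ph$texture,
                                     textureAmp = spec$textureAmp)
  clean <- fbpReconstruct(cleanSino, n, px)
  structure(list(clean = clean, corrupted = corrupted,
                 corruptedSino = corruptedSino, metalMask = ph$metalMask,
                 phantom = ph, seed = seed),
            class = "phantomPair")
}

#' Extract a metal artifact map
#'
#' The difference image corrupted minus clean, whose support carries the
#' dark bands and streaks induced by the metal (plus the metal itself).
#'
#' @param corrupted,clean \linkS4class{CTImage}s on the same grid.
#' @return A \linkS4class{CTImage}.
#' @export
extractArtifactMap <- function(corrupted, clean) {
  if (!identical(dim(corrupted@values), dim(clean@values)) ||
      abs(corrupted@pixelSize - clean@pixelSize) > 1e-9)
    stop("corrupted and clean images must share the grid")
  ctImage(corrupted@values - clean@values, corrupted@pixelSize)
}

#' Rotate a 2D grid about its centre
#'
#' @param m numeric matrix.
#' @param deg rotation angle (degrees, counter-clockwise).
#' @param interp \code{"bilinear"} or \code{"nearest"} (for masks).
#' @return rotated matrix, zero-filled outside.
#' @export
rotateGrid <- function(m, deg, interp = c("bilinear", "nearest")) {
  interp <- match.arg(interp)
  n <- nrow(m)
  th <- deg * pi / 180
  ct <- cos(th); st <- sin(th)
  c0 <- (n + 1) / 2
  idx <- seq_len(n) - c0
  X <- matrix(idx, n, n, byrow = TRUE)   # column offset
  Y <- matrix(idx, n, n)                 # row offset
  # inverse mapping (sample source at -theta)
  Xs <- ct * X + st * Y + c0
  Ys <- -st * X + ct * Y + c0
  if (interp == "nearest") {
    Xi <- round(Xs); Yi <- round(Ys)
    ok <- Xi >= 1 & Xi <= n & Yi >= 1 & Yi <= n
    out <- matrix(0, n, n)
    out[ok] <- m[cbind(Yi[ok], Xi[ok])]
    return(out)
  }
  X0 <- floor(Xs); Y0 <- floor(Ys)
  fx <- Xs - X0; fy <- Ys - Y0
  out <- matrix(0, n, n)
  for (dy in 0:1) for (dx in 0:1) {
    Xi <- X0 + dx; Yi <- Y0 + dy
    w <- (if (dx) fx else 1 - fx) * (if (dy) fy else 1 - fy)
    ok <- Xi >= 1 & Xi <= n & Yi >= 1 & Yi <= n & w > 0
    out[ok] <- out[ok] + w[ok] * m[cbind(Yi[ok], Xi[ok])]
  }
  out
}

#' Overlay a (rotated) artifact map onto a metal-free target slice
#'
#' Adds a rigidly rotated artifact map to a target image and applies the
#' identical rotation to the metal mask, producing a synthetic
#' metal-affected slice with a known label.
#'
#' @param map artifact map (\linkS4class{CTImage}).
#' @param target metal-free target slice (\linkS4class{CTImage}).
#' @param metalMask binary matrix to transform along with the map.
#' @param rotationDeg rotation in degrees; when \code{NULL}, drawn uniformly
#'   from [0, 360) using \code{seed}.
#' @param seed integer seed used when \code{rotationDeg} is NULL.
#' @return list with \code{image} (\linkS4class{CTImage}), \code{mask}
#'   (binary matrix) and \code{rotationDeg}.
#' @export
overlayArtifact <- function(map, target, metalMask = NULL,
                            rotationDeg = NULL, seed = 1L) {
  if (!identical(dim(map@values), dim(target@values)))
    stop("map and target grids are incompatible")
  if (is.null(rotationDeg)) {
    set.seed(seed)
    rotationDeg <- runif(1, 0, 360)
  }
  rmap <- rotateGrid(map@values, rotationDeg)
  mask <- NULL
  if (!is.null(metalMask))
    mask <- rotateGrid(metalMask * 1, rotationDeg, interp = "nearest") > 0.5
  list(image = ctImage(target@values + rmap, target@pixelSize),
       mask = mask, rotationDeg = rotationDeg)
}

#' Deterministic suite of paired phantom slices
#'
#' Generates \code{nPairs} phantom pairs from a base seed; the manifest of
#' per-pair seeds fully determines every slice.
#'
#' @param nPairs number of pairs.
#' @param spec phantom parameters (inserts are randomized per pair).
#' @param geom acquisition geometry.
#' @param spectrum polychromatic spectrum.
#' @param photonsPerRay blank photons per ray.
#' @param seed base seed; pair k uses seed \code{seed + 137 * k}.
#' @return list with \code{pairs} and \code{manifest} (data.frame of seeds).
#' @export
simulationSuite <- function(nPairs, spec = dentalPhantomSpec(),
                            geom = defaultGeometry(),
                            spectrum = makeSpectrum(),
                            photonsPerRay = 8e3, seed = 1L) {
  seeds <- seed + 137L * seq_len(nPairs)
  pairs <- lapply(seeds, function(s)
    makePhantomPair(spec, geom, spectrum, photonsPerRay, seed = s))
  list(pairs = pairs,
       manifest = data.frame(pair = seq_len(nPairs), seed = seeds))
}

#' Default desk-scale acquisition geometry
#'
#' 400 mm source-to-isocenter, 800 mm source-to-detector, 144 detector
#' elements at 4 mm pitch, 180 views over 360 degrees: a full-fan 2D
#' geometry whose field of view covers the 64 x 64 @ 3 mm working grid.
#'
#' @param nViews number of views (default 180).
#' @param arcDeg angular coverage (default 360).
#' @return A \linkS4class{FanBeamGeometry}.
#' @export
defaultGeometry <- function(nViews = 180, arcDeg = 360) {
  fanBeamGeometry(400, 800, nDet = 144, pitch = 4, nViews = nViews,
                  arcDeg = arcDeg)
}
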