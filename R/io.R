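## Plain-text/TIFF persistence: float TIFF for images, masks and sinograms,
## YAML configs, JSON manifests and evaluation reports.

#' Write / read a CT image as 32-bit float TIFF
#'
#' Pixel size (mm) and the affine intensity scaling are carried in a
#' JSON sidecar next to the TIFF.
#'
#' @param image a \linkS4class{CTImage}.
#' @param path output path.
#' @return \code{readImageTiff} returns a \linkS4class{CTImage}.
#' @export
writeImageTiff <- function(image, path) {
  stopifnot(is(image, "CTImage"))
  sc <- .tiffScale(image@values)
  tiff::writeTIFF(sc$scaled, path, bits.per.sample = 32L,
                  reduce = FALSE, compression = "none")
  # sidecar with grid metadata and the affine intensity scaling (TIFF
  # float storage is clamped to [0, 1] by the writer)
  jsonlite::write_json(list(pixelSize = image@pixelSize,
                            vmin = sc$vmin, vmax = sc$vmax),
                       paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

.tiffScale <- function(v) {
  vmin <- min(v); vmax <- max(v)
  rng <- vmax - vmin
  if (rng <= 0) rng <- 1
  list(scaled = (v - vmin) / rng, vmin = vmin, vmax = vmin + rng)
}

.tiffUnscale <- function(v, meta) {
  if (is.null(meta$vmin)) return(v)
  v * (meta$vmax - meta$vmin) + meta$vmin
}

#' @rdname writeImageTiff
#' @param pixelSize pixel size override when no sidecar is present.
#' @export
readImageTiff <- function(path, pixelSize = NULL) {
  v <- tiff::readTIFF(path, as.is = FALSE)
  if (length(dim(v)) == 3L) v <- v[, , 1]
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side) else list()
  v <- .tiffUnscale(v, meta)
  if (is.null(pixelSize))
    pixelSize <- if (!is.null(meta$pixelSize)) meta$pixelSize else 1
  ctImage(v, pixelSize)
}

#' Write / read a binary mask as 8-bit TIFF (0/255)
#'
#' @param mask logical matrix.
#' @param path file path.
#' @export
writeMaskTiff <- function(mask, path) {
  tiff::writeTIFF(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path,
                  bits.per.sample = 8L)
  invisible(path)
}

#' @rdname writeMaskTiff
#' @export
readMaskTiff <- function(path) {
  v <- tiff::readTIFF(path)
  if (length(dim(v)) == 3L) v <- v[, , 1]
  v > 0.5
}

#' Write / read a sinogram (float TIFF + geometry sidecar)
#'
#' @param sino a \linkS4class{Sinogram}.
#' @param path file path.
#' @export
writeSinogramTiff <- function(sino, path) {
  stopifnot(is(sino, "Sinogram"))
  g <- sino@geometry
  sc <- .tiffScale(sino@values)
  tiff::writeTIFF(sc$scaled, path, bits.per.sample = 32L,
                  compression = "none", reduce = FALSE)
  jsonlite::write_json(
    list(sid_mm = g@sid, sdd_mm = g@sdd, n_det = g@nDet, pitch_mm = g@pitch,
         offset_mm = g@offset, n_views = length(g@angles),
         arc_deg = g@arcDeg, vmin = sc$vmin, vmax = sc$vmax),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeSinogramTiff
#' @export
readSinogramTiff <- function(path) {
  v <- tiff::readTIFF(path, as.is = FALSE)
  if (length(dim(v)) == 3L) v <- v[, , 1]
  meta <- jsonlite::read_json(paste0(path, ".json"))
  v <- .tiffUnscale(v, meta)
  g <- fanBeamGeometry(meta$sid_mm, meta$sdd_mm, meta$n_det, meta$pitch_mm,
                       meta$n_views, meta$arc_deg, meta$offset_mm)
  sinogram(v, g)
}

#' Read an acquisition-geometry config from YAML
#'
#' Recognized keys (under \code{geometry:}): \code{sid_mm}, \code{sdd_mm},
#' \code{n_det}, \code{pitch_mm}, \code{offset_mm}, \code{n_views},
#' \code{arc_deg}.
#'
#' @param path YAML file path.
#' @return A \linkS4class{FanBeamGeometry}.
#' @export
readGeometryConfig <- function(path) {
  y <- yaml::read_yaml(path)
  gg <- if (!is.null(y$geometry)) y$geometry else y
  fanBeamGeometry(gg$sid_mm, gg$sdd_mm, gg$n_det, gg$pitch_mm, gg$n_views,
                  if (is.null(gg$arc_deg)) 360 else gg$arc_deg,
                  if (is.null(gg$offset_mm)) 0 else gg$offset_mm)
}

#' Write an evaluation report as JSON
#'
#' @param report an \code{"evalReport"} (or ablation table list).
#' @param path output path.
#' @export
writeReportJson <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE, pretty = TRUE)
  invisible(path)
}
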