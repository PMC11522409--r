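#' Calibrated grayscale image
#'
#' A pixel matrix together with its spatial calibration in micrometres per
#' pixel. The default calibration, 2803/2046 (about 1.37 um/px), matches a
#' 20x field covering 2803 micrometres over 2046 pixels.
#'
#' @param pixels numeric or integer matrix, 8- or 16-bit grayscale levels.
#' @param um_per_px micrometres per pixel (> 0).
#' @return Object of class `calibrated_image`.
#' @export
calibrated_image <- function(pixels, um_per_px = 2803 / 2046) {
  if (!is.matrix(pixels) || !length(pixels))
    stop("calibrated_image: 'pixels' must be a non-empty matrix")
  if (um_per_px <= 0) stop("calibrated_image: um_per_px must be positive")
  structure(list(pixels = pixels, um_per_px = um_per_px),
            class = "calibrated_image")
}

#' Read a micrograph from TIFF or PNG
#'
#' @param path image path (`.tif`, `.tiff` or `.png`).
#' @param um_per_px calibration in micrometres per pixel.
#' @return A [calibrated_image] with levels on the file's native scale.
#' @export
read_micrograph <- function(path, um_per_px = 2803 / 2046) {
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    tif = , tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("read_micrograph: package 'tiff' required for TIFF input")
      tiff::readTIFF(path)
    },
    png = {
      if (!requireNamespace("png", quietly = TRUE))
        stop("read_micrograph: package 'png' required for PNG input")
      png::readPNG(path)
    },
    stop("read_micrograph: unsupported extension '", ext, "'"))
  if (length(dim(px)) == 3) px <- apply(px[, , 1:min(3, dim(px)[3]), drop = FALSE],
                                        c(1, 2), mean)
  calibrated_image(round(px * 255), um_per_px)
}

# Min-max rescale to the 8-bit range 0..255 (identity for images already
# within it).
to_8bit <- function(pixels) {
  rng <- range(pixels)
  if (rng[1] >= 0 && rng[2] <= 255 &&
      all(pixels == round(pixels))) return(pixels)
  if (rng[2] == rng[1]) return(matrix(0, nrow(pixels), ncol(pixels)))
  round((pixels - rng[1]) / (rng[2] - rng[1]) * 255)
}

#' Maximum-entropy (Kapur) threshold
#'
#' Converts the image to 8-bit (min-max rescaling for 16-bit input), then
#' selects the intensity threshold maximising the sum of the Shannon
#' entropies of the foreground and background grey-level distributions over
#' the 256-bin histogram. The mask is `pixels > threshold`.
#'
#' @param image a [calibrated_image] (or plain matrix).
#' @return List with `threshold` (0--255) and `mask` (logical matrix).
#' @export
max_entropy_threshold <- function(image) {
  px <- if (inherits(image, "calibrated_image")) image$pixels else image
  px <- to_8bit(px)
  if (length(unique(as.vector(px))) < 2)
    stop("max_entropy_threshold: constant image, no threshold exists")
  h <- tabulate(as.vector(px) + 1L, nbins = 256)
  p <- h / sum(h)
  P <- cumsum(p)
  ent <- function(v) { v <- v[v > 0]; -sum(v * log(v)) }
  best <- -Inf; thr <- NA_integer_
  for (t in 0:254) {
    Pb <- P[t + 1]
    if (Pb <= 0 || Pb >= 1) next
    Hb <- ent(p[1:(t + 1)] / Pb)
    Hf <- ent(p[(t + 2):256] / (1 - Pb))
    if (Hb + Hf > best) { best <- Hb + Hf; thr <- t }
  }
  if (is.na(thr)) stop("max_entropy_threshold: no admissible threshold")
  list(threshold = thr, mask = px > thr)
}

#' Segment and measure particles in a binary mask
#'
#' Splits touching blobs with a distance-transform watershed, measures each
#' connected region, converts pixel areas to equivalent circular diameters
#' (`2 * sqrt(area / pi)`) in micrometres, and discards particles whose
#' equivalent diameter does not exceed `min_diameter` (5 um), the cut used
#' to reject antibody precipitates and autofluorescence.
#'
#' @param mask logical or 0/1 matrix.
#' @param um_per_px calibration in micrometres per pixel.
#' @param min_diameter retention cut on equivalent diameter (um, strict `>`).
#' @param tolerance watershed tolerance (minimum object-height separation in
#'   the distance transform).
#' @return List of class `particle_result`: `particles` (per-particle data
#'   frame), `n_before`, `n_after`, `min_diameter`, `um_per_px`.
#' @export
segment_particles <- function(mask, um_per_px = 2803 / 2046, min_diameter = 5,
                              tolerance = 1) {
  m <- (mask > 0) * 1
  if (!sum(m)) {
    return(structure(list(
      particles = data.frame(label = integer(0), area_px = numeric(0),
                             area_um2 = numeric(0),
                             equiv_diameter_um = numeric(0),
                             cx = numeric(0), cy = numeric(0)),
      n_before = 0L, n_after = 0L, min_diameter = min_diameter,
      um_per_px = um_per_px), class = "particle_result"))
  }
  dm <- EBImage::distmap(m)
  lab <- EBImage::watershed(dm, tolerance = tolerance, ext = 1)
  labs <- sort(unique(as.vector(lab)))
  labs <- labs[labs > 0]
  area <- vapply(labs, function(l) sum(lab == l), numeric(1))
  cx <- vapply(labs, function(l) mean(row(lab)[lab == l]), numeric(1))
  cy <- vapply(labs, function(l) mean(col(lab)[lab == l]), numeric(1))
  df <- data.frame(label = labs, area_px = area,
                   area_um2 = area * um_per_px^2,
                   equiv_diameter_um = 2 * sqrt(area * um_per_px^2 / pi),
                   cx = cx, cy = cy)
  keep <- df$equiv_diameter_um > min_diameter
  structure(list(particles = df[keep, , drop = FALSE],
                 n_before = nrow(df), n_after = sum(keep),
                 min_diameter = min_diameter, um_per_px = um_per_px),
            class = "particle_result")
}

#' Quantify particles in a calibrated micrograph
#'
#' Maximum-entropy threshold followed by watershed segmentation and the
#' size filter: the full particle-quantification chain for one image.
#'
#' @param image a [calibrated_image].
#' @param config an [analysis_config] (`um_per_px` is taken from the image).
#' @return A `particle_result` with the applied `threshold` attached.
#' @export
quantify_particles <- function(image, config = analysis_config()) {
  th <- max_entropy_threshold(image)
  res <- segment_particles(th$mask, um_per_px = image$um_per_px,
                           min_diameter = config$min_diameter,
                           tolerance = config$watershed_tolerance)
  res$threshold <- th$threshold
  res
}
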