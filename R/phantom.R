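#' Generate a particle-image phantom with known ground truth
#'
#' Renders bright disks on a dark background, mirroring fluorescent
#' amyloid-beta aggregates in a calibrated micrograph, and returns the
#' per-disk ground truth (rasterised pixel area and the resulting equivalent
#' circular diameter in micrometres) so segmentation can be scored exactly.
#'
#' @param width,height image size in pixels.
#' @param disks data frame with columns `cx`, `cy` (centres, px) and
#'   `diameter_um`; may have zero rows for a blank image.
#' @param um_per_px calibration, micrometres per pixel.
#' @param fg,bg foreground / background intensity (0--255).
#' @param noise_sd SD of additive Gaussian intensity noise (clipped to
#'   0--255); 0 for a noiseless phantom.
#' @param seed RNG seed for the noise.
#' @return A list with `image` (a [calibrated_image]) and `truth` (data frame
#'   of per-disk pixel area and equivalent diameter).
#' @export
make_particle_phantom <- function(width, height, disks, um_per_px = 2803 / 2046,
                                  fg = 200, bg = 10, noise_sd = 0, seed = 1) {
  img <- matrix(bg, nrow = width, ncol = height)
  truth <- data.frame(cx = numeric(0), cy = numeric(0),
                      diameter_um = numeric(0), area_px = numeric(0),
                      equiv_diameter_um = numeric(0))
  if (!is.null(disks) && nrow(disks)) {
    for (i in seq_len(nrow(disks))) {
      r_px <- (disks$diameter_um[i] / um_per_px) / 2
      if (disks$cx[i] - r_px < 1 || disks$cx[i] + r_px > width ||
          disks$cy[i] - r_px < 1 || disks$cy[i] + r_px > height)
        stop("make_particle_phantom: disk ", i, " extends outside the image")
      if (disks$diameter_um[i] <= 0)
        stop("make_particle_phantom: diameters must be positive")
      d2 <- outer((seq_len(width) - disks$cx[i])^2,
                  (seq_len(height) - disks$cy[i])^2, "+")
      inside <- d2 <= r_px^2
      area <- sum(inside)
      img[inside] <- fg
      truth <- rbind(truth, data.frame(
        cx = disks$cx[i], cy = disks$cy[i], diameter_um = disks$diameter_um[i],
        area_px = area,
        equiv_diameter_um = 2 * sqrt(area * um_per_px^2 / pi)))
    }
  }
  if (noise_sd > 0)
    img <- with_local_seed(seed, {
      pmin(pmax(img + matrix(rnorm(length(img), 0, noise_sd),
                             nrow = width), 0), 255)
    })
  list(image = calibrated_image(round(img), um_per_px), truth = truth)
}
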