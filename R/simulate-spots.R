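#' Render a synthetic single-molecule spot image with known ground truth
#'
#' Generates a 16-bit grayscale image as a constant background plus a sum of
#' isotropic Gaussian peaks and optional Gaussian pixel noise, rounded and
#' clipped to `[0, 65535]`. Spot centers are drawn at integer pixels, at
#' least `border_margin_px` from every edge and pairwise separated by at
#' least `6 * sigma_px`, so neighbouring spots do not merge. True centers
#' are recorded for recall/precision evaluation of the maxima finder.
#'
#' @param shape Integer vector `c(rows, cols)`.
#' @param n_spots Number of spots.
#' @param amplitude Peak height above background, intensity units.
#' @param sigma_px Gaussian sigma in pixels.
#' @param background Constant background level.
#' @param noise_sd Standard deviation of additive Gaussian noise (0 for
#'   noiseless images).
#' @param border_margin_px Minimum distance of centers from the image edge;
#'   set to 0 to allow spots on the border (for border-exclusion tests).
#' @param max_tries Placement retries before giving up on an infeasible
#'   packing.
#' @return A list of class `spot_truth`: `image` (integer matrix),
#'   `centers` (tibble `row`, `col`), and the generation parameters.
#' @export
#' @examples
#' set.seed(1)
#' st <- render_spot_image(c(128, 128), n_spots = 10, amplitude = 10000,
#'                         sigma_px = 2, background = 1000, noise_sd = 100)
#' nrow(find_maxima(st$image, 6000))
render_spot_image <- function(shape, n_spots, amplitude = 10000,
                              sigma_px = 2, background = 1000,
                              noise_sd = 0, border_margin_px = 8,
                              max_tries = 2000) {
  stopifnot(length(shape) == 2, all(shape >= 1))
  if (amplitude + background > 65535) {
    abort("amplitude + background exceeds the 16-bit range")
  }
  nr <- shape[1]; nc <- shape[2]
  min_sep2 <- (6 * sigma_px)^2
  rows <- integer(0); cols <- integer(0)
  lo_r <- 1 + border_margin_px; hi_r <- nr - border_margin_px
  lo_c <- 1 + border_margin_px; hi_c <- nc - border_margin_px
  if (n_spots > 0 && (lo_r > hi_r || lo_c > hi_c)) {
    abort("border margin leaves no room for spots")
  }
  tries <- 0
  while (length(rows) < n_spots) {
    if (tries >= max_tries) {
      abort("could not place spots with the required separation")
    }
    tries <- tries + 1
    r <- sample(lo_r:hi_r, 1); cc <- sample(lo_c:hi_c, 1)
    if (length(rows) == 0 ||
        all((rows - r)^2 + (cols - cc)^2 >= min_sep2)) {
      rows <- c(rows, r); cols <- c(cols, cc)
    }
  }
  img <- matrix(background, nr, nc)
  if (n_spots > 0) {
    ri <- matrix(seq_len(nr), nr, nc)
    ci <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    for (k in seq_len(n_spots)) {
      img <- img + amplitude *
        exp(-((ri - rows[k])^2 + (ci - cols[k])^2) / (2 * sigma_px^2))
    }
  }
  if (noise_sd > 0) img <- img + rnorm(nr * nc, sd = noise_sd)
  img <- matrix(as.integer(pmin(pmax(round(img), 0), 65535)), nr, nc)
  structure(
    list(image = img,
         centers = tibble(row = rows, col = cols),
         amplitude = amplitude, background = background,
         sigma_px = sigma_px, noise_sd = noise_sd),
    class = "spot_truth")
}
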