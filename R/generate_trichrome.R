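# Synthetic trichrome-like fields: a spatially smooth collagen/cytoplasm
# partition synthesized in optical-density space and converted to
# transmitted-light RGB, with the collagen mask as ground truth.

#' Generate a synthetic trichrome-stained field
#'
#' A smooth Gaussian random field is thresholded at the quantile matching
#' `collagen_fraction`, giving a spatially coherent collagen mask covering
#' that exact fraction of the tissue. Collagen pixels receive a high collagen
#' stain concentration and a low cytoplasm concentration (and conversely);
#' optional Gaussian concentration noise is added before conversion to RGB.
#' The RGB image is kept as floating point in [0, 255], so the
#' deconvolution round trip is exact when `noise_sd = 0`.
#'
#' @param collagen_fraction target collagen area fraction in [0, 1].
#' @param stain_od_matrix a `stain_model` (default [masson_stain_model()]).
#' @param size image dimensions `c(rows, cols)`.
#' @param collagen_od,cyto_od stain concentrations of the dominant stain in
#'   each compartment (OD units).
#' @param offdiag_od concentration of the minor stain in each compartment.
#' @param noise_sd Gaussian noise SD on concentrations (OD units).
#' @param smooth_sigma smoothing scale of the random field (px).
#' @param seed integer seed.
#' @return list with `rgb` (h x w x 3 double array, [0, 255]), `mask`
#'   (logical collagen mask), `concentrations` (h x w x 3 truth array) and
#'   `truth` (parameter record).
#' @export
generate_trichrome_image <- function(collagen_fraction,
                                     stain_od_matrix = masson_stain_model(),
                                     size = c(256L, 256L),
                                     collagen_od = 1.0, cyto_od = 0.8,
                                     offdiag_od = 0.05, noise_sd = 0,
                                     smooth_sigma = 8, seed = 1L) {
  stopifnot(collagen_fraction >= 0, collagen_fraction <= 1)
  model <- stain_model(stain_od_matrix)
  nr <- size[1]; nc <- size[2]
  withr::with_seed(mix_seed(seed, 401), {
    field <- matrix(stats::rnorm(nr * nc), nr, nc)
    brush_size <- min(2L * ceiling(3 * smooth_sigma) + 1L,
                      2L * ((min(nr, nc) - 1L) %/% 2L) + 1L)  # odd, fits field
    kern <- EBImage::makeBrush(brush_size, shape = "gaussian",
                               sigma = smooth_sigma)
    field <- as.matrix(EBImage::filter2(EBImage::Image(field), kern))
    mask <- if (collagen_fraction <= 0) {
      matrix(FALSE, nr, nc)
    } else if (collagen_fraction >= 1) {
      matrix(TRUE, nr, nc)
    } else {
      field >= stats::quantile(field, 1 - collagen_fraction, type = 7)
    }
    conc <- array(0, dim = c(nr, nc, 3))
    conc[, , 1] <- ifelse(mask, collagen_od, offdiag_od)
    conc[, , 2] <- ifelse(mask, offdiag_od, cyto_od)
    if (noise_sd > 0) {
      conc[, , 1:2] <- pmax(0, conc[, , 1:2] +
                              stats::rnorm(2 * nr * nc, 0, noise_sd))
    }
    rgb <- stains_to_rgb(conc, model)
    list(rgb = rgb, mask = mask, concentrations = conc,
         truth = list(collagen_fraction = collagen_fraction,
                      realized_fraction = mean(mask),
                      collagen_od = collagen_od, cyto_od = cyto_od,
                      noise_sd = noise_sd, seed = seed))
  })
}
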