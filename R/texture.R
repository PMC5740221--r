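#' Parameters for the synthetic intima texture
#'
#' The texture emulates the greyscale heterogeneity of a stained histology
#' image: a small number of latent tissue "modes" arranged in spatially
#' correlated patches, each with its own mean intensity, plus per-pixel noise.
#' It is the stand-in input for the intensity-based intima clustering stage.
#'
#' @param n_latent_modes number of latent intensity modes (>= 2 unless a
#'   degenerate single-mode texture is wanted for testing).
#' @param mode_mean_intensities strictly increasing mode means in `[0, 255]`.
#' @param mode_field_correlation_length correlation length of the latent
#'   patch fields (micrometres).
#' @param pixel_noise_sd standard deviation of additive pixel noise
#'   (intensity units).
#' @param seed integer seed.
#' @return an object of class `texture_params`.
#' @export
texture_params <- function(n_latent_modes = 4,
                           mode_mean_intensities = c(40, 100, 160, 220),
                           mode_field_correlation_length = 150,
                           pixel_noise_sd = 8,
                           seed = 1L) {
  if (length(mode_mean_intensities) != n_latent_modes)
    stop_param("mode_mean_intensities must have n_latent_modes entries")
  if (n_latent_modes > 1 && any(diff(mode_mean_intensities) <= 0))
    stop_param("mode_mean_intensities must be strictly increasing")
  if (any(mode_mean_intensities < 0 | mode_mean_intensities > 255))
    stop_param("mode means must lie in [0, 255]")
  if (mode_field_correlation_length <= 0)
    stop_param("mode_field_correlation_length must be positive")
  if (pixel_noise_sd < 0) stop_param("pixel_noise_sd must be >= 0")
  structure(list(n_latent_modes = as.integer(n_latent_modes),
                 mode_mean_intensities = mode_mean_intensities,
                 mode_field_correlation_length = mode_field_correlation_length,
                 pixel_noise_sd = pixel_noise_sd,
                 seed = as.integer(seed)),
            class = "texture_params")
}

#' Render a histology-like greyscale texture on the intima
#'
#' Draws one smoothed Gaussian random field per latent mode (white noise
#' blurred at the requested correlation length), labels each intima pixel by
#' the argmax field (a soft spatial tessellation into contiguous patches),
#' assigns the mode's mean intensity and adds independent pixel noise.
#' Intensities are clipped to `[0, 255]` and defined exactly on intima
#' pixels; all other pixels are NA.
#'
#' @param section a `plaque_section` from [generate_section()].
#' @param tex a [texture_params()] object.
#' @return the section with `intensity` filled in and the latent mode map
#'   stored as attribute `mode_map` of the intensity raster.
#' @export
render_intima_texture <- function(section, tex) {
  lab <- section$label_map
  mask <- lab == LBL_INTIMA
  n_in <- sum(mask)
  if (n_in == 0) stop_param("section has no intima pixels")
  if (n_in < tex$n_latent_modes)
    stop_param("fewer intima pixels (", n_in, ") than latent modes (",
               tex$n_latent_modes, ")")

  ps_um <- section$pixel_size_mm * 1000
  sigma_px <- tex$mode_field_correlation_length / ps_um
  nr <- nrow(lab); nc <- ncol(lab)

  set.seed(tex$seed)
  k <- tex$n_latent_modes
  if (k == 1L) {
    mode_map <- matrix(1L, nr, nc)
  } else {
    fields <- matrix(rnorm(nr * nc * k), nr * nc, k)
    for (m in seq_len(k)) {
      fields[, m] <- as.vector(blur_matrix(matrix(fields[, m], nr, nc),
                                           sigma_px))
    }
    mode_map <- matrix(max.col(fields, ties.method = "first"), nr, nc)
  }
  intensity <- matrix(NA_real_, nr, nc)
  base <- tex$mode_mean_intensities[mode_map[mask]]
  noise <- if (tex$pixel_noise_sd > 0) rnorm(n_in, 0, tex$pixel_noise_sd) else 0
  intensity[mask] <- pmin(255, pmax(0, base + noise))

  img <- raster_like(intensity, lab)
  mode_map[!mask] <- 0L
  attr(img, "mode_map") <- mode_map
  section$intensity <- img
  section$texture_params <- tex
  section
}
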