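#' Configuration of the stiffness sampling stage
#'
#' The intima clusters receive shear moduli drawn from the experimentally
#' reported local stiffness range of atherosclerotic intima, 1 to 149 kPa;
#' the homogeneous reference model uses the mean of that range, 75 kPa.
#'
#' @param n_samples number of Latin-hypercube stiffness combinations (study
#'   design: 100).
#' @param n_clusters number of intima clusters (4).
#' @param modulus_low,modulus_high bounds of the sampled shear modulus range
#'   (kPa); defaults 1 and 149.
#' @param homogeneous_modulus intima shear modulus of the homogeneous model
#'   (kPa); default 75.
#' @param smoothing_sigma Gaussian smoothing length for the modulus maps
#'   (micrometres); default 15 um (3 px at 5 um/px) — enough to remove
#'   single-pixel material transitions without erasing cluster structure.
#' @param wall_modulus,core_modulus,gel_modulus fixed shear moduli (kPa) of
#'   the vessel wall (200), lipid core (0.5) and surrounding gel (0.001).
#' @param seed integer seed for the LHS draw.
#' @return an object of class `sampling_config`.
#' @export
sampling_config <- function(n_samples = 100,
                            n_clusters = 4,
                            modulus_low = 1,
                            modulus_high = 149,
                            homogeneous_modulus = 75,
                            smoothing_sigma = 15,
                            wall_modulus = 200,
                            core_modulus = 0.5,
                            gel_modulus = 0.001,
                            seed = 1L) {
  if (!(modulus_low > 0 && modulus_low < modulus_high))
    stop_param("need 0 < modulus_low < modulus_high")
  if (homogeneous_modulus < modulus_low || homogeneous_modulus > modulus_high)
    stop_param("homogeneous_modulus must lie within [modulus_low, modulus_high]")
  if (smoothing_sigma < 0) stop_param("smoothing_sigma must be >= 0")
  if (n_samples < 1) stop_param("n_samples must be >= 1")
  structure(list(n_samples = as.integer(n_samples),
                 n_clusters = as.integer(n_clusters),
                 modulus_low = modulus_low,
                 modulus_high = modulus_high,
                 homogeneous_modulus = homogeneous_modulus,
                 smoothing_sigma = smoothing_sigma,
                 wall_modulus = wall_modulus,
                 core_modulus = core_modulus,
                 gel_modulus = gel_modulus,
                 seed = as.integer(seed)),
            class = "sampling_config")
}

#' Latin-hypercube sample of cluster shear moduli
#'
#' Stratified uniform sampling: per dimension the range
#' `[modulus_low, modulus_high]` is split into `n_samples` equal-width
#' strata, each containing exactly one sample (uniform jitter within the
#' stratum, independent random permutations across dimensions).
#'
#' @param cfg a [sampling_config()].
#' @return list of `stiffness_sample` objects, each with `cluster_moduli`
#'   (kPa, length `n_clusters`) and `sample_index`.
#' @export
latin_hypercube <- function(cfg) {
  set.seed(cfg$seed)
  u <- lhs::randomLHS(cfg$n_samples, cfg$n_clusters)
  vals <- cfg$modulus_low + u * (cfg$modulus_high - cfg$modulus_low)
  lapply(seq_len(cfg$n_samples), function(i) {
    structure(list(cluster_moduli = vals[i, ], sample_index = i),
              class = "stiffness_sample")
  })
}

#' Per-pixel shear modulus map for one stiffness sample
#'
#' Assigns each intima pixel the modulus of its cluster, then applies
#' mask-restricted renormalized Gaussian smoothing to avoid sharp material
#' transitions. Non-intima regions carry their fixed moduli unsmoothed:
#' wall, lipid core, and (as the raster background, standing for the
#' surrounding gel) the gel modulus; lumen pixels are NA.
#'
#' @param cmap a `cluster_map` covering the intima.
#' @param sample a `stiffness_sample`.
#' @param cfg a [sampling_config()].
#' @param section the `plaque_section` the cluster map belongs to.
#' @return an object of class `modulus_map` with `modulus_field` (kPa
#'   raster), `sample`, `config`.
#' @export
build_modulus_map <- function(cmap, sample, cfg, section) {
  lab <- section$label_map
  labels <- cmap$labels
  mask <- lab == LBL_INTIMA
  lv <- labels[mask]
  if (any(lv < 1 | lv > cfg$n_clusters))
    stop_param("cluster label outside 1..n_clusters found on the intima")
  mod <- matrix(NA_real_, nrow(lab), ncol(lab))
  mod[mask] <- sample$cluster_moduli[lv]
  sigma_px <- cfg$smoothing_sigma / (section$pixel_size_mm * 1000)
  mod <- masked_blur(mod, mask, sigma_px)
  mod[lab == LBL_WALL] <- cfg$wall_modulus
  mod[lab == LBL_CORE] <- cfg$core_modulus
  mod[lab == LBL_BACKGROUND] <- cfg$gel_modulus
  structure(list(modulus_field = raster_like(mod, lab),
                 sample = sample,
                 config = cfg),
            class = "modulus_map")
}

#' Homogeneous intima modulus map
#'
#' Constant intima modulus at `homogeneous_modulus` (75 kPa by default, the
#' midpoint/mean of the sampled range); other regions as in
#' [build_modulus_map()].
#'
#' @param section a `plaque_section`.
#' @param cfg a [sampling_config()].
#' @return a `modulus_map`.
#' @export
homogeneous_map <- function(section, cfg) {
  lab <- section$label_map
  mod <- matrix(NA_real_, nrow(lab), ncol(lab))
  mod[lab == LBL_INTIMA] <- cfg$homogeneous_modulus
  mod[lab == LBL_WALL] <- cfg$wall_modulus
  mod[lab == LBL_CORE] <- cfg$core_modulus
  mod[lab == LBL_BACKGROUND] <- cfg$gel_modulus
  structure(list(modulus_field = raster_like(mod, lab),
                 sample = structure(list(
                   cluster_moduli = rep(cfg$homogeneous_modulus,
                                        cfg$n_clusters),
                   sample_index = 0L), class = "stiffness_sample"),
                 config = cfg),
            class = "modulus_map")
}
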