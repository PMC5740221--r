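#' plaqhet: peak cap stress with heterogeneous intima
#'
#' Pipeline for studying how intima stiffness heterogeneity changes the peak
#' cap stress (PCS) of atherosclerotic plaque cross-sections: synthetic
#' histology-like sections, intensity-based intima clustering, Latin-hypercube
#' stiffness sampling, a plane-strain neo-Hookean finite-element solver with
#' initial stresses, and polynomial-chaos Sobol sensitivity analysis.
#'
#' @keywords internal
#' @aliases plaqhet-package
"_PACKAGE"

#' @importFrom stats rnorm runif quantile var coef lm cor median sd
#' @importFrom utils head tail write.csv
NULL

## kPa per mmHg, used everywhere pressures cross the interface
MMHG_TO_KPA <- 0.133322

#' Convert pressure from mmHg to kPa
#'
#' @param p_mmHg pressure in mmHg.
#' @return pressure in kPa (1 mmHg = 0.133322 kPa).
#' @export
mmHg_to_kPa <- function(p_mmHg) p_mmHg * MMHG_TO_KPA

#' Derive a reproducible child seed
#'
#' Deterministically hashes a master seed together with string/integer tags
#' (e.g. plaque id and pipeline stage) into a 31-bit seed, so that each stage
#' of a study is independently reproducible from the master seed.
#'
#' @param master_seed integer master seed.
#' @param ... tags (character or numeric) identifying the consumer.
#' @return a single integer in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(master_seed, ...) {
  tags <- paste(c(master_seed, ...), collapse = "|")
  bytes <- utf8ToInt(tags)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}

stop_param <- function(...) {
  stop(paste0(...), call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @useDynLib plaqhet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL
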