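#' Study design: plaques, samples, shared configurations
#'
#' @param plaque_params named list of [section_params()] (names are the
#'   plaque ids). Default: [default_plaque_set()] with 12 plaques.
#' @param n_heterogeneous_samples heterogeneous stiffness combinations per
#'   plaque (study design: 100).
#' @param sampling a [sampling_config()] (seed is re-derived per plaque).
#' @param texture a [texture_params()] template (seed re-derived per plaque).
#' @param clustering a [cluster_config()] template.
#' @param protocol a [loading_protocol()].
#' @param gpce a [gpce_config()].
#' @param target_edge_length FE mesh resolution (mm).
#' @param master_seed master seed; all per-plaque, per-stage seeds are
#'   hashed from it with [derive_seed()].
#' @return object of class `study_design`.
#' @export
study_design <- function(plaque_params = default_plaque_set(),
                         n_heterogeneous_samples = 100,
                         sampling = sampling_config(),
                         texture = texture_params(),
                         clustering = cluster_config(),
                         protocol = loading_protocol(),
                         gpce = gpce_config(),
                         target_edge_length = 0.025,
                         master_seed = 1L) {
  ids <- names(plaque_params)
  if (is.null(ids) || anyDuplicated(ids))
    stop_param("plaque_params must be a named list with unique names")
  sampling$n_samples <- as.integer(n_heterogeneous_samples)
  structure(list(plaque_ids = ids,
                 plaque_params = plaque_params,
                 n_heterogeneous_samples = as.integer(n_heterogeneous_samples),
                 sampling = sampling, texture = texture,
                 clustering = clustering, protocol = protocol,
                 gpce = gpce,
                 target_edge_length = target_edge_length,
                 master_seed = as.integer(master_seed)),
            class = "study_design")
}

#' Default synthetic plaque set
#'
#' Twelve synthetic coronary cross-sections spanning cap thickness from
#' 400 um down to 50 um with varying eccentricity and core size, loosely
#' emulating an advanced-plaque histology series.
#'
#' @param n number of plaques (default 12).
#' @param cap_range cap thickness range swept, mm (thick to thin).
#' @param image_resolution um/px for the rendered sections.
#' @return named list of [section_params()].
#' @export
default_plaque_set <- function(n = 12, cap_range = c(0.40, 0.05),
                               image_resolution = 5) {
  caps <- seq(cap_range[1], cap_range[2], length.out = n)
  spans <- rep(c(100, 120, 140), length.out = n)
  offs <- rep(c(0.40, 0.45, 0.50, 0.42), length.out = n)
  cores <- rep(c(0.40, 0.45, 0.35), length.out = n)
  out <- lapply(seq_len(n), function(i) {
    section_params(cap_thickness = caps[i],
                   core_angular_span = spans[i],
                   lumen_offset = offs[i],
                   core_max_thickness = cores[i],
                   image_resolution = image_resolution,
                   seed = i)
  })
  names(out) <- sprintf("plaque%02d", seq_len(n))
  out
}

#' Enumerate the simulation jobs of a study
#'
#' One homogeneous job (sample index 0) plus `n_heterogeneous_samples`
#' heterogeneous jobs per plaque; 12 plaques x (1 + 100) gives the 1212-run
#' design.
#'
#' @param design a [study_design()].
#' @return data frame with `plaque_id`, `sample_index` (0 = homogeneous),
#'   `seed`.
#' @export
enumerate_jobs <- function(design) {
  rows <- lapply(design$plaque_ids, function(id) {
    idx <- 0:design$n_heterogeneous_samples
    data.frame(plaque_id = id, sample_index = idx,
               seed = vapply(idx, function(i)
                 derive_seed(design$master_seed, id, "solve", i), numeric(1)))
  })
  do.call(rbind, rows)
}

#' Summary statistics of one plaque's PCS distribution
#'
#' Median and quartiles use the linear-interpolation convention
#' (`stats::quantile` type 7).
#'
#' @param pcs_values heterogeneous-model PCS values (kPa).
#' @param homogeneous_pcs homogeneous-model PCS (kPa).
#' @param sens optional `sensitivity_result` for the plaque.
#' @return object of class `plaque_summary`.
#' @export
summarize_plaque <- function(pcs_values, homogeneous_pcs, sens = NULL) {
  pcs_values <- pcs_values[is.finite(pcs_values)]
  if (length(pcs_values) < 1)
    stop_param("no heterogeneous PCS values to summarize")
  q <- unname(quantile(pcs_values, c(0.25, 0.5, 0.75), type = 7))
  hi <- if (!is.null(sens) && !sens$degenerate) {
    k <- which.max(sens$main_indices)
    c(index = sens$main_indices[k], cluster = k)
  } else c(index = NA_real_, cluster = NA_real_)
  structure(list(pcs_homogeneous = homogeneous_pcs,
                 pcs_median = q[2], pcs_iqr_low = q[1], pcs_iqr_high = q[3],
                 pcs_min = min(pcs_values), pcs_max = max(pcs_values),
                 pcs_range = max(pcs_values) - min(pcs_values),
                 highest_main_index = unname(hi["index"]),
                 highest_main_cluster = unname(hi["cluster"]),
                 n_values = length(pcs_values)),
            class = "plaque_summary")
}

#' Regression of heterogeneous PCS range on homogeneous PCS
#'
#' Ordinary least squares of per-plaque PCS range against the homogeneous
#' model PCS; R^2 is the squared Pearson correlation.
#'
#' @param summaries list of `plaque_summary` objects (>= 3).
#' @return list with `slope`, `intercept`, `r_squared`, and `defined`
#'   (FALSE when either variable has zero variance).
#' @export
correlate_homogeneous_vs_range <- function(summaries) {
  x <- vapply(summaries, function(s) s$pcs_homogeneous, numeric(1))
  y <- vapply(summaries, function(s) s$pcs_range, numeric(1))
  if (length(x) < 3) stop_param("need at least 3 plaques")
  if (var(x) == 0 || var(y) == 0) {
    return(list(slope = NA_real_, intercept = NA_real_,
                r_squared = NA_real_, defined = FALSE))
  }
  fit <- lm(y ~ x)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = cor(x, y)^2, defined = TRUE)
}

## run every stage for one plaque; returns PCS table + sensitivity
run_plaque <- function(design, id) {
  p <- design$plaque_params[[id]]
  section <- generate_section(p)
  tex <- design$texture
  tex$seed <- derive_seed(design$master_seed, id, "texture")
  section <- render_intima_texture(section, tex)
  ccfg <- design$clustering
  ccfg$seed <- derive_seed(design$master_seed, id, "cluster")
  cmap <- clean_clusters(kmeans_intensity(section, ccfg), ccfg)
  scfg <- design$sampling
  scfg$seed <- derive_seed(design$master_seed, id, "lhs")
  samples <- latin_hypercube(scfg)

  mmap_hom <- homogeneous_map(section, scfg)
  mesh <- mesh_section(section, mmap_hom, design$target_edge_length)
  pre <- fe_precompute(mesh)
  cap <- identify_cap(section, mesh)

  solve_one <- function(mmap) {
    # refresh element moduli for this sample on the shared mesh
    m2 <- mesh_moduli_update(mesh, mmap, section)
    pre2 <- fe_precompute(m2)
    sol <- solve_inflation(pre2, design$protocol)
    if (!isTRUE(sol$converged)) return(NA_real_)
    extract_pcs(sol, cap)$pcs_kPa
  }

  pcs_hom <- solve_one(mmap_hom)
  pcs_het <- vapply(samples, function(s) {
    solve_one(build_modulus_map(cmap, s, scfg, section))
  }, numeric(1))

  n_failed <- sum(!is.finite(pcs_het))
  if (n_failed > 0.2 * length(pcs_het))
    warning("plaque ", id, ": ", n_failed, " of ", length(pcs_het),
            " heterogeneous solves failed; summaries skipped")
  smp_mat <- do.call(rbind, lapply(samples, function(s) s$cluster_moduli))
  ok <- is.finite(pcs_het)
  sens <- if (sum(ok) > 8 && var(pcs_het[ok]) > 0) {
    gcfg <- design$gpce
    gcfg$input_low <- rep(scfg$modulus_low, gcfg$input_dimension)
    gcfg$input_high <- rep(scfg$modulus_high, gcfg$input_dimension)
    sobol_indices(fit_gpce(smp_mat[ok, , drop = FALSE], pcs_het[ok], gcfg))
  } else NULL

  list(id = id,
       pcs_table = data.frame(plaque_id = id,
                              sample_index = 0:length(samples),
                              C1 = c(NA, smp_mat[, 1]),
                              C2 = c(NA, smp_mat[, 2]),
                              C3 = c(NA, smp_mat[, 3]),
                              C4 = c(NA, smp_mat[, 4]),
                              pcs_kPa = c(pcs_hom, pcs_het)),
       summary = if (n_failed <= 0.2 * length(pcs_het))
         summarize_plaque(pcs_het, pcs_hom, sens) else NULL,
       sensitivity = sens,
       n_failed_solves = n_failed,
       min_cap_thickness_um = cap$min_cap_thickness_um)
}

#' Run the full heterogeneous-intima stress study
#'
#' For each plaque: generate the section and texture, cluster the intima,
#' draw the stiffness samples, run the homogeneous and all heterogeneous FE
#' solves, extract PCS, fit the gPCE metamodel and compute Sobol indices;
#' then assemble per-plaque summaries and the homogeneous-PCS vs PCS-range
#' regression. Fully reproducible from the master seed.
#'
#' @param design a [study_design()].
#' @param verbose print per-plaque progress.
#' @return object of class `study_result`: `pcs` (tidy per-solve table),
#'   `summaries` (per-plaque), `sensitivity` (per-plaque indices),
#'   `correlation` (range vs homogeneous PCS), `design`.
#' @export
run_study <- function(design, verbose = interactive()) {
  res <- lapply(design$plaque_ids, function(id) {
    if (verbose) message("solving ", id, " ...")
    run_plaque(design, id)
  })
  names(res) <- design$plaque_ids
  pcs <- do.call(rbind, lapply(res, `[[`, "pcs_table"))
  rownames(pcs) <- NULL
  summaries <- Filter(Negate(is.null), lapply(res, `[[`, "summary"))
  sens_tab <- do.call(rbind, lapply(res, function(r) {
    if (is.null(r$sensitivity)) return(NULL)
    s <- r$sensitivity
    data.frame(plaque_id = r$id,
               S1 = s$main_indices[1], S2 = s$main_indices[2],
               S3 = s$main_indices[3], S4 = s$main_indices[4],
               interaction_total = s$interaction_total,
               total_variance = s$total_variance)
  }))
  summary_tab <- do.call(rbind, lapply(names(summaries), function(id) {
    s <- summaries[[id]]
    data.frame(plaque_id = id,
               pcs_homogeneous = s$pcs_homogeneous,
               pcs_median = s$pcs_median,
               pcs_iqr_low = s$pcs_iqr_low, pcs_iqr_high = s$pcs_iqr_high,
               pcs_min = s$pcs_min, pcs_max = s$pcs_max,
               pcs_range = s$pcs_range,
               highest_main_index = s$highest_main_index,
               highest_main_cluster = s$highest_main_cluster,
               n_failed_solves = res[[id]]$n_failed_solves,
               min_cap_thickness_um = res[[id]]$min_cap_thickness_um)
  }))
  correlation <- if (length(summaries) >= 3)
    correlate_homogeneous_vs_range(summaries) else NULL
  structure(list(pcs = pcs, summaries = summaries,
                 summary_table = summary_tab,
                 sensitivity = sens_tab,
                 correlation = correlation,
                 design = design),
            class = "study_result")
}

#' @export
print.study_result <- function(x, ...) {
  cat("study_result:", length(x$design$plaque_ids), "plaques,",
      x$design$n_heterogeneous_samples, "heterogeneous samples each\n")
  if (!is.null(x$summary_table)) print(x$summary_table, digits = 3)
  if (!is.null(x$correlation) && isTRUE(x$correlation$defined))
    cat(sprintf("PCS range vs homogeneous PCS: R^2 = %.3f\n",
                x$correlation$r_squared))
  invisible(x)
}

#' Replace element moduli of an existing mesh from a new modulus map
#'
#' The mesh geometry depends only on the section, so all stiffness samples
#' of a plaque share one mesh; only element moduli change.
#'
#' @param mesh a `plaque_mesh`.
#' @param mmap the new `modulus_map`.
#' @param section the section the mesh was built from.
#' @return the mesh with updated `C`.
#' @export
mesh_moduli_update <- function(mesh, mmap, section) {
  cx <- mesh$centroids[, 1]; cy <- mesh$centroids[, 2]
  cfg <- mmap$config
  Cmod <- raster_at(mmap$modulus_field, cx, cy)
  Cmod[mesh$region == "gel"] <- cfg$gel_modulus
  Cmod[mesh$region == "wall" & is.na(Cmod)] <- cfg$wall_modulus
  Cmod[mesh$region == "core" & is.na(Cmod)] <- cfg$core_modulus
  fix <- which(is.na(Cmod))
  if (length(fix)) {
    lcx <- lumen_center_x(section$params)
    ps <- section$pixel_size_mm
    for (e in fix) {
      rr <- sqrt((cx[e] - lcx)^2 + cy[e]^2)
      ux <- (cx[e] - lcx) / rr; uy <- cy[e] / rr
      for (step in 1:5) {
        v <- raster_at(mmap$modulus_field, cx[e] + step * ps * ux,
                       cy[e] + step * ps * uy)
        if (!is.na(v)) { Cmod[e] <- v; break }
      }
      if (is.na(Cmod[e])) Cmod[e] <- cfg$homogeneous_modulus
    }
  }
  mesh$C <- Cmod
  mesh
}
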