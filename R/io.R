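## File interfaces: rasters as single-channel TIFF with JSON sidecars,
## meshes/solutions as Gmsh MSH 2.2 and legacy VTK ASCII.

raster_sidecar <- function(raster, extra = list()) {
  c(list(pixel_size_mm = attr(raster, "pixel_size_mm"),
         x0 = attr(raster, "x0"), y0 = attr(raster, "y0"),
         nrow = nrow(raster), ncol = ncol(raster)),
    extra)
}

#' Write a plaque section to a directory
#'
#' Label map as 8-bit TIFF, intensity image (if present) as 8-bit TIFF,
#' contours as JSON polygon vertex lists (mm), and a JSON sidecar with the
#' pixel size, physical origin and generator parameters.
#'
#' @param section a `plaque_section`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_section <- function(section, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tiff::writeTIFF(section$label_map / 255, file.path(dir, "labels.tif"),
                  bits.per.sample = 8)
  if (!is.null(section$intensity)) {
    img <- section$intensity
    img[is.na(img)] <- 0
    tiff::writeTIFF(round(img) / 255, file.path(dir, "intensity.tif"),
                    bits.per.sample = 8)
  }
  jsonlite::write_json(
    lapply(section$contours, function(m)
      list(x = m[, 1], y = m[, 2])),
    file.path(dir, "contours.json"), digits = NA, auto_unbox = TRUE)
  jsonlite::write_json(
    raster_sidecar(section$label_map,
                   list(params = unclass(section$params),
                        has_intensity = !is.null(section$intensity))),
    file.path(dir, "section.json"), digits = NA, auto_unbox = TRUE)
  invisible(dir)
}

#' Read a plaque section written by [write_section()]
#'
#' @param dir directory.
#' @return a `plaque_section`.
#' @export
read_section <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "section.json"),
                              simplifyVector = TRUE)
  lab <- round(tiff::readTIFF(file.path(dir, "labels.tif")) * 255)
  storage.mode(lab) <- "integer"
  lab <- new_raster(lab, meta$pixel_size_mm, meta$x0, meta$y0)
  params <- meta$params
  class(params) <- "section_params"
  cont <- jsonlite::read_json(file.path(dir, "contours.json"),
                              simplifyVector = TRUE)
  contours <- lapply(cont, function(p) cbind(x = p$x, y = p$y))
  intensity <- NULL
  if (isTRUE(meta$has_intensity)) {
    img <- tiff::readTIFF(file.path(dir, "intensity.tif")) * 255
    img[lab != LBL_INTIMA] <- NA_real_
    intensity <- raster_like(img, lab)
  }
  structure(list(label_map = lab, intensity = intensity,
                 pixel_size_mm = meta$pixel_size_mm,
                 contours = contours, params = params),
            class = "plaque_section")
}

#' Write a cluster map (TIFF + JSON sidecar)
#'
#' @param cmap a `cluster_map`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_cluster_map <- function(cmap, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tiff::writeTIFF(cmap$labels / 255, file.path(dir, "clusters.tif"),
                  bits.per.sample = 8)
  jsonlite::write_json(
    raster_sidecar(cmap$labels,
                   list(cluster_mean_intensity = cmap$cluster_mean_intensity,
                        iterations_used = cmap$iterations_used,
                        fixed_point = cmap$fixed_point,
                        wcss = cmap$wcss,
                        config = unclass(cmap$config))),
    file.path(dir, "clusters.json"), digits = NA, auto_unbox = TRUE)
  invisible(dir)
}

#' Write a modulus map (scaled 32-bit TIFF + JSON sidecar)
#'
#' TIFF sample values are stored on `[0, 1]`; the map is divided by its
#' maximum (kPa) which is recorded as `scale_kPa` in the sidecar, so
#' `pixel * scale_kPa` restores moduli (32-bit quantization, i.e. ~1e-9
#' relative).
#'
#' @param mmap a `modulus_map`.
#' @param dir output directory.
#' @param name basename for the pair of files.
#' @return `dir`, invisibly.
#' @export
write_modulus_map <- function(mmap, dir, name = "modulus") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- mmap$modulus_field
  m[is.na(m)] <- 0
  scale <- max(m)
  tiff::writeTIFF(m / scale, file.path(dir, paste0(name, ".tif")),
                  bits.per.sample = 32, reduce = FALSE)
  jsonlite::write_json(
    raster_sidecar(mmap$modulus_field,
                   list(scale_kPa = scale,
                        sample_index = mmap$sample$sample_index,
                        cluster_moduli = mmap$sample$cluster_moduli,
                        config = unclass(mmap$config))),
    file.path(dir, paste0(name, ".json")), digits = NA, auto_unbox = TRUE)
  invisible(dir)
}

#' Read a modulus map written by [write_modulus_map()]
#'
#' @param dir directory.
#' @param name basename used at write time.
#' @return list with `modulus_field` (kPa raster; zero-valued pixels are
#'   restored to NA), `sample_index`, `cluster_moduli`.
#' @export
read_modulus_map <- function(dir, name = "modulus") {
  side <- jsonlite::read_json(file.path(dir, paste0(name, ".json")),
                              simplifyVector = TRUE)
  m <- tiff::readTIFF(file.path(dir, paste0(name, ".tif"))) * side$scale_kPa
  m[m == 0] <- NA_real_
  list(modulus_field = new_raster(m, side$pixel_size_mm, side$x0, side$y0),
       sample_index = side$sample_index,
       cluster_moduli = side$cluster_moduli)
}

#' Export a mesh (plus optional element fields) as legacy VTK ASCII
#'
#' @param mesh a `plaque_mesh`.
#' @param file output path.
#' @param cell_data named list of per-element numeric vectors.
#' @return `file`, invisibly.
#' @export
write_mesh_vtk <- function(mesh, file, cell_data = list()) {
  con <- file(file, "w")
  on.exit(close(con))
  n <- nrow(mesh$nodes); e <- nrow(mesh$elems)
  writeLines(c("# vtk DataFile Version 3.0", "plaqhet mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               paste("POINTS", n, "double")), con)
  writeLines(paste(mesh$nodes[, 1], mesh$nodes[, 2], 0), con)
  writeLines(paste("CELLS", e, 5 * e), con)
  writeLines(paste(4, mesh$elems[, 1] - 1, mesh$elems[, 2] - 1,
                   mesh$elems[, 3] - 1, mesh$elems[, 4] - 1), con)
  writeLines(paste("CELL_TYPES", e), con)
  writeLines(as.character(rep(9L, e)), con)
  cell_data <- c(list(shear_modulus_kPa = mesh$C), cell_data)
  writeLines(paste("CELL_DATA", e), con)
  for (nm in names(cell_data)) {
    writeLines(c(paste("SCALARS", nm, "double", 1), "LOOKUP_TABLE default"),
               con)
    writeLines(as.character(cell_data[[nm]]), con)
  }
  invisible(file)
}

#' Export a mesh in Gmsh MSH 2.2 ASCII format
#'
#' Region tags become physical groups 1 = wall, 2 = intima, 3 = core,
#' 4 = gel.
#'
#' @param mesh a `plaque_mesh`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_mesh_msh <- function(mesh, file) {
  con <- file(file, "w")
  on.exit(close(con))
  tags <- c(wall = 1L, intima = 2L, core = 3L, gel = 4L)[mesh$region]
  n <- nrow(mesh$nodes); e <- nrow(mesh$elems)
  writeLines(c("$MeshFormat", "2.2 0 8", "$EndMeshFormat", "$Nodes",
               as.character(n)), con)
  writeLines(paste(seq_len(n), mesh$nodes[, 1], mesh$nodes[, 2], 0), con)
  writeLines(c("$EndNodes", "$Elements", as.character(e)), con)
  writeLines(paste(seq_len(e), 3, 2, tags, tags,
                   mesh$elems[, 1], mesh$elems[, 2], mesh$elems[, 3],
                   mesh$elems[, 4]), con)
  writeLines("$EndElements", con)
  invisible(file)
}

#' Export an FE solution as legacy VTK (deformed fields on the mesh)
#'
#' Writes nodal displacement and element fields: maximum principal Cauchy
#' stress at the final pressure, det F, and shear modulus.
#'
#' @param sol a converged `fe_solution`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_solution_vtk <- function(sol, file) {
  mesh <- sol$model$mesh
  con <- file(file, "w")
  n <- nrow(mesh$nodes); e <- nrow(mesh$elems)
  writeLines(c("# vtk DataFile Version 3.0", "plaqhet solution", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               paste("POINTS", n, "double")), con)
  writeLines(paste(mesh$nodes[, 1], mesh$nodes[, 2], 0), con)
  writeLines(paste("CELLS", e, 5 * e), con)
  writeLines(paste(4, mesh$elems[, 1] - 1, mesh$elems[, 2] - 1,
                   mesh$elems[, 3] - 1, mesh$elems[, 4] - 1), con)
  writeLines(paste("CELL_TYPES", e), con)
  writeLines(as.character(rep(9L, e)), con)
  writeLines(c(paste("POINT_DATA", n),
               "VECTORS displacement double"), con)
  ux <- sol$u_final[seq(1, 2 * n, 2)]; uy <- sol$u_final[seq(2, 2 * n, 2)]
  writeLines(paste(ux, uy, 0), con)
  writeLines(paste("CELL_DATA", e), con)
  fields <- list(max_principal_stress_kPa = sol$stress_final$max_principal,
                 detF = sol$stress_final$detF,
                 shear_modulus_kPa = mesh$C)
  for (nm in names(fields)) {
    writeLines(c(paste("SCALARS", nm, "double", 1), "LOOKUP_TABLE default"),
               con)
    writeLines(as.character(fields[[nm]]), con)
  }
  close(con)
  invisible(file)
}
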