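# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- build()
  .fixture_cache[[name]]
}

# small, quick section: 20 um/px so rasters stay ~200 px across
small_params <- function(...) {
  section_params(image_resolution = 20, ...)
}

small_textured_section <- function() {
  fixture("small_textured", function() {
    s <- generate_section(small_params())
    render_intima_texture(s, texture_params(seed = 7L))
  })
}

# coarse solvable plaque: section + homogeneous map + mesh + cap
coarse_plaque <- function() {
  fixture("coarse_plaque", function() {
    s <- generate_section(section_params(image_resolution = 10))
    s <- render_intima_texture(s, texture_params(seed = 11L))
    scfg <- sampling_config()
    mh <- homogeneous_map(s, scfg)
    mesh <- mesh_section(s, mh, target_edge_length = 0.12)
    list(section = s, sampling = scfg, map_hom = mh, mesh = mesh,
         cap = identify_cap(s, mesh))
  })
}

# minimal hand-built section: every pixel of `values` is intima with the
# given intensity (NA = background)
pixel_section <- function(values, pixel_size_mm = 0.005) {
  values <- as.matrix(values)
  lab <- matrix(0L, nrow(values), ncol(values))
  lab[!is.na(values)] <- 2L
  mk <- function(m) {
    attr(m, "pixel_size_mm") <- pixel_size_mm
    attr(m, "x0") <- 0; attr(m, "y0") <- 0
    m
  }
  structure(list(label_map = mk(lab), intensity = mk(values),
                 pixel_size_mm = pixel_size_mm,
                 contours = list(), params = NULL),
            class = "plaque_section")
}

coarse_homogeneous_solution <- function() {
  fixture("coarse_hom_sol", function() {
    cp <- coarse_plaque()
    solve_inflation(cp$mesh, loading_protocol())
  })
}
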