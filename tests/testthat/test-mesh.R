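test_that("plaque meshes are structurally sound", {
  cp <- coarse_plaque()
  mesh <- cp$mesh
  q <- mesh_quality(mesh)
  expect_gt(q$min_angle_deg, 15)
  expect_gt(q$min_area, 0)
  expect_setequal(unique(mesh$region), c("intima", "wall", "core", "gel"))
  # lumen edge set forms one closed loop
  ed <- mesh$lumen_edges
  expect_equal(sort(ed[, 1]), sort(ed[, 2]))
  # encastred dofs sit on the gel outer circle
  fixed_nodes <- unique(ceiling(mesh$fixed_dofs / 2))
  r <- sqrt(rowSums(mesh$nodes[fixed_nodes, ]^2))
  expect_equal(r, rep(mesh$gel_outer_radius, length(r)), tolerance = 1e-9)
  expect_equal(mesh$gel_outer_radius, 2.5 * cp$section$params$outer_wall_radius)
})

test_that("element moduli reflect the modulus map regionwise", {
  cp <- coarse_plaque()
  mesh <- cp$mesh
  expect_true(all(mesh$C[mesh$region == "wall"] == 200))
  expect_true(all(mesh$C[mesh$region == "core"] == 0.5))
  expect_true(all(mesh$C[mesh$region == "gel"] == 0.001))
  expect_true(all(mesh$C[mesh$region == "intima"] == 75))
})

test_that("halving the edge length multiplies element count by about 4", {
  cp <- coarse_plaque()
  m1 <- mesh_section(cp$section, cp$map_hom, target_edge_length = 0.16)
  m2 <- mesh_section(cp$section, cp$map_hom, target_edge_length = 0.08)
  ratio <- nrow(m2$elems) / nrow(m1$elems)
  expect_gt(ratio, 4 * 0.7)
  expect_lt(ratio, 4 * 1.3)
})

test_that("default resolution yields 10k-30k tissue elements", {
  s <- generate_section(section_params())
  mm <- homogeneous_map(s, sampling_config())
  mesh <- mesh_section(s, mm)
  n_tissue <- sum(mesh$region != "gel")
  expect_gte(n_tissue, 10000)
  expect_lte(n_tissue, 30000)
  expect_gt(mesh_quality(mesh)$min_angle_deg, 15)
})

test_that("cap identification respects span, margin and thickness", {
  cp <- coarse_plaque()
  cap0 <- identify_cap(cp$section, cp$mesh, shoulder_margin_deg = 0)
  cap10 <- identify_cap(cp$section, cp$mesh, shoulder_margin_deg = 10)
  expect_true(all(cap0$elements %in% cap10$elements))
  expect_true(all(cp$mesh$region[cap10$elements] == "intima"))
  expect_equal(cap10$min_cap_thickness_um, 200, tolerance = 0.01)
  # cap centroids lie between lumen and core inner boundary
  p <- cp$section$params
  cen <- cp$mesh$centroids[cap0$elements, , drop = FALSE]
  rho <- sqrt((cen[, 1] + p$lumen_offset)^2 + cen[, 2]^2)
  expect_true(all(rho > p$lumen_radius - 1e-9))
  expect_true(all(rho < p$lumen_radius + p$cap_thickness + 1e-9))
})

test_that("a 35 um cap is measured in the 30-40 um band", {
  s <- generate_section(section_params(cap_thickness = 0.035,
                                       image_resolution = 5))
  mm <- homogeneous_map(s, sampling_config())
  mesh <- mesh_section(s, mm, target_edge_length = 0.12)
  cap <- identify_cap(s, mesh)
  expect_gte(cap$min_cap_thickness_um, 30)
  expect_lte(cap$min_cap_thickness_um, 40)
  expect_gt(length(cap$elements), 0)
})

test_that("a near-circumferential core yields a cap ring around the lumen", {
  s <- generate_section(section_params(lumen_offset = 0.05,
                                       core_angular_span = 360,
                                       core_max_thickness = 0.25,
                                       cap_thickness = 0.15,
                                       image_resolution = 20))
  mm <- homogeneous_map(s, sampling_config())
  mesh <- mesh_section(s, mm, target_edge_length = 0.15)
  cap <- identify_cap(s, mesh, shoulder_margin_deg = 0)
  phi <- atan2(mesh$centroids[cap$elements, 2],
               mesh$centroids[cap$elements, 1] + 0.05)
  # cap elements in all four quadrants
  expect_equal(length(unique(floor((phi + pi) / (pi / 2)))) >= 4, TRUE)
})

test_that("sections without core refuse cap identification", {
  s <- generate_section(small_params(core_angular_span = 0))
  mm <- homogeneous_map(s, sampling_config())
  mesh <- mesh_section(s, mm, target_edge_length = 0.15)
  expect_error(identify_cap(s, mesh), "whole-intima")
})

test_that("mesh exports are written in valid envelope formats", {
  cp <- coarse_plaque()
  tmp <- withr::local_tempdir()
  vtk <- file.path(tmp, "mesh.vtk")
  msh <- file.path(tmp, "mesh.msh")
  write_mesh_vtk(cp$mesh, vtk)
  write_mesh_msh(cp$mesh, msh)
  lv <- readLines(vtk)
  expect_equal(lv[1], "# vtk DataFile Version 3.0")
  expect_true(any(grepl("^CELLS", lv)))
  lm <- readLines(msh)
  expect_equal(lm[1], "$MeshFormat")
  expect_equal(sum(lm == "$EndElements"), 1)
})
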