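test_that("zero pressure produces zero displacement and stress", {
  mesh <- mesh_annulus(1, 2, 75, n_rays = 16, n_layers = 4)
  sol <- solve_inflation(mesh, loading_protocol(image_pressure = 0,
                                                final_pressure = 0))
  expect_true(sol$converged)
  expect_equal(max(abs(sol$u_final)), 0)
  expect_lt(max(abs(sol$stress_final$max_principal)), 1e-12)
  expect_equal(sol$stress_final$detF, rep(1, nrow(mesh$elems)))
})

test_that("cylinder inflation matches the radial ODE oracle within 1%", {
  A <- 1; B <- 2; C <- 75
  mesh <- mesh_annulus(A, B, C, n_rays = 64, n_layers = 16)
  pre <- fe_precompute(mesh)
  for (P in c(5, 10)) {
    r <- plaqhet:::ramp_pressure(pre, plaqhet:::fp_identity(pre),
                                 numeric(pre$ndof), 0, P, 5)
    expect_true(r$converged)
    n1 <- mesh$lumen_edges[, 1]
    a_fe <- mean(sqrt((mesh$nodes[n1, 1] + r$u[2 * n1 - 1])^2 +
                        (mesh$nodes[n1, 2] + r$u[2 * n1])^2))
    a_oracle <- oracle_cylinder_radius(P, A, B, C)
    expect_lt(abs(a_fe / a_oracle - 1), 0.01, label = paste("P =", P))
  }
})

test_that("small-load hoop stress matches the Lame solution within 2%", {
  A <- 1; B <- 2; C <- 75; P <- 0.1
  mesh <- mesh_annulus(A, B, C, n_rays = 64, n_layers = 16)
  pre <- fe_precompute(mesh)
  r <- plaqhet:::ramp_pressure(pre, plaqhet:::fp_identity(pre),
                               numeric(pre$ndof), 0, P, 1)
  expect_true(r$converged)
  st <- plaqhet:::element_stress(pre, plaqhet:::fp_identity(pre), r$u)
  rad <- sqrt(rowSums(mesh$centroids^2))
  inner <- which(rad < min(rad) + 1e-9)
  th <- atan2(mesh$centroids[inner, 2], mesh$centroids[inner, 1])
  hoop <- st$sxx[inner] * sin(th)^2 - 2 * st$sxy[inner] * sin(th) * cos(th) +
    st$syy[inner] * cos(th)^2
  lame <- oracle_lame_hoop(P, A, B, rad[inner])
  expect_lt(max(abs(hoop / lame - 1)), 0.02)
})

test_that("near-incompressibility holds: det F within 1% for tissue", {
  sol <- coarse_homogeneous_solution()
  cp <- coarse_plaque()
  expect_true(sol$converged)
  tissue <- cp$mesh$region != "gel"
  expect_true(all(sol$stress_final$detF[tissue] >= 0.99))
  expect_true(all(sol$stress_final$detF[tissue] <= 1.01))
  # stress tensors are symmetric by construction; principal ordering holds
  expect_true(all(sol$stress_final$max_principal >=
                    sol$stress_final$min_principal))
})

test_that("initial-stress state reproduces the imaged geometry", {
  sol <- coarse_homogeneous_solution()
  cp <- coarse_plaque()
  expect_true(sol$converged)
  expect_lt(sol$geometry_error_mm,
            1e-3 * cp$section$params$lumen_radius)
})

test_that("lumen area grows monotonically with pressure", {
  sol <- coarse_homogeneous_solution()
  expect_gte(sol$lumen_area_final, sol$lumen_area_image)
})

test_that("the gel surround provides only weak support", {
  sol <- coarse_homogeneous_solution()
  cp <- coarse_plaque()
  pre <- sol$model
  int <- plaqhet:::assemble_internal(pre, sol$Fp, sol$u_final, want_K = FALSE)
  reaction <- sqrt(sum(int$f[cp$mesh$fixed_dofs]^2))
  p_fin <- mmHg_to_kPa(120)
  load_scale <- p_fin * 2 * pi * cp$section$params$lumen_radius
  expect_lt(reaction, 0.01 * load_scale)
})

test_that("rigid rotation of the geometry leaves PCS unchanged", {
  cp <- coarse_plaque()
  sol <- coarse_homogeneous_solution()
  pcs0 <- extract_pcs(sol, cp$cap)$pcs_kPa
  th <- 30 * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  mesh_rot <- cp$mesh
  mesh_rot$nodes <- cp$mesh$nodes %*% t(R)
  mesh_rot$centroids <- cp$mesh$centroids %*% t(R)
  sol_rot <- solve_inflation(mesh_rot, loading_protocol())
  expect_true(sol_rot$converged)
  pcs_rot <- max(sol_rot$stress_final$max_principal[cp$cap$elements])
  expect_lt(abs(pcs_rot / pcs0 - 1), 0.005)
})

test_that("PCS is stable under mesh refinement", {
  cp <- coarse_plaque()
  m_fine <- mesh_section(cp$section, cp$map_hom, target_edge_length = 0.06)
  sol_fine <- solve_inflation(m_fine, loading_protocol())
  expect_true(sol_fine$converged)
  cap_fine <- identify_cap(cp$section, m_fine)
  pcs_fine <- extract_pcs(sol_fine, cap_fine)$pcs_kPa
  pcs_coarse <- extract_pcs(coarse_homogeneous_solution(), cp$cap)$pcs_kPa
  expect_lt(abs(pcs_coarse / pcs_fine - 1), 0.05)
})

test_that("peak extraction takes the maximum with lowest-id tie-breaking", {
  fake <- structure(list(converged = TRUE,
                         stress_final = list(max_principal =
                                               c(10, 62, 41, 62))),
                    class = "fe_solution")
  cap <- structure(list(elements = 1:3), class = "cap_region")
  out <- extract_pcs(fake, cap)
  expect_equal(out$pcs_kPa, 62)
  expect_equal(out$element, 2L)
  tie <- structure(list(elements = c(2L, 4L)), class = "cap_region")
  expect_equal(extract_pcs(fake, tie)$element, 2L)
  allsame <- structure(list(converged = TRUE,
                            stress_final = list(max_principal = rep(5, 4))),
                       class = "fe_solution")
  expect_equal(extract_pcs(allsame, cap)$element, 1L)
  bad <- structure(list(converged = FALSE), class = "fe_solution")
  expect_error(extract_pcs(bad, cap), "unconverged")
})
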