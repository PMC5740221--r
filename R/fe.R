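## Plane-strain large-deformation FE solver for nearly incompressible
## neo-Hookean tissue.
##
## Formulation: total Lagrangian, 4-node quadrilaterals, selective reduced
## integration -- the isochoric terms of the strain energy are integrated
## with the full 2x2 Gauss rule and the volumetric penalty term at the
## element center only, which avoids volumetric locking (the behavioural
## contract of "hybrid" constant-pressure elements: det F stays within ~1%
## of 1 for tissue). Strain energy per unit reference area:
##     W(F) = C (I1 + 1 - 3) - 2 C ln J + (lambda/2) (ln J)^2
## with I1 = tr(F^T F) of the in-plane deformation gradient, J = det F; the
## out-of-plane stretch is 1 (plane strain). In the incompressible limit
## this reproduces W = C (I1_3D - 3) with the pressure as a reaction.
## Lumen pressure is a follower load on the current lumen boundary.
## Initial stresses at the imaged pressure are recovered by prestress
## accumulation: the incremental deformation gradient is absorbed into a
## per-Gauss-point history F_p while the reference geometry is held at the
## imaged configuration.

## penalty moduli: tissue is nearly incompressible (with a floor so very
## soft tissue still satisfies det F ~ 1 under physiological pressure);
## the gel surround is compressible with effective Poisson ratio 0.2
TISSUE_PENALTY_FACTOR <- 1000
TISSUE_PENALTY_FLOOR_KPA <- 2
GEL_POISSON <- 0.2

penalty_lambda <- function(C, region) {
  lam <- TISSUE_PENALTY_FACTOR * pmax(C, TISSUE_PENALTY_FLOOR_KPA)
  gel <- region == "gel"
  lam[gel] <- 2 * C[gel] * GEL_POISSON / (1 - 2 * GEL_POISSON)
  lam
}

#' Loading protocol for plaque inflation
#'
#' @param image_pressure intraluminal pressure at which the section was
#'   imaged/fixed (mmHg; default 100).
#' @param final_pressure systolic target pressure (mmHg; default 120).
#' @param load_steps_image pressure increments used to build up the initial
#'   stress state (>= 5 recommended).
#' @param load_steps_final increments for the image -> final pressure ramp.
#' @param newton_tolerance relative residual tolerance of the Newton solver.
#' @return object of class `loading_protocol`.
#' @export
loading_protocol <- function(image_pressure = 100, final_pressure = 120,
                             load_steps_image = 5, load_steps_final = 2,
                             newton_tolerance = 1e-8) {
  if (!(final_pressure >= image_pressure && image_pressure >= 0))
    stop_param("need final_pressure >= image_pressure >= 0")
  structure(list(image_pressure = image_pressure,
                 final_pressure = final_pressure,
                 load_steps_image = as.integer(load_steps_image),
                 load_steps_final = as.integer(load_steps_final),
                 newton_tolerance = newton_tolerance),
            class = "loading_protocol")
}

## Gauss rule: points 1..4 full 2x2 (weight 1), point 5 center (weight 4,
## used for the volumetric term only)
gauss_points <- function() {
  g <- 1 / sqrt(3)
  list(xi = c(-g, g, g, -g, 0), eta = c(-g, -g, g, g, 0),
       w = c(1, 1, 1, 1, 4))
}

#' Precompute FE operators for a mesh
#'
#' Shape-function gradients, integration weights, dof maps and penalty
#' moduli; everything that depends only on the reference geometry.
#'
#' @param mesh a `plaque_mesh`.
#' @return an object of class `fe_model` (internal structure).
#' @export
fe_precompute <- function(mesh) {
  el <- mesh$elems
  E <- nrow(el)
  Xx <- matrix(mesh$nodes[el, 1], E, 4)
  Xy <- matrix(mesh$nodes[el, 2], E, 4)
  xs <- c(-1, 1, 1, -1); es <- c(-1, -1, 1, 1)
  gp <- gauss_points()
  dN <- vector("list", 5)
  wdet <- matrix(0, E, 5)
  for (g in 1:5) {
    dNxi <- 0.25 * xs * (1 + es * gp$eta[g])
    dNeta <- 0.25 * es * (1 + xs * gp$xi[g])
    J11 <- Xx %*% dNxi; J12 <- Xx %*% dNeta
    J21 <- Xy %*% dNxi; J22 <- Xy %*% dNeta
    det <- J11 * J22 - J12 * J21
    if (any(det <= 0)) stop_param("inverted element in reference mesh")
    dNx <- matrix(0, E, 4); dNy <- matrix(0, E, 4)
    for (a in 1:4) {
      dNx[, a] <- (dNxi[a] * J22 - dNeta[a] * J21) / det
      dNy[, a] <- (-dNxi[a] * J12 + dNeta[a] * J11) / det
    }
    dN[[g]] <- list(x = dNx, y = dNy)
    wdet[, g] <- gp$w[g] * det
  }
  dofmat <- matrix(0L, E, 8)
  for (a in 1:4) {
    dofmat[, 2L * a - 1L] <- 2L * el[, a] - 1L
    dofmat[, 2L * a] <- 2L * el[, a]
  }
  # flat layouts for the compiled assembly kernel: column g*4 + a
  dNx_flat <- do.call(cbind, lapply(dN, `[[`, "x"))
  dNy_flat <- do.call(cbind, lapply(dN, `[[`, "y"))
  ndof <- 2L * nrow(mesh$nodes)
  free <- setdiff(seq_len(ndof), mesh$fixed_dofs)
  structure(list(mesh = mesh, E = E, ndof = ndof, free = free,
                 solver_cache = new.env(parent = emptyenv()),
                 dN = dN, wdet = wdet, dofmat = dofmat,
                 dNx_flat = dNx_flat, dNy_flat = dNy_flat,
                 C = mesh$C, lambda = penalty_lambda(mesh$C, mesh$region),
                 tissue = mesh$region != "gel"),
            class = "fe_model")
}

## prestress history: E x 20 matrix, columns g*4 + (1..4) = (F11,F12,F21,F22)
fp_identity <- function(pre) {
  m <- matrix(0, pre$E, 20)
  m[, 4 * (0:4) + 1] <- 1
  m[, 4 * (0:4) + 4] <- 1
  m
}

fp_cols <- function(g) 4L * (g - 1L) + 1:4

## deformation gradient of the displacement field at gauss point g;
## columns (F11, F12, F21, F22)
fu_at_gp <- function(pre, Ux, Uy, g) {
  dNx <- pre$dN[[g]]$x; dNy <- pre$dN[[g]]$y
  cbind(1 + rowSums(Ux * dNx), rowSums(Ux * dNy),
        rowSums(Uy * dNx), 1 + rowSums(Uy * dNy))
}

fmul <- function(A, B) {  # 2x2 matrix product, componentwise over elements
  cbind(A[, 1] * B[, 1] + A[, 2] * B[, 3],
        A[, 1] * B[, 2] + A[, 2] * B[, 4],
        A[, 3] * B[, 1] + A[, 4] * B[, 3],
        A[, 3] * B[, 2] + A[, 4] * B[, 4])
}

fdet <- function(F) F[, 1] * F[, 4] - F[, 2] * F[, 3]

## assemble internal force and (optionally) tangent via the compiled
## kernel. Returns NULL on element inversion (caller cuts the load step).
assemble_internal <- function(pre, Fp, u, want_K = TRUE) {
  out <- assemble_internal_cpp(pre$dNx_flat, pre$dNy_flat, pre$wdet, Fp,
                               u, pre$mesh$elems, pre$C, pre$lambda,
                               pre$ndof, want_K)
  if (!out$ok) return(NULL)
  list(f = out$f, Kv = out$Kv)
}

## follower pressure load on the current lumen boundary (p in kPa): for a
## straight edge under constant pressure the total force p * length * n_hat
## splits equally between its end nodes. Over the closed lumen loop this
## load is conservative -- it is the gradient of p x (enclosed area) -- so
## the assembled load stiffness is symmetric and can join the Cholesky
## Newton matrix.
external_load <- function(pre, u, p, want_K = FALSE) {
  ed <- pre$mesh$lumen_edges
  x <- pre$mesh$nodes[, 1] + u[seq(1, pre$ndof, 2)]
  y <- pre$mesh$nodes[, 2] + u[seq(2, pre$ndof, 2)]
  n1 <- ed[, 1]; n2 <- ed[, 2]
  dx <- x[n2] - x[n1]; dy <- y[n2] - y[n1]
  f <- numeric(pre$ndof)
  # each lumen node is first node of exactly one edge and second of one
  f[2 * n1 - 1] <- f[2 * n1 - 1] + p / 2 * dy
  f[2 * n1] <- f[2 * n1] - p / 2 * dx
  f[2 * n2 - 1] <- f[2 * n2 - 1] + p / 2 * dy
  f[2 * n2] <- f[2 * n2] - p / 2 * dx
  if (!want_K) return(list(f = f))
  # load stiffness d f_ext / d u
  ii <- jj <- vv <- numeric(0)
  for (m in list(n1, n2)) {
    ii <- c(ii, 2 * m - 1, 2 * m - 1, 2 * m, 2 * m)
    jj <- c(jj, 2 * n1, 2 * n2, 2 * n1 - 1, 2 * n2 - 1)
    vv <- c(vv, rep(-p / 2, length(m)), rep(p / 2, length(m)),
            rep(p / 2, length(m)), rep(-p / 2, length(m)))
  }
  list(f = f, ii = ii, jj = jj, vv = vv)
}

## linear solve of the Newton system. The full tangent (material +
## geometric + enclosed-cavity follower load) is symmetric, so the
## workhorse is a sparse Cholesky whose symbolic analysis is computed once
## per mesh and numerically updated each iteration; falls back to a sparse
## LU when the tangent is transiently indefinite (far from equilibrium or
## near a limit point).
solve_tangent <- function(pre, Kff, b) {
  Ks <- Matrix::symmpart(Kff)
  cache <- pre$solver_cache
  du <- tryCatch(suppressWarnings({
    if (is.null(cache$chol)) {
      cache$chol <- Matrix::Cholesky(Ks, LDL = FALSE, perm = TRUE)
    } else {
      cache$chol <- Matrix::update(cache$chol, Ks)
    }
    as.numeric(Matrix::solve(cache$chol, b, system = "A"))
  }), error = function(e) NULL)
  if (is.null(du)) {
    du <- tryCatch(as.numeric(Matrix::solve(Kff, b)),
                   error = function(e) NULL)
  }
  if (!is.null(du) && any(!is.finite(du))) du <- NULL
  du
}

## one Newton solve at fixed pressure; returns NULL-converged info on failure
newton_solve <- function(pre, Fp, u, p, tol = 1e-8, max_iter = 30) {
  free <- pre$free
  res_hist <- numeric(0)
  for (it in seq_len(max_iter)) {
    int <- assemble_internal(pre, Fp, u, want_K = TRUE)
    if (is.null(int)) return(list(u = u, converged = FALSE,
                                  reason = "element inversion",
                                  iterations = it - 1, res_hist = res_hist))
    ext <- external_load(pre, u, p, want_K = TRUE)
    r <- int$f - ext$f
    ref <- max(sqrt(sum(ext$f[free]^2)), 1e-9)
    rn <- sqrt(sum(r[free]^2))
    res_hist <- c(res_hist, rn / ref)
    if (rn <= tol * ref) {
      return(list(u = u, converged = TRUE, iterations = it - 1,
                  res_hist = res_hist))
    }
    ii <- rep(as.vector(pre$dofmat), times = 8)
    jj <- as.vector(pre$dofmat[, rep(1:8, each = 8)])
    K <- Matrix::sparseMatrix(
      i = c(ii, ext$ii), j = c(jj, ext$jj),
      x = c(as.vector(int$Kv), -ext$vv), dims = c(pre$ndof, pre$ndof))
    Kff <- K[free, free, drop = FALSE]
    du <- solve_tangent(pre, Kff, -r[free])
    if (is.null(du) || any(!is.finite(du)))
      return(list(u = u, converged = FALSE, reason = "singular tangent",
                  iterations = it, res_hist = res_hist))
    # backtracking line search on the residual norm
    alpha <- 1
    for (ls in 1:6) {
      u_try <- u
      u_try[free] <- u[free] + alpha * du
      int2 <- assemble_internal(pre, Fp, u_try, want_K = FALSE)
      if (!is.null(int2)) {
        ext2 <- external_load(pre, u_try, p)
        rn2 <- sqrt(sum((int2$f - ext2$f)[free]^2))
        if (rn2 < rn || alpha < 0.2) break
      }
      alpha <- alpha / 2
    }
    if (is.null(int2)) {
      return(list(u = u, converged = FALSE, reason = "element inversion",
                  iterations = it, res_hist = res_hist))
    }
    u <- u_try
  }
  list(u = u, converged = FALSE, reason = "max iterations",
       iterations = max_iter, res_hist = res_hist)
}

## absorb the converged incremental deformation into the prestress history
absorb_prestress <- function(pre, Fp, u) {
  E <- pre$E
  el <- pre$mesh$elems
  Ux <- matrix(u[2 * el - 1], E, 4)
  Uy <- matrix(u[2 * el], E, 4)
  out <- Fp
  for (g in 1:5) {
    cols <- fp_cols(g)
    out[, cols] <- fmul(fu_at_gp(pre, Ux, Uy, g), Fp[, cols])
  }
  out
}

## pressure ramp with adaptive step halving.
## absorb = TRUE implements the prestress-accumulation scheme: after every
## converged increment the deformation is folded into Fp and u reset to 0.
ramp_pressure <- function(pre, Fp, u, p_from, p_to, n_steps,
                          tol = 1e-8, max_iter = 30, absorb = FALSE,
                          min_frac = 1 / 64) {
  dp0 <- (p_to - p_from) / n_steps
  p <- p_from
  dp <- dp0
  total_iters <- 0L
  u_prev <- NULL; p_prev <- NA_real_; u_inc <- NULL; dp_inc <- NA_real_
  while (p < p_to - 1e-12 * max(1, p_to)) {
    p_try <- min(p + dp, p_to)
    # warm start: secant extrapolation along the loading path (or, in
    # absorb mode, the previous increment's displacement for a similar dp)
    guess <- u
    if (absorb) {
      if (!is.null(u_inc) && is.finite(dp_inc) && dp_inc > 0)
        guess <- u_inc * ((p_try - p) / dp_inc)
    } else if (!is.null(u_prev) && is.finite(p_prev) && p > p_prev) {
      guess <- u + (u - u_prev) * ((p_try - p) / (p - p_prev))
    }
    sol <- newton_solve(pre, Fp, guess, p_try, tol, max_iter)
    if (!sol$converged && !identical(guess, u)) {
      sol2 <- newton_solve(pre, Fp, u, p_try, tol, max_iter)
      total_iters <- total_iters + sol$iterations
      sol <- sol2
    }
    total_iters <- total_iters + sol$iterations
    if (!sol$converged) {
      if (dp <= abs(dp0) * min_frac)
        return(list(u = u, Fp = Fp, converged = FALSE, p_reached = p,
                    reason = sol$reason, iterations = total_iters))
      dp <- dp / 2
      next
    }
    if (absorb) {
      u_inc <- sol$u
      dp_inc <- p_try - p
      Fp <- absorb_prestress(pre, Fp, sol$u)
      u <- numeric(pre$ndof)
    } else {
      u_prev <- u; p_prev <- p
      u <- sol$u
    }
    p <- p_try
    dp <- min(dp * 1.5, dp0)
  }
  list(u = u, Fp = Fp, converged = TRUE, p_reached = p,
       iterations = total_iters)
}

#' Recover the initial-stress state at the imaged pressure
#'
#' Prestress accumulation: the imaged geometry is held as the reference
#' configuration while pressure is ramped to the imaged value; after each
#' converged increment the incremental deformation gradient is absorbed into
#' a per-Gauss-point history and the displacements reset, then the state is
#' "settled" (solve/absorb at constant pressure) until the equilibrium
#' configuration coincides with the imaged geometry.
#'
#' @param pre an `fe_model` from [fe_precompute()].
#' @param p_image_kPa imaged pressure (kPa).
#' @param n_increments pressure increments of the build-up ramp.
#' @param tol Newton relative residual tolerance.
#' @param settle_tol_mm settle until the maximal nodal displacement at the
#'   imaged pressure is below this (default: 1e-4 x lumen radius).
#' @param max_settle settle iteration cap.
#' @return list with `Fp` (prestress history), `converged`,
#'   `geometry_error_mm` (max nodal displacement at the imaged pressure).
#' @export
prestress_state <- function(pre, p_image_kPa, n_increments = 5,
                            tol = 1e-8, settle_tol_mm = NULL,
                            max_settle = 25) {
  Fp <- fp_identity(pre)
  u <- numeric(pre$ndof)
  if (p_image_kPa <= 0)
    return(list(Fp = Fp, converged = TRUE, geometry_error_mm = 0,
                n_settle = 0L))
  settle_tol_mm <- settle_tol_mm %||% (1e-4 * pre$mesh$lumen_radius)
  r1 <- ramp_pressure(pre, Fp, u, 0, p_image_kPa, n_increments,
                      tol = tol, absorb = TRUE)
  if (!r1$converged)
    return(list(Fp = r1$Fp, converged = FALSE, geometry_error_mm = NA_real_,
                reason = r1$reason))
  Fp <- r1$Fp
  err <- Inf
  n_settle <- 0L
  while (n_settle < max_settle) {
    sol <- newton_solve(pre, Fp, numeric(pre$ndof), p_image_kPa, tol)
    if (!sol$converged)
      return(list(Fp = Fp, converged = FALSE, geometry_error_mm = err,
                  reason = sol$reason))
    err <- max(abs(sol$u))
    n_settle <- n_settle + 1L
    Fp <- absorb_prestress(pre, Fp, sol$u)
    if (err <= settle_tol_mm) break
  }
  list(Fp = Fp, converged = err <= settle_tol_mm,
       geometry_error_mm = err, n_settle = n_settle)
}

## element-centroid Cauchy stress from the center Gauss point.
## sigma = (1/J) (2C B - 2C I + lambda ln J I), B = F F^T (in-plane block).
element_stress <- function(pre, Fp, u) {
  E <- pre$E
  el <- pre$mesh$elems
  Ux <- matrix(u[2 * el - 1], E, 4)
  Uy <- matrix(u[2 * el], E, 4)
  Ft <- fmul(fu_at_gp(pre, Ux, Uy, 5), Fp[, fp_cols(5)])
  J <- fdet(Ft)
  B11 <- Ft[, 1]^2 + Ft[, 2]^2
  B22 <- Ft[, 3]^2 + Ft[, 4]^2
  B12 <- Ft[, 1] * Ft[, 3] + Ft[, 2] * Ft[, 4]
  C2 <- 2 * pre$C
  lnJ <- log(J)
  sxx <- (C2 * (B11 - 1) + pre$lambda * lnJ) / J
  syy <- (C2 * (B22 - 1) + pre$lambda * lnJ) / J
  sxy <- C2 * B12 / J
  mid <- (sxx + syy) / 2
  rad <- sqrt(((sxx - syy) / 2)^2 + sxy^2)
  list(sxx = sxx, syy = syy, sxy = sxy,
       max_principal = mid + rad, min_principal = mid - rad,
       detF = J)
}

## area enclosed by the current lumen boundary loop (shoelace)
lumen_area <- function(pre, u) {
  n <- pre$mesh$lumen_edges[, 1]
  x <- pre$mesh$nodes[n, 1] + u[2 * n - 1]
  y <- pre$mesh$nodes[n, 2] + u[2 * n]
  j <- c(seq_along(n)[-1], 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

#' Solve the plaque inflation problem
#'
#' Two converged states: (i) the initial-stress state whose geometry equals
#' the imaged geometry at the imaged pressure, and (ii) the final state
#' after incrementing to the systolic pressure.
#'
#' @param mesh a `plaque_mesh` (or a precomputed `fe_model`).
#' @param protocol a [loading_protocol()].
#' @return object of class `fe_solution`: `u_final` (nodal displacement
#'   from the imaged geometry, mm), stress fields at both states
#'   (element-centroid Cauchy stress, kPa, with `max_principal` and `detF`),
#'   `lumen_area_image` / `lumen_area_final` (mm^2), `converged`,
#'   `geometry_error_mm` of the initial-stress step, and the model.
#' @export
solve_inflation <- function(mesh, protocol = loading_protocol()) {
  pre <- if (inherits(mesh, "fe_model")) mesh else fe_precompute(mesh)
  p_img <- mmHg_to_kPa(protocol$image_pressure)
  p_fin <- mmHg_to_kPa(protocol$final_pressure)
  tol <- protocol$newton_tolerance

  ps <- prestress_state(pre, p_img, n_increments = protocol$load_steps_image,
                        tol = tol)
  if (!isTRUE(ps$converged)) {
    return(structure(list(converged = FALSE, stage = "prestress",
                          reason = ps$reason %||% "geometry tolerance",
                          geometry_error_mm = ps$geometry_error_mm),
                     class = "fe_solution"))
  }
  Fp <- ps$Fp
  stress_image <- element_stress(pre, Fp, numeric(pre$ndof))
  area_img <- lumen_area(pre, numeric(pre$ndof))

  if (p_fin > p_img) {
    r2 <- ramp_pressure(pre, Fp, numeric(pre$ndof), p_img, p_fin,
                        protocol$load_steps_final, tol = tol, absorb = FALSE)
    if (!r2$converged) {
      return(structure(list(converged = FALSE, stage = "final-ramp",
                            reason = r2$reason,
                            geometry_error_mm = ps$geometry_error_mm),
                       class = "fe_solution"))
    }
    u_fin <- r2$u
  } else {
    u_fin <- numeric(pre$ndof)
  }
  stress_final <- element_stress(pre, Fp, u_fin)

  structure(list(converged = TRUE,
                 u_final = u_fin,
                 Fp = Fp,
                 stress_image = stress_image,
                 stress_final = stress_final,
                 lumen_area_image = area_img,
                 lumen_area_final = lumen_area(pre, u_fin),
                 geometry_error_mm = ps$geometry_error_mm,
                 protocol = protocol,
                 model = pre),
            class = "fe_solution")
}

#' @export
print.fe_solution <- function(x, ...) {
  if (!x$converged) {
    cat("fe_solution: NOT converged at stage", x$stage, "-", x$reason, "\n")
    return(invisible(x))
  }
  cat("fe_solution: converged;",
      "max principal stress (final):",
      round(max(x$stress_final$max_principal), 2), "kPa;",
      "lumen area", round(x$lumen_area_image, 4), "->",
      round(x$lumen_area_final, 4), "mm^2\n")
  invisible(x)
}

#' Peak cap stress
#'
#' Maximum of the element-centroid maximum-principal Cauchy stress over the
#' cap region at the final (systolic) pressure. Ties go to the lowest
#' element id.
#'
#' @param sol a converged `fe_solution`.
#' @param cap a `cap_region` from [identify_cap()].
#' @return list with `pcs_kPa` and `element` (argmax element id).
#' @export
extract_pcs <- function(sol, cap) {
  if (!isTRUE(sol$converged))
    stop_param("cannot extract PCS from an unconverged solution")
  s <- sol$stress_final$max_principal[cap$elements]
  k <- which.max(s)
  list(pcs_kPa = s[k], element = cap$elements[k])
}
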