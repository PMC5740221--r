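## Structured radial meshing of a plaque cross-section.
##
## The synthetic geometry family is star-shaped about the lumen center, so a
## mapped ray x layer quad grid is well posed: M rays fanning out from the
## lumen center, radial node layers running lumen -> inner wall -> outer wall
## -> gel ring. The intima band is graded geometrically (fine near the lumen
## so a thin cap holds >= 2 element layers) and the two core interface radii
## are snapped onto the nearest template nodes where the core is thick
## enough, which makes the cap/core interfaces node-conforming.

geometric_breaks <- function(n, first_frac) {
  # n intervals on [0,1]; first interval ~ first_frac, geometric growth
  if (first_frac * n >= 1) return(seq(0, 1, length.out = n + 1))
  f <- function(g) first_frac * (g^n - 1) / (g - 1) - 1
  g <- uniroot(f, c(1 + 1e-9, 100))$root
  c(0, cumsum(first_frac * g^(0:(n - 1)))) / (first_frac * (g^n - 1) / (g - 1))
}

#' Mesh a plaque section (with compliant gel surround)
#'
#' Builds a structured quadrilateral mesh of the tissue cross-section plus a
#' surrounding compressible gel annulus whose circular outer edge is fully
#' fixed (encastre). Element region tags are sampled from the label map at
#' element centroids; element shear moduli come from the modulus map.
#'
#' @param section a `plaque_section`.
#' @param mmap a `modulus_map` for the same section.
#' @param target_edge_length target element edge length (mm); default 0.025
#'   gives roughly 15-20k tissue elements on the default section.
#' @param gel_outer_factor gel outer radius as a multiple of the outer wall
#'   radius (default 2.5).
#' @param n_gel_layers radial gel layers (geometrically coarsened).
#' @return an object of class `plaque_mesh`: `nodes` (N x 2, mm), `elems`
#'   (E x 4 CCW node ids), `region` (factor: intima/wall/core/gel),
#'   `C` (element shear moduli, kPa), `lumen_edges` (CCW node pairs on the
#'   lumen boundary), `fixed_dofs` (encastred dofs), `centroids`, and meta.
#' @export
mesh_section <- function(section, mmap, target_edge_length = 0.025,
                         gel_outer_factor = 2.5, n_gel_layers = 5) {
  p <- section$params
  h <- target_edge_length
  r_l <- p$lumen_radius
  lcx <- lumen_center_x(p)
  r_gel <- gel_outer_factor * p$outer_wall_radius
  half_span <- p$core_angular_span / 2 * pi / 180

  # ray count from mid-intima circumference
  r_mid <- mean(c(r_l, p$outer_wall_radius - p$wall_thickness))
  M <- max(24L, as.integer(round(2 * pi * r_mid / h)))
  theta <- (seq_len(M) - 1) * 2 * pi / M

  T0 <- inner_wall_ray_radius(p, 0) - r_l  # intima thickness at cap midline
  if (T0 <= 0) stop_param("meshing failure: degenerate intima at the cap ",
                          "midline (inner wall contour inside the lumen)")
  first <- if (has_core(p)) min(h, p$cap_thickness / 2, T0 / 6) else min(h, T0 / 6)
  n_I <- max(8L, min(80L, as.integer(ceiling(T0 / h)) + 4L))
  s <- geometric_breaks(n_I, first / T0)
  n_W <- max(3L, as.integer(round(p$wall_thickness / h)))
  n_G <- as.integer(n_gel_layers)

  K <- n_I + n_W + n_G + 1L  # nodes per ray
  radii <- matrix(0, M, K)
  rho_in <- inner_wall_ray_radius(p, theta)
  rho_out <- ray_to_circle_radius(p, theta, p$outer_wall_radius)
  rho_gel <- ray_to_circle_radius(p, theta, r_gel)

  gel_w <- 1.6^(0:(n_G - 1)); gel_s <- c(0, cumsum(gel_w)) / sum(gel_w)
  for (j in seq_len(M)) {
    ri <- r_l + s * (rho_in[j] - r_l)
    # snap template nodes onto the core interface radii where the core is
    # resolvable, so the cap band is node-conforming
    wrapped <- atan2(sin(theta[j]), cos(theta[j]))
    if (has_core(p) && abs(wrapped) <= half_span) {
      rho_ci <- r_l + p$cap_thickness
      rho_co <- core_outer_radius(p, wrapped)
      spacing <- diff(ri)
      snap_to <- function(r, target, lo) {
        i <- which.min(abs(r - target))
        i <- max(i, lo)
        if (i > 1 && i < length(r) &&
            abs(r[i] - target) < 0.6 * max(spacing[max(1, i - 1)],
                                           spacing[min(length(spacing), i)])) {
          r[i] <- target
          attr(r, "snapped") <- i
        }
        r
      }
      ri <- snap_to(ri, rho_ci, 2L)
      i1 <- attr(ri, "snapped") %||% 0L
      if (rho_co - rho_ci > 1.2 * (ri[min(i1 + 2L, length(ri))] -
                                   ri[max(i1 + 1L, 2L)]) && i1 > 0) {
        ri2 <- snap_to(ri, rho_co, i1 + 2L)
        ri <- ri2
      }
      attr(ri, "snapped") <- NULL
      ri <- sort(ri)  # guard monotonicity after snapping
    }
    rw <- rho_in[j] + seq_len(n_W) / n_W * (rho_out[j] - rho_in[j])
    rg <- rho_out[j] + gel_s[-1] * (rho_gel[j] - rho_out[j])
    radii[j, ] <- c(ri, rw, rg)
  }

  node_id <- function(j, i) (j - 1L) * K + i
  nodes <- matrix(0, M * K, 2)
  for (j in seq_len(M)) {
    idx <- node_id(j, seq_len(K))
    nodes[idx, 1] <- lcx + radii[j, ] * cos(theta[j])
    nodes[idx, 2] <- radii[j, ] * sin(theta[j])
  }

  jn <- c(seq_len(M)[-1], 1L)  # next ray with wrap
  elems <- matrix(0L, M * (K - 1L), 4L)
  e <- 0L
  for (j in seq_len(M)) {
    for (i in seq_len(K - 1L)) {
      e <- e + 1L
      elems[e, ] <- c(node_id(j, i), node_id(j, i + 1L),
                      node_id(jn[j], i + 1L), node_id(jn[j], i))
    }
  }

  cx <- (nodes[elems[, 1], 1] + nodes[elems[, 2], 1] +
           nodes[elems[, 3], 1] + nodes[elems[, 4], 1]) / 4
  cy <- (nodes[elems[, 1], 2] + nodes[elems[, 2], 2] +
           nodes[elems[, 3], 2] + nodes[elems[, 4], 2]) / 4

  lab <- raster_at(section$label_map, cx, cy)
  r_origin <- sqrt(cx^2 + cy^2)
  region <- rep("gel", nrow(elems))
  region[!is.na(lab) & lab == LBL_WALL] <- "wall"
  region[!is.na(lab) & lab == LBL_INTIMA] <- "intima"
  region[!is.na(lab) & lab == LBL_CORE] <- "core"
  region[!is.na(lab) & lab == LBL_LUMEN] <- "intima"  # boundary rounding
  region[r_origin > p$outer_wall_radius] <- "gel"

  cfg <- mmap$config
  Cmod <- raster_at(mmap$modulus_field, cx, cy)
  # fallback for centroids off the raster or on lumen pixels: fixed region
  # moduli; intima fallback samples slightly outward along the ray
  bad <- is.na(Cmod) | region == "gel"
  Cmod[region == "gel"] <- cfg$gel_modulus
  fix <- which(is.na(Cmod))
  if (length(fix)) {
    for (e in fix) {
      if (region[e] == "wall") { Cmod[e] <- cfg$wall_modulus; next }
      if (region[e] == "core") { Cmod[e] <- cfg$core_modulus; next }
      rr <- sqrt((cx[e] - lcx)^2 + cy[e]^2)
      ux <- (cx[e] - lcx) / rr; uy <- cy[e] / rr
      ps <- section$pixel_size_mm
      for (step in 1:5) {
        v <- raster_at(mmap$modulus_field, cx[e] + step * ps * ux,
                       cy[e] + step * ps * uy)
        if (!is.na(v)) { Cmod[e] <- v; break }
      }
      if (is.na(Cmod[e])) Cmod[e] <- cfg$homogeneous_modulus
    }
  }

  lumen_edges <- cbind(node_id(seq_len(M), 1L), node_id(jn, 1L))
  outer_nodes <- node_id(seq_len(M), K)
  fixed_dofs <- as.integer(rbind(2L * outer_nodes - 1L, 2L * outer_nodes))

  mesh <- structure(list(nodes = nodes, elems = elems,
                         region = region, C = Cmod,
                         lumen_edges = lumen_edges,
                         fixed_dofs = fixed_dofs,
                         centroids = cbind(cx, cy),
                         lumen_center = c(lcx, 0),
                         lumen_radius = r_l,
                         n_rays = M, n_layers = K,
                         target_edge_length = h,
                         gel_outer_radius = r_gel,
                         section_params = p),
                    class = "plaque_mesh")
  q <- mesh_quality(mesh)
  if (q$min_angle_deg <= 5)
    stop_param("meshing failure: degenerate element (min corner angle ",
               round(q$min_angle_deg, 2), " deg)")
  mesh$quality <- q
  mesh
}

#' @export
print.plaque_mesh <- function(x, ...) {
  cat("plaque_mesh:", nrow(x$nodes), "nodes,", nrow(x$elems), "quads (",
      paste(names(table(x$region)), table(x$region), sep = "=",
            collapse = ", "), ")\n")
  if (!is.null(x$quality))
    cat("  min corner angle:", round(x$quality$min_angle_deg, 1), "deg\n")
  invisible(x)
}

#' Mesh quality: corner angles and signed areas
#'
#' @param mesh a `plaque_mesh`.
#' @return list with `min_angle_deg` and `min_area` (signed; negative means
#'   an inverted element).
#' @export
mesh_quality <- function(mesh) {
  n <- mesh$nodes; el <- mesh$elems
  xs <- matrix(n[el, 1], nrow(el), 4)
  ys <- matrix(n[el, 2], nrow(el), 4)
  area <- 0.5 * ((xs[, 1] * ys[, 2] - xs[, 2] * ys[, 1]) +
                   (xs[, 2] * ys[, 3] - xs[, 3] * ys[, 2]) +
                   (xs[, 3] * ys[, 4] - xs[, 4] * ys[, 3]) +
                   (xs[, 4] * ys[, 1] - xs[, 1] * ys[, 4]))
  min_ang <- Inf
  for (a in 1:4) {
    b <- a %% 4 + 1; c <- (a + 2) %% 4 + 1
    v1x <- xs[, b] - xs[, a]; v1y <- ys[, b] - ys[, a]
    v2x <- xs[, c] - xs[, a]; v2y <- ys[, c] - ys[, a]
    cosang <- (v1x * v2x + v1y * v2y) /
      (sqrt(v1x^2 + v1y^2) * sqrt(v2x^2 + v2y^2))
    min_ang <- min(min_ang, acos(pmax(-1, pmin(1, cosang))))
  }
  list(min_angle_deg = min_ang * 180 / pi, min_area = min(area))
}

#' Structured annulus mesh (benchmark geometry)
#'
#' Plain thick-walled cylinder cross-section with pressure on the inner
#' boundary and a free outer boundary; rigid modes are removed by symmetry
#' constraints on the coordinate axes (exact for the axisymmetric solution).
#'
#' @param inner_radius,outer_radius annulus radii (mm).
#' @param C shear modulus (kPa) for all elements.
#' @param n_rays,n_layers mesh resolution.
#' @return a `plaque_mesh` (region "intima" everywhere, no gel).
#' @export
mesh_annulus <- function(inner_radius, outer_radius, C,
                         n_rays = 48, n_layers = 10) {
  M <- as.integer(n_rays); K <- as.integer(n_layers) + 1L
  theta <- (seq_len(M) - 1) * 2 * pi / M
  rr <- seq(inner_radius, outer_radius, length.out = K)
  node_id <- function(j, i) (j - 1L) * K + i
  nodes <- matrix(0, M * K, 2)
  for (j in seq_len(M)) {
    nodes[node_id(j, seq_len(K)), 1] <- rr * cos(theta[j])
    nodes[node_id(j, seq_len(K)), 2] <- rr * sin(theta[j])
  }
  jn <- c(seq_len(M)[-1], 1L)
  elems <- matrix(0L, M * (K - 1L), 4L)
  e <- 0L
  for (j in seq_len(M)) for (i in seq_len(K - 1L)) {
    e <- e + 1L
    elems[e, ] <- c(node_id(j, i), node_id(j, i + 1L),
                    node_id(jn[j], i + 1L), node_id(jn[j], i))
  }
  # symmetry pins: u_y = 0 on the x-axis rays, u_x = 0 on the y-axis rays
  on_x <- which(abs(nodes[, 2]) < 1e-12)
  on_y <- which(abs(nodes[, 1]) < 1e-12)
  fixed_dofs <- c(2L * on_x, 2L * on_y - 1L)
  cx <- rowMeans(matrix(nodes[elems, 1], nrow(elems), 4))
  cy <- rowMeans(matrix(nodes[elems, 2], nrow(elems), 4))
  structure(list(nodes = nodes, elems = elems,
                 region = rep("intima", nrow(elems)),
                 C = rep(C, nrow(elems)),
                 lumen_edges = cbind(node_id(seq_len(M), 1L), node_id(jn, 1L)),
                 fixed_dofs = as.integer(fixed_dofs),
                 centroids = cbind(cx, cy),
                 lumen_center = c(0, 0),
                 lumen_radius = inner_radius,
                 n_rays = M, n_layers = K,
                 target_edge_length = 2 * pi * inner_radius / M,
                 gel_outer_radius = NA_real_,
                 section_params = NULL),
            class = "plaque_mesh")
}

#' Identify the cap region of a meshed plaque
#'
#' The cap is the set of intima elements whose centroid lies radially between
#' the lumen boundary and the core inner boundary, within the core's angular
#' span plus a shoulder margin.
#'
#' @param section the `plaque_section` (must have a core).
#' @param mesh the `plaque_mesh` built from it.
#' @param shoulder_margin_deg extra angular margin beyond the core span
#'   (default 10 degrees) so the cap shoulders are included.
#' @return an object of class `cap_region`: `elements` (element ids),
#'   `min_cap_thickness_um`, `shoulder_margin_deg`.
#' @export
identify_cap <- function(section, mesh, shoulder_margin_deg = 10) {
  p <- section$params
  if (!has_core(p))
    stop_param("section has no lipid core: no cap is defined; use the ",
               "whole-intima peak stress instead")
  half <- p$core_angular_span / 2 * pi / 180 +
    shoulder_margin_deg * pi / 180
  dx <- mesh$centroids[, 1] - lumen_center_x(p)
  dy <- mesh$centroids[, 2]
  phi <- atan2(dy, dx)
  rho <- sqrt(dx^2 + dy^2)
  sel <- which(mesh$region == "intima" & abs(phi) <= half &
                 rho <= p$lumen_radius + p$cap_thickness + 1e-12)
  if (length(sel) == 0)
    stop_param("cap identification failed: no intima elements between lumen ",
               "and core")
  mct <- contour_min_distance(section$contours$lumen, section$contours$core)
  structure(list(elements = sel,
                 min_cap_thickness_um = mct * 1000,
                 shoulder_margin_deg = shoulder_margin_deg),
            class = "cap_region")
}
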