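## Label codes for plaque section rasters
LBL_BACKGROUND <- 0L
LBL_WALL <- 1L
LBL_INTIMA <- 2L
LBL_CORE <- 3L
LBL_LUMEN <- 4L

#' Geometry parameters for a synthetic plaque cross-section
#'
#' Defines the circular-archetype plaque family: a circular outer wall
#' centered at the origin, an eccentric circular lumen offset along +x, and a
#' crescent-shaped lipid-rich necrotic core on the +x side of the lumen,
#' separated from it by a fibrous cap of prescribed thickness. The intima is
#' everything between the lumen and the inner wall boundary, minus the core.
#'
#' @param outer_wall_radius outer wall radius (mm).
#' @param wall_thickness thickness of the vessel wall ring (mm).
#' @param lumen_radius lumen radius (mm).
#' @param lumen_offset lumen center offset (mm); the lumen is displaced
#'   along -x so the intima is thickest on the +x side, where the cap and
#'   core sit. Controls plaque eccentricity.
#' @param core_angular_span angular span of the core crescent (degrees),
#'   measured at the lumen center around the +x midline. 0 means no core.
#' @param core_max_thickness maximal radial thickness of the core (mm).
#' @param cap_thickness minimal distance between core and lumen (mm).
#' @param image_resolution pixel size of the rendered rasters (micrometres
#'   per pixel). The default 5 um/px resolves a 35 um cap with >= 7 pixels.
#' @param seed integer seed (recorded; geometry itself is deterministic).
#' @return an object of class `section_params`.
#' @export
section_params <- function(outer_wall_radius = 2.0,
                           wall_thickness = 0.5,
                           lumen_radius = 0.6,
                           lumen_offset = 0.45,
                           core_angular_span = 120,
                           core_max_thickness = 0.45,
                           cap_thickness = 0.2,
                           image_resolution = 5,
                           seed = 1L) {
  p <- list(outer_wall_radius = outer_wall_radius,
            wall_thickness = wall_thickness,
            lumen_radius = lumen_radius,
            lumen_offset = lumen_offset,
            core_angular_span = core_angular_span,
            core_max_thickness = core_max_thickness,
            cap_thickness = cap_thickness,
            image_resolution = image_resolution,
            seed = as.integer(seed))
  class(p) <- "section_params"
  validate_section_params(p)
  p
}

validate_section_params <- function(p) {
  if (p$outer_wall_radius <= 0 || p$lumen_radius <= 0)
    stop_param("invalid geometry: radii must be positive")
  if (p$wall_thickness <= 0 || p$wall_thickness >= p$outer_wall_radius)
    stop_param("invalid geometry: wall_thickness must lie in (0, outer_wall_radius)")
  if (p$cap_thickness <= 0)
    stop_param("invalid geometry: cap_thickness must be positive")
  if (p$image_resolution <= 0)
    stop_param("invalid geometry: image_resolution must be positive")
  if (p$core_angular_span < 0 || p$core_angular_span > 360)
    stop_param("invalid geometry: core_angular_span must be in [0, 360] degrees")
  r_in <- p$outer_wall_radius - p$wall_thickness
  if (p$lumen_offset + p$lumen_radius >= r_in)
    stop_param("infeasible geometry: lumen not strictly inside the inner wall ",
               "(lumen_offset + lumen_radius >= inner wall radius)")
  if (has_core(p)) {
    ray <- inner_wall_ray_radius(p, seq(-1, 1, length.out = 361) *
                                   p$core_angular_span / 2 * pi / 180)
    rho_o <- core_outer_radius(p, seq(-1, 1, length.out = 361) *
                                 p$core_angular_span / 2 * pi / 180)
    if (any(rho_o >= ray))
      stop_param("infeasible geometry: core would intersect the inner wall ",
                 "(lumen_radius + cap_thickness + core_max_thickness too large ",
                 "for the intima at the cap midline)")
  }
  invisible(p)
}

has_core <- function(p) p$core_angular_span > 0 && p$core_max_thickness > 0

## x coordinate of the lumen center: offset along -x, so the cap/core side
## (+x) carries the thick intima
lumen_center_x <- function(p) -p$lumen_offset

## distance from the lumen center to a circle of radius R centered at the
## origin, along direction phi (phi measured from +x at the lumen center)
ray_to_circle_radius <- function(p, phi, R) {
  cx <- lumen_center_x(p)
  -cx * cos(phi) + sqrt(cx^2 * cos(phi)^2 - cx^2 + R^2)
}

inner_wall_ray_radius <- function(p, phi) {
  ray_to_circle_radius(p, phi, p$outer_wall_radius - p$wall_thickness)
}

## core radial bounds about the lumen center; outer boundary tapers to the
## inner one with a cosine profile so the crescent closes at the span edges
core_inner_radius <- function(p, phi) {
  rep(p$lumen_radius + p$cap_thickness, length(phi))
}
core_outer_radius <- function(p, phi) {
  half <- p$core_angular_span / 2 * pi / 180
  t <- ifelse(abs(phi) <= half,
              p$core_max_thickness * cos(pi * phi / (2 * half)),
              0)
  p$lumen_radius + p$cap_thickness + pmax(t, 0)
}

circle_contour <- function(cx, cy, r, n = 720) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(x = cx + r * cos(th), y = cy + r * sin(th))
}

core_contour <- function(p, n = 360) {
  half <- p$core_angular_span / 2 * pi / 180
  phi <- seq(-half, half, length.out = n)
  ri <- core_inner_radius(p, phi)
  ro <- core_outer_radius(p, phi)
  cx <- lumen_center_x(p)
  inner <- cbind(x = cx + ri * cos(phi), y = ri * sin(phi))
  outer <- cbind(x = cx + rev(ro) * cos(rev(phi)), y = rev(ro) * sin(rev(phi)))
  rbind(inner, outer)
}

#' Generate a labelled synthetic plaque cross-section
#'
#' Renders the label map (background = 0, wall = 1, intima = 2, lipid core =
#' 3, lumen = 4) and the analytic boundary contours for a parameter set. The
#' intensity image is added separately by [render_intima_texture()].
#'
#' @param params a [section_params()] object.
#' @return an object of class `plaque_section` with elements `label_map`
#'   (integer raster with physical-coordinate attributes), `intensity`
#'   (NULL until textured), `pixel_size_mm`, `contours` (lumen, inner_wall,
#'   outer_wall, and core when present; closed polygons in mm), and `params`.
#' @export
generate_section <- function(params) {
  p <- validate_section_params(params)
  ps <- p$image_resolution / 1000  # mm per pixel
  half_px <- ceiling(p$outer_wall_radius / ps) + 2L
  n <- 2L * half_px + 1L
  x0 <- -half_px * ps
  y0 <- half_px * ps

  grid <- raster_coords(new_raster(matrix(0L, n, n), ps, x0, y0))
  r_o <- sqrt(grid$x^2 + grid$y^2)
  dx <- grid$x - lumen_center_x(p)
  r_lm <- sqrt(dx^2 + grid$y^2)
  r_in <- p$outer_wall_radius - p$wall_thickness

  lab <- matrix(LBL_BACKGROUND, n, n)
  lab[r_o <= p$outer_wall_radius] <- LBL_WALL
  lab[r_o <= r_in] <- LBL_INTIMA
  if (has_core(p)) {
    phi <- atan2(grid$y, dx)
    half <- p$core_angular_span / 2 * pi / 180
    in_span <- abs(phi) <= half
    ro <- core_outer_radius(p, phi)
    is_core <- in_span & lab == LBL_INTIMA &
      r_lm >= (p$lumen_radius + p$cap_thickness) & r_lm <= ro
    lab[is_core] <- LBL_CORE
  }
  lab[r_lm <= p$lumen_radius] <- LBL_LUMEN

  contours <- list(
    lumen = circle_contour(lumen_center_x(p), 0, p$lumen_radius),
    inner_wall = circle_contour(0, 0, r_in),
    outer_wall = circle_contour(0, 0, p$outer_wall_radius))
  if (has_core(p)) contours$core <- core_contour(p)

  for (code in c(LBL_WALL, LBL_INTIMA)) {
    if (!any(lab == code)) stop_param("degenerate section: region code ",
                                      code, " has zero area")
  }

  structure(list(label_map = new_raster(lab, ps, x0, y0),
                 intensity = NULL,
                 pixel_size_mm = ps,
                 contours = contours,
                 params = p),
            class = "plaque_section")
}

#' @export
print.plaque_section <- function(x, ...) {
  n <- dim(x$label_map)
  cnt <- table(factor(x$label_map, levels = 0:4,
                      labels = c("background", "wall", "intima", "core", "lumen")))
  cat("plaque_section:", n[1], "x", n[2], "px at",
      x$pixel_size_mm * 1000, "um/px\n")
  cat("  pixels:", paste(names(cnt), cnt, sep = "=", collapse = ", "), "\n")
  cat("  intensity image:", if (is.null(x$intensity)) "absent" else "present", "\n")
  invisible(x)
}

#' Region areas of a section
#'
#' @param section a `plaque_section`.
#' @return named vector of areas in mm^2 for wall, intima, core, lumen.
#' @export
region_areas <- function(section) {
  ps2 <- section$pixel_size_mm^2
  codes <- c(wall = LBL_WALL, intima = LBL_INTIMA,
             core = LBL_CORE, lumen = LBL_LUMEN)
  vapply(codes, function(k) sum(section$label_map == k) * ps2, numeric(1))
}

#' Measure the minimal cap thickness from the rendered raster
#'
#' Minimal distance from any core pixel center to the lumen boundary; by
#' construction this should match the requested `cap_thickness` within one
#' pixel. Returns NA when the section has no core.
#'
#' @param section a `plaque_section`.
#' @return minimal cap thickness in mm, or NA.
#' @export
measured_cap_thickness <- function(section) {
  lab <- section$label_map
  if (!any(lab == LBL_CORE)) return(NA_real_)
  grid <- raster_coords(lab)
  sel <- lab == LBL_CORE
  p <- section$params
  d_lumen <- sqrt((grid$x[sel] - lumen_center_x(p))^2 + grid$y[sel]^2) -
    p$lumen_radius
  min(d_lumen)
}

#' Minimal distance between two polygonal contours
#'
#' Vertex-to-segment minimal distance, both directions; used for contour
#' based cap-thickness checks.
#'
#' @param a,b two-column matrices of polygon vertices (closed implicitly).
#' @return minimal distance.
#' @export
contour_min_distance <- function(a, b) {
  pt_seg <- function(px, py, x1, y1, x2, y2) {
    vx <- x2 - x1; vy <- y2 - y1
    L2 <- vx^2 + vy^2
    t <- pmin(1, pmax(0, ((px - x1) * vx + (py - y1) * vy) / pmax(L2, 1e-300)))
    sqrt((x1 + t * vx - px)^2 + (y1 + t * vy - py)^2)
  }
  one_way <- function(P, S) {
    n <- nrow(S)
    j <- c(seq_len(n)[-1], 1L)
    best <- Inf
    for (i in seq_len(nrow(P))) {
      d <- pt_seg(P[i, 1], P[i, 2], S[, 1], S[, 2], S[j, 1], S[j, 2])
      best <- min(best, min(d))
    }
    best
  }
  min(one_way(a, b), one_way(b, a))
}
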