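## Raster convention (fixed for the whole package):
## matrices are [row, col], row-major thinking, origin at the top-left pixel,
## pixel centers on an integer grid, 0-based indexing in the physical mapping;
## physical coordinates are in mm with y pointing up:
##   x = x0 + col_0based * ps,  y = y0 - row_0based * ps
## where ps is the pixel size in mm and (x0, y0) is the center of pixel [1,1].

#' Physical coordinates of all pixel centers
#'
#' @param raster a matrix with attributes `x0`, `y0`, `pixel_size_mm`.
#' @return list with matrices `x` and `y` (same dim as `raster`), in mm.
#' @keywords internal
raster_coords <- function(raster) {
  ps <- attr(raster, "pixel_size_mm")
  x0 <- attr(raster, "x0"); y0 <- attr(raster, "y0")
  nr <- nrow(raster); nc <- ncol(raster)
  x <- matrix(rep(x0 + (seq_len(nc) - 1) * ps, each = nr), nr, nc)
  y <- matrix(rep(y0 - (seq_len(nr) - 1) * ps, times = nc), nr, nc)
  list(x = x, y = y)
}

#' Nearest-pixel raster lookup at physical points
#'
#' @param raster matrix with raster attributes (see [raster_coords()]).
#' @param x,y physical coordinates (mm), vectors of equal length.
#' @return vector of raster values; NA outside the raster extent.
#' @keywords internal
raster_at <- function(raster, x, y) {
  ps <- attr(raster, "pixel_size_mm")
  x0 <- attr(raster, "x0"); y0 <- attr(raster, "y0")
  col <- round((x - x0) / ps) + 1L
  row <- round((y0 - y) / ps) + 1L
  ok <- row >= 1L & row <= nrow(raster) & col >= 1L & col <= ncol(raster)
  out <- rep(NA_real_, length(x))
  out[ok] <- raster[cbind(row[ok], col[ok])]
  out
}

new_raster <- function(mat, pixel_size_mm, x0, y0) {
  attr(mat, "pixel_size_mm") <- pixel_size_mm
  attr(mat, "x0") <- x0
  attr(mat, "y0") <- y0
  mat
}

## copy raster geometry attributes from template onto mat
raster_like <- function(mat, template) {
  new_raster(mat,
             attr(template, "pixel_size_mm"),
             attr(template, "x0"),
             attr(template, "y0"))
}

gaussian_kernel_1d <- function(sigma_px) {
  if (sigma_px <= 0) return(1)
  half <- max(1L, ceiling(3 * sigma_px))
  x <- seq(-half, half)
  k <- exp(-x^2 / (2 * sigma_px^2))
  k / sum(k)
}

## separable Gaussian blur of a plain matrix (zero padding at the border)
blur_matrix <- function(mat, sigma_px) {
  if (sigma_px <= 0) return(mat)
  k <- gaussian_kernel_1d(sigma_px)
  half <- (length(k) - 1L) / 2L
  conv1 <- function(m, along_rows) {
    n <- if (along_rows) nrow(m) else ncol(m)
    band <- Matrix::bandSparse(n, n, k = seq(-half, half),
                               diagonals = lapply(seq_along(k), function(i) {
                                 rep(k[i], n - abs(i - 1L - half))
                               }))
    if (along_rows) as.matrix(band %*% m) else as.matrix(m %*% band)
  }
  conv1(conv1(mat, TRUE), FALSE)
}

#' Masked, renormalized Gaussian smoothing
#'
#' Smooths `field` on the pixels where `mask` is TRUE with a Gaussian kernel
#' renormalized over the mask, so values outside the mask never bleed in and
#' the smoothing is a convex combination of in-mask values (a constant field
#' stays constant, and smoothed values stay within the in-mask range).
#'
#' @param field numeric matrix; values outside the mask are ignored.
#' @param mask logical matrix, same dim.
#' @param sigma_px Gaussian standard deviation in pixels; 0 returns `field`
#'   unchanged on the mask.
#' @return matrix equal to `field` outside the mask and smoothed inside.
#' @export
masked_blur <- function(field, mask, sigma_px) {
  stopifnot(all(dim(field) == dim(mask)))
  if (sigma_px <= 0) return(field)
  f <- field
  f[!mask] <- 0
  num <- blur_matrix(f, sigma_px)
  den <- blur_matrix(mask * 1, sigma_px)
  out <- field
  out[mask] <- num[mask] / den[mask]
  out
}
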