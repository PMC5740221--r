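# Independent oracles used to check the package implementations.

# Incompressible plane-strain neo-Hookean cylinder inflation: pressure as a
# function of the deformed inner radius, by numerical integration of the
# radial equilibrium equation with the incompressibility map
# r^2 = R^2 + a^2 - A^2.
oracle_cylinder_pressure <- function(a, A, B, C) {
  stats::integrate(function(R) {
    r2 <- R^2 + a^2 - A^2
    2 * C * (r2 / R^2 - R^2 / r2) * (R / r2)
  }, A, B, rel.tol = 1e-10)$value
}

oracle_cylinder_radius <- function(P, A, B, C) {
  stats::uniroot(function(a) oracle_cylinder_pressure(a, A, B, C) - P,
                 c(A, 5 * A), tol = 1e-12)$root
}

# Plane-strain Lame solution (linear elasticity, incompressible limit):
# hoop stress at radius r of an annulus A..B under internal pressure p.
oracle_lame_hoop <- function(p, A, B, r) {
  p * A^2 / (B^2 - A^2) * (1 + B^2 / r^2)
}

# Globally optimal 1-D k-means by exhaustive search over contiguous
# partitions of the sorted values (optimal 1-D clusterings are contiguous).
oracle_kmeans_1d <- function(x, k) {
  xs <- sort(x)
  n <- length(xs)
  best <- list(wcss = Inf)
  # compositions of n into k positive parts
  splits <- utils::combn(n - 1, k - 1)
  for (j in seq_len(ncol(splits))) {
    bounds <- c(0, splits[, j], n)
    wcss <- 0
    means <- numeric(k)
    for (i in seq_len(k)) {
      seg <- xs[(bounds[i] + 1):bounds[i + 1]]
      means[i] <- mean(seg)
      wcss <- wcss + sum((seg - means[i])^2)
    }
    if (wcss < best$wcss) best <- list(wcss = wcss, means = means)
  }
  best
}

# Connected-component sizes by breadth-first flood fill (8-connectivity);
# reference for the igraph-based component labelling.
oracle_component_sizes <- function(labels) {
  nr <- nrow(labels); nc <- ncol(labels)
  seen <- matrix(FALSE, nr, nc)
  sizes <- integer(0)
  for (r0 in seq_len(nr)) for (c0 in seq_len(nc)) {
    if (labels[r0, c0] == 0 || seen[r0, c0]) next
    lab <- labels[r0, c0]
    queue <- list(c(r0, c0)); seen[r0, c0] <- TRUE; size <- 0L
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]; size <- size + 1L
      for (dr in -1:1) for (dc in -1:1) {
        r <- p[1] + dr; c <- p[2] + dc
        if (r < 1 || r > nr || c < 1 || c > nc) next
        if (!seen[r, c] && labels[r, c] == lab) {
          seen[r, c] <- TRUE
          queue[[length(queue) + 1]] <- c(r, c)
        }
      }
    }
    sizes <- c(sizes, size)
  }
  sort(sizes)
}

# Analytic Sobol indices of the additive model Y = sum b_i X_i with
# X_i iid uniform: S_i = b_i^2 / sum(b^2).
oracle_additive_sobol <- function(b) b^2 / sum(b^2)
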