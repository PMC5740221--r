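#' Configuration for intensity-based intima clustering
#'
#' @param n_clusters number of clusters (4 in the study design: enough to
#'   capture presence/absence of the mechanically relevant constituents).
#' @param max_iterations iteration cap for the Lloyd fixed-point loop.
#' @param seed integer seed for the random initial means.
#' @param min_island_pixels connected components (8-connectivity) smaller
#'   than this are merged away during cleanup; default 25 (~ one 5x5 patch).
#' @param n_restarts independent random initialisations; the run with the
#'   lowest within-cluster sum of squares is kept.
#' @return an object of class `cluster_config`.
#' @export
cluster_config <- function(n_clusters = 4,
                           max_iterations = 100,
                           seed = 1L,
                           min_island_pixels = 25,
                           n_restarts = 10) {
  if (n_clusters < 1) stop_param("n_clusters must be >= 1")
  if (min_island_pixels < 1) stop_param("min_island_pixels must be >= 1")
  if (n_restarts < 1) stop_param("n_restarts must be >= 1")
  structure(list(n_clusters = as.integer(n_clusters),
                 max_iterations = as.integer(max_iterations),
                 seed = as.integer(seed),
                 min_island_pixels = as.integer(min_island_pixels),
                 n_restarts = as.integer(n_restarts)),
            class = "cluster_config")
}

## nearest-mean assignment in 1-D; ties at midpoints go to the lower-mean
## cluster. means must be sorted ascending.
assign_nearest <- function(x, means) {
  if (length(means) == 1L) return(rep(1L, length(x)))
  mids <- (means[-1] + means[-length(means)]) / 2
  findInterval(x, mids, left.open = TRUE) + 1L
}

wcss_of <- function(x, idx, means) sum((x - means[idx])^2)

## one Lloyd run from given initial means; returns fixed point
lloyd_run <- function(x, means0, k, max_iterations) {
  means <- sort(means0)
  n_reseed <- 0L
  wcss_trace <- numeric(0)
  iter <- 0L
  fixed_point <- FALSE
  repeat {
    iter <- iter + 1L
    idx <- assign_nearest(x, means)
    sums <- tabulate(idx, k)
    new_means <- means
    filled <- sums > 0
    if (any(filled)) {
      m <- rowsum(x, idx)
      new_means[sort(unique(idx))] <- m[, 1] / sums[sums > 0]
    }
    if (any(!filled)) {
      # re-seed an emptied cluster at the intensity farthest from the means
      for (j in which(!filled)) {
        d <- Reduce(pmin, lapply(new_means[filled], function(m) abs(x - m)))
        new_means[j] <- x[which.max(d)]
        n_reseed <- n_reseed + 1L
      }
    }
    new_means <- sort(new_means)
    wcss_trace <- c(wcss_trace, wcss_of(x, assign_nearest(x, new_means),
                                        new_means))
    if (isTRUE(all.equal(new_means, means, tolerance = 0)) ||
        identical(new_means, means)) {
      fixed_point <- TRUE
      means <- new_means
      break
    }
    means <- new_means
    if (iter >= max_iterations) break
  }
  idx <- assign_nearest(x, means)
  list(means = means, idx = idx, wcss = wcss_of(x, idx, means),
       iterations = iter, fixed_point = fixed_point,
       wcss_trace = wcss_trace, n_reseed = n_reseed)
}

#' Cluster the intima by greyscale intensity (iterative k-means)
#'
#' Lloyd's algorithm on the 1-D pixel intensities of the intima mask:
#' random initial means drawn uniformly in the observed intensity range,
#' alternating nearest-mean assignment and mean update until the means stop
#' changing. Several restarts are run and the solution with the lowest
#' within-cluster sum of squares is kept. Labels are canonically ordered by
#' ascending cluster mean.
#'
#' @param section a textured `plaque_section`.
#' @param cfg a [cluster_config()].
#' @return an object of class `cluster_map`: `labels` (raster, 1..k on
#'   intima, 0 elsewhere), `cluster_mean_intensity`, `iterations_used`,
#'   `fixed_point`, `wcss`, `wcss_trace`, `config`.
#' @export
kmeans_intensity <- function(section, cfg) {
  if (is.null(section$intensity))
    stop_param("section has no intensity image; run render_intima_texture first")
  mask <- section$label_map == LBL_INTIMA
  if (!any(mask)) stop_param("empty intima mask")
  x <- section$intensity[mask]
  k <- cfg$n_clusters
  if (length(unique(x)) < k)
    stop_param("fewer distinct intensity values (", length(unique(x)),
               ") than clusters (", k, ")")

  set.seed(cfg$seed)
  best <- NULL
  for (r in seq_len(cfg$n_restarts)) {
    means0 <- runif(k, min(x), max(x))
    run <- lloyd_run(x, means0, k, cfg$max_iterations)
    if (is.null(best) || run$wcss < best$wcss) best <- run
  }

  labels <- matrix(0L, nrow(section$label_map), ncol(section$label_map))
  labels[mask] <- best$idx
  structure(list(labels = raster_like(labels, section$label_map),
                 cluster_mean_intensity = best$means,
                 iterations_used = best$iterations,
                 fixed_point = best$fixed_point,
                 wcss = best$wcss,
                 wcss_trace = best$wcss_trace,
                 n_reseed = best$n_reseed,
                 config = cfg),
            class = "cluster_map")
}

#' @export
print.cluster_map <- function(x, ...) {
  cat("cluster_map:", length(x$cluster_mean_intensity), "clusters, means",
      paste(round(x$cluster_mean_intensity, 1), collapse = ", "),
      "|", x$iterations_used, "iterations",
      if (x$fixed_point) "(fixed point)" else "(iteration cap hit)", "\n")
  invisible(x)
}

## connected components of same-label pixels, 8-connectivity, via an
## igraph pixel graph restricted to the labelled mask
label_components <- function(labels) {
  nr <- nrow(labels); nc <- ncol(labels)
  idx <- matrix(seq_len(nr * nc), nr, nc)
  shifts <- list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(1L, -1L))
  edges <- vector("list", length(shifts))
  for (s in seq_along(shifts)) {
    dr <- shifts[[s]][1]; dc <- shifts[[s]][2]
    r1 <- seq_len(nr - dr)
    c1 <- if (dc >= 0) seq_len(nc - dc) else seq(1 - dc, nc)
    a <- idx[r1, c1, drop = FALSE]
    b <- idx[r1 + dr, c1 + dc, drop = FALSE]
    keep <- labels[a] == labels[b] & labels[a] > 0L
    edges[[s]] <- cbind(a[keep], b[keep])
  }
  ed <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = nr * nc, directed = FALSE)
  g <- igraph::add_edges(g, t(ed))
  comp <- igraph::components(g)$membership
  comp[labels == 0L] <- NA_integer_
  matrix(comp, nr, nc)
}

#' Remove isolated cluster islands (erosion and merging)
#'
#' Finds same-label connected components (8-connectivity) smaller than
#' `min_island_pixels` and reassigns their pixels to the adjacent cluster
#' whose mean intensity is closest to the island's own cluster mean (ties to
#' the lower mean). Repeats until no small island remains. No intima pixel
#' ever becomes unlabelled, so intima coverage is conserved; the operation is
#' idempotent on already clean maps.
#'
#' @param cmap a `cluster_map`.
#' @param cfg a [cluster_config()]; only `min_island_pixels` is used.
#' @return a cleaned `cluster_map` (cluster means are kept as fitted).
#' @export
clean_clusters <- function(cmap, cfg) {
  labels <- cmap$labels
  means <- cmap$cluster_mean_intensity
  nr <- nrow(labels); nc <- ncol(labels)
  repeat {
    comp <- label_components(labels)
    sizes <- table(comp[!is.na(comp)])
    small <- as.integer(names(sizes)[sizes < cfg$min_island_pixels])
    if (length(small) == 0) break
    # smallest islands first, component id as deterministic tie-break
    small <- small[order(sizes[as.character(small)], small)]
    changed <- FALSE
    for (cid in small) {
      sel <- which(!is.na(comp) & comp == cid)
      own_label <- labels[sel[1]]
      # adjacent labels: 8-neighbourhood of island pixels, different label
      rows <- (sel - 1L) %% nr + 1L
      cols <- (sel - 1L) %/% nr + 1L
      nb_lab <- integer(0)
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        rr <- rows + dr; cc <- cols + dc
        ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
        v <- labels[cbind(rr[ok], cc[ok])]
        nb_lab <- c(nb_lab, v[v > 0 & v != own_label])
      }
      if (length(nb_lab) == 0) next  # isolated fragment: nothing to merge into
      cand <- sort(unique(nb_lab))
      d <- abs(means[cand] - means[own_label])
      new_label <- cand[which.min(d)]  # which.min ties -> first = lower mean
      labels[sel] <- new_label
      changed <- TRUE
    }
    if (!changed) break
  }
  cmap$labels <- raster_like(labels, cmap$labels)
  cmap$cleaned <- TRUE
  cmap
}
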