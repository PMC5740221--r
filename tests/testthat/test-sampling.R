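test_that("LHS places exactly one sample per stratum in each dimension", {
  cfg <- sampling_config(n_samples = 100, seed = 42)
  samples <- latin_hypercube(cfg)
  expect_length(samples, 100)
  vals <- do.call(rbind, lapply(samples, `[[`, "cluster_moduli"))
  width <- (cfg$modulus_high - cfg$modulus_low) / cfg$n_samples
  expect_equal(width, 1.48)
  for (d in 1:4) {
    stratum <- floor((vals[, d] - cfg$modulus_low) / width)
    expect_equal(sort(stratum), 0:99)
  }
  expect_true(all(vals >= 1 & vals <= 149))
})

test_that("LHS is deterministic under seed; edge cases behave", {
  a <- latin_hypercube(sampling_config(n_samples = 7, seed = 1))
  b <- latin_hypercube(sampling_config(n_samples = 7, seed = 1))
  expect_identical(a, b)
  one <- latin_hypercube(sampling_config(n_samples = 1))
  expect_length(one, 1)
  expect_true(all(one[[1]]$cluster_moduli >= 1 &
                    one[[1]]$cluster_moduli <= 149))
  # n = 4 in one dimension: one sample per quarter of the range
  cfg <- sampling_config(n_samples = 4, n_clusters = 1,
                         modulus_low = 0.5, modulus_high = 4.5,
                         homogeneous_modulus = 2.5, seed = 3)
  v <- sort(vapply(latin_hypercube(cfg), function(s) s$cluster_moduli[1],
                   numeric(1)))
  expect_equal(findInterval(v, c(0.5, 1.5, 2.5, 3.5, 4.5),
                            rightmost.closed = TRUE), 1:4)
})

test_that("equal cluster moduli smooth to a constant field", {
  cp <- coarse_plaque()
  sm <- structure(list(cluster_moduli = rep(75, 4), sample_index = 1L),
                  class = "stiffness_sample")
  cm <- kmeans_intensity(cp$section, cluster_config(seed = 2))
  mm <- build_modulus_map(cm, sm, cp$sampling, cp$section)
  v <- mm$modulus_field[cp$section$label_map == 2L]
  expect_equal(v, rep(75, length(v)), tolerance = 1e-13)
})

test_that("zero smoothing returns the piecewise-constant cluster map", {
  cp <- coarse_plaque()
  cm <- kmeans_intensity(cp$section, cluster_config(seed = 2))
  cfg <- cp$sampling
  cfg$smoothing_sigma <- 0
  sm <- structure(list(cluster_moduli = c(10, 40, 90, 140),
                       sample_index = 1L), class = "stiffness_sample")
  mm <- build_modulus_map(cm, sm, cfg, cp$section)
  mask <- cp$section$label_map == 2L
  expect_equal(mm$modulus_field[mask],
               sm$cluster_moduli[cm$labels[mask]])
})

test_that("a blurred two-sided step passes through the midpoint", {
  # half-planes at 1 and 149 kPa, sigma = 2 px: the profile is an error
  # function and the interface midline sits at the 75 kPa midpoint
  field <- cbind(matrix(1, 41, 21), matrix(149, 41, 21))
  mask <- matrix(TRUE, 41, 42)
  sm <- masked_blur(field, mask, 2)
  mid <- (sm[21, 21] + sm[21, 22]) / 2
  expect_lt(abs(mid - 75) / 75, 0.01)
})

test_that("smoothing is a convex combination and respects regions", {
  cp <- coarse_plaque()
  cm <- kmeans_intensity(cp$section, cluster_config(seed = 2))
  sm <- structure(list(cluster_moduli = c(3, 50, 100, 140),
                       sample_index = 1L), class = "stiffness_sample")
  mm <- build_modulus_map(cm, sm, cp$sampling, cp$section)
  lab <- cp$section$label_map
  v <- mm$modulus_field[lab == 2L]
  expect_true(all(v >= 3 - 1e-9 & v <= 140 + 1e-9))
  expect_true(all(mm$modulus_field[lab == 1L] == 200))
  expect_true(all(mm$modulus_field[lab == 3L] == 0.5))
  expect_true(all(mm$modulus_field[lab == 0L] == 0.001))
  expect_true(all(mm$modulus_field > 0, na.rm = TRUE))
})

test_that("homogeneous map is 75 kPa on the intima, fixed elsewhere", {
  cp <- coarse_plaque()
  mm <- homogeneous_map(cp$section, cp$sampling)
  lab <- cp$section$label_map
  expect_true(all(mm$modulus_field[lab == 2L] == 75))
  vals <- unique(as.vector(mm$modulus_field))
  expect_true(all(vals[!is.na(vals)] %in% c(75, 200, 0.5, 0.001)))
  # 75 is the midpoint of the sampled range
  cfg <- cp$sampling
  expect_equal((cfg$modulus_low + cfg$modulus_high) / 2,
               cfg$homogeneous_modulus)
})

test_that("sampling configuration is validated", {
  expect_error(sampling_config(modulus_low = 0), "modulus_low")
  expect_error(sampling_config(homogeneous_modulus = 500), "homogeneous")
  expect_error(sampling_config(smoothing_sigma = -1), "smoothing")
})
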