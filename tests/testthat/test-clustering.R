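test_that("k-means reaches the known optimum on well-separated pairs", {
  x <- c(10, 12, 50, 52, 200, 202, 240, 242)
  s <- pixel_section(matrix(x, 2, 4))
  cm <- kmeans_intensity(s, cluster_config(n_clusters = 4, n_restarts = 20,
                                           seed = 5))
  expect_equal(cm$cluster_mean_intensity, c(11, 51, 201, 241))
  expect_true(cm$fixed_point)
  # agrees with the exhaustive contiguous-partition oracle
  oracle <- oracle_kmeans_1d(x, 4)
  expect_equal(cm$wcss, oracle$wcss, tolerance = 1e-12)
})

test_that("constant image with a single cluster returns the constant", {
  s <- pixel_section(matrix(77, 3, 3))
  cm <- kmeans_intensity(s, cluster_config(n_clusters = 1))
  expect_equal(cm$cluster_mean_intensity, 77)
  expect_true(all(cm$labels[s$label_map == 2L] == 1L))
})

test_that("k-means validates inputs and orders labels canonically", {
  s <- pixel_section(matrix(c(1, 1, 2, 2), 2, 2))
  expect_error(kmeans_intensity(s, cluster_config(n_clusters = 4)),
               "distinct")
  st <- small_textured_section()
  cm <- kmeans_intensity(st, cluster_config(seed = 2))
  expect_false(is.unsorted(cm$cluster_mean_intensity, strictly = TRUE))
  lab <- cm$labels[st$label_map == 2L]
  expect_true(all(lab %in% 1:4))
  expect_true(all(cm$labels[st$label_map != 2L] == 0L))
})

test_that("within-cluster sum of squares is non-increasing per iteration", {
  st <- small_textured_section()
  cm <- kmeans_intensity(st, cluster_config(seed = 9, n_restarts = 1))
  expect_true(all(diff(cm$wcss_trace) <= 1e-9))
  expect_lte(cm$iterations_used, cluster_config()$max_iterations)
  expect_true(cm$fixed_point)
})

test_that("restarts attain the brute-force optimum on tiny instances", {
  set.seed(42)
  for (trial in 1:5) {
    n <- sample(8:12, 1)
    x <- round(stats::runif(n, 0, 255), 1)
    if (length(unique(x)) < 4) next
    s <- pixel_section(matrix(c(x, rep(NA, 12 - n)), 3, 4))
    cm <- kmeans_intensity(s, cluster_config(n_clusters = 4,
                                             n_restarts = 25, seed = trial))
    oracle <- oracle_kmeans_1d(x, 4)
    expect_equal(cm$wcss, oracle$wcss, tolerance = 1e-9,
                 label = paste("trial", trial))
  }
})

test_that("cluster recovery on synthetic textures is within 10 intensity units", {
  st <- small_textured_section()
  cm <- kmeans_intensity(st, cluster_config(seed = 31))
  modes <- st$texture_params$mode_mean_intensities
  expect_lt(max(abs(cm$cluster_mean_intensity - modes)), 10)
})

test_that("island cleanup removes small components and conserves pixels", {
  # cluster 1 field with a single 1-pixel island of cluster 3
  m <- matrix(10, 9, 9)
  m[5, 5] <- 200
  s <- pixel_section(m)
  cm <- kmeans_intensity(s, cluster_config(n_clusters = 2, n_restarts = 5,
                                           seed = 1))
  cfg <- cluster_config(n_clusters = 2, min_island_pixels = 5)
  cleaned <- clean_clusters(cm, cfg)
  expect_true(all(cleaned$labels[s$label_map == 2L] == 1L))
  # idempotence
  again <- clean_clusters(cleaned, cfg)
  expect_identical(again$labels, cleaned$labels)
})

test_that("checkerboard cleanup leaves no tiny components, pixel count fixed", {
  n <- 8
  m <- matrix(ifelse((row(diag(n)) + col(diag(n))) %% 2 == 0, 40, 200), n, n)
  s <- pixel_section(m)
  cm <- kmeans_intensity(s, cluster_config(n_clusters = 2, n_restarts = 5,
                                           seed = 3))
  cfg <- cluster_config(n_clusters = 2, min_island_pixels = 2)
  cleaned <- clean_clusters(cm, cfg)
  sizes <- oracle_component_sizes(cleaned$labels)
  expect_true(all(sizes >= 2) || length(sizes) == 1)
  expect_equal(sum(cleaned$labels > 0), sum(cm$labels > 0))
})

test_that("component labelling matches the flood-fill oracle", {
  set.seed(8)
  lab <- matrix(sample(0:3, 15 * 15, TRUE), 15, 15)
  comp <- plaqhet:::label_components(lab)
  sizes <- sort(as.integer(table(comp[!is.na(comp)])))
  expect_equal(sizes, oracle_component_sizes(lab))
})
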