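test_that("job enumeration closes over plaques and samples", {
  d12 <- study_design(n_heterogeneous_samples = 100)
  jobs <- enumerate_jobs(d12)
  expect_equal(nrow(jobs), 12 * 101)
  one <- study_design(plaque_params = default_plaque_set(1),
                      n_heterogeneous_samples = 0)
  expect_equal(nrow(enumerate_jobs(one)), 1)
  three <- study_design(plaque_params = default_plaque_set(3),
                        n_heterogeneous_samples = 10)
  jobs3 <- enumerate_jobs(three)
  expect_equal(nrow(jobs3), 33)
  expect_equal(unique(table(jobs3$plaque_id)), 11L)
  expect_true(all(jobs3$seed >= 0 & jobs3$seed < 2^31))
  # derived seeds are deterministic and stage-specific
  expect_identical(enumerate_jobs(three)$seed, jobs3$seed)
  expect_false(derive_seed(1, "plaque01", "texture") ==
                 derive_seed(1, "plaque01", "cluster"))
})

test_that("plaque summaries implement the interpolated quantile convention", {
  s <- summarize_plaque(c(1, 2, 3, 4), homogeneous_pcs = 2.2)
  expect_equal(s$pcs_median, 2.5)
  expect_equal(s$pcs_iqr_low, 1.75)
  expect_equal(s$pcs_iqr_high, 3.25)
  expect_equal(s$pcs_range, 3)
  single <- summarize_plaque(7, 5)
  expect_equal(single$pcs_median, 7)
  expect_equal(single$pcs_min, 7)
  expect_equal(single$pcs_max, 7)
  expect_equal(single$pcs_range, 0)
  wide <- summarize_plaque(c(9, 20, 60, 100, 147), 62)
  expect_equal(wide$pcs_min, 9)
  expect_equal(wide$pcs_max, 147)
  expect_equal(wide$pcs_homogeneous, 62)
  expect_true(wide$pcs_min <= wide$pcs_iqr_low &
                wide$pcs_iqr_low <= wide$pcs_median &
                wide$pcs_median <= wide$pcs_iqr_high &
                wide$pcs_iqr_high <= wide$pcs_max)
  expect_error(summarize_plaque(numeric(0), 1), "no heterogeneous")
})

test_that("the range-vs-homogeneous regression matches hand computations", {
  mk <- function(x, y) structure(list(pcs_homogeneous = x, pcs_range = y),
                                 class = "plaque_summary")
  col <- lapply(1:4, function(i) mk(i, 2 * i))
  fit <- correlate_homogeneous_vs_range(col)
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 0, tolerance = 1e-12)
  flat <- lapply(1:4, function(i) mk(i, 5))
  expect_false(correlate_homogeneous_vs_range(flat)$defined)
  pts <- list(mk(1, 1), mk(2, 3), mk(3, 2))
  expect_equal(correlate_homogeneous_vs_range(pts)$r_squared, 0.25)
  expect_error(correlate_homogeneous_vs_range(pts[1:2]), "at least 3")
})

test_that("a tiny study runs end to end and is seed-reproducible", {
  plaques <- default_plaque_set(2, cap_range = c(0.30, 0.15),
                                image_resolution = 20)
  design <- study_design(plaque_params = plaques,
                         n_heterogeneous_samples = 2,
                         target_edge_length = 0.16,
                         master_seed = 99L)
  r1 <- run_study(design, verbose = FALSE)
  expect_equal(nrow(r1$pcs), 2 * 3)
  expect_true(all(is.finite(r1$pcs$pcs_kPa)))
  expect_equal(nrow(r1$summary_table), 2)
  expect_true(all(r1$summary_table$n_failed_solves == 0))
  r2 <- run_study(design, verbose = FALSE)
  expect_identical(r1$pcs, r2$pcs)
})
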