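# direct band-table builder for exact-arithmetic cases
band_rows <- function(cid, surface, total, actin = 50, n_exp = 4,
                      treatment = "mock") {
  data.frame(construct_id = cid, experiment_id = paste0("E", seq_len(n_exp)),
             treatment = treatment, surface = surface, total = total,
             actin = actin, stringsAsFactors = FALSE)
}

test_that("surface ratio arithmetic: 0.4x surface over 0.5x total is 80% corrected", {
  bands <- rbind(band_rows("WT", 100, 100),
                 band_rows("v", 40, 50))
  res <- surface_levels(bands)
  expect_equal(res$raw_surface_pct_of_wt, 40)
  expect_equal(res$corrected_surface_pct_of_wt, 80)
})

test_that("a construct identical to WT scores 100/100 and is unaffected", {
  bands <- rbind(band_rows("WT", 100, 100), band_rows("v", 100, 100))
  res <- run_surface_pipeline(bands)
  expect_equal(res$raw_surface_pct_of_wt, 100)
  expect_equal(res$corrected_surface_pct_of_wt, 100)
  expect_equal(res$mechanism, "unaffected")
  expect_false(res$severe)
})

test_that("mechanism rules separate transport deficiency from degradation", {
  cfg <- calibration_config()
  td <- mechanism_call(p_raw = 1e-4, p_corr = 1e-4, raw_pct = 25, corr_pct = 30,
                       config = cfg)
  expect_equal(td$mechanism, "transport_deficient"); expect_true(td$severe)
  td2 <- mechanism_call(1e-4, 0.01, 60, 70, cfg)
  expect_equal(td2$mechanism, "transport_deficient"); expect_false(td2$severe)
  dp <- mechanism_call(1e-3, 0.4, 40, 98, cfg)
  expect_equal(dp$mechanism, "degradation_prone"); expect_true(dp$severe)
  ok <- mechanism_call(0.3, 0.6, 100, 100, cfg)
  expect_equal(ok$mechanism, "unaffected"); expect_false(ok$severe)
  expect_error(mechanism_call(NA, 0.5, 100, 100, cfg), "insufficient")
})

test_that("corrected surface is invariant to total-lane exposure within an experiment", {
  st <- data.frame(construct_id = c("a", "b"), raw_pct = c(40, 90),
                   corr_pct = c(80, 95))
  spec <- generator_spec(seed = 5, sigma = 0.05, surface_truth = st,
                         activities = c(a = 10))
  bands <- generate_bands(spec)
  base <- surface_levels(bands)
  scaled <- bands
  idx <- scaled$experiment_id == "E3"
  scaled$total[idx] <- scaled$total[idx] * 4.2  # exposure change on one blot
  res <- surface_levels(scaled)
  expect_equal(res$corrected_surface_pct_of_wt, base$corrected_surface_pct_of_wt,
               tolerance = 1e-12)
  expect_equal(res$raw_surface_pct_of_wt, base$raw_surface_pct_of_wt)
})

test_that("noisy densitometry recovers the generated truth within tolerance", {
  st <- data.frame(construct_id = c("td", "dp", "ok"),
                   raw_pct = c(30, 40, 100), corr_pct = c(30, 95, 100))
  spec <- generator_spec(seed = 17, sigma = 0.05, surface_truth = st,
                         activities = c(td = 10))
  res <- run_surface_pipeline(generate_bands(spec))
  res <- res[match(st$construct_id, res$construct_id), ]
  expect_true(all(abs(res$raw_surface_pct_of_wt - st$raw_pct) < 15))
  expect_true(all(abs(res$corrected_surface_pct_of_wt - st$corr_pct) < 15))
  expect_equal(res$mechanism,
               c("transport_deficient", "degradation_prone", "unaffected"))
})

test_that("zero-noise densitometry recovers the truth exactly", {
  st <- data.frame(construct_id = c("td", "dp"), raw_pct = c(40, 40),
                   corr_pct = c(80, 100))
  spec <- generator_spec(seed = 5, sigma = 0, jitter = 0, surface_truth = st,
                         activities = c(td = 10))
  res <- surface_levels(generate_bands(spec))
  res <- res[match(st$construct_id, res$construct_id), ]
  expect_equal(res$raw_surface_pct_of_wt, st$raw_pct)
  expect_equal(res$corrected_surface_pct_of_wt, st$corr_pct)
})

test_that("degenerate band tables are rejected", {
  bands <- rbind(band_rows("WT", 0, 100), band_rows("v", 10, 50))
  expect_error(surface_levels(bands), "WT surface")
  bands2 <- rbind(band_rows("WT", 100, 100, actin = 0), band_rows("v", 10, 50))
  expect_error(surface_levels(bands2), "loading-control")
  expect_error(surface_levels(band_rows("v", 10, 50)), "no WT")
})
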