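test_that("raw efflux is the medium share of total signal", {
  expect_equal(raw_efflux(c(300, 300, 300), c(700, 700, 700)), 0.30)
  expect_equal(raw_efflux(c(0, 0, 0), c(500, 500, 500)), 0)
  # frozen from direct evaluation of the formula on the six numbers:
  # mean(250,310,340) / (mean(250,310,340) + mean(720,690,710)) = 0.29801324...
  expect_equal(raw_efflux(c(250, 310, 340), c(720, 690, 710)),
               0.298013245033113, tolerance = 1e-12)
  expect_error(raw_efflux(c(0, 0), c(0, 0)), "undefined efflux")
  expect_error(raw_efflux(c(-1, 2, 3), c(1, 1, 1)), "non-negative")
})

test_that("leakage correction subtracts the paired no-acceptor well-set", {
  acc <- efflux_measurement("p.A1B", "E1", "acceptor", "mock",
                            c(300, 300, 300), c(700, 700, 700))
  noa <- efflux_measurement("p.A1B", "E1", "no_acceptor", "mock",
                            c(50, 50, 50), c(950, 950, 950))
  expect_equal(corrected_efflux(acc, noa), 0.25)
  self <- efflux_measurement("p.A1B", "E1", "no_acceptor", "mock",
                             c(300, 300, 300), c(700, 700, 700))
  expect_equal(corrected_efflux(acc, self), 0)
  # stepwise oracle on arbitrary triplicates
  set.seed(42)
  m1 <- runif(3, 100, 400); l1 <- runif(3, 500, 900)
  m2 <- runif(3, 10, 60); l2 <- runif(3, 500, 900)
  a <- efflux_measurement("v", "E1", "acceptor", "mock", m1, l1)
  b <- efflux_measurement("v", "E1", "no_acceptor", "mock", m2, l2)
  expect_equal(corrected_efflux(a, b),
               mean(m1) / (mean(m1) + mean(l1)) - mean(m2) / (mean(m2) + mean(l2)))
  wrong <- efflux_measurement("v", "E2", "no_acceptor", "mock", m2, l2)
  expect_error(corrected_efflux(a, wrong), "pairing error")
})

test_that("WT normalization is per experiment and drops bad experiments", {
  expect_equal(unname(normalize_to_wt(c(E1 = 0.11), c(E1 = 0.22))), 50)
  same <- c(E1 = 0.2, E2 = 0.25, E3 = 0.18)
  expect_equal(unname(normalize_to_wt(same, same)), rep(100, 3))
  set.seed(7)
  ratios <- runif(4, 0.2, 1.2)
  wt <- runif(4, 0.1, 0.3)
  names(ratios) <- names(wt) <- paste0("E", 1:4)
  rel <- normalize_to_wt(ratios * wt, wt)
  expect_equal(mean(rel), mean(100 * ratios))
  expect_equal(sd(rel), sd(100 * ratios))
  expect_warning(out <- normalize_to_wt(c(E1 = 0.1, E2 = 0.1),
                                        c(E1 = 0.2, E2 = -0.01)), "dropped")
  expect_named(out, "E1")
  expect_error(suppressWarnings(normalize_to_wt(c(E1 = 0.1), c(E1 = 0))),
               "no experiment")
})

test_that("categories follow the thresholds with exclusive boundaries", {
  cfg <- calibration_config()
  expect_equal(categorize_efflux(84, cfg), "normal")
  expect_equal(categorize_efflux(9, cfg), "loss_of_function")
  expect_equal(categorize_efflux(c(41, 58, 80), cfg), rep("uncertain", 3))
  expect_equal(categorize_efflux(40.99, cfg), "loss_of_function")
  expect_equal(categorize_efflux(80.01, cfg), "normal")
  # alternative clinically anchored cutoff: 58 itself stays uncertain
  expect_equal(categorize_efflux(58, cfg, use_alternative = TRUE), "uncertain")
  expect_equal(categorize_efflux(57.9, cfg, use_alternative = TRUE),
               "loss_of_function")
  # monotone: raising the mean never moves toward loss of function
  ord <- c(loss_of_function = 1, uncertain = 2, normal = 3)
  grid <- seq(0, 120, by = 0.5)
  lev <- ord[categorize_efflux(grid, cfg)]
  expect_true(all(diff(lev) >= 0))
})

test_that("the pipeline inverts a noise-free plate exactly", {
  spec <- generator_spec(seed = 1, sigma = 0, jitter = 0,
                         activities = c(p.A10V = 50))
  res <- run_efflux_pipeline(generate_plates(spec))
  expect_equal(res$mean_rel_efflux_pct, 50)
  expect_equal(res$category, "uncertain")
  expect_equal(res$n, 4L)
})

test_that("the pipeline is invariant to row order and per-experiment rescaling", {
  spec <- generator_spec(seed = 9, sigma = 0.1, jitter = 0.15,
                         activities = c(v1 = 30, v2 = 90))
  plates <- generate_plates(spec)
  base <- run_efflux_pipeline(plates)

  shuffled <- plates[sample(nrow(plates)), ]
  expect_equal(as.data.frame(run_efflux_pipeline(shuffled)),
               as.data.frame(base))

  scaled <- plates
  idx <- scaled$experiment_id == "E2"
  scaled[idx, c("rep1", "rep2", "rep3")] <-
    scaled[idx, c("rep1", "rep2", "rep3")] * 7.3
  expect_equal(as.data.frame(run_efflux_pipeline(scaled)),
               as.data.frame(base), tolerance = 1e-12)
})

test_that("pipeline errors when controls are missing", {
  spec <- generator_spec(seed = 2, sigma = 0, jitter = 0,
                         activities = c(v = 50))
  plates <- generate_plates(spec)
  expect_error(run_efflux_pipeline(plates[plates$construct_id != "mock", ]),
               "mock")
  expect_error(run_efflux_pipeline(plates[plates$construct_id != "WT", ]),
               "WT")
})

test_that("study replicates reproduce their tabulated mean and SD exactly", {
  s <- abca1_synthetic_study()
  reps <- as.matrix(s[paste0("rep", 1:4)])
  expect_equal(rowMeans(reps), s$mean_rel_efflux_pct)
  expect_equal(apply(reps, 1, sd), s$sd_pct)
})
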