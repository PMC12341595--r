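test_that("criterion tokens parse to code, strength and direction", {
  expect_equal(parse_criterion("PM2"),
               list(code = "PM2", strength = "moderate", benign = FALSE,
                    token = "PM2"))
  expect_equal(parse_criterion("PP4_strong")$strength, "strong")
  expect_equal(parse_criterion("PM1_supporting")$strength, "supporting")
  expect_equal(parse_criterion("BS3_moderate")$benign, TRUE)
  expect_equal(parse_criterion("BA1")$strength, "stand_alone")
  # normalization drops a redundant native-strength suffix
  expect_equal(parse_criterion("PM2_moderate")$token, "PM2")
  expect_error(parse_criterion("PX9"), "unknown ACMG")
  expect_error(parse_criterion("PM2_huge"), "unknown strength")
  expect_error(parse_criterion("BS1_very_strong"), "benign")
  expect_error(parse_criterion("PS3_stand_alone"), "stand_alone")
})

test_that("frequency rules fire at the gene-calibrated cutoffs", {
  cfg <- calibration_config()
  expect_equal(frequency_criteria(0.006, cfg), "BA1")
  expect_equal(frequency_criteria(0.003, cfg), "BS1")
  expect_equal(frequency_criteria(0.0001, cfg), "PM2")
  expect_null(frequency_criteria(0.001, cfg))
  expect_null(frequency_criteria(NA, cfg))
  # inclusive boundaries: >= for BA1/BS1, <= for PM2
  expect_equal(frequency_criteria(0.005, cfg), "BA1")
  expect_equal(frequency_criteria(0.002, cfg), "BS1")
  expect_equal(frequency_criteria(0.0002, cfg), "PM2")
  expect_error(frequency_criteria(1.2, cfg), "outside")
})

test_that("PP4 tiers follow HDL-C with Tangier as strong", {
  cfg <- calibration_config()
  expect_equal(phenotype_criterion(0.45, FALSE, cfg), "PP4")
  expect_equal(phenotype_criterion(0.25, FALSE, cfg), "PP4_moderate")
  expect_equal(phenotype_criterion(0.05, FALSE, cfg), "PP4_strong")
  expect_equal(phenotype_criterion(NA, TRUE, cfg), "PP4_strong")
  expect_equal(phenotype_criterion(0.45, TRUE, cfg), "PP4_strong")  # strictest wins
  expect_null(phenotype_criterion(0.8, FALSE, cfg))
  expect_null(phenotype_criterion(NA, FALSE, cfg))
  expect_error(phenotype_criterion(-0.1, FALSE, cfg), "non-negative")
})

test_that("the efflux category maps to PS3/BS3 at the validated strength", {
  expect_equal(functional_criterion("loss_of_function", "moderate"), "PS3_moderate")
  expect_equal(functional_criterion("normal", "moderate"), "BS3_moderate")
  expect_null(functional_criterion("uncertain", "moderate"))
  expect_null(functional_criterion(NA, "moderate"))
  expect_equal(functional_criterion("loss_of_function", "supporting"),
               "PS3_supporting")
})

test_that("assay validation needs controls, replicates and >= 11 variant controls", {
  cfg <- calibration_config()
  expect_equal(validate_assay(15, TRUE, TRUE, cfg), "moderate")
  expect_equal(validate_assay(11, TRUE, TRUE, cfg), "moderate")  # inclusive
  expect_equal(validate_assay(10, TRUE, TRUE, cfg), "supporting")
  expect_equal(validate_assay(5, TRUE, TRUE, cfg), "supporting")
  expect_equal(validate_assay(15, FALSE, TRUE, cfg), "supporting")
  expect_equal(validate_assay(15, TRUE, FALSE, cfg), "supporting")
})

test_that("evidence combination reproduces the published worked examples", {
  expect_equal(as.integer(combine_criteria(
    c("PM2", "PM3", "PP3", "PP4_strong", "PS3_moderate"))), 5L)
  expect_equal(as.integer(combine_criteria(c("PM2", "PM3", "PP3", "PP4_strong"))), 4L)
  expect_equal(as.integer(combine_criteria(c("BS1", "BS3_moderate"))), 2L)
  expect_equal(as.integer(combine_criteria("BS1")), 3L)
  expect_equal(as.integer(combine_criteria(c("PM2", "PP3", "PP4"))), 3L)
  expect_equal(as.integer(combine_criteria(c("PM2", "PP3", "PP4", "PS3_moderate"))), 4L)
  expect_equal(as.integer(combine_criteria(character())), 3L)
  expect_equal(as.integer(combine_criteria("BA1")), 1L)
  # conflict: pathogenic and benign rules both met resolves to uncertain
  expect_equal(as.integer(combine_criteria(c("PS1", "PS2", "BS1", "BS2"))), 3L)
})

test_that("combination rejects duplicates and is order-invariant", {
  expect_error(combine_criteria(c("PM2", "PM2")), "duplicate")
  expect_error(combine_criteria(c("PM2", "PM2_supporting")), "duplicate")
  set.seed(5)
  tokens <- c("PM2", "PM3", "PP3", "PP4_strong", "PS3_moderate")
  for (i in 1:10)
    expect_equal(combine_criteria(sample(tokens)), combine_criteria(tokens),
                 ignore_attr = TRUE)
})

test_that("combine agrees with the brute-force rule evaluator on all small multisets", {
  grid <- atom_multisets(4)
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    tokens <- tokens_for_counts(g$s, g$m, g$p, g$bs, g$bp)
    expect_identical(as.integer(combine_criteria(tokens)),
                     oracle_acmg_class(s = g$s, m = g$m, p = g$p,
                                       ba = 0, bs = g$bs, bp = g$bp),
                     label = paste(tokens, collapse = "+"))
  }
})

test_that("adding loss-of-function evidence to an uncertain set never yields a benign class", {
  grid <- atom_multisets(3)
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    tokens <- tokens_for_counts(g$s, g$m, g$p, g$bs, g$bp)
    before <- as.integer(combine_criteria(tokens))
    after <- as.integer(combine_criteria(c(tokens, "PS4_moderate")))
    if (before == 3L) expect_false(after %in% c(1L, 2L))
    # class never drops toward benign except via the conflict rule
    expect_true(after >= before || after == 3L)
  }
})

test_that("classification composes asserted and derived criteria", {
  r <- classify_variant("p.S1157N", category = "normal", criteria = "BP4")
  expect_equal(r$class_without, 3L); expect_equal(r$class_with, 2L)
  expect_true(r$changed)
  r2 <- classify_variant("p.N1185S", category = "normal")
  expect_equal(r2$class_without, 3L); expect_equal(r2$class_with, 2L)
  r3 <- classify_variant("p.G1346E", category = "uncertain",
                         criteria = c("PM2", "PP3"))
  expect_false(r3$changed)
  # derived frequency + phenotype criteria join the asserted ones
  r4 <- classify_variant("p.F2009S", category = "loss_of_function",
                         faf = 1e-5, hdl_c = 0.05,
                         criteria = c("PM3", "PP3"))
  expect_setequal(r4$criteria_without, c("PM3", "PP3", "PM2", "PP4_strong"))
  expect_equal(r4$class_without, 4L); expect_equal(r4$class_with, 5L)
  # an asserted token wins a code collision with a derived one
  r5 <- classify_variant("p.F2009S", category = NA, faf = 1e-5,
                         hdl_c = 0.2, criteria = c("PM2", "PP4_strong"))
  expect_setequal(r5$criteria_without, c("PM2", "PP4_strong"))
})

test_that("reclassification report counts transitions", {
  t1 <- abca1_table1()
  cats <- setNames(t1$category, t1$variant_p)
  cls <- classify_variants(data.frame(variant_p = t1$variant_p,
                                      criteria = t1$criteria,
                                      stringsAsFactors = FALSE),
                           categories = cats)
  rep <- reclassification_report(cls)
  expect_equal(rep$n_changed, 12L)
  expect_equal(rep$n_total, 12L)
  tr <- rep$transitions
  expect_equal(tr$n[tr$from == 3 & tr$to == 2], 5L)
  expect_equal(tr$n[tr$from == 3 & tr$to == 4], 5L)
  expect_equal(tr$n[tr$from == 4 & tr$to == 5], 2L)
  empty <- reclassification_report(classify_variants(
    data.frame(variant_p = character(), criteria = character())))
  expect_equal(empty$n_changed, 0L)
})
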