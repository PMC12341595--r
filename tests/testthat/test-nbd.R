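test_that("identical duplicated domains align at 100% identity with a constant offset", {
  d <- generate_duplicated_domain_sequence(50, divergence = 0, seed = 3)
  em <- align_nbds(d$sequence, d$nbd1_window, d$nbd2_window)
  expect_equal(em$percent_identity, 100)
  expect_equal(em$percent_similarity, 100)
  offs <- em$pairs$nbd2_pos - em$pairs$nbd1_pos
  expect_true(all(offs == offs[1]))
  expect_equal(nrow(em$pairs), 50)
})

test_that("a single-residue deletion is mapped around correctly (hand oracle)", {
  # domain 1: ACDEFGHIKL (positions 5-14); domain 2 identical minus the F
  # (positions 19-27). The only optimal global alignment puts one gap
  # opposite the F at position 9; the other nine columns pair identically.
  seq <- paste0("GGGG", "ACDEFGHIKL", "GGGG", "ACDEGHIKL", "GGGG")
  em <- align_nbds(seq, c(5, 14), c(19, 27))
  expect_equal(em$n_columns, 10)
  expect_equal(nrow(em$pairs), 9)
  expect_true(all(em$pairs$conserved))
  expect_equal(em$pairs$nbd1_pos, c(5:8, 10:14))
  expect_equal(em$pairs$nbd2_pos, 19:27)
  expect_equal(unname(domain_similarity(em)), c(90, 90))
})

test_that("alignment is deterministic and monotone in both coordinates", {
  d <- generate_duplicated_domain_sequence(80, divergence = 0.4, seed = 9)
  em1 <- align_nbds(d$sequence, d$nbd1_window, d$nbd2_window)
  em2 <- align_nbds(d$sequence, d$nbd1_window, d$nbd2_window)
  expect_identical(em1$pairs, em2$pairs)
  expect_true(all(diff(em1$pairs$nbd1_pos) > 0))
  expect_true(all(diff(em1$pairs$nbd2_pos) > 0))
  # injective partial map in both directions
  expect_false(anyDuplicated(em1$pairs$nbd1_pos) > 0)
  expect_false(anyDuplicated(em1$pairs$nbd2_pos) > 0)
})

test_that("planted conserved positions are recovered across the two domains", {
  d <- generate_duplicated_domain_sequence(80, divergence = 0.3, seed = 21)
  em <- align_nbds(d$sequence, d$nbd1_window, d$nbd2_window)
  truth <- d$pairs
  got <- merge(truth, em$pairs, by = "nbd1_pos", suffixes = c("_true", "_aln"))
  expect_equal(nrow(got), nrow(truth))        # equal-length domains: no gaps
  expect_equal(got$nbd2_pos_aln, got$nbd2_pos_true)
  expect_equal(got$conserved_aln, got$conserved_true)
})

test_that("equivalent variants are proposed only at conserved aligned positions", {
  d <- generate_duplicated_domain_sequence(60, divergence = 0.3, seed = 33)
  em <- align_nbds(d$sequence, d$nbd1_window, d$nbd2_window)
  truth <- d$pairs
  aa <- strsplit(d$sequence, "")[[1]]
  cons <- truth[truth$conserved, ][1, ]
  ref <- aa[cons$nbd1_pos]
  alt <- setdiff(c("A", "V", "L", "S"), ref)[1]
  v <- sprintf("p.%s%d%s", ref, cons$nbd1_pos, alt)
  expect_equal(equivalent_variant(v, em),
               sprintf("p.%s%d%s", ref, cons$nbd2_pos, alt))
  # mirroring works from the second domain back to the first
  v2 <- sprintf("p.%s%d%s", ref, cons$nbd2_pos, alt)
  expect_equal(equivalent_variant(v2, em),
               sprintf("p.%s%d%s", ref, cons$nbd1_pos, alt))
  nc <- truth[!truth$conserved, ][1, ]
  ref_nc <- aa[nc$nbd1_pos]
  alt_nc <- setdiff(c("A", "V", "L", "S"), ref_nc)[1]
  expect_null(equivalent_variant(
    sprintf("p.%s%d%s", ref_nc, nc$nbd1_pos, alt_nc), em))
  expect_error(equivalent_variant("p.A1V", em), "neither NBD window")
})

test_that("windows are validated against the sequence", {
  expect_error(align_nbds("ACDEF", c(1, 10), c(1, 3)), "out of bounds")
  expect_error(align_nbds("ACDEFGHIKL", c(3, 2), c(5, 8)), "out of bounds")
})

test_that("the published equivalent-pair table is internally consistent", {
  pairs <- abca1_equivalent_pairs()
  expect_equal(nrow(pairs), 16L)
  expect_equal(sum(!pairs$alignment_consistent), 1L)
  p1 <- parse_protein_variant(pairs$nbd1)
  p2 <- parse_protein_variant(pairs$nbd2)
  # mirrored variants keep reference and alternate residues
  expect_equal(p1$ref_aa, p2$ref_aa)
  expect_equal(p1$alt_aa, p2$alt_aa)
  ok <- pairs$alignment_consistent
  offs <- p2$position[ok] - p1$position[ok]
  # offsets of monotone-consistent pairs stay within one gap of the window offset
  expect_true(all(abs(offs - 1013) <= 1))
})
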