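# Chemical-chaperone (4-PBA) rescue analysis. A variant is "rescued" when its
# cholesterol efflux increases significantly under 4-PBA (one-tailed test vs
# vehicle treatment). Variants that are not rescued despite a significant
# increase in cell-surface protein, and that sit in an ATP-binding motif
# (Walker A, Walker B or signature), are flagged as suspected
# ATPase-deficient: the protein reaches the membrane but cannot hydrolyze ATP.

#' One-tailed rescue test
#'
#' F-test-gated two-sample t-test for an *increase* under 4-PBA relative to
#' vehicle treatment.
#'
#' @param mock_values,pba_values Replicate efflux values (percent of
#'   mock-treated WT) under vehicle and 4-PBA.
#' @param alpha Significance level.
#' @param variance_test_alpha Level of the gating F-test.
#' @return A list with `p_one_tailed`, `rescued` (significant increase),
#'   `mean_mock`, `mean_pba`.
#' @export
rescue_test <- function(mock_values, pba_values, alpha = 0.05,
                        variance_test_alpha = 0.05) {
  cmp <- compare_to_wt(pba_values, mock_values,
                       variance_test_alpha = variance_test_alpha,
                       alternative = "greater")
  list(p_one_tailed = cmp$p_value,
       rescued = cmp$p_value < alpha && mean(pba_values) > mean(mock_values),
       mean_mock = mean(mock_values), mean_pba = mean(pba_values))
}

#' Flag suspected ATPase deficiency
#'
#' @param rescued Logical; significant efflux increase under 4-PBA.
#' @param surface_increased Logical; significant cell-surface increase under
#'   4-PBA.
#' @param motif Motif label for the variant position (from [assign_motif()]),
#'   or `NA`.
#' @return `TRUE` iff not rescued, surface increased, and the variant lies in
#'   a Walker A, Walker B or signature motif.
#' @export
flag_atpase_deficiency <- function(rescued, surface_increased, motif) {
  core <- sub("\\(.*\\)$", "", as.character(motif))
  !isTRUE(rescued) && isTRUE(surface_increased) &&
    !is.na(motif) && core %in% c("Walker_A", "Walker_B", "signature")
}

#' Run the 4-PBA rescue pipeline
#'
#' For every non-control construct: relative efflux under vehicle and 4-PBA
#' (both normalized per experiment to the *mock-treated* WT), the one-tailed
#' rescue test, a one-tailed test for a cell-surface increase under 4-PBA
#' (when band data are given), and the ATPase-deficiency flag (when a domain
#' map is given).
#'
#' @param plates Long plate table covering both treatments (see
#'   [run_efflux_pipeline()]).
#' @param bands Optional densitometry table covering both treatments (see
#'   [surface_levels()]).
#' @param map Optional `"domain_map"` for motif lookup; variant names that do
#'   not parse as protein variants get `motif = NA`.
#' @param config A [calibration_config()].
#' @return A data frame of class `"rescue_result"`: `construct_id`,
#'   `efflux_mock_pct`, `efflux_4pba_pct`, `p_one_tailed`, `rescued`,
#'   `surface_increased`, `motif`, `atpase_deficiency_suspected`.
#' @export
run_rescue_pipeline <- function(plates, bands = NULL, map = abca1_domain_map(),
                                config = calibration_config()) {
  spec <- specific_efflux_table(plates)
  wt_mock <- spec[spec$construct_id == "WT" & spec$treatment == "mock", ]
  if (!nrow(wt_mock))
    stop("no mock-treated WT wells in the plate table", call. = FALSE)
  wt_by_exp <- stats::setNames(wt_mock$specific, wt_mock$experiment_id)

  rel_for <- function(cid, trt) {
    v <- spec[spec$construct_id == cid & spec$treatment == trt, ]
    normalize_to_wt(stats::setNames(v$specific, v$experiment_id), wt_by_exp)
  }

  constructs <- setdiff(unique(spec$construct_id), "WT")
  rows <- lapply(constructs, function(cid) {
    rel_mock <- rel_for(cid, "mock")
    rel_pba <- rel_for(cid, "4pba")
    rt <- rescue_test(rel_mock, rel_pba, alpha = config$alpha,
                      variance_test_alpha = config$variance_test_alpha)
    surface_up <- NA
    if (!is.null(bands)) {
      bm <- bands[bands$construct_id == cid & bands$treatment == "mock", ]
      bp <- bands[bands$construct_id == cid & bands$treatment == "4pba", ]
      if (nrow(bm) >= 2L && nrow(bp) >= 2L) {
        cmp <- compare_to_wt(bp$surface / bp$actin, bm$surface / bm$actin,
                             variance_test_alpha = config$variance_test_alpha,
                             alternative = "greater")
        surface_up <- cmp$p_value < config$alpha
      }
    }
    motif <- tryCatch(assign_motif(parse_protein_variant(cid)$position, map),
                      error = function(e) NA_character_)
    data.frame(construct_id = cid,
               efflux_mock_pct = mean(rel_mock),
               efflux_4pba_pct = mean(rel_pba),
               p_one_tailed = rt$p_one_tailed,
               rescued = rt$rescued,
               surface_increased = surface_up,
               motif = motif,
               atpase_deficiency_suspected =
                 flag_atpase_deficiency(rt$rescued, surface_up, motif),
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows), class = c("rescue_result", "data.frame"))
}

#' @export
print.rescue_result <- function(x, ...) {
  cat("<rescue_result>", nrow(x), "constructs;",
      sum(x$rescued), "rescued,",
      sum(x$atpase_deficiency_suspected), "suspected ATPase-deficient\n")
  y <- as.data.frame(x)
  y$efflux_mock_pct <- round(y$efflux_mock_pct, 1)
  y$efflux_4pba_pct <- round(y$efflux_4pba_pct, 1)
  y$p_one_tailed <- signif(y$p_one_tailed, 2)
  print(y, row.names = FALSE)
  invisible(x)
}
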