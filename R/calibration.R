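#' Calibration configuration for the ABCA1 assay pipeline
#'
#' Holds every threshold used across the pipeline so none is hard-coded in
#' logic: functional category cutoffs on relative efflux (percent of WT),
#' significance levels, the surface-deficiency severity cutoff, the
#' gene-calibrated allele-frequency cutoffs for BA1/BS1/PM2, the tiered HDL-C
#' cutoffs for PP4, and the minimum variant-control count for moderate-strength
#' functional evidence.
#'
#' Defaults reflect the ABCA1 calibration of the shipped study data:
#' loss-of-function below 41% of WT (efflux of the p.W590S control), normal
#' above 80%, an optional alternative loss-of-function cutoff of 58%, BA1/BS1
#' at filtering allele frequency >= 0.005 / >= 0.002, PM2 at <= 0.0002, PP4
#' supporting/moderate/strong below HDL-C 0.5/0.3/0.1 mmol/l (or Tangier
#' disease for strong), and at least 11 class-1/2/4/5 variant controls for
#' moderate assay strength.
#'
#' @param lof_threshold,normal_threshold,alternative_lof_threshold Category
#'   cutoffs, percent of WT.
#' @param alpha Significance level for tests against WT.
#' @param variance_test_alpha Level of the F-test that gates pooled vs Welch
#'   t-tests.
#' @param surface_deficiency_threshold Percent of WT below which a surface
#'   reduction is flagged severe.
#' @param freq_ba1,freq_bs1,freq_pm2 Filtering-allele-frequency cutoffs.
#' @param pp4_supporting_hdl,pp4_moderate_hdl,pp4_strong_hdl HDL-C cutoffs
#'   (mmol/l) for the PP4 tiers.
#' @param min_variant_controls_for_moderate Minimum count of class-1/2/4/5
#'   variant controls for moderate-strength PS3/BS3.
#' @return A list of class `"calibration_config"`.
#' @export
calibration_config <- function(lof_threshold = 41,
                               normal_threshold = 80,
                               alternative_lof_threshold = 58,
                               alpha = 0.05,
                               variance_test_alpha = 0.05,
                               surface_deficiency_threshold = 50,
                               freq_ba1 = 0.005,
                               freq_bs1 = 0.002,
                               freq_pm2 = 0.0002,
                               pp4_supporting_hdl = 0.5,
                               pp4_moderate_hdl = 0.3,
                               pp4_strong_hdl = 0.1,
                               min_variant_controls_for_moderate = 11) {
  cfg <- structure(as.list(environment()), class = "calibration_config")
  validate_calibration_config(cfg)
}

validate_calibration_config <- function(cfg) {
  with(cfg, {
    if (!(0 < lof_threshold && lof_threshold < normal_threshold &&
          normal_threshold <= 100))
      stop("require 0 < lof_threshold < normal_threshold <= 100", call. = FALSE)
    if (!(freq_pm2 < freq_bs1 && freq_bs1 < freq_ba1))
      stop("require freq_pm2 < freq_bs1 < freq_ba1", call. = FALSE)
    if (!(pp4_strong_hdl < pp4_moderate_hdl && pp4_moderate_hdl < pp4_supporting_hdl))
      stop("PP4 HDL-C cutoffs must be strictly decreasing with strength",
           call. = FALSE)
    if (alpha <= 0 || alpha >= 1 || variance_test_alpha <= 0 || variance_test_alpha >= 1)
      stop("alpha levels must lie in (0, 1)", call. = FALSE)
  })
  cfg
}

#' @export
print.calibration_config <- function(x, ...) {
  cat("<calibration_config>\n")
  cat(sprintf("  efflux categories: loss-of-function < %g%%, normal > %g%% of WT (alt. LoF cutoff %g%%)\n",
              x$lof_threshold, x$normal_threshold, x$alternative_lof_threshold))
  cat(sprintf("  tests: alpha %g, F-test gate %g\n", x$alpha, x$variance_test_alpha))
  cat(sprintf("  frequency cutoffs: BA1 >= %g, BS1 >= %g, PM2 <= %g\n",
              x$freq_ba1, x$freq_bs1, x$freq_pm2))
  cat(sprintf("  PP4 HDL-C (mmol/l): supporting < %g, moderate < %g, strong < %g or Tangier\n",
              x$pp4_supporting_hdl, x$pp4_moderate_hdl, x$pp4_strong_hdl))
  invisible(x)
}

#' Read / write the calibration configuration as JSON
#'
#' @param path JSON file path.
#' @return `read_calibration_config()` returns a `"calibration_config"`;
#'   `write_calibration_config()` returns `path` invisibly.
#' @export
read_calibration_config <- function(path) {
  vals <- jsonlite::fromJSON(path)
  known <- names(formals(calibration_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown calibration field(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  do.call(calibration_config, vals)
}

#' @rdname read_calibration_config
#' @param config A `"calibration_config"`.
#' @export
write_calibration_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
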