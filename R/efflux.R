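# Cholesterol efflux quantification from plate fluorescence.
#
# Per well-set the efflux fraction is medium / (medium + lysate) on triplicate
# means; HDL-nonspecific leakage is removed by subtracting the no-acceptor
# efflux, and ABCA1-nonspecific efflux by subtracting the mock-transfected
# efflux of the same experiment; the result is expressed per experiment as a
# percentage of the same experiment's WT before averaging across experiments.

#' Raw cholesterol efflux fraction
#'
#' `mean(medium) / (mean(medium) + mean(lysate))` on the replicate
#' fluorescence signals of one well-set; always in `[0, 1]`.
#'
#' @param medium_signals,lysate_signals Numeric vectors (typically
#'   triplicates) of background-free fluorescence, arbitrary units, >= 0.
#' @return Efflux fraction in `[0, 1]`.
#' @examples
#' raw_efflux(c(300, 300, 300), c(700, 700, 700))
#' @export
raw_efflux <- function(medium_signals, lysate_signals) {
  stopifnot(length(medium_signals) >= 1L, length(lysate_signals) >= 1L)
  if (any(medium_signals < 0) || any(lysate_signals < 0))
    stop("fluorescence signals must be non-negative", call. = FALSE)
  m <- mean(medium_signals); l <- mean(lysate_signals)
  if (m + l <= 0)
    stop("undefined efflux: medium and lysate signals both sum to zero",
         call. = FALSE)
  m / (m + l)
}

#' One well-set of efflux measurements
#'
#' @param construct_id Variant name, `"WT"`, or `"mock"`.
#' @param experiment_id Identifier of the independent experiment.
#' @param condition `"acceptor"` (HDL present) or `"no_acceptor"`.
#' @param treatment `"mock"` (vehicle) or `"4pba"`.
#' @param medium_signals,lysate_signals Replicate fluorescence values;
#'   triplicates expected, fewer are accepted with a warning.
#' @return A list of class `"efflux_measurement"`.
#' @export
efflux_measurement <- function(construct_id, experiment_id,
                               condition = c("acceptor", "no_acceptor"),
                               treatment = c("mock", "4pba"),
                               medium_signals, lysate_signals) {
  condition <- match.arg(condition); treatment <- match.arg(treatment)
  if (any(medium_signals < 0) || any(lysate_signals < 0))
    stop("fluorescence signals must be non-negative", call. = FALSE)
  if (length(medium_signals) < 3L || length(lysate_signals) < 3L)
    warning("fewer than 3 replicate signals for ", construct_id, call. = FALSE)
  structure(list(construct_id = construct_id, experiment_id = experiment_id,
                 condition = condition, treatment = treatment,
                 medium_signals = medium_signals, lysate_signals = lysate_signals),
            class = "efflux_measurement")
}

#' Acceptor-specific (leakage-corrected) efflux
#'
#' Subtracts the no-acceptor efflux (HDL-nonspecific leakage) from the
#' acceptor efflux of the same construct, experiment and treatment. The
#' difference may be negative and is deliberately not clamped.
#'
#' @param acceptor,no_acceptor `"efflux_measurement"` objects for the same
#'   construct/experiment/treatment under the two conditions.
#' @return Corrected efflux fraction in `[-1, 1]`.
#' @export
corrected_efflux <- function(acceptor, no_acceptor) {
  stopifnot(inherits(acceptor, "efflux_measurement"),
            inherits(no_acceptor, "efflux_measurement"))
  if (acceptor$condition != "acceptor" || no_acceptor$condition != "no_acceptor")
    stop("arguments must be an acceptor and a no-acceptor measurement",
         call. = FALSE)
  if (acceptor$construct_id != no_acceptor$construct_id ||
      acceptor$experiment_id != no_acceptor$experiment_id ||
      acceptor$treatment != no_acceptor$treatment)
    stop("pairing error: acceptor and no-acceptor well-sets disagree on ",
         "construct, experiment or treatment", call. = FALSE)
  raw_efflux(acceptor$medium_signals, acceptor$lysate_signals) -
    raw_efflux(no_acceptor$medium_signals, no_acceptor$lysate_signals)
}

#' ABCA1-specific efflux
#'
#' Subtracts the leakage-corrected efflux of mock-transfected cells
#' (ABCA1-nonspecific efflux) measured in the same experiment and treatment.
#'
#' @param construct_corrected,mock_corrected Leakage-corrected efflux
#'   fractions from [corrected_efflux()].
#' @return Specific efflux fraction.
#' @export
specific_efflux <- function(construct_corrected, mock_corrected) {
  construct_corrected - mock_corrected
}

#' Normalize specific efflux to wild type, per experiment
#'
#' Experiments where the WT specific efflux is missing or non-positive are
#' dropped with a warning; it is an error if no experiment remains.
#'
#' @param construct_specific,wt_specific Named numeric vectors of specific
#'   efflux per experiment (names are experiment ids).
#' @return Named numeric vector of relative efflux (percent of WT) for the
#'   experiments retained.
#' @export
normalize_to_wt <- function(construct_specific, wt_specific) {
  stopifnot(!is.null(names(construct_specific)), !is.null(names(wt_specific)))
  shared <- intersect(names(construct_specific), names(wt_specific))
  ok <- shared[!is.na(wt_specific[shared]) & wt_specific[shared] > 0]
  dropped <- setdiff(names(construct_specific), ok)
  if (length(dropped))
    warning("experiment(s) dropped (missing or non-positive WT specific efflux): ",
            paste(dropped, collapse = ", "), call. = FALSE)
  if (!length(ok))
    stop("no experiment with positive WT specific efflux", call. = FALSE)
  100 * construct_specific[ok] / wt_specific[ok]
}

#' Assign the functional category from mean relative efflux
#'
#' Below the loss-of-function threshold: `"loss_of_function"`; above the
#' normal threshold: `"normal"`; otherwise `"uncertain"`. Outer thresholds are
#' exclusive, so values exactly at a cutoff stay `"uncertain"`. With
#' `use_alternative = TRUE` the alternative (clinically anchored) cutoff
#' replaces the loss-of-function threshold.
#'
#' @param mean_relative_efflux Numeric vector, percent of WT.
#' @param config A [calibration_config()].
#' @param use_alternative Use `alternative_lof_threshold` instead of
#'   `lof_threshold`.
#' @return Character vector of categories.
#' @examples
#' categorize_efflux(c(9, 58, 84))
#' @export
categorize_efflux <- function(mean_relative_efflux,
                              config = calibration_config(),
                              use_alternative = FALSE) {
  lof <- if (use_alternative) config$alternative_lof_threshold else config$lof_threshold
  ifelse(mean_relative_efflux < lof, "loss_of_function",
         ifelse(mean_relative_efflux > config$normal_threshold, "normal",
                "uncertain"))
}

# Collapse a long plate table (one row per construct x experiment x treatment x
# condition x well_type, signal replicates in rep* columns) to leakage- and
# mock-corrected specific efflux per construct x experiment x treatment.
specific_efflux_table <- function(plates) {
  req <- c("construct_id", "experiment_id", "condition", "treatment", "well_type")
  miss <- setdiff(req, names(plates))
  if (length(miss)) stop("plate table lacks column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  repcols <- grep("^rep[0-9]+$", names(plates), value = TRUE)
  if (!length(repcols)) stop("plate table lacks rep* signal columns", call. = FALSE)
  sig <- rowMeans(as.matrix(plates[repcols]), na.rm = TRUE)
  if (any(sig < 0, na.rm = TRUE))
    stop("fluorescence signals must be non-negative", call. = FALSE)

  key <- interaction(plates$construct_id, plates$experiment_id,
                     plates$treatment, plates$condition, drop = TRUE, sep = "\r")
  agg <- tapply(seq_along(sig), key, function(idx) {
    wt <- plates$well_type[idx]
    m <- sig[idx][wt == "medium"]; l <- sig[idx][wt == "lysate"]
    if (!length(m) || !length(l)) return(NA_real_)
    raw_efflux(m, l)
  })
  parts <- do.call(rbind, strsplit(names(agg), "\r", fixed = TRUE))
  raw <- data.frame(construct_id = parts[, 1], experiment_id = parts[, 2],
                    treatment = parts[, 3], condition = parts[, 4],
                    raw = as.numeric(agg), stringsAsFactors = FALSE)

  wide <- merge(raw[raw$condition == "acceptor",
                    c("construct_id", "experiment_id", "treatment", "raw")],
                raw[raw$condition == "no_acceptor",
                    c("construct_id", "experiment_id", "treatment", "raw")],
                by = c("construct_id", "experiment_id", "treatment"),
                suffixes = c("_acc", "_noacc"))
  wide$corrected <- wide$raw_acc - wide$raw_noacc

  mock <- wide[wide$construct_id == "mock",
               c("experiment_id", "treatment", "corrected")]
  if (!nrow(mock))
    stop("configuration error: no mock-transfected wells in the plate table",
         call. = FALSE)
  names(mock)[3] <- "mock_corrected"
  out <- merge(wide[wide$construct_id != "mock", ], mock,
               by = c("experiment_id", "treatment"))
  out$specific <- specific_efflux(out$corrected, out$mock_corrected)
  out[order(out$construct_id, out$experiment_id, out$treatment),
      c("construct_id", "experiment_id", "treatment", "raw_acc", "raw_noacc",
        "corrected", "specific")]
}

#' Run the cholesterol efflux pipeline
#'
#' Computes, for every non-control construct: per-experiment relative efflux
#' (percent of the same experiment's WT specific efflux), its mean and SD
#' across experiments, the F-test-gated t-test p-value of its specific efflux
#' against WT, and the functional category.
#'
#' @param plates Data frame in long plate format with columns `construct_id`,
#'   `experiment_id`, `condition` (`acceptor`/`no_acceptor`), `treatment`
#'   (`mock`/`4pba`), `well_type` (`medium`/`lysate`) and replicate signal
#'   columns `rep1`, `rep2`, ... Every experiment must contain `WT` and
#'   `mock` wells.
#' @param config A [calibration_config()].
#' @param treatment Which treatment arm to summarize (default `"mock"`,
#'   i.e. untreated).
#' @param use_alternative Passed to [categorize_efflux()].
#' @return A data frame of class `"efflux_result"` with one row per construct:
#'   `construct_id`, `mean_rel_efflux_pct`, `sd_pct`, `n`, `p_vs_wt`,
#'   `category`. The per-experiment relative efflux values are attached as
#'   attribute `"per_experiment"`.
#' @export
run_efflux_pipeline <- function(plates, config = calibration_config(),
                                treatment = "mock", use_alternative = FALSE) {
  spec <- specific_efflux_table(plates)
  spec <- spec[spec$treatment == treatment, ]
  if (!any(spec$construct_id == "WT"))
    stop("configuration error: no WT wells for treatment '", treatment, "'",
         call. = FALSE)
  wt <- spec[spec$construct_id == "WT", ]
  wt_by_exp <- stats::setNames(wt$specific, wt$experiment_id)

  constructs <- setdiff(unique(spec$construct_id), "WT")
  per_exp <- list()
  rows <- lapply(constructs, function(cid) {
    v <- spec[spec$construct_id == cid, ]
    vals <- stats::setNames(v$specific, v$experiment_id)
    rel <- normalize_to_wt(vals, wt_by_exp)
    per_exp[[cid]] <<- rel
    shared <- intersect(names(vals), names(wt_by_exp))
    p <- if (length(shared) >= 2L)
      compare_to_wt(vals[shared], wt_by_exp[shared],
                    variance_test_alpha = config$variance_test_alpha)$p_value
    else NA_real_
    data.frame(construct_id = cid,
               mean_rel_efflux_pct = mean(rel),
               sd_pct = if (length(rel) > 1L) stats::sd(rel) else NA_real_,
               n = length(rel), p_vs_wt = p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$category <- categorize_efflux(res$mean_rel_efflux_pct, config,
                                    use_alternative = use_alternative)
  structure(res, per_experiment = per_exp, config = config,
            class = c("efflux_result", "data.frame"))
}

#' @export
print.efflux_result <- function(x, digits = 1, ...) {
  cat("<efflux_result>", nrow(x), "constructs\n")
  y <- as.data.frame(x)
  y$mean_rel_efflux_pct <- round(y$mean_rel_efflux_pct, digits)
  y$sd_pct <- round(y$sd_pct, digits)
  y$p_vs_wt <- signif(y$p_vs_wt, 2)
  print(y, row.names = FALSE)
  invisible(x)
}

#' @export
summary.efflux_result <- function(object, ...) {
  tab <- table(factor(object$category,
                      levels = c("loss_of_function", "uncertain", "normal")))
  cat("Functional categories (relative cholesterol efflux):\n")
  print(tab)
  invisible(tab)
}
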