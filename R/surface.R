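# Cell-surface ABCA1 quantification from biotinylation densitometry.
#
# Raw surface level: surface band over the beta-actin loading control,
# relative to WT's same ratio in the same experiment. Total-corrected surface:
# surface band over the total-ABCA1 band (its own denominator; the loading
# control cancels and is not reapplied), relative to WT. Separating the two
# distinguishes a transport (trafficking) deficiency from an increased
# degradation rate.

#' Per-experiment and aggregated cell-surface levels
#'
#' @param bands Data frame with columns `construct_id`, `experiment_id`,
#'   `treatment`, `surface`, `total`, `actin` (densitometry units; `actin`
#'   must be positive).
#' @param treatment Treatment arm to analyze (default `"mock"`).
#' @return A data frame of class `"surface_result"`, one row per non-WT
#'   construct: `construct_id`, `raw_surface_pct_of_wt`,
#'   `corrected_surface_pct_of_wt`, their SDs, `n`, one-sided p-values
#'   `p_raw_vs_wt` / `p_corr_vs_wt` (alternative: below WT). Per-experiment
#'   percentages are attached as attribute `"per_experiment"`.
#' @export
surface_levels <- function(bands, treatment = "mock") {
  req <- c("construct_id", "experiment_id", "treatment", "surface", "total", "actin")
  miss <- setdiff(req, names(bands))
  if (length(miss)) stop("band table lacks column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  b <- bands[bands$treatment == treatment, ]
  if (any(b$actin <= 0)) stop("loading-control band must be positive", call. = FALSE)
  if (any(b$surface < 0 | b$total < 0))
    stop("band intensities must be non-negative", call. = FALSE)
  b$raw_ratio <- b$surface / b$actin
  b$corr_ratio <- ifelse(b$total > 0, b$surface / b$total, NA_real_)

  wt <- b[b$construct_id == "WT", ]
  if (!nrow(wt)) stop("no WT rows in the band table", call. = FALSE)
  if (any(wt$surface <= 0))
    stop("normalization error: WT surface band is zero", call. = FALSE)
  wt_raw  <- stats::setNames(wt$raw_ratio,  wt$experiment_id)
  wt_corr <- stats::setNames(wt$corr_ratio, wt$experiment_id)

  constructs <- setdiff(unique(b$construct_id), "WT")
  per_exp <- list()
  rows <- lapply(constructs, function(cid) {
    v <- b[b$construct_id == cid, ]
    shared <- intersect(v$experiment_id, names(wt_raw))
    v <- v[v$experiment_id %in% shared, ]
    raw_pct  <- 100 * v$raw_ratio  / wt_raw[v$experiment_id]
    corr_pct <- 100 * v$corr_ratio / wt_corr[v$experiment_id]
    per_exp[[cid]] <<- data.frame(experiment_id = v$experiment_id,
                                  raw_pct = raw_pct, corr_pct = corr_pct)
    p_raw <- p_corr <- NA_real_
    if (nrow(v) >= 2L) {
      p_raw <- compare_to_wt(v$raw_ratio, wt_raw[v$experiment_id],
                             alternative = "less")$p_value
      p_corr <- compare_to_wt(v$corr_ratio, wt_corr[v$experiment_id],
                              alternative = "less")$p_value
    }
    data.frame(construct_id = cid,
               raw_surface_pct_of_wt = mean(raw_pct),
               raw_sd = if (length(raw_pct) > 1L) stats::sd(raw_pct) else NA_real_,
               corrected_surface_pct_of_wt = mean(corr_pct),
               corrected_sd = if (length(corr_pct) > 1L) stats::sd(corr_pct) else NA_real_,
               n = nrow(v), p_raw_vs_wt = p_raw, p_corr_vs_wt = p_corr,
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows), per_experiment = per_exp,
            class = c("surface_result", "data.frame"))
}

#' Call the loss-of-surface mechanism for one construct
#'
#' `"transport_deficient"` when the total-corrected surface level is
#' significantly below WT (one-sided test at `alpha`): the protein that is
#' made does not reach the membrane. `"degradation_prone"` when the raw
#' surface level is significantly below WT but the corrected level is not:
#' the surface reduction is explained by reduced total protein.
#' `"unaffected"` otherwise. `severe` flags the relevant percentage below
#' the surface-deficiency threshold (50% of WT by default).
#'
#' @param p_raw,p_corr One-sided p-values (below WT) for the raw and
#'   total-corrected surface level.
#' @param raw_pct,corr_pct Aggregated percentages of WT.
#' @param config A [calibration_config()].
#' @return A list with `mechanism` and `severe`.
#' @export
mechanism_call <- function(p_raw, p_corr, raw_pct, corr_pct,
                           config = calibration_config()) {
  if (any(is.na(c(p_raw, p_corr, raw_pct, corr_pct))))
    stop("insufficient replicates for a mechanism call", call. = FALSE)
  thr <- config$surface_deficiency_threshold
  if (p_corr < config$alpha) {
    list(mechanism = "transport_deficient", severe = corr_pct < thr)
  } else if (p_raw < config$alpha) {
    list(mechanism = "degradation_prone", severe = raw_pct < thr)
  } else {
    list(mechanism = "unaffected", severe = FALSE)
  }
}

#' Run the cell-surface pipeline
#'
#' [surface_levels()] plus a mechanism call per construct.
#'
#' @inheritParams surface_levels
#' @param config A [calibration_config()].
#' @return The `"surface_result"` data frame with `mechanism` and `severe`
#'   columns appended.
#' @export
run_surface_pipeline <- function(bands, config = calibration_config(),
                                 treatment = "mock") {
  res <- surface_levels(bands, treatment = treatment)
  calls <- lapply(seq_len(nrow(res)), function(i)
    mechanism_call(res$p_raw_vs_wt[i], res$p_corr_vs_wt[i],
                   res$raw_surface_pct_of_wt[i],
                   res$corrected_surface_pct_of_wt[i], config))
  res$mechanism <- vapply(calls, `[[`, character(1), "mechanism")
  res$severe <- vapply(calls, `[[`, logical(1), "severe")
  res
}

#' @export
print.surface_result <- function(x, digits = 1, ...) {
  cat("<surface_result>", nrow(x), "constructs\n")
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], function(v) signif(v, 3))
  print(y, row.names = FALSE)
  invisible(x)
}
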