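# Tabular I/O. All tables are UTF-8 TSV/CSV with fixed headers; "." marks a
# missing value on read and write.

na_tokens <- c("", ".", "NA")

#' Read a variant annotation table
#'
#' TSV with columns `variant_p`, `variant_c`, `faf`, `hdl_c`, `tangier`,
#' `criteria` (semicolon-separated ACMG tokens; `"."` for none). Variant
#' names, frequencies and criterion tokens are validated; errors name the
#' offending row and column.
#'
#' @param path TSV file path.
#' @return Data frame with typed columns.
#' @export
read_variant_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = na_tokens,
                          colClasses = "character")
  req <- c("variant_p", "faf", "hdl_c", "tangier", "criteria")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("variant table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!nrow(df)) {
    df$faf <- numeric(); df$hdl_c <- numeric(); df$tangier <- logical()
    return(df)
  }
  for (i in seq_len(nrow(df))) {
    ctx <- function(col) sprintf(" (row %d, column %s)", i, col)
    tryCatch(parse_protein_variant(df$variant_p[i]),
             error = function(e) stop(conditionMessage(e), ctx("variant_p"),
                                      call. = FALSE))
    if (!is.na(df$faf[i])) {
      v <- suppressWarnings(as.numeric(df$faf[i]))
      if (is.na(v) || v < 0 || v > 1)
        stop("bad filtering allele frequency '", df$faf[i], "'", ctx("faf"),
             call. = FALSE)
    }
    if (!is.na(df$criteria[i])) {
      tokens <- split_criteria(df$criteria[i])
      for (tk in tokens)
        tryCatch(parse_criterion(tk),
                 error = function(e) stop(conditionMessage(e), ctx("criteria"),
                                          call. = FALSE))
    }
  }
  df$faf <- suppressWarnings(as.numeric(df$faf))
  df$hdl_c <- suppressWarnings(as.numeric(df$hdl_c))
  df$tangier <- tolower(df$tangier) %in% c("true", "t", "1", "yes")
  df$criteria[is.na(df$criteria)] <- ""
  df
}

#' Write a data frame as TSV with "." for missing values
#'
#' @param df Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = ".", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a long plate table (CSV or TSV by extension)
#'
#' @param path File path; `.csv` is read as comma-separated, anything else as
#'   TSV.
#' @return Data frame in the layout of [run_efflux_pipeline()].
#' @export
read_plate_table <- function(path) {
  df <- if (grepl("\\.csv$", path, ignore.case = TRUE))
    utils::read.csv(path, stringsAsFactors = FALSE, na.strings = na_tokens)
  else utils::read.delim(path, stringsAsFactors = FALSE, na.strings = na_tokens)
  req <- c("construct_id", "experiment_id", "condition", "treatment", "well_type")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("plate table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad <- setdiff(unique(df$condition), c("acceptor", "no_acceptor"))
  if (length(bad)) stop("unknown condition value(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  df
}

#' Read a densitometry band table (CSV or TSV by extension)
#'
#' @inheritParams read_plate_table
#' @return Data frame in the layout of [surface_levels()].
#' @export
read_band_table <- function(path) {
  df <- if (grepl("\\.csv$", path, ignore.case = TRUE))
    utils::read.csv(path, stringsAsFactors = FALSE, na.strings = na_tokens)
  else utils::read.delim(path, stringsAsFactors = FALSE, na.strings = na_tokens)
  req <- c("construct_id", "experiment_id", "treatment", "surface", "total", "actin")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("band table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  df
}

#' Assemble the end-to-end study report
#'
#' Joins the stage outputs into one wide per-variant table plus the
#' class-transition summary and the functional-category counts. Construct ids
#' present in an optional stage but absent from the classifications raise a
#' join error listing the orphans.
#'
#' @param classifications An `"abca1_classification"` data frame (required).
#' @param efflux Optional `"efflux_result"`.
#' @param surface Optional `"surface_result"`.
#' @param rescue Optional `"rescue_result"`.
#' @return A list of class `"abca1_report"`: `per_variant` (wide data frame),
#'   `transitions`, `category_counts`.
#' @export
full_report <- function(classifications, efflux = NULL, surface = NULL,
                        rescue = NULL) {
  stopifnot(is.data.frame(classifications), nrow(classifications) >= 0)
  wide <- as.data.frame(classifications)
  join <- function(wide, stage, cols, label) {
    if (is.null(stage)) return(wide)
    stage <- as.data.frame(stage)
    orphans <- setdiff(stage$construct_id, wide$variant)
    if (length(orphans))
      stop("join error: ", label, " construct id(s) absent from the ",
           "classifications: ", paste(orphans, collapse = ", "), call. = FALSE)
    merge(wide, stage[c("construct_id", cols)],
          by.x = "variant", by.y = "construct_id", all.x = TRUE, sort = FALSE)
  }
  wide <- join(wide, efflux, c("mean_rel_efflux_pct", "sd_pct", "p_vs_wt"),
               "efflux")
  wide <- join(wide, surface,
               c("raw_surface_pct_of_wt", "corrected_surface_pct_of_wt",
                 "mechanism", "severe"), "surface")
  wide <- join(wide, rescue,
               c("efflux_mock_pct", "efflux_4pba_pct", "rescued",
                 "atpase_deficiency_suspected"), "rescue")
  cat_counts <- if ("category" %in% names(classifications))
    table(factor(classifications$category,
                 levels = c("loss_of_function", "uncertain", "normal")))
  else NULL
  structure(list(per_variant = wide,
                 transitions = reclassification_report(classifications),
                 category_counts = cat_counts),
            class = "abca1_report")
}

#' @export
print.abca1_report <- function(x, ...) {
  cat("<abca1_report>", nrow(x$per_variant), "variants\n")
  if (!is.null(x$category_counts)) {
    cat("Functional categories:\n"); print(x$category_counts)
  }
  tr <- x$transitions
  cat("Reclassified by functional evidence:", tr$n_changed, "of", tr$n_total, "\n")
  ch <- tr$transitions[tr$transitions$from != tr$transitions$to, , drop = FALSE]
  if (nrow(ch)) print(ch, row.names = FALSE)
  invisible(x)
}

#' Write the report to a directory
#'
#' Emits `report_per_variant.tsv`, `report_transitions.tsv`,
#' `report_summary.json` and a run manifest.
#'
#' @param report An `"abca1_report"`.
#' @param dir Output directory (created if needed).
#' @param manifest Optional list from [run_manifest()].
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir, manifest = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(report$per_variant, file.path(dir, "report_per_variant.tsv"))
  write_tsv(report$transitions$transitions,
            file.path(dir, "report_transitions.tsv"))
  summary <- list(n_total = report$transitions$n_total,
                  n_changed = report$transitions$n_changed,
                  category_counts = as.list(report$category_counts))
  jsonlite::write_json(summary, file.path(dir, "report_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(manifest))
    jsonlite::write_json(manifest, file.path(dir, "run_manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Build a run manifest
#'
#' Records the command, input file checksums (MD5), seed and package version
#' so a run can be reproduced and its outputs tied to their inputs.
#'
#' @param command Character label of the command executed.
#' @param inputs Character vector of input file paths.
#' @param seed Integer seed used, or `NA`.
#' @return A list with `command`, `inputs` (path + md5), `seed`, `timestamp`,
#'   `package_version`.
#' @export
run_manifest <- function(command, inputs = character(), seed = NA_integer_) {
  sums <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  list(command = command, inputs = sums, seed = seed,
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
       package_version = as.character(utils::packageVersion("abca1fc")))
}
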