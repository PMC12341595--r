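# ACMG/AMP evidence combination with the ABCA1-specific calibration.
#
# Criterion tokens look like "PM2", "PP4_strong", "PM1_supporting",
# "BS3_moderate": the code determines direction (pathogenic/benign) and its
# native strength; an optional suffix overrides the strength. A benign
# criterion applied at moderate strength counts as two supporting benign
# criteria (the ClinGen SVI equivalence used for BS3_moderate). Combining
# rules follow the standard ACMG/AMP tables; conflicting pathogenic and
# benign rule hits resolve to class 3 (uncertain significance).

ACMG_CODES <- c("PVS1",
                paste0("PS", 1:4), paste0("PM", 1:6), paste0("PP", 1:5),
                "BA1", paste0("BS", 1:4), paste0("BP", 1:7))

ACMG_STRENGTHS <- c("stand_alone", "very_strong", "strong", "moderate", "supporting")

native_strength <- function(code) {
  switch(substr(code, 1, 2),
         PV = "very_strong",
         PS = "strong",
         PM = "moderate",
         PP = "supporting",
         BA = "stand_alone",
         BS = "strong",
         BP = "supporting",
         stop("unknown ACMG criterion code: '", code, "'", call. = FALSE))
}

#' Parse an ACMG criterion token
#'
#' @param token A string like `"PM2"`, `"PP4_strong"` or `"BS3_moderate"`.
#' @return A list with `code`, `strength`, `benign` (logical), `token`
#'   (normalized: suffix dropped when it equals the native strength).
#' @examples
#' parse_criterion("PP4_strong")
#' @export
parse_criterion <- function(token) {
  token <- trimws(token)
  parts <- strsplit(token, "_", fixed = TRUE)[[1]]
  code <- toupper(parts[1])
  if (!code %in% ACMG_CODES)
    stop("unknown ACMG criterion code: '", token, "'", call. = FALSE)
  strength <- native_strength(code)
  if (length(parts) > 1L) {
    override <- paste(tolower(parts[-1]), collapse = "_")
    if (!override %in% ACMG_STRENGTHS)
      stop("unknown strength modifier in '", token, "'", call. = FALSE)
    strength <- override
  }
  benign <- substr(code, 1, 1) == "B"
  if (benign && strength == "very_strong")
    stop("benign criteria cannot carry very_strong strength: '", token, "'",
         call. = FALSE)
  if (!benign && strength == "stand_alone")
    stop("stand_alone strength is reserved for benign criteria: '", token, "'",
         call. = FALSE)
  norm <- if (strength == native_strength(code)) code
          else paste0(code, "_", strength)
  list(code = code, strength = strength, benign = benign, token = norm)
}

#' Combine ACMG/AMP criteria into the five-tier class
#'
#' Tallies pathogenic evidence by strength (very strong / strong / moderate /
#' supporting) and benign evidence (stand-alone / strong / supporting, with a
#' benign criterion at moderate strength counted as two supporting) and
#' applies the standard combining rules:
#'
#' * Pathogenic (5): 1 very strong with (>=1 strong, or >=2 moderate, or
#'   1 moderate + 1 supporting, or >=2 supporting); or >=2 strong; or 1 strong
#'   with (>=3 moderate, or 2 moderate + >=2 supporting, or
#'   1 moderate + >=4 supporting).
#' * Likely pathogenic (4): 1 very strong + 1 moderate; 1 strong +
#'   1-2 moderate; 1 strong + >=2 supporting; >=3 moderate; 2 moderate +
#'   >=2 supporting; 1 moderate + >=4 supporting.
#' * Benign (1): stand-alone (BA1); or >=2 benign strong.
#' * Likely benign (2): 1 benign strong + 1 benign supporting; or >=2 benign
#'   supporting.
#'
#' If both a pathogenic and a benign rule fire, or none does, the class is 3
#' (uncertain significance). Duplicate criterion codes are rejected.
#'
#' @param criteria Character vector of criterion tokens (possibly empty).
#' @return Integer class 1-5. The evidence tally is attached as attribute
#'   `"tally"`.
#' @examples
#' combine_criteria(c("PM2", "PM3", "PP3", "PP4_strong", "PS3_moderate"))
#' combine_criteria(c("BS1", "BS3_moderate"))
#' @export
combine_criteria <- function(criteria) {
  parsed <- lapply(criteria, parse_criterion)
  codes <- vapply(parsed, `[[`, character(1), "code")
  if (anyDuplicated(codes))
    stop("duplicate criterion code(s): ",
         paste(unique(codes[duplicated(codes)]), collapse = ", "), call. = FALSE)

  vs <- s <- m <- p <- 0L          # pathogenic tallies
  ba <- bs <- bp <- 0L             # benign tallies
  for (cr in parsed) {
    if (cr$benign) {
      switch(cr$strength,
             stand_alone = ba <- ba + 1L,
             strong      = bs <- bs + 1L,
             moderate    = bp <- bp + 2L,  # ClinGen: moderate benign = 2 supporting
             supporting  = bp <- bp + 1L)
    } else {
      switch(cr$strength,
             very_strong = vs <- vs + 1L,
             strong      = s <- s + 1L,
             moderate    = m <- m + 1L,
             supporting  = p <- p + 1L)
    }
  }

  pathogenic <- (vs >= 1L && (s >= 1L || m >= 2L || (m >= 1L && p >= 1L) || p >= 2L)) ||
    s >= 2L ||
    (s >= 1L && (m >= 3L || (m >= 2L && p >= 2L) || (m >= 1L && p >= 4L)))
  likely_pathogenic <- (vs >= 1L && m >= 1L) ||
    (s >= 1L && m >= 1L) || (s >= 1L && p >= 2L) ||
    m >= 3L || (m >= 2L && p >= 2L) || (m >= 1L && p >= 4L)
  benign <- ba >= 1L || bs >= 2L
  likely_benign <- (bs >= 1L && bp >= 1L) || bp >= 2L

  path_hit <- pathogenic || likely_pathogenic
  benign_hit <- benign || likely_benign
  cls <- if (path_hit && benign_hit) 3L
         else if (pathogenic) 5L
         else if (likely_pathogenic) 4L
         else if (benign) 1L
         else if (likely_benign) 2L
         else 3L
  structure(cls, tally = c(vs = vs, s = s, m = m, p = p, ba = ba, bs = bs, bp = bp))
}

#' Allele-frequency criterion
#'
#' Gene-calibrated frequency rule: filtering allele frequency at or above the
#' BA1 cutoff yields `"BA1"` (stand-alone benign); else at or above the BS1
#' cutoff yields `"BS1"` (strong benign); else at or below the PM2 cutoff
#' yields `"PM2"` (moderate pathogenic); otherwise (or when the frequency is
#' missing) no criterion.
#'
#' @param faf Filtering allele frequency in `[0, 1]` or `NA`.
#' @param config A [calibration_config()].
#' @return A criterion token or `NULL`.
#' @export
frequency_criteria <- function(faf, config = calibration_config()) {
  if (is.na(faf)) return(NULL)
  if (faf < 0 || faf > 1)
    stop("filtering allele frequency outside [0, 1]: ", faf, call. = FALSE)
  if (faf >= config$freq_ba1) "BA1"
  else if (faf >= config$freq_bs1) "BS1"
  else if (faf <= config$freq_pm2) "PM2"
  else NULL
}

#' Phenotype-specificity criterion (PP4, tiered)
#'
#' PP4 at supporting strength for a carrier with HDL-C below 0.5 mmol/l,
#' moderate below 0.3 mmol/l, strong below 0.1 mmol/l or with Tangier
#' disease; the strictest satisfied tier wins.
#'
#' @param hdl_c HDL cholesterol in mmol/l, or `NA`.
#' @param tangier Logical Tangier-disease flag.
#' @param config A [calibration_config()].
#' @return A criterion token (`"PP4"`, `"PP4_moderate"`, `"PP4_strong"`) or
#'   `NULL`.
#' @export
phenotype_criterion <- function(hdl_c, tangier = FALSE,
                                config = calibration_config()) {
  if (!is.na(hdl_c) && hdl_c < 0)
    stop("HDL-C must be non-negative: ", hdl_c, call. = FALSE)
  if (isTRUE(tangier) || (!is.na(hdl_c) && hdl_c < config$pp4_strong_hdl))
    return("PP4_strong")
  if (is.na(hdl_c)) return(NULL)
  if (hdl_c < config$pp4_moderate_hdl) return("PP4_moderate")
  if (hdl_c < config$pp4_supporting_hdl) return("PP4")
  NULL
}

#' Functional-assay criterion from the efflux category
#'
#' Loss-of-function yields PS3, functionally normal yields BS3, both at the
#' validated assay strength; an uncertain category contributes no evidence.
#'
#' @param category `"loss_of_function"`, `"normal"`, `"uncertain"` or `NA`.
#' @param assay_strength `"moderate"` or `"supporting"`, from
#'   [validate_assay()].
#' @return A criterion token or `NULL`.
#' @export
functional_criterion <- function(category, assay_strength = "moderate") {
  if (is.null(category) || is.na(category) || category == "uncertain") return(NULL)
  stopifnot(assay_strength %in% c("moderate", "supporting"))
  code <- switch(category,
                 loss_of_function = "PS3",
                 normal = "BS3",
                 stop("unknown efflux category: '", category, "'", call. = FALSE))
  if (assay_strength == native_strength(code)) code
  else paste0(code, "_", assay_strength)
}

#' Maximum permitted strength of the functional assay evidence
#'
#' ClinGen-style assay validation: moderate strength requires normal and null
#' controls, sample replicates, and at least the configured number
#' (default 11) of variant controls with ACMG/AMP class 1, 2, 4 or 5;
#' otherwise the assay supports only supporting strength.
#'
#' @param n_variant_controls Count of class-1/2/4/5 variant controls.
#' @param has_normal_and_null_controls,has_replicates Logical assay-design
#'   flags.
#' @param config A [calibration_config()].
#' @return `"moderate"` or `"supporting"`.
#' @export
validate_assay <- function(n_variant_controls, has_normal_and_null_controls,
                           has_replicates, config = calibration_config()) {
  stopifnot(n_variant_controls >= 0)
  if (isTRUE(has_normal_and_null_controls) && isTRUE(has_replicates) &&
      n_variant_controls >= config$min_variant_controls_for_moderate)
    "moderate"
  else "supporting"
}

#' Classify one variant with and without functional evidence
#'
#' Builds the criterion set from the asserted tokens plus the derived
#' frequency and phenotype rules (an asserted token wins on a code
#' collision), computes the class, then adds the functional-assay criterion
#' implied by the efflux category and recomputes.
#'
#' @param variant A [variant_record()], or a protein variant name (then
#'   `faf`/`hdl_c`/`tangier`/`criteria` may be passed directly).
#' @param category Efflux category for the variant, or `NA`.
#' @param config A [calibration_config()].
#' @param assay_strength Strength at which PS3/BS3 is applied.
#' @inheritParams variant_record
#' @return A list of class `"classification_result"`: `variant`,
#'   `criteria_without`, `class_without`, `criteria_with`, `class_with`,
#'   `changed`.
#' @export
classify_variant <- function(variant, category = NA_character_,
                             config = calibration_config(),
                             assay_strength = "moderate",
                             faf = NA_real_, hdl_c = NA_real_,
                             tangier = FALSE, criteria = character()) {
  if (!inherits(variant, "variant_record"))
    variant <- variant_record(variant, faf = faf, hdl_c = hdl_c,
                              tangier = tangier, criteria = criteria)
  asserted <- variant$criteria
  asserted_codes <- vapply(asserted, function(tk) parse_criterion(tk)$code, character(1))
  derived <- c(frequency_criteria(variant$faf, config),
               phenotype_criterion(variant$hdl_c, variant$tangier, config))
  if (length(derived)) {
    derived_codes <- vapply(derived, function(tk) parse_criterion(tk)$code, character(1))
    derived <- derived[!derived_codes %in% asserted_codes]
  }
  without <- c(asserted, derived)
  class_without <- as.integer(combine_criteria(without))
  fc <- functional_criterion(category, assay_strength)
  with <- c(without, fc)
  class_with <- as.integer(combine_criteria(with))
  structure(list(variant = variant$name,
                 criteria_without = without, class_without = class_without,
                 criteria_with = with, class_with = class_with,
                 changed = class_without != class_with),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("%s: class %d {%s}", x$variant, x$class_without,
              paste(x$criteria_without, collapse = ", ")))
  cat(sprintf(" -> class %d {%s}%s\n", x$class_with,
              paste(x$criteria_with, collapse = ", "),
              if (x$changed) "  [changed]" else ""))
  invisible(x)
}

#' Classify a table of variants
#'
#' @param variants Data frame with columns `variant_p` and optionally
#'   `variant_c`, `faf`, `hdl_c`, `tangier`, `criteria`
#'   (semicolon-separated tokens; `"."` or `""` for none).
#' @param categories Named character vector (or data frame with
#'   `construct_id`/`category` columns, e.g. an `"efflux_result"`) mapping
#'   variant names to efflux categories; variants without an entry receive no
#'   functional evidence.
#' @param config A [calibration_config()].
#' @param assay_strength Strength at which PS3/BS3 is applied.
#' @return A data frame of class `"abca1_classification"`: `variant`,
#'   `category`, `criteria_without`, `class_without`, `criteria_with`,
#'   `class_with`, `changed`.
#' @export
classify_variants <- function(variants, categories = NULL,
                              config = calibration_config(),
                              assay_strength = "moderate") {
  if (is.data.frame(categories)) {
    nm <- if ("construct_id" %in% names(categories)) "construct_id" else "variant"
    categories <- stats::setNames(categories$category, categories[[nm]])
  }
  if (!nrow(variants)) {
    return(structure(data.frame(variant = character(), category = character(),
                                criteria_without = character(),
                                class_without = integer(),
                                criteria_with = character(),
                                class_with = integer(), changed = logical(),
                                stringsAsFactors = FALSE),
                     class = c("abca1_classification", "data.frame")))
  }
  get_col <- function(col, default) {
    if (col %in% names(variants)) variants[[col]] else rep(default, nrow(variants))
  }
  faf <- suppressWarnings(as.numeric(get_col("faf", NA)))
  hdl <- suppressWarnings(as.numeric(get_col("hdl_c", NA)))
  tng <- as.logical(get_col("tangier", FALSE)); tng[is.na(tng)] <- FALSE
  crit <- as.character(get_col("criteria", ""))
  rows <- lapply(seq_len(nrow(variants)), function(i) {
    name <- variants$variant_p[i]
    tokens <- split_criteria(crit[i])
    cat_i <- if (!is.null(categories) && name %in% names(categories))
      categories[[name]] else NA_character_
    r <- classify_variant(name, category = cat_i, config = config,
                          assay_strength = assay_strength,
                          faf = faf[i], hdl_c = hdl[i], tangier = tng[i],
                          criteria = tokens)
    data.frame(variant = r$variant, category = cat_i,
               criteria_without = paste(r$criteria_without, collapse = ";"),
               class_without = r$class_without,
               criteria_with = paste(r$criteria_with, collapse = ";"),
               class_with = r$class_with, changed = r$changed,
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows), class = c("abca1_classification", "data.frame"))
}

split_criteria <- function(x) {
  if (is.na(x) || x %in% c("", ".", "-")) return(character())
  trimws(strsplit(x, ";", fixed = TRUE)[[1]])
}

#' Summarize class transitions
#'
#' @param results An `"abca1_classification"` data frame.
#' @return A list with `transitions` (data frame `from` / `to` / `n` for every
#'   observed without-to-with pair), `n_changed`, `n_total`.
#' @export
reclassification_report <- function(results) {
  if (!nrow(results)) {
    return(list(transitions = data.frame(from = integer(), to = integer(),
                                         n = integer()),
                n_changed = 0L, n_total = 0L))
  }
  tab <- as.data.frame(table(from = results$class_without,
                             to = results$class_with),
                       stringsAsFactors = FALSE)
  tab <- tab[tab$Freq > 0L, ]
  transitions <- data.frame(from = as.integer(tab$from), to = as.integer(tab$to),
                            n = as.integer(tab$Freq))
  transitions <- transitions[order(transitions$from, transitions$to), ]
  rownames(transitions) <- NULL
  list(transitions = transitions,
       n_changed = sum(results$changed),
       n_total = nrow(results))
}

#' @export
print.abca1_classification <- function(x, ...) {
  rep <- reclassification_report(x)
  cat("<abca1_classification>", rep$n_total, "variants,",
      rep$n_changed, "reclassified by functional evidence\n")
  ch <- rep$transitions[rep$transitions$from != rep$transitions$to, , drop = FALSE]
  if (nrow(ch)) {
    for (i in seq_len(nrow(ch)))
      cat(sprintf("  class %d -> %d: %d\n", ch$from[i], ch$to[i], ch$n[i]))
  }
  invisible(x)
}

#' @export
summary.abca1_classification <- function(object, ...) {
  rep <- reclassification_report(object)
  cat("Baseline classes (without functional evidence):\n")
  print(table(factor(object$class_without, levels = 1:5)))
  cat("Classes with functional evidence:\n")
  print(table(factor(object$class_with, levels = 1:5)))
  cat("Changed:", rep$n_changed, "of", rep$n_total, "\n")
  invisible(rep)
}
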