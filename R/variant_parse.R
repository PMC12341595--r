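# Amino-acid code tables. The assay covers missense substitutions only, so
# stop ("X", "Ter") and ambiguity codes are deliberately unsupported.
AA_3TO1 <- c(
  Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C",
  Gln = "Q", Glu = "E", Gly = "G", His = "H", Ile = "I",
  Leu = "L", Lys = "K", Met = "M", Phe = "F", Pro = "P",
  Ser = "S", Thr = "T", Trp = "W", Tyr = "Y", Val = "V"
)
AA_1 <- unname(AA_3TO1)

#' Normalize an amino-acid code to its 1-letter form
#'
#' @param code A 1-letter (e.g. `"K"`) or 3-letter (e.g. `"Lys"`) amino-acid
#'   code; 3-letter codes are case-insensitive.
#' @return The 1-letter code.
#' @keywords internal
aa_to_1 <- function(code) {
  if (nchar(code) == 1L) {
    up <- toupper(code)
    if (!up %in% AA_1) stop("unknown amino-acid code: '", code, "'", call. = FALSE)
    return(up)
  }
  key <- paste0(toupper(substr(code, 1, 1)), tolower(substr(code, 2, 3)))
  out <- AA_3TO1[key]
  if (is.na(out)) stop("unknown amino-acid code: '", code, "'", call. = FALSE)
  unname(out)
}

#' Parse a protein-level missense variant name
#'
#' Parses names of the form `p.<ref><position><alt>` with 1- or 3-letter
#' amino-acid codes (the `p.` prefix is optional). Positions are 1-based codon
#' numbers on the reference transcript (NM_005502.4 for ABCA1, ATG = codon 1).
#'
#' @param name Character vector of variant names, e.g. `"p.W590S"` or
#'   `"p.Lys939Met"`.
#' @return A data frame with columns `name`, `ref_aa`, `position`, `alt_aa`
#'   (1-letter codes).
#' @examples
#' parse_protein_variant(c("p.W590S", "p.Lys939Met"))
#' @export
parse_protein_variant <- function(name) {
  stopifnot(is.character(name), length(name) >= 1L)
  m <- regmatches(name, regexec("^(?:p\\.)?([A-Za-z]{3}|[A-Za-z])([0-9]+)([A-Za-z]{3}|[A-Za-z])$",
                                trimws(name)))
  out <- lapply(seq_along(name), function(i) {
    g <- m[[i]]
    if (length(g) != 4L)
      stop("malformed protein variant name: '", name[i], "'", call. = FALSE)
    ref <- aa_to_1(g[2])
    alt <- aa_to_1(g[4])
    pos <- as.integer(g[3])
    if (pos < 1L) stop("position must be >= 1 in '", name[i], "'", call. = FALSE)
    if (ref == alt)
      stop("reference and alternate residues are identical in '", name[i], "'",
           call. = FALSE)
    data.frame(name = name[i], ref_aa = ref, position = pos, alt_aa = alt,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Construct a variant record
#'
#' Bundles a parsed protein change with its annotations: optional cDNA name,
#' filtering allele frequency, patient phenotype (HDL-C in mmol/l, Tangier
#' disease flag) and ACMG/AMP criteria asserted upstream of this package.
#'
#' @param variant_p Protein variant name (HGVS p. style).
#' @param variant_c Optional cDNA HGVS string (metadata only).
#' @param faf Filtering allele frequency in `[0, 1]`, or `NA`.
#' @param hdl_c Patient HDL cholesterol in mmol/l, or `NA`.
#' @param tangier Logical; Tangier disease in the carrier.
#' @param criteria Character vector of asserted ACMG criterion tokens,
#'   e.g. `c("PM2", "PP4_strong")`.
#' @return A list of class `"variant_record"`.
#' @export
variant_record <- function(variant_p, variant_c = NA_character_, faf = NA_real_,
                           hdl_c = NA_real_, tangier = FALSE,
                           criteria = character()) {
  parsed <- parse_protein_variant(variant_p)
  if (!is.na(faf) && (faf < 0 || faf > 1))
    stop("filtering allele frequency must lie in [0, 1]: ", faf, call. = FALSE)
  if (!is.na(hdl_c) && hdl_c < 0)
    stop("HDL-C must be non-negative: ", hdl_c, call. = FALSE)
  criteria <- criteria[nzchar(criteria)]
  if (length(criteria)) lapply(criteria, parse_criterion)  # validate tokens
  structure(list(
    name = parsed$name, ref_aa = parsed$ref_aa, position = parsed$position,
    alt_aa = parsed$alt_aa, variant_c = variant_c, faf = faf, hdl_c = hdl_c,
    tangier = isTRUE(tangier), criteria = criteria
  ), class = "variant_record")
}

#' @export
print.variant_record <- function(x, ...) {
  cat(sprintf("<variant_record> %s (%s%d%s)\n", x$name, x$ref_aa, x$position, x$alt_aa))
  if (!is.na(x$faf)) cat("  filtering allele frequency:", format(x$faf), "\n")
  if (!is.na(x$hdl_c)) cat("  HDL-C:", x$hdl_c, "mmol/l\n")
  if (x$tangier) cat("  Tangier disease\n")
  if (length(x$criteria)) cat("  asserted criteria:", paste(x$criteria, collapse = ", "), "\n")
  invisible(x)
}
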