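# NBD1 <-> NBD2 equivalence mapping. The two nucleotide-binding domains of
# ABCA1 are homologous; a deterministic global (Needleman-Wunsch) pairwise
# alignment of the two windows (BLOSUM62, gap open 10 / extend 0.5) yields a
# monotone map of equivalent residue positions in full-protein coordinates,
# from which mirrored ("equivalent") variants are proposed at conserved
# positions.

blosum62_matrix <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

#' Align the two nucleotide-binding domains of a protein sequence
#'
#' Extracts the two windows (inclusive, 1-based, full-protein coordinates),
#' aligns them globally, and records every matched (non-gap) column as an
#' equivalent position pair.
#'
#' @param sequence Protein sequence: a character string, an
#'   `Biostrings::AAString`, or a named character vector of length 1 (e.g.
#'   from a FASTA file).
#' @param nbd1_window,nbd2_window Integer length-2 vectors `c(start, end)`.
#'   Defaults are the ABCA1 NBD alignment windows 923-1121 and 1936-2134.
#' @param gap_open,gap_extend Gap penalties (positive costs).
#' @param substitution_matrix Scoring matrix name or matrix; default BLOSUM62.
#' @return An object of class `"nbd_equivalence"`: a list with `pairs`
#'   (data frame `nbd1_pos`, `nbd2_pos`, `nbd1_aa`, `nbd2_aa`, `conserved`,
#'   `positive_score`), `n_columns` (alignment columns incl. gaps),
#'   `percent_identity`, `percent_similarity`, `params`, and the two aligned
#'   (gapped) strings.
#' @export
align_nbds <- function(sequence,
                       nbd1_window = c(923, 1121),
                       nbd2_window = c(1936, 2134),
                       gap_open = 10, gap_extend = 0.5,
                       substitution_matrix = "BLOSUM62") {
  if (inherits(sequence, "XStringSet")) sequence <- as.character(sequence)[1]
  sequence <- toupper(as.character(sequence)[1])
  n <- nchar(sequence)
  check_window <- function(w, label) {
    if (length(w) != 2L || w[1] > w[2] || w[1] < 1L || w[2] > n)
      stop(label, " window out of bounds for a sequence of length ", n,
           call. = FALSE)
  }
  check_window(nbd1_window, "NBD1"); check_window(nbd2_window, "NBD2")
  s1 <- substr(sequence, nbd1_window[1], nbd1_window[2])
  s2 <- substr(sequence, nbd2_window[1], nbd2_window[2])

  subst <- if (is.character(substitution_matrix)) {
    if (substitution_matrix != "BLOSUM62") {
      e <- new.env()
      utils::data(list = substitution_matrix, package = "Biostrings", envir = e)
      get(substitution_matrix, envir = e)
    } else blosum62_matrix()
  } else substitution_matrix

  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(s1), Biostrings::AAString(s2),
    type = "global", substitutionMatrix = subst,
    gapOpening = gap_open, gapExtension = gap_extend)
  a1 <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  a2 <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]

  i1 <- cumsum(a1 != "-"); i2 <- cumsum(a2 != "-")
  matched <- which(a1 != "-" & a2 != "-")
  pos_score <- vapply(matched, function(k) subst[a1[k], a2[k]] > 0, logical(1))
  pairs <- data.frame(
    nbd1_pos = nbd1_window[1] - 1L + i1[matched],
    nbd2_pos = nbd2_window[1] - 1L + i2[matched],
    nbd1_aa = a1[matched], nbd2_aa = a2[matched],
    conserved = a1[matched] == a2[matched],
    positive_score = pos_score,
    stringsAsFactors = FALSE)

  n_col <- length(a1)
  structure(list(
    pairs = pairs,
    n_columns = n_col,
    percent_identity = 100 * sum(pairs$conserved) / n_col,
    percent_similarity = 100 * sum(pairs$positive_score) / n_col,
    params = list(nbd1_window = nbd1_window, nbd2_window = nbd2_window,
                  gap_open = gap_open, gap_extend = gap_extend,
                  substitution_matrix = if (is.character(substitution_matrix))
                    substitution_matrix else "custom"),
    aligned_nbd1 = paste(a1, collapse = ""),
    aligned_nbd2 = paste(a2, collapse = "")
  ), class = "nbd_equivalence")
}

#' @export
print.nbd_equivalence <- function(x, ...) {
  cat(sprintf("<nbd_equivalence> %d aligned pairs over %d columns\n",
              nrow(x$pairs), x$n_columns))
  cat(sprintf("  windows: %d-%d vs %d-%d\n",
              x$params$nbd1_window[1], x$params$nbd1_window[2],
              x$params$nbd2_window[1], x$params$nbd2_window[2]))
  cat(sprintf("  identity %.1f%%, similarity %.1f%% (positive %s score, gaps in denominator)\n",
              x$percent_identity, x$percent_similarity,
              x$params$substitution_matrix))
  invisible(x)
}

#' Propose the equivalent variant in the opposite NBD
#'
#' A variant inside one NBD window is mirrored to the aligned position in the
#' other domain, but only when the aligned residues are identical (conserved
#' column) and match the variant's reference residue.
#'
#' @param variant A protein variant name or [variant_record()].
#' @param map An `"nbd_equivalence"` from [align_nbds()].
#' @return The mirrored variant name (e.g. `"p.S2046N"`), or `NULL` when the
#'   aligned column is not conserved, the reference residue disagrees with
#'   the sequence, or the position is unaligned.
#' @export
equivalent_variant <- function(variant, map) {
  stopifnot(inherits(map, "nbd_equivalence"))
  v <- if (inherits(variant, "variant_record")) variant
       else parse_protein_variant(variant)
  pos <- v$position[1]; ref <- v$ref_aa[1]; alt <- v$alt_aa[1]
  w1 <- map$params$nbd1_window; w2 <- map$params$nbd2_window
  in1 <- pos >= w1[1] && pos <= w1[2]
  in2 <- pos >= w2[1] && pos <= w2[2]
  if (!in1 && !in2)
    stop("position ", pos, " lies in neither NBD window", call. = FALSE)
  p <- map$pairs
  row <- if (in1) p[p$nbd1_pos == pos, ] else p[p$nbd2_pos == pos, ]
  if (!nrow(row) || !row$conserved[1]) return(NULL)
  here_aa <- if (in1) row$nbd1_aa[1] else row$nbd2_aa[1]
  if (here_aa != ref) return(NULL)
  mirrored_pos <- if (in1) row$nbd2_pos[1] else row$nbd1_pos[1]
  sprintf("p.%s%d%s", ref, mirrored_pos, alt)
}

#' Inter-domain identity and similarity
#'
#' Identity: identical aligned pairs over all alignment columns (gaps in the
#' denominator). Similarity: aligned pairs with a positive substitution-matrix
#' score over all columns.
#'
#' @param map An `"nbd_equivalence"`.
#' @return Named numeric vector `c(identity = , similarity = )`, percent.
#' @export
domain_similarity <- function(map) {
  stopifnot(inherits(map, "nbd_equivalence"))
  if (!nrow(map$pairs)) stop("empty equivalence map", call. = FALSE)
  c(identity = map$percent_identity, similarity = map$percent_similarity)
}
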