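# ABCA1 topological regions and ATP-binding motifs, inclusive 1-based residue
# ranges on the NM_005502.4 protein product. Only ranges with published residue
# bounds for the intracellular regions are encoded; positions outside them map
# to "linker/other" rather than to invented ECD/TMD ranges.

#' Read a domain map from JSON
#'
#' The JSON layout is `{"regions":[{"name","start","end"},...],
#' "motifs":[{"name","domain","start","end"},...]}`. Ranges are inclusive and
#' 1-based. Motif ranges must fall inside their parent region.
#'
#' @param path Path to a JSON file.
#' @return A validated object of class `"domain_map"`.
#' @seealso [abca1_domain_map()] for the shipped default.
#' @export
read_domain_map <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  validate_domain_map(structure(list(
    regions = as.data.frame(raw$regions, stringsAsFactors = FALSE),
    motifs  = as.data.frame(raw$motifs,  stringsAsFactors = FALSE)
  ), class = "domain_map"))
}

#' The ABCA1 intracellular-domain map
#'
#' Default map of ABCA1 intracellular regions: the two nucleotide-binding
#' domains (NBD1 903-1147, NBD2 1907-2143), the regulatory domains
#' (R1 1182-1251, R2 2155-2220), the four intracellular coupling helices
#' (IH1 3-20, IH2 667-673, IH3 1327-1344, IH4 1684-1690), and the Walker A
#' (926-942 / 1939-1955), Walker B (1056-1065 / 2068-2077) and signature
#' (1033-1040 / 2045-2052) ATP-binding motifs within the NBDs.
#'
#' @return An object of class `"domain_map"` with `regions` and `motifs`
#'   data frames.
#' @export
abca1_domain_map <- function() {
  read_domain_map(system.file("extdata", "abca1_domain_map.json",
                              package = "abca1fc", mustWork = TRUE))
}

validate_domain_map <- function(map) {
  r <- map$regions; m <- map$motifs
  stopifnot(all(c("name", "start", "end") %in% names(r)))
  r$start <- as.integer(r$start); r$end <- as.integer(r$end)
  if (any(r$start > r$end)) stop("region with start > end", call. = FALSE)
  if (anyDuplicated(r$name)) stop("duplicate region names", call. = FALSE)
  # regions must not overlap (assignment is a partition)
  o <- order(r$start)
  if (any(r$start[o][-1] <= r$end[o][-nrow(r)]))
    stop("overlapping region ranges", call. = FALSE)
  if (nrow(m)) {
    stopifnot(all(c("name", "domain", "start", "end") %in% names(m)))
    m$start <- as.integer(m$start); m$end <- as.integer(m$end)
    for (i in seq_len(nrow(m))) {
      parent <- r[r$name == m$domain[i], ]
      if (nrow(parent) != 1L || m$start[i] < parent$start || m$end[i] > parent$end)
        stop("motif '", m$name[i], "' not inside its parent region '",
             m$domain[i], "'", call. = FALSE)
    }
  }
  map$regions <- r; map$motifs <- m
  map
}

#' @export
print.domain_map <- function(x, ...) {
  cat("<domain_map>", nrow(x$regions), "regions,", nrow(x$motifs), "motifs\n")
  print(x$regions, row.names = FALSE)
  invisible(x)
}

#' Assign protein positions to topological regions
#'
#' Every position gets exactly one label: the unique region whose range
#' contains it, or `"linker/other"` when no encoded range does.
#'
#' @param position Integer vector of 1-based residue positions.
#' @param map A `"domain_map"`; defaults to the shipped ABCA1 map.
#' @return Character vector of region names.
#' @examples
#' assign_region(c(11, 1244, 1))
#' @export
assign_region <- function(position, map = abca1_domain_map()) {
  stopifnot(all(position >= 1))
  r <- map$regions
  vapply(position, function(p) {
    hit <- which(r$start <= p & p <= r$end)
    if (length(hit)) r$name[hit[1]] else "linker/other"
  }, character(1))
}

#' Assign protein positions to ATP-binding motifs
#'
#' @inheritParams assign_region
#' @param qualify If `TRUE` (default) labels carry the parent domain, e.g.
#'   `"Walker_A(NBD2)"`; otherwise just the motif name.
#' @return Character vector of motif labels, `NA` where the position lies in
#'   no motif.
#' @examples
#' assign_motif(c(1948, 2046, 1100))
#' @export
assign_motif <- function(position, map = abca1_domain_map(), qualify = TRUE) {
  stopifnot(all(position >= 1))
  m <- map$motifs
  vapply(position, function(p) {
    hit <- which(m$start <= p & p <= m$end)
    if (!length(hit)) return(NA_character_)
    if (qualify) sprintf("%s(%s)", m$name[hit[1]], m$domain[hit[1]]) else m$name[hit[1]]
  }, character(1))
}

#' Count variants per topological region
#'
#' @param variants Character vector of protein variant names, or a data frame
#'   with a `position` column (e.g. from [parse_protein_variant()]).
#' @param map A `"domain_map"`.
#' @return A data frame `region` / `n` covering every region in the map plus
#'   `"linker/other"`; counts sum to the number of input variants.
#' @export
count_by_region <- function(variants, map = abca1_domain_map()) {
  pos <- if (is.character(variants)) {
    if (length(variants)) parse_protein_variant(variants)$position else integer()
  } else variants$position
  lab <- if (length(pos)) assign_region(pos, map) else character()
  levels <- c(map$regions$name, "linker/other")
  tab <- table(factor(lab, levels = levels))
  data.frame(region = names(tab), n = as.integer(tab), row.names = NULL,
             stringsAsFactors = FALSE)
}
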