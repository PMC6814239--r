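# Shared small helpers.

# Missing-value sentinels used by ANNOVAR/VEP outputs.
MISSING_SENTINELS <- c(".", "", "NA", "na", "NaN")

is_absent <- function(x) {
  is.na(x) | (as.character(x) %in% MISSING_SENTINELS)
}

#' Convert an annotation string to numeric, mapping sentinels to NA
#' @noRd
parse_num <- function(x) {
  x <- as.character(x)
  x[is_absent(x)] <- NA_character_
  suppressWarnings(as.numeric(x))
}

parse_chr <- function(x) {
  x <- as.character(x)
  x[is_absent(x)] <- NA_character_
  x
}

# Three-letter -> one-letter amino acid codes (protein change parsing).
AA3TO1 <- c(
  Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C", Gln = "Q",
  Glu = "E", Gly = "G", His = "H", Ile = "I", Leu = "L", Lys = "K",
  Met = "M", Phe = "F", Pro = "P", Ser = "S", Thr = "T", Trp = "W",
  Tyr = "Y", Val = "V", Ter = "*"
)

#' Parse a protein-change string into residue components
#'
#' Accepts one-letter ("p.R175H") or three-letter ("p.Arg175His") HGVS-like
#' notation. Returns NULL when the string cannot be parsed.
#' @noRd
parse_aa_change <- function(aa) {
  if (length(aa) != 1 || is.na(aa)) return(NULL)
  m <- stringr::str_match(aa, "p\\.([A-Z*])([0-9]+)([A-Z*])$")
  if (!is.na(m[1, 1])) {
    return(list(ref = m[1, 2], pos = as.integer(m[1, 3]), alt = m[1, 4]))
  }
  m <- stringr::str_match(aa, "p\\.([A-Z][a-z]{2})([0-9]+)([A-Z][a-z]{2}|\\*)$")
  if (!is.na(m[1, 1])) {
    ref <- unname(AA3TO1[m[1, 2]])
    alt <- if (m[1, 4] == "*") "*" else unname(AA3TO1[m[1, 4]])
    if (is.na(ref) || is.na(alt)) return(NULL)
    return(list(ref = ref, pos = as.integer(m[1, 3]), alt = alt))
  }
  NULL
}

# Extract the first protein-change token from an ANNOVAR AAChange field,
# e.g. "TP53:NM_000546:exon5:c.524G>A:p.R175H,..." -> "p.R175H".
extract_p_notation <- function(x) {
  if (is.na(x)) return(NA_character_)
  hit <- stringr::str_extract(x, "p\\.[A-Za-z*]+[0-9]+[A-Za-z*]+")
  hit
}
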