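# IUPAC degeneracy handling for splice-motif patterns.

iupac_letters <- function() names(Biostrings::IUPAC_CODE_MAP)

# Degeneracy set of one IUPAC letter, as a character vector of concrete bases.
# N in the subject sequence never matches unless allow_n_match is TRUE: calls
# inside assembly gaps are suppressed by default.
iupac_bases <- function(letter, allow_n_match = FALSE) {
  set <- Biostrings::IUPAC_CODE_MAP[[letter]]
  if (is.null(set) || is.na(set))
    stop("not an IUPAC nucleotide letter: '", letter, "'")
  bases <- strsplit(set, "")[[1]]
  if (allow_n_match) bases <- unique(c(bases, "N"))
  bases
}

#' Test a fixed-width window against an IUPAC pattern
#'
#' Returns `TRUE` iff every position of `window` lies in the degeneracy set of
#' the corresponding pattern letter. The comparison is in DNA space; `U` in
#' either argument is treated as `T`.
#'
#' @param pattern IUPAC string (e.g. `"GTRHGH"`).
#' @param window DNA string of the same length.
#' @param allow_n_match if `TRUE`, `N` in the window matches every pattern
#'   letter; by default `N` matches nothing.
#' @return logical scalar.
#' @examples
#' match_iupac("GTRHGH", "GTGAGT")
#' match_iupac("RCTRAY", "GCTAAC")
#' @export
match_iupac <- function(pattern, window, allow_n_match = FALSE) {
  pattern <- chartr("u", "t", toupper(pattern))
  pattern <- chartr("U", "T", pattern)
  window <- chartr("U", "T", toupper(window))
  if (nchar(pattern) != nchar(window))
    stop("pattern and window lengths differ (", nchar(pattern), " vs ",
         nchar(window), ")")
  p <- strsplit(pattern, "")[[1]]
  w <- strsplit(window, "")[[1]]
  bad <- setdiff(p, iupac_letters())
  if (length(bad))
    stop("non-IUPAC letter in pattern: ", paste(bad, collapse = ", "))
  all(vapply(seq_along(p), function(i) {
    w[i] %in% iupac_bases(p[i], allow_n_match = allow_n_match)
  }, logical(1)))
}

# Translate an IUPAC pattern into a base-R regular expression built from
# concrete-base character classes, so that N in the subject never matches
# unless requested.
iupac_regex <- function(pattern, allow_n_match = FALSE) {
  pattern <- chartr("U", "T", toupper(pattern))
  p <- strsplit(pattern, "")[[1]]
  bad <- setdiff(p, iupac_letters())
  if (length(bad))
    stop("non-IUPAC letter in pattern: ", paste(bad, collapse = ", "))
  paste0(vapply(p, function(l) {
    bases <- iupac_bases(l, allow_n_match = allow_n_match)
    if (length(bases) == 1) bases else paste0("[", paste(bases, collapse = ""), "]")
  }, character(1)), collapse = "")
}

# All 0-based start offsets at which `pattern` matches inside `subject`
# (overlapping matches included).
iupac_match_starts <- function(pattern, subject, allow_n_match = FALSE) {
  rx <- paste0("(?=", iupac_regex(pattern, allow_n_match), ")")
  m <- gregexpr(rx, subject, perl = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m) - 1L
}
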