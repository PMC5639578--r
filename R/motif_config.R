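# The splice-motif grammar that parameterises all scanning.

#' U2 splice-site motif grammar
#'
#' Defaults are the tightest IUPAC covers of the donor, lariat branch point
#' and acceptor motifs observed in the *lipS* stwintrons: donors
#' GTACGT/GTATGC/GTGAGT/GTAAGA are covered by `GTRHGH`, branch motifs
#' ACTGAC/GCTAAC/GCTAAT/GCTGAC by `RCTRAY` (branch adenosine at position 5),
#' acceptors CAG/TAG/AAG by `HAG`. The branch-to-acceptor gap default 3–12 nt
#' generously brackets the observed 4–7 nt. All values are overridable.
#'
#' @param donor_patterns character vector of IUPAC donor patterns, each
#'   beginning `GT`.
#' @param branch_pattern IUPAC branch-point pattern.
#' @param branch_a_index 1-based position of the branch adenosine within
#'   `branch_pattern`; the pattern letter there must admit `A`.
#' @param acceptor_pattern IUPAC acceptor pattern ending `AG`.
#' @param branch_to_acceptor_gap inclusive integer range (length 2) of
#'   nucleotides between branch-motif end and acceptor-motif start.
#' @param min_intron_len,max_intron_len intron length bounds (nt).
#' @param min_exon_len minimum exon length between neighbouring intervening
#'   sequences (nt); surfaced for intron-definition-style filtering.
#' @param allow_n_match if `TRUE`, `N` bases match pattern letters; off by
#'   default to avoid calls in assembly gaps.
#' @return object of class `motif_config`.
#' @export
motif_config <- function(donor_patterns = c("GTRHGH"),
                         branch_pattern = "RCTRAY",
                         branch_a_index = 5L,
                         acceptor_pattern = "HAG",
                         branch_to_acceptor_gap = c(3L, 12L),
                         min_intron_len = 40L,
                         max_intron_len = 1000L,
                         min_exon_len = 20L,
                         allow_n_match = FALSE) {
  norm <- function(p) chartr("U", "T", toupper(p))
  donor_patterns <- norm(donor_patterns)
  branch_pattern <- norm(branch_pattern)
  acceptor_pattern <- norm(acceptor_pattern)
  for (p in c(donor_patterns, branch_pattern, acceptor_pattern)) {
    bad <- setdiff(strsplit(p, "")[[1]], iupac_letters())
    if (length(bad)) stop("invalid IUPAC pattern '", p, "'")
  }
  if (any(substr(donor_patterns, 1, 2) != "GT"))
    stop("donor patterns must begin 'GT'")
  if (any(substr(acceptor_pattern, nchar(acceptor_pattern) - 1,
                 nchar(acceptor_pattern)) != "AG"))
    stop("acceptor pattern must end 'AG'")
  branch_a_index <- as.integer(branch_a_index)
  if (branch_a_index < 1 || branch_a_index > nchar(branch_pattern))
    stop("branch_a_index outside branch pattern")
  if (!"A" %in% iupac_bases(substr(branch_pattern, branch_a_index, branch_a_index)))
    stop("branch pattern letter at branch_a_index does not admit A")
  gap <- as.integer(branch_to_acceptor_gap)
  if (length(gap) != 2 || gap[1] > gap[2] || gap[1] < 0)
    stop("branch_to_acceptor_gap must be a non-empty non-negative range")
  min_intron_len <- as.integer(min_intron_len)
  max_intron_len <- as.integer(max_intron_len)
  floor_len <- min(nchar(donor_patterns)) + nchar(branch_pattern) +
    nchar(acceptor_pattern)
  if (min_intron_len < floor_len)
    stop("min_intron_len must be >= |donor| + |branch| + |acceptor| (", floor_len, ")")
  if (max_intron_len < min_intron_len) stop("empty intron length range")
  structure(list(donor_patterns = donor_patterns,
                 branch_pattern = branch_pattern,
                 branch_a_index = branch_a_index,
                 acceptor_pattern = acceptor_pattern,
                 branch_to_acceptor_gap = gap,
                 min_intron_len = min_intron_len,
                 max_intron_len = max_intron_len,
                 min_exon_len = as.integer(min_exon_len),
                 allow_n_match = isTRUE(allow_n_match)),
            class = "motif_config")
}

#' Strict-acceptor preset
#'
#' Identical to [motif_config()] but with acceptor `YAG`, excluding the `AAG`
#' acceptor observed only inside stwintron composites.
#' @param ... overrides passed to [motif_config()].
#' @export
motif_config_strict_acceptor <- function(...) {
  motif_config(acceptor_pattern = "YAG", ...)
}

#' @export
print.motif_config <- function(x, ...) {
  cat("<motif_config>\n",
      " donors: ", paste(x$donor_patterns, collapse = ", "), "\n",
      " branch: ", x$branch_pattern, " (A at ", x$branch_a_index, ")\n",
      " acceptor: ", x$acceptor_pattern, "\n",
      " branch-acceptor gap: ", x$branch_to_acceptor_gap[1], "-",
      x$branch_to_acceptor_gap[2], " nt\n",
      " intron length: ", x$min_intron_len, "-", x$max_intron_len, " nt\n",
      sep = "")
  invisible(x)
}

#' Read / write a motif grammar config file
#'
#' Flat key–value YAML with the fields of [motif_config()].
#' @param path file path.
#' @return [read_motif_config()] returns a `motif_config`.
#' @export
read_motif_config <- function(path) {
  v <- yaml::read_yaml(path)
  do.call(motif_config, v)
}

#' @param cfg a `motif_config`.
#' @rdname read_motif_config
#' @export
write_motif_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
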