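# Coordinate conventions, sequence records and gene-model arithmetic.
#
# All internal coordinates are 0-based, half-open; GFF3 export converts to
# 1-based inclusive. RNA letters (U) are normalised to DNA (T) on ingest and
# all motif comparisons happen in DNA space.

#' Create a normalised sequence record
#'
#' Uppercases the residues, maps `U` to `T`, and validates the alphabet
#' (`A`, `C`, `G`, `T`, `N`).
#'
#' @param id non-empty identifier.
#' @param residues DNA/RNA string.
#' @param description free text.
#' @return an object of class `sequence_record` with fields `id`, `residues`,
#'   `description`.
#' @export
sequence_record <- function(id, residues, description = "") {
  if (!is.character(id) || length(id) != 1 || !nzchar(id))
    stop("id must be a non-empty string")
  residues <- chartr("Uu", "Tt", as.character(residues))
  residues <- toupper(residues)
  if (grepl("[^ACGTN]", residues))
    stop("residues contain letters outside {A,C,G,T,N} after normalisation")
  structure(list(id = id, residues = residues, description = description),
            class = "sequence_record")
}

#' @export
print.sequence_record <- function(x, ...) {
  cat(sprintf("<sequence_record> %s (%d nt) %s\n", x$id, nchar(x$residues),
              x$description))
  invisible(x)
}

# Accept either a sequence_record or a plain string.
as_dna_string <- function(seq) {
  if (inherits(seq, "sequence_record")) return(seq$residues)
  sequence_record("seq", seq)$residues
}

#' Reverse-complement a DNA string
#'
#' Minus-strand input is handled by reverse-complementing up front so that all
#' detection runs on the sense strand.
#' @param x DNA string.
#' @return reverse-complemented string.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' 0-based half-open region
#'
#' @param start 0-based inclusive offset.
#' @param end 0-based exclusive offset; `end >= start`.
#' @return a `region` object (named integer vector).
#' @export
region <- function(start, end) {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 0 || end < start)
    stop("invalid region: need 0 <= start <= end, got [", start, ", ", end, ")")
  structure(c(start = start, end = end), class = "region")
}

region_len <- function(r) unname(r["end"] - r["start"])

#' Construct a gene model over one sequence
#'
#' Exons are derived as the complement of the intervening sequences over the
#' full span `[0, length)`, so exons and introns alternate and tile the span
#' by construction. Stwintrons are carried as single intervening rows with a
#' `class` tag and internal-intron offsets.
#'
#' @param seq `sequence_record` or DNA string (sense strand).
#' @param cds_start 0-based offset of the `A` of the start codon.
#' @param introns `data.frame` with 0-based half-open columns `start`, `end`;
#'   optional columns `class` (`NA`, `"D1_2"`, `"D2_3"`, `"A2_3"`),
#'   `internal_start`, `internal_end` (absolute offsets of the internal intron
#'   of a stwintron row).
#' @param seq_id identifier used in exports.
#' @param strand `"+"` or `"-"`; minus-strand input is reverse-complemented on
#'   ingest (coordinates must then refer to the reverse-complemented strand).
#' @param coding_complete flag asserting the model's CDS is complete; when
#'   `TRUE` the spliced CDS must be a multiple of 3 ending in a stop codon.
#' @return object of class `gene_model`.
#' @export
gene_model <- function(seq, cds_start, introns = NULL, seq_id = "gene",
                       strand = "+", coding_complete = FALSE) {
  s <- if (inherits(seq, "sequence_record")) seq$residues else as_dna_string(seq)
  if (identical(strand, "-")) s <- revcomp(s)
  L <- nchar(s)
  cds_start <- as.integer(cds_start)
  if (cds_start < 0 || cds_start >= L) stop("cds_start outside sequence")
  if (is.null(introns) || nrow(introns) == 0) {
    introns <- data.frame(start = integer(0), end = integer(0),
                          class = character(0),
                          internal_start = integer(0), internal_end = integer(0))
  } else {
    introns <- as.data.frame(introns)
    introns$start <- as.integer(introns$start)
    introns$end <- as.integer(introns$end)
    if (is.null(introns$class)) introns$class <- NA_character_
    if (is.null(introns$internal_start)) introns$internal_start <- NA_integer_
    if (is.null(introns$internal_end)) introns$internal_end <- NA_integer_
    introns$internal_start <- as.integer(introns$internal_start)
    introns$internal_end <- as.integer(introns$internal_end)
    introns <- introns[order(introns$start), , drop = FALSE]
    rownames(introns) <- NULL
    if (any(introns$start < 0 | introns$end > L | introns$start >= introns$end))
      stop("intron coordinates outside sequence or empty")
    if (nrow(introns) > 1 &&
        any(introns$start[-1] < introns$end[-nrow(introns)]))
      stop("overlapping intervening sequences: features ",
           paste(which(introns$start[-1] < introns$end[-nrow(introns)]),
                 collapse = ", "), " collide with their successors")
  }
  # derive exons as the complement
  bounds <- c(0L, as.vector(rbind(introns$start, introns$end)), L)
  ex <- matrix(bounds, ncol = 2, byrow = TRUE)
  exons <- data.frame(start = ex[, 1], end = ex[, 2])
  exons <- exons[exons$end > exons$start, , drop = FALSE]
  rownames(exons) <- NULL
  in_intron <- any(introns$start <= cds_start & cds_start < introns$end)
  if (in_intron) stop("cds_start falls inside an intervening sequence")
  gm <- structure(list(seq_id = seq_id, seq = s, cds_start = cds_start,
                       introns = introns, exons = exons,
                       strand = strand, coding_complete = coding_complete),
                  class = "gene_model")
  if (coding_complete) {
    orf <- spliced_orf(gm)
    if (nchar(orf$orf) %% 3 != 0 || !orf$stop_found)
      stop("coding-complete model lacks an in-frame stop codon")
  }
  gm
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s: %d nt, %d exon(s), %d intervening sequence(s), cds_start=%d\n",
              x$seq_id, nchar(x$seq), nrow(x$exons), nrow(x$introns), x$cds_start))
  invisible(x)
}

#' Intron phase from the count of preceding coding nucleotides
#'
#' The phase of an intervening sequence is the number of nucleotides of the
#' interrupted codon lying upstream of its first nucleotide, i.e. the
#' preceding coding-nucleotide count modulo 3. For a stwintron the first
#' nucleotide is the external donor's leading `G`, one nt upstream of the
#' internal intron's donor — which is why a composite can be phase 1 while the
#' auto-annotated intervening sequence starting at the internal donor is
#' phase 2.
#'
#' @param preceding_coding_nt non-negative integer.
#' @return integer in `{0, 1, 2}`.
#' @examples
#' compute_phase(69)   # 0: falls between codons 23 and 24
#' compute_phase(565)  # 1
#' @export
compute_phase <- function(preceding_coding_nt) {
  n <- as.integer(preceding_coding_nt)
  if (length(n) != 1 || is.na(n) || n < 0)
    stop("preceding_coding_nt must be a single non-negative integer")
  n %% 3L
}

#' Coding offset of a genomic position
#'
#' Number of coding nucleotides strictly before `genomic_pos`. The position
#' must lie within an exon at or downstream of `cds_start`.
#'
#' @param gene `gene_model`.
#' @param genomic_pos 0-based offset.
#' @return non-negative integer.
#' @export
coding_offset <- function(gene, genomic_pos) {
  pos <- as.integer(genomic_pos)
  if (pos < gene$cds_start)
    stop("position ", pos, " is upstream of cds_start (", gene$cds_start, ")")
  hit <- which(gene$introns$start < pos & pos < gene$introns$end)
  if (length(hit))
    stop("position ", pos, " lies inside intervening sequence #", hit[1],
         " [", gene$introns$start[hit[1]], ", ", gene$introns$end[hit[1]], ")")
  if (pos > nchar(gene$seq)) stop("position beyond sequence end")
  ex <- gene$exons
  sum(pmax(0L, pmin(ex$end, pos) - pmax(ex$start, gene$cds_start)))
}

# Spliced (mature-transcript) coordinate of a genomic position within an exon.
genomic_to_spliced <- function(gene, pos) {
  ex <- gene$exons
  sum(pmax(0L, pmin(ex$end, pos) - ex$start))
}

#' Mature mRNA of a gene model
#'
#' Concatenation of the exon sequences.
#' @param gene `gene_model`.
#' @return DNA string.
#' @export
mature_mrna <- function(gene) {
  paste0(substring(gene$seq, gene$exons$start + 1, gene$exons$end),
         collapse = "")
}

# ORF from the spliced transcript starting at cds_start, through the first
# in-frame stop codon.
spliced_orf <- function(gene) {
  mrna <- mature_mrna(gene)
  off <- genomic_to_spliced(gene, gene$cds_start)
  cds <- substr(mrna, off + 1, nchar(mrna))
  n_codon <- nchar(cds) %/% 3
  stops <- c("TAA", "TAG", "TGA")
  stop_at <- 0L
  for (k in seq_len(n_codon)) {
    if (substr(cds, 3 * k - 2, 3 * k) %in% stops) { stop_at <- k; break }
  }
  if (stop_at > 0) list(orf = substr(cds, 1, 3 * stop_at), stop_found = TRUE)
  else list(orf = substr(cds, 1, 3 * n_codon), stop_found = FALSE)
}

#' Split-codon arithmetic for one intervening sequence
#'
#' Computes the phase and the 1-based codon number of the interrupted codon,
#' assembling the codon's three coding nucleotides across the intervening
#' sequence when phase > 0. Phase-0 boundaries are anchored to the residue
#' *after* the boundary.
#'
#' @param gene coding `gene_model`.
#' @param intron_index 1-based index into the model's intervening sequences.
#' @return a list with `intron_index`, `phase`, `residue_index`, `codon_nt`,
#'   or `NULL` (with a warning) when the feature lies upstream of the CDS.
#' @export
split_codon <- function(gene, intron_index) {
  i <- as.integer(intron_index)
  if (i < 1 || i > nrow(gene$introns))
    stop("intron_index out of range: ", i)
  st <- gene$introns$start[i]
  if (st < gene$cds_start) {
    warning("intervening sequence #", i, " lies upstream of cds_start; non-coding")
    return(NULL)
  }
  n <- coding_offset(gene, st)
  phase <- n %% 3L
  residue_index <- n %/% 3L + 1L
  mrna <- mature_mrna(gene)
  off <- genomic_to_spliced(gene, gene$cds_start)
  codon_nt <- substr(mrna, off + 3 * (residue_index - 1) + 1,
                     off + 3 * residue_index)
  list(intron_index = i, phase = phase, residue_index = residue_index,
       codon_nt = codon_nt)
}
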