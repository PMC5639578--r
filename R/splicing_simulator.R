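# Ordered splicing intermediates, mature mRNA, ORF and conceptual translation.

#' Simulate splicing of a gene model
#'
#' Enumerates the splicing intermediates. Stwintron rows (intervening
#' sequences carrying a `class` tag and internal offsets) are excised in two
#' steps, internal intron strictly first — the external intron's splice sites
#' only become functional after internal excision. Otherwise excision proceeds
#' 5' to 3'. Any valid ordering respecting internal-before-external yields the
#' same mature mRNA.
#'
#' @param gene `gene_model`; stwintron rows need `class`, `internal_start`,
#'   `internal_end`.
#' @param order optional character vector permuting the excision steps. Steps
#'   are labelled `"<i>"` for a plain intron row `i` and `"<i>.internal"` /
#'   `"<i>.external"` for a stwintron row; requesting an external before its
#'   internal is an ordering error.
#' @return object of class `splicing_path`: list with `steps` (each holding
#'   `label`, `excised` region in the coordinates of the then-current
#'   sequence, `excised_seq`, `sequence`), `mature_mrna`, `orf`, `protein`,
#'   `stop_found`.
#' @export
splice_gene <- function(gene, order = NULL) {
  iv <- gene$introns
  plan <- list()
  for (i in seq_len(nrow(iv))) {
    if (!is.na(iv$class[i])) {
      if (is.na(iv$internal_start[i]) || is.na(iv$internal_end[i]))
        stop("stwintron row ", i, " lacks internal intron offsets")
      plan[[length(plan) + 1]] <- list(
        label = paste0(i, ".internal"), row = i,
        parts = list(c(iv$internal_start[i], iv$internal_end[i])))
      plan[[length(plan) + 1]] <- list(
        label = paste0(i, ".external"), row = i,
        parts = list(c(iv$start[i], iv$internal_start[i]),
                     c(iv$internal_end[i], iv$end[i])))
    } else {
      plan[[length(plan) + 1]] <- list(label = as.character(i), row = i,
                                       parts = list(c(iv$start[i], iv$end[i])))
    }
  }
  labels <- vapply(plan, `[[`, character(1), "label")
  if (!is.null(order)) {
    if (!setequal(order, labels) || length(order) != length(labels))
      stop("order must be a permutation of: ", paste(labels, collapse = ", "))
    for (i in seq_len(nrow(iv))) {
      if (!is.na(iv$class[i])) {
        if (match(paste0(i, ".external"), order) <
            match(paste0(i, ".internal"), order))
          stop("ordering error: external intron of stwintron row ", i,
               " requested before its internal intron")
      }
    }
    plan <- plan[match(order, labels)]
  }
  current <- gene$seq
  removed <- matrix(numeric(0), ncol = 2)  # original-coordinate regions removed
  steps <- list()
  for (st in plan) {
    # map original start to current coordinates (all parts of one step are
    # contiguous in the current sequence once earlier steps are applied)
    p1 <- st$parts[[1]]
    shift <- if (nrow(removed)) sum(pmax(0, pmin(removed[, 2], p1[1]) -
                                           removed[, 1])) else 0
    cur_start <- p1[1] - shift
    len <- sum(vapply(st$parts, function(p) p[2] - p[1], numeric(1)))
    excised_seq <- substr(current, cur_start + 1, cur_start + len)
    current <- paste0(substr(current, 1, cur_start),
                      substr(current, cur_start + len + 1, nchar(current)))
    removed <- rbind(removed, do.call(rbind, st$parts))
    steps[[length(steps) + 1]] <- list(label = st$label,
                                       excised = region(cur_start, cur_start + len),
                                       excised_seq = excised_seq,
                                       sequence = current)
  }
  if (length(steps) == 0)
    steps <- list(list(label = "none", excised = region(0, 0),
                       excised_seq = "", sequence = current))
  mrna <- mature_mrna(gene)
  stopifnot(identical(current, mrna))   # mature mRNA = exon concatenation
  orf <- spliced_orf(gene)
  tr <- if (nchar(orf$orf) >= 3) translate_orf(orf$orf)
        else list(protein = "", stop_found = FALSE, premature_stop = FALSE)
  structure(list(steps = steps, mature_mrna = mrna, orf = orf$orf,
                 protein = tr$protein, stop_found = tr$stop_found),
            class = "splicing_path")
}

#' @export
print.splicing_path <- function(x, ...) {
  cat(sprintf("<splicing_path> %d step(s); mature mRNA %d nt; ORF %d nt; protein %d aa\n",
              length(x$steps), nchar(x$mature_mrna), nchar(x$orf),
              nchar(x$protein)))
  invisible(x)
}

#' Conceptual translation under the standard genetic code
#'
#' Translates an ORF, stopping at the first stop codon.
#'
#' @param orf DNA string, length >= 3; trailing partial codons are ignored.
#' @return list with `protein`, `stop_found`, and `premature_stop` (`TRUE`
#'   when a stop codon occurs before the final codon).
#' @examples
#' translate_orf("ATGCCCTAA")$protein   # "MP"
#' @export
translate_orf <- function(orf) {
  orf <- as_dna_string(orf)
  if (nchar(orf) < 3) stop("ORF must be at least 3 nt")
  n_codon <- nchar(orf) %/% 3
  codons <- substring(orf, 3 * seq_len(n_codon) - 2, 3 * seq_len(n_codon))
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"   # codons containing N
  stop_idx <- which(aa == "*")
  if (length(stop_idx)) {
    first <- stop_idx[1]
    list(protein = paste(aa[seq_len(first - 1)], collapse = ""),
         stop_found = TRUE, premature_stop = first < n_codon)
  } else {
    warning("no stop codon found in ORF")
    list(protein = paste(aa, collapse = ""), stop_found = FALSE,
         premature_stop = FALSE)
  }
}

#' Write splicing intermediates as FASTA
#'
#' Emits the pre-mRNA, every intermediate, the mature mRNA and the protein,
#' with step provenance in the description lines.
#' @param path output FASTA path.
#' @param gene `gene_model`.
#' @param sp `splicing_path` from [splice_gene()].
#' @export
write_splicing_fasta <- function(path, gene, sp) {
  ids <- c(paste0(gene$seq_id, "_premrna"),
           vapply(seq_along(sp$steps), function(i)
             paste0(gene$seq_id, "_step", i), character(1)),
           paste0(gene$seq_id, "_mrna"), paste0(gene$seq_id, "_protein"))
  desc <- c("unspliced",
            vapply(sp$steps, function(st)
              paste0("after excision of feature ", st$label, " (",
                     nchar(st$excised_seq), " nt)"), character(1)),
            "mature mRNA", "conceptual translation")
  seqs <- c(gene$seq, vapply(sp$steps, `[[`, character(1), "sequence"),
            sp$mature_mrna, sp$protein)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(ids)) {
    writeLines(paste0(">", ids[i], " ", desc[i]), con)
    writeLines(gsub("(.{70})", "\\1\n", seqs[i]), con)
  }
  invisible(path)
}
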