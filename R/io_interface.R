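# Readers/writers for the standard formats.
#
# Internal coordinates are 0-based half-open; GFF3 input/output is 1-based
# inclusive with the strand column honoured (minus-strand records are
# reverse-complemented on ingest by the callers that need sense-strand
# scanning).

#' Read a (multi-record, wrapped, case-insensitive) FASTA file
#'
#' @param path FASTA path.
#' @return list of [sequence_record()]; the id is the first whitespace-token
#'   of the header, the rest becomes the description.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  lapply(seq_along(ss), function(i) {
    hdr <- names(ss)[i]
    id <- strsplit(hdr, "\\s+")[[1]][1]
    desc <- sub("^\\S+\\s*", "", hdr)
    sequence_record(id, as.character(ss[[i]]), desc)
  })
}

#' Write sequence records as FASTA
#'
#' @param records list of [sequence_record()] (or a named character vector).
#' @param path output path.
#' @export
write_fasta <- function(records, path) {
  if (is.character(records))
    records <- lapply(names(records), function(n) sequence_record(n, records[[n]]))
  ss <- Biostrings::DNAStringSet(vapply(records, `[[`, character(1), "residues"))
  names(ss) <- vapply(records, function(r)
    trimws(paste(r$id, r$description)), character(1))
  Biostrings::writeXStringSet(ss, path, width = 70)
  invisible(path)
}

#' Export a gene model (with stwintron calls) as GFF3
#'
#' Coordinates are converted to 1-based inclusive. Each stwintron composite
#' becomes one `intron` feature carrying `stwintron_class`, `validated` and
#' `alternative_parse` attributes, with two child `intron` features
#' (`part=internal` / `part=external`) linked by `Parent`.
#'
#' @param gene `gene_model`.
#' @param path output GFF3 path.
#' @param calls optional `stwintron_calls` to annotate composite rows with
#'   validation and alternative-parse status.
#' @export
export_gff3 <- function(gene, path, calls = NULL) {
  rows <- list()
  add <- function(start, end, type, id, parent = NA, extra = list()) {
    rows[[length(rows) + 1]] <<- c(list(start = start + 1L, end = end,
                                        type = type, ID = id,
                                        Parent = parent), extra)
  }
  gid <- gene$seq_id
  add(0L, nchar(gene$seq), "gene", gid)
  for (i in seq_len(nrow(gene$exons)))
    add(gene$exons$start[i], gene$exons$end[i], "exon",
        paste0(gid, ":exon", i), gid)
  for (i in seq_len(nrow(gene$introns))) {
    iv <- gene$introns[i, ]
    iid <- paste0(gid, ":iv", i)
    if (is.na(iv$class)) {
      add(iv$start, iv$end, "intron", iid, gid)
    } else {
      cl <- NULL
      if (!is.null(calls))
        for (c2 in calls)
          if (c2$composite[["start"]] == iv$start &&
              c2$composite[["end"]] == iv$end) cl <- c2
      add(iv$start, iv$end, "intron", iid, gid,
          list(stwintron_class = iv$class,
               validated = tolower(as.character(
                 if (is.null(cl)) NA else cl$validated)),
               alternative_parse = tolower(as.character(
                 if (is.null(cl)) NA else !is.null(cl$alternative_parse)))))
      add(iv$internal_start, iv$internal_end, "intron",
          paste0(iid, ".internal"), iid, list(part = "internal"))
      add(iv$start, iv$internal_start, "intron",
          paste0(iid, ".external5"), iid, list(part = "external"))
      add(iv$internal_end, iv$end, "intron",
          paste0(iid, ".external3"), iid, list(part = "external"))
    }
  }
  all_keys <- unique(unlist(lapply(rows, names)))
  df <- do.call(rbind, lapply(rows, function(r) {
    r <- r[all_keys]
    names(r) <- all_keys
    as.data.frame(lapply(r, function(v) if (is.null(v)) NA else v),
                  stringsAsFactors = FALSE)
  }))
  gr <- GenomicRanges::GRanges(
    seqnames = gene$seq_id,
    ranges = IRanges::IRanges(start = df$start, end = df$end),
    strand = gene$strand)
  S4Vectors::mcols(gr)$type <- df$type
  S4Vectors::mcols(gr)$ID <- df$ID
  S4Vectors::mcols(gr)$Parent <- ifelse(is.na(df$Parent), NA, df$Parent)
  for (k in setdiff(all_keys, c("start", "end", "type", "ID", "Parent")))
    S4Vectors::mcols(gr)[[k]] <- df[[k]]
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Import a GFF3 file
#'
#' Thin wrapper over `rtracklayer::import` returning a `GRanges` (1-based
#' inclusive, strand column honoured).
#' @param path GFF3 path.
#' @export
import_gff3 <- function(path) rtracklayer::import(path, format = "gff3")

#' Read a rooted Newick tree
#'
#' Branch lengths are ignored by the inference; leaf labels must be unique.
#' @param path Newick path (or a `text=` string).
#' @param text optional Newick string instead of a file.
#' @return `phylo` tree.
#' @export
read_newick <- function(path = NULL, text = NULL) {
  tr <- if (!is.null(text)) ape::read.tree(text = text) else ape::read.tree(path)
  if (is.null(tr)) stop("could not parse Newick input")
  if (anyDuplicated(tr$tip.label))
    stop("duplicate leaf labels in tree")
  tr
}

#' Write a JSON report
#'
#' Scalars are unboxed; used for run reports and stwintron call dumps.
#' @param x list to serialise.
#' @param path output path.
#' @export
write_report_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE, force = TRUE)
  invisible(path)
}

# stwintron calls as plain lists for JSON reports
calls_to_list <- function(calls) {
  lapply(calls, function(cl) {
    list(class_tag = cl$class_tag,
         composite = list(start = cl$composite[["start"]],
                          end = cl$composite[["end"]],
                          length = region_len(cl$composite)),
         internal = list(start = cl$internal$start, end = cl$internal$end,
                         length = cl$internal$length,
                         donor = cl$internal$donor,
                         branch = cl$internal$branch,
                         acceptor = cl$internal$acceptor),
         external_length = cl$external_length,
         reconstructed_donor = cl$reconstructed_donor,
         reconstructed_acceptor = cl$reconstructed_acceptor,
         validated = cl$validated,
         alternative_parse = if (is.null(cl$alternative_parse)) NULL else
           calls_to_list(list(cl$alternative_parse))[[1]])
  })
}
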