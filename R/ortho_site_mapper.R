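# Projection of intron positions onto a protein multiple alignment.
#
# Homology of intron positions is positional: two observations are the same
# site iff they map to the identical (alignment column, phase). Phase-0
# boundaries are anchored to the residue AFTER the boundary. No tolerance
# window is applied by default — positions are treated as exact.

#' Aligned protein sequence
#'
#' Normalises `.` gaps to `-` and uppercases. The residue-to-column map is a
#' bijection on non-gap columns.
#'
#' @param species_id identifier.
#' @param aligned aligned residue string including gap characters.
#' @return object of class `aligned_protein`.
#' @export
aligned_protein <- function(species_id, aligned) {
  aligned <- toupper(chartr(".", "-", as.character(aligned)))
  structure(list(species_id = species_id, aligned = aligned),
            class = "aligned_protein")
}

ungapped <- function(ap) gsub("-", "", ap$aligned)

#' Alignment column of a residue
#'
#' @param ap `aligned_protein`.
#' @param residue_index 1-based index into the ungapped protein.
#' @return 1-based alignment column.
#' @export
residue_to_column <- function(ap, residue_index) {
  chars <- strsplit(ap$aligned, "")[[1]]
  non_gap <- which(chars != "-")
  i <- as.integer(residue_index)
  if (i < 1 || i > length(non_gap))
    stop("residue_index ", i, " out of range 1..", length(non_gap),
         " for ", ap$species_id)
  non_gap[i]
}

# Inverse map: residue index at a column, or NA when the column is a gap.
column_to_residue <- function(ap, column) {
  chars <- strsplit(ap$aligned, "")[[1]]
  if (column < 1 || column > length(chars))
    stop("column ", column, " outside alignment of width ", length(chars))
  if (chars[column] == "-") return(NA_integer_)
  sum(chars[seq_len(column)] != "-")
}

#' Protein-level position of an intervening sequence
#'
#' @param gene coding `gene_model`.
#' @param intron_index 1-based feature index.
#' @return integer vector `c(residue_index, phase)`, or `NULL` with a notice
#'   for a non-coding feature.
#' @export
intron_protein_position <- function(gene, intron_index) {
  sc <- withCallingHandlers(
    split_codon(gene, intron_index),
    warning = function(w) {
      message("excluded: ", conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  if (is.null(sc)) return(NULL)
  c(residue_index = sc$residue_index, phase = sc$phase)
}

site_tag <- function(column, phase) paste0("c", column, "p", phase)

#' Build the species-by-site intron state matrix
#'
#' For every species' gene model, each intervening sequence is mapped to its
#' (alignment column, phase) site and classified: `S` when the feature span is
#' a validated stwintron composite, `I` when it is a grammar-compliant lone
#' intron, `NC` when the annotated intervening sequence fails the grammar.
#' Species whose residue at a site's column exists intron-free score `A`;
#' species with a gap at that column (or missing from the alignment) score
#' `NG`. Every species' ungapped aligned protein must equal the conceptual
#' translation of its gene model.
#'
#' @param alignment list of [aligned_protein()] (or named character vector of
#'   aligned strings).
#' @param gene_models named list of `gene_model`, names matching species ids.
#' @param cfg [motif_config()].
#' @param detections optional named list, per species a list with elements
#'   `calls` and `candidates`; computed from the sequences when absent.
#' @return object of class `intron_site_matrix`: list with `sites`
#'   (`data.frame` of `column`, `phase`, `tag`, sorted, no duplicates),
#'   `states` (species x site character matrix over `{S,I,A,NC,NG}`), and
#'   `provenance`.
#' @export
build_site_matrix <- function(alignment, gene_models, cfg = motif_config(),
                              detections = NULL) {
  if (is.character(alignment))
    alignment <- lapply(names(alignment), function(n)
      aligned_protein(n, alignment[[n]]))
  names(alignment) <- vapply(alignment, `[[`, character(1), "species_id")
  species <- names(alignment)
  # checksum: gene model translation must match the ungapped aligned protein
  for (sp in names(gene_models)) {
    if (!sp %in% species) next
    prot <- translate_orf(spliced_orf(gene_models[[sp]])$orf)$protein
    if (!identical(prot, ungapped(alignment[[sp]])))
      stop("protein/alignment mismatch for species '", sp, "'")
  }
  obs <- list()
  for (sp in names(gene_models)) {
    gm <- gene_models[[sp]]
    if (!sp %in% species) next
    det <- if (!is.null(detections) && !is.null(detections[[sp]])) {
      detections[[sp]]
    } else {
      list(calls = detect_stwintrons(gm$seq, cfg),
           candidates = find_intron_candidates(gm$seq, cfg))
    }
    for (i in seq_len(nrow(gm$introns))) {
      pp <- intron_protein_position(gm, i)
      if (is.null(pp)) next
      col <- residue_to_column(alignment[[sp]], pp["residue_index"])
      st <- gm$introns$start[i]; en <- gm$introns$end[i]
      is_call <- any(vapply(det$calls, function(cl)
        isTRUE(cl$validated) && cl$composite[["start"]] == st &&
          cl$composite[["end"]] == en, logical(1)))
      state <- if (is_call) "S"
      else if (any(det$candidates$start == st & det$candidates$end == en)) "I"
      else "NC"
      obs[[length(obs) + 1]] <- list(species = sp, column = col,
                                     phase = unname(pp["phase"]), state = state)
    }
  }
  if (!length(obs)) {
    sites <- data.frame(column = integer(0), phase = integer(0),
                        tag = character(0))
    states <- matrix(character(0), nrow = length(species), ncol = 0,
                     dimnames = list(species, NULL))
    return(structure(list(sites = sites, states = states,
                          provenance = list(cfg = unclass(cfg))),
                     class = "intron_site_matrix"))
  }
  odf <- do.call(rbind, lapply(obs, as.data.frame))
  sites <- unique(odf[, c("column", "phase")])
  sites <- sites[order(sites$column, sites$phase), , drop = FALSE]
  sites$tag <- site_tag(sites$column, sites$phase)
  rownames(sites) <- NULL
  states <- matrix("A", nrow = length(species), ncol = nrow(sites),
                   dimnames = list(species, sites$tag))
  for (k in seq_len(nrow(sites))) {
    for (sp in species) {
      res <- column_to_residue(alignment[[sp]], sites$column[k])
      if (is.na(res)) states[sp, k] <- "NG"
    }
  }
  for (i in seq_len(nrow(odf))) {
    tag <- site_tag(odf$column[i], odf$phase[i])
    prev <- states[odf$species[i], tag]
    if (!prev %in% c("A", "NG") && prev != odf$state[i])
      warning("conflicting states at ", tag, " for ", odf$species[i])
    states[odf$species[i], tag] <- odf$state[i]
  }
  structure(list(sites = sites, states = states,
                 provenance = list(cfg = unclass(cfg))),
            class = "intron_site_matrix")
}

#' @export
print.intron_site_matrix <- function(x, ...) {
  cat(sprintf("<intron_site_matrix> %d species x %d site(s)\n",
              nrow(x$states), nrow(x$sites)))
  if (ncol(x$states)) print(x$states)
  invisible(x)
}

#' Joint states of two sites across species
#'
#' Contingency view for co-loss screening: which species lost both features,
#' which retain a stwintron at one site and an intron at the other, and so on.
#'
#' @param matrix_ `intron_site_matrix`.
#' @param site_a,site_b site tags (e.g. `"c189p1"`) or indices.
#' @return `data.frame` with `species`, `state_a`, `state_b`, plus a
#'   `"table"` attribute holding the joint contingency table.
#' @export
neighbour_site_cooccurrence <- function(matrix_, site_a, site_b) {
  resolve <- function(s) {
    if (is.numeric(s)) {
      if (s < 1 || s > nrow(matrix_$sites)) stop("unknown site index ", s)
      return(matrix_$sites$tag[s])
    }
    if (!s %in% matrix_$sites$tag) stop("unknown site: ", s)
    s
  }
  a <- resolve(site_a); b <- resolve(site_b)
  df <- data.frame(species = rownames(matrix_$states),
                   state_a = matrix_$states[, a],
                   state_b = matrix_$states[, b],
                   stringsAsFactors = FALSE)
  rownames(df) <- NULL
  attr(df, "table") <- table(df$state_a, df$state_b, dnn = c(a, b))
  df
}

#' Read an aligned protein FASTA
#'
#' Gap characters `.` are normalised to `-`.
#' @param path aligned FASTA path.
#' @return list of [aligned_protein()].
#' @export
read_alignment_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  lapply(seq_along(ss), function(i) {
    id <- strsplit(names(ss)[i], "\\s+")[[1]][1]
    aligned_protein(id, as.character(ss[[i]]))
  })
}

#' Write / read the site matrix as TSV
#'
#' Rows are species, columns are site tags `c<column>p<phase>`, cells are in
#' `{S,I,A,NC,NG}`. The header comment names the convention.
#' @param matrix_ `intron_site_matrix`.
#' @param path file path.
#' @export
write_site_matrix_tsv <- function(matrix_, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# stwintrons site matrix; sites are (alignment column, ",
                    "phase); phase-0 boundaries anchor to the residue after ",
                    "the boundary; cells S,I,A,NC,NG"), con)
  df <- data.frame(species = rownames(matrix_$states), matrix_$states,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_site_matrix_tsv
#' @export
read_site_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  states <- as.matrix(df[, -1, drop = FALSE])
  rownames(states) <- df$species
  tags <- colnames(states)
  m <- regmatches(tags, regexec("^c(\\d+)p(\\d+)$", tags))
  sites <- data.frame(column = as.integer(vapply(m, `[`, character(1), 2)),
                      phase = as.integer(vapply(m, `[`, character(1), 3)),
                      tag = tags, stringsAsFactors = FALSE)
  structure(list(sites = sites, states = states, provenance = list()),
            class = "intron_site_matrix")
}
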