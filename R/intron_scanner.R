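# Candidate U2 intron enumeration under the motif grammar.

empty_candidates <- function(cfg) {
  structure(data.frame(start = integer(0), end = integer(0),
                       length = integer(0),
                       donor = character(0), branch = character(0),
                       branch_start = integer(0), branch_alts = character(0),
                       acceptor = character(0), acceptor_start = integer(0),
                       stringsAsFactors = FALSE),
            class = c("intron_candidates", "data.frame"), cfg = cfg)
}

#' Enumerate candidate U2 introns in a window
#'
#' Returns *all* (donor, branch, acceptor) triples satisfying the grammar:
#' a donor-pattern match at the intron start, an acceptor-pattern match at its
#' end, and a branch-point match between them with the configured gap to the
#' acceptor, within the intron length bounds. Overlapping candidates are all
#' reported — the stwintron detector needs the full candidate lattice. For
#' each (donor, acceptor) pair with several compliant branch hits, the
#' reported `branch_start` is the 3'-most hit; the others are retained in
#' `branch_alts` (comma-separated 0-based offsets).
#'
#' @param seq `sequence_record` or DNA string.
#' @param cfg [motif_config()].
#' @param window optional [region()] (or length-2 vector, 0-based half-open)
#'   restricting the scan; candidates must lie entirely within it.
#' @return a `data.frame` of class `intron_candidates` with 0-based half-open
#'   columns `start`, `end` and motif hit columns, sorted by (start, end).
#'   A window shorter than `min_intron_len` yields an empty result.
#' @examples
#' cfg <- motif_config()
#' s <- paste0("GTACGT", strrep("A", 33), "ACTGAC", "AACA", "CAG")
#' find_intron_candidates(s, cfg)
#' @export
find_intron_candidates <- function(seq, cfg = motif_config(), window = NULL) {
  s <- as_dna_string(seq)
  w0 <- 0L; w1 <- nchar(s)
  if (!is.null(window)) {
    w0 <- as.integer(window[[1]]); w1 <- as.integer(window[[2]])
    if (w0 < 0 || w1 > nchar(s) || w0 > w1) stop("window outside sequence bounds")
  }
  sub <- substr(s, w0 + 1, w1)
  if (nchar(sub) < cfg$min_intron_len) return(empty_candidates(cfg))

  alen <- nchar(cfg$acceptor_pattern)
  blen <- nchar(cfg$branch_pattern)

  donors <- lapply(cfg$donor_patterns, function(p) {
    st <- iupac_match_starts(p, sub, cfg$allow_n_match)
    if (!length(st)) return(NULL)
    data.frame(d_start = st, d_len = nchar(p))
  })
  donors <- do.call(rbind, donors)
  if (is.null(donors) || nrow(donors) == 0) return(empty_candidates(cfg))
  donors <- donors[!duplicated(donors$d_start), , drop = FALSE]
  donors <- donors[order(donors$d_start), , drop = FALSE]

  b_starts <- iupac_match_starts(cfg$branch_pattern, sub, cfg$allow_n_match)
  a_starts <- iupac_match_starts(cfg$acceptor_pattern, sub, cfg$allow_n_match)
  if (!length(b_starts) || !length(a_starts)) return(empty_candidates(cfg))

  g1 <- cfg$branch_to_acceptor_gap[1]; g2 <- cfg$branch_to_acceptor_gap[2]
  rows <- vector("list", 64); nr <- 0L
  for (a in a_starts) {
    iv_end <- a + alen
    bc <- b_starts[b_starts + blen + g1 <= a & b_starts + blen + g2 >= a]
    if (!length(bc)) next
    for (k in seq_len(nrow(donors))) {
      d <- donors$d_start[k]; dlen <- donors$d_len[k]
      len <- iv_end - d
      if (len < cfg$min_intron_len || len > cfg$max_intron_len) next
      ok <- bc[bc >= d + dlen]
      if (!length(ok)) next
      b <- max(ok)                      # 3'-most compliant branch hit
      alts <- sort(setdiff(ok, b))
      nr <- nr + 1L
      if (nr > length(rows)) rows <- c(rows, vector("list", length(rows)))
      rows[[nr]] <- data.frame(
        start = w0 + d, end = w0 + iv_end, length = len,
        donor = substr(sub, d + 1, d + dlen),
        branch = substr(sub, b + 1, b + blen),
        branch_start = w0 + b,
        branch_alts = paste(w0 + alts, collapse = ","),
        acceptor = substr(sub, a + 1, a + alen),
        acceptor_start = w0 + a,
        stringsAsFactors = FALSE)
    }
  }
  if (nr == 0) return(empty_candidates(cfg))
  out <- do.call(rbind, rows[seq_len(nr)])
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("intron_candidates", "data.frame"), cfg = cfg)
}

#' Re-check one candidate against every grammar rule
#'
#' Diagnostic operation: one pass/fail entry per rule (donor, branch, gap,
#' acceptor, length) with the offending values on failure.
#'
#' @param cand one-row `data.frame` (or list) with the candidate's fields.
#' @param cfg [motif_config()].
#' @return `data.frame` with columns `rule`, `pass`, `detail`.
#' @export
validate_candidate <- function(cand, cfg = motif_config()) {
  cand <- as.list(cand)
  donor_ok <- any(vapply(cfg$donor_patterns, function(p)
    nchar(cand$donor) == nchar(p) &&
      match_iupac(p, cand$donor, cfg$allow_n_match), logical(1)))
  branch_ok <- nchar(cand$branch) == nchar(cfg$branch_pattern) &&
    match_iupac(cfg$branch_pattern, cand$branch, cfg$allow_n_match)
  gap <- cand$acceptor_start - (cand$branch_start + nchar(cand$branch))
  gap_ok <- gap >= cfg$branch_to_acceptor_gap[1] &&
    gap <= cfg$branch_to_acceptor_gap[2]
  acc_ok <- nchar(cand$acceptor) == nchar(cfg$acceptor_pattern) &&
    match_iupac(cfg$acceptor_pattern, cand$acceptor, cfg$allow_n_match)
  len <- cand$end - cand$start
  len_ok <- len >= cfg$min_intron_len && len <= cfg$max_intron_len
  data.frame(
    rule = c("donor", "branch", "gap", "acceptor", "length"),
    pass = c(donor_ok, branch_ok, gap_ok, acc_ok, len_ok),
    detail = c(
      paste0("donor '", cand$donor, "' at ", cand$start),
      paste0("branch '", cand$branch, "' at ", cand$branch_start),
      paste0("gap ", gap, " nt (allowed ", cfg$branch_to_acceptor_gap[1],
             "-", cfg$branch_to_acceptor_gap[2], ")"),
      paste0("acceptor '", cand$acceptor, "' at ", cand$acceptor_start),
      paste0("length ", len, " nt (allowed ", cfg$min_intron_len, "-",
             cfg$max_intron_len, ")")),
    stringsAsFactors = FALSE)
}

#' Write candidates to TSV
#'
#' 0-based half-open coordinates; a header comment states the convention.
#' @param cands `intron_candidates`.
#' @param path output file.
#' @param seq_id sequence identifier column value.
#' @export
write_candidates_tsv <- function(cands, path, seq_id = "seq") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# stwintrons candidate dump; coordinates 0-based, ",
                    "half-open; package version ",
                    as.character(utils::packageVersion("stwintrons"))), con)
  df <- data.frame(seq_id = rep(seq_id, nrow(cands)),
                   cands[, c("start", "end", "length", "donor", "branch",
                             "acceptor")])
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
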