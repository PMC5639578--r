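# Independent oracles used across the suite. These deliberately avoid the
# package's scanning/DP code paths: motif location goes through Biostrings'
# ambiguity matching, candidate enumeration through literal nested loops, and
# ancestral-state minimisation through exhaustive enumeration of internal
# node assignments.

# 0-based motif match starts via Biostrings (independent of the regex route)
bf_motif_starts <- function(pattern, subject) {
  hits <- Biostrings::matchPattern(Biostrings::DNAString(pattern),
                                   Biostrings::DNAString(subject),
                                   fixed = FALSE)
  as.integer(BiocGenerics::start(hits)) - 1L
}

# Exhaustive (donor, branch, acceptor) triple enumeration. Returns a
# data.frame of start/end/branch_start matching the scanner's contract
# (3'-most compliant branch per donor-acceptor pair).
bf_candidates <- function(s, cfg) {
  out <- list()
  alen <- nchar(cfg$acceptor_pattern)
  blen <- nchar(cfg$branch_pattern)
  b_all <- bf_motif_starts(cfg$branch_pattern, s)
  a_all <- bf_motif_starts(cfg$acceptor_pattern, s)
  for (dp in cfg$donor_patterns) {
    dlen <- nchar(dp)
    for (d in bf_motif_starts(dp, s)) {
      for (a in a_all) {
        len <- a + alen - d
        if (len < cfg$min_intron_len || len > cfg$max_intron_len) next
        ok <- c()
        for (b in b_all) {
          gap <- a - (b + blen)
          if (b >= d + dlen && gap >= cfg$branch_to_acceptor_gap[1] &&
              gap <= cfg$branch_to_acceptor_gap[2]) ok <- c(ok, b)
        }
        if (length(ok))
          out[[length(out) + 1]] <- data.frame(start = d, end = a + alen,
                                               branch_start = max(ok))
      }
    }
  }
  if (!length(out)) return(data.frame(start = integer(0), end = integer(0),
                                      branch_start = integer(0)))
  df <- unique(do.call(rbind, out))
  df <- df[order(df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# Brute-force stwintron enumeration from the bf candidate set: for every
# internal candidate and class, test the flanking geometry and whether the
# excision product is itself a full-span bf candidate; external resolved to
# the shortest compliant product.
bf_stwintrons <- function(s, cfg) {
  cands <- bf_candidates(s, cfg)
  L <- nchar(s)
  full_span_bf <- function(str) {
    cc <- bf_candidates(str, cfg)
    any(cc$start == 0 & cc$end == nchar(str))
  }
  shortest_5p <- function(str) {
    cc <- bf_candidates(str, cfg)
    cc <- cc[cc$start == 0, , drop = FALSE]
    if (nrow(cc) == 0) NA_integer_ else min(cc$end)
  }
  shortest_3p <- function(str) {
    cc <- bf_candidates(str, cfg)
    cc <- cc[cc$end == nchar(str), , drop = FALSE]
    if (nrow(cc) == 0) NA_integer_ else nchar(str) - max(cc$start)
  }
  calls <- list()
  for (i in seq_len(nrow(cands))) {
    ist <- cands$start[i]; ien <- cands$end[i]
    down <- substr(s, ien + 1, min(L, ien + cfg$max_intron_len))
    up <- substr(s, max(0, ist - cfg$max_intron_len) + 1, ist)
    if (ist >= 1 && substr(s, ist, ist) == "G") {
      el <- shortest_5p(paste0("G", down))
      if (!is.na(el))
        calls[[length(calls) + 1]] <- data.frame(
          class = "D1_2", start = as.integer(ist - 1),
          end = as.integer(ien + el - 1))
    }
    if (ist >= 2 && substr(s, ist - 1, ist) == "GT") {
      el <- shortest_5p(paste0("GT", down))
      if (!is.na(el))
        calls[[length(calls) + 1]] <- data.frame(
          class = "D2_3", start = as.integer(ist - 2),
          end = as.integer(ien + el - 2))
    }
    if (ien < L && substr(s, ien + 1, ien + 1) == "G") {
      el <- shortest_3p(paste0(up, "G"))
      if (!is.na(el))
        calls[[length(calls) + 1]] <- data.frame(
          class = "A2_3", start = as.integer(ist - (el - 1)),
          end = as.integer(ien + 1))
    }
  }
  if (!length(calls)) return(data.frame(class = character(0),
                                        start = integer(0), end = integer(0)))
  df <- unique(do.call(rbind, calls))
  df <- df[order(df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# Exhaustive minimum over all internal-node state assignments.
bf_sankoff <- function(tree, tip_states, cost, root_state = NULL,
                       loss_states = NULL) {
  states <- c("S", "I", "N")
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  edge <- tree$edge
  tips <- match(tip_states[tree$tip.label], states)
  grids <- do.call(expand.grid, rep(list(1:3), nnode))
  asn <- cbind(matrix(rep(tips, each = nrow(grids)), nrow = nrow(grids)),
               as.matrix(grids))
  if (!is.null(root_state))
    asn <- asn[asn[, ntip + 1] == match(root_state, states), , drop = FALSE]
  costs <- numeric(nrow(asn))
  losses <- numeric(nrow(asn))
  for (r in seq_len(nrow(edge))) {
    par <- asn[, edge[r, 1]]; ch <- asn[, edge[r, 2]]
    costs <- costs + cost[cbind(par, ch)]
    if (!is.null(loss_states))
      losses <- losses + (paste(states[par], states[ch]) %in% loss_states)
  }
  m <- min(costs)
  opt <- is.finite(costs) & costs == m
  list(cost = m, n_opt = as.numeric(sum(opt)),
       min_losses = if (is.null(loss_states)) NA else min(losses[opt]),
       max_losses = if (is.null(loss_states)) NA else max(losses[opt]))
}

# Random DNA string
random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

# Random intron skeleton under the default grammar
random_skeleton <- function() {
  donors <- c("GTACGT", "GTATGC", "GTGAGT", "GTAAGA")
  branches <- c("ACTGAC", "GCTAAC", "GCTAAT", "GCTGAC")
  acceptors <- c("CAG", "TAG", "AAG")
  intron_skeleton(sample(donors, 1), sample(25:40, 1), sample(branches, 1),
                  sample(3:8, 1), sample(acceptors, 1))
}

random_stw_skeleton <- function(class_tag = "D1_2") {
  stwintron_skeleton(class_tag, internal = random_skeleton(),
                     external = random_skeleton())
}

# Exon filler free of G/T (cannot create donor, branch or acceptor motifs)
safe_fill <- function(n) paste(sample(c("A", "C"), n, replace = TRUE),
                               collapse = "")

# Random topology with named tips
random_tree <- function(ntip) {
  tr <- ape::rtree(ntip, rooted = TRUE)
  tr$tip.label <- paste0("sp", seq_len(ntip))
  tr
}
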