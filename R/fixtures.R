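# Deterministic synthetic-data generator.
#
# Instantiates intron/stwintron motif skeletons, assembles genes with known
# truth models, and simulates orthologue families with planted site states.
# Exonic fill uses proline/threonine codons drawn from {CCA, CCC, ACA, ACC}:
# with no G or T outside the planted splice elements (and the anchored codons
# and stop), the fill can create neither donor (GT..), branch (.CT..) nor
# acceptor (.AG) motifs, which makes planted features uniquely recoverable.
# Strict mode additionally resamples intron spacers until the detection
# grammar applied to the assembled sequence recovers exactly the planted
# truth.

fill_codons <- c("CCA", "CCC", "ACA", "ACC")

sample_fill_codons <- function(n) {
  if (n == 0) return("")
  paste(sample(fill_codons, n, replace = TRUE), collapse = "")
}

#' Intron motif skeleton
#'
#' The published skeleton notation `donor—spacer1—branch—spacer2—acceptor`,
#' e.g. the 52-nt canonical intron `GUACGU—33-nt—ACUGAC—4-nt—CAG`.
#'
#' @param donor,branch,acceptor literal motif strings (RNA accepted, stored
#'   as DNA).
#' @param spacer1_len,spacer2_len spacer lengths in nt.
#' @return object of class `intron_skeleton` with an implied `length`.
#' @export
intron_skeleton <- function(donor, spacer1_len, branch, spacer2_len, acceptor) {
  norm <- function(x) chartr("U", "T", toupper(x))
  sk <- list(donor = norm(donor), spacer1_len = as.integer(spacer1_len),
             branch = norm(branch), spacer2_len = as.integer(spacer2_len),
             acceptor = norm(acceptor))
  sk$length <- nchar(sk$donor) + sk$spacer1_len + nchar(sk$branch) +
    sk$spacer2_len + nchar(sk$acceptor)
  structure(sk, class = "intron_skeleton")
}

#' Stwintron skeleton
#'
#' An internal [intron_skeleton()] nested inside an external one, with the
#' split position implied by the class tag: after external donor nt 1
#' (`D1_2`), after donor nt 2 (`D2_3`), or between the acceptor's penultimate
#' A and ultimate G (`A2_3`).
#'
#' @param class_tag `"D1_2"`, `"D2_3"` or `"A2_3"`.
#' @param internal,external [intron_skeleton()]s.
#' @return object of class `stwintron_skeleton`; `length` is the composite
#'   length (internal + external).
#' @export
stwintron_skeleton <- function(class_tag, internal, external) {
  class_tag <- match.arg(class_tag, c("D1_2", "D2_3", "A2_3"))
  structure(list(class_tag = class_tag, internal = internal,
                 external = external,
                 length = internal$length + external$length),
            class = "stwintron_skeleton")
}

# Raw instantiation without strictness checks; uses the current RNG.
instantiate_intron <- function(sk) {
  spacer <- function(n) if (n == 0) "" else
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
  paste0(sk$donor, spacer(sk$spacer1_len), sk$branch, spacer(sk$spacer2_len),
         sk$acceptor)
}

#' Build an intron sequence from a skeleton
#'
#' Spacers are filled by seeded rejection sampling; in strict mode the built
#' intron must be recovered by [find_intron_candidates()] as exactly one
#' candidate spanning its full length, with no additional donor-pattern match
#' inside (at most `max_resample` attempts, then an error).
#'
#' @param sk [intron_skeleton()].
#' @param seed optional integer seed (the session RNG is left untouched).
#' @param cfg [motif_config()] used for the strict-mode recovery check.
#' @param strict enforce unique recoverability (default `TRUE`).
#' @param max_resample resampling budget.
#' @return DNA string of length `sk$length`.
#' @export
build_intron <- function(sk, seed = NULL, cfg = motif_config(), strict = TRUE,
                         max_resample = 1000L) {
  with_seed(seed, {
    for (k in seq_len(max_resample)) {
      s <- instantiate_intron(sk)
      if (!strict) return(s)
      if (intron_unique(s, cfg)) return(s)
    }
    stop("unsatisfiable strict constraint: could not build an uniquely ",
         "recoverable intron from this skeleton in ", max_resample, " attempts")
  })
}

# TRUE iff `s` scans as exactly one full-span candidate with its only
# donor-pattern match at offset 0.
intron_unique <- function(s, cfg) {
  cands <- find_intron_candidates(s, cfg)
  if (nrow(cands) != 1 || cands$start != 0 || cands$end != nchar(s))
    return(FALSE)
  extra_donor <- any(vapply(cfg$donor_patterns, function(p)
    length(setdiff(iupac_match_starts(p, s, cfg$allow_n_match), 0L)) > 0,
    logical(1)))
  !extra_donor
}

#' Build a stwintron composite from a skeleton
#'
#' The external intron sequence is split at the class-specific position and
#' the internal intron sequence inserted; composite length is
#' internal + external by construction.
#'
#' @inheritParams build_intron
#' @param sk [stwintron_skeleton()].
#' @return list with `composite` (DNA string), `internal_offset` (0-based
#'   offset of the internal intron within the composite), `internal_seq`,
#'   `external_seq`.
#' @export
build_stwintron <- function(sk, seed = NULL, cfg = motif_config(),
                            strict = TRUE, max_resample = 1000L) {
  with_seed(seed, {
    for (k in seq_len(max_resample)) {
      int_s <- instantiate_intron(sk$internal)
      ext_s <- instantiate_intron(sk$external)
      if (strict && (!intron_unique(int_s, cfg) || !intron_unique(ext_s, cfg)))
        next
      off <- switch(sk$class_tag, D1_2 = 1L, D2_3 = 2L,
                    A2_3 = nchar(ext_s) - 1L)
      comp <- paste0(substr(ext_s, 1, off), int_s,
                     substr(ext_s, off + 1, nchar(ext_s)))
      return(list(composite = comp, internal_offset = off,
                  internal_seq = int_s, external_seq = ext_s))
    }
    stop("unsatisfiable strict constraint while building stwintron composite")
  })
}

# ---------------------------------------------------------------------------
# Gene assembly

# Assemble a gene from alternating parts. `parts` is a list of entries:
#   list(type = "exon", seq = ...) or
#   list(type = "intron", seq = ...) or
#   list(type = "stwintron", seq = ..., class = ..., internal_offset = ...,
#        internal_len = ...)
assemble_gene_seq <- function(parts, seq_id, cds_start = 0L) {
  seqs <- vapply(parts, `[[`, character(1), "seq")
  s <- paste0(seqs, collapse = "")
  offs <- cumsum(c(0L, nchar(seqs)))
  introns <- list()
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (p$type == "intron") {
      introns[[length(introns) + 1]] <- data.frame(
        start = offs[i], end = offs[i + 1], class = NA_character_,
        internal_start = NA_integer_, internal_end = NA_integer_)
    } else if (p$type == "stwintron") {
      introns[[length(introns) + 1]] <- data.frame(
        start = offs[i], end = offs[i + 1], class = p$class,
        internal_start = offs[i] + p$internal_offset,
        internal_end = offs[i] + p$internal_offset + p$internal_len)
    }
  }
  introns <- if (length(introns)) do.call(rbind, introns) else NULL
  gene_model(s, cds_start = cds_start, introns = introns, seq_id = seq_id,
             coding_complete = TRUE)
}

# TRUE iff detection on the assembled gene recovers exactly the planted truth:
# every planted intervening sequence is recovered with exact boundaries, every
# planted stwintron yields a validated call at the composite span, and no
# non-planted validated stwintron call is emitted.
gene_roundtrip_ok <- function(gm, cfg, exact_calls = FALSE) {
  cands <- find_intron_candidates(gm$seq, cfg)
  calls <- detect_stwintrons(gm$seq, cfg)
  call_spans <- vapply(calls, function(cl)
    paste0(cl$composite[["start"]], "-", cl$composite[["end"]]), character(1))
  for (i in seq_len(nrow(gm$introns))) {
    st <- gm$introns$start[i]; en <- gm$introns$end[i]
    if (is.na(gm$introns$class[i])) {
      if (!any(cands$start == st & cands$end == en)) return(FALSE)
    } else {
      if (!paste0(st, "-", en) %in% call_spans) return(FALSE)
    }
  }
  if (exact_calls) {
    # single-stwintron presets: the call set must equal the planted truth
    planted <- with(gm$introns[!is.na(gm$introns$class), , drop = FALSE],
                    paste0(start, "-", end))
    return(all(call_spans %in% planted))
  }
  # extra calls are tolerated only when they re-parse planted material
  # (cross-feature nestings are legitimate under the grammar); fill must
  # never create a stwintron of its own
  for (cl in calls) {
    overlaps <- any(cl$composite[["start"]] < gm$introns$end &
                      gm$introns$start < cl$composite[["end"]])
    if (!overlaps) return(FALSE)
  }
  TRUE
}

# ---------------------------------------------------------------------------
# Published lipS presets

skeleton_anidulans <- function() {
  list(intron1 = intron_skeleton("GTACGT", 33, "ACTGAC", 4, "CAG"),
       stw = stwintron_skeleton(
         "D1_2",
         internal = intron_skeleton("GTATGC", 33, "GCTAAC", 5, "TAG"),
         external = intron_skeleton("GTGAGT", 25, "GCTGAC", 6, "AAG")),
       intron3 = intron_skeleton("GTGAGT", 28, "GCTAAT", 6, "CAG"))
}

skeleton_aniger <- function() {
  list(stw = stwintron_skeleton(
    "D1_2",
    internal = intron_skeleton("GTAAGA", 31, "GCTAAC", 6, "CAG"),
    external = intron_skeleton("GTGAGT", 35, "GCTAAT", 7, "CAG")))
}

#' Aspergillus nidulans lipS preset
#'
#' Deterministic instantiation of the published motif skeletons of the
#' four-exon *A. nidulans* lipS gene model: a 52-nt first intron 69 nt behind
#' the ATG (between the His23 and Tyr24 codons), the 99-nt D1_2 stwintron
#' (53-nt internal + 46-nt external) splitting the CCC codon of Pro189 in
#' phase 1, a 142-nt exon, and a 49-nt third intron, with a coding ORF of
#' 2616 nt (871 residues plus stop). Exon fill is neutral Pro/Thr codons;
#' the protein is therefore synthetic apart from the anchored codons.
#'
#' @param seed integer seed; identical seeds give byte-identical sequence.
#' @param cfg [motif_config()] used for the strict recovery check.
#' @param max_resample resampling budget for strict assembly.
#' @return list with `record` ([sequence_record()]), `gene` (truth
#'   `gene_model`), `skeletons`.
#' @export
preset_anidulans_lipS <- function(seed = 1L, cfg = motif_config(),
                                  max_resample = 1000L) {
  sks <- skeleton_anidulans()
  with_seed(seed, {
    for (k in seq_len(max_resample)) {
      exon1 <- paste0(sample_fill_codons(22), "CAC")            # His23
      i1 <- instantiate_intron(sks$intron1)
      exon2 <- paste0(sample_fill_codons(165), "C")             # Pro189 nt 1
      stw <- tryCatch(build_stwintron(sks$stw, cfg = cfg, strict = FALSE),
                      error = function(e) NULL)
      exon3 <- paste0("CC", sample_fill_codons(46), "CC")       # Pro189 nt 2-3
      i3 <- instantiate_intron(sks$intron3)
      exon4 <- paste0("C", sample_fill_codons(635), "TAA",
                      sample_fill_codons(2))
      gm <- assemble_gene_seq(list(
        list(type = "exon", seq = exon1),
        list(type = "intron", seq = i1),
        list(type = "exon", seq = exon2),
        list(type = "stwintron", seq = stw$composite, class = "D1_2",
             internal_offset = stw$internal_offset,
             internal_len = nchar(stw$internal_seq)),
        list(type = "exon", seq = exon3),
        list(type = "intron", seq = i3),
        list(type = "exon", seq = exon4)), seq_id = "Anidulans_lipS")
      if (gene_roundtrip_ok(gm, cfg, exact_calls = TRUE)) {
        rec <- sequence_record("Anidulans_lipS", gm$seq,
                               sprintf("synthetic lipS locus (seed %d)", seed))
        return(list(record = rec, gene = gm, skeletons = sks))
      }
    }
    stop("could not assemble a strictly recoverable A. nidulans preset")
  })
}

#' Aspergillus niger lipS preset
#'
#' Deterministic instantiation of the *A. niger* lipS stwintron skeleton: the
#' 109-nt D1_2 composite (52-nt internal + 57-nt external) splitting the CCT
#' codon of Pro184 in phase 1, within a coding ORF of 2730 nt (909 residues
#' plus stop). Exon offsets other than the stwintron anchor are synthetic:
#' the published account gives the composite structure and codon position but
#' not the remaining exon sizes.
#'
#' @inheritParams preset_anidulans_lipS
#' @export
preset_aniger_lipS <- function(seed = 1L, cfg = motif_config(),
                               max_resample = 1000L) {
  sks <- skeleton_aniger()
  with_seed(seed, {
    for (k in seq_len(max_resample)) {
      exon1 <- paste0(sample_fill_codons(183), "C")             # Pro184 nt 1
      stw <- tryCatch(build_stwintron(sks$stw, cfg = cfg, strict = FALSE),
                      error = function(e) NULL)
      exon2 <- paste0("CT", sample_fill_codons(725), "TAA",     # Pro184 nt 2-3
                      sample_fill_codons(2))
      gm <- assemble_gene_seq(list(
        list(type = "exon", seq = exon1),
        list(type = "stwintron", seq = stw$composite, class = "D1_2",
             internal_offset = stw$internal_offset,
             internal_len = nchar(stw$internal_seq)),
        list(type = "exon", seq = exon2)), seq_id = "Aniger_lipS")
      if (gene_roundtrip_ok(gm, cfg, exact_calls = TRUE)) {
        rec <- sequence_record("Aniger_lipS", gm$seq,
                               sprintf("synthetic lipS locus (seed %d)", seed))
        return(list(record = rec, gene = gm, skeletons = sks))
      }
    }
    stop("could not assemble a strictly recoverable A. niger preset")
  })
}

# ---------------------------------------------------------------------------
# Orthologue family simulation

#' Propagate a planted event history down a tree
#'
#' Assigns a state to every node from a root state and a list of branch
#' events, returning the tip states and the event table — the planted truth
#' for [simulate_family()] and for exercising [sankoff()].
#'
#' @param tree rooted `phylo`.
#' @param root_state state at the root (`"S"`, `"I"` or `"N"`).
#' @param events list of `list(branch_child = <tip or node label>, to =
#'   <state>)`; each event rewrites the state on the branch leading to that
#'   node, inherited by the whole subtree below.
#' @return list with `tip_states` (named), `node_states`, `events`
#'   (`data.frame` with `branch_child`, `from`, `to`, `kind`).
#' @export
plant_history <- function(tree, root_state, events = list()) {
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  labels <- c(tree$tip.label, paste0("node", (ntip + 1):nn))
  states <- rep(NA_character_, nn)
  root <- ntip + 1L
  states[root] <- root_state
  ed <- ape::reorder.phylo(tree, "cladewise")$edge
  ev_to <- setNames(vapply(events, `[[`, character(1), "to"),
                    vapply(events, `[[`, character(1), "branch_child"))
  bad <- setdiff(names(ev_to), labels)
  if (length(bad)) stop("unknown branch_child: ", paste(bad, collapse = ", "))
  evt <- list()
  for (r in seq_len(nrow(ed))) {
    par <- ed[r, 1]; ch <- ed[r, 2]
    lab <- labels[ch]
    if (lab %in% names(ev_to)) {
      states[ch] <- ev_to[[lab]]
      evt[[length(evt) + 1]] <- data.frame(
        branch_child = lab, from = states[par], to = states[ch],
        kind = event_kind(states[par], states[ch]), stringsAsFactors = FALSE)
    } else states[ch] <- states[par]
  }
  names(states) <- labels
  list(tip_states = states[seq_len(ntip)], node_states = states,
       events = if (length(evt)) do.call(rbind, evt) else
         data.frame(branch_child = character(0), from = character(0),
                    to = character(0), kind = character(0)))
}

#' Simulate an orthologue family with planted intron-site states
#'
#' Generates one gene per tree leaf over a shared synthetic protein
#' (identical across species up to seeded synonymous third-position
#' variation, so the trivially correct ungapped alignment is emitted).
#' At each planted site — a codon split in phase 1 behind its first
#' nucleotide — a species carries a validating stwintron composite (`S`), a
#' validating standard intron (`I`), or clean exonic sequence (`A`) according
#' to the site plan.
#'
#' @param tree rooted `phylo` with named leaves.
#' @param site_plan list of sites; each site is a list with `codon` (1-based
#'   residue index) and either `states` (named character vector over the
#'   leaves, values in `{S, I, A}`) or `root_state` + `events` as understood
#'   by [plant_history()] (states other than `S`, `I` map to `A` at the
#'   sequence level).
#' @param n_codons length of the synthetic protein (excluding the stop).
#' @param seed integer seed; identical seeds give byte-identical output.
#' @param stw_skeleton,intron_skeleton_ skeletons used for planted `S` / `I`
#'   features (defaults: the A. nidulans stwintron / 52-nt intron skeletons).
#' @param cfg [motif_config()].
#' @param max_resample per-species strict-assembly budget.
#' @return list with `sequences` (named character), `records`, `gene_models`,
#'   `alignment` (list of [aligned_protein()]), `truth_matrix`
#'   (`intron_site_matrix` of planted states), `truth_events` (per site),
#'   `tip_states` (per site), `tree`.
#' @export
simulate_family <- function(tree, site_plan, n_codons = 120L, seed = 1L,
                            stw_skeleton = skeleton_anidulans()$stw,
                            intron_skeleton_ = skeleton_anidulans()$intron1,
                            cfg = motif_config(), max_resample = 200L) {
  species <- tree$tip.label
  if (is.null(species) || anyDuplicated(species))
    stop("tree leaves must be uniquely named")
  # resolve per-site tip states and truth events
  sites <- lapply(site_plan, function(site) {
    if (!is.null(site$states)) {
      st <- toupper(unlist(site$states))
      if (!setequal(names(st), species))
        stop("site plan states do not match tree leaves")
      list(codon = site$codon, tip_states = st[species],
           events = NULL)
    } else {
      ph <- plant_history(tree, site$root_state, site$events)
      list(codon = site$codon, tip_states = ph$tip_states, events = ph$events)
    }
  })
  codons_at <- vapply(sites, `[[`, numeric(1), "codon")
  if (anyDuplicated(codons_at)) stop("duplicate site codons in plan")
  if (any(codons_at < 2 | codons_at > n_codons - 1))
    stop("site codons must lie strictly inside the protein")
  bad <- unlist(lapply(sites, function(s)
    setdiff(unique(s$tip_states), c("S", "I", "A", "N"))))
  if (length(bad)) stop("site plan states must be in {S, I, A}")

  with_seed(seed, {
    aa_fill <- sample(c("P", "T"), n_codons, replace = TRUE)
    aa_fill[codons_at] <- "P"     # planted sites split a proline codon
    syn <- list(P = c("CCA", "CCC"), T = c("ACA", "ACC"))
    seqs <- character(0); gms <- list()
    for (sp in species) {
      ok <- FALSE
      for (k in seq_len(max_resample)) {
        codons <- vapply(aa_fill, function(a) sample(syn[[a]], 1), character(1))
        codons[codons_at] <- "CCC"
        parts <- list(); cursor <- 1L
        for (j in order(codons_at)) {
          site <- sites[[j]]; cd <- site$codon
          state <- site$tip_states[[sp]]
          # exon up to and including the first nt of the split codon
          upstream <- if (cursor <= cd - 1)
            paste(codons[cursor:(cd - 1)], collapse = "") else ""
          exon_seq <- paste0(upstream, substr(codons[cd], 1, 1))
          parts[[length(parts) + 1]] <- list(type = "exon", seq = exon_seq)
          if (state == "S") {
            stw <- build_stwintron(stw_skeleton, cfg = cfg, strict = FALSE)
            parts[[length(parts) + 1]] <- list(
              type = "stwintron", seq = stw$composite,
              class = stw_skeleton$class_tag,
              internal_offset = stw$internal_offset,
              internal_len = nchar(stw$internal_seq))
          } else if (state == "I") {
            parts[[length(parts) + 1]] <- list(
              type = "intron", seq = instantiate_intron(intron_skeleton_))
          }
          # the remaining 2 nt of the split codon start the next exon chunk
          parts[[length(parts) + 1]] <- list(
            type = "exon", seq = substr(codons[cd], 2, 3))
          cursor <- cd + 1L
        }
        tail_seq <- paste0(paste(codons[cursor:n_codons], collapse = ""), "TAA")
        parts[[length(parts) + 1]] <- list(type = "exon", seq = tail_seq)
        # merge consecutive exon parts
        merged <- list()
        for (p in parts) {
          n <- length(merged)
          if (p$type == "exon" && n > 0 && merged[[n]]$type == "exon")
            merged[[n]]$seq <- paste0(merged[[n]]$seq, p$seq)
          else merged[[n + 1]] <- p
        }
        gm <- assemble_gene_seq(merged, seq_id = sp)
        if (gene_roundtrip_ok(gm, cfg)) { ok <- TRUE; break }
      }
      if (!ok) stop("could not assemble species '", sp, "' strictly")
      seqs[sp] <- gm$seq
      gms[[sp]] <- gm
    }
    protein <- paste(aa_fill, collapse = "")
    alignment <- lapply(species, function(sp) aligned_protein(sp, protein))
    names(alignment) <- species
    # truth matrix straight from the plan
    site_cols <- order(codons_at)
    sdf <- data.frame(column = codons_at[site_cols], phase = 1L,
                      tag = site_tag(codons_at[site_cols], 1L))
    states <- matrix("A", nrow = length(species), ncol = nrow(sdf),
                     dimnames = list(species, sdf$tag))
    for (j in seq_along(sites)) {
      tg <- site_tag(sites[[j]]$codon, 1L)
      st <- sites[[j]]$tip_states
      st[st == "N"] <- "A"
      states[names(st), tg] <- st
    }
    truth <- structure(list(sites = sdf, states = states,
                            provenance = list(seed = seed)),
                       class = "intron_site_matrix")
    list(sequences = seqs,
         records = lapply(species, function(sp)
           sequence_record(sp, seqs[[sp]],
                           sprintf("simulated orthologue (seed %d)", seed))),
         gene_models = gms, alignment = alignment, truth_matrix = truth,
         truth_events = lapply(sites, `[[`, "events"),
         tip_states = lapply(sites, `[[`, "tip_states"),
         tree = tree)
  })
}
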