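# Nested twin-intron (stwintron) detection and two-step excision.
#
# A stwintron is a complex intervening sequence in which an internal canonical
# U2 intron interrupts a splice element of an external U2 intron; removal
# requires two consecutive splicing reactions, internal first. Classes:
#   D1_2 - internal splits the external donor between its 1st and 2nd nt
#          (composite begins "GG": external G, then the internal's GT donor)
#   D2_3 - internal splits the external donor between its 2nd and 3rd nt
#          (composite begins "GT", internal starts at offset 2)
#   A2_3 - internal splits the external acceptor between its penultimate A and
#          ultimate G (the final composite nt is that G)

# substring in 0-based half-open coordinates
sub0 <- function(s, start, end) substr(s, start + 1, end)

# Shortest grammar-compliant intron candidate anchored at the start of `ctx`.
anchored_candidate_5p <- function(ctx, cfg) {
  cands <- find_intron_candidates(ctx, cfg)
  cands <- cands[cands$start == 0L, , drop = FALSE]
  if (nrow(cands) == 0) return(NULL)
  cands[which.min(cands$end), , drop = FALSE]
}

# Shortest compliant candidate whose acceptor ends exactly at the end of `ctx`.
anchored_candidate_3p <- function(ctx, cfg) {
  cands <- find_intron_candidates(ctx, cfg)
  cands <- cands[cands$end == nchar(ctx), , drop = FALSE]
  if (nrow(cands) == 0) return(NULL)
  cands[which.max(cands$start), , drop = FALSE]
}

new_stwintron_call <- function(class_tag, composite, composite_seq, internal,
                               external_parts, external_seq, ext_cand,
                               validated = TRUE, alternative_parse = NULL) {
  donor_side <- class_tag %in% c("D1_2", "D2_3")
  structure(list(
    class_tag = class_tag,
    composite = composite,
    composite_seq = composite_seq,
    internal = internal,
    external_parts = external_parts,
    external_length = nchar(external_seq),
    external_seq = external_seq,
    reconstructed_donor = if (donor_side) ext_cand$donor else NA_character_,
    reconstructed_acceptor = if (!donor_side) ext_cand$acceptor else NA_character_,
    external_branch = ext_cand$branch,
    validated = validated,
    alternative_parse = alternative_parse), class = "stwintron_call")
}

#' @export
print.stwintron_call <- function(x, ...) {
  cat(sprintf("<stwintron_call> [%s] composite [%d, %d) %d nt = internal %d + external %d%s\n",
              x$class_tag, x$composite["start"], x$composite["end"],
              region_len(x$composite), x$internal$length, x$external_length,
              if (!is.null(x$alternative_parse)) " (alternative parse available)" else ""))
  invisible(x)
}

#' Detect stwintrons in a sequence
#'
#' For every internal intron candidate and every nesting class, emits a call
#' when the flanking context satisfies that class's geometry *and* the product
#' of excising the internal intron is itself a grammar-compliant intron
#' (so `validated` is always `TRUE` for emitted calls). For each internal and
#' class, the external intron is resolved to the shortest compliant excision
#' product — the most proximal donor/acceptor couple, as strict intron
#' definition demands. Nesting is depth 2 only: one internal inside one
#' external. D1_2 calls additionally carry an `alternative_parse` (an A2_3
#' reading of the same composite) when the 1-nt lookahead into the downstream
#' exon is a `G` (see [find_alternative_parse()]).
#'
#' @param seq `sequence_record` or DNA string.
#' @param cfg [motif_config()].
#' @param window optional scan [region()].
#' @return list of `stwintron_call` objects sorted by composite start (class
#'   `stwintron_calls`); zero calls is a normal outcome.
#' @export
detect_stwintrons <- function(seq, cfg = motif_config(), window = NULL) {
  s <- as_dna_string(seq)
  L <- nchar(s)
  cands <- find_intron_candidates(s, cfg, window)
  calls <- list()
  for (i in seq_len(nrow(cands))) {
    internal <- as.list(cands[i, ])
    ist <- internal$start; ien <- internal$end
    down <- sub0(s, ien, min(L, ien + cfg$max_intron_len))
    up <- sub0(s, max(0L, ist - cfg$max_intron_len), ist)

    if (ist >= 1 && sub0(s, ist - 1, ist) == "G") {        # D1_2 geometry
      ctx <- paste0("G", down)
      ext <- anchored_candidate_5p(ctx, cfg)
      if (!is.null(ext)) {
        ext <- as.list(ext)
        comp <- region(ist - 1, ien + ext$length - 1)
        calls[[length(calls) + 1]] <- new_stwintron_call(
          "D1_2", comp, sub0(s, comp["start"], comp["end"]), internal,
          list(region(ist - 1, ist), region(ien, ien + ext$length - 1)),
          substr(ctx, 1, ext$length), ext)
      }
    }
    if (ist >= 2 && sub0(s, ist - 2, ist) == "GT") {       # D2_3 geometry
      ctx <- paste0("GT", down)
      ext <- anchored_candidate_5p(ctx, cfg)
      if (!is.null(ext)) {
        ext <- as.list(ext)
        comp <- region(ist - 2, ien + ext$length - 2)
        calls[[length(calls) + 1]] <- new_stwintron_call(
          "D2_3", comp, sub0(s, comp["start"], comp["end"]), internal,
          list(region(ist - 2, ist), region(ien, ien + ext$length - 2)),
          substr(ctx, 1, ext$length), ext)
      }
    }
    if (ien < L && sub0(s, ien, ien + 1) == "G") {         # A2_3 geometry
      ctx <- paste0(up, "G")
      ext <- anchored_candidate_3p(ctx, cfg)
      if (!is.null(ext)) {
        ext <- as.list(ext)
        comp <- region(ist - (ext$length - 1), ien + 1)
        calls[[length(calls) + 1]] <- new_stwintron_call(
          "A2_3", comp, sub0(s, comp["start"], comp["end"]), internal,
          list(region(comp["start"], ist), region(ien, ien + 1)),
          substr(ctx, nchar(ctx) - ext$length + 1, nchar(ctx)), ext)
      }
    }
  }
  if (length(calls)) {
    ord <- order(vapply(calls, function(cl) cl$composite[["start"]], numeric(1)),
                 vapply(calls, function(cl) cl$composite[["end"]], numeric(1)),
                 vapply(calls, function(cl) region_len(cl$composite), numeric(1)))
    calls <- calls[ord]
    # attach D1_2/A2_3 alternative parses where one nt of lookahead exists
    for (k in seq_along(calls)) {
      cl <- calls[[k]]
      if (cl$class_tag == "D1_2" && cl$composite[["end"]] < L) {
        base <- sub0(s, cl$composite[["end"]], cl$composite[["end"]] + 1)
        calls[[k]]$alternative_parse <- find_alternative_parse(cl, base, cfg)
      }
    }
  }
  structure(calls, class = "stwintron_calls")
}

#' @export
print.stwintron_calls <- function(x, ...) {
  cat("<stwintron_calls> ", length(x), " call(s)\n", sep = "")
  for (cl in x) print(cl)
  invisible(x)
}

#' Excise the internal intron from a composite
#'
#' Returns the composite with the internal region deleted — the first of the
#' two consecutive splicing reactions. For D1_2/D2_3 the result begins with
#' the reconstructed donor; for A2_3 it ends with the reconstructed acceptor.
#'
#' @param composite DNA string of the full composite.
#' @param call `stwintron_call` whose geometry describes the nesting.
#' @return DNA string of the retained external intron.
#' @export
excise_internal <- function(composite, call) {
  L <- nchar(composite)
  ilen <- call$internal$length
  off <- switch(call$class_tag,
                D1_2 = 1L, D2_3 = 2L,
                A2_3 = L - 1L - ilen,
                stop("unknown class tag: ", call$class_tag))
  if (ilen == 0) return(composite)
  if (off < 0 || off + ilen > L)
    stop("geometry mismatch for class ", call$class_tag,
         ": internal [", off, ", ", off + ilen, ") outside composite of ", L, " nt")
  inner <- sub0(composite, off, off + ilen)
  if (substr(inner, 1, 2) != "GT" ||
      substr(inner, ilen - 1, ilen) != "AG")
    stop("geometry mismatch for class ", call$class_tag,
         ": region [", off, ", ", off + ilen,
         ") is not a GT..AG intron within the composite")
  paste0(sub0(composite, 0, off), sub0(composite, off + ilen, L))
}

#' Alternative [D1,2]/[A2,3] parse of a composite
#'
#' A validated D1_2 composite beginning `GG` admits a second, mutually
#' exclusive sequential splicing pathway whenever the first base of the
#' downstream exon is also a `G`: the composite window shifts one nt 3', the
#' old external intron (which begins at the internal intron's terminal `G`)
#' becomes the new internal, and the old internal — its final `G` replaced by
#' the exonic `G` — becomes the new external whose acceptor is split between
#' its penultimate `A` and that `G`. Both parses yield the identical mature
#' mRNA, which this function asserts.
#'
#' @param call validated `stwintron_call` of class tag `D1_2`.
#' @param downstream_exon_first_nt single base, the first nt of the exon
#'   following the composite.
#' @param cfg [motif_config()].
#' @return an A2_3 `stwintron_call` over the shifted composite, or `NULL`
#'   when no alternative parse exists.
#' @export
find_alternative_parse <- function(call, downstream_exon_first_nt,
                                   cfg = motif_config()) {
  if (!identical(call$class_tag, "D1_2"))
    stop("alternative parse search applies to D1_2 calls only")
  if (!isTRUE(call$validated)) stop("call must be validated")
  comp <- call$composite_seq
  if (substr(comp, 1, 2) != "GG") return(NULL)   # necessary condition
  if (!identical(toupper(downstream_exon_first_nt), "G")) return(NULL)
  L <- nchar(comp)
  ilen <- call$internal$length
  # shifted composite: drop the leading G, append the exonic G
  shifted <- paste0(substr(comp, 2, L), "G")
  new_internal_seq <- substr(comp, ilen + 1, L)            # old external
  new_external_seq <- paste0(substr(comp, 2, ilen), "G")   # old internal, last G swapped
  full_span <- function(str) {
    cands <- find_intron_candidates(str, cfg)
    hit <- cands[cands$start == 0L & cands$end == nchar(str), , drop = FALSE]
    if (nrow(hit) == 0) NULL else as.list(hit[1, ])
  }
  int_c <- full_span(new_internal_seq)
  if (is.null(int_c)) return(NULL)
  ext_c <- full_span(new_external_seq)
  if (is.null(ext_c)) return(NULL)
  # mRNA identity of the two pathways on the extended window
  extended <- paste0(comp, "G")
  after_d12 <- substr(extended, L + 1, L + 1)
  after_a23 <- {
    step1 <- paste0(substr(extended, 1, ilen),
                    substr(extended, L + 1, L + 1))   # internal' excised
    substr(step1, 1, 1)                               # external' excised
  }
  stopifnot(identical(after_d12, after_a23))
  cs <- call$composite[["start"]]; ce <- call$composite[["end"]]
  int_abs <- int_c
  int_abs$start <- cs + ilen; int_abs$end <- ce
  int_abs$branch_start <- int_abs$branch_start + cs + ilen
  int_abs$acceptor_start <- int_abs$acceptor_start + cs + ilen
  new_stwintron_call(
    "A2_3", region(cs + 1, ce + 1), shifted, int_abs,
    list(region(cs + 1, cs + ilen), region(ce, ce + 1)),
    new_external_seq, ext_c)
}

#' Classify the intron state at one mapped position
#'
#' @param seq `sequence_record` or DNA string of the species' locus.
#' @param position 0-based offset of the site (first nt of the intervening
#'   sequence, were one present).
#' @param cfg [motif_config()].
#' @param calls,candidates optional precomputed [detect_stwintrons()] /
#'   [find_intron_candidates()] results for `seq`.
#' @param annotated optional [region()] of an annotated intervening sequence
#'   at the position, used to diagnose non-canonical splice sites.
#' @return single state string: `"STWINTRON"` when a validated call covers the
#'   position, `"INTRON"` when a lone candidate covers it, `"NONCANONICAL"`
#'   when an annotated intervening sequence fails the grammar, `"ABSENT"`
#'   otherwise; conflicting overlapping evidence yields `"AMBIGUOUS"` with
#'   both records attached as the `"evidence"` attribute.
#' @export
classify_site <- function(seq, position, cfg = motif_config(),
                          calls = NULL, candidates = NULL, annotated = NULL) {
  s <- as_dna_string(seq)
  if (is.null(calls)) calls <- detect_stwintrons(s, cfg)
  if (is.null(candidates)) candidates <- find_intron_candidates(s, cfg)
  pos <- as.integer(position)
  # evidence is anchored at the site: a covering validated call, or a lone
  # candidate whose first nucleotide is the site position
  cov_calls <- Filter(function(cl) isTRUE(cl$validated) &&
                        cl$composite[["start"]] <= pos &&
                        pos < cl$composite[["end"]], calls)
  anchored <- candidates[candidates$start == pos, , drop = FALSE]
  if (length(cov_calls)) {
    # a candidate starting at the site that is not contained in any covering
    # call is conflicting evidence, reported rather than silently resolved
    lone <- anchored[!vapply(seq_len(nrow(anchored)), function(i)
      any(vapply(cov_calls, function(cl)
        anchored$start[i] >= cl$composite[["start"]] &&
          anchored$end[i] <= cl$composite[["end"]], logical(1))),
      logical(1)), , drop = FALSE]
    if (nrow(lone) > 0)
      return(structure("AMBIGUOUS",
                       evidence = list(calls = cov_calls, candidates = lone)))
    return("STWINTRON")
  }
  if (nrow(anchored) > 0) return("INTRON")
  if (!is.null(annotated)) {
    ann <- find_intron_candidates(s, cfg,
                                  window = c(annotated[["start"]],
                                             annotated[["end"]]))
    full <- ann[ann$start == annotated[["start"]] &
                  ann$end == annotated[["end"]], , drop = FALSE]
    if (nrow(full) == 0) return("NONCANONICAL")
  }
  "ABSENT"
}
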