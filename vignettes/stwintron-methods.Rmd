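---
title: "Detecting spliceosomal twin introns and tracing their gain and loss"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting spliceosomal twin introns and tracing their gain and loss}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stwintrons)
```

## The model

A canonical U2 intron is recognised here by three sequence elements: a donor
at its 5' end (beginning `GT`), a lariat branch-point motif carrying the
branch adenosine, and an acceptor at its 3' end (ending `AG`), with the
branch motif a short, bounded distance upstream of the acceptor. A
**stwintron** (spliceosomal twin intron) is a composite intervening sequence
in which a second, "internal" U2 intron interrupts one of these elements of
an "external" intron. The external intron's element is only restored — and
the external intron only spliceable — after the internal intron has been
excised, so removal is an obligatory two-step process, internal first.

Three nesting classes are supported, named for the interrupted element and
the split position:

* **[D1,2]** — the internal intron sits between nucleotides 1 and 2 of the
  external donor. Because the internal intron itself begins `GT`, every
  [D1,2] composite begins `GG`.
* **[D2,3]** — the split lies between donor nucleotides 2 and 3; the
  composite begins `GT`.
* **[A2,3]** — the internal intron splits the external acceptor between its
  penultimate `A` and ultimate `G`; the composite's final nucleotide is that
  `G`.

A validated [D1,2] composite admits an **alternative [A2,3] parse** exactly
when the first base of the downstream exon is also a `G`: the composite
window shifts one nucleotide 3', the old external intron (which, as a string,
begins at the internal intron's terminal `G`) becomes the new internal, and
the old internal — its final `G` replaced by the exonic `G` — becomes the new
external. Both sequential pathways excise the same multiset of nucleotides
and yield the identical mature mRNA; `find_alternative_parse()` asserts this
identity rather than assuming it.

**Intron phase** is the number of nucleotides of the interrupted codon lying
upstream of the intervening sequence (0, 1 or 2). For a stwintron the
reference point is the composite's first nucleotide — the external donor's
`G`, one nucleotide upstream of the internal donor. This is why the same
locus can read as a phase-1 stwintron but as a phase-2 intervening sequence
under the naive single-intron annotation that starts at the internal donor.

## The motif grammar and its defaults

All scanning is parameterised by `motif_config()`:

| parameter | default | meaning |
|---|---|---|
| `donor_patterns` | `GTRHGH` | IUPAC donor; tightest cover of the donors GTACGT, GTATGC, GTGAGT, GTAAGA observed in the lipS structures |
| `branch_pattern` | `RCTRAY` | branch-point motif; covers ACTGAC, GCTAAC, GCTAAT, GCTGAC; adenosine at position 5 |
| `acceptor_pattern` | `HAG` | covers CAG, TAG and the AAG acceptor seen in an external intron; a `YAG` preset (`motif_config_strict_acceptor()`) is provided for genome-wide scans where AAG acceptors are doubtful |
| `branch_to_acceptor_gap` | 3–12 nt | brackets the observed 4–7 nt gaps with slack |
| `min_intron_len`, `max_intron_len` | 40, 1000 nt | U2 intron length bounds typical of filamentous fungi |
| `min_exon_len` | 20 nt | minimum exon between neighbouring intervening sequences; surfaced for intron-definition-style filtering, not enforced during detection |

Every default is overridable, and config files round-trip through
`read_motif_config()` / `write_motif_config()`. `N` bases match no pattern
letter unless `allow_n_match = TRUE`, so assembly gaps never produce calls.

`find_intron_candidates()` reports **all** (donor, branch, acceptor) triples
satisfying the grammar — overlapping candidates included — because the
stwintron detector needs the full candidate lattice. For a (donor, acceptor)
pair with several compliant branch hits the 3'-most hit is reported (the
biologically favoured proximal branch point), the rest retained in
`branch_alts`.

`detect_stwintrons()` then tests, for every candidate and every class,
whether the 1–2 nt of flanking context satisfies the class geometry and
whether excising the candidate leaves a grammar-compliant external intron.
The external intron is resolved to the **shortest** compliant excision
product, i.e. the most proximal donor/branch/acceptor couple, which is what
strict intron definition predicts; calls are emitted only when validation
succeeds. Nesting is restricted to depth 2 (one internal inside one
external); every structure in scope has this form, and deeper stacks would
be reported as separate overlapping calls rather than silently nested.

## Coordinates, strands, degenerate inputs

Internal coordinates are 0-based half-open throughout; GFF3 import/export
converts to 1-based inclusive. RNA input (`U`) is normalised to DNA (`T`) on
ingest and all motif comparisons happen in DNA space. Minus-strand input is
reverse-complemented up front so that detection has a single sense-strand
code path. Empty windows, windows shorter than the minimum intron length and
motif-free sequences yield empty results, not errors; zero stwintron calls is
a normal outcome. Ties in candidate ordering are broken by (start, end);
co-optimal ancestral labelings (below) are counted, never silently broken.

## Splicing simulation

`splice_gene()` excises features 5'→3', expanding each stwintron into its
internal step followed by its external step. Any user-supplied order that
keeps internal-before-external yields the same mature mRNA (asserted against
independent exon concatenation); requesting the external first is an
ordering error, matching the biochemistry. Translation uses the standard
nuclear genetic code only.

## Homologous intron sites

Two intron observations in different species are the same site iff they map
to the identical (protein alignment column, phase) pair. Phase inclusion
prevents spurious matches one nucleotide apart; no column-slack window is
applied, since positions are treated as exact. Phase-0 boundaries are
anchored to the residue *after* the boundary (an arbitrary but fixed and
documented convention). The alignment is consumed, never inferred — aligner
choice and trimming are upstream decisions. `build_site_matrix()` verifies
that each gene model's conceptual translation equals its ungapped aligned
sequence before projecting, and distinguishes `A` (residue present,
intron-free) from `NG` (gap or missing orthologue) at each site.

## Gain/loss inference

`sankoff()` runs an exact dynamic program over the three site states
S (stwintron), I (standard intron), N (no intronic sequence) with the cost
model:

|  from\\to | S | I | N |
|---|---|---|---|
| **S** | 0 | 1 | 1 |
| **I** | 1 | 0 | 1 |
| **N** | ∞ | ∞ | 0 |

Regain after complete loss is forbidden (Dollo), while stwintronisation
(I→S, the appearance of an internal intron within a pre-extant intron) is
permitted at finite cost — that gain is precisely the event of interest.
A `strict_dollo` switch additionally forbids I→S once a history's gain
branch has been fixed. The root state is unconstrained by default (the
minimum is taken over root states); `root_state` fixes it when outside
evidence dictates the ancestral condition, e.g. a site known to predate the
clade is rooted at `I`. Both the count of co-optimal labelings and, in
`count_independent_losses()`, the minimum/maximum number of loss branches
across co-optimal labelings (with an ambiguity flag) are reported, because
minimal histories genuinely disagree in cases like a loss shared by a stem
versus two terminal losses.

## What the synthetic-data generator emulates

The fixtures module instantiates intron skeletons of the form
`donor—spacer—branch—spacer—acceptor` and assembles genes around them.
Two presets encode the published lipS architectures end to end: the
*A. nidulans* preset plants the 52-nt first intron 69 nt behind the ATG, the
99-nt [D1,2] composite (53-nt internal + 46-nt external) splitting the CCC
codon of Pro189, the 142-nt inter-intron exon and the 49-nt third intron
inside a 2616-nt ORF (871 residues); the *A. niger* preset plants the 109-nt
composite (52 + 57 nt) at the Pro184 CCT codon inside a 2730-nt ORF
(909 residues). The *A. niger* exon sizes other than the stwintron anchor
are not published and are therefore synthetic, as is all exonic sequence in
both presets.

Exonic fill is drawn from proline/threonine codons over {A, C}
(`CCA/CCC/ACA/ACC`). This composition contains no G or T outside the planted
elements, so fill can create neither donors, branch motifs nor acceptors —
the planted features are uniquely recoverable and the worked examples are
unambiguous. Strict mode additionally resamples intron spacers until the
detection grammar, applied to the assembled gene, recovers exactly the
planted truth (for the single-stwintron presets, the emitted call set must
equal the planted composite). In multi-site simulated families, additional
*cross-feature* nested parses — e.g. an internal donor of one composite
pairing with the acceptor of a downstream feature — are legitimate under the
grammar and are tolerated as long as they re-parse planted material; fill
alone must never produce a call.

`simulate_family()` plants per-species site states (S/I/A) at shared codon
positions over a protein that is identical across species up to seeded
synonymous third-position variation, so the trivially correct ungapped
alignment is emitted alongside. What this deliberately does **not** emulate:
substitution and indel evolution, codon-usage realism, alignment error,
annotation error, or splice-site strength variation. Passing round-trip tests
therefore shows that the detection, mapping and inference machinery is
internally consistent under its own grammar — not that the grammar captures
every real splice site, nor that real alignments are error-free.

All generators are deterministic under a fixed seed (byte-identical output)
and restore the session RNG state.

## Problem sizes used in the checks

The shipped checks run at desk scale: preset loci of ~2.8 kb, random-sequence
scanner cross-checks up to 5 kb against an exhaustive enumeration oracle, 200
random composites for the two-step-excision identity, every rooted topology
on up to six leaves for the Sankoff-versus-enumeration identity, and
simulated families of up to a dozen species. These sizes exercise every code
path; the algorithms themselves are linear-to-quadratic in sequence length
and linear in tree size, and genome-scale scanning is a matter of windowing,
not of different code.

## Known limitations

* The grammar is combinatorial, not probabilistic: there is no PWM scoring,
  no polypyrimidine-tract model, and no use of expression evidence, so
  genome-wide scans over-call relative to a trained splice-site model.
* Homology of intron positions by (column, phase) inherits the quality of
  the input alignment; misalignment shifts a site's column and splits true
  homologous sites.
* The loss-mode distinction (S→I versus S→N) is encoded in the cost matrix,
  not inferred mechanistically; reverse-transcription-mediated mechanisms
  are bookkeeping states here, not simulated processes.
* U12/minor-spliceosome introns, trans-splicing and nesting deeper than two
  are out of scope.
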