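# stwintrons

Detection and evolutionary analysis of **spliceosomal twin introns
("stwintrons")** in fungal genes.

A stwintron is a complex intervening sequence in which an "internal" canonical
U2 intron interrupts one of the functional sequence elements — the donor, the
lariat branch-point region, or the acceptor — of an "external" U2 intron.
Removal therefore requires two consecutive splicing reactions: only after the
internal intron is excised does the external intron's splice element become
functional. Classes are named for the interrupted element: **[D1,2]** and
**[D2,3]** stwintrons split the external donor between its 1st–2nd or 2nd–3rd
nucleotides; **[A2,3]** stwintrons split the external acceptor between its
penultimate A and ultimate G. A [D1,2] composite whose downstream exon begins
with G additionally admits an alternative, mutually exclusive [A2,3] parse
that yields the identical mature mRNA.

The package is aimed at people annotating fungal (or other intron-rich)
genomes and at people studying intron gain and loss. It provides:

* **`find_intron_candidates()`** — enumerate candidate U2 introns under a
  configurable IUPAC motif grammar (`motif_config()`): donor `GTRHGH`,
  branch point `RCTRAY` (branch adenosine at position 5), acceptor `HAG`,
  branch-to-acceptor gap 3–12 nt, intron length 40–1000 nt by default.
* **`detect_stwintrons()`** — nested twin-intron detection over the full
  candidate lattice, validated by simulated excision: a call is emitted only
  when deleting the internal candidate leaves a grammar-compliant external
  intron. `find_alternative_parse()` handles the [D1,2]/[A2,3] duality.
* **`splice_gene()` / `translate_orf()`** — ordered splicing intermediates
  (internal strictly before external), mature mRNA, ORF and conceptual
  translation; phases and split codons via `split_codon()`.
* **`build_site_matrix()`** — projection of intron positions onto a protein
  multiple alignment; homologous sites are identical (alignment column,
  phase) pairs, giving a species × site state matrix over
  {stwintron, intron, absent, non-canonical, no gene}.
* **`sankoff()` / `count_independent_losses()`** — exact minimal-cost
  gain/loss histories on a rooted tree under a Dollo-style cost model
  (`cost_model()`) that distinguishes full stwintron loss (S→N) from
  internal-intron-only loss (S→I, reversal to a standard intron), with exact
  counts of co-optimal labelings.
* **`preset_anidulans_lipS()` / `preset_aniger_lipS()` /
  `simulate_family()`** — a deterministic synthetic-data generator that
  instantiates published motif skeletons (e.g.
  `5'-GUACGU—33nt—ACUGAC—4nt—CAG`) and simulates orthologue families with
  planted site states, so the whole pipeline runs without downloads.

A thin command-line wrapper with subcommands `scan`, `detect`, `splice`,
`map-sites`, `infer-events` and `make-fixtures` is installed at
`system.file("cli", "stwintron.R", package = "stwintrons")`.

## Worked example

```r
library(stwintrons)

px <- preset_anidulans_lipS(seed = 1)   # synthetic A. nidulans lipS locus
calls <- detect_stwintrons(px$record)
calls
#> <stwintron_calls> 1 call(s)
#> <stwintron_call> [D1_2] composite [617, 716) 99 nt = internal 53 + external 46

cl <- calls[[1]]
excise_internal(cl$composite_seq, cl)   # 46-nt external intron
#> begins "GTGAGT" — the donor reconstructed by the first splicing step

split_codon(px$gene, 2)[c("phase", "residue_index", "codon_nt")]
#> $phase          1
#> $residue_index  189
#> $codon_nt       "CCC"

sp <- splice_gene(px$gene)
sp
#> <splicing_path> 4 step(s); mature mRNA 2622 nt; ORF 2616 nt; protein 871 aa
```

The 99-nt [D1,2] composite is excised in two consecutive reactions (53-nt
internal intron first, then the 46-nt external intron whose `GTGAGT` donor
only exists after the first step). It splits the CCC codon of Pro189 in
phase 1, while the naive single-intron reading of the same region — from the
internal donor to the downstream acceptor — would be a 289-nt phase-2
intervening sequence. The spliced ORF of 2616 nt encodes 871 residues.

On a phylogenetic toy, the two-step loss scenario:

```r
tr <- read_newick(text = "((Pcap,Pcit),(X,Y));")
sankoff(tr, c(Pcap = "N", Pcit = "I", X = "S", Y = "S"), root_state = "S")
#> <event_labeling> total cost 2; 2 event(s); 2 co-optimal labeling(s)
```

Both minimal histories need two events — either internal-intron loss on the
genus stem followed by full loss in one species, or the two losses on the two
terminal branches — and the tie is reported, not broken.

## Scope

The package consumes protein alignments and rooted Newick trees; it does not
infer alignments or trees (MAFFT/PhyML-style inference is upstream), does no
BLAST orthologue searching, no probabilistic splice-site scoring, and no
RNA-seq quantification. See the methods vignette
(`vignettes/stwintron-methods.Rmd`) for the model, parameter defaults and
design decisions.
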