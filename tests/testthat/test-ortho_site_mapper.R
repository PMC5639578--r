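cfg <- motif_config()

test_that("residue/column maps are inverse bijections on non-gap columns", {
  ap <- aligned_protein("x", "M-KR")
  expect_identical(residue_to_column(ap, 1), 1L)
  expect_identical(residue_to_column(ap, 2), 3L)
  expect_error(residue_to_column(ap, 4), "out of range")
  ug <- aligned_protein("y", "MKR")
  for (i in 1:3) expect_identical(residue_to_column(ug, i), i)
  # random gapped toys against an inverse-mapping oracle
  set.seed(9)
  for (rep in 1:20) {
    chars <- sample(c(LETTERS[1:6], "-"), 30, replace = TRUE)
    ap <- aligned_protein("z", paste(chars, collapse = ""))
    n_res <- sum(chars != "-")
    if (n_res == 0) next
    for (i in sample(n_res, min(5, n_res))) {
      col <- residue_to_column(ap, i)
      expect_identical(sum(chars[1:col] != "-"), i)   # inverse map
      expect_true(chars[col] != "-")
    }
  }
})

test_that("intron positions project onto protein coordinates", {
  px <- preset_anidulans_lipS(1)
  expect_identical(intron_protein_position(px$gene, 1),
                   c(residue_index = 24L, phase = 0L))
  expect_identical(intron_protein_position(px$gene, 2),
                   c(residue_index = 189L, phase = 1L))
})

test_that("a mixed stwintron/intron family maps to one shared site", {
  tr <- read_newick(text = "((a,b),(c,d));")
  tr$tip.label <- paste0("sp", 1:4)
  fam <- simulate_family(tr, list(list(codon = 20, states = c(
    sp1 = "S", sp2 = "S", sp3 = "I", sp4 = "I"))), n_codons = 60, seed = 11)
  m <- build_site_matrix(fam$alignment, fam$gene_models, cfg)
  expect_identical(nrow(m$sites), 1L)
  expect_identical(m$sites$column, 20L)
  expect_identical(m$sites$phase, 1L)
  expect_identical(unname(m$states[, 1]), c("S", "S", "I", "I"))
})

test_that("families without introns give an empty matrix", {
  tr <- random_tree(3)
  fam <- simulate_family(tr, list(list(codon = 20, states = c(
    sp1 = "A", sp2 = "A", sp3 = "A"))), n_codons = 50, seed = 2)
  m <- build_site_matrix(fam$alignment, fam$gene_models, cfg)
  expect_identical(nrow(m$sites), 0L)
})

test_that("planted site states are recovered exactly on a simulated family", {
  set.seed(19)
  tr <- random_tree(12)
  states1 <- setNames(sample(c("S", "I", "A"), 12, replace = TRUE),
                      tr$tip.label)
  states2 <- setNames(sample(c("S", "I", "A"), 12, replace = TRUE),
                      tr$tip.label)
  fam <- simulate_family(tr, list(list(codon = 15, states = states1),
                                  list(codon = 45, states = states2)),
                         n_codons = 80, seed = 23)
  m <- build_site_matrix(fam$alignment, fam$gene_models, cfg)
  expect_identical(m$states[rownames(fam$truth_matrix$states),
                            colnames(fam$truth_matrix$states)],
                   fam$truth_matrix$states)
})

test_that("gaps and missing orthologues are marked NO_GENE", {
  tr <- random_tree(2)
  fam <- simulate_family(tr, list(list(codon = 20, states = c(
    sp1 = "S", sp2 = "I"))), n_codons = 50, seed = 4)
  aln <- fam$alignment
  prot <- aln$sp1$aligned
  # a third species whose orthologue lacks the site column
  aln$sp3 <- aligned_protein("sp3", paste0(substr(prot, 1, 19), "-",
                                           substr(prot, 21, nchar(prot))))
  m <- build_site_matrix(aln, fam$gene_models, cfg)
  expect_identical(unname(m$states["sp3", 1]), "NG")
  expect_identical(unname(m$states[c("sp1", "sp2"), 1]), c("S", "I"))
})

test_that("protein/alignment mismatches are a hard error naming the species", {
  tr <- random_tree(2)
  fam <- simulate_family(tr, list(list(codon = 20, states = c(
    sp1 = "S", sp2 = "I"))), n_codons = 50, seed = 4)
  aln <- fam$alignment
  aln$sp2 <- aligned_protein("sp2", paste0("W", substr(aln$sp2$aligned, 2,
                                                       nchar(aln$sp2$aligned))))
  expect_error(build_site_matrix(aln, fam$gene_models, cfg), "sp2")
})

test_that("shifting an intron by one codon moves the residue, not the phase", {
  set.seed(33)
  codons <- sample(c("CCA", "CCC", "ACA", "ACC"), 40, replace = TRUE)
  iv <- build_intron(random_skeleton(), cfg = cfg, strict = FALSE)
  for (cut in c(31, 34)) {   # +3 coding nt
    s <- paste0(paste(substring(paste(codons, collapse = ""), 1, cut)),
                iv, substring(paste(codons, collapse = ""), cut + 1), "TAA")
    gm <- gene_model(s, 0, introns = data.frame(start = cut, end = cut + nchar(iv)))
    pp <- intron_protein_position(gm, 1)
    if (cut == 31) first <- pp
  }
  expect_identical(unname(pp["phase"]), unname(first["phase"]))
  expect_identical(unname(pp["residue_index"]), unname(first["residue_index"] + 1L))
})

test_that("site co-occurrence tabulates joint states for co-loss screening", {
  tr <- random_tree(5)
  st1 <- c(sp1 = "S", sp2 = "S", sp3 = "A", sp4 = "A", sp5 = "A")
  st2 <- c(sp1 = "I", sp2 = "I", sp3 = "A", sp4 = "A", sp5 = "I")
  fam <- simulate_family(tr, list(list(codon = 15, states = st1),
                                  list(codon = 40, states = st2)),
                         n_codons = 60, seed = 6)
  m <- build_site_matrix(fam$alignment, fam$gene_models, cfg)
  co <- neighbour_site_cooccurrence(m, "c15p1", "c40p1")
  # co-loss in sp3 and sp4
  expect_identical(sum(co$state_a == "A" & co$state_b == "A"), 2L)
  # the A. terreus-type pattern: stwintron lost, downstream intron retained
  expect_identical(sum(co$state_a == "A" & co$state_b == "I"), 1L)
  tab <- attr(co, "table")
  expect_identical(unname(tab["S", "I"]), 2L)
  # a site against itself is diagonal
  self <- neighbour_site_cooccurrence(m, 1, 1)
  expect_true(all(self$state_a == self$state_b))
  expect_error(neighbour_site_cooccurrence(m, "c99p0", 1), "unknown site")
})

test_that("the site matrix survives a TSV round trip", {
  tr <- random_tree(10)
  sts <- setNames(sample(c("S", "I", "A"), 10, replace = TRUE), tr$tip.label)
  fam <- simulate_family(tr, list(list(codon = 25, states = sts)),
                         n_codons = 60, seed = 8)
  m <- build_site_matrix(fam$alignment, fam$gene_models, cfg)
  path <- tempfile(fileext = ".tsv")
  write_site_matrix_tsv(m, path)
  m2 <- read_site_matrix_tsv(path)
  expect_identical(m2$states, m$states)
  expect_identical(m2$sites$column, m$sites$column)
  expect_identical(m2$sites$phase, m$sites$phase)
})
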