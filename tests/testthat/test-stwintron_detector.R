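cfg <- motif_config()

test_that("the A. nidulans lipS preset yields one validated D1_2 call", {
  px <- preset_anidulans_lipS(1)
  calls <- detect_stwintrons(px$record, cfg)
  expect_length(calls, 1)
  cl <- calls[[1]]
  expect_identical(cl$class_tag, "D1_2")
  expect_identical(cl$internal$length, 53L)
  expect_identical(cl$external_length, 46L)
  expect_identical(unname(cl$composite["end"] - cl$composite["start"]), 99L)
  expect_identical(cl$reconstructed_donor, "GTGAGT")
  expect_true(cl$validated)
  expect_identical(substr(cl$composite_seq, 1, 2), "GG")
  # the downstream exon resumes mid-CCC codon, so no alternative parse
  expect_null(cl$alternative_parse)
})

test_that("the A. niger lipS preset yields the 109-nt D1_2 call", {
  py <- preset_aniger_lipS(1)
  calls <- detect_stwintrons(py$record, cfg)
  expect_length(calls, 1)
  cl <- calls[[1]]
  expect_identical(cl$internal$length, 52L)
  expect_identical(cl$external_length, 57L)
  expect_identical(unname(cl$composite["end"] - cl$composite["start"]), 109L)
  expect_identical(cl$reconstructed_donor, "GTGAGT")
})

test_that("a lone standard intron triggers zero calls", {
  set.seed(8)
  s <- paste0(safe_fill(40),
              build_intron(intron_skeleton("GTACGT", 33, "ACTGAC", 4, "CAG")),
              safe_fill(40))
  expect_length(detect_stwintrons(s, cfg), 0)
})

test_that("all three nesting classes are detected on planted composites", {
  set.seed(21)
  for (tag in c("D1_2", "D2_3", "A2_3")) {
    ok <- FALSE
    for (try in 1:20) {
      stw <- build_stwintron(random_stw_skeleton(tag), cfg = cfg)
      s <- paste0(safe_fill(35), stw$composite, safe_fill(35))
      calls <- detect_stwintrons(s, cfg)
      hit <- Filter(function(cl) cl$class_tag == tag &&
                      cl$composite[["start"]] == 35 &&
                      cl$composite[["end"]] == 35 + nchar(stw$composite), calls)
      if (length(hit) == 1) { ok <- TRUE; break }
    }
    expect_true(ok, label = paste("planted", tag, "recovered"))
  }
})

test_that("excising the internal reconstructs the external splice site", {
  px <- preset_anidulans_lipS(1)
  cl <- detect_stwintrons(px$record, cfg)[[1]]
  ext <- excise_internal(cl$composite_seq, cl)
  expect_identical(nchar(ext), 46L)
  expect_identical(substr(ext, 1, 6), "GTGAGT")
  py <- preset_aniger_lipS(1)
  cl2 <- detect_stwintrons(py$record, cfg)[[1]]
  ext2 <- excise_internal(cl2$composite_seq, cl2)
  expect_identical(nchar(ext2), 57L)
  expect_identical(substr(ext2, 1, 6), "GTGAGT")
  # geometry mismatch is rejected with class and offsets
  bad <- cl; bad$class_tag <- "D2_3"
  expect_error(excise_internal(cl$composite_seq, bad), "geometry mismatch")
})

test_that("two-step excision equals one-step composite deletion", {
  set.seed(31)
  n_ok <- 0
  for (rep in 1:60) {
    stw <- build_stwintron(random_stw_skeleton(sample(c("D1_2", "D2_3", "A2_3"), 1)),
                           cfg = cfg, strict = FALSE)
    left <- safe_fill(30); right <- safe_fill(30)
    s <- paste0(left, stw$composite, right)
    calls <- detect_stwintrons(s, cfg)
    for (cl in calls) {
      cs <- cl$composite[["start"]]; ce <- cl$composite[["end"]]
      # step 1: excise the internal intron from the full sequence
      after1 <- paste0(substr(s, 1, cl$internal$start),
                       substr(s, cl$internal$end + 1, nchar(s)))
      # the retained external intron is now contiguous at the composite start
      ext <- substr(after1, cs + 1, cs + cl$external_length)
      expect_identical(ext, excise_internal(cl$composite_seq, cl))
      # step 2: excise the external intron
      two_step <- paste0(substr(after1, 1, cs),
                         substr(after1, cs + cl$external_length + 1,
                                nchar(after1)))
      one_step <- paste0(substr(s, 1, cs), substr(s, ce + 1, nchar(s)))
      expect_identical(two_step, one_step)
      n_ok <- n_ok + 1
    }
  }
  expect_gt(n_ok, 40)   # most random composites validate and were exercised
})

test_that("alternative D1_2/A2_3 parses require a downstream G and preserve the mRNA", {
  set.seed(13)
  found <- FALSE
  for (try in 1:30) {
    stw <- build_stwintron(random_stw_skeleton("D1_2"), cfg = cfg)
    s <- paste0(safe_fill(30), stw$composite, "G", safe_fill(29))
    calls <- detect_stwintrons(s, cfg)
    d12 <- Filter(function(cl) cl$class_tag == "D1_2" &&
                    cl$composite[["start"]] == 30, calls)
    if (length(d12) != 1) next
    alt <- d12[[1]]$alternative_parse
    if (is.null(alt)) next
    found <- TRUE
    expect_identical(alt$class_tag, "A2_3")
    # shifted composite: one nt 3' of the original
    expect_identical(unname(alt$composite["start"]),
                     unname(d12[[1]]$composite["start"] + 1L))
    expect_identical(unname(alt$composite["end"] - alt$composite["start"]),
                     unname(d12[[1]]$composite["end"] - d12[[1]]$composite["start"]))
    # the standalone A2_3 scan finds the same shifted composite
    a23 <- Filter(function(cl) cl$class_tag == "A2_3" &&
                    identical(cl$composite, alt$composite), calls)
    expect_length(a23, 1)
    # both pathways excise to the identical mature sequence
    one <- paste0(substr(s, 1, 30), substr(s, 30 + 1 + nchar(stw$composite), nchar(s)))
    two <- paste0(substr(s, 1, 30 + 1),
                  substr(s, 30 + 1 + nchar(stw$composite) + 1, nchar(s)))
    expect_identical(one, two)
    break
  }
  expect_true(found)
  # downstream base not G: no alternative parse
  px <- preset_anidulans_lipS(1)
  cl <- detect_stwintrons(px$record, cfg)[[1]]
  expect_null(find_alternative_parse(cl, "C", cfg))
  d23 <- cl; d23$class_tag <- "D2_3"
  expect_error(find_alternative_parse(d23, "G", cfg), "D1_2")
})

test_that("detector equals the brute-force nesting oracle on planted sequences", {
  set.seed(57)
  for (rep in 1:6) {
    stw <- build_stwintron(random_stw_skeleton(sample(c("D1_2", "D2_3"), 1)),
                           cfg = cfg, strict = FALSE)
    iv <- build_intron(random_skeleton(), cfg = cfg, strict = FALSE)
    s <- paste0(random_dna(80), stw$composite, random_dna(60), iv,
                random_dna(80))
    got <- unique(do.call(rbind, lapply(detect_stwintrons(s, cfg), function(cl)
      data.frame(class = cl$class_tag,
                 start = unname(cl$composite["start"]),
                 end = unname(cl$composite["end"])))))
    want <- bf_stwintrons(s, cfg)
    if (is.null(got))
      got <- data.frame(class = character(0), start = integer(0),
                        end = integer(0))
    got <- got[order(got$start, got$end, got$class), , drop = FALSE]
    want <- want[order(want$start, want$end, want$class), , drop = FALSE]
    rownames(got) <- rownames(want) <- NULL
    expect_identical(got, want)
  }
})

test_that("classify_site distinguishes stwintron, intron, absence and non-canonical sites", {
  px <- preset_anidulans_lipS(1)
  s <- px$gene$seq
  expect_identical(as.character(classify_site(s, 617, cfg)), "STWINTRON")
  expect_identical(as.character(classify_site(s, 69, cfg)), "INTRON")
  # Tuber-like orthologue: a standard intron at the homologous position
  set.seed(3)
  iv <- build_intron(intron_skeleton("GTACGT", 33, "ACTGAC", 4, "CAG"))
  t_seq <- paste0(safe_fill(90), iv, safe_fill(90))
  expect_identical(as.character(classify_site(t_seq, 90, cfg)), "INTRON")
  # clean exonic sequence
  expect_identical(as.character(classify_site(safe_fill(200), 100, cfg)), "ABSENT")
  # annotated intervening sequence with the non-canonical GAAAGA donor
  nc <- paste0("GAAAGA", substr(iv, 7, nchar(iv)))
  nc_seq <- paste0(safe_fill(90), nc, safe_fill(90))
  expect_identical(
    as.character(classify_site(nc_seq, 90, cfg,
                               annotated = region(90, 90 + nchar(nc)))),
    "NONCANONICAL")
})
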