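test_that("a planted intron after coding nt 12 is recovered with phase 0, anchor 5", {
  set.seed(201)
  cds <- random_cds(30)
  locus <- plant_introns(cds, 12L, test_intron(60L))
  protein <- translate_cds(cds)
  # the 4-codon first exon needs a shorter seed than the default 5
  gs <- structure_from_alignment(protein, locus, gene_id = "toy", seed_k = 3L)
  expect_equal(nrow(gs$introns), 1L)
  expect_equal(gs$introns$cds_offset, 12L)
  expect_equal(gs$introns$phase, 0L)
  expect_equal(gs$introns$anchor_residue, 5L)
  expect_equal(gs$introns$g_start, 12L)
  expect_equal(gs$introns$intron_length, 60L)
  expect_equal(gs$introns$donor, "GT")
  expect_equal(gs$introns$acceptor, "AG")
})

test_that("length filter is strict: a 20-nt GT..AG gap is rejected as LENGTH", {
  set.seed(202)
  cds <- random_cds(30)
  locus <- plant_introns(cds, 45L, test_intron(20L))
  protein <- translate_cds(cds)
  res <- check_intron_candidate(locus, 45L, 65L, 45L, protein)
  expect_false(res$accepted)
  expect_equal(res$reason, "LENGTH")
  # and a 21-nt intron passes the same filter
  locus2 <- plant_introns(cds, 45L, test_intron(21L))
  res2 <- check_intron_candidate(locus2, 45L, 66L, 45L, protein)
  expect_true(res2$accepted)
})

test_that("non-canonical splice sites are rejected as SITE", {
  set.seed(203)
  cds <- random_cds(40)
  locus <- plant_introns(cds, 60L, test_intron(80L, donor = "GC"))
  protein <- translate_cds(cds)
  res <- check_intron_candidate(locus, 60L, 140L, 60L, protein)
  expect_false(res$accepted)
  expect_equal(res$reason, "SITE")
})

test_that("junction translation mismatches are rejected as JUNCTION", {
  set.seed(204)
  cds <- random_cds(40)
  locus <- plant_introns(cds, 60L, test_intron(80L))
  protein <- translate_cds(cds)
  # corrupt the protein residue just downstream of the junction
  aa <- strsplit(protein, "")[[1]]
  aa[21] <- setdiff(c("A", "G"), aa[21])[1]
  bad <- paste(aa, collapse = "")
  res <- check_intron_candidate(locus, 60L, 140L, 60L, bad)
  expect_false(res$accepted)
  expect_equal(res$reason, "JUNCTION")
})

test_that("verify_junction handles identity, mismatch and split codons", {
  set.seed(205)
  cds <- random_cds(30)
  protein <- translate_cds(cds)
  # phase-0 junction at offset 45
  locus0 <- plant_introns(cds, 45L, test_intron(50L))
  expect_true(verify_junction(locus0, 45L, 95L, 45L, protein))
  aa <- strsplit(protein, "")[[1]]
  aa[16] <- setdiff(c("L", "V"), aa[16])[1]
  expect_false(verify_junction(locus0, 45L, 95L, 45L, paste(aa, collapse = "")))
  # hand-built phase-1 intron: split codon reassembled across the junction
  locus1 <- plant_introns(cds, 46L, test_intron(50L))
  expect_true(verify_junction(locus1, 46L, 96L, 46L, protein))
  expect_equal(46L %% 3L, 1L)
  # frame inconsistency is an error
  expect_error(verify_junction(locus1, 46L, 96L, 0L, protein),
               class = "introntrace_consistency_error")
})

test_that("planted non-canonical intron lands in the rejection log, not the output", {
  set.seed(206)
  cds <- random_cds(60)
  locus <- plant_introns(cds, c(45L, 120L),
                         c(test_intron(66L), test_intron(70L, donor = "GC")))
  protein <- translate_cds(cds)
  gs <- structure_from_alignment(protein, locus)
  expect_equal(gs$introns$cds_offset, 45L)
  rej <- attr(gs, "rejections")
  expect_equal(nrow(rej), 1L)
  expect_equal(rej$reason, "SITE")
  expect_equal(rej$intron_length, 70L)
})

test_that("relaxing the minimum intron length only adds introns", {
  set.seed(207)
  for (rep in 1:10) {
    cds <- random_cds(80)
    offsets <- c(60L, 150L)
    lens <- sample(c(22L, 25L, 40L, 80L), 2L)
    locus <- plant_introns(cds, offsets,
                           vapply(lens, test_intron, character(1)))
    protein <- translate_cds(cds)
    strict <- structure_from_alignment(protein, locus, min_intron_length = 30L)
    relaxed <- structure_from_alignment(protein, locus, min_intron_length = 21L)
    strict_keys <- paste(strict$introns$cds_offset, strict$introns$phase)
    relaxed_keys <- paste(relaxed$introns$cds_offset, relaxed$introns$phase)
    expect_true(all(strict_keys %in% relaxed_keys))
  }
})

test_that("phase and anchor are consistent on all recovered structures", {
  set.seed(208)
  cfg <- sim_config(seed = 208, n_genes = 3)
  truth <- simulate_dataset(cfg)
  for (fam in truth$families) for (sp in names(fam$structures)) {
    st <- fam$structures[[sp]]
    gs <- structure_from_alignment(st$protein, fam$loci[[sp]]$sequence)
    if (nrow(gs$introns) == 0L) next
    expect_equal(gs$introns$phase, gs$introns$cds_offset %% 3L)
    expect_equal(gs$introns$anchor_residue, gs$introns$cds_offset %/% 3L + 1L)
    expect_false(is.unsorted(gs$introns$cds_offset, strictly = TRUE))
  }
})

test_that("gene_structure enforces its invariants", {
  intr <- data.frame(cds_offset = 10L, phase = 1L, anchor_residue = 4L,
                     g_start = 10L, g_end = 80L, intron_length = 70L,
                     donor = "GT", acceptor = "AG")
  expect_s3_class(gene_structure("g", "s", strrep("M", 20), intr), "gene_structure")
  bad <- intr; bad$phase <- 2L
  expect_error(gene_structure("g", "s", strrep("M", 20), bad),
               class = "introntrace_structure_error")
  bad2 <- intr; bad2$cds_offset <- 80L   # >= cds_len
  bad2$phase <- 2L; bad2$anchor_residue <- 27L
  expect_error(gene_structure("g", "s", strrep("M", 20), bad2),
               class = "introntrace_structure_error")
})
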