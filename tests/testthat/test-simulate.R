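test_that("config validation enforces the stated world", {
  expect_error(sim_config(), class = "introntrace_config_error")
  expect_error(sim_config(seed = 1, intron_length = c(20L, 100L)),
               class = "introntrace_config_error")
  expect_error(sim_config(seed = 1, gain_rate = -1),
               class = "introntrace_config_error")
  cfg <- sim_config(seed = 1)
  expect_equal(cfg$phase_weights, c(5, 3, 2) / 10)
  expect_equal(length(cfg$tree$tip.label), 12L)
})

test_that("zero gain rate leaves every nuclear gene intron-free", {
  cfg <- sim_config(seed = 701, n_genes = 3, gain_rate = 0)
  truth <- simulate_dataset(cfg)
  for (fam in truth$families) {
    expect_true(all(vapply(fam$structures, function(s) nrow(s$introns) == 0L,
                           logical(1))))
  }
})

test_that("the same seed reproduces byte-identical datasets", {
  cfg <- sim_config(seed = 702, n_genes = 3)
  d1 <- file.path(tempfile(), "a"); d2 <- file.path(tempfile(), "b")
  write_dataset(simulate_dataset(cfg), d1)
  write_dataset(simulate_dataset(cfg), d2)
  f1 <- sort(list.files(d1, recursive = TRUE))
  f2 <- sort(list.files(d2, recursive = TRUE))
  expect_equal(f1, f2)
  for (f in f1) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
})

test_that("introns exist only in lineages below a transfer event", {
  cfg <- sim_config(seed = 703, n_genes = 6)
  truth <- simulate_dataset(cfg)
  tree <- truth$tree
  labels <- c(tree$tip.label, tree$node.label)
  desc <- introntrace:::.descendant_tips(tree)
  for (fam in truth$families) {
    nodes <- match(fam$transfer_branches, labels)
    below <- tree$tip.label[colSums(desc[nodes, , drop = FALSE]) > 0L]
    for (sp in names(fam$structures)) {
      s <- fam$structures[[sp]]
      if (!sp %in% below) {
        expect_equal(s$compartment, "mitochondrial")
        expect_equal(nrow(s$introns), 0L)
      } else {
        expect_equal(s$compartment, "nuclear")
      }
    }
    # every gain event happened on a branch at or below a transfer node
    if (nrow(fam$events) > 0L) {
      anc <- introntrace:::.ancestor_sets(tree)
      for (b in fam$events$branch) {
        v <- match(b, labels)
        expect_true(any(nodes %in% anc[[v]]))
      }
    }
  }
})

test_that("emit_genomic inserts GT..AG introns and splices back exactly", {
  set.seed(704)
  # spec example: one 100-nt intron at offset 12
  cds <- random_cds(30)
  em <- emit_genomic(cds, data.frame(cds_offset = 12L, phase = 0L,
                                     length = 100L))
  expect_equal(nchar(em$locus), nchar(cds) + 100L)
  expect_equal(substr(em$locus, 13L, 14L), "GT")
  expect_equal(substr(em$locus, 111L, 112L), "AG")
  expect_error(emit_genomic(cds, data.frame(cds_offset = 12L, phase = 0L,
                                            length = 20L)),
               class = "introntrace_config_error")
  expect_equal(emit_genomic(cds, NULL)$locus, cds)
  # round-trip over many random structures
  for (rep in 1:50) {
    cds <- random_cds(sample(60:150, 1))
    n <- sample(0:4, 1)
    offs <- sort(sample(seq(30L, nchar(cds) - 30L), n))
    if (n > 1L) offs <- offs[c(TRUE, diff(offs) >= 30L)]
    em <- emit_genomic(cds, data.frame(cds_offset = offs,
                                       phase = offs %% 3L,
                                       length = sample(60:200, length(offs),
                                                       replace = TRUE)))
    spliced <- em$locus
    for (i in rev(seq_len(nrow(em$introns)))) {
      spliced <- paste0(substr(spliced, 1L, em$introns$g_start[i]),
                        substring(spliced, em$introns$g_end[i] + 1L))
    }
    expect_identical(spliced, cds)
  }
})

test_that("evolve_introns matches its Poisson gain and loss model", {
  set.seed(705)
  cfg <- sim_config(seed = 705, gain_rate = 2, loss_rate = 0,
                    min_intron_spacing = 0L)
  cds <- random_cds(500)   # 1.5 kb -> lambda = 2 * 1.5 * t
  t <- 4 / 3               # expected gains = 4
  n_rep <- 400L
  gains <- vapply(seq_len(n_rep), function(i)
    nrow(evolve_introns(cds, t, cfg)$events), integer(1))
  expect_lt(abs(mean(gains) - 4), 3 * sqrt(4 / n_rep))
  # loss limit: enormous loss rate removes everything
  cfg_loss <- sim_config(seed = 705, gain_rate = 0, loss_rate = 100)
  start <- data.frame(cds_offset = c(60L, 300L), phase = c(0L, 0L),
                      length = c(80L, 90L))
  res <- evolve_introns(cds, 10, cfg_loss, introns = start)
  expect_equal(nrow(res$introns), 0L)
})

test_that("indel-free alignments are positional; simple indels track homology", {
  cfg <- sim_config(seed = 706, n_genes = 2)
  truth <- simulate_dataset(cfg)
  fam <- truth$families[[1]]
  aln <- make_alignment(fam)
  expect_false(any(grepl("-", aln$rows, fixed = TRUE)))
  expect_equal(aln$n_columns, nchar(fam$structures[[1]]$protein))
  # simple-indel mode: rows ungap to their proteins, intron columns stay valid
  cfg2 <- sim_config(seed = 707, n_genes = 2, indel_mode = "simple",
                     indel_rate = 0.02)
  truth2 <- simulate_dataset(cfg2)
  fam2 <- truth2$families[[1]]
  aln2 <- make_alignment(fam2)
  expect_true(any(grepl("-", aln2$rows, fixed = TRUE)))
  for (sp in names(fam2$structures)) {
    id <- paste(fam2$gene_id, sp, sep = "|")
    expect_identical(gsub("-", "", aln2$rows[[id]], fixed = TRUE),
                     fam2$structures[[sp]]$protein)
  }
  rec <- fam2$intron_records
  if (nrow(rec) > 0L) {
    for (i in seq_len(nrow(rec))) {
      id <- paste(fam2$gene_id, rec$species_id[i], sep = "|")
      row <- strsplit(aln2$rows[[id]], "")[[1]]
      expect_true(row[rec$column[i]] != "-")
    }
  }
})

test_that("truth labels partition shared positions into descent and parallel", {
  cfg <- sim_config(seed = 708, n_genes = 8)
  truth <- simulate_dataset(cfg)
  for (fam in truth$families) {
    lab <- truth_position_labels(fam)
    if (nrow(lab) == 0L) next
    expect_true(all(lab$label %in% c("descent", "parallel")))
    expect_true(all(lab$n_events[lab$label == "descent"] == 1L))
    expect_true(all(lab$n_events[lab$label == "parallel"] >= 2L))
    # cross-module consistency: truth shared positions equal the
    # shared entries seen by find_shared_positions on the truth matrix
    structs <- fam$structures
    m <- map_introns_to_alignment(fam$alignment, structs)
    tb <- find_shared_positions(m, setNames(names(structs), names(structs)))
    shared_keys <- with(tb$positions[tb$positions$n_groups >= 2L, ],
                        paste(column, phase))
    expect_setequal(paste(lab$column, lab$phase), shared_keys)
  }
})
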