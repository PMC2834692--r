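test_that("textbook four-leaf cases place events as expected", {
  tr <- species_tree("((A,B)ab,(C,D)cd)root;")
  one <- infer_transfers(tr, c(A = "N", B = "N", C = "M", D = "M"), "g1")
  expect_equal(one$n_events, 1L)
  expect_equal(one$transfer_branches, "ab")
  expect_true(one$resolved)
  none <- infer_transfers(tr, c(A = "M", B = "M", C = "M", D = "M"), "g2")
  expect_equal(none$n_events, 0L)
  two <- infer_transfers(tr, c(A = "N", B = "M", C = "N", D = "M"), "g3")
  expect_equal(two$n_events, 2L)
  expect_equal(two$transfer_branches, c("A", "C"))
  # all-N: one ancestral event on the root stem
  all_n <- infer_transfers(tr, c(A = "N", B = "N", C = "N", D = "N"), "g4")
  expect_equal(all_n$n_events, 1L)
  expect_equal(all_n$transfer_branches, "root")
  # error cases
  expect_error(infer_transfers(tr, c(A = "U", B = "U", C = "U", D = "U")),
               class = "introntrace_degenerate_error")
  expect_error(infer_transfers(tr, c(A = "N", A = "M", B = "M", C = "M",
                                     D = "M")),
               class = "introntrace_state_error")
})

test_that("parsimony matches the exhaustive oracle on the small-tree panel", {
  set.seed(401)
  for (tr in small_tree_panel()) {
    for (st in all_state_assignments(tr)) {
      if (all(st == "U")) next
      orc <- oracle_transfers(tr, st)
      sc <- infer_transfers(tr, st)
      expect_equal(sc$n_events, orc$min_events)
      # canonical scenario must be one of the minimal sets, and the full
      # alternative list must be exactly the set of minimal scenarios
      expect_true(list(sc$transfer_branches) %in% orc$sets)
      expect_setequal(vapply(sc$alternatives, paste, character(1), collapse = "/"),
                      vapply(orc$sets, paste, character(1), collapse = "/"))
      expect_equal(sc$resolved, length(orc$sets) == 1L)
    }
  }
})

test_that("parsimony matches the oracle on random multifurcating 5-6 leaf trees", {
  set.seed(402)
  for (n in c(5L, 6L)) {
    for (rep in 1:4) {
      tr <- random_multi_tree(n)
      assignments <- all_state_assignments(tr)
      pick <- if (n == 5L) seq_along(assignments) else
        sample(seq_along(assignments), 120L)
      for (i in pick) {
        st <- assignments[[i]]
        if (all(st == "U")) next
        orc <- oracle_transfers(tr, st)
        sc <- infer_transfers(tr, st)
        expect_equal(sc$n_events, orc$min_events)
        expect_equal(sc$resolved, length(orc$sets) == 1L)
      }
    }
  }
})

test_that("state flips behave monotonically", {
  # U -> N never decreases the count and adds at most one event;
  # U -> M never decreases it (it can split one event into several)
  set.seed(403)
  for (rep in 1:30) {
    tr <- random_multi_tree(sample(4:7, 1))
    tips <- tr$tip.label
    st <- setNames(sample(c("M", "N", "U"), length(tips), replace = TRUE,
                          prob = c(0.4, 0.4, 0.2)), tips)
    us <- names(st)[st == "U"]
    if (length(us) == 0L || all(st %in% c("U", "M"))) next
    base <- if (all(st[st != "U"] == "M")) NA_integer_ else
      infer_transfers(tr, st)$n_events
    if (is.na(base)) next
    flip <- sample(us, 1L)
    st_n <- st; st_n[flip] <- "N"
    st_m <- st; st_m[flip] <- "M"
    n_after <- infer_transfers(tr, st_n)$n_events
    m_after <- infer_transfers(tr, st_m)$n_events
    expect_gte(n_after, base)
    expect_lte(n_after, base + 1L)
    expect_gte(m_after, base)
  }
})

test_that("no scenario ever stacks two events on one root-to-leaf path", {
  set.seed(404)
  for (rep in 1:20) {
    tr <- random_multi_tree(sample(5:8, 1))
    tips <- tr$tip.label
    st <- setNames(sample(c("M", "N", "U"), length(tips), replace = TRUE), tips)
    if (all(st == "U") || !any(st == "N")) next
    sc <- infer_transfers(tr, st)
    P <- oracle_path_matrix(tr)
    labels <- c(tr$tip.label, tr$node.label)
    for (alt in sc$alternatives) {
      sel <- match(alt, labels)
      if (length(sel) == 0L) next
      expect_true(all(rowSums(P[, sel, drop = FALSE]) <= 1L))
    }
  }
})

test_that("independent transfers table reports the multi-event genes", {
  # a nad7-like pattern: nuclear in the green alga and in animals+fungi,
  # mitochondrial in plants and protists -> two independent events
  tr <- sim_config(seed = 1)$tree
  st <- setNames(rep("M", 12), tr$tip.label)
  st[c("hsa", "dre", "dme", "cel", "sce", "spo", "afu")] <- "N"
  st["cre"] <- "N"
  nad7 <- infer_transfers(tr, st, "nad7")
  expect_equal(nad7$n_events, 2L)
  expect_setequal(nad7$transfer_branches, c("unikonts", "cre"))
  root_only <- infer_transfers(tr, setNames(rep("N", 12), tr$tip.label), "sdh2")
  expect_equal(root_only$n_events, 1L)
  tab <- find_independent_transfers(list(nad7 = nad7, sdh2 = root_only))
  expect_equal(tab$gene_id, "nad7")
  expect_equal(tab$n_events, 2L)
  expect_match(tab$transfers, "cre")
})

test_that("relative timing orders nested events and leaves siblings unordered", {
  tr <- species_tree("((A,B)ab,(C,D)cd)root;")
  anc <- infer_transfers(tr, c(A = "N", B = "N", C = "N", D = "N"), "old")
  tipA <- infer_transfers(tr, c(A = "N", B = "M", C = "M", D = "M"), "young")
  sib <- infer_transfers(tr, c(A = "M", B = "M", C = "N", D = "M"), "side")
  rk <- rank_transfer_times(list(anc, tipA, sib), tr, focal_species = "A")
  p <- rk$pairs
  rel_anc_tip <- p$relation[p$gene_a == "old" & p$gene_b == "young"]
  expect_equal(rel_anc_tip, "more_ancient")
  rel_tip_sib <- p$relation[p$gene_a == "young" & p$gene_b == "side"]
  expect_equal(rel_tip_sib, "incomparable")
  fc <- rk$focal_classes
  expect_equal(fc$gene_id, c("old", "young"))   # root stem before tip branch
  expect_equal(fc$rank, c(1L, 2L))
})
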