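mk_structure <- function(gene, sp, protein, offsets) {
  intr <- data.frame(cds_offset = offsets, phase = offsets %% 3L,
                     anchor_residue = offsets %/% 3L + 1L,
                     g_start = offsets, g_end = offsets + 100L,
                     intron_length = 100L, donor = "GT", acceptor = "AG")
  if (length(offsets) == 0L) intr <- intr[0, ]
  gene_structure(gene, sp, protein, intr)
}

test_that("mapping to an ungapped alignment keeps anchor residues as columns", {
  prot <- strrep("MKV", 10)
  aln <- protein_alignment(c("g|a" = prot, "g|b" = prot), "fam")
  s1 <- mk_structure("g", "a", prot, c(9L, 16L))
  s2 <- mk_structure("g", "b", prot, 9L)
  m <- map_introns_to_alignment(aln, list(s1, s2))
  expect_equal(m$column[m$sequence_id == "g|a"], c(4L, 6L))
  expect_equal(m$phase[m$sequence_id == "g|a"], c(0L, 1L))
})

test_that("leading gap columns shift intron columns by the gap count", {
  prot <- strrep("MKV", 10)
  aln <- protein_alignment(c("g|a" = paste0("---", prot),
                             "g|b" = paste0(strrep("MKV", 11), "")), "fam")
  s1 <- mk_structure("g", "a", prot, 9L)
  m <- map_introns_to_alignment(aln, list(s1))
  # brute-force residue -> column oracle
  cols <- which(strsplit(paste0("---", prot), "")[[1]] != "-")
  expect_equal(m$column, cols[4L])
  expect_equal(m$column, 4L + 3L)
})

test_that("protein/alignment mismatches are reported with the sequence name", {
  prot <- strrep("MKV", 10)
  aln <- protein_alignment(c("g|a" = sub("M", "W", prot)), "fam")
  expect_error(map_introns_to_alignment(aln, list(mk_structure("g", "a", prot, 9L))),
               class = "introntrace_alignment_error")
})

test_that("shared positions require identical column and phase", {
  grouping <- c(a = "G1", b = "G2")
  entries <- data.frame(sequence_id = c("g|a", "g|b"),
                        column = c(5L, 5L), phase = c(0L, 0L))
  tb <- find_shared_positions(entries, grouping)
  expect_equal(tb$shared["G1", "G2"], 1L)
  expect_equal(sum(tb$diagonal), 0L)
  # same column, phases 1 vs 2: not shared
  entries2 <- data.frame(sequence_id = c("g|a", "g|b"),
                         column = c(5L, 5L), phase = c(1L, 2L))
  tb2 <- find_shared_positions(entries2, grouping)
  expect_equal(tb2$shared["G1", "G2"], 0L)
  expect_equal(unname(tb2$diagonal), c(1L, 1L))
  expect_error(find_shared_positions(entries, character(0)),
               class = "introntrace_grouping_error")
})

test_that("shared counting matches naive enumeration on random families", {
  set.seed(501)
  for (rep in 1:30) {
    n_seq <- sample(3:20, 1)
    n_col <- sample(50:500, 1)
    sps <- paste0("sp", seq_len(n_seq))
    grouping <- setNames(sample(paste0("G", 1:4), n_seq, replace = TRUE), sps)
    n_entries <- sample(5:60, 1)
    entries <- unique(data.frame(
      sequence_id = paste0("g|", sample(sps, n_entries, replace = TRUE)),
      column = sample(n_col, n_entries, replace = TRUE),
      phase = sample(0:2, n_entries, replace = TRUE)))
    tb <- find_shared_positions(entries, grouping)
    orc <- oracle_shared(entries, grouping)
    expect_equal(tb$diagonal, orc$diagonal)
    expect_equal(tb$shared, orc$shared)
    expect_equal(tb$total_positions, orc$total)
    # conservation of positions: specific + distinct shared == total
    n_shared_distinct <- sum(tb$positions$n_groups >= 2L)
    expect_equal(sum(tb$diagonal) + n_shared_distinct, tb$total_positions)
    # percentages are over the total distinct positions
    if (tb$total_positions > 0) {
      expect_equal(tb$shared_pct, 100 * tb$shared / tb$total_positions)
    }
  }
})

test_that("identical ungapped sequences give one block spanning all columns", {
  prot <- strrep("MKVLDQEW", 10)
  aln <- protein_alignment(setNames(rep(prot, 4), paste0("s", 1:4)), "fam")
  b <- detect_conserved_blocks(aln)
  expect_equal(nrow(b), 1L)
  expect_equal(b$col_start, 1L)
  expect_equal(b$col_end, nchar(prot))
})

test_that("a high-gap column splits surrounding blocks", {
  prot <- strrep("MKVLDQEW", 5)
  rows <- setNames(rep(prot, 4), paste0("s", 1:4))
  mid <- 20L
  rows_gap <- vapply(seq_along(rows), function(i) {
    r <- strsplit(rows[[i]], "")[[1]]
    if (i <= 3) r[mid] <- "-"              # 75% gaps in one column
    paste(r, collapse = "")
  }, character(1))
  names(rows_gap) <- names(rows)
  b <- detect_conserved_blocks(protein_alignment(rows_gap, "fam"))
  expect_gte(nrow(b), 2L)
  expect_false(any(b$col_start <= mid & mid <= b$col_end))
})

test_that("random unrelated sequences yield no conserved blocks", {
  set.seed(502)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  none <- 0L
  for (rep in 1:50) {
    rows <- setNames(vapply(1:20, function(i)
      paste(sample(aa, 200, replace = TRUE), collapse = ""), character(1)),
      paste0("s", 1:20))
    b <- detect_conserved_blocks(protein_alignment(rows, "fam"))
    if (nrow(b) == 0L) none <- none + 1L
  }
  expect_gte(none, 49L)
})

test_that("block restriction is monotone and its edge cases are exact", {
  grouping <- c(a = "G1", b = "G2")
  entries <- structure(
    data.frame(sequence_id = c("g|a", "g|b", "g|a", "g|b"),
               column = c(5L, 5L, 40L, 40L), phase = c(0L, 0L, 2L, 2L)),
    class = c("intron_matrix", "data.frame"), n_columns = 60L)
  all_tb <- find_shared_positions(entries, grouping)
  expect_equal(all_tb$shared["G1", "G2"], 2L)
  no_blocks <- data.frame(col_start = integer(0), col_end = integer(0),
                          mean_identity = numeric(0))
  tb0 <- restrict_to_blocks(entries, grouping, no_blocks)
  expect_equal(sum(tb0$diagonal) + sum(tb0$shared), 0L)
  full <- data.frame(col_start = 1L, col_end = 60L, mean_identity = 1)
  tb_full <- restrict_to_blocks(entries, grouping, full)
  expect_equal(tb_full$shared, all_tb$shared)
  expect_equal(tb_full$diagonal, all_tb$diagonal)
  half <- data.frame(col_start = 1L, col_end = 20L, mean_identity = 1)
  tb_half <- restrict_to_blocks(entries, grouping, half)
  expect_equal(tb_half$shared["G1", "G2"], 1L)
  expect_true(all(tb_half$shared <= all_tb$shared))
})

test_that("transfer-class comparison computes class percentages and ratio", {
  grouping <- c(a = "G1", b = "G2")
  mk_tb <- function(shared_n, total_extra) {
    cols <- c(seq_len(shared_n), 100L + seq_len(total_extra))
    entries <- data.frame(
      sequence_id = c(rep(c("g|a", "g|b"), shared_n),
                      rep("g|a", total_extra)),
      column = c(rep(seq_len(shared_n), each = 2L), 100L + seq_len(total_extra)),
      phase = 0L)
    find_shared_positions(entries, grouping)
  }
  # constructed class: 2 shared of 40 total positions -> 5%
  tb_ind <- mk_tb(2L, 38L)
  expect_equal(tb_ind$total_positions, 40L)
  sc2 <- list(n_events = 2L); class(sc2) <- "transfer_scenario"
  sc1 <- list(n_events = 1L); class(sc1) <- "transfer_scenario"
  cmp <- compare_transfer_classes(list(gA = tb_ind, gB = mk_tb(1L, 39L)),
                                  list(gA = sc2, gB = sc1), c("G1", "G2"))
  expect_equal(cmp$independent$pct, 5)
  expect_equal(cmp$single$pct, 2.5)
  expect_equal(cmp$ratio, 2)
  # identical sharing -> ratio 1; empty class -> undefined
  cmp2 <- compare_transfer_classes(list(gA = tb_ind, gB = tb_ind),
                                   list(gA = sc2, gB = sc1), c("G1", "G2"))
  expect_equal(cmp2$ratio, 1)
  cmp3 <- compare_transfer_classes(list(gA = tb_ind), list(gA = sc2),
                                   c("G1", "G2"))
  expect_true(is.na(cmp3$single$pct))
})
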