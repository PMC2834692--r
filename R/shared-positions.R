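# Mapping intron positions onto protein multiple alignments, shared-position
# counting between taxonomic groups, conserved-block restriction, and the
# independent- vs single-transfer shared-fraction comparison.
#
# A "position" is an (alignment column, phase) pair: requiring phase equality
# makes positions nucleotide-exact (two introns in the same codon at phases 1
# and 2 are different positions).

#' Protein multiple alignment container
#'
#' @param rows Named character vector of gapped amino-acid strings (gap `-`),
#'   all of equal length. Names are sequence ids (`gene|species` convention).
#' @param family_id Identifier.
#' @return A `protein_alignment` object with `n_columns`.
#' @export
protein_alignment <- function(rows, family_id = NA_character_) {
  if (length(rows) == 0L || is.null(names(rows)) || anyDuplicated(names(rows))) {
    .intron_stop("alignment rows must be a uniquely named character vector",
                 "introntrace_alignment_error")
  }
  w <- unique(nchar(rows))
  if (length(w) != 1L) {
    .intron_stop("alignment rows must all have equal length",
                 "introntrace_alignment_error")
  }
  structure(list(family_id = family_id, rows = rows, n_columns = w),
            class = "protein_alignment")
}

#' @export
print.protein_alignment <- function(x, ...) {
  cat(sprintf("<protein_alignment> %s: %d sequences x %d columns\n",
              x$family_id, length(x$rows), x$n_columns))
  invisible(x)
}

# residue index (1-based) -> alignment column (1-based) for one gapped row
.residue_columns <- function(row) which(strsplit(row, "")[[1]] != "-")

#' Map intron positions onto alignment columns
#'
#' Each intron contributes one occurrence at (sequence id, alignment column of
#' its anchor residue, phase). Every structure's protein must equal its
#' ungapped alignment row.
#'
#' @param alignment A [protein_alignment()].
#' @param structures List of [gene_structure()]; each is matched to the row
#'   named `gene_id|species_id` (falling back to `species_id`).
#' @return An `intron_matrix` data frame (sequence_id, column, phase) with
#'   attribute `n_columns`.
#' @export
map_introns_to_alignment <- function(alignment, structures) {
  structures <- .as_structure_list(structures)
  entries <- list()
  for (s in structures) {
    key <- paste(s$gene_id, s$species_id, sep = "|")
    if (!key %in% names(alignment$rows)) key <- s$species_id
    if (!key %in% names(alignment$rows)) {
      .intron_stop(sprintf("no alignment row for sequence '%s|%s'",
                           s$gene_id, s$species_id),
                   "introntrace_alignment_error")
    }
    row <- alignment$rows[[key]]
    ungapped <- gsub("-", "", row, fixed = TRUE)
    if (!identical(ungapped, s$protein)) {
      .intron_stop(sprintf("protein of '%s' does not match its ungapped alignment row",
                           key), "introntrace_alignment_error")
    }
    if (nrow(s$introns) == 0L) next
    cols <- .residue_columns(row)
    entries[[length(entries) + 1L]] <- data.frame(
      sequence_id = key,
      column = cols[s$introns$anchor_residue],
      phase = s$introns$phase)
  }
  out <- if (length(entries) > 0L) do.call(rbind, entries) else
    data.frame(sequence_id = character(0), column = integer(0), phase = integer(0))
  rownames(out) <- NULL
  structure(out, class = c("intron_matrix", "data.frame"),
            n_columns = alignment$n_columns)
}

#' Count group-specific and shared intron positions
#'
#' A distinct (column, phase) position is shared between two groups iff at
#' least one sequence in each carries an intron there, and group-specific iff
#' its carriers all belong to one group. Percentages are relative to the total
#' number of distinct positions across all groups.
#'
#' @param matrix An `intron_matrix` from [map_introns_to_alignment()].
#' @param grouping Named character vector: sequence id (or its species part)
#'   -> group label.
#' @param variant Label stored on the table (`"all_columns"` or
#'   `"conserved_blocks"`).
#' @return A `shared_position_table`: `groups`, `diagonal` (group-specific
#'   counts), `shared` and `shared_pct` (symmetric matrices), `positions`
#'   (per-position detail), `total_positions`, `variant`.
#' @export
find_shared_positions <- function(matrix, grouping,
                                  variant = "all_columns") {
  if (length(grouping) == 0L || is.null(names(grouping))) {
    .intron_stop("grouping must be a non-empty named vector",
                 "introntrace_grouping_error")
  }
  seq_group <- function(id) {
    if (id %in% names(grouping)) return(grouping[[id]])
    sp <- sub("^.*\\|", "", id)
    if (sp %in% names(grouping)) return(grouping[[sp]])
    .intron_stop(sprintf("sequence '%s' has no group assignment", id),
                 "introntrace_grouping_error")
  }
  groups <- sort(unique(unname(grouping)))
  diag_counts <- setNames(rep(0L, length(groups)), groups)
  shared <- matrix(0L, length(groups), length(groups),
                   dimnames = list(groups, groups))
  detail <- data.frame(column = integer(0), phase = integer(0),
                       n_groups = integer(0), groups = character(0),
                       carriers = character(0))
  if (nrow(matrix) > 0L) {
    matrix$group <- vapply(matrix$sequence_id, seq_group, character(1))
    key <- paste(matrix$column, matrix$phase, sep = "_")
    for (k in unique(key)) {
      sel <- matrix[key == k, , drop = FALSE]
      gs <- sort(unique(sel$group))
      if (length(gs) == 1L) {
        diag_counts[gs] <- diag_counts[gs] + 1L
      } else {
        prs <- combn(gs, 2L)
        for (j in seq_len(ncol(prs))) {
          a <- prs[1L, j]; b <- prs[2L, j]
          shared[a, b] <- shared[a, b] + 1L
          shared[b, a] <- shared[b, a] + 1L
        }
      }
      detail[nrow(detail) + 1L, ] <- list(
        sel$column[1L], sel$phase[1L], length(gs),
        paste(gs, collapse = ","),
        paste(sort(unique(sel$sequence_id)), collapse = ","))
    }
  }
  total <- nrow(detail)
  structure(list(groups = groups, diagonal = diag_counts, shared = shared,
                 shared_pct = if (total > 0L) 100 * shared / total else shared * NA_real_,
                 positions = detail[order(detail$column, detail$phase), ,
                                    drop = FALSE],
                 total_positions = total, variant = variant),
            class = "shared_position_table")
}

#' @export
print.shared_position_table <- function(x, ...) {
  cat(sprintf("<shared_position_table> variant=%s, %d distinct positions\n",
              x$variant, x$total_positions))
  m <- x$shared
  diag(m) <- x$diagonal[colnames(m)]
  print(m)
  invisible(x)
}

#' Detect conserved alignment blocks
#'
#' Emulates a conserved-block finder: a column passes when its gap fraction is
#' at most `max_gap` and the mean pairwise identity averaged over a sliding
#' window of `window` columns is at least `min_identity`; maximal runs of at
#' least `min_length` passing columns become blocks. Column identity is the
#' fraction of identical residue pairs among row pairs that are both non-gap
#' (0 when fewer than two rows are non-gap).
#'
#' @param alignment A [protein_alignment()].
#' @param window Sliding-window width in columns (default 10).
#' @param min_identity Minimum windowed mean pairwise identity (default 0.5).
#' @param max_gap Maximum per-column gap fraction (default 0.1).
#' @param min_length Minimum block length in columns (default 8).
#' @return Data frame (col_start, col_end, mean_identity) of non-overlapping
#'   sorted blocks, 1-based inclusive.
#' @export
detect_conserved_blocks <- function(alignment, window = 10L,
                                    min_identity = 0.5, max_gap = 0.1,
                                    min_length = 8L) {
  chars <- do.call(rbind, strsplit(unname(alignment$rows), ""))
  nc <- ncol(chars)
  nr <- nrow(chars)
  gap_frac <- colMeans(chars == "-")
  ident <- vapply(seq_len(nc), function(j) {
    col <- chars[, j]
    col <- col[col != "-"]
    n <- length(col)
    if (n < 2L) return(0)
    tab <- table(col)
    sum(tab * (tab - 1)) / (n * (n - 1))
  }, numeric(1))
  half <- as.integer(window) %/% 2L
  win_mean <- vapply(seq_len(nc), function(j) {
    lo <- max(1L, j - half); hi <- min(nc, j + half)
    mean(ident[lo:hi])
  }, numeric(1))
  pass <- gap_frac <= max_gap & win_mean >= min_identity
  blocks <- data.frame(col_start = integer(0), col_end = integer(0),
                       mean_identity = numeric(0))
  if (any(pass)) {
    r <- rle(pass)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & r$lengths >= min_length
    if (any(keep)) {
      blocks <- data.frame(col_start = starts[keep], col_end = ends[keep],
                           mean_identity = vapply(which(keep), function(j)
                             mean(ident[starts[j]:ends[j]]), numeric(1)))
    }
  }
  blocks
}

#' Recompute a shared-position table inside conserved blocks
#'
#' @param matrix The `intron_matrix` the all-columns table was built from.
#' @param grouping As in [find_shared_positions()].
#' @param blocks Blocks from [detect_conserved_blocks()] on the same alignment.
#' @return A `shared_position_table` with `variant = "conserved_blocks"`;
#'   every cell is at most its all-columns counterpart.
#' @export
restrict_to_blocks <- function(matrix, grouping, blocks) {
  in_block <- rep(FALSE, nrow(matrix))
  if (nrow(blocks) > 0L && nrow(matrix) > 0L) {
    for (j in seq_len(nrow(blocks))) {
      in_block <- in_block | (matrix$column >= blocks$col_start[j] &
                              matrix$column <= blocks$col_end[j])
    }
  }
  sub <- matrix[in_block, , drop = FALSE]
  attr(sub, "n_columns") <- attr(matrix, "n_columns")
  class(sub) <- class(matrix)
  find_shared_positions(sub, grouping, variant = "conserved_blocks")
}

#' Shared-position fractions of independently vs singly transferred genes
#'
#' Genes are partitioned by their number of transfer events (>= 2 =
#' independent, 1 = single). For each class the percentage is
#' `100 * (positions shared between the two focal groups, summed over the
#' class's families) / (total distinct positions in the class's families)`.
#'
#' @param tables Named list (by gene_id) of `shared_position_table` objects,
#'   one per gene family.
#' @param scenarios Named list (by gene_id) of [infer_transfers()] results.
#' @param focal_groups Character vector of two group labels.
#' @return List with per-class `shared`, `total`, `pct` (NA when a class is
#'   empty) and `ratio` (independent / single).
#' @export
compare_transfer_classes <- function(tables, scenarios, focal_groups) {
  stopifnot(length(focal_groups) == 2L)
  g1 <- focal_groups[1L]; g2 <- focal_groups[2L]
  cls <- vapply(names(tables), function(g) {
    s <- scenarios[[g]]
    if (is.null(s)) return(NA_character_)
    if (s$n_events >= 2L) "independent" else if (s$n_events == 1L) "single"
    else NA_character_
  }, character(1))
  tally <- function(which_class) {
    sel <- tables[!is.na(cls) & cls == which_class]
    if (length(sel) == 0L) {
      return(list(shared = NA_integer_, total = NA_integer_, pct = NA_real_,
                  n_genes = 0L))
    }
    shared <- sum(vapply(sel, function(tb) tb$shared[g1, g2], numeric(1)))
    total <- sum(vapply(sel, function(tb) tb$total_positions, numeric(1)))
    list(shared = shared, total = total,
         pct = if (total > 0) 100 * shared / total else NA_real_,
         n_genes = length(sel))
  }
  ind <- tally("independent")
  sgl <- tally("single")
  list(independent = ind, single = sgl,
       ratio = if (!is.na(ind$pct) && !is.na(sgl$pct) && sgl$pct > 0)
         ind$pct / sgl$pct else NA_real_)
}
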