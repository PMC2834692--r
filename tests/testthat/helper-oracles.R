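# Independent brute-force oracles. These deliberately re-derive results by
# exhaustive enumeration and never call the code paths they check.

# Exhaustive enumeration of all colinear block chains (same compatibility
# rules as the aligner, including the small-overlap trim), returning the best
# net residue coverage. Feasible for <= ~12 blocks.
oracle_chain_cover <- function(blocks, max_overlap = 3L) {
  m <- nrow(blocks)
  if (m == 0L) return(0L)
  best <- 0L
  rec <- function(last, cover) {
    best <<- max(best, cover)
    for (i in seq_len(m)) {
      leni <- blocks$p_end[i] - blocks$p_start[i]
      if (is.null(last)) {
        rec(i, leni)
      } else {
        if (blocks$p_start[i] < blocks$p_start[last]) next
        if (i == last) next
        o <- max(0L, blocks$p_end[last] - blocks$p_start[i])
        if (o > max_overlap || o >= leni) next
        if (blocks$g_start[i] + 3L * o < blocks$g_end[last]) next
        if ((blocks$g_start[i] + 3L * o - blocks$g_end[last]) <
            3L * (blocks$p_start[i] + o - blocks$p_end[last])) next
        rec(i, cover + leni - o)
      }
    }
  }
  rec(NULL, 0L)
  best
}

# root-path incidence matrix: tips x nodes, TRUE when node (branch above it,
# or the root stem for the root node) lies on the tip's root path
oracle_path_matrix <- function(tree) {
  ntip <- length(tree$tip.label)
  n <- ntip + tree$Nnode
  par <- rep(NA_integer_, n)
  par[tree$edge[, 2]] <- tree$edge[, 1]
  P <- matrix(FALSE, ntip, n)
  for (t in seq_len(ntip)) {
    v <- t
    while (!is.na(v)) { P[t, v] <- TRUE; v <- par[v] }
  }
  P
}

# Minimal transfer sets by exhaustive subset search over branch combinations,
# increasing the subset size until a valid assignment exists. states: named
# M/N/U vector over tips. Returns min count and every minimal valid set
# (as sorted node-label character vectors).
oracle_transfers <- function(tree, states) {
  tree <- introntrace::species_tree(tree)
  ntip <- length(tree$tip.label)
  n <- ntip + tree$Nnode
  labels <- c(tree$tip.label, tree$node.label)
  P <- oracle_path_matrix(tree)
  st <- states[tree$tip.label]
  iN <- which(st == "N"); iM <- which(st == "M"); iU <- which(st == "U")
  valid <- function(sel) {
    cnt <- rowSums(P[, sel, drop = FALSE])
    all(cnt[iN] == 1L) && all(cnt[iM] == 0L) && all(cnt[iU] <= 1L)
  }
  if (valid(integer(0))) return(list(min_events = 0L, sets = list(character(0))))
  for (k in seq_len(ntip)) {
    combos <- combn(n, k)
    hits <- list()
    for (c in seq_len(ncol(combos))) {
      if (valid(combos[, c])) hits[[length(hits) + 1L]] <- sort(labels[combos[, c]])
    }
    if (length(hits) > 0L) return(list(min_events = k, sets = hits))
  }
  list(min_events = NA_integer_, sets = list())
}

# naive shared-position enumeration over all (column, phase, group pair)
oracle_shared <- function(entries, grouping) {
  groups <- sort(unique(unname(grouping)))
  entries$group <- unname(grouping[sub("^.*\\|", "", entries$sequence_id)])
  na <- is.na(entries$group)
  entries$group[na] <- unname(grouping[entries$sequence_id[na]])
  keys <- unique(entries[, c("column", "phase")])
  diag_counts <- setNames(rep(0L, length(groups)), groups)
  shared <- matrix(0L, length(groups), length(groups),
                   dimnames = list(groups, groups))
  for (r in seq_len(nrow(keys))) {
    gs <- character(0)
    for (g in groups) {
      any_carrier <- any(entries$column == keys$column[r] &
                         entries$phase == keys$phase[r] &
                         entries$group == g)
      if (any_carrier) gs <- c(gs, g)
    }
    if (length(gs) == 1L) diag_counts[gs] <- diag_counts[gs] + 1L
    if (length(gs) >= 2L) {
      for (i in seq_len(length(gs) - 1L)) for (j in (i + 1L):length(gs)) {
        shared[gs[i], gs[j]] <- shared[gs[i], gs[j]] + 1L
        shared[gs[j], gs[i]] <- shared[gs[j], gs[i]] + 1L
      }
    }
  }
  list(diagonal = diag_counts, shared = shared, total = nrow(keys))
}

# random rooted multifurcating tree with unit branch lengths
random_multi_tree <- function(n, p_collapse = 0.4) {
  t <- ape::rtree(n, rooted = TRUE)
  t$edge.length <- rep(1, nrow(t$edge))
  ntip <- length(t$tip.label)
  internal <- which(t$edge[, 2] > ntip)
  drop <- internal[runif(length(internal)) < p_collapse]
  if (length(drop) > 0) {
    t$edge.length[drop] <- 0
    t <- ape::di2multi(t, tol = 1e-6)
  }
  t$edge.length <- rep(1, nrow(t$edge))
  t$node.label <- NULL
  introntrace::species_tree(t)
}

# a fixed panel of small rooted topologies (2-4 leaves, incl multifurcations)
small_tree_panel <- function() {
  lapply(c("(A,B);", "((A,B),C);", "(A,B,C);",
           "((A,B),(C,D));", "(((A,B),C),D);", "((A,B,C),D);",
           "(A,B,C,D);", "((A,B),C,D);"),
         introntrace::species_tree)
}

# all 3^n M/N/U assignments for the tips of a tree
all_state_assignments <- function(tree) {
  tips <- tree$tip.label
  grid <- expand.grid(rep(list(c("M", "N", "U")), length(tips)),
                      stringsAsFactors = FALSE)
  lapply(seq_len(nrow(grid)),
         function(i) setNames(unlist(grid[i, ], use.names = FALSE), tips))
}
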