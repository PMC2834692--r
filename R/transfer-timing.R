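# Dollo parsimony placement of irreversible mitochondrion-to-nucleus transfer
# events on a rooted species tree. The ancestral (root) state is M
# (mitochondrial-encoded); a transfer on a branch turns every leaf below it N.
# A virtual root-stem branch (named after the root node) is a legal location,
# so a gene nuclear in every sampled species is one ancestral event.

#' Prepare a rooted species tree
#'
#' Accepts a newick string, a file path, or an `ape::phylo` object;
#' multifurcations are allowed. Internal nodes without labels get
#' deterministic labels `node<k>`.
#'
#' @param tree Newick string, path to a newick file, or `phylo`.
#' @return A `phylo` with unique tip and node labels.
#' @export
species_tree <- function(tree) {
  if (is.character(tree)) {
    tree <- if (grepl(";", tree)) ape::read.tree(text = tree) else ape::read.tree(tree)
  }
  if (!inherits(tree, "phylo")) {
    .intron_stop("tree must be a newick string/file or an ape phylo object",
                 "introntrace_tree_error")
  }
  if (anyDuplicated(tree$tip.label)) {
    .intron_stop("species tree tip labels must be unique", "introntrace_tree_error")
  }
  n_int <- tree$Nnode
  lab <- tree$node.label
  if (is.null(lab)) lab <- rep("", n_int)
  empty <- is.na(lab) | lab == ""
  lab[empty] <- paste0("node", which(empty))
  tree$node.label <- make.unique(lab)
  tree
}

.node_labels <- function(tree) c(tree$tip.label, tree$node.label)

.parents <- function(tree) {
  n <- length(tree$tip.label) + tree$Nnode
  p <- rep.int(NA_integer_, n)
  p[tree$edge[, 2L]] <- tree$edge[, 1L]
  p
}

.node_depths <- function(tree) {
  par <- .parents(tree)
  root <- length(tree$tip.label) + 1L
  n <- length(par)
  d <- rep.int(NA_integer_, n)
  d[root] <- 0L
  # edges in ape are not guaranteed topologically sorted; iterate to fixpoint
  repeat {
    todo <- which(is.na(d) & !is.na(d[par]))
    if (length(todo) == 0L) break
    d[todo] <- d[par[todo]] + 1L
  }
  d
}

# logical matrix [node, tip]: tip is a descendant-or-self of node
.descendant_tips <- function(tree) {
  ntip <- length(tree$tip.label)
  n <- ntip + tree$Nnode
  par <- .parents(tree)
  m <- matrix(FALSE, n, ntip)
  for (t in seq_len(ntip)) {
    v <- t
    while (!is.na(v)) { m[v, t] <- TRUE; v <- par[v] }
  }
  m
}

.resolve_states <- function(tree, states) {
  tips <- tree$tip.label
  if (is.null(names(states))) {
    .intron_stop("localization states must be a named vector", "introntrace_state_error")
  }
  bad <- setdiff(unique(states), c("M", "N", "U"))
  if (length(bad) > 0L) {
    .intron_stop(sprintf("unknown localization state(s): %s",
                         paste(bad, collapse = ", ")), "introntrace_state_error")
  }
  dup <- names(states)[duplicated(names(states))]
  for (s in unique(dup)) {
    if (length(unique(states[names(states) == s])) > 1L) {
      .intron_stop(sprintf("species '%s' marked with conflicting states", s),
                   "introntrace_state_error")
    }
  }
  states <- states[!duplicated(names(states))]
  unmapped <- setdiff(names(states), tips)
  st <- setNames(rep("U", length(tips)), tips)
  known <- intersect(names(states), tips)
  st[known] <- states[known]
  list(states = st, unmapped = unmapped)
}

#' Infer mitochondrion-to-nucleus transfer events by Dollo parsimony
#'
#' Finds the minimal set of branches such that every N (nuclear-encoded) leaf
#' has exactly one transfer on its root path and every M (mitochondrial) leaf
#' has none; U (unknown/absent) leaves are unconstrained. Transfers are
#' irreversible and the root state is M. The canonical scenario places each
#' event on the most rootward branch consistent with minimality; when deeper
#' equally parsimonious placements exist (U-only subtrees, multifurcations),
#' `resolved` is `FALSE` and all alternative branch sets are enumerated.
#'
#' @param tree A [species_tree()] (newick string, path or `phylo`).
#' @param states Named character vector, species -> `"M"`/`"N"`/`"U"`.
#' @param gene_id Identifier carried through to the result.
#' @return A `transfer_scenario`: `transfer_branches` (branch = label of the
#'   node below it; the root label denotes the root-stem branch), `n_events`,
#'   `resolved`, `alternatives` (list of equally parsimonious branch sets,
#'   including the canonical one), `event_depths`, `unmapped_species`.
#' @export
infer_transfers <- function(tree, states, gene_id = NA_character_) {
  tree <- species_tree(tree)
  rs <- .resolve_states(tree, states)
  st <- rs$states
  if (all(st == "U")) {
    .intron_stop("no informative leaf: all states are U",
                 "introntrace_degenerate_error")
  }
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  labels <- .node_labels(tree)
  desc <- .descendant_tips(tree)
  isN <- st == "N"
  isM <- st == "M"
  nN <- as.integer(desc %*% isN)
  nM <- as.integer(desc %*% isM)
  legal <- nM == 0L & nN > 0L
  par <- .parents(tree)
  is_event <- legal & (seq_along(legal) == root | !legal[par])
  is_event[is.na(is_event)] <- legal[is.na(par)] & seq_along(legal) == root
  events <- which(is_event)
  depths <- .node_depths(tree)
  alt_paths <- lapply(events, function(v) {
    ntips_below <- which(desc[v, ])
    n_below <- ntips_below[isN[ntips_below]]
    lca <- if (length(n_below) == 1L) n_below else ape::getMRCA(tree, n_below)
    path <- lca
    while (path[length(path)] != v) path <- c(path, par[path[length(path)]])
    rev(path)          # rootward first
  })
  n_alt <- prod(lengths(alt_paths))
  alternatives <- list()
  truncated <- FALSE
  if (length(events) == 0L) {
    alternatives <- list(character(0))
  } else if (n_alt <= 10000) {
    grid <- expand.grid(alt_paths, KEEP.OUT.ATTRS = FALSE)
    alternatives <- lapply(seq_len(nrow(grid)), function(i)
      sort(labels[unlist(grid[i, ], use.names = FALSE)]))
  } else {
    truncated <- TRUE
    alternatives <- list(sort(labels[events]))
  }
  structure(list(
    gene_id = gene_id,
    transfer_branches = sort(labels[events]),
    event_nodes = events,
    n_events = length(events),
    resolved = all(vapply(alt_paths, length, integer(1)) == 1L),
    alternatives = alternatives,
    alternatives_truncated = truncated,
    event_depths = setNames(depths[events], labels[events]),
    event_lineages = setNames(
      vapply(events, function(v)
        paste(tree$tip.label[which(desc[v, seq_len(ntip)])], collapse = ","),
        character(1)),
      labels[events]),
    unmapped_species = rs$unmapped,
    tree_labels = labels
  ), class = "transfer_scenario")
}

#' @export
print.transfer_scenario <- function(x, ...) {
  cat(sprintf("<transfer_scenario> %s: %d event(s)%s on %s\n",
              x$gene_id, x$n_events,
              if (x$resolved) "" else " (unresolved)",
              paste(x$transfer_branches, collapse = ", ")))
  invisible(x)
}

#' Genes transferred independently more than once
#'
#' @param scenarios List of [infer_transfers()] results on a common tree.
#' @return Data frame (gene_id, n_events, resolved, transfers) restricted to
#'   genes with `n_events >= 2`; `transfers` lists, per event, the species
#'   below the transfer branch (semicolon-separated between events).
#' @export
find_independent_transfers <- function(scenarios) {
  rows <- lapply(scenarios, function(s) {
    if (s$n_events < 2L) return(NULL)
    data.frame(gene_id = s$gene_id, n_events = s$n_events,
               resolved = s$resolved,
               transfers = paste(unname(s$event_lineages), collapse = " ; "))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    return(data.frame(gene_id = character(0), n_events = integer(0),
                      resolved = logical(0), transfers = character(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$gene_id), , drop = FALSE]
}

#' Relative timing of transfer events
#'
#' Events are partially ordered by ancestor-descendant relations of their
#' branches (canonical scenario): a transfer on a branch ancestral to another
#' is relatively more ancient; events on incomparable branches are unordered.
#' Given a focal species, genes with an event on that species' root path are
#' binned into relative age classes by branch depth (depth 0 = root stem =
#' most ancient).
#'
#' @param scenarios List of `transfer_scenario` objects.
#' @param tree The common [species_tree()].
#' @param focal_species Optional tip label.
#' @return List with `pairs` (pairwise relations `more_ancient` /
#'   `more_recent` / `same_branch` / `incomparable` between events of
#'   different genes) and, when `focal_species` is given, `focal_classes`
#'   (gene_id, branch, depth, rank; rank 1 = most ancient).
#' @export
rank_transfer_times <- function(scenarios, tree, focal_species = NULL) {
  tree <- species_tree(tree)
  labels <- .node_labels(tree)
  par <- .parents(tree)
  depths <- .node_depths(tree)
  anc_of <- function(v) { # ancestors-or-self
    out <- v
    while (!is.na(par[out[length(out)]])) out <- c(out, par[out[length(out)]])
    out
  }
  ev <- do.call(rbind, lapply(scenarios, function(s) {
    if (s$n_events == 0L) return(NULL)
    data.frame(gene_id = s$gene_id, node = s$event_nodes,
               branch = labels[s$event_nodes], depth = depths[s$event_nodes])
  }))
  if (is.null(ev)) {
    ev <- data.frame(gene_id = character(0), node = integer(0),
                     branch = character(0), depth = integer(0))
  }
  pairs <- data.frame(gene_a = character(0), branch_a = character(0),
                      gene_b = character(0), branch_b = character(0),
                      relation = character(0))
  if (nrow(ev) > 1L) {
    anc_sets <- lapply(ev$node, anc_of)
    idx <- combn(nrow(ev), 2L)
    rel <- vapply(seq_len(ncol(idx)), function(j) {
      a <- idx[1L, j]; b <- idx[2L, j]
      if (ev$node[a] == ev$node[b]) "same_branch"
      else if (ev$node[a] %in% anc_sets[[b]]) "more_ancient"
      else if (ev$node[b] %in% anc_sets[[a]]) "more_recent"
      else "incomparable"
    }, character(1))
    pairs <- data.frame(gene_a = ev$gene_id[idx[1L, ]],
                        branch_a = ev$branch[idx[1L, ]],
                        gene_b = ev$gene_id[idx[2L, ]],
                        branch_b = ev$branch[idx[2L, ]],
                        relation = rel)
  }
  out <- list(pairs = pairs, events = ev)
  if (!is.null(focal_species)) {
    tip <- match(focal_species, tree$tip.label)
    if (is.na(tip)) {
      .intron_stop(sprintf("focal species '%s' not in tree", focal_species),
                   "introntrace_tree_error")
    }
    path <- anc_of(tip)
    on_path <- ev[ev$node %in% path, , drop = FALSE]
    if (nrow(on_path) > 0L) {
      on_path <- on_path[order(on_path$depth, on_path$gene_id), , drop = FALSE]
      on_path$rank <- match(on_path$depth, sort(unique(on_path$depth)))
      rownames(on_path) <- NULL
    }
    out$focal_classes <- on_path
  }
  out
}
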