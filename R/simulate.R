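# Synthetic gene families with known evolutionary history: a rooted species
# tree, irreversible mitochondrion-to-nucleus transfer events, post-transfer
# intron gain/loss with phase preference or proto-splice targeting, and
# compartment-specific codon usage. Ground truth for every pipeline stage.

#' Default 12-leaf species tree preset
#'
#' Four animals, three fungi, three plants/green alga and two protists, with
#' unikonts (animals + fungi) sister to neither plants nor protists: the root
#' is a trifurcation, so multifurcation handling is exercised by default.
#' All branch lengths are 1.
#'
#' @return Newick string.
#' @export
default_tree <- function() {
  paste0("((((hsa:1,dre:1)anc_vert:1,(dme:1,cel:1)anc_inv:1)animals:1,",
         "(sce:1,(spo:1,afu:1)anc_asc:1)fungi:1)unikonts:1,",
         "((ath:1,osa:1)anc_plant:1,cre:1)plants:1,",
         "(ddi:1,pfa:1)protists:1)root;")
}

#' Default species-to-group assignment for the preset tree
#'
#' @return Named character vector, species -> taxonomic group.
#' @export
default_groups <- function() {
  c(hsa = "animals", dre = "animals", dme = "animals", cel = "animals",
    sce = "fungi", spo = "fungi", afu = "fungi",
    ath = "plants", osa = "plants", cre = "plants",
    ddi = "protists", pfa = "protists")
}

#' Default compartment-specific codon usage
#'
#' Synonymous codons are uniform within each amino acid except glutamine,
#' which carries the compartment contrast observed between mitochondrial and
#' nuclear genes: nuclear Gln is 90% CAG, mitochondrial Gln 90% CAA.
#'
#' @return List with `nuclear` and `mitochondrial`, each a list mapping
#'   one-letter amino acids to named codon-probability vectors.
#' @export
default_codon_usage <- function() {
  gc <- genetic_code("1")
  aas <- setdiff(unique(gc), "*")
  base <- lapply(setNames(aas, aas), function(a) {
    cods <- names(gc)[gc == a]
    setNames(rep(1 / length(cods), length(cods)), cods)
  })
  nuc <- base; mit <- base
  nuc[["Q"]] <- c(CAA = 0.1, CAG = 0.9)
  mit[["Q"]] <- c(CAA = 0.9, CAG = 0.1)
  list(nuclear = nuc, mitochondrial = mit)
}

#' Simulation configuration
#'
#' Encodes the stated world of the synthetic study: genes start
#' mitochondrial-encoded and intron-less; a transfer event on a branch makes
#' the lineage nuclear, adapts codon usage, and opens the gene to intron gain.
#'
#' @param seed Mandatory integer seed.
#' @param tree Newick string / file / `phylo` (default [default_tree()]);
#'   missing branch lengths are set to 1.
#' @param n_genes Number of gene families (default 20).
#' @param protein_length Integer range for root protein length in residues
#'   (default 200-400).
#' @param transfers `"sample"` (default: 1-3 minimal events per gene with
#'   weights 0.5/0.3/0.2) or a list of branch-label character vectors, one
#'   per gene.
#' @param gain_rate Intron gains per kb coding sequence per unit branch
#'   length (default 2).
#' @param loss_rate Intron loss rate per unit branch length (default 0.1).
#' @param phase_weights Relative weights of phases 0,1,2 for new introns in
#'   uniform-site mode (default 5:3:2).
#' @param site_model `"uniform"` (anchor codon uniform, phase from weights)
#'   or `"proto_splice_targeted"` (sites from [scan_proto_splice_sites()],
#'   phase implied by the site).
#' @param intron_length Integer range of intron lengths in nt (default
#'   60-500); a minimum of 20 or less is a configuration error because it
#'   would plant introns the length filter must reject.
#' @param substitution_rate Amino-acid substitution probability per residue
#'   per unit branch length (default 0.02).
#' @param codon_usage Compartment codon-usage tables
#'   (default [default_codon_usage()]).
#' @param indel_mode `"none"` (default; the true alignment is positional) or
#'   `"simple"` (codon-level insertions/deletions with tracked homology).
#' @param indel_rate Insertion and deletion probability per codon per unit
#'   branch length in simple mode (default 0.002).
#' @param min_intron_spacing Minimum distance in nt between intron sites and
#'   from the cds ends (default 30), keeping every exon long enough to seed
#'   the spliced aligner.
#' @param stem_length Branch length of the virtual root stem (default 1),
#'   used when a transfer is placed at the root.
#' @param u_prob Probability that a leaf's localization is reported `U`
#'   (default 0).
#' @param groups Named species -> group vector (default [default_groups()]
#'   for the preset tree, else one group per species).
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(seed,
                       tree = default_tree(),
                       n_genes = 20L,
                       protein_length = c(200L, 400L),
                       transfers = "sample",
                       gain_rate = 2,
                       loss_rate = 0.1,
                       phase_weights = c(5, 3, 2),
                       site_model = c("uniform", "proto_splice_targeted"),
                       intron_length = c(60L, 500L),
                       substitution_rate = 0.02,
                       codon_usage = default_codon_usage(),
                       indel_mode = c("none", "simple"),
                       indel_rate = 0.002,
                       min_intron_spacing = 30L,
                       stem_length = 1,
                       u_prob = 0,
                       groups = NULL) {
  if (missing(seed) || is.null(seed) || is.na(seed)) {
    .intron_stop("a seed is mandatory for every simulation run",
                 "introntrace_config_error")
  }
  site_model <- match.arg(site_model)
  indel_mode <- match.arg(indel_mode)
  if (intron_length[1L] <= 20L) {
    .intron_stop("configured minimum intron length must exceed 20 nt",
                 "introntrace_config_error")
  }
  if (gain_rate < 0 || loss_rate < 0 || substitution_rate < 0 ||
      indel_rate < 0 || u_prob < 0 || u_prob > 1) {
    .intron_stop("rates must be non-negative (u_prob in [0,1])",
                 "introntrace_config_error")
  }
  if (any(phase_weights <= 0) || length(phase_weights) != 3L) {
    .intron_stop("phase_weights must be three positive numbers",
                 "introntrace_config_error")
  }
  phy <- species_tree(tree)
  if (is.null(phy$edge.length)) phy$edge.length <- rep(1, nrow(phy$edge))
  if (is.null(groups)) {
    groups <- if (setequal(phy$tip.label, names(default_groups())))
      default_groups() else setNames(phy$tip.label, phy$tip.label)
  }
  structure(list(seed = as.integer(seed), tree = phy,
                 n_genes = as.integer(n_genes),
                 protein_length = as.integer(protein_length),
                 transfers = transfers, gain_rate = gain_rate,
                 loss_rate = loss_rate,
                 phase_weights = phase_weights / sum(phase_weights),
                 site_model = site_model,
                 intron_length = as.integer(intron_length),
                 substitution_rate = substitution_rate,
                 codon_usage = codon_usage, indel_mode = indel_mode,
                 indel_rate = indel_rate,
                 min_intron_spacing = as.integer(min_intron_spacing),
                 stem_length = stem_length, u_prob = u_prob,
                 groups = groups),
            class = "sim_config")
}

.sample_codon <- function(aa, usage) {
  tab <- usage[[aa]]
  if (length(tab) == 1L) return(names(tab))
  sample(names(tab), 1L, prob = tab)
}

.sample_protein_codons <- function(n, usage) {
  aas <- sample(names(usage), n, replace = TRUE)
  vapply(aas, .sample_codon, character(1), usage = usage)
}

# Intron sequence: GT + interior + AG. The interior is resampled until the
# donor GT is the only GT in the first 15 nt and the acceptor AG the only AG
# in the last 15 nt, so the boundary-rescue shift window of the aligner
# cannot find a competing canonical placement inside the intron.
.make_intron_seq <- function(len) {
  stopifnot(len >= 24L)
  repeat {
    interior <- paste(sample(c("A", "C", "G", "T"), len - 4L, replace = TRUE),
                      collapse = "")
    s <- paste0("GT", interior, "AG")
    head15 <- substr(s, 2L, 16L)
    tail15 <- substr(s, len - 15L, len - 1L)
    if (!grepl("GT", head15, fixed = TRUE) &&
        !grepl("AG", tail15, fixed = TRUE)) return(s)
  }
}

# current cds offset of each intron given the codon keys it anchors to
.intron_offsets <- function(introns, keys) {
  if (nrow(introns) == 0L) return(integer(0))
  idx <- match(introns$key, keys)
  3L * (idx - 1L) + introns$phase
}

.empty_sim_introns <- function() {
  data.frame(event_id = integer(0), key = numeric(0), phase = integer(0),
             length = integer(0), seq = character(0))
}

# One branch of intron gain/loss on a (codons, keys, introns) state.
# Returns the updated introns plus a log of gain events.
.gain_loss_branch <- function(codons, keys, introns, t, config, counter) {
  events <- data.frame(event_id = integer(0), cds_offset = integer(0),
                       phase = integer(0), length = integer(0))
  # losses
  if (nrow(introns) > 0L && config$loss_rate > 0 && t > 0) {
    lost <- rbinom(nrow(introns), 1L, 1 - exp(-config$loss_rate * t)) == 1L
    introns <- introns[!lost, , drop = FALSE]
  }
  # gains
  cds_len <- 3L * length(codons)
  lambda <- config$gain_rate * (cds_len / 1000) * t
  n_gain <- if (lambda > 0) rpois(1L, lambda) else 0L
  if (n_gain > 0L) {
    sp <- config$min_intron_spacing
    for (g in seq_len(n_gain)) {
      offsets <- .intron_offsets(introns, keys)
      o <- NA_integer_
      if (config$site_model == "uniform") {
        for (try in seq_len(50L)) {
          ph <- sample(0:2, 1L, prob = config$phase_weights)
          ci <- sample.int(length(codons), 1L)
          cand <- 3L * (ci - 1L) + ph
          if (cand >= max(3L, sp) && cand <= cds_len - max(1L, sp) &&
              (length(offsets) == 0L || min(abs(offsets - cand)) >= max(1L, sp)) &&
              !cand %in% offsets) { o <- cand; break }
        }
      } else {
        cds <- paste(codons, collapse = "")
        sites <- scan_proto_splice_sites(cds)
        sites <- sites[sites >= max(3L, sp) & sites <= cds_len - max(1L, sp)]
        if (length(offsets) > 0L && sp > 0L) {
          sites <- sites[vapply(sites, function(s)
            min(abs(offsets - s)) >= sp, logical(1))]
        }
        sites <- setdiff(sites, offsets)
        if (length(sites) > 0L) o <- sites[sample.int(length(sites), 1L)]
      }
      if (is.na(o)) next
      counter$id <- counter$id + 1L
      len <- sample(seq.int(config$intron_length[1L], config$intron_length[2L]), 1L)
      introns <- rbind(introns, data.frame(
        event_id = counter$id, key = keys[o %/% 3L + 1L], phase = o %% 3L,
        length = len, seq = .make_intron_seq(len)))
      events <- rbind(events, data.frame(
        event_id = counter$id, cds_offset = o, phase = o %% 3L, length = len))
    }
  }
  list(introns = introns, events = events)
}

#' Evolve introns along one branch
#'
#' Gain count is Poisson with mean `gain_rate * cds_len/1000 * branch_length`;
#' sites are uniform over legal anchor codons with phase drawn from
#' `phase_weights` (uniform mode) or drawn from the proto-splice sites of the
#' current cds (targeted mode, phase implied by the site). Each existing
#' intron is lost with probability `1 - exp(-loss_rate * branch_length)`.
#' Uses the current RNG state; seed the session for reproducibility.
#'
#' @param cds In-frame coding sequence of the gene.
#' @param branch_length Branch length.
#' @param config A [sim_config()].
#' @param introns Existing introns as a data frame with columns `cds_offset`,
#'   `phase`, `length` (and optionally `event_id`, `seq`).
#' @return List with `introns` (data frame `event_id`, `cds_offset`, `phase`,
#'   `length`, `seq`, ordered by offset) and `events` (gains on this branch).
#' @export
evolve_introns <- function(cds, branch_length, config,
                           introns = NULL) {
  .validate_dna(cds, "cds")
  n <- nchar(cds)
  if (n %% 3L != 0L) {
    .intron_stop("cds length must be divisible by 3", "introntrace_frame_error")
  }
  codons <- substring(cds, seq.int(1L, n - 2L, 3L), seq.int(3L, n, 3L))
  keys <- as.numeric(seq_along(codons))
  sim_introns <- .empty_sim_introns()
  if (!is.null(introns) && nrow(introns) > 0L) {
    sim_introns <- data.frame(
      event_id = if ("event_id" %in% names(introns)) introns$event_id else
        -seq_len(nrow(introns)),
      key = as.numeric(introns$cds_offset %/% 3L + 1L),
      phase = introns$cds_offset %% 3L,
      length = introns$length,
      seq = if ("seq" %in% names(introns)) introns$seq else
        vapply(introns$length, .make_intron_seq, character(1)))
  }
  counter <- new.env(parent = emptyenv()); counter$id <- 0L
  res <- .gain_loss_branch(codons, keys, sim_introns, branch_length, config,
                           counter)
  out <- res$introns
  out$cds_offset <- .intron_offsets(out, keys)
  out <- out[order(out$cds_offset),
             c("event_id", "cds_offset", "phase", "length", "seq")]
  rownames(out) <- NULL
  list(introns = out, events = res$events)
}

#' Insert introns into a coding sequence
#'
#' Builds the genomic locus by inserting each intron (GT + interior + AG) at
#' its cds offset. Splicing the result with the true structure reproduces the
#' cds exactly.
#'
#' @param cds In-frame coding sequence.
#' @param introns Data frame with `cds_offset`, `phase`, `length` and
#'   optionally `seq` (generated when absent); lengths of 20 nt or less are a
#'   configuration error.
#' @return List with `locus` (DNA string) and `introns` (the input plus
#'   `g_start`, `g_end`, `donor`, `acceptor`, `intron_length`, ordered by
#'   offset).
#' @export
emit_genomic <- function(cds, introns) {
  .validate_dna(cds, "cds")
  if (is.null(introns) || nrow(introns) == 0L) {
    return(list(locus = cds,
                introns = cbind(.empty_introns())))
  }
  if (any(introns$length <= 20L)) {
    .intron_stop("intron lengths must exceed 20 nt by construction",
                 "introntrace_config_error")
  }
  introns <- introns[order(introns$cds_offset), , drop = FALSE]
  if (!"seq" %in% names(introns) || anyNA(introns$seq)) {
    introns$seq <- vapply(introns$length, .make_intron_seq, character(1))
  }
  pieces <- character(0)
  pos <- 0L
  g_start <- integer(nrow(introns))
  cum <- 0L
  for (i in seq_len(nrow(introns))) {
    o <- introns$cds_offset[i]
    pieces <- c(pieces, substr(cds, pos + 1L, o), introns$seq[i])
    g_start[i] <- o + cum
    cum <- cum + introns$length[i]
    pos <- o
  }
  pieces <- c(pieces, substr(cds, pos + 1L, nchar(cds)))
  locus <- paste(pieces, collapse = "")
  out <- data.frame(cds_offset = introns$cds_offset, phase = introns$phase,
                    anchor_residue = introns$cds_offset %/% 3L + 1L,
                    g_start = g_start, g_end = g_start + introns$length,
                    intron_length = introns$length,
                    donor = substr(introns$seq, 1L, 2L),
                    acceptor = substring(introns$seq, introns$length - 1L))
  if ("event_id" %in% names(introns)) out$event_id <- introns$event_id
  list(locus = locus, introns = out)
}

# --- transfer-history sampling -------------------------------------------

.ancestor_sets <- function(tree) {
  par <- .parents(tree)
  lapply(seq_along(par), function(v) {
    out <- v
    while (!is.na(par[out[length(out)]])) out <- c(out, par[out[length(out)]])
    out
  })
}

# sample k pairwise-incomparable transfer nodes whose induced leaf states are
# recovered exactly by parsimony (a minimal planted history)
.sample_transfer_nodes <- function(tree, k, max_tries = 200L) {
  n <- length(tree$tip.label) + tree$Nnode
  anc <- .ancestor_sets(tree)
  labels <- .node_labels(tree)
  desc <- .descendant_tips(tree)
  for (try in seq_len(max_tries)) {
    nodes <- sort(sample.int(n, k))
    incomparable <- TRUE
    if (k > 1L) {
      for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
        if (nodes[i] %in% anc[[nodes[j]]] || nodes[j] %in% anc[[nodes[i]]]) {
          incomparable <- FALSE
        }
      }
    }
    if (!incomparable) next
    states <- setNames(rep("M", length(tree$tip.label)), tree$tip.label)
    for (v in nodes) states[desc[v, ]] <- "N"
    if (all(states == "N") && k > 1L) next
    sc <- infer_transfers(tree, states)
    if (sc$n_events == k && setequal(sc$transfer_branches, labels[nodes])) {
      return(nodes)
    }
  }
  .intron_stop(sprintf("could not sample a minimal %d-event history", k),
               "introntrace_config_error")
}

# --- whole-family simulation ---------------------------------------------

.substitute_codons <- function(codons, t, config, usage, protected = numeric(0),
                               keys = NULL) {
  if (config$substitution_rate <= 0 || t <= 0) return(codons)
  p <- 1 - exp(-config$substitution_rate * t)
  hit <- which(runif(length(codons)) < p)
  if (!is.null(keys) && length(protected) > 0L) {
    hit <- hit[!keys[hit] %in% protected]
  }
  if (length(hit) == 0L) return(codons)
  gc <- genetic_code("1")
  aas <- names(usage)
  for (i in hit) {
    old_aa <- unname(gc[codons[i]])
    new_aa <- sample(setdiff(aas, old_aa), 1L)
    codons[i] <- .sample_codon(new_aa, usage)
  }
  codons
}

.apply_indels <- function(state, t, config, usage, key_counter) {
  if (config$indel_mode != "simple" || config$indel_rate <= 0 || t <= 0) {
    return(state)
  }
  p <- 1 - exp(-config$indel_rate * t)
  n <- length(state$codons)
  # deletions (never delete the last codon standing)
  del <- which(runif(n) < p)
  if (length(del) >= n) del <- del[-1L]
  if (length(del) > 0L) {
    dropped_keys <- state$keys[del]
    state$codons <- state$codons[-del]
    state$keys <- state$keys[-del]
    state$introns <- state$introns[!state$introns$key %in% dropped_keys, ,
                                   drop = FALSE]
  }
  # insertions: one codon after each hit position
  n <- length(state$codons)
  ins <- which(runif(n) < p)
  if (length(ins) > 0L) {
    for (i in rev(ins)) {
      key_counter$k <- key_counter$k + 1L
      left <- state$keys[i]
      right <- if (i < length(state$keys)) state$keys[i + 1L] else left + 2
      new_key <- (left + right) / 2
      aa <- sample(names(usage), 1L)
      state$codons <- append(state$codons, .sample_codon(aa, usage), after = i)
      state$keys <- append(state$keys, new_key, after = i)
    }
  }
  state
}

.resample_synonymous <- function(codons, usage) {
  gc <- genetic_code("1")
  vapply(unname(gc[codons]), .sample_codon, character(1), usage = usage)
}

#' Simulate one gene family on the species tree
#'
#' The root coding sequence is sampled from the mitochondrial codon usage;
#' sequences evolve down the tree by amino-acid substitution. On the branch
#' carrying that gene's transfer event the lineage turns nuclear, synonymous
#' codons are resampled from nuclear usage, and intron gain/loss starts;
#' mitochondrial lineages stay intron-free. Uses the current RNG state.
#'
#' @param config A [sim_config()].
#' @param gene_id Gene identifier.
#' @param transfer_nodes Optional explicit transfer branch labels; when
#'   `NULL`, sampled per `config$transfers`.
#' @return A `sim_family` list: `gene_id`, `transfer_branches`, `structures`
#'   (per species [gene_structure()]), `loci`, `cds`, `alignment`
#'   ([protein_alignment()] of the true homology), `events` (gain log with
#'   branch labels), `intron_records` (per extant intron: species, column,
#'   phase, cds_offset, event_id), `localization` (species/state data frame).
#' @export
simulate_family <- function(config, gene_id = "g1", transfer_nodes = NULL) {
  tree <- config$tree
  labels <- .node_labels(tree)
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  if (is.null(transfer_nodes)) {
    if (is.list(config$transfers)) {
      tn <- config$transfers[[gene_id]]
      if (is.null(tn)) {
        .intron_stop(sprintf("no explicit transfer branches for gene '%s'",
                             gene_id), "introntrace_config_error")
      }
      transfer_nodes <- match(tn, labels)
      if (anyNA(transfer_nodes)) {
        .intron_stop("unknown transfer branch label", "introntrace_config_error")
      }
    } else {
      k <- sample(1:3, 1L, prob = c(0.5, 0.3, 0.2))
      transfer_nodes <- .sample_transfer_nodes(tree, k)
    }
  }
  usage <- config$codon_usage
  n_aa <- if (config$protein_length[1L] == config$protein_length[2L])
    config$protein_length[1L] else
    sample(seq.int(config$protein_length[1L], config$protein_length[2L]), 1L)
  root_codons <- .sample_protein_codons(n_aa, usage$mitochondrial)
  counter <- new.env(parent = emptyenv()); counter$id <- 0L
  key_counter <- new.env(parent = emptyenv()); key_counter$k <- 0L
  events_log <- data.frame(event_id = integer(0), branch = character(0),
                           cds_offset = integer(0), phase = integer(0),
                           length = integer(0))
  event_key <- new.env(parent = emptyenv())   # event_id -> anchor key/phase

  children_of <- split(tree$edge[, 2L], tree$edge[, 1L])
  edge_len <- setNames(tree$edge.length, tree$edge[, 2L])

  leaf_states <- vector("list", ntip)

  evolve_node <- function(v, state) {
    if (v %in% transfer_nodes && state$compartment == "mitochondrial") {
      state$compartment <- "nuclear"
      state$codons <- .resample_synonymous(state$codons, usage$nuclear)
    }
    t <- if (v == root) {
      if (root %in% transfer_nodes) config$stem_length else 0
    } else unname(edge_len[as.character(v)])
    if (t > 0) {
      cu <- usage[[state$compartment]]
      state$codons <- .substitute_codons(state$codons, t, config, cu,
                                         keys = state$keys)
      state <- .apply_indels(state, t, config, cu, key_counter)
      if (state$compartment == "nuclear") {
        res <- .gain_loss_branch(state$codons, state$keys, state$introns, t,
                                 config, counter)
        state$introns <- res$introns
        if (nrow(res$events) > 0L) {
          for (j in seq_len(nrow(res$events))) {
            eid <- res$events$event_id[j]
            event_key[[as.character(eid)]] <- list(
              key = state$introns$key[state$introns$event_id == eid],
              phase = res$events$phase[j])
          }
          events_log <<- rbind(events_log, cbind(
            res$events[, c("event_id", "cds_offset", "phase", "length")],
            branch = labels[v])[, c("event_id", "branch", "cds_offset",
                                    "phase", "length")])
        }
      }
    }
    if (v <= ntip) {
      leaf_states[[v]] <<- state
    } else {
      for (ch in children_of[[as.character(v)]]) evolve_node(ch, state)
    }
  }

  init <- list(codons = root_codons, keys = as.numeric(seq_len(n_aa)),
               introns = .empty_sim_introns(), compartment = "mitochondrial")
  evolve_node(root, init)

  # assemble leaf outputs
  all_keys <- sort(unique(unlist(lapply(leaf_states, `[[`, "keys"))))
  structures <- list(); loci <- list(); cds_out <- character(0)
  rows <- character(0)
  intron_records <- data.frame(species_id = character(0), column = integer(0),
                               phase = integer(0), cds_offset = integer(0),
                               event_id = integer(0))
  loc <- data.frame(gene_id = character(0), species_id = character(0),
                    state = character(0))
  for (tip in seq_len(ntip)) {
    sp <- tree$tip.label[tip]
    st <- leaf_states[[tip]]
    cds <- paste(st$codons, collapse = "")
    protein <- translate_cds(cds)
    intr <- st$introns
    if (st$compartment == "mitochondrial") stopifnot(nrow(intr) == 0L)
    offs <- .intron_offsets(intr, st$keys)
    ord <- order(offs)
    intr <- intr[ord, , drop = FALSE]; offs <- offs[ord]
    emit_df <- data.frame(cds_offset = offs, phase = intr$phase,
                          length = intr$length, seq = intr$seq,
                          event_id = intr$event_id)
    em <- emit_genomic(cds, emit_df)
    gs_introns <- em$introns[, c("cds_offset", "phase", "anchor_residue",
                                 "g_start", "g_end", "intron_length",
                                 "donor", "acceptor"), drop = FALSE]
    structures[[sp]] <- gene_structure(gene_id, sp, protein,
                                       introns = gs_introns,
                                       compartment = st$compartment)
    loci[[sp]] <- genomic_locus(paste(gene_id, sp, sep = "|"), em$locus, sp)
    cds_out[sp] <- cds
    # gapped alignment row from homology keys
    aa <- strsplit(protein, "")[[1]]
    row <- rep("-", length(all_keys))
    row[match(st$keys, all_keys)] <- aa
    rows[paste(gene_id, sp, sep = "|")] <- paste(row, collapse = "")
    if (nrow(intr) > 0L) {
      cols <- match(intr$key, all_keys)
      intron_records <- rbind(intron_records, data.frame(
        species_id = sp, column = cols, phase = intr$phase,
        cds_offset = offs, event_id = intr$event_id))
    }
    state <- if (st$compartment == "nuclear") "N" else "M"
    if (config$u_prob > 0 && runif(1L) < config$u_prob) state <- "U"
    loc <- rbind(loc, data.frame(gene_id = gene_id, species_id = sp,
                                 state = state))
  }
  alignment <- protein_alignment(rows, family_id = gene_id)
  structure(list(gene_id = gene_id,
                 transfer_branches = sort(labels[transfer_nodes]),
                 transfer_nodes = transfer_nodes,
                 structures = structures, loci = loci, cds = cds_out,
                 alignment = alignment, events = events_log,
                 intron_records = intron_records, localization = loc),
            class = "sim_family")
}

#' Simulate a full synthetic dataset
#'
#' Seeds the RNG from `config$seed` and simulates `config$n_genes` families
#' on the configured tree. Deterministic: identical configs give identical
#' output.
#'
#' @param config A [sim_config()].
#' @return A `synthetic_truth` list: `config`, `tree`, `families` (named list
#'   of [simulate_family()] results), `localization` (long data frame over
#'   all genes) and `groups`.
#' @export
simulate_dataset <- function(config) {
  set.seed(config$seed)
  gene_ids <- sprintf("g%02d", seq_len(config$n_genes))
  families <- lapply(gene_ids, function(g) simulate_family(config, g))
  names(families) <- gene_ids
  localization <- do.call(rbind, lapply(families, `[[`, "localization"))
  rownames(localization) <- NULL
  structure(list(config = config, tree = config$tree, families = families,
                 localization = localization, groups = config$groups),
            class = "synthetic_truth")
}

#' True protein alignment of a simulated family
#'
#' Indel-free simulations return the positional alignment (column i =
#' residue i); simple-indel simulations return the homology alignment from
#' the simulator's own column registry.
#'
#' @param family A `sim_family`.
#' @return A [protein_alignment()].
#' @export
make_alignment <- function(family) family$alignment

#' Truth labels for shared intron positions
#'
#' Classifies every distinct (alignment column, phase) position carried by
#' two or more sequences as `descent` (all carriers trace to one gain event)
#' or `parallel` (at least two independent gain events).
#'
#' @param family A `sim_family`.
#' @return Data frame (column, phase, n_carriers, n_events, label).
#' @export
truth_position_labels <- function(family) {
  rec <- family$intron_records
  out <- data.frame(column = integer(0), phase = integer(0),
                    n_carriers = integer(0), n_events = integer(0),
                    label = character(0))
  if (nrow(rec) == 0L) return(out)
  key <- paste(rec$column, rec$phase, sep = "_")
  for (k in unique(key)) {
    sel <- rec[key == k, , drop = FALSE]
    if (length(unique(sel$species_id)) < 2L) next
    ne <- length(unique(sel$event_id))
    out[nrow(out) + 1L, ] <- list(sel$column[1L], sel$phase[1L],
                                  length(unique(sel$species_id)), ne,
                                  if (ne == 1L) "descent" else "parallel")
  }
  out[order(out$column, out$phase), , drop = FALSE]
}
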