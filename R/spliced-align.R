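# Seed-and-chain spliced alignment of a protein query against a genomic locus.
# Replaces the external BLAT step: exact amino-acid k-mer seeds against the
# three forward-frame translations of the locus, merged into maximal exact
# matches and chained by dynamic programming with zero gap (intron) penalty.

.empty_blocks <- function() {
  data.frame(p_start = integer(0), p_end = integer(0),
             g_start = integer(0), g_end = integer(0))
}

# Maximal exact matches (>= k residues) between protein and the three
# forward-frame translations. Coordinates 0-based half-open; g in nucleotides.
.find_blocks <- function(protein, gseq, k) {
  n_aa <- nchar(protein)
  pk_pos <- seq_len(n_aa - k + 1L)
  pk <- substring(protein, pk_pos, pk_pos + k - 1L)
  pmap <- split(pk_pos, pk)
  out <- vector("list", 3L)
  for (f in 0:2) {
    usable <- ((nchar(gseq) - f) %/% 3L) * 3L
    if (usable < 3L * k) next
    tr <- translate_cds(substr(gseq, f + 1L, f + usable))
    tl <- nchar(tr)
    tpos <- seq_len(tl - k + 1L)
    tk <- substring(tr, tpos, tpos + k - 1L)
    hit <- which(tk %in% names(pmap))
    if (length(hit) == 0L) next
    plist <- pmap[tk[hit]]
    p1 <- unlist(plist, use.names = FALSE)
    t1 <- rep.int(hit, lengths(plist))
    d <- t1 - p1
    df <- data.frame(p = p1, d = d)
    df <- df[order(df$d, df$p), , drop = FALSE]
    new_run <- c(TRUE, diff(df$d) != 0L | diff(df$p) != 1L)
    run_id <- cumsum(new_run)
    starts <- df$p[new_run]
    lens <- tabulate(run_id) + k - 1L
    dd <- df$d[new_run]
    out[[f + 1L]] <- data.frame(
      p_start = starts - 1L,
      p_end = starts - 1L + lens,
      g_start = f + 3L * (starts + dd - 1L),
      g_end = f + 3L * (starts + dd - 1L + lens)
    )
  }
  blocks <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(blocks) || nrow(blocks) == 0L) return(.empty_blocks())
  unique(blocks)
}

#' Spliced alignment of a protein to a genomic locus
#'
#' Finds a colinear chain of exact translated match blocks maximizing the
#' number of protein residues covered. Blocks come from exact amino-acid
#' k-mer seeding against the three forward-frame translations of the locus,
#' extended to maximal exact matches and chained by dynamic programming with
#' zero penalty for genomic gaps (putative introns). Overlaps are forbidden;
#' equal-score chains are broken deterministically toward the leftmost genomic
#' start and flagged via the `ambiguous` attribute.
#'
#' @param protein Amino-acid query string.
#' @param locus A [genomic_locus()] or plain DNA string in coding orientation
#'   (forward strand only).
#' @param seed_k Seed k-mer length in residues (default 5).
#' @param min_coverage Minimum fraction of protein residues that must be
#'   covered by the best chain (default 0.9); below it a
#'   `introntrace_no_alignment` error is thrown.
#' @return A `splice_chain` data frame with columns `p_start`, `p_end`
#'   (protein, 0-based half-open), `g_start`, `g_end` (genomic nt, 0-based
#'   half-open), and attributes `coverage`, `ambiguous`, `protein_length`.
#' @export
spliced_align <- function(protein, locus, seed_k = 5L, min_coverage = 0.9) {
  .validate_protein(protein)
  gseq <- .locus_seq(locus)
  n_aa <- nchar(protein)
  if (n_aa < seed_k) {
    .intron_stop("protein shorter than seed k-mer length", "introntrace_no_alignment")
  }
  blocks <- .find_blocks(protein, gseq, as.integer(seed_k))
  if (nrow(blocks) == 0L) {
    .intron_stop("no spliced alignment: no seed matches found",
                 "introntrace_no_alignment")
  }
  blocks <- blocks[order(blocks$p_start, blocks$g_start), , drop = FALSE]
  m <- nrow(blocks)
  len <- blocks$p_end - blocks$p_start
  # Chain DP. Adjacent exon blocks may overlap by a residue or two when a
  # maximal match overshoots a split codon by chance (the bogus codon happens
  # to translate to the right residue), so small protein overlaps are allowed
  # and resolved by trimming the downstream block's start at reconstruction;
  # the scored coverage is the trimmed (net) residue count.
  max_overlap <- 3L
  score <- len
  pred <- rep.int(0L, m)
  trim <- rep.int(0L, m)
  ambig <- rep.int(FALSE, m)
  for (i in seq_len(m)) {
    if (i == 1L) next
    j <- seq_len(i - 1L)
    o <- pmax(0L, blocks$p_end[j] - blocks$p_start[i])
    keep <- o <= max_overlap & o < len[i] &
      (blocks$g_start[i] + 3L * o) >= blocks$g_end[j] &
      (blocks$g_start[i] + 3L * o - blocks$g_end[j]) >=
        3L * (blocks$p_start[i] + o - blocks$p_end[j])
    if (!any(keep)) next
    jk <- j[keep]
    s <- score[jk] - o[keep]
    best <- max(s)
    if (len[i] + best <= score[i]) next
    cand <- jk[s == best]
    if (length(cand) > 1L) {
      pick <- cand[order(blocks$g_start[cand], blocks$g_end[cand])][1L]
      if (any(blocks$g_start[cand] != blocks$g_start[pick])) ambig[i] <- TRUE
    } else {
      pick <- cand
    }
    ambig[i] <- ambig[i] || ambig[pick]
    score[i] <- len[i] + best
    pred[i] <- pick
    trim[i] <- max(0L, blocks$p_end[pick] - blocks$p_start[i])
  }
  top <- max(score)
  ends <- which(score == top)
  chain_of <- function(e) {
    idx <- integer(0)
    while (e != 0L) { idx <- c(e, idx); e <- pred[e] }
    idx
  }
  chains <- lapply(ends, chain_of)
  ambiguous <- length(ends) > 1L
  if (length(chains) > 1L) {
    firsts <- vapply(chains, function(ix) blocks$g_start[ix[1L]], integer(1))
    keys <- vapply(chains, function(ix)
      paste(sprintf("%012d", blocks$g_start[ix]), collapse = ","), character(1))
    pick <- order(firsts, keys)[1L]
    ambiguous <- ambiguous && length(unique(keys)) > 1L
    chain <- chains[[pick]]
    ambiguous <- ambiguous || ambig[ends[pick]]
  } else {
    chain <- chains[[1L]]
    ambiguous <- ambig[ends[1L]]
  }
  res <- blocks[chain, , drop = FALSE]
  tr <- trim[chain]
  tr[1L] <- 0L
  res$p_start <- res$p_start + tr
  res$g_start <- res$g_start + 3L * tr
  rownames(res) <- NULL
  coverage <- sum(res$p_end - res$p_start) / n_aa
  if (coverage < min_coverage) {
    .intron_stop(sprintf(
      "no spliced alignment: best chain covers %.1f%% of the protein (minimum %.1f%%)",
      100 * coverage, 100 * min_coverage), "introntrace_no_alignment")
  }
  # sanity: each block translates exactly to its protein substring
  for (i in seq_len(nrow(res))) {
    tr <- translate_cds(.gsub0(gseq, res$g_start[i], res$g_end[i]))
    stopifnot(identical(tr, substr(protein, res$p_start[i] + 1L, res$p_end[i])))
  }
  structure(res, class = c("splice_chain", "data.frame"),
            coverage = coverage, ambiguous = ambiguous, protein_length = n_aa)
}
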