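# Intron identification from a spliced-alignment chain, with the three
# acceptance filters: length > 20 nt, canonical GT..AG sites, and a translated
# junction check (9 + 9 exonic nt spliced across the junction).

.empty_introns <- function() {
  data.frame(cds_offset = integer(0), phase = integer(0),
             anchor_residue = integer(0), g_start = integer(0),
             g_end = integer(0), intron_length = integer(0),
             donor = character(0), acceptor = character(0))
}

.empty_rejections <- function() {
  data.frame(junction = integer(0), g_start = integer(0), g_end = integer(0),
             intron_length = integer(0), reason = character(0))
}

#' Gene structure: a protein plus its ordered intron positions
#'
#' @param gene_id,species_id Identifiers.
#' @param protein Amino-acid string (stop codon excluded).
#' @param introns Data frame with columns `cds_offset`, `phase`,
#'   `anchor_residue`, `g_start`, `g_end`, `intron_length`, `donor`,
#'   `acceptor` (possibly 0 rows). Offsets must be strictly increasing and
#'   each phase/anchor must be consistent with its offset.
#' @param compartment `"nuclear"` or `"mitochondrial"`.
#' @return A `gene_structure` object; `cds_len` is `3 * nchar(protein)`.
#' @export
gene_structure <- function(gene_id, species_id, protein,
                           introns = .empty_introns(),
                           compartment = c("nuclear", "mitochondrial")) {
  compartment <- match.arg(compartment)
  .validate_protein(protein)
  cds_len <- 3L * nchar(protein)
  if (nrow(introns) > 0L) {
    o <- introns$cds_offset
    if (any(o <= 0L) || any(o >= cds_len)) {
      .intron_stop("intron cds_offset out of range (0, cds_len)",
                   "introntrace_structure_error")
    }
    if (is.unsorted(o, strictly = TRUE)) {
      .intron_stop("intron cds_offsets must be strictly increasing",
                   "introntrace_structure_error")
    }
    if (any(introns$phase != o %% 3L) ||
        any(introns$anchor_residue != o %/% 3L + 1L)) {
      .intron_stop("intron phase/anchor inconsistent with cds_offset",
                   "introntrace_structure_error")
    }
  }
  structure(list(gene_id = gene_id, species_id = species_id,
                 compartment = compartment, protein = protein,
                 cds_len = cds_len, introns = introns),
            class = "gene_structure")
}

#' @export
print.gene_structure <- function(x, ...) {
  cat(sprintf("<gene_structure> %s|%s (%s): %d aa, %d intron(s)\n",
              x$gene_id, x$species_id, x$compartment,
              nchar(x$protein), nrow(x$introns)))
  invisible(x)
}

# Translated junction check on complete codons of the spliced 9+9 window.
# up_bound/down_bound restrict the windows to known-exonic sequence (the
# flanking alignment blocks); the window is truncated symmetrically when a
# flank is shorter than `w` nt.
.junction_check <- function(gseq, g_start, g_end, cds_offset, protein,
                            up_bound = 0L, down_bound = nchar(gseq), w = 9L) {
  n_aa <- nchar(protein)
  up_avail <- g_start - max(0L, up_bound)
  dn_avail <- min(nchar(gseq), down_bound) - g_end
  w_eff <- min(w, up_avail, dn_avail, cds_offset, 3L * n_aa - cds_offset)
  if (w_eff < 3L) return(FALSE)
  window <- paste0(.gsub0(gseq, g_start - w_eff, g_start),
                   .gsub0(gseq, g_end, g_end + w_eff))
  lo <- cds_offset - w_eff
  c0 <- (lo + 2L) %/% 3L                      # first complete codon (0-based)
  c1 <- (cds_offset + w_eff) %/% 3L - 1L      # last complete codon
  if (c1 < c0) return(FALSE)
  sub <- substr(window, 3L * c0 - lo + 1L, 3L * (c1 + 1L) - lo)
  tr <- tryCatch(translate_cds(sub), error = function(e) NULL)
  if (is.null(tr)) return(FALSE)
  identical(tr, substr(protein, c0 + 1L, c1 + 1L))
}

#' Verify a candidate intron junction by local translation
#'
#' Splices the (up to) 9 exonic nucleotides upstream of the donor with the
#' (up to) 9 downstream of the acceptor, translates the complete codons of
#' the spliced window in the coding frame, and compares them with the query
#' protein. For phase 1/2 introns the split codon is reassembled across the
#' junction and always lies inside the window. The window is truncated
#' symmetrically when fewer than 9 exonic nucleotides exist on one side.
#'
#' @param locus A [genomic_locus()] or DNA string.
#' @param g_start,g_end Candidate intron span, 0-based half-open.
#' @param cds_offset Number of coding nucleotides preceding the intron.
#' @param protein Amino-acid query.
#' @param exon_bounds Optional `c(lo, hi)` genomic bounds of known-exonic
#'   sequence around the junction (e.g. the flanking alignment blocks).
#' @param window Half-window size in nt (default 9).
#' @return `TRUE` iff the spliced translation matches the protein.
#' @export
verify_junction <- function(locus, g_start, g_end, cds_offset, protein,
                            exon_bounds = NULL, window = 9L) {
  gseq <- .locus_seq(locus)
  if (g_end <= g_start || g_start < 0L || g_end > nchar(gseq)) {
    .intron_stop("candidate intron span out of locus bounds",
                 "introntrace_span_error")
  }
  if (cds_offset <= 0L || cds_offset >= 3L * nchar(protein)) {
    .intron_stop("cds_offset inconsistent with protein length",
                 "introntrace_consistency_error")
  }
  if (is.null(exon_bounds)) exon_bounds <- c(0L, nchar(gseq))
  .junction_check(gseq, g_start, g_end, cds_offset, protein,
                  up_bound = exon_bounds[1L], down_bound = exon_bounds[2L],
                  w = as.integer(window))
}

#' Classify one intron candidate against the acceptance filters
#'
#' Applies, in order: length > `min_intron_length - 1` nt (reason `LENGTH`),
#' canonical GT donor / AG acceptor (reason `SITE`), and the translated
#' junction check (reason `JUNCTION`).
#'
#' @inheritParams verify_junction
#' @param min_intron_length Minimum accepted length in nt; the default 21
#'   encodes the strict "longer than 20 nucleotides" rule.
#' @return List with `accepted` (logical) and `reason` (`NA` or the first
#'   failing filter: `"LENGTH"`, `"SITE"`, `"JUNCTION"`).
#' @export
check_intron_candidate <- function(locus, g_start, g_end, cds_offset, protein,
                                   exon_bounds = NULL,
                                   min_intron_length = 21L) {
  gseq <- .locus_seq(locus)
  len <- g_end - g_start
  if (len < min_intron_length) {
    return(list(accepted = FALSE, reason = "LENGTH"))
  }
  donor <- .gsub0(gseq, g_start, g_start + 2L)
  acceptor <- .gsub0(gseq, g_end - 2L, g_end)
  if (donor != "GT" || acceptor != "AG") {
    return(list(accepted = FALSE, reason = "SITE"))
  }
  ok <- verify_junction(locus, g_start, g_end, cds_offset, protein,
                        exon_bounds = exon_bounds)
  if (!ok) return(list(accepted = FALSE, reason = "JUNCTION"))
  list(accepted = TRUE, reason = NA_character_)
}

#' Identify intron positions from a spliced-alignment chain
#'
#' Each inter-block genomic gap is a putative intron. Block boundaries are
#' locally shifted (within `shift_window` nt) toward a placement whose gap
#' starts GT and ends AG, provided the shift preserves translation identity;
#' ties prefer the smallest shift, then the leftmost genomic start. The
#' chosen placement is then filtered in order: length > 20 nt (`LENGTH`),
#' canonical splice sites (`SITE`), translated junction check (`JUNCTION`).
#'
#' @param blocks A `splice_chain` from [spliced_align()].
#' @param locus The same locus the chain was built on.
#' @param protein The query protein.
#' @param min_intron_length Minimum accepted intron length (default 21 nt,
#'   i.e. strictly longer than 20).
#' @param shift_window Maximum boundary-rescue shift in nt (default 12).
#' @return List with `introns` (accepted positions, ordered by `cds_offset`)
#'   and `rejections` (one row per rejected gap with the first failing
#'   filter as reason code).
#' @export
identify_introns <- function(blocks, locus, protein,
                             min_intron_length = 21L, shift_window = 12L) {
  gseq <- .locus_seq(locus)
  glen <- nchar(gseq)
  nb <- nrow(blocks)
  introns <- .empty_introns()
  rejections <- .empty_rejections()
  if (nb < 2L) return(list(introns = introns, rejections = rejections))
  for (i in seq_len(nb - 1L)) {
    p1e <- blocks$p_end[i];   g1e <- blocks$g_end[i]
    p2s <- blocks$p_start[i + 1L]; g2s <- blocks$g_start[i + 1L]
    dp <- p2s - p1e
    dg <- g2s - g1e
    if (dg <= 0L) {
      .intron_stop("malformed chain: non-positive genomic gap",
                   "introntrace_chain_error")
    }
    L <- dg - 3L * dp
    reject <- function(reason, gs = g1e, ge = g1e + max(L, 0L)) {
      rejections[nrow(rejections) + 1L, ] <<-
        list(i, gs, ge, max(L, 0L), reason)
    }
    if (L < min_intron_length) { reject("LENGTH"); next }
    if (dp > 1L) { reject("JUNCTION"); next }   # unmodellable residue gap
    centers <- if (dp == 0L) g1e else c(g1e + 1L, g1e + 2L)
    starts <- sort(unique(unlist(lapply(centers, function(cc)
      (cc - shift_window):(cc + shift_window)))))
    starts <- starts[starts >= max(0L, blocks$g_start[i]) &
                     starts + L <= min(glen, blocks$g_end[i + 1L])]
    cand <- data.frame(start = starts)
    cand$offset <- 3L * p1e + (cand$start - g1e)
    cand <- cand[cand$offset > 0L & cand$offset < 3L * nchar(protein), ,
                 drop = FALSE]
    cand$site <- substring(gseq, cand$start + 1L, cand$start + 2L) == "GT" &
      substring(gseq, cand$start + L - 1L, cand$start + L) == "AG"
    cand$dist <- vapply(cand$start, function(s) min(abs(s - centers)), integer(1))
    cand$junction <- vapply(seq_len(nrow(cand)), function(j) {
      .junction_check(gseq, cand$start[j], cand$start[j] + L, cand$offset[j],
                      protein, up_bound = blocks$g_start[i],
                      down_bound = blocks$g_end[i + 1L])
    }, logical(1))
    ok <- cand[cand$junction, , drop = FALSE]
    if (nrow(ok) > 0L) {
      ok <- ok[order(!ok$site, ok$dist, ok$start), , drop = FALSE]
      chosen <- ok[1L, ]
    } else {
      base <- cand[cand$dist == 0L, , drop = FALSE]
      if (nrow(base) == 0L) base <- cand
      base <- base[order(!base$site, base$dist, base$start), , drop = FALSE]
      chosen <- base[1L, ]
    }
    gs <- chosen$start; ge <- gs + L
    if (!chosen$site) { reject("SITE", gs, ge); next }
    if (!chosen$junction) { reject("JUNCTION", gs, ge); next }
    o <- chosen$offset
    introns[nrow(introns) + 1L, ] <- list(
      o, o %% 3L, o %/% 3L + 1L, gs, ge, L,
      substring(gseq, gs + 1L, gs + 2L), substring(gseq, ge - 1L, ge))
  }
  introns <- introns[order(introns$cds_offset), , drop = FALSE]
  rownames(introns) <- NULL
  list(introns = introns, rejections = rejections)
}

#' Build a gene structure by spliced alignment and intron filtering
#'
#' Composition of [spliced_align()] and [identify_introns()]: deterministic
#' for fixed inputs and parameters. The rejection log is attached as the
#' `rejections` attribute of the returned object.
#'
#' @inheritParams spliced_align
#' @inheritParams identify_introns
#' @param gene_id,species_id,compartment Passed to [gene_structure()].
#' @return A [gene_structure()] containing only accepted introns.
#' @export
structure_from_alignment <- function(protein, locus, gene_id = "gene",
                                     species_id = NA_character_,
                                     compartment = "nuclear",
                                     seed_k = 5L, min_coverage = 0.9,
                                     min_intron_length = 21L,
                                     shift_window = 12L) {
  chain <- spliced_align(protein, locus, seed_k = seed_k,
                         min_coverage = min_coverage)
  res <- identify_introns(chain, locus, protein,
                          min_intron_length = min_intron_length,
                          shift_window = shift_window)
  gs <- gene_structure(gene_id, species_id, protein, introns = res$introns,
                       compartment = compartment)
  attr(gs, "rejections") <- res$rejections
  attr(gs, "ambiguous_chain") <- isTRUE(attr(chain, "ambiguous"))
  gs
}

#' Tabulate intron positions of one or more gene structures
#'
#' @param structures A `gene_structure` or list of them.
#' @return Data frame with one row per intron (gene_id, species_id,
#'   cds_offset, phase, anchor_residue, intron_length, donor, acceptor).
#' @export
intron_table <- function(structures) {
  if (inherits(structures, "gene_structure")) structures <- list(structures)
  rows <- lapply(structures, function(s) {
    if (nrow(s$introns) == 0L) return(NULL)
    cbind(data.frame(gene_id = s$gene_id, species_id = s$species_id),
          s$introns[, c("cds_offset", "phase", "anchor_residue",
                        "intron_length", "donor", "acceptor")])
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    return(data.frame(gene_id = character(0), species_id = character(0),
                      cds_offset = integer(0), phase = integer(0),
                      anchor_residue = integer(0), intron_length = integer(0),
                      donor = character(0), acceptor = character(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
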