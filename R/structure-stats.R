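# Gene-structure statistics: intron density (introns per kb coding sequence),
# phase distribution, and exon symmetry classes of internal exons.

#' Intron density of a gene
#'
#' Number of introns per 1 kb of coding sequence (stop codon excluded from
#' `cds_len` by construction).
#'
#' @param gene A [gene_structure()].
#' @return Non-negative real, `1000 * n_introns / cds_len`.
#' @export
intron_density <- function(gene) {
  if (is.null(gene$cds_len) || gene$cds_len <= 0L) {
    .intron_stop("invalid gene: cds_len must be positive",
                 "introntrace_structure_error")
  }
  1000 * nrow(gene$introns) / gene$cds_len
}

.as_structure_list <- function(genes) {
  if (inherits(genes, "gene_structure")) return(list(genes))
  genes
}

#' Intron phase distribution
#'
#' @param genes A `gene_structure` or list of them.
#' @return List with `counts` (named integer vector over phases 0,1,2) and
#'   `fractions` (summing to 1, or `NULL` when there are no introns).
#' @export
phase_distribution <- function(genes) {
  genes <- .as_structure_list(genes)
  phases <- unlist(lapply(genes, function(g) g$introns$phase))
  counts <- vapply(0:2, function(p) sum(phases == p), integer(1))
  names(counts) <- c("0", "1", "2")
  fractions <- if (sum(counts) > 0L) counts / sum(counts) else NULL
  list(counts = counts, fractions = fractions)
}

#' Exon symmetry classification
#'
#' Every internal exon (flanked by two introns) contributes one count to the
#' class `upstream phase`-`downstream phase`; terminal exons are excluded.
#' Symmetric classes are 0-0, 1-1, 2-2.
#'
#' @param genes A `gene_structure` or list of them.
#' @return List with `matrix` (3x3 counts, rows = upstream phase),
#'   `symmetric`, `asymmetric` counts and `symmetric_fraction` (`NA` when no
#'   internal exon exists).
#' @export
exon_symmetry <- function(genes) {
  genes <- .as_structure_list(genes)
  m <- matrix(0L, 3, 3, dimnames = list(up = 0:2, down = 0:2))
  for (g in genes) {
    ph <- g$introns$phase
    if (length(ph) < 2L) next
    for (j in seq_len(length(ph) - 1L)) {
      m[ph[j] + 1L, ph[j + 1L] + 1L] <- m[ph[j] + 1L, ph[j + 1L] + 1L] + 1L
    }
  }
  total <- sum(m)
  sym <- sum(diag(m))
  list(matrix = m, symmetric = sym, asymmetric = total - sym,
       symmetric_fraction = if (total > 0L) sym / total else NA_real_)
}

#' All gene-structure statistics, optionally grouped
#'
#' @param genes List of `gene_structure` objects.
#' @param by Optional character vector (same length as `genes`) of group
#'   labels, e.g. species, to compute per-group panels.
#' @return For `by = NULL`: list with `density` (per-gene data frame),
#'   `phase` and `symmetry` (as in [phase_distribution()] /
#'   [exon_symmetry()]). Otherwise a named list of such lists per group.
#' @export
structure_stats <- function(genes, by = NULL) {
  genes <- .as_structure_list(genes)
  if (!is.null(by)) {
    stopifnot(length(by) == length(genes))
    return(lapply(split(genes, by), structure_stats))
  }
  density <- data.frame(
    gene_id = vapply(genes, `[[`, character(1), "gene_id"),
    species_id = vapply(genes, `[[`, character(1), "species_id"),
    n_introns = vapply(genes, function(g) nrow(g$introns), integer(1)),
    cds_len = vapply(genes, `[[`, integer(1), "cds_len"))
  density$density <- 1000 * density$n_introns / density$cds_len
  list(density = density,
       phase = phase_distribution(genes),
       symmetry = exon_symmetry(genes))
}
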