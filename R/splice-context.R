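# Proto-splice-site context around intron positions and compartment-resolved
# codon usage. The proto-splice consensus is (C|A)AG before the insertion
# point and (A|G) immediately after, evaluated on the spliced coding sequence.

#' Extract the splice-site context of an intron
#'
#' @param cds Spliced coding sequence (DNA string) of the gene.
#' @param cds_offset Coding nucleotides preceding the intron (an
#'   `IntronPosition` row's `cds_offset`, or any offset `3 <= o < cds_len`).
#' @return List with `upstream_tri` (last 3 exonic nt before the intron) and
#'   `downstream_nt` (first exonic nt after it).
#' @export
extract_context <- function(cds, cds_offset) {
  .validate_dna(cds, "cds")
  n <- nchar(cds)
  o <- as.integer(cds_offset)
  if (o < 3L) {
    .intron_stop("truncated context: fewer than 3 coding nt precede the intron",
                 "introntrace_context_error")
  }
  if (o >= n) {
    .intron_stop("cds_offset out of range of the coding sequence",
                 "introntrace_context_error")
  }
  list(upstream_tri = substr(cds, o - 2L, o),
       downstream_nt = substr(cds, o + 1L, o + 1L))
}

#' Proto-splice-site test
#'
#' `TRUE` iff the upstream trinucleotide matches `[CA]AG` and the downstream
#' nucleotide matches `[AG]` — the classical proto-splice consensus
#' (C|A)AG - (A|G).
#'
#' @param ctx A context from [extract_context()], or a list with fields
#'   `upstream_tri` and `downstream_nt`.
#' @return Logical.
#' @export
is_proto_splice <- function(ctx) {
  grepl("^[CA]AG$", ctx$upstream_tri) && grepl("^[AG]$", ctx$downstream_nt)
}

#' Scan a coding sequence for proto-splice sites
#'
#' Returns every cds offset `o` (with `3 <= o < cds_len`) whose context passes
#' [is_proto_splice()]; these are the candidate insertion points used by the
#' simulator's targeted-gain mode.
#'
#' @param cds In-frame coding sequence.
#' @return Integer vector of qualifying cds offsets (possibly empty).
#' @export
scan_proto_splice_sites <- function(cds) {
  .validate_dna(cds, "cds")
  n <- nchar(cds)
  if (n < 4L) return(integer(0))
  o <- 3:(n - 1L)
  tri <- substring(cds, o - 2L, o)
  nxt <- substring(cds, o + 1L, o + 1L)
  o[grepl("^[CA]AG$", tri) & nxt %in% c("A", "G")]
}

#' Codon usage table
#'
#' Per-amino-acid codon fractions computed from in-frame coding sequences.
#'
#' @param cds Character vector of in-frame coding sequences.
#' @param compartment Label stored on the table (`"nuclear"` or
#'   `"mitochondrial"`).
#' @param amino_acids Optional one-letter filter (e.g. `"Q"` for glutamine).
#' @param table Genetic-code table id; `"1"` standard (nuclear), `"2"`
#'   vertebrate mitochondrial.
#' @return A `codon_usage_table` data frame (compartment, amino_acid, codon,
#'   count, fraction); fractions sum to 1 within each amino acid. Amino acids
#'   with no observed codon are absent.
#' @export
codon_usage <- function(cds, compartment = "nuclear", amino_acids = NULL,
                        table = "1") {
  gc <- genetic_code(table)
  counts <- integer(0)
  for (s in cds) {
    n <- nchar(s)
    if (n %% 3L != 0L) {
      .intron_stop("cds length not divisible by 3", "introntrace_frame_error")
    }
    if (n == 0L) next
    .validate_dna(s, "cds")
    codons <- substring(s, seq.int(1L, n - 2L, 3L), seq.int(3L, n, 3L))
    tab <- base::table(codons)
    counts <- c(counts, setNames(as.integer(tab), names(tab)))
  }
  counts <- tapply(counts, names(counts), sum)
  if (length(counts) == 0L) {
    return(structure(data.frame(compartment = character(0),
                                amino_acid = character(0), codon = character(0),
                                count = integer(0), fraction = numeric(0)),
                     class = c("codon_usage_table", "data.frame")))
  }
  out <- data.frame(compartment = compartment,
                    amino_acid = unname(gc[names(counts)]),
                    codon = names(counts),
                    count = as.integer(counts))
  out <- out[out$amino_acid != "*", , drop = FALSE]
  if (!is.null(amino_acids)) {
    out <- out[out$amino_acid %in% amino_acids, , drop = FALSE]
  }
  tot <- tapply(out$count, out$amino_acid, sum)
  out$fraction <- out$count / as.numeric(tot[out$amino_acid])
  out <- out[order(out$amino_acid, out$codon), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("codon_usage_table", "data.frame"))
}
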