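# Low-level sequence utilities shared by all modules. Translation uses the
# genetic-code tables shipped with Biostrings; nothing here re-derives a code.

#' Genetic code lookup
#'
#' Returns a named character vector mapping DNA codons to one-letter amino
#' acids, from Biostrings' genetic-code tables. Cached per table id.
#'
#' @param table NCBI genetic-code table id as a string; `"1"` is the standard
#'   code, `"2"` the vertebrate mitochondrial code.
#' @return Named character vector of length 64.
#' @export
genetic_code <- function(table = "1") {
  key <- paste0("gc_", table)
  if (is.null(.pkg_cache[[key]])) {
    .pkg_cache[[key]] <- Biostrings::getGeneticCode(table)
  }
  .pkg_cache[[key]]
}

#' Translate an in-frame coding sequence
#'
#' @param cds DNA string (A/C/G/T) whose length is divisible by 3.
#' @param table Genetic-code table id (see [genetic_code()]).
#' @return One-letter amino-acid string; stop codons become `*`.
#' @export
translate_cds <- function(cds, table = "1") {
  n <- nchar(cds)
  if (n %% 3L != 0L) {
    .intron_stop("cds length must be divisible by 3", "introntrace_frame_error")
  }
  if (n == 0L) return("")
  gc <- genetic_code(table)
  codons <- substring(cds, seq.int(1L, n - 2L, 3L), seq.int(3L, n, 3L))
  aa <- unname(gc[codons])
  if (anyNA(aa)) {
    .intron_stop("cds contains letters outside {A,C,G,T}", "introntrace_alphabet_error")
  }
  paste(aa, collapse = "")
}

.validate_dna <- function(seq, what = "sequence") {
  if (length(seq) != 1L || !is.character(seq) || is.na(seq) || nchar(seq) == 0L) {
    .intron_stop(sprintf("%s must be a non-empty DNA string", what),
                 "introntrace_alphabet_error")
  }
  if (grepl("[^ACGT]", seq)) {
    bad <- unique(strsplit(gsub("[ACGT]", "", seq), "")[[1]])
    .intron_stop(sprintf("%s contains letters outside {A,C,G,T}: %s",
                         what, paste(bad, collapse = ", ")),
                 "introntrace_alphabet_error")
  }
  invisible(seq)
}

.validate_protein <- function(protein) {
  if (length(protein) != 1L || !is.character(protein) || is.na(protein) ||
      nchar(protein) == 0L || grepl("[^ACDEFGHIKLMNPQRSTVWY]", protein)) {
    .intron_stop("protein must be a non-empty string over the 20 amino-acid letters",
                 "introntrace_alphabet_error")
  }
  invisible(protein)
}

#' Genomic locus container
#'
#' @param locus_id,species_id Identifier strings.
#' @param sequence DNA string restricted to A/C/G/T (coding orientation;
#'   reverse-strand input is the caller's responsibility).
#' @return A `genomic_locus` object.
#' @export
genomic_locus <- function(locus_id, sequence, species_id = NA_character_) {
  .validate_dna(sequence, sprintf("locus '%s'", locus_id))
  structure(list(locus_id = locus_id, sequence = sequence,
                 species_id = species_id),
            class = "genomic_locus")
}

.locus_seq <- function(locus) {
  if (inherits(locus, "genomic_locus")) return(locus$sequence)
  .validate_dna(locus, "locus")
  locus
}

#' @export
print.genomic_locus <- function(x, ...) {
  cat(sprintf("<genomic_locus> %s (%s), %d nt\n",
              x$locus_id, x$species_id, nchar(x$sequence)))
  invisible(x)
}

# Reverse-sorted substring helpers (0-based half-open genomic coordinates are
# used everywhere internally; substr is 1-based, hence the +1 shifts).
.gsub0 <- function(seq, start0, end0) {
  if (end0 <= start0) return("")
  substr(seq, start0 + 1L, end0)
}
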