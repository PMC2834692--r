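# File-format adapters. FASTA via Biostrings, trees via ape, JSON via
# jsonlite, tables as plain TSV. Sequence ids follow the `gene_id|species_id`
# convention.

#' Read a FASTA file
#'
#' @param path FASTA file (plain text; wrapped lines allowed).
#' @param type `"AA"` or `"DNA"`.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path, type = c("AA", "DNA")) {
  type <- match.arg(type)
  set <- if (type == "AA") Biostrings::readAAStringSet(path) else
    Biostrings::readDNAStringSet(path)
  out <- as.character(set)
  names(out) <- sub("\\s.*$", "", names(out))
  if (anyDuplicated(names(out))) {
    .intron_stop(sprintf("duplicate sequence ids in '%s'", path),
                 "introntrace_io_error")
  }
  out
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector.
#' @param path Output file.
#' @param type `"AA"` or `"DNA"`.
#' @export
write_fasta <- function(seqs, path, type = c("AA", "DNA")) {
  type <- match.arg(type)
  set <- if (type == "AA") Biostrings::AAStringSet(seqs) else
    Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Read a localization table
#'
#' @param path TSV with columns `gene_id`, `species_id`, `state`
#'   (M/N/U).
#' @return Data frame with validated states.
#' @export
read_localization <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "species_id", "state")
  if (!all(need %in% names(df))) {
    .intron_stop(sprintf("localization table '%s' must have columns %s",
                         path, paste(need, collapse = ", ")),
                 "introntrace_io_error")
  }
  bad <- which(!df$state %in% c("M", "N", "U"))
  if (length(bad) > 0L) {
    .intron_stop(sprintf("localization table '%s': unknown state '%s' in row %d",
                         path, df$state[bad[1L]], bad[1L]),
                 "introntrace_io_error")
  }
  df
}

#' Read a species grouping table
#'
#' @param path TSV with columns `species_id`, `group`.
#' @return Named character vector species -> group.
#' @export
read_grouping <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("species_id", "group") %in% names(df))) {
    .intron_stop(sprintf("grouping table '%s' must have columns species_id, group",
                         path), "introntrace_io_error")
  }
  setNames(df$group, df$species_id)
}

#' Read an aligned FASTA as a protein alignment
#'
#' @param path Aligned FASTA.
#' @param family_id Identifier (defaults to the file name).
#' @return A [protein_alignment()].
#' @export
read_alignment <- function(path, family_id = NULL) {
  if (is.null(family_id)) {
    family_id <- sub("\\.[^.]*$", "", basename(path))
  }
  protein_alignment(read_fasta(path, "AA"), family_id = family_id)
}

.write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a simulated dataset to disk
#'
#' Emits genomic/protein/cds FASTA (ids `gene|species`), a localization TSV,
#' a grouping TSV, the newick tree, one aligned FASTA per family, and a truth
#' JSON (transfer branches, gain events, per-intron records).
#'
#' @param truth A `synthetic_truth` from [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(truth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "alignments"), showWarnings = FALSE)
  gseqs <- character(0); pseqs <- character(0); cseqs <- character(0)
  for (fam in truth$families) {
    for (sp in names(fam$structures)) {
      id <- paste(fam$gene_id, sp, sep = "|")
      gseqs[id] <- fam$loci[[sp]]$sequence
      pseqs[id] <- fam$structures[[sp]]$protein
      cseqs[id] <- fam$cds[[sp]]
    }
    write_fasta(fam$alignment$rows,
                file.path(dir, "alignments", paste0(fam$gene_id, ".fasta")),
                "AA")
  }
  write_fasta(gseqs, file.path(dir, "genomic.fasta"), "DNA")
  write_fasta(pseqs, file.path(dir, "protein.fasta"), "AA")
  write_fasta(cseqs, file.path(dir, "cds.fasta"), "DNA")
  .write_tsv(truth$localization, file.path(dir, "localization.tsv"))
  .write_tsv(data.frame(species_id = names(truth$groups),
                        group = unname(truth$groups)),
             file.path(dir, "grouping.tsv"))
  ape::write.tree(truth$tree, file.path(dir, "tree.nwk"))
  truth_json <- lapply(truth$families, function(fam) {
    list(gene_id = fam$gene_id,
         transfer_branches = fam$transfer_branches,
         events = fam$events,
         intron_records = fam$intron_records)
  })
  jsonlite::write_json(truth_json, file.path(dir, "truth.json"),
                       dataframe = "columns", auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
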