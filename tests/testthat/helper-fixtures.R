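# Fixture builders: synthetic genes constructed by hand (independent of the
# simulator where the simulator is the thing under test).

# random in-frame cds without stop codons, from the default nuclear usage
random_cds <- function(n_codons, usage = introntrace::default_codon_usage()$nuclear) {
  aas <- sample(names(usage), n_codons, replace = TRUE)
  paste(vapply(aas, function(a) {
    tab <- usage[[a]]
    if (length(tab) == 1L) names(tab) else sample(names(tab), 1L, prob = tab)
  }, character(1)), collapse = "")
}

# plant introns into a cds by direct string surgery (not via emit_genomic)
plant_introns <- function(cds, offsets, intron_seqs) {
  stopifnot(length(offsets) == length(intron_seqs),
            !is.unsorted(offsets, strictly = TRUE))
  pieces <- character(0); pos <- 0L
  for (i in seq_along(offsets)) {
    pieces <- c(pieces, substr(cds, pos + 1L, offsets[i]), intron_seqs[i])
    pos <- offsets[i]
  }
  paste(c(pieces, substr(cds, pos + 1L, nchar(cds))), collapse = "")
}

# intron sequence with controllable donor/acceptor; interior avoids GT/AG
# near the ends so boundary rescue has a unique solution
test_intron <- function(len, donor = "GT", acceptor = "AG") {
  stopifnot(len >= 8L)
  interior <- paste(rep(c("C", "T", "C", "A"), length.out = len - 4L),
                    collapse = "")
  paste0(donor, interior, acceptor)
}

# one shared synthetic dataset for expensive acceptance checks (built once)
.fixture_env <- new.env(parent = emptyenv())
default_truth <- function() {
  if (is.null(.fixture_env$truth)) {
    cfg <- introntrace::sim_config(seed = 20100223L)  # fixed stated world
    .fixture_env$truth <- introntrace::simulate_dataset(cfg)
  }
  .fixture_env$truth
}

map_all_structures <- function(truth) {
  if (!is.null(.fixture_env$structs)) return(.fixture_env$structs)
  out <- list()
  for (fam in truth$families) {
    for (sp in names(fam$structures)) {
      id <- paste(fam$gene_id, sp, sep = "|")
      out[[id]] <- introntrace::structure_from_alignment(
        fam$structures[[sp]]$protein, fam$loci[[sp]]$sequence,
        gene_id = fam$gene_id, species_id = sp,
        compartment = fam$structures[[sp]]$compartment)
    }
  }
  .fixture_env$structs <- out
  out
}
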