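Package: introntrace
Title: Spliceosomal Intron Evolution After Endosymbiotic Gene Transfer
Version: 0.1.0
Authors@R:
    person("Repo", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to study spliceosomal intron gain in genes transferred from
    the mitochondrion to the nucleus. Identifies intron positions and phases by
    spliced alignment of a protein against its genomic locus with canonical
    GT..AG filters, computes gene-structure statistics (intron density, phase
    distribution, exon symmetry), places transfer events on a rooted species
    tree by Dollo parsimony with relative timing, maps intron positions onto
    protein multiple alignments to count shared and group-specific positions
    (optionally restricted to conserved blocks), analyses proto-splice-site
    context and compartment-specific codon usage, and simulates gene families
    with known transfer and intron-gain histories for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
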