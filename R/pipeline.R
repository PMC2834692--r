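# End-to-end orchestration: simulate (or load) -> map introns -> structure
# statistics -> transfer timing -> shared positions -> splice context.
# Deterministic for a fixed config; every output is a plain-text file.

#' Pipeline configuration
#'
#' @param out_dir Output directory; never equal to the input directory.
#' @param simulate Optional [sim_config()]: simulate first, then analyse.
#' @param input_dir Optional directory holding a dataset in the layout of
#'   [write_dataset()] (used when `simulate` is `NULL`).
#' @param stages Character subset of
#'   `c("map", "stats", "timing", "shared", "context")`; the simulate stage
#'   runs iff `simulate` is given.
#' @param params Named list of per-module overrides: `seed_k`,
#'   `min_coverage`, `min_intron_length`, `shift_window`, `block_window`,
#'   `block_min_identity`, `block_max_gap`, `block_min_length`,
#'   `focal_groups`.
#' @return A validated `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, simulate = NULL, input_dir = NULL,
                            stages = c("map", "stats", "timing", "shared",
                                       "context"),
                            params = list()) {
  if (is.null(simulate) && is.null(input_dir)) {
    .intron_stop("pipeline needs either a simulation config or an input_dir",
                 "introntrace_config_error")
  }
  if (!is.null(input_dir)) {
    if (!dir.exists(input_dir)) {
      .intron_stop(sprintf("input_dir '%s' does not exist", input_dir),
                   "introntrace_config_error")
    }
    if (normalizePath(input_dir) == suppressWarnings(normalizePath(out_dir,
                                                     mustWork = FALSE))) {
      .intron_stop("outputs must not overwrite inputs: out_dir == input_dir",
                   "introntrace_config_error")
    }
  }
  bad <- setdiff(stages, c("map", "stats", "timing", "shared", "context"))
  if (length(bad) > 0L) {
    .intron_stop(sprintf("unknown stage(s): %s", paste(bad, collapse = ", ")),
                 "introntrace_config_error")
  }
  defaults <- list(seed_k = 5L, min_coverage = 0.9, min_intron_length = 21L,
                   shift_window = 12L, block_window = 10L,
                   block_min_identity = 0.5, block_max_gap = 0.1,
                   block_min_length = 8L, focal_groups = NULL)
  defaults[names(params)] <- params
  structure(list(out_dir = out_dir, simulate = simulate,
                 input_dir = input_dir, stages = stages, params = defaults),
            class = "pipeline_config")
}

.load_dataset <- function(dir) {
  proteins <- read_fasta(file.path(dir, "protein.fasta"), "AA")
  genomic <- read_fasta(file.path(dir, "genomic.fasta"), "DNA")
  cds <- read_fasta(file.path(dir, "cds.fasta"), "DNA")
  localization <- read_localization(file.path(dir, "localization.tsv"))
  groups <- read_grouping(file.path(dir, "grouping.tsv"))
  tree <- species_tree(file.path(dir, "tree.nwk"))
  aln_files <- sort(list.files(file.path(dir, "alignments"),
                               pattern = "\\.fasta$", full.names = TRUE))
  alignments <- lapply(aln_files, read_alignment)
  names(alignments) <- vapply(alignments, `[[`, character(1), "family_id")
  list(proteins = proteins, genomic = genomic, cds = cds,
       localization = localization, groups = groups, tree = tree,
       alignments = alignments)
}

.truth_as_dataset <- function(truth) {
  proteins <- character(0); genomic <- character(0); cds <- character(0)
  alignments <- list()
  for (fam in truth$families) {
    for (sp in names(fam$structures)) {
      id <- paste(fam$gene_id, sp, sep = "|")
      proteins[id] <- fam$structures[[sp]]$protein
      genomic[id] <- fam$loci[[sp]]$sequence
      cds[id] <- fam$cds[[sp]]
    }
    alignments[[fam$gene_id]] <- fam$alignment
  }
  list(proteins = proteins, genomic = genomic, cds = cds,
       localization = truth$localization, groups = truth$groups,
       tree = truth$tree, alignments = alignments)
}

#' Run the full analysis pipeline
#'
#' Stages run in dependency order; outputs are TSV/JSON files under
#' `config$out_dir`. When the run starts from a simulation, the report gains
#' a truth-comparison section (planted-intron recall and false positives).
#'
#' @param config A [pipeline_config()].
#' @return A `run_report` (also written to `out_dir/report.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  p <- config$params
  report <- list(stages = list(), config = list(
    stages = config$stages, params = p[!vapply(p, is.null, logical(1))]))
  truth <- NULL
  if (!is.null(config$simulate)) {
    truth <- simulate_dataset(config$simulate)
    write_dataset(truth, file.path(out, "data"))
    report$stages$simulate <- list(
      n_genes = length(truth$families),
      n_species = length(truth$tree$tip.label),
      seed = config$simulate$seed)
    data <- .truth_as_dataset(truth)
  } else {
    data <- .load_dataset(config$input_dir)
  }

  structures <- list()
  if ("map" %in% config$stages) {
    rejections_all <- .empty_rejections()
    rej_meta <- data.frame(gene_id = character(0), species_id = character(0))
    for (id in sort(names(data$proteins))) {
      parts <- strsplit(id, "|", fixed = TRUE)[[1]]
      gene <- parts[1L]; sp <- parts[2L]
      comp <- "nuclear"
      lrow <- data$localization[data$localization$gene_id == gene &
                                data$localization$species_id == sp, ]
      if (nrow(lrow) == 1L && lrow$state == "M") comp <- "mitochondrial"
      gs <- structure_from_alignment(
        data$proteins[[id]], data$genomic[[id]], gene_id = gene,
        species_id = sp, compartment = comp, seed_k = p$seed_k,
        min_coverage = p$min_coverage,
        min_intron_length = p$min_intron_length,
        shift_window = p$shift_window)
      structures[[id]] <- gs
      rej <- attr(gs, "rejections")
      if (nrow(rej) > 0L) {
        rejections_all <- rbind(rejections_all, rej)
        rej_meta <- rbind(rej_meta, data.frame(
          gene_id = rep(gene, nrow(rej)), species_id = rep(sp, nrow(rej))))
      }
    }
    itab <- intron_table(structures)
    .write_tsv(itab, file.path(out, "introns.tsv"))
    .write_tsv(cbind(rej_meta, rejections_all),
               file.path(out, "rejections.tsv"))
    n_acc <- nrow(itab); n_rej <- nrow(rejections_all)
    report$stages$map <- list(genes = length(structures),
                              introns_accepted = n_acc,
                              introns_rejected = n_rej,
                              candidates = n_acc + n_rej)
    if (!is.null(truth)) {
      tp <- 0L; fp <- 0L; fn <- 0L
      for (fam in truth$families) {
        for (sp in names(fam$structures)) {
          id <- paste(fam$gene_id, sp, sep = "|")
          want <- fam$structures[[sp]]$introns[, c("cds_offset", "phase")]
          got <- structures[[id]]$introns[, c("cds_offset", "phase")]
          wk <- paste(want$cds_offset, want$phase)
          gk <- paste(got$cds_offset, got$phase)
          tp <- tp + sum(wk %in% gk)
          fn <- fn + sum(!wk %in% gk)
          fp <- fp + sum(!gk %in% wk)
        }
      }
      report$truth_comparison <- list(
        planted = tp + fn, recovered = tp, false_positives = fp,
        recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_)
    }
  }

  if ("stats" %in% config$stages && length(structures) > 0L) {
    st <- structure_stats(structures)
    .write_tsv(st$density, file.path(out, "density.tsv"))
    phase_df <- data.frame(phase = 0:2, count = as.integer(st$phase$counts),
                           fraction = if (is.null(st$phase$fractions))
                             NA_real_ else as.numeric(st$phase$fractions))
    .write_tsv(phase_df, file.path(out, "phases.tsv"))
    sym <- st$symmetry$matrix
    sym_df <- data.frame(up_phase = rep(0:2, each = 3),
                         down_phase = rep(0:2, 3),
                         count = as.integer(t(sym)))
    .write_tsv(sym_df, file.path(out, "exon_symmetry.tsv"))
    report$stages$stats <- list(
      introns = sum(st$phase$counts),
      internal_exons = st$symmetry$symmetric + st$symmetry$asymmetric,
      symmetric_fraction = st$symmetry$symmetric_fraction)
  }

  scenarios <- NULL
  if ("timing" %in% config$stages) {
    genes <- sort(unique(data$localization$gene_id))
    scenarios <- lapply(genes, function(g) {
      sub <- data$localization[data$localization$gene_id == g, ]
      infer_transfers(data$tree, setNames(sub$state, sub$species_id),
                      gene_id = g)
    })
    names(scenarios) <- genes
    scen_json <- lapply(scenarios, function(s)
      list(gene_id = s$gene_id, transfer_branches = s$transfer_branches,
           n_events = s$n_events, resolved = s$resolved,
           alternatives = s$alternatives))
    jsonlite::write_json(scen_json, file.path(out, "scenarios.json"),
                         auto_unbox = TRUE, digits = NA)
    indep <- find_independent_transfers(scenarios)
    .write_tsv(indep, file.path(out, "independent_transfers.tsv"))
    report$stages$timing <- list(
      genes = length(scenarios),
      events = sum(vapply(scenarios, `[[`, integer(1), "n_events")),
      independent = nrow(indep),
      unresolved = sum(!vapply(scenarios, `[[`, logical(1), "resolved")))
  }

  if ("shared" %in% config$stages && length(structures) > 0L) {
    tables <- list(); tables_blocks <- list()
    detail <- list()
    for (g in names(data$alignments)) {
      aln <- data$alignments[[g]]
      fam_structs <- structures[paste0(g, "|") ==
                                  substr(names(structures), 1L, nchar(g) + 1L)]
      if (length(fam_structs) == 0L) next
      mat <- map_introns_to_alignment(aln, fam_structs)
      tables[[g]] <- find_shared_positions(mat, data$groups)
      blocks <- detect_conserved_blocks(
        aln, window = p$block_window, min_identity = p$block_min_identity,
        max_gap = p$block_max_gap, min_length = p$block_min_length)
      tables_blocks[[g]] <- restrict_to_blocks(mat, data$groups, blocks)
      if (nrow(tables[[g]]$positions) > 0L) {
        d <- tables[[g]]$positions
        d$family <- g
        d$in_block <- d$column %in% unlist(lapply(seq_len(nrow(blocks)),
          function(j) blocks$col_start[j]:blocks$col_end[j]))
        detail[[g]] <- d
      }
    }
    agg <- .aggregate_tables(tables, "all_columns")
    agg_b <- .aggregate_tables(tables_blocks, "conserved_blocks")
    .write_tsv(agg, file.path(out, "shared_positions_all.tsv"))
    .write_tsv(agg_b, file.path(out, "shared_positions_blocks.tsv"))
    if (length(detail) > 0L) {
      .write_tsv(do.call(rbind, detail), file.path(out, "positions_detail.tsv"))
    }
    report$stages$shared <- list(
      families = length(tables),
      positions = sum(vapply(tables, `[[`, numeric(1), "total_positions")),
      specific = sum(vapply(tables, function(tb) sum(tb$diagonal), numeric(1))))
    if (!is.null(scenarios) && !is.null(p$focal_groups)) {
      cmp <- compare_transfer_classes(tables, scenarios, p$focal_groups)
      report$stages$shared$class_comparison <- cmp
    }
  }

  if ("context" %in% config$stages && length(structures) > 0L) {
    ctx_rows <- list()
    for (id in sort(names(structures))) {
      s <- structures[[id]]
      if (nrow(s$introns) == 0L || !id %in% names(data$cds)) next
      cds <- data$cds[[id]]
      for (j in seq_len(nrow(s$introns))) {
        o <- s$introns$cds_offset[j]
        if (o < 3L || o >= nchar(cds)) next
        ctx <- extract_context(cds, o)
        ctx_rows[[length(ctx_rows) + 1L]] <- data.frame(
          gene_id = s$gene_id, species_id = s$species_id, cds_offset = o,
          phase = s$introns$phase[j], upstream_tri = ctx$upstream_tri,
          downstream_nt = ctx$downstream_nt,
          proto_splice = is_proto_splice(ctx))
      }
    }
    ctx_df <- if (length(ctx_rows) > 0L) do.call(rbind, ctx_rows) else
      data.frame(gene_id = character(0), species_id = character(0),
                 cds_offset = integer(0), phase = integer(0),
                 upstream_tri = character(0), downstream_nt = character(0),
                 proto_splice = logical(0))
    .write_tsv(ctx_df, file.path(out, "splice_context.tsv"))
    comp_of <- function(id) {
      if (id %in% names(structures)) structures[[id]]$compartment else "nuclear"
    }
    comps <- vapply(names(data$cds), comp_of, character(1))
    usage <- do.call(rbind, lapply(c("nuclear", "mitochondrial"), function(cm) {
      sel <- data$cds[comps == cm]
      if (length(sel) == 0L) return(NULL)
      codon_usage(sel, compartment = cm)
    }))
    .write_tsv(usage, file.path(out, "codon_usage.tsv"))
    report$stages$context <- list(
      introns = nrow(ctx_df),
      proto_splice = sum(ctx_df$proto_splice),
      compartments = length(unique(comps)))
  }

  files <- sort(list.files(out, recursive = TRUE, full.names = TRUE))
  files <- files[basename(files) != "report.json"]
  report$checksums <- setNames(unname(tools::md5sum(files)),
                               sub(paste0("^", out, "/?"), "", files))
  report <- structure(report, class = "run_report")
  jsonlite::write_json(unclass(report), file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  report
}

# Sum per-family shared-position tables into one Tables 1-2-shaped frame.
.aggregate_tables <- function(tables, variant) {
  if (length(tables) == 0L) {
    return(data.frame(group_a = character(0), group_b = character(0),
                      count = integer(0), pct = numeric(0),
                      variant = character(0)))
  }
  groups <- tables[[1L]]$groups
  diag_sum <- Reduce(`+`, lapply(tables, `[[`, "diagonal"))
  shared_sum <- Reduce(`+`, lapply(tables, `[[`, "shared"))
  total <- sum(vapply(tables, `[[`, numeric(1), "total_positions"))
  rows <- list()
  for (a in groups) {
    rows[[length(rows) + 1L]] <- data.frame(
      group_a = a, group_b = a, count = as.integer(diag_sum[a]),
      pct = if (total > 0) 100 * diag_sum[a] / total else NA_real_,
      variant = variant)
  }
  for (i in seq_along(groups)) for (j in seq_along(groups)) {
    if (j <= i) next
    a <- groups[i]; b <- groups[j]
    rows[[length(rows) + 1L]] <- data.frame(
      group_a = a, group_b = b, count = shared_sum[a, b],
      pct = if (total > 0) 100 * shared_sum[a, b] / total else NA_real_,
      variant = variant)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  for (st in names(x$stages)) {
    fields <- x$stages[[st]]
    flat <- fields[!vapply(fields, is.list, logical(1))]
    cat(sprintf("  %s: %s\n", st,
                paste(names(flat), unlist(flat), sep = "=", collapse = ", ")))
  }
  if (!is.null(x$truth_comparison)) {
    tc <- x$truth_comparison
    cat(sprintf("  truth: planted=%d recovered=%d false_positives=%d recall=%.3f\n",
                tc$planted, tc$recovered, tc$false_positives, tc$recall))
  }
  invisible(x)
}
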