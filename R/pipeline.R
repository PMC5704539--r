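#' Pipeline configuration
#'
#' Collects every knob of the end-to-end workflow in one flat object so a
#' run is reproducible from its config alone. Optional stages (host
#' screen, anchor filter, organelle screen) are enabled by supplying their
#' inputs and can be disabled individually, e.g. for study groups without
#' contamination concerns.
#'
#' @param unigenes focal sequence records (all taxa, `taxon` column set).
#' @param reference either a prebuilt reference-gene tibble, or a list
#'   with elements `primary`, `scg_db` and optionally `secondary` to run
#'   the reference builder.
#' @param gene_models gene-model tibble ([read_gene_models()]) or a GFF3
#'   path.
#' @param mode homology search mode, `"gapped"` or `"ungapped"`.
#' @param thresholds [filter_thresholds()] for COS assignment.
#' @param max_evalue search reporting cutoff.
#' @param hits optional precomputed hit tibble (or outfmt-6 TSV path) to
#'   inject in place of the internal search.
#' @param host_db,host_identity,host_taxa host screen inputs (`NULL`
#'   host_db skips the stage).
#' @param paralog_overlap subject-coordinate overlap cutoff in aa.
#' @param anchor anchor taxon (`NULL` disables anchor filtering and the
#'   anchor bait-yield filter).
#' @param aligner `"internal"` or `"mafft"`.
#' @param min_exon_len minimum degapped exon length in bp.
#' @param tiling [tiling_params()].
#' @param min_baits minimum anchor-taxon baits per retained locus.
#' @param cluster_identity redundancy-clustering cutoff in percent.
#' @param organelle_db,organelle_identity organelle screen inputs (`NULL`
#'   db skips the stage).
#' @param out_dir optional output directory for all artifacts.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(unigenes, reference, gene_models = NULL,
                            mode = c("gapped", "ungapped"),
                            thresholds = filter_thresholds(),
                            max_evalue = 1e-10, hits = NULL,
                            host_db = NULL, host_identity = 95,
                            host_taxa = NULL, paralog_overlap = 30,
                            anchor = NULL,
                            aligner = c("internal", "mafft"),
                            min_exon_len = 120, tiling = tiling_params(),
                            min_baits = 4L, cluster_identity = 90,
                            organelle_db = NULL, organelle_identity = 90,
                            out_dir = NULL) {
  structure(list(
    unigenes = unigenes, reference = reference, gene_models = gene_models,
    mode = match.arg(mode), thresholds = thresholds,
    max_evalue = max_evalue, hits = hits, host_db = host_db,
    host_identity = host_identity, host_taxa = host_taxa,
    paralog_overlap = paralog_overlap, anchor = anchor,
    aligner = match.arg(aligner), min_exon_len = min_exon_len,
    tiling = tiling, min_baits = min_baits,
    cluster_identity = cluster_identity, organelle_db = organelle_db,
    organelle_identity = organelle_identity, out_dir = out_dir),
    class = "pipeline_config")
}

#' Validate a pipeline configuration
#'
#' Checks paths, taxon labels and threshold ranges, aggregating every
#' problem instead of failing on the first.
#'
#' @param config a [pipeline_config()].
#' @return Character vector of error messages (empty when valid).
#' @export
validate_config <- function(config) {
  errs <- character(0)
  push <- function(msg) errs <<- c(errs, msg)
  if (!inherits(config, "pipeline_config")) {
    return("not a pipeline_config object")
  }
  if (!is.data.frame(config$unigenes) || nrow(config$unigenes) == 0) {
    push("unigenes: no focal sequences supplied")
  }
  if (!config$mode %in% c("gapped", "ungapped")) push("mode: unknown mode")
  if (!inherits(config$thresholds, "filter_thresholds")) {
    push("thresholds: not a filter_thresholds object")
  }
  if (!inherits(config$tiling, "tiling_params")) {
    push("tiling: not a tiling_params object")
  }
  if (is.data.frame(config$reference)) {
    if (!all(c("gene_id", "cds", "protein") %in% names(config$reference))) {
      push("reference: prebuilt reference lacks gene_id/cds/protein columns")
    }
  } else if (is.list(config$reference)) {
    if (is.null(config$reference$primary)) {
      push("reference: builder input lacks a `primary` species")
    }
    if (is.null(config$reference$scg_db)) {
      push("reference: builder input lacks `scg_db`")
    }
  } else {
    push("reference: supply a reference-gene tibble or builder inputs")
  }
  if (!is.null(config$anchor) && is.data.frame(config$unigenes) &&
      !config$anchor %in% config$unigenes$taxon) {
    push(paste0("anchor: taxon '", config$anchor,
                "' absent from unigenes"))
  }
  if (!is.null(config$host_taxa) && is.null(config$host_db)) {
    push("host_db: host_taxa given but no host database supplied")
  }
  if (config$paralog_overlap < 0) push("paralog_overlap: must be >= 0")
  for (f in c("host_identity", "cluster_identity", "organelle_identity")) {
    v <- config[[f]]
    if (!is.numeric(v) || v <= 0 || v > 100) {
      push(paste0(f, ": must be a percentage in (0, 100]"))
    }
  }
  if (is.character(config$gene_models) && !file.exists(config$gene_models)) {
    push(paste0("gene_models: file not found: ", config$gene_models))
  }
  if (is.character(config$hits) && !file.exists(config$hits)) {
    push(paste0("hits: file not found: ", config$hits))
  }
  errs
}

#' Run the full bait-design workflow
#'
#' Executes, in order: reference build (skipped for a prebuilt reference),
#' translated homology search (skipped when hits are injected), best-hit
#' COS assignment, host screen (optional), paralog removal, locus
#' bundling, anchor filter (optional), locus alignment, exon projection,
#' and bait design (tiling, anchor yield filter, redundancy clustering,
#' organelle screen). The returned report carries one row per stage with
#' input/output counts; filtering stages never increase counts.
#'
#' @param config a validated [pipeline_config()].
#' @return List with `report` (stage tibble), `reference`, `hits`,
#'   `assignments`, `bundles`, `exon_blocks`, `baits`, `retained_loci`,
#'   `dropped_organelle_loci` and `summary` (per-taxon locus/CDS/probe
#'   statistics).
#' @export
run_pipeline <- function(config) {
  errs <- validate_config(config)
  if (length(errs)) {
    stop("invalid pipeline config:\n  ", paste(errs, collapse = "\n  "),
         call. = FALSE)
  }
  report <- list()
  note <- function(stage, status, n_in, n_out, unit) {
    report[[length(report) + 1L]] <<- tibble(
      stage = stage, status = status, n_in = as.integer(n_in),
      n_out = as.integer(n_out), unit = unit)
  }

  # 1. reference
  if (is.data.frame(config$reference)) {
    reference <- config$reference
    note("reference_build", "skipped", nrow(reference), nrow(reference),
         "genes")
  } else {
    n_in <- nrow(config$reference$primary) +
      if (!is.null(config$reference$secondary))
        nrow(config$reference$secondary) else 0L
    reference <- build_reference(config$reference$primary,
                                 config$reference$scg_db,
                                 secondary = config$reference$secondary,
                                 thresholds = config$thresholds,
                                 mode = config$mode)
    note("reference_build", "run", n_in, nrow(reference), "genes")
  }

  # 2. search (or injected hits)
  unigenes <- config$unigenes
  if (!is.null(config$hits)) {
    hits <- if (is.character(config$hits)) read_hits(config$hits)
            else config$hits
    note("homology_search", "skipped", nrow(unigenes), nrow(hits), "hits")
  } else {
    hits <- search_homology(unigenes, ref_protein_records(reference),
                            mode = config$mode, program = "blastx",
                            max_evalue = config$max_evalue)
    note("homology_search", "run", nrow(unigenes), nrow(hits), "hits")
  }

  # 3. best-hit COS assignment
  assignments <- best_hit_per_query(hits, config$thresholds,
                                    unigenes = unigenes)
  note("cos_assignment", "run", nrow(unigenes), nrow(assignments),
       "unigenes")

  # 4. host screen
  if (is.null(config$host_db)) {
    note("host_screen", "skipped", nrow(assignments), nrow(assignments),
         "unigenes")
  } else {
    n_in <- nrow(assignments)
    assignments <- remove_host_like(assignments, unigenes, config$host_db,
                                    min_identity = config$host_identity,
                                    mode = config$mode,
                                    taxa = config$host_taxa)
    note("host_screen", "run", n_in, nrow(assignments), "unigenes")
  }

  # 5. paralog removal
  n_in <- nrow(assignments)
  assignments <- remove_paralogs(assignments, config$paralog_overlap)
  note("paralog_removal", "run", n_in, nrow(assignments), "unigenes")

  # 6. bundling
  bundles <- bundle_by_reference(assignments, unigenes, reference)
  note("locus_bundling", "run", nrow(assignments), length(bundles), "loci")

  # 7. anchor filter
  if (is.null(config$anchor)) {
    note("anchor_filter", "skipped", length(bundles), length(bundles),
         "loci")
  } else {
    n_in <- length(bundles)
    bundles <- require_anchor_taxon(bundles, config$anchor,
                                    known_taxa = unique(unigenes$taxon))
    note("anchor_filter", "run", n_in, length(bundles), "loci")
  }

  # 8. alignment
  bundles <- align_loci(bundles, aligner = config$aligner)
  note("locus_alignment", "run", length(bundles), length(bundles), "loci")

  # 9. exon projection
  models <- config$gene_models
  if (is.character(models)) models <- read_gene_models(models)
  if (is.null(models)) {
    models <- tibble(gene_id = character(), exon_lengths = list())
  }
  exon_blocks <- split_exons_all(bundles, models,
                                 min_len = config$min_exon_len)
  note("exon_projection", "run", length(bundles), nrow(exon_blocks),
       "exon sequences")

  # 10. bait design
  baits <- design_baits(exon_blocks, config$tiling)
  n_raw <- nrow(baits)
  yield <- filter_low_yield_loci(baits, config$anchor, config$min_baits)
  baits <- yield$baits
  baits <- cluster_redundant_baits(baits, config$cluster_identity,
                                   taxon_order = unique(unigenes$taxon))
  org <- drop_organelle_loci(baits, config$organelle_db,
                             identity = config$organelle_identity,
                             max_evalue = config$max_evalue)
  baits <- org$baits
  note("bait_design", "run", n_raw, nrow(baits), "baits")

  report <- dplyr::bind_rows(report)
  result <- list(report = report, reference = reference, hits = hits,
                 assignments = assignments, bundles = bundles,
                 exon_blocks = exon_blocks, baits = baits,
                 retained_loci = sort(unique(baits$ref_gene_id)),
                 dropped_organelle_loci = org$dropped_loci)
  result$summary <- summarize_run(result)
  if (!is.null(config$out_dir)) write_pipeline_outputs(result, config)
  result
}

#' Per-taxon run summary
#'
#' The headline statistics of a finished run, per focal taxon: number of
#' retained loci the taxon contributes to, average length of its retained
#' unigenes, average length of the aligned (conserved orthologous) region
#' the search recovered, number and average length of its exon (CDS)
#' sequences, and its probe count. The aligned-region average is the
#' statistic the search mode acts on: ungapped searches truncate or miss
#' indel-bearing loci, gapped searches span them.
#'
#' @param result the list returned by [run_pipeline()].
#' @return A tibble with one row per taxon.
#' @export
summarize_run <- function(result) {
  loci <- result$retained_loci
  a <- result$assignments[result$assignments$ref_gene_id %in% loci, ,
                          drop = FALSE]
  e <- result$exon_blocks[result$exon_blocks$ref_gene_id %in% loci, ,
                          drop = FALSE]
  b <- result$baits
  taxa <- sort(unique(a$taxon))
  dplyr::bind_rows(lapply(taxa, function(t) {
    at <- a[a$taxon == t, ]
    et <- e[e$taxon == t, ]
    tibble(taxon = t,
           n_loci = length(unique(at$ref_gene_id)),
           avg_locus_len = round(mean(at$qlen), 1),
           avg_aligned_len = round(mean(abs(at$qend - at$qstart) + 1), 1),
           n_cds = nrow(et),
           avg_cds_len = if (nrow(et)) round(mean(et$width), 1) else NA_real_,
           n_probes = sum(b$taxon == t))
  }))
}

write_pipeline_outputs <- function(result, config) {
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  write_tabular_hits(result$hits, file.path(out, "hits.tsv"))
  utils::write.table(result$assignments, file.path(out, "assignments.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(result$report, file.path(out, "report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(report = result$report, summary = result$summary,
         retained_loci = result$retained_loci,
         dropped_organelle_loci = result$dropped_organelle_loci),
    file.path(out, "report.json"), dataframe = "rows", auto_unbox = TRUE,
    digits = NA, pretty = TRUE)
  write_baits_fasta(result$baits, file.path(out, "baits.fa"))
  utils::write.table(result$baits, file.path(out, "baits_manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(result$exon_blocks[, setdiff(names(result$exon_blocks),
                                                  "seq")],
                     file.path(out, "exons.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  loci_dir <- file.path(out, "loci")
  dir.create(loci_dir, showWarnings = FALSE)
  for (b in result$bundles) {
    d <- file.path(loci_dir, b$ref_gene_id)
    dir.create(d, showWarnings = FALSE)
    write_fasta(seq_records(c(paste0("ref|", b$ref_gene_id),
                              b$members$unigene),
                            c(b$ref_cds, b$members$seq)),
                file.path(d, "sequences.fa"))
    if (!is.null(b$alignment)) {
      writeLines(paste0(">", b$alignment$row_id, "\n", b$alignment$seq),
                 file.path(d, "aligned.fa"))
    }
  }
  invisible(out)
}
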