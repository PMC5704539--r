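#' Reference gene tables
#'
#' A reference species contributes, per gene, a protein and its CDS. Genes
#' travel as a tibble with columns `gene_id`, `cds`, `protein` and
#' `species_role` (`"primary"` or `"secondary"`). When `protein` is omitted
#' it is obtained by translating the CDS. Translated CDS length must agree
#' with the protein length to within one residue (stop-codon handling).
#'
#' @param gene_id unique gene identifiers.
#' @param cds coding sequences (nucleotide strings).
#' @param protein protein sequences; translated from `cds` when `NULL`.
#' @param species_role `"primary"` or `"secondary"`.
#' @return A reference-gene tibble.
#' @export
reference_genes <- function(gene_id, cds, protein = NULL,
                            species_role = c("primary", "secondary")) {
  species_role <- match.arg(species_role)
  cds <- toupper(cds)
  if (is.null(protein)) {
    protein <- vapply(cds, function(s) sub("\\*$", "", translate_nt(s, 1L)),
                      character(1), USE.NAMES = FALSE)
  }
  protein <- toupper(protein)
  if (anyDuplicated(gene_id)) {
    stop("duplicate gene ids in reference set", call. = FALSE)
  }
  ok <- abs(nchar(cds) %/% 3L - nchar(protein)) <= 1L
  if (!all(ok)) {
    stop("CDS/protein length mismatch for gene(s): ",
         paste(head(gene_id[!ok], 3), collapse = ", "), call. = FALSE)
  }
  tibble(gene_id = as.character(gene_id), cds = cds, protein = protein,
         species_role = species_role)
}

#' Load one reference species from FASTA files
#'
#' Reads the protein and CDS FASTA of a reference species and pairs records
#' by id (FASTA ids must match between the two files).
#'
#' @param protein_fa,cds_fa FASTA paths.
#' @param species_role `"primary"` or `"secondary"`.
#' @return A reference-gene tibble.
#' @export
read_reference_species <- function(protein_fa, cds_fa,
                                   species_role = c("primary", "secondary")) {
  species_role <- match.arg(species_role)
  prot <- read_fasta(protein_fa, kind = "protein")
  cds <- read_fasta(cds_fa, kind = "nucleotide")
  missing <- setdiff(prot$id, cds$id)
  if (length(missing)) {
    stop("genes present in protein FASTA but absent from CDS FASTA: ",
         paste(head(missing, 3), collapse = ", "), call. = FALSE)
  }
  cds_seq <- setNames(cds$seq, cds$id)[prot$id]
  reference_genes(prot$id, cds_seq, prot$seq, species_role = species_role)
}

ref_cds_records <- function(genes) {
  seq_records(genes$gene_id, genes$cds, kind = "nucleotide")
}

ref_protein_records <- function(genes) {
  seq_records(genes$gene_id, genes$protein, kind = "protein")
}

#' Single-copy screen against a known SCG set
#'
#' A candidate reference gene is kept only when its threshold-passing hit
#' set against the single-copy-gene database has cardinality exactly one:
#' similar enough to a known SCG, but matching just that one. Genes hitting
#' zero or several SCGs are dropped.
#'
#' @param genes a reference-gene tibble.
#' @param scg_db protein sequence-record tibble of known single-copy genes.
#' @param thresholds a [filter_thresholds()] object.
#' @param mode search mode (default gapped).
#' @return The subset of `genes` with exactly one passing SCG match.
#' @export
find_single_match_genes <- function(genes, scg_db,
                                    thresholds = filter_thresholds(),
                                    mode = "gapped") {
  if (nrow(genes) == 0) return(genes)
  hits <- search_homology(ref_cds_records(genes), scg_db, mode = mode,
                          program = "blastx")
  hits <- hits[hits_passing(hits, thresholds), , drop = FALSE]
  n_match <- table(unique(hits[c("qseqid", "sseqid")])$qseqid)
  keep <- names(n_match)[n_match == 1L]
  genes[genes$gene_id %in% keep, , drop = FALSE]
}

#' Remove within-species duplicates
#'
#' All-vs-all search among candidate genes of one species; any gene with a
#' threshold-passing non-self hit is removed, and both members of a similar
#' pair go (retaining either would risk a hidden paralog).
#'
#' @inheritParams find_single_match_genes
#' @return The subset of `genes` with no non-self similarity.
#' @export
self_dedup <- function(genes, thresholds = filter_thresholds(),
                       mode = "gapped") {
  if (nrow(genes) < 2) return(genes)
  hits <- search_homology(ref_cds_records(genes), ref_protein_records(genes),
                          mode = mode, program = "blastx")
  hits <- hits[hits$qseqid != hits$sseqid & hits_passing(hits, thresholds), ,
               drop = FALSE]
  dup <- unique(c(hits$qseqid, hits$sseqid))
  genes[!(genes$gene_id %in% dup), , drop = FALSE]
}

#' Merge primary and secondary reference sets
#'
#' Every primary gene survives; a secondary gene is added only when it has
#' no threshold-passing hit against any primary gene, keeping the merged
#' reference non-redundant.
#'
#' @param primary,secondary reference-gene tibbles that already passed the
#'   single-match and self-dedup screens.
#' @inheritParams find_single_match_genes
#' @return The merged reference-gene tibble with `species_role` recorded.
#' @export
merge_references <- function(primary, secondary,
                             thresholds = filter_thresholds(),
                             mode = "gapped") {
  primary$species_role <- "primary"
  if (is.null(secondary) || nrow(secondary) == 0) return(primary)
  clash <- intersect(primary$gene_id, secondary$gene_id)
  if (length(clash)) {
    stop("gene id collision between reference species (namespace the ids): ",
         paste(head(clash, 3), collapse = ", "), call. = FALSE)
  }
  secondary$species_role <- "secondary"
  hits <- search_homology(ref_cds_records(secondary),
                          ref_protein_records(primary),
                          mode = mode, program = "blastx")
  hits <- hits[hits_passing(hits, thresholds), , drop = FALSE]
  redundant <- unique(hits$qseqid)
  dplyr::bind_rows(primary,
                   secondary[!(secondary$gene_id %in% redundant), ,
                             drop = FALSE])
}

#' Build the non-redundant SCG reference database
#'
#' Runs the full reference-construction chain: single-match screening of
#' each species against the SCG database, within-species deduplication, and
#' the redundancy-aware merge of primary and secondary species.
#'
#' @param primary,secondary reference-gene tibbles (secondary optional).
#' @param scg_db protein sequence-record tibble of known single-copy genes.
#' @inheritParams find_single_match_genes
#' @return The merged reference-gene tibble.
#' @export
build_reference <- function(primary, scg_db, secondary = NULL,
                            thresholds = filter_thresholds(),
                            mode = "gapped") {
  p <- self_dedup(find_single_match_genes(primary, scg_db, thresholds, mode),
                  thresholds, mode)
  s <- NULL
  if (!is.null(secondary) && nrow(secondary) > 0) {
    s <- self_dedup(find_single_match_genes(secondary, scg_db, thresholds,
                                            mode),
                    thresholds, mode)
  }
  merge_references(p, s, thresholds, mode)
}
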