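#' Ortholog-assignment thresholds
#'
#' The stringency triple applied when turning raw translated-search hits
#' into conserved-orthologous-sequence (COS) assignments: percent identity
#' at least 40, E-value at most 1e-20, and an alignment length of at least
#' 100 amino-acid positions (300 bp). All bounds are inclusive.
#'
#' @param min_identity minimum percent identity (0-100).
#' @param max_evalue maximum E-value.
#' @param min_aln_len minimum alignment length in amino-acid columns.
#' @return A `filter_thresholds` list.
#' @export
filter_thresholds <- function(min_identity = 40, max_evalue = 1e-20,
                              min_aln_len = 100) {
  if (min_identity <= 0 || max_evalue <= 0 || min_aln_len <= 0) {
    stop("all thresholds must be strictly positive", call. = FALSE)
  }
  structure(list(min_identity = min_identity, max_evalue = max_evalue,
                 min_aln_len = min_aln_len), class = "filter_thresholds")
}

hits_passing <- function(hits, thresholds) {
  hits$pident >= thresholds$min_identity &
    hits$evalue <= thresholds$max_evalue &
    hits$length >= thresholds$min_aln_len
}

#' Best-hit COS assignment
#'
#' Per query unigene, discard hits failing the thresholds and retain the
#' single best survivor: highest bitscore, ties broken by lower E-value,
#' then longer alignment, then lexicographic subject id. Queries with no
#' passing hit are absent from the output.
#'
#' @param hits a hit tibble from [search_homology()] or [read_hits()]
#'   (translated search: `length` in aa units).
#' @param thresholds a [filter_thresholds()] object.
#' @param unigenes optional sequence-record tibble; when given, `taxon` and
#'   `qlen` columns are attached from it.
#' @return An assignment tibble: one row per retained unigene with columns
#'   `unigene`, `taxon`, `ref_gene_id` and the retained hit fields.
#' @export
best_hit_per_query <- function(hits, thresholds = filter_thresholds(),
                               unigenes = NULL) {
  keep <- hits[hits_passing(hits, thresholds), , drop = FALSE]
  keep <- dplyr::arrange(keep, .data$qseqid, dplyr::desc(.data$bitscore),
                         .data$evalue, dplyr::desc(.data$length),
                         .data$sseqid)
  best <- dplyr::distinct(keep, .data$qseqid, .keep_all = TRUE)
  out <- tibble(unigene = best$qseqid, ref_gene_id = best$sseqid,
                pident = best$pident, length = best$length,
                evalue = best$evalue, bitscore = best$bitscore,
                qstart = best$qstart, qend = best$qend,
                sstart = best$sstart, send = best$send)
  if (!is.null(unigenes)) {
    meta <- tibble(unigene = unigenes$id, taxon = unigenes$taxon,
                   qlen = nchar(unigenes$seq))
    out <- dplyr::left_join(out, meta, by = "unigene")
  } else if (!"taxon" %in% names(out)) {
    out$taxon <- NA_character_
  }
  dplyr::relocate(out, "unigene", "taxon", "ref_gene_id")
}

#' Remove host-like assignments
#'
#' Transcriptome builds of parasitic plants can contain transcripts of the
#' host the parasite was grown on. Assigned unigenes are searched
#' (nucleotide, both strands) against a host sequence database and removed
#' when any hit reaches the identity cutoff (default 95 percent). The step
#' is skippable when contamination is not a concern.
#'
#' @param assignments an assignment tibble from [best_hit_per_query()].
#' @param unigenes sequence-record tibble holding the assigned unigenes.
#' @param host_db nucleotide sequence-record tibble of host sequences.
#' @param min_identity removal cutoff in percent identity (inclusive).
#' @param mode search mode for the screen (gapped by default).
#' @param taxa optional taxa to screen; others pass through untouched.
#' @return The assignment tibble minus host-like rows.
#' @export
remove_host_like <- function(assignments, unigenes, host_db,
                             min_identity = 95, mode = "gapped",
                             taxa = NULL) {
  if (is.null(host_db) || nrow(host_db) == 0) {
    warning("empty host database: host screen left assignments unchanged")
    return(assignments)
  }
  screened <- assignments
  if (!is.null(taxa)) {
    screened <- screened[screened$taxon %in% taxa, , drop = FALSE]
  }
  if (nrow(screened) == 0) return(assignments)
  qs <- unigenes[unigenes$id %in% screened$unigene, , drop = FALSE]
  hits <- search_homology(qs, host_db, mode = mode, program = "blastn")
  host_like <- unique(hits$qseqid[hits$pident >= min_identity])
  assignments[!(assignments$unigene %in% host_like), , drop = FALSE]
}

#' Remove putative paralogs by reference-overlap
#'
#' Two or more unigenes of one focal taxon assigned to the same reference
#' gene are fragments of one transcript when they occupy different parts of
#' the reference, but putative paralogs when their reference (subject)
#' intervals overlap. Whenever any pair within a (taxon, reference gene)
#' group overlaps by more than `overlap_cutoff` amino acids, the entire
#' group is removed for that taxon; the locus itself may persist through
#' other taxa. Singleton groups always pass.
#'
#' @param assignments an assignment tibble.
#' @param overlap_cutoff maximum tolerated subject-coordinate overlap in
#'   amino acids (default 30); overlaps strictly greater trigger removal.
#' @return The assignment tibble minus flagged groups.
#' @export
remove_paralogs <- function(assignments, overlap_cutoff = 30) {
  if (overlap_cutoff < 0) {
    stop("`overlap_cutoff` must be non-negative", call. = FALSE)
  }
  if (nrow(assignments) == 0) return(assignments)
  s_lo <- pmin(assignments$sstart, assignments$send)
  s_hi <- pmax(assignments$sstart, assignments$send)
  grp <- paste(assignments$taxon, assignments$ref_gene_id, sep = "\r")
  drop_grp <- vapply(split(seq_len(nrow(assignments)), grp), function(ix) {
    if (length(ix) < 2) return(FALSE)
    for (a in seq_along(ix)[-length(ix)]) {
      for (b in seq((a + 1), length(ix))) {
        ov <- min(s_hi[ix[a]], s_hi[ix[b]]) - max(s_lo[ix[a]], s_lo[ix[b]]) + 1L
        if (ov > overlap_cutoff) return(TRUE)
      }
    }
    FALSE
  }, logical(1))
  assignments[!drop_grp[grp], , drop = FALSE]
}
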