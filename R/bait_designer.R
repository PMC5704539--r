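#' Bait tiling parameters
#'
#' Defaults encode the published layout: 120-bp baits at 2x tiling (step =
#' half the bait length, i.e., consecutive baits overlap by 50%), plus one
#' terminal bait flush with the 3' end whenever its overlap with the last
#' regular bait does not exceed 80 bp. The terminal bait makes better use
#' of exon 3' ends without undue redundancy: a 160-bp fragment still yields
#' two baits overlapping by 80 bp.
#'
#' @param bait_len bait length in bp.
#' @param step tiling step in bp (`bait_len / 2` gives 2x tiling).
#' @param max_overlap maximum tolerated overlap of the terminal bait with
#'   the preceding regular bait, in bp.
#' @return A `tiling_params` list.
#' @export
tiling_params <- function(bait_len = 120L, step = 60L, max_overlap = 80L) {
  bait_len <- as.integer(bait_len)
  step <- as.integer(step)
  max_overlap <- as.integer(max_overlap)
  if (bait_len <= 0 || step <= 0 || step > bait_len) {
    stop("need 0 < step <= bait_len", call. = FALSE)
  }
  if (max_overlap < 0 || max_overlap >= bait_len) {
    stop("need 0 <= max_overlap < bait_len", call. = FALSE)
  }
  structure(list(bait_len = bait_len, step = step, max_overlap = max_overlap),
            class = "tiling_params")
}

#' Tile baits over one gap-free sequence
#'
#' Regular baits start at offsets 0, step, 2*step, ... while they fit; if
#' the last regular bait does not reach the 3' end, one terminal bait is
#' placed flush with the end provided its overlap with the last regular
#' bait is at most `max_overlap`. Sequences shorter than the bait yield
#' nothing.
#'
#' @param seq a gap-free nucleotide string (or its length, for counting).
#' @param params a [tiling_params()] object.
#' @return Tibble with 0-based `start` offsets and bait `sequence`s (empty
#'   when only a length was supplied).
#' @examples
#' nrow(tile_baits(strrep("A", 160)))  # 2 baits overlapping by 80 bp
#' @export
tile_baits <- function(seq, params = tiling_params()) {
  L <- if (is.character(seq)) nchar(seq) else as.integer(seq)
  bl <- params$bait_len
  starts <- integer(0)
  if (L >= bl) {
    starts <- seq.int(0L, L - bl, by = params$step)
    last_end <- starts[length(starts)] + bl
    if (last_end < L) {
      term <- L - bl
      if (last_end - term <= params$max_overlap) starts <- c(starts, term)
    }
  }
  if (is.character(seq)) {
    if (grepl("-", seq, fixed = TRUE)) {
      stop("tile_baits requires a gap-free sequence", call. = FALSE)
    }
    tibble(start = starts,
           sequence = substring(seq, starts + 1L, starts + bl))
  } else {
    tibble(start = starts, sequence = character(length(starts)))
  }
}

#' Tile baits over a table of exon blocks
#'
#' Applies [tile_baits()] to every (locus, exon, taxon) sequence of an
#' exon-block table and keeps provenance on each bait.
#'
#' @param exon_blocks exon-block tibble from [split_exons_all()].
#' @param params a [tiling_params()] object.
#' @return A bait tibble: `ref_gene_id`, `exon_index`, `taxon`, `unigene`,
#'   0-based `start` within the degapped exon sequence, and `sequence`.
#' @export
design_baits <- function(exon_blocks, params = tiling_params()) {
  rows <- lapply(seq_len(nrow(exon_blocks)), function(i) {
    b <- tile_baits(exon_blocks$seq[i], params)
    if (nrow(b) == 0) return(NULL)
    tibble(ref_gene_id = exon_blocks$ref_gene_id[i],
           exon_index = exon_blocks$exon_index[i],
           taxon = exon_blocks$taxon[i],
           unigene = exon_blocks$unigene[i],
           start = b$start, sequence = b$sequence)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble(ref_gene_id = character(), exon_index = integer(),
                  taxon = character(), unigene = character(),
                  start = integer(), sequence = character())
  }
  out
}

#' Drop loci with too few anchor-taxon baits
#'
#' A locus is worth capturing only when the best-assembled (anchor) taxon
#' contributes at least `min_baits` baits across its exons -- with the
#' default four 120-bp baits this corresponds to a minimum of 280 bp of
#' usable sequence. All baits (every taxon) of a dropped locus are
#' discarded. With `anchor = NULL` the filter is disabled.
#'
#' @param baits a bait tibble from [design_baits()].
#' @param anchor anchor taxon label, or `NULL` to keep every locus.
#' @param min_baits minimum anchor-taxon bait count per locus.
#' @return List with `baits` (filtered tibble) and `retained_loci`
#'   (character vector of surviving reference gene ids).
#' @export
filter_low_yield_loci <- function(baits, anchor, min_baits = 4L) {
  if (is.null(anchor)) {
    return(list(baits = baits, retained_loci = unique(baits$ref_gene_id)))
  }
  counts <- table(baits$ref_gene_id[baits$taxon == anchor])
  retained <- names(counts)[counts >= min_baits]
  list(baits = baits[baits$ref_gene_id %in% retained, , drop = FALSE],
       retained_loci = retained)
}

# position-wise identity of two equal-length gap-free sequences, in percent;
# ambiguity codes never count as matches
bait_identity <- function(a, b) {
  ac <- strsplit(a, "", fixed = TRUE)[[1]]
  bc <- strsplit(b, "", fixed = TRUE)[[1]]
  100 * sum(ac == bc & ac %in% .NT_UNAMBIG) / length(ac)
}

#' Remove redundant baits by greedy identity clustering
#'
#' cd-hit-style clustering specialised to equal-length probes: baits are
#' sorted deterministically (locus, exon, taxon order as supplied, start),
#' each bait joins the first cluster whose representative it matches at or
#' above the identity cutoff -- ungapped position-wise comparison over the
#' bait length, in forward and reverse-complement orientation -- otherwise
#' it founds a new cluster. Only representatives are returned, so near-
#' identical probes shared among taxa collapse to one.
#'
#' @param baits a bait tibble.
#' @param identity redundancy cutoff in percent (default 90; two 120-mers
#'   differing at 12 positions are 90% identical and collapse).
#' @param taxon_order optional taxon ordering used in the deterministic
#'   sort (defaults to order of appearance).
#' @return The bait tibble reduced to cluster representatives.
#' @export
cluster_redundant_baits <- function(baits, identity = 90,
                                    taxon_order = NULL) {
  if (nrow(baits) <= 1) return(baits)
  if (is.null(taxon_order)) taxon_order <- unique(baits$taxon)
  ord <- order(baits$ref_gene_id, baits$exon_index,
               match(baits$taxon, taxon_order), baits$start)
  b <- baits[ord, , drop = FALSE]
  enc <- function(x) {
    m <- matrix(match(unlist(strsplit(x, "", fixed = TRUE)), .NT_UNAMBIG),
                nrow = length(x), byrow = TRUE)
    m[is.na(m)] <- 5L
    m - 1L
  }
  rep_of <- cpp_greedy_cluster(enc(b$sequence), enc(revcomp(b$sequence)),
                               identity)
  b[rep_of == seq_len(nrow(b)), , drop = FALSE]
}

#' Drop loci whose baits match an organelle genome
#'
#' Plastid DNA is vastly overrepresented in total-DNA extracts, so a locus
#' containing even one bait that matches a plastid (or mitochondrial)
#' genome at or above the identity cutoff would soak up off-target reads;
#' all baits of such loci are removed. With no database the input passes
#' through with a warning.
#'
#' @param baits a bait tibble.
#' @param organelle_db nucleotide sequence-record tibble (plastid and/or
#'   mitochondrial genomes), or `NULL`.
#' @param identity flagging cutoff in percent identity (default 90).
#' @param max_evalue reporting cutoff of the nucleotide screen.
#' @return List with `baits` (filtered) and `dropped_loci`.
#' @export
drop_organelle_loci <- function(baits, organelle_db, identity = 90,
                                max_evalue = 1e-10) {
  if (is.null(organelle_db) || nrow(organelle_db) == 0) {
    if (!is.null(organelle_db)) {
      warning("empty organelle database: no loci screened")
    }
    return(list(baits = baits, dropped_loci = character(0)))
  }
  if (nrow(baits) == 0) return(list(baits = baits, dropped_loci = character(0)))
  qs <- seq_records(paste0("bait", seq_len(nrow(baits))), baits$sequence)
  hits <- search_homology(qs, organelle_db, mode = "gapped",
                          program = "blastn", max_evalue = max_evalue)
  flagged <- hits$qseqid[hits$pident >= identity]
  ix <- as.integer(sub("^bait", "", flagged))
  dropped <- unique(baits$ref_gene_id[ix])
  list(baits = baits[!(baits$ref_gene_id %in% dropped), , drop = FALSE],
       dropped_loci = dropped)
}

#' Write baits to FASTA
#'
#' Headers carry full provenance as `refgene|exon|taxon|unigene|start`
#' (0-based start within the degapped exon sequence). The source unigene is
#' part of the header so that two fragments of one taxon tiling the same
#' exon cannot collide.
#'
#' @param baits a bait tibble.
#' @param path output file path.
#' @export
write_baits_fasta <- function(baits, path) {
  ids <- sprintf("%s|%d|%s|%s|%d", baits$ref_gene_id, baits$exon_index,
                 baits$taxon, baits$unigene, baits$start)
  writeLines(paste0(">", ids, "\n", baits$sequence), path)
  invisible(path)
}
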