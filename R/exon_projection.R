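#' Parse reference gene models from GFF3
#'
#' Extracts, per gene, the ordered CDS-segment lengths of one mRNA in
#' transcript orientation: segments are sorted by genomic start and the
#' order reversed for minus-strand genes, so lengths always run 5' to 3' of
#' the transcript. CDS features (not `exon` features) are used because the
#' reference sequences are coding sequences; when a gene has several mRNAs
#' the one with the longest summed CDS is chosen (ties broken by mRNA id).
#'
#' @param gff3 path to a GFF3 file, or a `GRanges` already imported.
#' @param cds_lengths optional named vector of reference CDS lengths (bp);
#'   when given, a gene whose segment lengths do not sum to its CDS length
#'   is a model error.
#' @return A tibble with columns `gene_id`, `mrna_id`, `strand`, `n_exons`
#'   and the list-column `exon_lengths` (bp, transcript order).
#' @export
read_gene_models <- function(gff3, cds_lengths = NULL) {
  gr <- if (is.character(gff3)) rtracklayer::import(gff3, format = "gff3")
        else gff3
  type <- as.character(gr$type)
  first_parent <- function(p) {
    vapply(p, function(x) if (length(x)) x[1] else NA_character_, character(1))
  }
  mrna <- gr[type == "mRNA"]
  mrna_gene <- setNames(first_parent(mrna$Parent), mrna$ID)
  cds <- gr[type == "CDS"]
  if (length(cds) == 0) {
    warning("no CDS features in GFF3")
    return(tibble(gene_id = character(), mrna_id = character(),
                  strand = character(), n_exons = integer(),
                  exon_lengths = list()))
  }
  parent <- first_parent(cds$Parent)
  seg <- tibble(parent = parent,
                start = BiocGenerics::start(cds),
                width = BiocGenerics::width(cds),
                strand = as.character(BiocGenerics::strand(cds)))
  per_mrna <- lapply(split(seg, seg$parent), function(d) {
    d <- d[order(d$start), , drop = FALSE]
    lens <- d$width
    if (d$strand[1] == "-") lens <- rev(lens)
    list(lens = lens, strand = d$strand[1], total = sum(d$width))
  })
  gene_of <- function(p) if (p %in% names(mrna_gene)) unname(mrna_gene[p]) else p
  tab <- tibble(mrna_id = names(per_mrna),
                gene_id = vapply(names(per_mrna), gene_of, character(1)),
                total = vapply(per_mrna, `[[`, numeric(1), "total"))
  tab <- dplyr::arrange(tab, .data$gene_id, dplyr::desc(.data$total),
                        .data$mrna_id)
  tab <- dplyr::distinct(tab, .data$gene_id, .keep_all = TRUE)
  out <- tibble(
    gene_id = tab$gene_id,
    mrna_id = tab$mrna_id,
    strand = unname(vapply(per_mrna[tab$mrna_id], `[[`, character(1),
                           "strand")),
    n_exons = unname(vapply(per_mrna[tab$mrna_id], function(x)
      length(x$lens), integer(1))),
    exon_lengths = unname(lapply(per_mrna[tab$mrna_id], `[[`, "lens")))
  if (!is.null(cds_lengths)) {
    known <- intersect(out$gene_id, names(cds_lengths))
    tot <- vapply(out$exon_lengths, sum, numeric(1))
    bad <- known[tot[match(known, out$gene_id)] != cds_lengths[known]]
    if (length(bad)) {
      stop("CDS segment lengths do not sum to the CDS length for gene(s): ",
           paste(head(bad, 3), collapse = ", "), call. = FALSE)
    }
    missing_model <- setdiff(names(cds_lengths), out$gene_id)
    if (length(missing_model)) {
      warning("gene(s) without CDS features skipped: ",
              paste(head(missing_model, 3), collapse = ", "))
    }
  }
  out
}

#' Project reference exon boundaries onto alignment columns
#'
#' Walks the reference row of a locus alignment, counting non-gap
#' characters, and maps each cumulative exon end (reference CDS
#' coordinates) to the alignment column holding that reference residue.
#' The final breakpoint is extended to the alignment width so that member
#' insertions beyond the reference 3' end stay attached to the last exon
#' and the slices tile the alignment exactly.
#'
#' @param alignment the `alignment` tibble of an aligned locus bundle.
#' @param exon_lengths integer vector of CDS segment lengths; must sum to
#'   the degapped reference row length.
#' @return Ascending integer vector of breakpoint columns (1-based,
#'   inclusive slice ends), one per exon; the last equals the alignment
#'   width.
#' @export
project_exon_boundaries <- function(alignment, exon_lengths) {
  ref_row <- alignment$seq[alignment$role == "reference"]
  if (length(ref_row) != 1) {
    stop("alignment must contain exactly one reference row", call. = FALSE)
  }
  chars <- strsplit(ref_row, "", fixed = TRUE)[[1]]
  n_res <- sum(chars != "-")
  if (sum(exon_lengths) != n_res) {
    stop("gene model length (", sum(exon_lengths),
         ") does not match the reference row (", n_res, " residues)",
         call. = FALSE)
  }
  res_col <- which(chars != "-")
  bp <- res_col[cumsum(exon_lengths)]
  bp[length(bp)] <- length(chars)
  as.integer(bp)
}

#' Split an aligned locus into degapped exon blocks
#'
#' Slices the alignment column-wise at the projected breakpoints, degaps
#' every member row of every slice, and drops individual (taxon, exon)
#' sequences shorter than the minimum bait length -- a 119-bp exon sequence
#' cannot host a 120-bp bait. Removal is per member sequence, not per
#' block; the reference row is a coordinate device and is not emitted.
#'
#' @param bundle an aligned locus bundle.
#' @param exon_lengths CDS segment lengths for the bundle's reference gene.
#' @param min_len minimum degapped length in bp to keep (default 120).
#' @return An exon-block tibble: `ref_gene_id`, `exon_index`, `unigene`,
#'   `taxon`, `seq`, `width`, and the 0-based half-open reference CDS
#'   interval `ref_start`, `ref_end`.
#' @export
split_exons <- function(bundle, exon_lengths, min_len = 120) {
  stopifnot(inherits(bundle, "locus_bundle"), !is.null(bundle$alignment))
  aln <- bundle$alignment
  bp <- project_exon_boundaries(aln, exon_lengths)
  starts <- c(1L, head(bp, -1) + 1L)
  cum <- cumsum(exon_lengths)
  ref0 <- c(0L, head(cum, -1))
  members <- aln[aln$role == "member", , drop = FALSE]
  out <- vector("list", length(bp))
  for (k in seq_along(bp)) {
    piece <- degap(substr(members$seq, starts[k], bp[k]))
    keep <- nchar(piece) >= max(1L, min_len)
    if (!any(keep)) next
    out[[k]] <- tibble(ref_gene_id = bundle$ref_gene_id, exon_index = k,
                       unigene = members$row_id[keep],
                       taxon = members$taxon[keep],
                       seq = piece[keep], width = nchar(piece[keep]),
                       ref_start = as.integer(ref0[k]),
                       ref_end = as.integer(cum[k]))
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    res <- tibble(ref_gene_id = character(), exon_index = integer(),
                  unigene = character(), taxon = character(),
                  seq = character(), width = integer(),
                  ref_start = integer(), ref_end = integer())
  }
  res
}

#' @rdname split_exons
#' @param bundles list of aligned locus bundles.
#' @param models gene-model tibble from [read_gene_models()].
#' @export
split_exons_all <- function(bundles, models, min_len = 120) {
  lens <- setNames(models$exon_lengths, models$gene_id)
  out <- lapply(bundles, function(b) {
    el <- lens[[b$ref_gene_id]]
    if (is.null(el)) {
      warning("no gene model for ", b$ref_gene_id, "; treated as single exon")
      el <- nchar(b$ref_cds)
    }
    split_exons(b, el, min_len = min_len)
  })
  dplyr::bind_rows(out)
}
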