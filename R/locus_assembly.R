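#' Group assignments into per-reference-gene locus bundles
#'
#' One bundle per reference gene that received at least one assignment;
#' bundles partition the assignments. Member unigenes that hit the
#' reference protein in a reverse frame (descending subject interval) come
#' from the antisense strand of an unstranded assembly and are
#' reverse-complemented here, so all downstream alignment is sense-strand.
#'
#' @param assignments assignment tibble from the COS filtering stage.
#' @param unigenes sequence-record tibble holding the assigned unigenes.
#' @param reference reference-gene tibble providing the CDS anchor row.
#' @return A list of `locus_bundle` objects, each with `ref_gene_id`,
#'   `ref_cds`, a `members` tibble (`unigene`, `taxon`, `seq` oriented
#'   sense-strand, `minus`) and an empty `alignment` slot.
#' @export
bundle_by_reference <- function(assignments, unigenes, reference) {
  if (nrow(assignments) == 0) return(list())
  seqs <- setNames(unigenes$seq, unigenes$id)
  cds <- setNames(reference$cds, reference$gene_id)
  missing <- setdiff(assignments$ref_gene_id, names(cds))
  if (length(missing)) {
    stop("assignments reference unknown gene(s): ",
         paste(head(missing, 3), collapse = ", "), call. = FALSE)
  }
  bundles <- lapply(split(assignments, assignments$ref_gene_id), function(a) {
    minus <- a$sstart > a$send
    s <- unname(seqs[a$unigene])
    s[minus] <- revcomp(s[minus])
    structure(list(
      ref_gene_id = a$ref_gene_id[1],
      ref_cds = unname(cds[a$ref_gene_id[1]]),
      members = tibble(unigene = a$unigene, taxon = a$taxon, seq = s,
                       minus = minus),
      alignment = NULL), class = "locus_bundle")
  })
  unname(bundles)[order(vapply(bundles, `[[`, "", "ref_gene_id"))]
}

#' Anchor-taxon locus filter
#'
#' Optionally retain only loci containing at least one sequence of the
#' best-assembled focal taxon (highest N50). Filtering on a single taxon
#' trades completeness for per-locus quality and can bias locus choice, so
#' it is skippable (`anchor = NULL` returns the input unchanged).
#'
#' @param bundles list of locus bundles.
#' @param anchor anchor taxon label, or `NULL` to disable.
#' @param known_taxa taxa considered valid; defaults to the taxa observed
#'   across bundle members. An `anchor` outside this set is a
#'   configuration error.
#' @return The filtered bundle list.
#' @export
require_anchor_taxon <- function(bundles, anchor, known_taxa = NULL) {
  if (is.null(anchor)) return(bundles)
  if (is.null(known_taxa)) {
    known_taxa <- unique(unlist(lapply(bundles, function(b) b$members$taxon)))
  }
  if (!anchor %in% known_taxa) {
    stop("unknown anchor taxon: ", anchor, call. = FALSE)
  }
  Filter(function(b) anchor %in% b$members$taxon, bundles)
}

#' Align one locus bundle
#'
#' Produces a multiple alignment whose first row is the reference CDS --
#' the coordinate anchor that later exon projection walks -- followed by
#' one row per member unigene. Two backends are available: an external
#' MAFFT call (`--genafpair --maxiterate 1000`, the E-INS-i strategy suited
#' to multi-domain sequences with long gaps) and a self-contained
#' reference-anchored aligner that aligns each member to the reference CDS
#' by overlap (free end gap) affine dynamic programming and merges the
#' pairwise gap structures into one matrix. Degapping any row reproduces
#' its input sequence exactly under either backend.
#'
#' @param bundle a `locus_bundle`.
#' @param aligner `"internal"` or `"mafft"`.
#' @return The bundle with its `alignment` slot filled: a tibble with
#'   columns `row_id`, `taxon`, `role` (`reference`/`member`) and the
#'   gapped row `seq` (gap character `-`), all rows of equal width.
#' @export
align_locus <- function(bundle, aligner = c("internal", "mafft")) {
  aligner <- match.arg(aligner)
  stopifnot(inherits(bundle, "locus_bundle"), nrow(bundle$members) >= 1)
  rows <- if (aligner == "mafft") {
    mafft_align(bundle)
  } else {
    star_align(bundle$ref_cds, bundle$members$seq)
  }
  bundle$alignment <- tibble(
    row_id = c(paste0("ref|", bundle$ref_gene_id), bundle$members$unigene),
    taxon = c(NA_character_, bundle$members$taxon),
    role = c("reference", rep("member", nrow(bundle$members))),
    seq = rows)
  bundle
}

#' @rdname align_locus
#' @param bundles a list of locus bundles.
#' @export
align_loci <- function(bundles, aligner = c("internal", "mafft")) {
  aligner <- match.arg(aligner)
  lapply(bundles, align_locus, aligner = aligner)
}

# reference-anchored star alignment: each member is pairwise-aligned to the
# reference; insertion lengths after each reference position are unioned
# (max) across members and every row is laid out on the merged column set
star_align <- function(ref, members) {
  sc <- scoring_params("blastn")
  unk <- match(sc$unknown, sc$alphabet)
  rcode <- encode_seq(ref, sc$alphabet, unk)
  n <- nchar(ref)
  pw <- lapply(members, function(m) {
    cpp_overlap_affine(encode_seq(m, sc$alphabet, unk), rcode, sc$smat,
                       sc$gap_open, sc$gap_ext)
  })
  # per member: match_at[r] = member char aligned to ref position r;
  # ins[[slot]] = member chars inserted after ref position slot-1 (slot 1 =
  # before the first reference residue)
  layouts <- lapply(seq_along(members), function(mi) {
    a <- pw[[mi]]$a_idx
    b <- pw[[mi]]$b_idx
    mchars <- strsplit(members[mi], "", fixed = TRUE)[[1]]
    match_at <- rep(NA_character_, n)
    sel <- b >= 0L & a >= 0L
    match_at[b[sel] + 1L] <- mchars[a[sel] + 1L]
    last_ref <- cummax(ifelse(b >= 0L, b, -1L))
    ins_cols <- which(b < 0L & a >= 0L)
    ins <- split(mchars[a[ins_cols] + 1L], last_ref[ins_cols] + 2L)
    list(match_at = match_at, ins = ins)
  })
  master_ins <- integer(n + 1L)
  for (l in layouts) {
    sl <- as.integer(names(l$ins))
    master_ins[sl] <- pmax(master_ins[sl], lengths(l$ins))
  }
  rchars <- strsplit(ref, "", fixed = TRUE)[[1]]
  total <- sum(master_ins) + n
  pos_ref <- cumsum(master_ins[seq_len(n)] + 1L)
  block_start <- c(0L, pos_ref)  # block for slot s begins after this column
  build_row <- function(match_at, ins) {
    chars <- rep("-", total)
    if (!is.null(match_at)) {
      chars[pos_ref[!is.na(match_at)]] <- match_at[!is.na(match_at)]
    }
    for (s in names(ins)) {
      blk <- ins[[s]]
      st <- block_start[as.integer(s)]
      chars[st + seq_along(blk)] <- blk
    }
    paste(chars, collapse = "")
  }
  ref_row <- {
    chars <- rep("-", total)
    chars[pos_ref] <- rchars
    paste(chars, collapse = "")
  }
  member_rows <- vapply(layouts, function(l) build_row(l$match_at, l$ins),
                        character(1))
  c(ref_row, member_rows)
}

mafft_align <- function(bundle) {
  if (Sys.which("mafft") == "") {
    stop("mafft binary not found on PATH; use aligner = \"internal\"",
         call. = FALSE)
  }
  ids <- c(paste0("ref|", bundle$ref_gene_id), bundle$members$unigene)
  tmp <- tempfile(fileext = ".fa")
  on.exit(unlink(tmp), add = TRUE)
  writeLines(paste0(">", ids, "\n",
                    c(bundle$ref_cds, bundle$members$seq)), tmp)
  out <- suppressWarnings(
    system2("mafft", c("--genafpair", "--maxiterate", "1000", "--quiet",
                       shQuote(tmp)),
            stdout = TRUE, stderr = FALSE))
  if (length(out) == 0) stop("mafft produced no output", call. = FALSE)
  tmp2 <- tempfile(fileext = ".fa")
  on.exit(unlink(tmp2), add = TRUE)
  writeLines(out, tmp2)
  aln <- Biostrings::readBStringSet(tmp2)
  rows <- toupper(as.character(aln))
  names(rows) <- sub("\\s.*$", "", names(aln))
  unname(rows[ids])
}

# degap helper shared by the round-trip invariants and exon splitting
degap <- function(x) gsub("-", "", x, fixed = TRUE)
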