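#' Sequence record tables
#'
#' All sequence sets in the package travel as plain tibbles with one row per
#' record: `id` (unique, non-empty), `taxon` (free-text label, may be `NA`),
#' `seq` (upper-case residues) and `kind` (`"nucleotide"` or `"protein"`).
#' Construction validates alphabet consistency; IUPAC ambiguity codes are
#' permitted.
#'
#' @param id character vector of unique identifiers.
#' @param seq character vector of residues (same length as `id`).
#' @param taxon taxon label(s), recycled; defaults to `NA`.
#' @param kind `"nucleotide"` or `"protein"`.
#' @return A tibble with columns `id`, `taxon`, `seq`, `kind`.
#' @examples
#' seq_records(c("u1", "u2"), c("ATGGCC", "TTTAAA"), taxon = "taxA")
#' @export
seq_records <- function(id, seq, taxon = NA_character_,
                        kind = c("nucleotide", "protein")) {
  kind <- match.arg(kind)
  id <- as.character(id)
  seq <- toupper(as.character(seq))
  if (length(id) != length(seq)) {
    stop("`id` and `seq` must have the same length", call. = FALSE)
  }
  if (length(id) == 0) {
    return(tibble(id = character(), taxon = character(),
                  seq = character(), kind = character()))
  }
  if (anyNA(id) || any(!nzchar(id))) {
    stop("sequence ids must be non-empty", call. = FALSE)
  }
  if (anyDuplicated(id)) {
    stop("duplicate sequence ids: ",
         paste(unique(id[duplicated(id)]), collapse = ", "), call. = FALSE)
  }
  if (any(!nzchar(seq))) stop("empty sequences are not allowed", call. = FALSE)
  alphabet <- if (kind == "nucleotide") .NT_ALLOWED else .AA_ALLOWED
  bad <- !grepl(paste0("^[", alphabet, "]+$"), seq)
  if (any(bad)) {
    stop("sequence(s) ", paste(head(id[bad], 3), collapse = ", "),
         " contain characters outside the ", kind, " alphabet", call. = FALSE)
  }
  tibble(id = id, taxon = rep_len(as.character(taxon), length(id)),
         seq = seq, kind = kind)
}

.NT_ALLOWED <- "ACGTUNRYSWKMBDHV"
.AA_ALLOWED <- "ACDEFGHIKLMNPQRSTVWYBJZX\\*U"
.NT_UNAMBIG <- c("A", "C", "G", "T")
.AA_UNAMBIG <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                 "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Read and write FASTA sequence sets
#'
#' Thin wrappers around Biostrings readers/writers that return or accept the
#' package's sequence-record tibble. The record id is the first
#' whitespace-delimited token of the FASTA header.
#'
#' @param path file path.
#' @param taxon taxon label to attach to every record.
#' @param kind sequence kind, `"nucleotide"` or `"protein"`.
#' @return `read_fasta()` returns a sequence-record tibble.
#' @export
read_fasta <- function(path, taxon = NA_character_,
                       kind = c("nucleotide", "protein")) {
  kind <- match.arg(kind)
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  seq_records(ids, as.character(ss), taxon = taxon, kind = kind)
}

#' @rdname read_fasta
#' @param records a sequence-record tibble.
#' @export
write_fasta <- function(records, path) {
  stopifnot(all(c("id", "seq") %in% names(records)))
  ss <- Biostrings::BStringSet(setNames(records$seq, records$id))
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

#' Assembly N50
#'
#' The standard assembly-contiguity statistic: the largest length `L` such
#' that contigs of length at least `L` jointly cover at least half of the
#' total assembly. Used to pick the anchor (best-assembled) focal taxon.
#'
#' @param transcriptome a sequence-record tibble, or a numeric vector of
#'   contig lengths.
#' @return N50 in bp.
#' @examples
#' assembly_n50(c(1, 2, 3, 4, 10))  # 10
#' @export
assembly_n50 <- function(transcriptome) {
  lens <- if (is.data.frame(transcriptome)) nchar(transcriptome$seq)
          else as.numeric(transcriptome)
  if (length(lens) == 0) stop("empty assembly has no N50", call. = FALSE)
  lens <- sort(lens, decreasing = TRUE)
  lens[which(cumsum(lens) >= sum(lens) / 2)[1]]
}

#' Reverse complement
#'
#' IUPAC-aware reverse complement of nucleotide strings.
#'
#' @param x character vector of nucleotide sequences.
#' @return character vector.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTUNRYSWKMBDHVacgtun", "TGCAANYRSWMKVHDBtgcaan", x)
  vapply(comp, function(s) intToUtf8(rev(utf8ToInt(s))), character(1),
         USE.NAMES = FALSE)
}

.pkg_cache <- new.env(parent = emptyenv())

codon_table <- function() {
  if (is.null(.pkg_cache$codons)) {
    gc <- Biostrings::GENETIC_CODE
    .pkg_cache$codons <- setNames(as.character(gc), names(gc))
  }
  .pkg_cache$codons
}

# translate a nucleotide string starting at offset `f`; ambiguous codons
# become X, stop codons *
translate_nt <- function(s, f = 1L) {
  n_codon <- (nchar(s) - f + 1L) %/% 3L
  if (n_codon < 1L) return("")
  starts <- f + 3L * (seq_len(n_codon) - 1L)
  aa <- codon_table()[substring(s, starts, starts + 2L)]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

# the six blastx frames, labelled +1,+2,+3,-1,-2,-3
translate_frames <- function(seq) {
  rc <- revcomp(seq)
  list(`+1` = translate_nt(seq, 1L), `+2` = translate_nt(seq, 2L),
       `+3` = translate_nt(seq, 3L), `-1` = translate_nt(rc, 1L),
       `-2` = translate_nt(rc, 2L), `-3` = translate_nt(rc, 3L))
}

# ---- internal: alphabet encodings for the DP kernels ----

.protein_alphabet <- function() {
  c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M", "F",
    "P", "S", "T", "W", "Y", "V", "B", "J", "Z", "X", "*")
}

.nt_alphabet <- function() c("A", "C", "G", "T", "N")

# encode a string as 0-based indices into an alphabet; characters outside
# the alphabet map to the designated unknown symbol (X for protein, N for nt)
encode_seq <- function(seq, alphabet, unknown = length(alphabet)) {
  ix <- match(strsplit(seq, "", fixed = TRUE)[[1]], alphabet)
  ix[is.na(ix)] <- unknown
  as.integer(ix - 1L)
}

decode_seq <- function(codes, alphabet) {
  paste(alphabet[codes + 1L], collapse = "")
}
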