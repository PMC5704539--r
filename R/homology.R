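#' Scoring parameters for the internal homology search
#'
#' BLAST-like defaults: BLOSUM62 with gap open 11 / extend 1 for translated
#' (protein-level) searches; match +2 / mismatch -3 with gap open 5 /
#' extend 2 for nucleotide searches. Bit scores use fixed Karlin-Altschul
#' parameters (lambda = 0.318, K = 0.13), and a gap of length g costs
#' `gap_open + g * gap_ext`. Ambiguity symbols score -1 against everything
#' and never count as identities.
#'
#' @param program `"blastx"` (translated nucleotide query vs protein
#'   subjects) or `"blastn"` (nucleotide vs nucleotide, both strands).
#' @param gap_open,gap_ext affine gap penalties (positive numbers).
#' @param match,mismatch nucleotide match/mismatch scores (blastn only).
#' @param word_size exact-seed length (3 for protein, 11 for nucleotide).
#' @return A list of scoring parameters consumed by [search_homology()].
#' @export
scoring_params <- function(program = c("blastx", "blastn"),
                           gap_open = NULL, gap_ext = NULL,
                           match = 2L, mismatch = -3L,
                           word_size = NULL) {
  program <- match.arg(program)
  if (program == "blastx") {
    al <- .protein_alphabet()
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    sm <- e$BLOSUM62[al, al]
    storage.mode(sm) <- "integer"
    list(program = program, alphabet = al, smat = sm,
         gap_open = as.integer(gap_open %||% 11L),
         gap_ext = as.integer(gap_ext %||% 1L),
         lambda = 0.318, K = 0.13,
         word_size = as.integer(word_size %||% 3L),
         trigger_score = 40L, unknown = "X",
         unambiguous = .AA_UNAMBIG, aa_units = TRUE)
  } else {
    al <- .nt_alphabet()
    sm <- matrix(as.integer(mismatch), 5L, 5L, dimnames = list(al, al))
    diag(sm) <- as.integer(match)
    sm[5L, ] <- -1L
    sm[, 5L] <- -1L
    list(program = program, alphabet = al, smat = sm,
         gap_open = as.integer(gap_open %||% 5L),
         gap_ext = as.integer(gap_ext %||% 2L),
         lambda = 0.318, K = 0.13,
         word_size = as.integer(word_size %||% 11L),
         trigger_score = 40L, unknown = "N",
         unambiguous = .NT_UNAMBIG, aa_units = FALSE)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

empty_hits <- function() {
  tibble(qseqid = character(), sseqid = character(), pident = numeric(),
         length = integer(), mismatch = integer(), gapopen = integer(),
         qstart = integer(), qend = integer(), sstart = integer(),
         send = integer(), evalue = numeric(), bitscore = numeric())
}

#' Desk-scale gapped/ungapped local homology search
#'
#' A seed-and-extend local search over small sequence sets, sufficient to
#' drive ortholog screening without an external aligner. Exact word seeds
#' (`word_size` in [scoring_params()]) nominate candidate subjects; each
#' candidate pair is then scored by the maximal ungapped segment pair
#' (ungapped mode) or, when the ungapped seed extension clears a trigger
#' score, by full affine-gap Smith-Waterman (gapped mode). Translated
#' (`blastx`) searches examine all six query frames; `blastn` searches both
#' strands. Per query/subject pair the single best frame or strand is
#' reported.
#'
#' E-values follow the Karlin-Altschul form `E = m * n * 2^(-bitscore)` with
#' `m` the query length in search units (aa for blastx) and `n` the total
#' residue count of the subject set. Coordinates are 1-based inclusive;
#' reverse-frame and minus-strand hits carry `sstart > send`, query
#' coordinates always ascend.
#'
#' @param queries,subjects sequence-record tibbles ([seq_records()]). For
#'   `blastx`, queries must be nucleotide and subjects protein; for
#'   `blastn`, both nucleotide.
#' @param mode `"gapped"` or `"ungapped"`. Ungapped hits never contain gaps;
#'   gapped hits on the same pair are at least as long.
#' @param program `"blastx"` or `"blastn"`.
#' @param max_evalue reporting cutoff (default 1e-10); stricter thresholds
#'   belong to downstream filtering, not the search.
#' @param scoring optional [scoring_params()] override.
#' @return A hit tibble in 12-column BLAST tabular (outfmt 6) shape:
#'   `qseqid, sseqid, pident, length, mismatch, gapopen, qstart, qend,
#'   sstart, send, evalue, bitscore`. `length` is in amino-acid columns for
#'   translated searches.
#' @export
search_homology <- function(queries, subjects,
                            mode = c("gapped", "ungapped"),
                            program = c("blastx", "blastn"),
                            max_evalue = 1e-10, scoring = NULL) {
  mode <- match.arg(mode)
  program <- match.arg(program)
  if (nrow(queries) == 0 || nrow(subjects) == 0) return(empty_hits())
  if (program == "blastx") {
    if (any(queries$kind != "nucleotide")) {
      stop("blastx-like search requires nucleotide queries", call. = FALSE)
    }
    if (any(subjects$kind != "protein")) {
      stop("blastx-like search requires protein subjects", call. = FALSE)
    }
  } else if (any(queries$kind != "nucleotide") ||
             any(subjects$kind != "nucleotide")) {
    stop("blastn-like search requires nucleotide queries and subjects",
         call. = FALSE)
  }
  sc <- scoring %||% scoring_params(program)
  al <- sc$alphabet
  k <- sc$word_size
  unk <- match(sc$unknown, al)
  subj_codes <- lapply(subjects$seq, encode_seq, alphabet = al, unknown = unk)
  n_db <- sum(nchar(subjects$seq))
  index <- seed_index(subjects$seq, k)

  out <- vector("list", nrow(queries))
  for (qi in seq_len(nrow(queries))) {
    qseq <- queries$seq[qi]
    Lq <- nchar(qseq)
    frames <- if (program == "blastx") translate_frames(qseq)
              else list(`+` = qseq, `-` = revcomp(qseq))
    m_len <- if (program == "blastx") max(1L, Lq %/% 3L) else Lq
    best <- list()  # per subject index: list(score, row)
    for (fname in names(frames)) {
      fseq <- frames[[fname]]
      Lf <- nchar(fseq)
      if (Lf < k) next
      cand <- seeded_subjects(fseq, index, k)
      if (length(cand) == 0) next
      qcodes <- encode_seq(fseq, al, unknown = unk)
      for (ci in seq_along(cand)) {
        si <- as.integer(names(cand)[ci])
        trig <- cpp_diag_ungapped_score(qcodes, subj_codes[[si]], sc$smat,
                                        cand[[ci]])
        if (trig < sc$trigger_score) next
        if (mode == "ungapped") {
          bu <- cpp_best_ungapped(qcodes, subj_codes[[si]], sc$smat)
          raw <- bu$score
          st <- ungapped_stats(fseq, subjects$seq[si], bu, sc$unambiguous)
          a_start <- bu$a_start; a_end <- bu$a_end
          b_start <- bu$b_start; b_end <- bu$b_end
        } else {
          la <- cpp_local_affine(qcodes, subj_codes[[si]], sc$smat,
                                 sc$gap_open, sc$gap_ext)
          if (la$score <= 0) next
          raw <- la$score
          st <- gapped_stats(fseq, subjects$seq[si], la, sc$unambiguous)
          a_start <- la$a_start; a_end <- la$a_end
          b_start <- la$b_start; b_end <- la$b_end
        }
        bits <- (sc$lambda * raw - log(sc$K)) / log(2)
        ev <- m_len * n_db * 2^(-bits)
        if (ev > max_evalue) next
        co <- map_hit_coords(program, fname, Lq, a_start, a_end,
                             b_start, b_end)
        prev <- best[[as.character(si)]]
        if (!is.null(prev) && prev$score >= raw) next
        best[[as.character(si)]] <- list(score = raw, row = tibble(
          qseqid = queries$id[qi], sseqid = subjects$id[si],
          pident = as.numeric(sprintf("%.2f", 100 * st$matches / st$aln_len)),
          length = st$aln_len, mismatch = st$mismatch, gapopen = st$gapopen,
          qstart = co$qstart, qend = co$qend,
          sstart = co$sstart, send = co$send,
          evalue = as.numeric(sprintf("%.3e", ev)),
          bitscore = as.numeric(sprintf("%.1f", bits))))
      }
    }
    if (length(best)) {
      out[[qi]] <- dplyr::bind_rows(lapply(best, `[[`, "row"))
    }
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) return(empty_hits())
  dplyr::arrange(res, .data$qseqid, dplyr::desc(.data$bitscore), .data$sseqid)
}

# exact-word seed index: environment mapping k-mer -> 2-column matrix of
# (subject index, 1-based word start)
seed_index <- function(seqs, k) {
  si_l <- vector("list", length(seqs))
  pos_l <- vector("list", length(seqs))
  km_l <- vector("list", length(seqs))
  for (si in seq_along(seqs)) {
    L <- nchar(seqs[si])
    if (L < k) next
    p <- 1:(L - k + 1L)
    km_l[[si]] <- substring(seqs[si], p, p + k - 1L)
    pos_l[[si]] <- p
    si_l[[si]] <- rep.int(si, length(p))
  }
  km <- unlist(km_l, use.names = FALSE)
  sis <- unlist(si_l, use.names = FALSE)
  poss <- unlist(pos_l, use.names = FALSE)
  env <- new.env(hash = TRUE, parent = emptyenv())
  for (grp in split(seq_along(km), km)) {
    env[[km[grp[1]]]] <- cbind(sis[grp], poss[grp])
  }
  env
}

# two-hit seeding: a subject is a candidate for a query frame when some
# diagonal carries word matches spanning at least one word length, with
# neighbouring matches at most 32 positions apart (BLAST's two-hit idea).
# Returns, per candidate subject (named by index), the 0-based seeded
# diagonals to scan for the gapped-extension trigger.
seeded_subjects <- function(fseq, index, k, window = 32L) {
  Lf <- nchar(fseq)
  p <- 1:(Lf - k + 1L)
  qk <- substring(fseq, p, p + k - 1L)
  ml <- mget(qk, envir = index, ifnotfound = list(NULL))
  nl <- vapply(ml, NROW, integer(1))
  if (sum(nl) == 0) return(list())
  mat <- do.call(rbind, ml[nl > 0])
  qpos <- rep.int(p, nl)
  si <- mat[, 1]
  dg <- qpos - mat[, 2]
  o <- order(si, dg, qpos)
  si <- si[o]; dg <- dg[o]; qs <- qpos[o]
  n <- length(qs)
  new_grp <- c(TRUE, si[-1] != si[-n] | dg[-1] != dg[-n])
  grp_id <- cumsum(new_grp)
  last_ix <- c(which(new_grp[-1]), n)
  span_ok <- (qs[last_ix] - qs[new_grp]) >= k
  d <- c(NA_integer_, qs[-1] - qs[-n])
  d[new_grp] <- NA_integer_
  has_close <- grp_id %in% grp_id[!is.na(d) & d <= window]
  keep <- span_ok & has_close[new_grp]
  if (!any(keep)) return(list())
  split(dg[new_grp][keep], si[new_grp][keep])
}

# identity/mismatch bookkeeping; ambiguity symbols never count as matches
ungapped_stats <- function(fseq, sseq, bu, unambiguous) {
  qa <- strsplit(substr(fseq, bu$a_start, bu$a_end), "", fixed = TRUE)[[1]]
  sb <- strsplit(substr(sseq, bu$b_start, bu$b_end), "", fixed = TRUE)[[1]]
  matches <- sum(qa == sb & qa %in% unambiguous)
  list(aln_len = length(qa), matches = matches,
       mismatch = length(qa) - matches, gapopen = 0L)
}

gapped_stats <- function(fseq, sseq, la, unambiguous) {
  qc <- strsplit(fseq, "", fixed = TRUE)[[1]]
  sb <- strsplit(sseq, "", fixed = TRUE)[[1]]
  ai <- la$a_idx
  bi <- la$b_idx
  qch <- rep("-", length(ai))
  qch[ai >= 0] <- qc[ai[ai >= 0] + 1L]
  sch <- rep("-", length(bi))
  sch[bi >= 0] <- sb[bi[bi >= 0] + 1L]
  both <- ai >= 0 & bi >= 0
  matches <- sum(both & qch == sch & qch %in% unambiguous)
  n_gap_runs <- function(v) {
    g <- v < 0
    sum(g & !c(FALSE, g[-length(g)]))
  }
  list(aln_len = length(ai), matches = matches,
       mismatch = sum(both) - matches,
       gapopen = n_gap_runs(ai) + n_gap_runs(bi))
}

# frame-space to query/subject coordinates; reverse frames flag themselves
# by a descending subject interval (query coordinates always ascend)
map_hit_coords <- function(program, fname, Lq, a_start, a_end, b_start, b_end) {
  if (program == "blastn") {
    if (fname == "+") {
      list(qstart = a_start, qend = a_end, sstart = b_start, send = b_end)
    } else {
      list(qstart = Lq - a_end + 1L, qend = Lq - a_start + 1L,
           sstart = b_end, send = b_start)
    }
  } else {
    f <- as.integer(substr(fname, 2L, 2L))
    nt_start <- f + 3L * (a_start - 1L)
    nt_end <- f + 3L * a_end - 1L
    if (substr(fname, 1L, 1L) == "+") {
      list(qstart = nt_start, qend = nt_end, sstart = b_start, send = b_end)
    } else {
      list(qstart = Lq - nt_end + 1L, qend = Lq - nt_start + 1L,
           sstart = b_end, send = b_start)
    }
  }
}

#' Read and write BLAST tabular hit tables
#'
#' `parse_tabular_hits()` accepts the 12-column tab-separated outfmt-6
#' dialect, so hits produced by an external BLAST run can be injected in
#' place of the internal engine. Lines starting with `#` are skipped; a line
#' with fewer than 12 fields is a parse error reporting the line number.
#' `write_tabular_hits()` is its inverse: `parse(write(x))` reproduces `x`.
#'
#' @param lines character vector of raw lines.
#' @return A hit tibble (see [search_homology()] for columns).
#' @export
parse_tabular_hits <- function(lines) {
  lines <- lines[!grepl("^#", lines)]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(empty_hits())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 12L)) {
    bad <- which(nf < 12L)[1]
    stop("malformed tabular hit line ", bad, ": expected >= 12 tab-separated ",
         "fields, found ", nf[bad], call. = FALSE)
  }
  m <- do.call(rbind, lapply(parts, `[`, 1:12))
  num <- function(j) as.numeric(m[, j])
  int <- function(j) as.integer(as.numeric(m[, j]))
  hits <- tibble(qseqid = m[, 1], sseqid = m[, 2], pident = num(3),
                 length = int(4), mismatch = int(5), gapopen = int(6),
                 qstart = int(7), qend = int(8), sstart = int(9),
                 send = int(10), evalue = num(11), bitscore = num(12))
  bad <- which(is.na(hits$pident) | is.na(hits$length) | is.na(hits$evalue) |
                 is.na(hits$bitscore) | is.na(hits$qstart) | is.na(hits$qend))
  if (length(bad)) {
    stop("malformed tabular hit line ", bad[1], ": non-numeric field",
         call. = FALSE)
  }
  hits
}

#' @rdname parse_tabular_hits
#' @param path file path to a tabular hits TSV.
#' @export
read_hits <- function(path) parse_tabular_hits(readLines(path))

#' @rdname parse_tabular_hits
#' @param hits a hit tibble.
#' @export
write_tabular_hits <- function(hits, path = NULL) {
  fmt <- function(v) vapply(v, function(x) as.character(x), character(1))
  lines <- if (nrow(hits) == 0) character(0) else {
    paste(hits$qseqid, hits$sseqid, fmt(hits$pident), hits$length,
          hits$mismatch, hits$gapopen, hits$qstart, hits$qend, hits$sstart,
          hits$send, fmt(hits$evalue), fmt(hits$bitscore), sep = "\t")
  }
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(path)
}
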