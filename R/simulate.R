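#' Simulation configuration for planted-truth fixtures
#'
#' Describes a fully synthetic study system with the statistical structure
#' the pipeline assumes: a reference species carrying known single-copy
#' genes and planted duplicated pairs, focal taxa derived from the
#' reference CDS by substitutions, in-frame indels and fragmentation, plus
#' host-contaminant and plastid-derived transcripts. Per-taxon parameters
#' (`divergence`, `indel_rate`, `frag_prob`) recycle from scalars. The
#' first taxon is the anchor: full-length, undiverged-most assembly, so its
#' N50 dominates.
#'
#' Gene structures are resampled until each single-copy gene yields at
#' least `min_anchor_baits` baits from its exons, so every planted locus is
#' recoverable by construction and recovery metrics measure the pipeline,
#' not the lottery of gene lengths.
#'
#' @param seed integer RNG seed; identical seeds give byte-identical
#'   outputs.
#' @param n_scg number of planted true single-copy genes.
#' @param n_paralog_pairs number of planted duplicated gene pairs
#'   (intra-pair nucleotide divergence ~0.05).
#' @param taxa character vector of focal taxon labels (first = anchor).
#' @param exon_length_range,exons_per_gene_range gene-structure ranges.
#' @param divergence per-taxon substitution probability per site.
#' @param indel_rate per-taxon probability per site of starting an
#'   in-frame (multiple-of-3) indel; exercises gapped search.
#' @param frag_prob per-taxon probability that a unigene is split into two
#'   disjoint fragments (lowers that taxon's N50).
#' @param n_host_contaminants host-derived transcripts planted into
#'   non-anchor taxa.
#' @param n_plastid_transcripts plastid-derived transcripts planted across
#'   taxa.
#' @param host_divergence nucleotide divergence of host genes from their
#'   reference counterparts (>= 0.10 keeps clean orthologs below the 95%
#'   host-identity removal cutoff).
#' @param contaminant_divergence divergence of planted contaminant
#'   transcripts from the host genes (small, so the 95% screen fires).
#' @param plastid_divergence divergence of plastid transcripts from the toy
#'   plastid genome.
#' @param random_orientation emit unigenes on a random strand, as in an
#'   unstranded assembly.
#' @param min_anchor_baits minimum bait yield per planted gene (see above).
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(seed = 1L, n_scg = 50L, n_paralog_pairs = 5L,
                              taxa = c("taxonA", "taxonB", "taxonC",
                                       "taxonD"),
                              exon_length_range = c(120L, 600L),
                              exons_per_gene_range = c(1L, 4L),
                              divergence = c(0.02, 0.04, 0.05, 0.06),
                              indel_rate = 0,
                              frag_prob = c(0, 0.2, 0.3, 0.4),
                              n_host_contaminants = 5L,
                              n_plastid_transcripts = 5L,
                              host_divergence = 0.12,
                              contaminant_divergence = 0.02,
                              plastid_divergence = 0.02,
                              random_orientation = TRUE,
                              min_anchor_baits = 4L) {
  nt <- length(taxa)
  cfg <- list(seed = as.integer(seed), n_scg = as.integer(n_scg),
              n_paralog_pairs = as.integer(n_paralog_pairs), taxa = taxa,
              exon_length_range = as.integer(exon_length_range),
              exons_per_gene_range = as.integer(exons_per_gene_range),
              divergence = setNames(rep_len(divergence, nt), taxa),
              indel_rate = setNames(rep_len(indel_rate, nt), taxa),
              frag_prob = setNames(rep_len(frag_prob, nt), taxa),
              n_host_contaminants = as.integer(n_host_contaminants),
              n_plastid_transcripts = as.integer(n_plastid_transcripts),
              host_divergence = host_divergence,
              contaminant_divergence = contaminant_divergence,
              plastid_divergence = plastid_divergence,
              random_orientation = isTRUE(random_orientation),
              min_anchor_baits = as.integer(min_anchor_baits))
  probs <- c(cfg$divergence, cfg$indel_rate, cfg$frag_prob,
             host_divergence, contaminant_divergence, plastid_divergence)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (any(c(cfg$n_scg, cfg$n_paralog_pairs, cfg$n_host_contaminants,
            cfg$n_plastid_transcripts) < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  structure(cfg, class = "simulation_config")
}

.STOP_CODONS <- c("TAA", "TAG", "TGA")

random_cds <- function(n_codons) {
  codons <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                              c("A", "C", "G", "T")), 1, paste, collapse = "")
  codons <- setdiff(codons, .STOP_CODONS)
  paste(sample(codons, n_codons, replace = TRUE), collapse = "")
}

# site-wise substitutions at the given per-site rate; any stop codon created
# in the reading frame is repaired so the CDS stays translatable
mutate_cds <- function(seq, rate, frame_safe = TRUE) {
  if (rate <= 0) return(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(ch)) < rate)
  for (i in hit) {
    ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
  }
  s <- paste(ch, collapse = "")
  if (frame_safe) {
    n_codon <- nchar(s) %/% 3L
    cod <- substring(s, 3L * seq_len(n_codon) - 2L, 3L * seq_len(n_codon))
    bad <- which(cod %in% .STOP_CODONS)
    for (i in bad) cod[i] <- sub("A$|G$", "C", cod[i])
    s <- paste0(paste(cod, collapse = ""),
                substr(s, 3L * n_codon + 1L, nchar(s)))
  }
  s
}

random_nt <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = "")

# sample an exon structure whose tiled bait yield meets the floor and whose
# total length is a stop-free multiple of three of at least 330 bp
sample_gene_structure <- function(cfg) {
  repeat {
    k <- sample(seq(cfg$exons_per_gene_range[1], cfg$exons_per_gene_range[2]),
                1)
    lens <- sample(seq(cfg$exon_length_range[1], cfg$exon_length_range[2]),
                   k, replace = TRUE)
    lens[k] <- lens[k] + (3L - sum(lens) %% 3L) %% 3L
    if (sum(lens) < 330L) next
    yield <- sum(vapply(lens, function(L) nrow(tile_baits(L)), integer(1)))
    if (yield >= cfg$min_anchor_baits) return(as.integer(lens))
  }
}

#' Generate the synthetic reference species
#'
#' Emits the raw reference proteome the reference builder screens:
#' `n_scg` true single-copy genes plus `n_paralog_pairs` duplicated pairs
#' (members `_a`/`_b`, intra-pair divergence ~0.05). Every gene -- singleton
#' or pair -- has one counterpart in the SCG database (divergence <= 0.1 at
#' the protein level), so pairs survive the single-match screen and must be
#' caught by self-deduplication. A GFF3 gene model (alternating strands,
#' 150-bp introns) accompanies each gene and is consistent with its CDS.
#'
#' @param config a [simulation_config()].
#' @return List with `genes` (reference-gene tibble), `models` (gene-model
#'   tibble), `gff` (GFF3 text lines), `scg_db` (protein sequence records)
#'   and `structures` (named list of exon-length vectors).
#' @export
generate_reference <- function(config) {
  set.seed(config$seed)
  ids <- c(sprintf("scg_%03d", seq_len(config$n_scg)),
           if (config$n_paralog_pairs > 0)
             paste0(rep(sprintf("par_%02d", seq_len(config$n_paralog_pairs)),
                        each = 2), c("_a", "_b")))
  structures <- list()
  cds <- character(0)
  scg_db_seq <- character(0)
  scg_db_id <- character(0)
  for (g in sprintf("scg_%03d", seq_len(config$n_scg))) {
    structures[[g]] <- sample_gene_structure(config)
    cds[g] <- random_cds(sum(structures[[g]]) %/% 3L)
    scg_db_id <- c(scg_db_id, paste0("db_", g))
    scg_db_seq <- c(scg_db_seq,
                    translate_cds(mutate_cds(cds[g], 0.05)))
  }
  if (config$n_paralog_pairs > 0) {
    for (p in sprintf("par_%02d", seq_len(config$n_paralog_pairs))) {
      st <- sample_gene_structure(config)
      a <- random_cds(sum(st) %/% 3L)
      b <- mutate_cds(a, 0.05)
      structures[[paste0(p, "_a")]] <- st
      structures[[paste0(p, "_b")]] <- st
      cds[paste0(p, "_a")] <- a
      cds[paste0(p, "_b")] <- b
      scg_db_id <- c(scg_db_id, paste0("db_", p))
      scg_db_seq <- c(scg_db_seq, translate_cds(mutate_cds(a, 0.05)))
    }
  }
  genes <- reference_genes(ids, unname(cds[ids]), species_role = "primary")
  gff <- build_gff3(structures)
  models <- tibble(gene_id = names(structures),
                   mrna_id = paste0(names(structures), ".t1"),
                   strand = rep(c("+", "-"),
                                length.out = length(structures)),
                   n_exons = lengths(structures),
                   exon_lengths = unname(structures))
  list(genes = genes, models = models, gff = gff,
       scg_db = seq_records(scg_db_id, scg_db_seq, kind = "protein"),
       structures = structures)
}

translate_cds <- function(s) {
  sub("\\*$", "", translate_nt(s, 1L))
}

# one scaffold per gene, 150-bp introns, strands alternating; on the minus
# strand the genomic segment order is the reverse of transcript order
build_gff3 <- function(structures) {
  lines <- "##gff-version 3"
  strands <- rep(c("+", "-"), length.out = length(structures))
  for (gi in seq_along(structures)) {
    g <- names(structures)[gi]
    lens <- structures[[gi]]
    strand <- strands[gi]
    genomic <- if (strand == "-") rev(lens) else lens
    cur <- 101L
    segs <- matrix(0L, nrow = length(genomic), ncol = 2)
    for (i in seq_along(genomic)) {
      segs[i, ] <- c(cur, cur + genomic[i] - 1L)
      cur <- cur + genomic[i] + 150L
    }
    chrom <- paste0("chr_", g)
    span <- c(min(segs), max(segs))
    lines <- c(lines,
      paste(chrom, "sim", "gene", span[1], span[2], ".", strand, ".",
            paste0("ID=", g), sep = "\t"),
      paste(chrom, "sim", "mRNA", span[1], span[2], ".", strand, ".",
            paste0("ID=", g, ".t1;Parent=", g), sep = "\t"),
      vapply(seq_len(nrow(segs)), function(i) {
        paste(chrom, "sim", "CDS", segs[i, 1], segs[i, 2], ".", strand,
              "0", paste0("ID=cds_", g, ".", i, ";Parent=", g, ".t1"),
              sep = "\t")
      }, character(1)))
  }
  lines
}

#' Generate focal transcriptomes with planted truth
#'
#' Derives per-taxon unigenes from the reference CDS by substitutions,
#' in-frame indels and optional fragmentation; paralog-pair genes emit both
#' copies in every taxon. Host contaminants (near-copies of a divergent
#' host gene set that itself descends from reference genes, as when a
#' parasite is grown on a related host) go into non-anchor taxa; plastid
#' transcripts are near-copies of windows of a toy plastid genome. A truth
#' table labels every unigene.
#'
#' @param config a [simulation_config()].
#' @param reference output of [generate_reference()].
#' @return List with `unigenes` (sequence records, `taxon` set), `truth`
#'   (tibble: `unigene`, `taxon`, `class` in ortholog/paralog/host/plastid,
#'   `source`), `host_db` and `plastid_db` (sequence records).
#' @export
generate_focal_transcriptomes <- function(config, reference) {
  set.seed(config$seed + 7919L)
  genes <- reference$genes
  is_pair <- grepl("^par_", genes$gene_id)
  ids <- character(0); seqs <- character(0); taxs <- character(0)
  cls <- character(0); src <- character(0)
  counter <- 0L
  emit <- function(seq, taxon, class, source) {
    counter <<- counter + 1L
    id <- sprintf("%s_u%04d", taxon, counter)
    ids <<- c(ids, id); seqs <<- c(seqs, seq); taxs <<- c(taxs, taxon)
    cls <<- c(cls, class); src <<- c(src, source)
  }
  orient <- function(s) {
    if (config$random_orientation && stats::runif(1) < 0.5) revcomp(s) else s
  }
  for (taxon in config$taxa) {
    div <- config$divergence[[taxon]]
    irate <- config$indel_rate[[taxon]]
    fprob <- config$frag_prob[[taxon]]
    for (gi in seq_len(nrow(genes))) {
      s <- mutate_cds(genes$cds[gi], div)
      if (irate > 0) s <- plant_indels(s, irate)
      class <- if (is_pair[gi]) "paralog" else "ortholog"
      if (fprob > 0 && stats::runif(1) < fprob && nchar(s) >= 400L) {
        cut <- sample(seq(150L, nchar(s) - 150L), 1)
        emit(orient(substr(s, 1L, cut)), taxon, class, genes$gene_id[gi])
        emit(orient(substr(s, cut + 1L, nchar(s))), taxon, class,
             genes$gene_id[gi])
      } else {
        emit(orient(s), taxon, class, genes$gene_id[gi])
      }
    }
  }
  # host database: divergent copies of the first singleton genes
  n_host <- min(config$n_host_contaminants, config$n_scg)
  host_src <- genes$gene_id[!is_pair][seq_len(n_host)]
  host_seq <- vapply(host_src, function(g) {
    mutate_cds(genes$cds[genes$gene_id == g], config$host_divergence)
  }, character(1))
  host_db <- seq_records(sprintf("host_%s", host_src), unname(host_seq),
                         taxon = "host")
  non_anchor <- setdiff(config$taxa, config$taxa[1])
  if (config$n_host_contaminants > 0 && length(non_anchor) > 0) {
    for (i in seq_len(config$n_host_contaminants)) {
      hi <- ((i - 1L) %% n_host) + 1L
      taxon <- non_anchor[((i - 1L) %% length(non_anchor)) + 1L]
      emit(orient(mutate_cds(host_seq[hi], config$contaminant_divergence)),
           taxon, "host", paste0("host_", host_src[hi]))
    }
  }
  # toy plastid genome and derived transcripts
  plastid <- random_nt(6000L)
  plastid_db <- seq_records("plastid_genome", plastid, taxon = "plastid")
  if (config$n_plastid_transcripts > 0) {
    for (i in seq_len(config$n_plastid_transcripts)) {
      w <- sample(300:800, 1)
      st <- sample(seq_len(6000L - w), 1)
      taxon <- config$taxa[((i - 1L) %% length(config$taxa)) + 1L]
      emit(orient(mutate_cds(substr(plastid, st, st + w - 1L),
                             config$plastid_divergence,
                             frame_safe = FALSE)),
           taxon, "plastid", "plastid_genome")
    }
  }
  unigenes <- seq_records(ids, seqs, taxon = taxs)
  list(unigenes = unigenes,
       truth = tibble(unigene = ids, taxon = taxs, class = cls,
                      source = src),
       host_db = host_db, plastid_db = plastid_db)
}

# indels come in multiples of 3 so reading frames stay intact and the
# gapped/ungapped contrast is isolated from frameshift handling
plant_indels <- function(seq, rate) {
  n_events <- stats::rbinom(1L, nchar(seq), rate)
  for (e in seq_len(n_events)) {
    L <- nchar(seq)
    size <- 3L * sample(1:3, 1)
    pos <- sample(seq(30L, max(31L, L - 30L)), 1)
    if (stats::runif(1) < 0.5 && L - size >= 120L) {
      seq <- paste0(substr(seq, 1L, pos), substr(seq, pos + size + 1L, L))
    } else {
      seq <- paste0(substr(seq, 1L, pos), random_nt(size),
                    substr(seq, pos + 1L, L))
    }
  }
  seq
}

#' Write a complete simulated dataset to disk
#'
#' Materialises a simulated study as the file layout the pipeline (and its
#' CLI) consumes: reference protein/CDS FASTA + GFF3, SCG database FASTA,
#' one transcriptome FASTA per focal taxon, host and plastid databases, and
#' the truth table TSV.
#'
#' @param config a [simulation_config()].
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with the generated objects and file `paths`.
#' @export
simulate_dataset <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ref <- generate_reference(config)
  focal <- generate_focal_transcriptomes(config, ref)
  p <- list(
    ref_proteins = file.path(out_dir, "ref_proteins.fa"),
    ref_cds = file.path(out_dir, "ref_cds.fa"),
    gff = file.path(out_dir, "ref.gff3"),
    scg_db = file.path(out_dir, "scg_db.fa"),
    host_db = file.path(out_dir, "host_db.fa"),
    plastid_db = file.path(out_dir, "plastid_db.fa"),
    truth = file.path(out_dir, "truth.tsv"))
  write_fasta(ref_protein_records(ref$genes), p$ref_proteins)
  write_fasta(ref_cds_records(ref$genes), p$ref_cds)
  writeLines(ref$gff, p$gff)
  write_fasta(ref$scg_db, p$scg_db)
  write_fasta(focal$host_db, p$host_db)
  write_fasta(focal$plastid_db, p$plastid_db)
  utils::write.table(focal$truth, p$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  p$transcriptomes <- setNames(
    file.path(out_dir, paste0(config$taxa, ".fa")), config$taxa)
  for (taxon in config$taxa) {
    write_fasta(focal$unigenes[focal$unigenes$taxon == taxon, ],
                p$transcriptomes[[taxon]])
  }
  invisible(list(config = config, reference = ref, focal = focal,
                 paths = p))
}
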