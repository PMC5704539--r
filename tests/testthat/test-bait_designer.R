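test_that("tiling reproduces the published worked examples", {
  expect_equal(tile_baits(119)$start, integer(0))
  expect_equal(tile_baits(120)$start, 0L)
  b160 <- tile_baits(160)
  expect_equal(b160$start, c(0L, 40L))
  expect_equal((b160$start[1] + 120) - b160$start[2], 80L)  # 80-bp overlap
  expect_equal(tile_baits(280)$start, c(0L, 60L, 120L, 160L))
  expect_equal(tile_baits(279)$start, c(0L, 60L, 120L))  # terminal would overlap 81
})

test_that("smallest lengths yielding 1..4 baits are 120, 160, 220, 280", {
  counts <- vapply(1:400, function(L) nrow(tile_baits(L)), integer(1))
  firsts <- vapply(1:4, function(k) which(counts >= k)[1], integer(1))
  expect_equal(firsts, c(120L, 160L, 220L, 280L))
})

test_that("tiling matches the exhaustive placement oracle for L up to 1000", {
  for (L in 1:1000) {
    expect_identical(nrow(tile_baits(L)), as.integer(oracle_bait_count(L)))
  }
  # and under non-default parameters
  p <- tiling_params(bait_len = 100, step = 50, max_overlap = 60)
  for (L in c(99:105, 149:151, 189:191, 240:260)) {
    expect_identical(nrow(tile_baits(L, p)),
                     as.integer(oracle_bait_count(L, 100, 50, 60)))
  }
})

test_that("baits are exact 120-mers lying inside their source sequence", {
  set.seed(81)
  for (r in 1:20) {
    s <- rand_cds(sample(40:220, 1))
    b <- tile_baits(s)
    if (nrow(b) == 0) next
    expect_true(all(nchar(b$sequence) == 120))
    expect_true(all(b$start + 120 <= nchar(s)))
    expect_true(all(b$sequence == substring(s, b$start + 1, b$start + 120)))
  }
  expect_error(tile_baits("ACGT-ACGT"), "gap-free")
})

test_that("tiling parameter validation catches impossible layouts", {
  expect_error(tiling_params(step = 0), "step")
  expect_error(tiling_params(step = 121), "step")
  expect_error(tiling_params(max_overlap = 120), "max_overlap")
})

mk_baits <- function(ref_gene_id, taxon, n, seqs = NULL) {
  set.seed(nchar(ref_gene_id) + n)
  tibble::tibble(ref_gene_id = ref_gene_id, exon_index = 1L, taxon = taxon,
                 unigene = paste0(taxon, "_u"),
                 start = seq(0L, by = 60L, length.out = n),
                 sequence = seqs %||% replicate(n, rand_cds(40)))
}

test_that("low-yield filter counts anchor baits per locus", {
  b <- dplyr::bind_rows(
    mk_baits("g_poor", "anchor", 3),   # 3 anchor baits -> dropped
    mk_baits("g_poor", "other", 6),
    mk_baits("g_rich", "anchor", 4),   # 4 anchor baits -> kept
    mk_baits("g_rich", "other", 1))
  out <- filter_low_yield_loci(b, "anchor", min_baits = 4)
  expect_equal(out$retained_loci, "g_rich")
  expect_true(all(out$baits$ref_gene_id == "g_rich"))  # all taxa of g_poor gone
  # a single 280-bp anchor exon yields four baits and is never dropped
  exon <- tibble::tibble(ref_gene_id = "g280", exon_index = 1L,
                         taxon = "anchor", unigene = "u",
                         seq = strrep("ACGT", 70), width = 280L,
                         ref_start = 0L, ref_end = 280L)
  out2 <- filter_low_yield_loci(design_baits(exon), "anchor", 4)
  expect_equal(out2$retained_loci, "g280")
  # disabled filter keeps everything
  expect_equal(nrow(filter_low_yield_loci(b, NULL)$baits), nrow(b))
})

test_that("redundancy clustering collapses at 90% and spares 89.2%", {
  set.seed(82)
  base <- rand_cds(40)  # 120 nt
  diff12 <- mutate_sites(base, seq(5, 5 + 10 * 11, by = 10))  # 12 diffs: 90.0%
  diff13 <- mutate_sites(base, seq(5, 5 + 9 * 12, by = 9))    # 13 diffs: 89.2%
  mk <- function(id, taxon, seq) {
    tibble::tibble(ref_gene_id = id, exon_index = 1L, taxon = taxon,
                   unigene = taxon, start = 0L, sequence = seq)
  }
  # identical pair collapses to one
  two <- dplyr::bind_rows(mk("g1", "tA", base), mk("g1", "tB", base))
  expect_equal(nrow(cluster_redundant_baits(two)), 1L)
  # 12/120 differences = 90.0% identity: still redundant
  expect_equal(nrow(cluster_redundant_baits(
    dplyr::bind_rows(mk("g1", "tA", base), mk("g1", "tB", diff12)))), 1L)
  # 13/120 differences = 89.2%: both kept
  expect_equal(nrow(cluster_redundant_baits(
    dplyr::bind_rows(mk("g1", "tA", base), mk("g1", "tB", diff13)))), 2L)
  # reverse-complement duplicates are caught
  expect_equal(nrow(cluster_redundant_baits(
    dplyr::bind_rows(mk("g1", "tA", base), mk("g1", "tB", revcomp(base))))), 1L)
})

test_that("surviving representatives are mutually non-redundant and stable", {
  set.seed(83)
  pool <- c(replicate(6, rand_cds(40)))
  baits <- tibble::tibble(
    ref_gene_id = rep(paste0("g", 1:3), each = 8),
    exon_index = rep(1:2, 12),
    taxon = rep(c("tA", "tB"), 12),
    unigene = "u",
    start = rep(seq(0L, 180L, by = 60L), 6),
    sequence = c(vapply(rep(pool, 4), function(s)
      mutate_sites(s, sample(120, 2)), character(1))))
  out <- cluster_redundant_baits(baits, identity = 90)
  # no retained pair matches at >= 90% in either orientation
  ident <- function(a, b) scgbaits:::bait_identity(a, b)
  for (i in seq_len(nrow(out))) {
    for (j in seq_len(nrow(out))) {
      if (i >= j) next
      expect_lt(max(ident(out$sequence[i], out$sequence[j]),
                    ident(out$sequence[i], revcomp(out$sequence[j]))), 90)
    }
  }
  # deterministic given the sort order
  expect_identical(cluster_redundant_baits(baits, identity = 90), out)
})

test_that("organelle screen removes whole loci on a single >= 90% bait hit", {
  set.seed(84)
  plastid <- rand_cds(700)
  db <- seq_records("plastid1", plastid)
  # 10 spaced mismatches: 110/120 = 91.7% identity, seeds intact
  hit92 <- mutate_sites(substr(plastid, 301, 420), seq(6, 114, by = 12))
  # 5 mismatch triplets: 105/120 = 87.5% identity, still seedable
  hit89 <- mutate_sites(substr(plastid, 301, 420),
                        as.vector(outer(0:2, seq(15, 95, by = 20), `+`)))
  clean <- rand_cds(40)
  mk <- function(id, seqs) {
    tibble::tibble(ref_gene_id = id, exon_index = 1L, taxon = "tA",
                   unigene = "u", start = seq_along(seqs) * 0L,
                   sequence = seqs)
  }
  baits <- dplyr::bind_rows(mk("g_plastid", c(hit92, replicate(9, rand_cds(40)))),
                            mk("g_clean", clean))
  out <- drop_organelle_loci(baits, db)
  expect_equal(out$dropped_loci, "g_plastid")   # 10/120 diffs = 91.7%: locus out
  expect_equal(unique(out$baits$ref_gene_id), "g_clean")
  # 15/120 differences = 87.5% stays below the cutoff
  out2 <- drop_organelle_loci(mk("g_borderline", hit89), db)
  expect_equal(out2$dropped_loci, character(0))
  # no database: nothing happens; empty database warns
  expect_equal(drop_organelle_loci(baits, NULL)$baits, baits)
  expect_warning(drop_organelle_loci(baits, db[0, ]), "empty")
})
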