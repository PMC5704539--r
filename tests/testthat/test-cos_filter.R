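mk_hit <- function(qseqid, sseqid, pident = 50, length = 150L,
                   evalue = 1e-30, bitscore = 200, sstart = 1L,
                   send = length, qstart = 1L, qend = 3L * length) {
  tibble::tibble(qseqid = qseqid, sseqid = sseqid, pident = pident,
                 length = as.integer(length), mismatch = 0L, gapopen = 0L,
                 qstart = as.integer(qstart), qend = as.integer(qend),
                 sstart = as.integer(sstart), send = as.integer(send),
                 evalue = evalue, bitscore = bitscore)
}

test_that("best-hit assignment enforces inclusive thresholds at the boundary", {
  th <- filter_thresholds()
  # passing sole hit is assigned
  expect_equal(best_hit_per_query(mk_hit("u1", "g1", pident = 45,
                                         evalue = 1e-25))$ref_gene_id, "g1")
  # identity 39.9 fails despite excellent e-value and length
  expect_equal(nrow(best_hit_per_query(
    mk_hit("u1", "g1", pident = 39.9, evalue = 1e-30, length = 200L))), 0L)
  expect_equal(nrow(best_hit_per_query(
    mk_hit("u1", "g1", pident = 40, evalue = 1e-30, length = 200L))), 1L)
  # e-value reading is inclusive: exactly 1e-20 passes, just above fails
  expect_equal(nrow(best_hit_per_query(mk_hit("u1", "g1", evalue = 1e-20))), 1L)
  expect_equal(nrow(best_hit_per_query(mk_hit("u1", "g1", evalue = 1.1e-20))),
               0L)
  # alignment length boundary
  expect_equal(nrow(best_hit_per_query(mk_hit("u1", "g1", length = 99L))), 0L)
  expect_equal(nrow(best_hit_per_query(mk_hit("u1", "g1", length = 100L))), 1L)
})

test_that("best-hit selection keeps one hit per query with full tie-breaking", {
  hits <- dplyr::bind_rows(
    mk_hit("u1", "g1", bitscore = 120),
    mk_hit("u1", "g2", bitscore = 118),
    mk_hit("u2", "gA", bitscore = 100, evalue = 1e-30),
    mk_hit("u2", "gB", bitscore = 100, evalue = 1e-40),
    mk_hit("u3", "gC", bitscore = 90, evalue = 1e-30, length = 150L),
    mk_hit("u3", "gD", bitscore = 90, evalue = 1e-30, length = 180L),
    mk_hit("u4", "gZ", bitscore = 80),
    mk_hit("u4", "gA", bitscore = 80))
  a <- best_hit_per_query(hits)
  expect_equal(nrow(a), 4L)
  expect_equal(anyDuplicated(a$unigene), 0L)
  got <- setNames(a$ref_gene_id, a$unigene)
  expect_equal(got[["u1"]], "g1")   # max bitscore
  expect_equal(got[["u2"]], "gB")   # tie -> lower evalue
  expect_equal(got[["u3"]], "gD")   # tie -> longer alignment
  expect_equal(got[["u4"]], "gA")   # tie -> lexicographic subject
  expect_true(all(scgbaits:::hits_passing(
    dplyr::rename(a, qseqid = unigene, sseqid = ref_gene_id), filter_thresholds())))
})

test_that("tightening any threshold never increases the assignment count", {
  set.seed(41)
  hits <- dplyr::bind_rows(lapply(1:120, function(i) {
    mk_hit(paste0("u", sample(40, 1)), paste0("g", sample(10, 1)),
           pident = runif(1, 20, 90), length = sample(60:250, 1),
           evalue = 10^-runif(1, 5, 60), bitscore = runif(1, 40, 300))
  }))
  base <- nrow(best_hit_per_query(hits, filter_thresholds()))
  expect_lte(nrow(best_hit_per_query(hits, filter_thresholds(min_identity = 55))),
             base)
  expect_lte(nrow(best_hit_per_query(hits, filter_thresholds(max_evalue = 1e-30))),
             base)
  expect_lte(nrow(best_hit_per_query(hits, filter_thresholds(min_aln_len = 150))),
             base)
  loose <- nrow(best_hit_per_query(hits, filter_thresholds(min_identity = 20,
                                                           max_evalue = 1e-5,
                                                           min_aln_len = 60)))
  expect_gte(loose, base)
})

test_that("host screen removes sequences at >= 95% identity and spares the rest", {
  set.seed(42)
  clean <- rand_cds(200)                                   # 600 nt
  host_gene <- mutate_sites(clean, seq(7, 590, by = 10))   # ~10% diverged
  contaminant <- mutate_sites(host_gene, seq(13, 590, by = 60))  # ~1.7% from host
  at95 <- mutate_sites(host_gene, seq(11, 11 + 18 * 29, by = 18))  # exactly 30/600
  unigenes <- seq_records(c("u_clean", "u_cont", "u_at95"),
                          c(clean, contaminant, at95), taxon = "tx")
  assign_all <- tibble::tibble(unigene = unigenes$id, taxon = "tx",
                               ref_gene_id = "g1", sstart = 1L, send = 200L)
  host_db <- seq_records("host1", host_gene, taxon = "host")
  out <- remove_host_like(assign_all, unigenes, host_db)
  expect_true("u_clean" %in% out$unigene)     # ~90% identity, kept
  expect_false("u_cont" %in% out$unigene)     # ~98% identity, removed
  expect_false("u_at95" %in% out$unigene)     # exactly 95.00%, inclusive removal
  # empty host database: warning, unchanged
  expect_warning(out2 <- remove_host_like(assign_all, unigenes, host_db[0, ]),
                 "empty")
  expect_equal(out2, assign_all)
})

test_that("host screen boundary sits between 94.9 and 95.0 percent identity", {
  set.seed(43)
  base <- rand_cds(400)  # 1200 nt, mutate interior positions only
  h950 <- mutate_sites(base, seq(21, 21 + 19 * 59, by = 19))  # 60 diffs = 95.00
  h949 <- mutate_sites(base, seq(21, 21 + 19 * 60, by = 19))  # 61 diffs = 94.92
  unigenes <- seq_records(c("x950", "x949"), c(h950, h949), taxon = "tx")
  a <- tibble::tibble(unigene = unigenes$id, taxon = "tx",
                      ref_gene_id = "g", sstart = 1L, send = 100L)
  out <- remove_host_like(a, unigenes, seq_records("hostX", base))
  expect_false("x950" %in% out$unigene)
  expect_true("x949" %in% out$unigene)
})

test_that("paralog-overlap removal drops whole same-taxon groups past the cutoff", {
  a <- tibble::tibble(
    unigene = c("u1", "u2", "u3", "u4", "u5"),
    taxon = c("t1", "t1", "t2", "t2", "t3"),
    ref_gene_id = c("g1", "g1", "g1", "g1", "g1"),
    sstart = c(1L, 100L, 1L, 150L, 1L),
    send = c(120L, 200L, 120L, 300L, 80L))
  # t1 intervals [1,120] and [100,200] overlap by 21
  out20 <- remove_paralogs(a, overlap_cutoff = 20)
  expect_false(any(c("u1", "u2") %in% out20$unigene))  # 21 > 20: both removed
  expect_true(all(c("u3", "u4", "u5") %in% out20$unigene))  # locus persists
  out21 <- remove_paralogs(a, overlap_cutoff = 21)
  expect_true(all(c("u1", "u2") %in% out21$unigene))   # 21 <= 21: fragments
  # reverse-frame (descending) subject intervals are normalised first
  flipped <- a
  flipped$sstart <- a$send
  flipped$send <- a$sstart
  expect_equal(sort(remove_paralogs(flipped, 20)$unigene),
               sort(out20$unigene))
  # idempotent and order-independent
  expect_equal(remove_paralogs(out20, 20), out20)
  perm <- a[sample(nrow(a)), ]
  expect_setequal(remove_paralogs(perm, 20)$unigene, out20$unigene)
  expect_error(remove_paralogs(a, -1), "non-negative")
})

test_that("assembly N50 follows the standard definition", {
  expect_equal(assembly_n50(c(2, 2, 2)), 2)
  expect_equal(assembly_n50(c(1, 2, 3, 4, 10)), 10)
  expect_equal(assembly_n50(7), 7)
  recs <- seq_records(c("a", "b"), c("ACGTACGT", "AC"))
  expect_equal(assembly_n50(recs), 8)
  expect_error(assembly_n50(numeric(0)), "empty")
})
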