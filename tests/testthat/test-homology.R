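test_that("tabular hit parsing maps fields, skips comments, rejects bad lines", {
  line <- "u1\tg1\t45.0\t150\t80\t2\t1\t450\t1\t150\t1e-30\t120"
  h <- parse_tabular_hits(c("# comment", line))
  expect_equal(nrow(h), 1L)
  expect_equal(h$qseqid, "u1")
  expect_equal(h$sseqid, "g1")
  expect_equal(h$pident, 45)
  expect_equal(h$length, 150L)
  expect_equal(h$evalue, 1e-30)
  expect_equal(h$bitscore, 120)

  expect_equal(nrow(parse_tabular_hits(character(0))), 0L)
  expect_error(parse_tabular_hits("a\tb\t1\t2\t3\t4\t5\t6\t7\t8\t9"),
               "line 1")
  expect_error(parse_tabular_hits(c(line, "short\tline")), "line 2")
})

test_that("write/parse round-trips hit tables exactly", {
  set.seed(7)
  cds <- rand_cds(80)
  q <- seq_records(c("q1", "q2"), c(cds, revcomp(cds)))
  s <- seq_records("g1", scgbaits:::translate_cds(cds), kind = "protein")
  h <- search_homology(q, s, mode = "gapped", program = "blastx")
  expect_identical(parse_tabular_hits(write_tabular_hits(h)), h)
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_tabular_hits(h, tmp)
  expect_identical(read_hits(tmp), h)
  # hand-written external values survive a write/read cycle too
  ext <- parse_tabular_hits("u1\tg1\t33.33\t150\t80\t2\t1\t450\t1\t150\t1e-30\t120")
  expect_identical(parse_tabular_hits(write_tabular_hits(ext)), ext)
})

test_that("self-hits are perfect and full-length in both modes and programs", {
  set.seed(11)
  cds <- rand_cds(100)
  prot <- scgbaits:::translate_cds(cds)
  q <- seq_records("u1", cds)
  s <- seq_records("g1", prot, kind = "protein")
  for (mode in c("gapped", "ungapped")) {
    h <- search_homology(q, s, mode = mode, program = "blastx")
    expect_equal(nrow(h), 1L)
    expect_equal(h$pident, 100)
    expect_equal(h$length, nchar(prot))   # translated length
    expect_equal(h$gapopen, 0L)
    expect_equal(c(h$qstart, h$qend), c(1L, 300L))
    expect_equal(c(h$sstart, h$send), c(1L, nchar(prot)))
  }
  hn <- search_homology(seq_records("a", cds), seq_records("b", cds),
                        mode = "gapped", program = "blastn")
  expect_equal(hn$pident, 100)
  expect_equal(hn$length, nchar(cds))
})

test_that("reverse-orientation hits keep ascending query coords and flip subject", {
  set.seed(12)
  cds <- rand_cds(90)
  s <- seq_records("g1", scgbaits:::translate_cds(cds), kind = "protein")
  fwd <- search_homology(seq_records("u", cds), s, "gapped", "blastx")
  rev <- search_homology(seq_records("u", revcomp(cds)), s, "gapped", "blastx")
  expect_equal(rev$bitscore, fwd$bitscore)
  expect_equal(rev$pident, fwd$pident)
  expect_lt(rev$send, rev$sstart)        # reverse frame flagged on subject
  expect_lt(rev$qstart, rev$qend)        # query coords always ascend
  expect_equal(sort(c(rev$sstart, rev$send)), c(fwd$sstart, fwd$send))

  nt_s <- seq_records("b", cds)
  nrev <- search_homology(seq_records("a", revcomp(cds)), nt_s, "gapped",
                          "blastn")
  expect_lt(nrev$send, nrev$sstart)
  expect_equal(nrev$pident, 100)
})

test_that("an internal in-frame insertion separates gapped from ungapped mode", {
  set.seed(13)
  cds <- rand_cds(120)                       # 360 nt
  ins <- paste0(substr(cds, 1, 180), "GGATTCGAT", substr(cds, 181, 360))
  prot <- scgbaits:::translate_cds(cds)
  q <- seq_records("ui", ins)
  s <- seq_records("g1", prot, kind = "protein")
  hg <- search_homology(q, s, "gapped", "blastx")
  hu <- search_homology(q, s, "ungapped", "blastx")
  expect_gte(hg$gapopen, 1L)
  expect_equal(hu$gapopen, 0L)
  expect_gt(hg$length, hu$length)            # gapped spans both flanks
  # exhaustive DP oracles agree with the engine on this pair
  sc <- scoring_params("blastx")
  fa <- encode_prot(scgbaits:::translate_frames(ins)[["+1"]])
  fb <- encode_prot(prot)
  expect_equal(oracle_ungapped(fa, fb, sc$smat)$len, hu$length)
  raw_g <- (hg$bitscore * log(2) + log(sc$K)) / sc$lambda
  expect_equal(raw_g, oracle_sw_score(fa, fb, sc$smat, 11, 1),
               tolerance = 0.01)
})

test_that("engine agrees with brute-force oracles on seeded homologous pairs", {
  set.seed(99)
  sc <- scoring_params("blastx")
  n_checked <- 0L
  for (r in 1:100) {
    cds <- rand_cds(sample(60:140, 1))
    mut <- mutate_sites(cds, sample(nchar(cds), ceiling(nchar(cds) * 0.03)))
    if (runif(1) < 0.5) {
      p <- 3 * sample(10:(nchar(mut) / 3 - 10), 1)
      mut <- paste0(substr(mut, 1, p), rand_cds(sample(1:3, 1)),
                    substr(mut, p + 1, nchar(mut)))
    }
    prot <- scgbaits:::translate_cds(cds)
    q <- seq_records("q", mut)
    s <- seq_records("s", prot, kind = "protein")
    hg <- search_homology(q, s, "gapped", "blastx")
    hu <- search_homology(q, s, "ungapped", "blastx")
    if (nrow(hu) == 0 || nrow(hg) == 0) next
    n_checked <- n_checked + 1L
    # ungapped never longer than gapped on the same pair
    expect_lte(hu$length, hg$length)
    fa <- encode_prot(scgbaits:::translate_frames(mut)[["+1"]])
    fb <- encode_prot(prot)
    expect_equal(oracle_ungapped(fa, fb, sc$smat)$len, hu$length)
    raw_g <- (hg$bitscore * log(2) + log(sc$K)) / sc$lambda
    expect_equal(raw_g, oracle_sw_score(fa, fb, sc$smat, 11, 1),
                 tolerance = 0.01)
  }
  expect_gte(n_checked, 90L)  # near-identical pairs must practically always hit
})

test_that("gapped hits are a superset of ungapped hits on indel fixtures", {
  set.seed(55)
  cds_set <- replicate(6, rand_cds(sample(70:120, 1)))
  subjects <- seq_records(paste0("g", 1:6),
                          vapply(cds_set, scgbaits:::translate_cds,
                                 character(1)),
                          kind = "protein")
  qs <- vapply(cds_set, function(s) {
    p <- 3 * sample(15:25, 1)
    paste0(substr(s, 1, p), rand_cds(3), substr(s, p + 1, nchar(s)))
  }, character(1))
  queries <- seq_records(paste0("q", 1:6), qs)
  hg <- search_homology(queries, subjects, "gapped", "blastx")
  hu <- search_homology(queries, subjects, "ungapped", "blastx")
  expect_true(all(hu$qseqid %in% hg$qseqid))
  expect_true(all(hu$gapopen == 0L))
})

test_that("degenerate searches behave per contract", {
  q <- seq_records("q1", "ATGGCCAAATTTGGGCCCAAA")
  s_prot <- seq_records("s1", "WWWWWWWWWW", kind = "protein")
  # no word in common with any subject
  expect_equal(nrow(search_homology(q, s_prot, "gapped", "blastx")), 0L)
  # empty inputs give empty hit lists, not errors
  expect_equal(nrow(search_homology(q[0, ], s_prot, "gapped", "blastx")), 0L)
  expect_equal(nrow(search_homology(q, s_prot[0, ], "gapped", "blastx")), 0L)
  # protein queries are rejected in translated mode
  expect_error(search_homology(s_prot, s_prot, "gapped", "blastx"),
               "nucleotide")
  expect_error(search_homology(q, q, "gapped", "blastx"), "protein")
  expect_error(search_homology(q, s_prot, "gapped", "blastn"), "nucleotide")
})
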