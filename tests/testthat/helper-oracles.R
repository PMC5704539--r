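# Independent brute-force oracles used to cross-check the C++ kernels and
# the tiling rule. These deliberately re-derive everything in plain R.

# full Smith-Waterman with affine gaps (gap of length g costs go + g*ge);
# returns the optimal local score only
oracle_sw_score <- function(a, b, smat, go, ge) {
  m <- length(a); n <- length(b)
  M <- matrix(0, m + 1, n + 1)
  X <- matrix(-1e9, m + 1, n + 1)
  Y <- matrix(-1e9, m + 1, n + 1)
  best <- 0
  for (i in 2:(m + 1)) {
    for (j in 2:(n + 1)) {
      X[i, j] <- max(M[i - 1, j] - go - ge, X[i - 1, j] - ge)
      Y[i, j] <- max(M[i, j - 1] - go - ge, Y[i, j - 1] - ge)
      d <- max(0, M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1])
      M[i, j] <- max(0, d + smat[a[i - 1] + 1, b[j - 1] + 1])
      best <- max(best, M[i, j])
    }
  }
  best
}

# best ungapped segment pair: max-subarray over every diagonal
oracle_ungapped <- function(a, b, smat) {
  m <- length(a); n <- length(b)
  best <- 0; best_len <- 0
  for (d in (-(n - 1)):(m - 1)) {
    i <- max(1, d + 1); j <- i - d
    run <- 0; len <- 0
    while (i <= m && j <= n) {
      run <- run + smat[a[i] + 1, b[j] + 1]
      len <- len + 1
      if (run <= 0) { run <- 0; len <- 0 }
      if (run > best) { best <- run; best_len <- len }
      i <- i + 1; j <- j + 1
    }
  }
  list(score = best, len = best_len)
}

# closed-form bait count under the tiling rule, derived independently of
# tile_baits(): regular lattice plus one bounded-overlap terminal bait
oracle_bait_count <- function(L, bait_len = 120, step = 60, max_overlap = 80) {
  if (L < bait_len) return(0L)
  n_reg <- (L - bait_len) %/% step + 1L
  last_end <- (n_reg - 1L) * step + bait_len
  if (last_end < L && last_end - (L - bait_len) <= max_overlap) {
    n_reg <- n_reg + 1L
  }
  n_reg
}

# deterministic random CDS helpers for engine tests (no stop codons)
rand_cds <- function(n_codons) {
  codons <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                              c("A", "C", "G", "T")), 1, paste, collapse = "")
  codons <- setdiff(codons, c("TAA", "TAG", "TGA"))
  paste(sample(codons, n_codons, replace = TRUE), collapse = "")
}

mutate_sites <- function(seq, positions, to = NULL) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  for (p in positions) {
    repl <- setdiff(c("A", "C", "G", "T"), ch[p])
    ch[p] <- if (is.null(to)) repl[1] else to
  }
  paste(ch, collapse = "")
}

encode_prot <- function(x) {
  al <- scgbaits:::.protein_alphabet()
  scgbaits:::encode_seq(x, al, unknown = match("X", al))
}

encode_nt <- function(x) {
  scgbaits:::encode_seq(x, scgbaits:::.nt_alphabet(), unknown = 5L)
}

# tiny simulated study used by several files; memoised per session
mini_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- simulation_config(seed = 404L, n_scg = 8, n_paralog_pairs = 2,
                               divergence = 0, indel_rate = 0, frag_prob = 0,
                               n_host_contaminants = 3,
                               n_plastid_transcripts = 3)
      ref <- generate_reference(cfg)
      foc <- generate_focal_transcriptomes(cfg, ref)
      cache <<- list(cfg = cfg, ref = ref, foc = foc)
    }
    cache
  }
})

`%||%` <- function(a, b) if (is.null(a)) b else a
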