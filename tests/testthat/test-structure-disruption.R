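# Folding engine invariants against exhaustive enumeration, window
# extraction, the local-region distance maximization, and empirical
# p-values.

test_that("sequences without admissible pairs give all-zero matrices", {
  expect_true(all(base_pair_probabilities("AAAAAAA") == 0))
  # the only candidate pair in ACGU violates the minimum loop
  expect_true(all(base_pair_probabilities("ACGU") == 0))
  expect_error(base_pair_probabilities("ACGX"), "A,C,G,U")
  expect_error(base_pair_probabilities(""), "length")
})

test_that("pair probabilities equal Boltzmann-weighted enumeration", {
  P <- base_pair_probabilities("GGGAAAACCC")
  Q <- oracle_bpp("GGGAAAACCC")
  expect_lt(max(abs(P - Q)), 1e-12)

  set.seed(42)
  for (rep in 1:20) {
    n <- sample(5:22, 1)
    seq <- paste(sample(c("A", "C", "G", "U"), n, TRUE), collapse = "")
    P <- base_pair_probabilities(seq)
    expect_lt(max(abs(P - oracle_bpp(seq))), 1e-9)
    # structural invariants
    expect_equal(P, t(P))
    expect_true(all(P >= 0 & P <= 1))
    expect_true(all(rowSums(P) <= 1 + 1e-9))
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (abs(i - j) < 4) expect_equal(P[i, j], 0)
      }
    }
  }
})

test_that("wobble-free sequences mirror under reverse complement", {
  set.seed(7)
  for (alphabet in list(c("G", "C"), c("A", "U"))) {
    for (rep in 1:10) {
      n <- sample(10:40, 1)
      seq <- paste(sample(alphabet, n, TRUE), collapse = "")
      P <- base_pair_probabilities(seq)
      Q <- base_pair_probabilities(reverse_complement(seq))
      expect_lt(max(abs(P - Q[n:1, n:1])), 1e-12)
    }
  }
})

test_that("deterministic output and numeric stability on long sequences", {
  set.seed(3)
  seq <- paste(sample(c("A", "C", "G", "U"), 401, TRUE), collapse = "")
  P1 <- base_pair_probabilities(seq)
  P2 <- base_pair_probabilities(seq)
  expect_identical(P1, P2)
  expect_true(all(is.finite(P1)))
  expect_true(all(rowSums(P1) <= 1 + 1e-9))
  # highly structured sequence still in range
  Pg <- base_pair_probabilities(strrep("GC", 200))
  expect_true(all(is.finite(Pg)))
})

test_that("window extraction clips at transcript ends and checks ref", {
  tx <- paste(rep(c("A", "C", "G", "U"), 250), collapse = "")  # 1000 nt
  lnc <- lncrna_gene("L", "chr1", 1, 1001, "+", transcript_seq = tx)
  mk_assign <- function(off) {
    data.frame(variant_id = "v", lnc_id = "L", inside_exon = TRUE,
               offset_in_transcript = off)
  }
  # offset 500 -> full 401 nt window centred on the variant
  v <- variant("v", "chr1", 1 + 500 + 1, "A", "G")  # transcript base A at 500
  w <- extract_window(lnc, mk_assign(500), v)
  expect_equal(nchar(w$wt), 401)
  expect_equal(w$snp_offset, 200)
  expect_equal(substr(w$mut, 201, 201), "G")
  expect_equal(substr(w$wt, 201, 201), "A")

  # offset 10 -> clipped left, length 211
  v10 <- variant("v", "chr1", 1 + 10 + 1, "G", "T")  # base at 10 is G
  w10 <- extract_window(lnc, mk_assign(10), v10)
  expect_equal(nchar(w10$wt), 211)
  expect_equal(w10$snp_offset, 10)

  # reference mismatch is an error
  vbad <- variant("v", "chr1", 1 + 500 + 1, "G", "T")
  expect_error(extract_window(lnc, mk_assign(500), vbad), "mismatch")

  # minus-strand genes complement the alleles
  lnc_m <- lncrna_gene("Lm", "chr1", 1, 1001, "-", transcript_seq = tx)
  # genomic pos0 500; minus-strand offset = 1000 - 1 - 500 = 499;
  # transcript base at 499 is U, so genomic ref must be A
  vm <- variant("v", "chr1", 1 + 500 + 1, "A", "C")
  wm <- extract_window(lnc_m, mk_assign(499), vm)
  expect_equal(substr(wm$wt, wm$snp_offset + 1, wm$snp_offset + 1), "U")
  expect_equal(substr(wm$mut, wm$snp_offset + 1, wm$snp_offset + 1), "G")

  # intronic assignment is not scoreable
  expect_error(extract_window(lnc, data.frame(variant_id = "v",
                                              lnc_id = "L",
                                              inside_exon = FALSE,
                                              offset_in_transcript = NA),
                              v), "scoreable")
})

test_that("identical matrices give d = 0 with the tie-break region", {
  P <- matrix(0, 80, 80)
  r <- disruption_score(P, P, snp_offset = 60, min_region = 50)
  expect_equal(r$d, 0)
  # all regions tie at 0; smallest i then smallest j wins
  expect_equal(r$region, c(0, 60))
  r2 <- disruption_score(P, P, snp_offset = 10, min_region = 50)
  expect_equal(r2$region, c(0, 49))
})

test_that("region maximization equals an exhaustive scan", {
  exhaustive <- function(p_wt, p_mut, s0, mr) {
    n <- nrow(p_wt)
    best <- list(d = -1)
    for (i in 0:s0) {
      j_lo <- max(s0, i + mr - 1)
      if (j_lo > n - 1) next
      for (j in j_lo:(n - 1)) {
        tot <- 0
        for (u in i:(j - 1)) {
          for (v in (u + 1):j) tot <- tot + (p_wt[u + 1, v + 1] -
                                               p_mut[u + 1, v + 1])^2
        }
        d <- sqrt(tot) / (j - i + 1)
        if (d > best$d) best <- list(region = c(i, j), d = d)
      }
    }
    best
  }
  set.seed(5)
  # handcrafted 60 x 60 matrices differing in one entry
  A <- matrix(0, 60, 60)
  B <- A
  B[10, 30] <- B[30, 10] <- 0.9
  got <- disruption_score(A, B, snp_offset = 20, min_region = 50)
  want <- exhaustive(A, B, 20, 50)
  expect_equal(got$d, want$d, tolerance = 1e-12)
  expect_equal(got$region, want$region)

  # random symmetric perturbations
  for (rep in 1:5) {
    n <- 55
    A <- matrix(runif(n * n, 0, 0.2), n, n); A <- (A + t(A)) / 2
    B <- A + matrix(rnorm(n * n, 0, 0.05), n, n); B <- (B + t(B)) / 2
    s0 <- sample(0:(n - 1), 1)
    got <- disruption_score(A, B, s0, 50)
    want <- exhaustive(A, B, s0, 50)
    expect_equal(got$d, want$d, tolerance = 1e-10)
    expect_equal(got$region, want$region)
  }

  # distance symmetry under argument swap
  expect_equal(disruption_score(A, B, 10, 50)$d,
               disruption_score(B, A, 10, 50)$d)
  expect_error(disruption_score(A, matrix(0, 10, 10), 5), "dimension")
})

test_that("empirical p-values respect the add-one-smoothed bounds", {
  set.seed(9)
  seq <- paste(sample(c("A", "C", "G", "U"), 60, TRUE), collapse = "")
  # an observed distance larger than any background draw
  p_top <- empirical_pvalue(1e6, seq, n_background = 39, seed = 4)
  expect_equal(p_top, 1 / 40)
  # d = 0 is never extreme
  p_zero <- empirical_pvalue(0, seq, n_background = 39, seed = 4)
  expect_equal(p_zero, 1)
  # monotone non-increasing in the observed distance, same background
  d_grid <- c(0, 1e-4, 1e-3, 1e-2, 1)
  ps <- vapply(d_grid, empirical_pvalue, numeric(1), wt_window = seq,
               n_background = 39, seed = 4)
  expect_true(all(diff(ps) <= 0))
  # reproducible given the seed
  expect_identical(empirical_pvalue(1e-3, seq, n_background = 39, seed = 4),
                   empirical_pvalue(1e-3, seq, n_background = 39, seed = 4))
  expect_error(empirical_pvalue(1, seq, n_background = 10), ">= 19")
})

test_that("variants in unstructured poly-A context are never significant", {
  fx <- generate_structure_fixture(sim_config(seed = 3))
  am <- map_variants(list(fx$disruptive, fx$neutral), list(fx$lnc))
  res <- score_variant(fx$lnc, am[am$variant_id == "rs_neutral", ],
                       fx$neutral, list(n_background = 19, seed = 3))
  expect_equal(res$d, 0)
  expect_equal(res$p_value, 1)
  expect_false(res$significant)
  # identical inputs and seed give identical results
  res2 <- score_variant(fx$lnc, am[am$variant_id == "rs_neutral", ],
                        fx$neutral, list(n_background = 19, seed = 3))
  expect_identical(res, res2)
})
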