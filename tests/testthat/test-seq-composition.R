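# GC content, Welch t, repeat-class overlap composition, and chi-square
# enrichment with adjusted standardized residuals.

test_that("GC content excludes ambiguity codes from both sides", {
  expect_equal(gc_content("GGCC"), 1.0)
  expect_equal(gc_content("ATAT"), 0.0)
  expect_equal(gc_content("GCATN"), 0.5)
  expect_equal(gc_content("gcau"), 0.5)
  expect_error(gc_content(""), "non-empty")
  expect_error(gc_content("NNN"), "unambiguous")
  # invariant under reverse complement
  set.seed(13)
  for (rep in 1:10) {
    s <- paste(sample(c("A", "C", "G", "U"), 50, TRUE), collapse = "")
    expect_equal(gc_content(s), gc_content(reverse_complement(s)))
  }
})

test_that("Welch t matches the reference implementation to 1e-9", {
  x <- rnorm(10); w <- welch_t_test(x, x)
  expect_equal(w$statistic, 0)
  expect_equal(w$p_value, 1)
  set.seed(17)
  for (rep in 1:25) {
    x <- rnorm(sample(5:40, 1), mean = runif(1, -2, 2),
               sd = runif(1, 0.5, 3))
    y <- rnorm(sample(5:40, 1), mean = runif(1, -2, 2),
               sd = runif(1, 0.5, 3))
    got <- welch_t_test(x, y)
    ref <- t.test(x, y)
    expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(got$df, unname(ref$parameter), tolerance = 1e-9)
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-9)
  }
  expect_error(welch_t_test(1, rnorm(5)), "at least 2")
  expect_error(welch_t_test(rep(1, 5), rep(2, 5)), "degenerate")
})

test_that("repeat overlap counting is strand-agnostic and by-record", {
  lnc <- lncrna_gene("L1", "chr1", 1000, 2000, "+")
  reps <- data.frame(chrom = "chr1", start = 1100, end = 1150,
                     strand = "-", repeat_name = "AluSx",
                     repeat_class = "SINE")
  rc <- repeat_composition(reps, list(lnc))
  expect_equal(unname(rc$class_counts["SINE"]), 1L)
  expect_equal(unname(rc$class_fractions["SINE"]), 1.0)
  expect_equal(rc$harboring_fraction, 1.0)

  outside <- data.frame(chrom = "chr1", start = 5000, end = 5100,
                        strand = "+", repeat_name = "L1M5",
                        repeat_class = "LINE")
  rc0 <- repeat_composition(outside, list(lnc))
  expect_true(all(rc0$class_counts == 0))
  expect_equal(rc0$harboring_fraction, 0)
})

test_that("repeat composition equals brute-force overlap on random data", {
  set.seed(19)
  lncs <- lapply(1:40, function(i) random_lnc(sprintf("L%02d", i), "chrR"))
  classes <- c("SINE", "LINE", "LTR", "DNA", "Simple", "Low_complexity",
               "Other")
  reps <- do.call(rbind, lapply(1:120, function(i) {
    s <- sample.int(2e5, 1)
    data.frame(chrom = "chrR", start = s, end = s + sample(20:400, 1),
               strand = "+", repeat_name = "r",
               repeat_class = sample(classes, 1))
  }))
  rc <- repeat_composition(reps, lncs)
  # brute force
  hit <- logical(nrow(reps)); lnc_hit <- logical(length(lncs))
  for (i in seq_len(nrow(reps))) {
    for (k in seq_along(lncs)) {
      if (min(reps$end[i], lncs[[k]]$end) -
            max(reps$start[i], lncs[[k]]$start) >= 1) {
        hit[i] <- TRUE; lnc_hit[k] <- TRUE
      }
    }
  }
  want <- table(factor(reps$repeat_class[hit], levels = classes))
  expect_equal(unname(rc$class_counts), as.integer(want))
  expect_equal(rc$harboring_fraction, mean(lnc_hit))
})

test_that("chi-square enrichment matches the reference and flags residuals", {
  bg <- c(SINE = 100, LINE = 80, LTR = 40, DNA = 30)
  # observed exactly proportional to background -> zero statistic
  obs <- bg * 2
  r0 <- chisq_enrichment(obs, bg)
  expect_equal(r0$statistic, 0)
  expect_true(all(abs(r0$residuals) < 1e-12))

  set.seed(23)
  for (rep in 1:25) {
    k <- sample(3:6, 1)
    bg <- setNames(sample(20:200, k), paste0("c", seq_len(k)))
    obs <- setNames(sample(5:300, k), names(bg))
    got <- chisq_enrichment(obs, bg)
    ref <- suppressWarnings(chisq.test(obs, p = bg / sum(bg)))
    expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(got$df, unname(ref$parameter))
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-9)
    # sign convention: observed above expected means positive residual
    expect_true(all(sign(got$residuals[got$residuals != 0]) ==
                      sign((obs - got$expected)[got$residuals != 0])))
    # the adjusted residual equals the reference standardized residual
    expect_equal(unname(got$residuals), unname(ref$stdres),
                 tolerance = 1e-9)
  }
  # pearson variant available behind the flag
  gotp <- chisq_enrichment(c(a = 30, b = 10), c(a = 20, b = 20),
                           residual_type = "pearson")
  expect_equal(unname(gotp$residuals),
               unname((c(30, 10) - 20) / sqrt(20)), tolerance = 1e-12)

  expect_error(chisq_enrichment(c(a = 5), c(a = 10)), "2 classes")
  expect_error(chisq_enrichment(c(a = 5, b = 1), c(a = 0, b = 3)), "> 0")
})

test_that("chi-square type-I error is near nominal under the null", {
  withr::with_seed(29, {
    bg <- c(300, 250, 120, 90, 60)
    hits <- replicate(500, {
      obs <- as.vector(stats::rmultinom(1, 400, bg / sum(bg)))
      chisq_enrichment(obs, bg)$p_value < 0.05
    })
    expect_gte(mean(hits), 0.03)
    expect_lte(mean(hits), 0.07)
  })
})

test_that("composition summaries report per-gene means", {
  lncs <- list(
    lncrna_gene("a", "chr1", 0 + 1, 101, "+",
                transcript_seq = strrep("GC", 50)),
    lncrna_gene("b", "chr1", 200, 500, "+",
                transcript_seq = strrep("AU", 150)))
  s <- composition_summary(lncs)
  expect_equal(s$n, 2)
  expect_equal(s$mean_length, (100 + 300) / 2)
  expect_equal(s$mean_gc, 0.5)
})
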