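# Generators: determinism, truth-by-construction category recovery, the
# planted hairpin switch, LD targets and planted expression correlation.

test_that("generators are pure functions of their configuration", {
  cfg <- sim_config(seed = 5, n_genes = 20, n_lncs = 40, n_variants = 50)
  b1 <- generate_fixture_bundle(cfg)
  b2 <- generate_fixture_bundle(cfg)
  expect_identical(b1, b2)
  b3 <- generate_fixture_bundle(sim_config(seed = 6, n_genes = 20,
                                           n_lncs = 40, n_variants = 50))
  expect_false(identical(b1$lncs, b3$lncs))
})

test_that("configuration validation catches impossible mixes", {
  expect_error(sim_config(category_mix = c(sense_exonic = 0.5,
                                           sense_non_exonic = 0.2,
                                           antisense = 0.2,
                                           intergenic = 0.2)), "sum to 1")
  expect_error(generate_locus_fixture(
    sim_config(n_genes = 0, n_lncs = 10)), "infeasible")
  expect_error(generate_structure_fixture(sim_config(stem_len = 4)),
               ">= 6")
  expect_error(generate_expression_fixture(sim_config(n_tissues = 2)),
               ">= 3")
})

test_that("planted categories are recovered exactly by the classifier", {
  cfg <- sim_config(seed = 8, n_genes = 50, n_lncs = 200)
  fx <- generate_locus_fixture(cfg)
  got <- vapply(fx$lncs, assign_category, character(1), genes = fx$genes,
                flank = cfg$flank)
  expect_equal(unname(got), fx$truth$category)
  # generated records pass core validation (constructors already enforce it;
  # a spot check that the pieces cohere)
  for (l in fx$lncs[1:10]) {
    expect_equal(nchar(l$transcript_seq), sum(l$exons$end - l$exons$start))
  }
})

test_that("a 100% intergenic mix classifies as intergenic everywhere", {
  cfg <- sim_config(seed = 9, n_genes = 30, n_lncs = 60,
                    category_mix = c(sense_exonic = 0, sense_non_exonic = 0,
                                     antisense = 0, intergenic = 1))
  fx <- generate_locus_fixture(cfg)
  got <- vapply(fx$lncs, assign_category, character(1), genes = fx$genes)
  expect_true(all(got == "intergenic"))
})

test_that("planted variants match the transcript reference allele", {
  cfg <- sim_config(seed = 10, n_genes = 30, n_lncs = 60, n_variants = 200,
                    frac_in_lnc = 0.2)
  fx <- generate_locus_fixture(cfg)
  vx <- generate_variant_fixture(cfg, fx$lncs)
  planted <- vx$variants[vx$truth$planted_in_lnc]
  am <- map_variants(planted, fx$lncs)
  expect_true(all(vapply(planted, `[[`, character(1), "id") %in%
                    am$variant_id))
  # every planted variant is scoreable against at least one lncRNA: the one
  # it was planted in matches the transcript reference (assignments to a
  # second, overlapping lncRNA may legitimately mismatch and are skipped by
  # the pipeline)
  lid <- vapply(fx$lncs, `[[`, character(1), "gene_id")
  pid <- vapply(planted, `[[`, character(1), "id")
  ok <- setNames(logical(length(planted)), pid)
  for (k in seq_len(nrow(am))) {
    if (!am$inside_exon[k] || is.na(am$offset_in_transcript[k])) next
    v <- planted[[match(am$variant_id[k], pid)]]
    l <- fx$lncs[[match(am$lnc_id[k], lid)]]
    res <- tryCatch({
      extract_window(l, am[k, ], v)
      TRUE
    }, error = function(e) FALSE)
    if (res) ok[v$id] <- TRUE
  }
  expect_true(all(ok))
})

test_that("the hairpin fixture separates disruptive from neutral variants", {
  fx <- generate_structure_fixture(sim_config(seed = 2))
  am <- map_variants(list(fx$disruptive, fx$neutral), list(fx$lnc))
  cfgs <- list(n_background = 19, seed = 2)
  rd <- score_variant(fx$lnc, am[am$variant_id == "rs_disruptive", ],
                      fx$disruptive, cfgs)
  rn <- score_variant(fx$lnc, am[am$variant_id == "rs_neutral", ],
                      fx$neutral, cfgs)
  expect_gt(rd$d, rn$d)
  expect_equal(rn$d, 0)   # pairing-free window by construction
})

test_that("LD dosage fixtures hit their targets", {
  cfg <- sim_config(seed = 12, n_genes = 10, n_lncs = 10, n_variants = 20)
  fx <- generate_locus_fixture(cfg)
  vx <- generate_variant_fixture(cfg, fx$lncs)
  ev <- generate_evidence_fixture(cfg, vx$variants, fx$genes)
  for (pair in ev$dosage_pairs) {
    if (pair$r2_target == 0) next
    expect_lt(abs(ld_r2(pair$a, pair$b) - pair$r2_target), 0.05)
  }
  # a zero extreme-iHS fraction flags nothing
  cfg0 <- sim_config(seed = 12, n_genes = 10, n_lncs = 10, n_variants = 50,
                     ihs_extreme_frac = 0)
  ev0 <- generate_evidence_fixture(cfg0, vx$variants, fx$genes)
  att <- attach_evidence(vx$variants, ihs_table = ev0$ihs_table)
  # only rarely would a standard normal draw exceed 2.5; tolerate none here
  expect_lte(sum(att$under_selection), 2)
  expect_error(simulate_ld_pair(1.5, 100), "\\[0, 1\\]")
})

test_that("planted expression pairs carry the target rank correlation", {
  rs <- vapply(1:40, function(s) {
    fx <- generate_expression_fixture(sim_config(seed = s, n_tissues = 14))
    out <- host_lnc_correlations(fx$fpkm, fx$pairs[1, , drop = FALSE])
    out$correlations$r_s
  }, numeric(1))
  expect_lt(abs(mean(rs) - 0.8), 0.1)
  # perfect correlation at rho = 1
  fx1 <- generate_expression_fixture(sim_config(seed = 1, planted_rho = 1))
  out1 <- host_lnc_correlations(fx1$fpkm, fx1$pairs)
  expect_true(all(abs(out1$correlations$r_s - 1) < 1e-12))
})

test_that("fixture bundles survive a round trip through files", {
  cfg <- sim_config(seed = 14, n_genes = 15, n_lncs = 25, n_variants = 40)
  bundle <- generate_fixture_bundle(cfg)
  dir <- withr::local_tempdir()
  write_fixture_bundle(bundle, dir)
  back <- read_fixture_bundle(dir)
  expect_equal(length(back$lncs), length(bundle$lncs))
  expect_equal(back$variants, bundle$variants)
  expect_equal(vapply(back$lncs, `[[`, character(1), "transcript_seq"),
               vapply(bundle$lncs, `[[`, character(1), "transcript_seq"))
  expect_equal(unname(back$fpkm), unname(bundle$fpkm), tolerance = 1e-10)
})
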