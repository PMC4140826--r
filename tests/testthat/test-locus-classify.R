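# Strand-aware relation regimes and the four-category taxonomy, checked
# against definition cases, boundary conditions and a brute-force all-pairs
# oracle.

test_that("relation regimes follow the overlap and containment rules", {
  gene <- gene_model("BACH2", "chr6", 10000, 20000, "-")
  lnc_in <- lncrna_gene("L1", "chr6", 12000, 13000, "-")
  r <- classify_relation(lnc_in, gene)
  expect_equal(r$relation, "sense_full_overlap")
  expect_equal(r$overlap_bp, 1000L)
  expect_equal(r$distance_bp, 0L)

  # partial same-strand overlap of >= 1 nt
  lnc_edge <- lncrna_gene("L2", "chr6", 9500, 10001, "-")
  expect_equal(classify_relation(lnc_edge, gene)$relation,
               "sense_intersecting")
  expect_equal(classify_relation(lnc_edge, gene)$overlap_bp, 1L)

  # opposite strand overlap
  lnc_anti <- lncrna_gene("L3", "chr6", 12000, 13000, "+")
  expect_equal(classify_relation(lnc_anti, gene)$relation,
               "antisense_intersecting")

  # 2 kb upstream of a plus-strand gene, opposite strand lncRNA
  hormad2 <- gene_model("HORMAD2", "chr22", 50000, 60000, "+")
  lnc_up <- lncrna_gene("L4", "chr22", 47000, 48000, "-")
  r4 <- classify_relation(lnc_up, hormad2)
  expect_equal(r4$relation, "flanking_antisense")
  expect_equal(r4$distance_bp, -2000L)

  # different chromosome -> none
  expect_equal(classify_relation(lnc_in,
                                 gene_model("G", "chr1", 12000, 13000, "-")
               )$relation, "none")
  # unstranded input rejected
  expect_error(classify_relation(lncrna_gene("L", "chr6", 1, 10, "."), gene),
               "strand")
})

test_that("the flank rule is inclusive at exactly 5000 bp", {
  gene <- gene_model("G", "chr1", 100000, 105000, "+")
  at_flank <- lncrna_gene("L", "chr1", 94000, 95000, "+")     # gap = 5000
  beyond <- lncrna_gene("L2", "chr1", 93999, 94999, "+")      # gap = 5001
  expect_equal(classify_relation(at_flank, gene)$relation, "flanking_sense")
  expect_equal(classify_relation(beyond, gene)$relation, "none")
  # downstream distance is positive in gene-strand orientation
  down <- lncrna_gene("L3", "chr1", 106000, 107000, "+")
  expect_equal(classify_relation(down, gene)$distance_bp, 1000L)
})

test_that("category assignment follows the documented precedence", {
  gene <- gene_model("G", "chr1", 1000, 4000, "+",
                     exons = data.frame(start = c(1000, 3000),
                                        end = c(1500, 4000)))
  expect_equal(assign_category(lncrna_gene("L", "chr1", 1400, 1600, "+"),
                               list(gene)), "sense_exonic")
  expect_equal(assign_category(lncrna_gene("L", "chr1", 1600, 2900, "+"),
                               list(gene)), "sense_non_exonic")
  expect_equal(assign_category(lncrna_gene("L", "chr1", 1600, 2900, "-"),
                               list(gene)), "antisense")
  expect_equal(assign_category(lncrna_gene("L", "chr1", 5000, 5500, "-"),
                               list(gene)), "intergenic")
  expect_equal(assign_category(lncrna_gene("L", "chr1", 50000, 50500, "+"),
                               list(gene)), "unassociated")
  # precedence across multiple genes: exonic to one gene wins over
  # antisense to another
  gene2 <- gene_model("G2", "chr1", 1200, 1300, "-")
  expect_equal(assign_category(lncrna_gene("L", "chr1", 1250, 1450, "+"),
                               list(gene2, gene)), "sense_exonic")
})

test_that("association tables count regimes with full-overlap nesting", {
  gene <- gene_model("G", "chr1", 1000, 5000, "+")
  lnc <- lncrna_gene("L", "chr1", 2000, 3000, "+")
  out <- build_association_table(list(lnc), list(gene))
  expect_equal(nrow(out$records), 1)
  expect_equal(out$records$relation, "sense_full_overlap")
  s <- out$summary
  expect_equal(s$n_lnc[s$regime == "sense_intersecting"], 1L)
  expect_equal(s$n_lnc[s$regime == "sense_full_overlap"], 1L)

  # no overlaps anywhere -> empty table, all counts 0
  far <- lncrna_gene("L2", "chr9", 1, 100, "+")
  out0 <- build_association_table(list(far), list(gene))
  expect_equal(nrow(out0$records), 0)
  expect_true(all(out0$summary$n_lnc == 0))
})

test_that("interval-tree classification equals the brute-force oracle", {
  set.seed(101)
  genes <- lapply(1:60, function(i) {
    random_gene(sprintf("G%03d", i), sample(c("chrA", "chrB"), 1))
  })
  lncs <- lapply(1:300, function(i) {
    random_lnc(sprintf("L%03d", i), sample(c("chrA", "chrB"), 1))
  })
  got <- build_association_table(lncs, genes)$records
  want <- oracle_relations(lncs, genes)
  want <- want[want$relation != "none", , drop = FALSE]
  want <- want[order(want$lnc_id, want$gene_id), , drop = FALSE]
  rownames(want) <- NULL
  expect_equal(got$lnc_id, want$lnc_id)
  expect_equal(got$gene_id, want$gene_id)
  expect_equal(got$relation, want$relation)
  expect_equal(got$overlap_bp, want$overlap_bp)

  # regime nesting: full-overlap pairs are a subset of intersecting pairs
  full <- got[got$relation == "sense_full_overlap", ]
  expect_true(all(full$overlap_bp ==
                    (vapply(lncs, `[[`, integer(1), "end") -
                       vapply(lncs, `[[`, integer(1), "start"))[
                         match(full$lnc_id,
                               vapply(lncs, `[[`, character(1),
                                      "gene_id"))]))

  # order invariance
  got2 <- build_association_table(rev(lncs), sample(genes))$records
  expect_equal(got, got2)

  # category partition: every lncRNA receives exactly one category
  cats <- vapply(lncs, assign_category, character(1), genes = genes)
  expect_true(all(cats %in% c("sense_exonic", "sense_non_exonic",
                              "antisense", "intergenic", "unassociated")))
  expect_length(cats, length(lncs))
})
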