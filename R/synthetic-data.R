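# Fixture generators with known ground truth for every pipeline stage:
# gene/lncRNA architectures planted to satisfy the category definitions,
# variant tables with p-value mixtures, foldable transcripts with planted
# stem-breaking variants, evidence tables, dosage pairs at target LD, and
# FPKM matrices with planted host-lncRNA rank correlation. Every generator
# is a pure function of its config (seed included).

#' Simulation configuration with defaults
#'
#' The defaults define the study conditions the package is exercised under:
#' 200 candidate genes, 500 lncRNAs mixed over the four categories, 2,000
#' variants of which 10% are nominally significant (p < 0.01), 14 tissues,
#' planted host-lncRNA rank correlation 0.8, LD targets \{0, 0.5, 1\}, and a
#' 10 bp GC stem for the planted structure-disruptive variant.
#'
#' @param seed integer master seed
#' @param n_genes,n_lncs counts of candidate genes and lncRNAs
#' @param category_mix named proportions over
#'   sense_exonic/sense_non_exonic/antisense/intergenic (must sum to 1)
#' @param flank flanking window in bp
#' @param gc_target transcript GC fraction
#' @param n_variants,frac_nominal variant count and fraction with p < 0.01
#' @param frac_in_lnc fraction of variants planted inside lncRNA exons
#' @param n_tissues number of expression tissues
#' @param planted_rho target host-lncRNA Spearman correlation
#' @param ld_targets vector of target r-squared values for dosage pairs
#' @param n_individuals individuals per simulated dosage vector
#' @param stem_len planted hairpin stem length in bp (>= 6)
#' @param transcript_len structure-fixture transcript length in nt
#' @param ihs_extreme_frac fraction of variants with |iHS| beyond 2.5
#' @param repeat_harbor_frac fraction of lncRNAs harboring a planted repeat
#' @param repeat_class_probs named class proportions for planted repeats
#' @return list of class `sim_config`
#' @export
sim_config <- function(seed = 1,
                       n_genes = 200,
                       n_lncs = 500,
                       category_mix = c(sense_exonic = 0.30,
                                        sense_non_exonic = 0.20,
                                        antisense = 0.20,
                                        intergenic = 0.30),
                       flank = 5000,
                       gc_target = 0.45,
                       n_variants = 2000,
                       frac_nominal = 0.10,
                       frac_in_lnc = 0.05,
                       n_tissues = 14,
                       planted_rho = 0.8,
                       ld_targets = c(0, 0.5, 1.0),
                       n_individuals = 10000,
                       stem_len = 10,
                       transcript_len = 440,
                       ihs_extreme_frac = 0.05,
                       repeat_harbor_frac = 0.81,
                       repeat_class_probs = c(SINE = 0.34, LINE = 0.27,
                                              LTR = 0.13, DNA = 0.09,
                                              Simple = 0.04,
                                              Low_complexity = 0.04,
                                              Other = 0.09)) {
  cfg <- list(seed = seed, n_genes = n_genes, n_lncs = n_lncs,
              category_mix = category_mix, flank = flank,
              gc_target = gc_target, n_variants = n_variants,
              frac_nominal = frac_nominal, frac_in_lnc = frac_in_lnc,
              n_tissues = n_tissues, planted_rho = planted_rho,
              ld_targets = ld_targets, n_individuals = n_individuals,
              stem_len = stem_len, transcript_len = transcript_len,
              ihs_extreme_frac = ihs_extreme_frac,
              repeat_harbor_frac = repeat_harbor_frac,
              repeat_class_probs = repeat_class_probs)
  if (abs(sum(category_mix) - 1) > 1e-8) {
    stop("category_mix proportions must sum to 1", call. = FALSE)
  }
  if (any(unlist(cfg[c("n_genes", "n_lncs", "n_variants", "n_tissues")]) < 0)) {
    stop("counts must be >= 0", call. = FALSE)
  }
  class(cfg) <- "sim_config"
  cfg
}

random_rna <- function(n, gc) {
  paste(sample(RNA_BASES, n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Generate the gene / lncRNA locus architecture with planted categories
#'
#' Genes (3 exons of 300 bp, 800 bp introns) are laid out along four
#' chromosomes with inter-gene gaps of 3x flank so category assignments
#' cannot interfere. Each lncRNA is then *constructed* to satisfy exactly
#' its planted category under the classifier's definitions: overlapping a
#' same-strand exon, contained in a same-strand intron, overlapping the
#' gene body on the opposite strand, or disjoint but within the flank.
#'
#' @param cfg a [sim_config()]
#' @return list with `genes`, `lncs` (with transcript sequences) and
#'   `truth` (data.frame: lnc_id, category)
#' @export
generate_locus_fixture <- function(cfg) {
  mix <- cfg$category_mix
  if (cfg$n_genes == 0 && any(mix[c("sense_exonic", "sense_non_exonic",
                                    "antisense", "intergenic")] > 0) &&
      cfg$n_lncs > 0) {
    stop("infeasible mix: no genes to host gene-associated lncRNAs",
         call. = FALSE)
  }
  with_seed(derive_seed(cfg$seed, "locus"), {
    chroms <- paste0("chr", 1:4)
    exon_len <- 300L; intron_len <- 800L
    gene_span <- 3L * exon_len + 2L * intron_len
    gap <- 3L * cfg$flank
    genes <- vector("list", cfg$n_genes)
    cursor <- setNames(rep(10000L, length(chroms)), chroms)
    for (i in seq_len(cfg$n_genes)) {
      chrom <- chroms[((i - 1L) %% length(chroms)) + 1L]
      start <- cursor[[chrom]]
      ex_starts <- start + (0:2) * (exon_len + intron_len)
      genes[[i]] <- gene_model(
        sprintf("GENE%04d", i), chrom, start, start + gene_span,
        strand = sample(c("+", "-"), 1L),
        exons = data.frame(start = ex_starts, end = ex_starts + exon_len))
      cursor[[chrom]] <- start + gene_span + gap +
        sample.int(2000L, 1L)
    }

    cats <- rep(names(mix), floor(mix * cfg$n_lncs))
    while (length(cats) < cfg$n_lncs) {
      cats <- c(cats, names(mix)[which.max(mix)])
    }
    cats <- sample(cats)

    lncs <- vector("list", cfg$n_lncs)
    for (k in seq_len(cfg$n_lncs)) {
      g <- genes[[sample.int(length(genes), 1L)]]
      L <- sample(150:300, 1L)
      placed <- switch(
        cats[k],
        sense_exonic = {
          ex <- g$exons[sample.int(3L, 1L), ]
          s <- ex$start + sample.int(exon_len - 50L, 1L)
          c(s, s + L, g$strand)
        },
        sense_non_exonic = {
          intron_start <- g$exons$end[1]
          s <- intron_start + sample.int(intron_len - L - 2L, 1L)
          c(s, s + L, g$strand)
        },
        antisense = {
          s <- g$start + sample.int(gene_span - L - 1L, 1L)
          c(s, s + L, if (g$strand == "+") "-" else "+")
        },
        intergenic = {
          d <- sample.int(cfg$flank, 1L)
          e <- g$start - d
          c(e - L, e, sample(c("+", "-"), 1L))
        })
      s <- as.integer(placed[1]); e <- as.integer(placed[2])
      lncs[[k]] <- lncrna_gene(
        sprintf("LNC%04d", k), g$chrom, s, e, placed[3],
        transcript_seq = random_rna(e - s, cfg$gc_target))
    }
    list(genes = genes, lncs = lncs,
         truth = data.frame(
           lnc_id = vapply(lncs, `[[`, character(1), "gene_id"),
           category = cats))
  })
}

#' Generate a variant table over a locus fixture
#'
#' A fraction `frac_in_lnc` of variants is planted inside lncRNA exons with
#' the reference allele matching the transcript (strand-aware); the rest are
#' placed at random intergenic positions. Association p-values for the two
#' disease labels are drawn from a mixture: with probability `frac_nominal`
#' uniform below 0.01, otherwise uniform on [0.01, 1].
#'
#' @param cfg a [sim_config()]
#' @param lncs list of [lncrna_gene()] objects (from
#'   [generate_locus_fixture()])
#' @param diseases disease labels (default `c("IBD", "T1D")`)
#' @return list with `variants` and `truth` (data.frame: variant_id,
#'   planted_in_lnc)
#' @export
generate_variant_fixture <- function(cfg, lncs,
                                     diseases = c("IBD", "T1D")) {
  with_seed(derive_seed(cfg$seed, "variants"), {
    n_in <- round(cfg$n_variants * cfg$frac_in_lnc)
    variants <- vector("list", cfg$n_variants)
    in_lnc <- logical(cfg$n_variants)
    draw_p <- function() {
      p <- vapply(diseases, function(d) {
        if (runif(1) < cfg$frac_nominal) runif(1, 1e-6, 0.00999)
        else runif(1, 0.01, 1)
      }, numeric(1))
      setNames(p, diseases)
    }
    for (i in seq_len(cfg$n_variants)) {
      id <- sprintf("rs%06d", i)
      if (i <= n_in && length(lncs)) {
        l <- lncs[[sample.int(length(lncs), 1L)]]
        ex <- l$exons[sample.int(nrow(l$exons), 1L), ]
        pos0 <- ex$start + sample.int(ex$end - ex$start, 1L) - 1L
        off <- transcript_offset(l, pos0)
        base_tx <- substr(l$transcript_seq, off + 1L, off + 1L)
        ref <- if (l$strand == "-") {
          complement_base(base_tx, rna = FALSE)
        } else {
          gsub("U", "T", base_tx, fixed = TRUE)
        }
        alt <- sample(setdiff(DNA_BASES, ref), 1L)
        variants[[i]] <- variant(id, l$chrom, pos0 + 1L, ref, alt, draw_p())
        in_lnc[i] <- TRUE
      } else {
        chrom <- paste0("chr", sample.int(4L, 1L))
        pos1 <- sample.int(2000000L, 1L)
        alleles <- sample(DNA_BASES, 2L)
        variants[[i]] <- variant(id, chrom, pos1, alleles[1], alleles[2],
                                 draw_p())
      }
    }
    list(variants = variants,
         truth = data.frame(
           variant_id = vapply(variants, `[[`, character(1), "id"),
           planted_in_lnc = in_lnc))
  })
}

#' Generate a transcript with a planted hairpin and paired test variants
#'
#' Embeds a perfect GC stem-loop (stem `stem_len` bp, 4 nt A loop, mixed G/C
#' arms) in the interior of a low-structure poly-A background, followed
#' immediately by a decoy arm that can re-pair the 3' stem arm in an
#' alternative register capped at `stem_len - 1` pairs by the minimum-loop
#' constraint. The perfect stem is therefore the unique pairing maximum in
#' the wild type, while the disruptive mid-stem G-to-A substitution reduces
#' it to the decoy's level, splitting the ensemble across both registers and
#' rearranging base-pair probabilities over the whole element (a
#' conformational switch, the concentrated signal the scorer is meant to
#' detect). The neutral variant is an A-to-C substitution in a poly-A
#' stretch placed so that its folding window excludes all paired elements,
#' making its disruption distance exactly zero by construction.
#'
#' @param cfg a [sim_config()] (`stem_len >= 6`)
#' @return list with `lnc` (single-exon, plus strand), `disruptive`,
#'   `neutral` ([variant()] objects) and `truth`
#' @export
generate_structure_fixture <- function(cfg) {
  if (cfg$stem_len < 6) stop("stem_len must be >= 6", call. = FALSE)
  with_seed(derive_seed(cfg$seed, "structure"), {
    pad <- sample(100:140, 1L)
    stem <- cfg$stem_len
    mid <- stem %/% 2L
    gc_swap <- function(x) ifelse(x == "G", "C", "G")
    # 5' arm: mixed G/C, G at the mutated mid position, no homopolymer run
    # longer than 2 and low self-similarity under shifts of 1..4, so the
    # pairing register of the planted stem is unique (shifted or periodic
    # registers would smear the wild-type ensemble)
    max_run <- function(x) max(rle(x)$lengths)
    shifted_match <- function(x, s) {
      mean(x[seq_len(length(x) - s)] == x[seq_len(length(x) - s) + s])
    }
    repeat {
      arm1 <- sample(c("G", "C"), stem, replace = TRUE)
      if (!(arm1[mid + 1L] == "G" && max_run(arm1) <= 2L &&
            all(vapply(1:4, shifted_match, numeric(1), x = arm1) <= 0.6))) {
        next
      }
      # verify the construction: the planted mid-stem break must rearrange
      # the element's pairing ensemble substantially (folded in isolation,
      # deterministically), else redraw the arm
      arm2 <- rev(gc_swap(arm1))
      decoy <- c("A", "A", "A",
                 vapply(3:(stem + 1L), function(j) {
                   gc_swap(arm2[stem + 2L - j])
                 }, character(1)))
      probe <- paste0(strrep("A", 30), paste(arm1, collapse = ""), "AAAA",
                      paste(arm2, collapse = ""),
                      paste(decoy, collapse = ""), strrep("A", 30))
      probe_mut <- probe
      substr(probe_mut, 31L + mid, 31L + mid) <- "A"
      dp <- base_pair_probabilities(probe) -
        base_pair_probabilities(probe_mut)
      if (sum(dp[upper.tri(dp)]^2) >= 1.7) break
    }
    # 3' arm pairs arm1 in reverse
    arm2 <- rev(gc_swap(arm1))
    # decoy directly after arm2: re-pairs arm2 slots 0..stem-2 in a shifted
    # register; the 3 leading A's plus the minimum-loop rule cap it at
    # stem - 1 pairs, one short of the perfect stem
    decoy <- c("A", "A", "A",
               vapply(3:(stem + 1L), function(j) gc_swap(arm2[stem + 2L - j]),
                      character(1)))
    head_len <- pad + stem + 4L + stem + length(decoy)
    if (cfg$transcript_len < head_len + 50L) {
      stop("transcript_len too short for the planted hairpin", call. = FALSE)
    }
    tx <- paste0(strrep("A", pad), paste(arm1, collapse = ""), "AAAA",
                 paste(arm2, collapse = ""), paste(decoy, collapse = ""),
                 strrep("A", cfg$transcript_len - head_len))
    gstart <- 1000L
    lnc <- lncrna_gene("LNC_HAIRPIN", "chrS", gstart,
                       gstart + cfg$transcript_len, "+",
                       transcript_seq = tx)
    dis_off <- pad + mid                                 # mid-stem G
    neu_off <- cfg$transcript_len - sample(10:25, 1L)    # deep in poly-A tail
    disruptive <- variant("rs_disruptive", "chrS", gstart + dis_off + 1L,
                          "G", "A", c(SIM = 0.001))
    neutral <- variant("rs_neutral", "chrS", gstart + neu_off + 1L,
                       "A", "C", c(SIM = 0.001))
    list(lnc = lnc, disruptive = disruptive, neutral = neutral,
         truth = data.frame(variant_id = c("rs_disruptive", "rs_neutral"),
                            disruptive = c(TRUE, FALSE)))
  })
}

#' Simulate a pair of dosage vectors at a target LD r-squared
#'
#' Haplotypes at two biallelic loci with allele frequency 0.5 and
#' disequilibrium `D = sqrt(r2)/4`; dosages are sums of two independent
#' haplotype draws. `r2 = 1` yields identical dosage vectors.
#'
#' @param r2_target target squared correlation in `[0, 1]`
#' @param n number of individuals
#' @return list with `a`, `b` (integer dosage vectors)
#' @export
simulate_ld_pair <- function(r2_target, n) {
  if (r2_target < 0 || r2_target > 1) {
    stop("r2_target must lie in [0, 1]", call. = FALSE)
  }
  D <- sqrt(r2_target) / 4
  hap_p <- c(AB = 0.25 + D, Ab = 0.25 - D, aB = 0.25 - D, ab = 0.25 + D)
  if (any(hap_p < -1e-12)) {
    stop("unreachable r2 for the given allele frequencies", call. = FALSE)
  }
  hap_p <- pmax(hap_p, 0)
  h1 <- sample.int(4L, n, replace = TRUE, prob = hap_p)
  h2 <- sample.int(4L, n, replace = TRUE, prob = hap_p)
  a_allele <- c(1L, 1L, 0L, 0L)  # carries A at locus 1
  b_allele <- c(1L, 0L, 1L, 0L)  # carries B at locus 2
  list(a = a_allele[h1] + a_allele[h2], b = b_allele[h1] + b_allele[h2])
}

#' Generate evidence tables (regulome, iHS, eQTL, TSS) and LD dosage pairs
#'
#' @param cfg a [sim_config()]
#' @param variants list of [variant()] objects
#' @param genes list of [gene_model()] objects (eQTL targets and TSS table)
#' @return list with `regulome_table`, `ihs_table`, `eqtl_table`,
#'   `tss_table`, `dosage_pairs` (one element per `cfg$ld_targets` entry)
#' @export
generate_evidence_fixture <- function(cfg, variants, genes) {
  with_seed(derive_seed(cfg$seed, "evidence"), {
    ids <- vapply(variants, `[[`, character(1), "id")
    n <- length(ids)

    reg_ids <- sample(ids, size = round(0.5 * n))
    regulome_table <- data.frame(
      variant_id = reg_ids,
      score = sample(regulome_levels_default(), length(reg_ids),
                     replace = TRUE))

    extreme <- runif(n) < cfg$ihs_extreme_frac
    ihs <- rnorm(n, 0, 1)
    ihs[extreme] <- sample(c(-1, 1), sum(extreme), replace = TRUE) *
      (2.5 + stats::rexp(sum(extreme)))
    ihs_table <- data.frame(variant_id = ids, ihs = ihs)

    tss_table <- data.frame(
      gene_id = vapply(genes, `[[`, character(1), "gene_id"),
      tss = vapply(genes, function(g) {
        if (g$strand == "-") g$end else g$start + 1L
      }, integer(1)))
    gene_chrom <- vapply(genes, `[[`, character(1), "chrom")
    gene_tss0 <- tss_table$tss - 1L

    tissues <- c("adipose_subcutaneous", "artery_tibial",
                 "heart_left_ventricle", "lung", "muscle_skeletal",
                 "nerve_tibial", "skin_sun_exposed", "thyroid",
                 "whole_blood")
    eqtl_rows <- list()
    for (i in seq_len(n)) {
      if (runif(1) >= 0.3) next
      v <- variants[[i]]
      near <- which(gene_chrom == v$chrom &
                      abs(gene_tss0 - v$pos) <= 1e6)
      if (!length(near)) next
      pick <- sample(near, min(length(near), sample.int(3L, 1L)))
      eqtl_rows[[length(eqtl_rows) + 1L]] <- data.frame(
        variant_id = v$id,
        gene_id = tss_table$gene_id[pick],
        tissue = sample(tissues, length(pick), replace = TRUE),
        p = runif(length(pick), 1e-8, 0.05))
    }
    eqtl_table <- if (length(eqtl_rows)) {
      do.call(rbind, eqtl_rows)
    } else {
      data.frame(variant_id = character(0), gene_id = character(0),
                 tissue = character(0), p = numeric(0))
    }

    dosage_pairs <- lapply(cfg$ld_targets, function(r2) {
      c(list(r2_target = r2), simulate_ld_pair(r2, cfg$n_individuals))
    })
    list(regulome_table = regulome_table, ihs_table = ihs_table,
         eqtl_table = eqtl_table, tss_table = tss_table,
         dosage_pairs = dosage_pairs)
  })
}

#' Generate a RepeatMasker-style repeat annotation over a lncRNA set
#'
#' Plants one repeat inside a `repeat_harbor_frac` fraction of the lncRNAs
#' (class drawn from `repeat_class_probs`) plus an equal number of decoy
#' repeats far from every lncRNA.
#'
#' @param cfg a [sim_config()]
#' @param lncs list of [lncrna_gene()] objects
#' @return list with `repeats` (data.frame: chrom, start, end, strand,
#'   repeat_name, repeat_class) and `truth` (harboring lnc ids)
#' @export
generate_repeat_fixture <- function(cfg, lncs) {
  with_seed(derive_seed(cfg$seed, "repeats"), {
    n_h <- round(cfg$repeat_harbor_frac * length(lncs))
    harb <- sample(seq_along(lncs), n_h)
    probs <- cfg$repeat_class_probs
    rows <- lapply(harb, function(k) {
      l <- lncs[[k]]
      w <- min(50L, l$end - l$start)
      s <- l$start + sample.int(max(1L, l$end - l$start - w), 1L) - 1L
      cls <- sample(names(probs), 1L, prob = probs)
      data.frame(chrom = l$chrom, start = s, end = s + w,
                 strand = sample(c("+", "-"), 1L),
                 repeat_name = paste0(cls, "_rep"), repeat_class = cls)
    })
    decoys <- lapply(seq_len(n_h), function(i) {
      cls <- sample(names(probs), 1L, prob = probs)
      data.frame(chrom = "chrDecoy", start = i * 1000L,
                 end = i * 1000L + 50L, strand = "+",
                 repeat_name = paste0(cls, "_rep"), repeat_class = cls)
    })
    list(repeats = do.call(rbind, c(rows, decoys)),
         truth = vapply(lncs[harb], `[[`, character(1), "gene_id"))
  })
}

#' Generate an FPKM matrix with planted host-lncRNA rank correlation
#'
#' Planted (lnc, gene) pairs share a latent per-tissue effect scaled so the
#' population Spearman correlation equals `planted_rho` (via the bivariate
#' normal relation where Pearson `2 sin(pi rho / 6)` on the log scale
#' yields Spearman rho; rank
#' correlation cannot distinguish the log from the FPKM scale). Unplanted
#' genes are
#' independent log-normal noise.
#'
#' @param cfg a [sim_config()]
#' @param pairs optional data.frame with `lnc_id`, `gene_id` naming the
#'   planted pairs; defaults to 20 synthetic pairs
#' @param extra_ids additional ids to include as unplanted rows
#' @return list with `fpkm` (matrix), `pairs` (the planted truth)
#' @export
generate_expression_fixture <- function(cfg, pairs = NULL,
                                        extra_ids = character(0)) {
  if (cfg$n_tissues < 3) stop("n_tissues must be >= 3", call. = FALSE)
  with_seed(derive_seed(cfg$seed, "expression"), {
    if (is.null(pairs)) {
      pairs <- data.frame(lnc_id = sprintf("LNCX%03d", 1:20),
                          gene_id = sprintf("GENEX%03d", 1:20))
    }
    r <- 2 * sin(pi * cfg$planted_rho / 6)
    nt <- cfg$n_tissues
    tissues <- sprintf("tissue_%02d", seq_len(nt))
    rows <- list()
    for (k in seq_len(nrow(pairs))) {
      z <- rnorm(nt)
      lg_l <- 0.5 + 0.6 * z
      lg_g <- 0.8 + 0.6 * (r * z + sqrt(1 - r^2) * rnorm(nt))
      rows[[pairs$lnc_id[k]]] <- 10^lg_l
      rows[[pairs$gene_id[k]]] <- 10^lg_g
    }
    for (id in setdiff(extra_ids, names(rows))) {
      rows[[id]] <- 10^(0.3 + 0.7 * rnorm(nt))
    }
    m <- do.call(rbind, rows)
    colnames(m) <- tissues
    validate_expression_matrix(m)
    list(fpkm = m, pairs = pairs)
  })
}

#' Generate a complete fixture bundle for the end-to-end pipeline
#'
#' Fans the master seed out to per-stage seeds so each sub-generator is
#' independently reproducible, then assembles genes, lncRNAs (with
#' transcripts), variants, evidence tables, repeats and an FPKM matrix whose
#' planted pairs are the fixture's own sense-overlapping (lnc, gene) pairs.
#'
#' @param cfg a [sim_config()]
#' @return list of class `fixture_bundle`
#' @export
generate_fixture_bundle <- function(cfg) {
  locus <- generate_locus_fixture(cfg)
  vars <- generate_variant_fixture(cfg, locus$lncs)
  evid <- generate_evidence_fixture(cfg, vars$variants, locus$genes)
  reps <- generate_repeat_fixture(cfg, locus$lncs)
  sense <- locus$truth$lnc_id[locus$truth$category %in%
                                c("sense_exonic", "sense_non_exonic")]
  host <- vapply(sense, function(id) {
    l <- locus$lncs[[match(id, locus$truth$lnc_id)]]
    hits <- vapply(locus$genes, function(g) {
      g$chrom == l$chrom && min(l$end, g$end) - max(l$start, g$start) >= 1
    }, logical(1))
    locus$genes[[which(hits)[1]]]$gene_id
  }, character(1))
  pairs <- data.frame(lnc_id = sense, gene_id = unname(host))
  n_pairs <- min(nrow(pairs), 25L)
  pairs <- pairs[seq_len(n_pairs), , drop = FALSE]
  all_ids <- c(vapply(locus$lncs, `[[`, character(1), "gene_id"),
               vapply(locus$genes, `[[`, character(1), "gene_id"))
  expr <- generate_expression_fixture(cfg, pairs = pairs,
                                      extra_ids = all_ids)
  structure(
    list(config = cfg, genes = locus$genes, lncs = locus$lncs,
         category_truth = locus$truth, variants = vars$variants,
         variant_truth = vars$truth, regulome_table = evid$regulome_table,
         ihs_table = evid$ihs_table, eqtl_table = evid$eqtl_table,
         tss_table = evid$tss_table, dosage_pairs = evid$dosage_pairs,
         repeats = reps$repeats, fpkm = expr$fpkm,
         expression_pairs = expr$pairs),
    class = "fixture_bundle"
  )
}

#' Write a fixture bundle to disk in the formats the pipeline reads
#'
#' @param bundle a `fixture_bundle`
#' @param dir output directory (created if missing)
#' @return the directory, invisibly
#' @export
write_fixture_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_gene_bed(bundle$genes, file.path(dir, "genes.bed"))
  write_gene_bed(bundle$lncs, file.path(dir, "lncs.bed"))
  tx <- vapply(bundle$lncs, function(l) {
    if (is.null(l$transcript_seq)) "" else l$transcript_seq
  }, character(1))
  ids <- vapply(bundle$lncs, `[[`, character(1), "gene_id")
  keep <- nzchar(tx)
  writeLines(paste0(">", ids[keep], "\n", tx[keep]),
             file.path(dir, "transcripts.fa"))
  write_variant_table(bundle$variants, file.path(dir, "variants.tsv"))
  for (nm in c("regulome_table", "ihs_table", "eqtl_table", "tss_table",
               "repeats")) {
    write.table(bundle[[nm]], file.path(dir, paste0(nm, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  fpkm_out <- data.frame(gene_id = rownames(bundle$fpkm), bundle$fpkm,
                         check.names = FALSE)
  write.table(fpkm_out, file.path(dir, "fpkm.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}
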