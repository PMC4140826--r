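# End-to-end orchestration: classify -> map -> score -> annotate -> rank ->
# composition stats -> expression, with deterministic outputs and a run
# manifest.

#' Pipeline configuration
#'
#' Thresholds default to the analysis conditions: nominal cut-off
#' alpha = 0.01 (strict), 5 kb flank, +/-200 nt folding window, 50 nt
#' minimum disruption region, disruption significance p <= 0.2, +/-1 Mb cis
#' window, |iHS| >= 2.5, FPKM > 1.
#'
#' @param bundle a `fixture_bundle` (in-memory inputs), or NULL when
#'   `input_dir` is given
#' @param input_dir directory of files written by [write_fixture_bundle()]
#' @param outdir output directory for TSVs and the manifest (NULL = keep
#'   results in memory only)
#' @param diseases disease labels to analyse (default: all labels present)
#' @param alpha,flank,radius,min_region,p_threshold,n_background,cis_window,ihs_threshold,fpkm_threshold,pair_weight,seed
#'   stage parameters; see the stage functions
#' @return list of class `pipeline_config`
#' @export
pipeline_config <- function(bundle = NULL, input_dir = NULL, outdir = NULL,
                            diseases = NULL, alpha = 0.01, flank = 5000,
                            radius = 200, min_region = 50,
                            p_threshold = 0.2, n_background = 200,
                            cis_window = 1e6, ihs_threshold = 2.5,
                            fpkm_threshold = 1.0, pair_weight = exp(3.5),
                            seed = 1) {
  check_prob_open_closed(alpha, "alpha")
  check_prob_open_closed(p_threshold, "p_threshold")
  stopifnot(flank >= 0, radius >= 1, min_region >= 1, n_background >= 19,
            cis_window >= 0, ihs_threshold >= 0, fpkm_threshold >= 0,
            pair_weight > 0)
  structure(
    list(bundle = bundle, input_dir = input_dir, outdir = outdir,
         diseases = diseases, alpha = alpha, flank = flank, radius = radius,
         min_region = min_region, p_threshold = p_threshold,
         n_background = n_background, cis_window = cis_window,
         ihs_threshold = ihs_threshold, fpkm_threshold = fpkm_threshold,
         pair_weight = pair_weight, seed = seed),
    class = "pipeline_config"
  )
}

#' Read a fixture bundle back from files
#' @param dir directory written by [write_fixture_bundle()]
#' @return list with the pipeline's input tables
#' @export
read_fixture_bundle <- function(dir) {
  lncs <- read_gene_bed(file.path(dir, "lncs.bed"), biotype = "lncRNA")
  tx <- read_fasta(file.path(dir, "transcripts.fa"))
  lncs <- lapply(lncs, function(l) {
    if (l$gene_id %in% names(tx)) {
      l <- lncrna_gene(l$gene_id, l$chrom, l$start, l$end, l$strand,
                       l$exons, tx[[l$gene_id]])
    }
    l
  })
  list(
    genes = read_gene_bed(file.path(dir, "genes.bed")),
    lncs = lncs,
    variants = read_variant_table(file.path(dir, "variants.tsv")),
    regulome_table = read_table(file.path(dir, "regulome_table.tsv"),
                                c(variant_id = "character",
                                  score = "character")),
    ihs_table = read_table(file.path(dir, "ihs_table.tsv"),
                           c(variant_id = "character", ihs = "numeric")),
    eqtl_table = read_table(file.path(dir, "eqtl_table.tsv"),
                            c(variant_id = "character",
                              gene_id = "character", tissue = "character",
                              p = "numeric")),
    tss_table = read_table(file.path(dir, "tss_table.tsv"),
                           c(gene_id = "character", tss = "integer")),
    repeats = read_table(file.path(dir, "repeats.tsv"),
                         c(chrom = "character", start = "integer",
                           end = "integer", repeat_class = "character")),
    fpkm = read_fpkm_matrix(file.path(dir, "fpkm.tsv"))
  )
}

#' Run the full analysis pipeline
#'
#' Stages, in order: lncRNA-gene classification; nominal-variant filtering
#' and mapping per disease; structure-disruption scoring of exonic
#' assignments; evidence annotation and ranking; sequence-composition
#' statistics; expression filtering and host-gene correlations. Unscoreable
#' variants (intronic, missing transcript, reference mismatch) are recorded
#' in a skipped list, never dropped silently. Outputs are deterministic
#' given the seed; re-running with the same configuration produces
#' byte-identical files.
#'
#' @param cfg a [pipeline_config()]
#' @return list of class `pipeline_result` with elements `association`,
#'   `categories`, `per_disease` (assignments, disruption results, ranked
#'   table, skipped list per disease), `composition`, `repeat_stats`,
#'   `expression`, `counts`, `manifest`
#' @export
run_pipeline <- function(cfg) {
  bundle <- if (!is.null(cfg$input_dir)) {
    read_fixture_bundle(cfg$input_dir)
  } else if (!is.null(cfg$bundle)) {
    cfg$bundle
  } else {
    stop("pipeline needs a bundle or an input_dir", call. = FALSE)
  }
  genes <- bundle$genes
  lncs <- bundle$lncs
  variants <- bundle$variants

  assoc <- build_association_table(lncs, genes, cfg$flank)
  categories <- data.frame(
    lnc_id = vapply(lncs, `[[`, character(1), "gene_id"),
    category = vapply(lncs, assign_category, character(1), genes = genes,
                      flank = cfg$flank))

  diseases <- cfg$diseases
  if (is.null(diseases)) {
    diseases <- sort(unique(unlist(lapply(variants, function(v) {
      names(v$assoc_p)
    }))))
  }
  lnc_ids <- vapply(lncs, `[[`, character(1), "gene_id")
  var_ids <- vapply(variants, `[[`, character(1), "id")

  score_cfg <- list(radius = cfg$radius, min_region = cfg$min_region,
                    n_background = cfg$n_background,
                    p_threshold = cfg$p_threshold,
                    pair_weight = cfg$pair_weight,
                    seed = derive_seed(cfg$seed, "score"))

  per_disease <- list()
  for (d in diseases) {
    nominal <- filter_nominal(variants, d, cfg$alpha)
    assignments <- map_variants(nominal, lncs)
    exonic <- assignments[assignments$inside_exon &
                            !is.na(assignments$offset_in_transcript), ,
                          drop = FALSE]
    results <- list()
    skipped <- list()
    if (nrow(assignments)) {
      for (k in seq_len(nrow(assignments))) {
        a <- assignments[k, ]
        l <- lncs[[match(a$lnc_id, lnc_ids)]]
        v <- nominal[[match(a$variant_id,
                            vapply(nominal, `[[`, character(1), "id"))]]
        if (!a$inside_exon || is.na(a$offset_in_transcript)) {
          skipped[[length(skipped) + 1L]] <- data.frame(
            variant_id = a$variant_id, lnc_id = a$lnc_id,
            reason = if (!a$inside_exon) "intronic" else "no transcript")
          next
        }
        res <- tryCatch(score_variant(l, a, v, score_cfg),
                        error = function(e) conditionMessage(e))
        if (is.character(res)) {
          skipped[[length(skipped) + 1L]] <- data.frame(
            variant_id = a$variant_id, lnc_id = a$lnc_id, reason = res)
        } else {
          results[[length(results) + 1L]] <- res
        }
      }
    }
    res_df <- if (length(results)) {
      do.call(rbind, lapply(results, function(r) {
        data.frame(variant_id = r$variant_id, lnc_id = r$lnc_id,
                   region_start = r$region[1], region_end = r$region[2],
                   d = r$d, p_value = r$p_value,
                   significant = r$significant)
      }))
    } else {
      data.frame(variant_id = character(0), lnc_id = character(0),
                 region_start = integer(0), region_end = integer(0),
                 d = numeric(0), p_value = numeric(0),
                 significant = logical(0))
    }
    evidence <- attach_evidence(nominal, bundle$regulome_table,
                                bundle$eqtl_table, bundle$ihs_table,
                                bundle$tss_table, cfg$cis_window,
                                cfg$ihs_threshold)
    ranked <- rank_variants(res_df[, c("variant_id", "lnc_id", "d",
                                       "p_value")],
                            evidence, nominal, cfg$p_threshold)
    per_disease[[d]] <- list(
      n_nominal = length(nominal),
      assignments = assignments,
      n_mapped_exonic = nrow(exonic),
      disruption = res_df,
      skipped = if (length(skipped)) do.call(rbind, skipped) else
        data.frame(variant_id = character(0), lnc_id = character(0),
                   reason = character(0)),
      evidence = evidence,
      ranked = ranked)
  }

  composition <- composition_summary(lncs)
  repeat_stats <- if (!is.null(bundle$repeats)) {
    rc_all <- repeat_composition(bundle$repeats, lncs)
    hit_lncs <- unique(unlist(lapply(per_disease, function(pd) {
      pd$assignments$lnc_id
    })))
    enrich <- NULL
    if (length(hit_lncs) >= 2) {
      rc_hit <- repeat_composition(
        bundle$repeats, lncs[lnc_ids %in% hit_lncs])
      keep <- rc_all$class_counts > 0
      if (sum(keep) >= 2 && sum(rc_hit$class_counts[keep]) > 0) {
        enrich <- chisq_enrichment(rc_hit$class_counts[keep],
                                   rc_all$class_counts[keep])
      }
    }
    list(all = rc_all, enrichment = enrich)
  }

  expression <- if (!is.null(bundle$fpkm)) {
    pairs <- if (!is.null(bundle$expression_pairs)) {
      bundle$expression_pairs
    } else {
      sense <- assoc$records[assoc$records$relation %in%
                               c("sense_intersecting",
                                 "sense_full_overlap"), , drop = FALSE]
      unique(sense[, c("lnc_id", "gene_id")])
    }
    list(expressed = expressed_across_all(bundle$fpkm, cfg$fpkm_threshold),
         not_detected = fraction_not_detected(bundle$fpkm,
                                              cfg$fpkm_threshold),
         host_correlations = host_lnc_correlations(bundle$fpkm, pairs))
  }

  counts <- do.call(rbind, lapply(names(per_disease), function(d) {
    pd <- per_disease[[d]]
    data.frame(disease = d, n_nominal = pd$n_nominal,
               n_mapped = nrow(pd$assignments),
               n_mapped_exonic = pd$n_mapped_exonic,
               n_scored = nrow(pd$disruption),
               n_significant = sum(pd$disruption$significant),
               n_ranked = nrow(pd$ranked))
  }))

  result <- structure(
    list(association = assoc, categories = categories,
         per_disease = per_disease, composition = composition,
         repeat_stats = repeat_stats, expression = expression,
         counts = counts,
         manifest = pipeline_manifest(cfg)),
    class = "pipeline_result"
  )
  if (!is.null(cfg$outdir)) write_pipeline_result(result, cfg$outdir)
  result
}

#' Run manifest: configuration hash, seed and package version
#' @keywords internal
pipeline_manifest <- function(cfg) {
  show <- cfg[setdiff(names(cfg), c("bundle", "outdir"))]
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(paste(names(show),
                   vapply(show, function(x) paste(format(x), collapse = ","),
                          character(1)),
                   sep = "="), tmp)
  data.frame(key = c("config_md5", "seed", "package_version"),
             value = c(unname(tools::md5sum(tmp)), format(cfg$seed),
                       as.character(utils::packageVersion("lncdisrupt"))))
}

#' Write all pipeline result tables as TSV
#' @param result a `pipeline_result`
#' @param dir output directory
#' @export
write_pipeline_result <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(x, name) {
    write.table(x, file.path(dir, paste0(name, ".tsv")), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  wt(result$association$records, "association")
  wt(result$association$summary, "association_summary")
  wt(result$categories, "categories")
  for (d in names(result$per_disease)) {
    pd <- result$per_disease[[d]]
    wt(pd$assignments, paste0("assignments_", d))
    wt(pd$disruption, paste0("disruption_", d))
    wt(pd$skipped, paste0("skipped_", d))
    wt(pd$ranked, paste0("ranked_", d))
  }
  wt(result$counts, "counts")
  wt(result$composition, "composition")
  if (!is.null(result$expression)) {
    writeLines(result$expression$expressed,
               file.path(dir, "expressed_all_tissues.txt"))
    wt(result$expression$host_correlations$correlations,
       "host_correlations")
  }
  wt(result$manifest, "manifest")
  invisible(dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat("  lncRNA-gene association records:", nrow(x$association$records),
      "\n")
  print(x$counts)
  invisible(x)
}
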