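# Annotation of structure-disruptive variants with regulatory scores,
# cis-eQTL hits, recent-selection flags and LD, and the lexicographic
# ranking of significant variants.

#' Default ordered RegulomeDB-style category vocabulary (best evidence first)
#' @export
regulome_levels_default <- function() {
  c("1a", "1b", "1c", "1d", "1e", "1f", "2a", "2b", "2c",
    "3a", "3b", "4", "5", "6", "7")
}

#' Attach regulatory / eQTL / selection evidence to variants
#'
#' Annotation never changes the variant set: variants absent from a table get
#' an unknown score, an empty eQTL list, or `under_selection = FALSE`. eQTL
#' rows are retained only when the variant lies within `cis_window` bp
#' (inclusive) of the target gene's transcription start site.
#' `under_selection` is TRUE iff `|iHS| >= ihs_threshold` (inclusive).
#'
#' @param variants list of [variant()] objects
#' @param regulome_table data.frame with columns `variant_id`, `score`
#' @param eqtl_table data.frame with columns `variant_id`, `gene_id`,
#'   `tissue`, `p`
#' @param ihs_table data.frame with columns `variant_id`, `ihs`
#' @param tss_table data.frame with columns `gene_id`, `tss` (1-based bp)
#' @param cis_window cis window in bp around the TSS (default 1e6, inclusive)
#' @param ihs_threshold absolute iHS cut-off for recent positive selection
#'   (default 2.5, inclusive)
#' @param regulome_levels ordered category vocabulary, best evidence first
#' @return data.frame with one row per variant: `variant_id`,
#'   `regulome_score` (NA = unknown), `n_eqtl`, `under_selection`, `ihs`,
#'   plus a list-column `eqtl_hits` of per-variant data.frames
#' @export
attach_evidence <- function(variants, regulome_table = NULL,
                            eqtl_table = NULL, ihs_table = NULL,
                            tss_table = NULL, cis_window = 1e6,
                            ihs_threshold = 2.5,
                            regulome_levels = regulome_levels_default()) {
  ids <- vapply(variants, `[[`, character(1), "id")
  pos0 <- setNames(vapply(variants, `[[`, integer(1), "pos"), ids)

  reg <- rep(NA_character_, length(ids))
  if (!is.null(regulome_table) && nrow(regulome_table)) {
    bad <- setdiff(regulome_table$score, regulome_levels)
    if (length(bad)) {
      stop("unknown regulome score(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    m <- match(ids, regulome_table$variant_id)
    reg <- regulome_table$score[m]
  }

  ihs <- rep(NA_real_, length(ids))
  if (!is.null(ihs_table) && nrow(ihs_table)) {
    v <- suppressWarnings(as.numeric(ihs_table$ihs))
    if (anyNA(v)) stop("malformed iHS value(s)", call. = FALSE)
    m <- match(ids, ihs_table$variant_id)
    ihs <- v[m]
  }
  under_sel <- !is.na(ihs) & abs(ihs) >= ihs_threshold

  eqtl_hits <- rep(list(data.frame(gene_id = character(0),
                                   tissue = character(0),
                                   p = numeric(0))), length(ids))
  if (!is.null(eqtl_table) && nrow(eqtl_table)) {
    if (is.null(tss_table)) {
      stop("eqtl_table requires a tss_table for cis-window pruning",
           call. = FALSE)
    }
    p_num <- suppressWarnings(as.numeric(eqtl_table$p))
    check_prob_open_closed(p_num[!is.na(p_num)], "eQTL p")
    tss0 <- setNames(as.numeric(tss_table$tss) - 1, tss_table$gene_id)
    for (k in seq_along(ids)) {
      rows <- eqtl_table[eqtl_table$variant_id == ids[k], , drop = FALSE]
      if (!nrow(rows)) next
      tss_k <- tss0[rows$gene_id]
      in_cis <- !is.na(tss_k) & abs(pos0[[k]] - tss_k) <= cis_window
      rows <- rows[in_cis, c("gene_id", "tissue", "p"), drop = FALSE]
      rows$p <- as.numeric(rows$p)
      rownames(rows) <- NULL
      eqtl_hits[[k]] <- rows
    }
  }

  out <- data.frame(variant_id = ids, regulome_score = reg,
                    n_eqtl = vapply(eqtl_hits, nrow, integer(1)),
                    under_selection = under_sel, ihs = ihs)
  out$eqtl_hits <- eqtl_hits
  out
}

#' Squared allelic correlation (composite LD) from genotype dosages
#'
#' The square of the Pearson correlation between two dosage vectors coded
#' 0/1/2 over the same individuals; symmetric and invariant to swapping
#' allele coding (d -> 2 - d).
#'
#' @param dosages_a,dosages_b numeric vectors of equal length >= 3, values in
#'   \{0, 1, 2\}, neither constant
#' @return r-squared in `[0, 1]`
#' @export
ld_r2 <- function(dosages_a, dosages_b) {
  if (length(dosages_a) != length(dosages_b) || length(dosages_a) < 3) {
    stop("dosage vectors must have equal length >= 3", call. = FALSE)
  }
  if (!all(dosages_a %in% 0:2) || !all(dosages_b %in% 0:2)) {
    stop("dosages must be 0, 1 or 2", call. = FALSE)
  }
  if (stats::var(dosages_a) == 0 || stats::var(dosages_b) == 0) {
    stop("LD undefined for a constant dosage vector", call. = FALSE)
  }
  cor(dosages_a, dosages_b)^2
}

#' Rank significant structure-disruptive variants by combined evidence
#'
#' Admits only results with disruption p-value at or below `p_threshold`
#' and sorts them by the lexicographic comparator: (1) regulome score
#' ascending with unknown last; (2) variants with at least one cis-eQTL hit
#' before those with none; (3) under recent selection before not; (4)
#' disruption p-value ascending; (5) tie-break by (chrom, pos, variant_id).
#' The ordering is deterministic, total, and invariant to input order.
#'
#' @param results list of `disruption_result` objects (from
#'   [score_variant()]) or a data.frame with columns `variant_id`, `lnc_id`,
#'   `d`, `p_value`
#' @param evidence data.frame from [attach_evidence()]
#' @param variants list of [variant()] objects (for chrom/pos tie-breaks)
#' @param p_threshold significance cut-off on the disruption p-value
#'   (default 0.2, inclusive)
#' @param regulome_levels ordered category vocabulary
#' @return data.frame with columns `rank`, `variant_id`, `lnc_id`, `d`,
#'   `p_value`, `regulome_score`, `n_eqtl`, `under_selection`
#' @export
rank_variants <- function(results, evidence, variants, p_threshold = 0.2,
                          regulome_levels = regulome_levels_default()) {
  if (!is.data.frame(results)) {
    results <- do.call(rbind, lapply(results, function(r) {
      data.frame(variant_id = r$variant_id, lnc_id = r$lnc_id, d = r$d,
                 p_value = r$p_value)
    }))
  }
  empty <- data.frame(rank = integer(0), variant_id = character(0),
                      lnc_id = character(0), d = numeric(0),
                      p_value = numeric(0), regulome_score = character(0),
                      n_eqtl = integer(0), under_selection = logical(0))
  if (is.null(results) || !nrow(results)) return(empty)
  results <- results[results$p_value <= p_threshold, , drop = FALSE]
  if (!nrow(results)) return(empty)

  ev <- evidence[match(results$variant_id, evidence$variant_id), , drop = FALSE]
  ids <- vapply(variants, `[[`, character(1), "id")
  vm <- match(results$variant_id, ids)
  chrom <- vapply(seq_along(vm), function(k) {
    if (is.na(vm[k])) "" else variants[[vm[k]]]$chrom
  }, character(1))
  pos <- vapply(seq_along(vm), function(k) {
    if (is.na(vm[k])) NA_integer_ else variants[[vm[k]]]$pos
  }, integer(1))

  reg_idx <- match(ev$regulome_score, regulome_levels)
  reg_idx[is.na(reg_idx)] <- length(regulome_levels) + 1L  # unknown last
  has_eqtl <- !is.na(ev$n_eqtl) & ev$n_eqtl > 0
  under_sel <- !is.na(ev$under_selection) & ev$under_selection

  o <- order(reg_idx, !has_eqtl, !under_sel, results$p_value, chrom, pos,
             results$variant_id, method = "radix")
  out <- data.frame(rank = seq_along(o),
                    variant_id = results$variant_id[o],
                    lnc_id = results$lnc_id[o],
                    d = results$d[o],
                    p_value = results$p_value[o],
                    regulome_score = ev$regulome_score[o],
                    n_eqtl = ifelse(is.na(ev$n_eqtl[o]), 0L, ev$n_eqtl[o]),
                    under_selection = under_sel[o])
  rownames(out) <- NULL
  out
}
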