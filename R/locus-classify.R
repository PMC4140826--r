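# Strand-aware classification of lncRNAs against candidate genes: overlap
# regimes (sense intersecting / sense 100% overlapping / antisense
# intersecting / flanking) and the four-category taxonomy (sense exonic,
# sense non-exonic, antisense, intergenic).

RELATION_LEVELS <- c("sense_full_overlap", "sense_intersecting",
                     "antisense_intersecting", "flanking_sense",
                     "flanking_antisense", "none")

CATEGORY_LEVELS <- c("sense_exonic", "sense_non_exonic", "antisense",
                     "intergenic", "unassociated")

#' Classify the relation of one lncRNA to one candidate gene
#'
#' Overlap regimes, in precedence order: same-strand overlap with the lncRNA
#' span fully inside the gene span is `sense_full_overlap`; any same-strand
#' overlap of at least 1 nt is `sense_intersecting`; opposite-strand overlap
#' is `antisense_intersecting`. Non-overlapping pairs whose boundary gap is
#' at most `flank` bp (inclusive, measured from the gene-span boundaries)
#' are `flanking_sense` / `flanking_antisense` by strand match; everything
#' else (including different chromosomes) is `none`.
#'
#' `distance_bp` is 0 for overlapping pairs and otherwise signed in
#' gene-strand orientation: negative when the lncRNA lies upstream of the
#' gene's 5' end, positive when downstream of its 3' end.
#'
#' @param lnc an [lncrna_gene()]
#' @param gene a [gene_model()]
#' @param flank flanking window in bp (default 5000)
#' @return list with elements `relation`, `overlap_bp`, `distance_bp`
#' @export
classify_relation <- function(lnc, gene, flank = 5000) {
  if (lnc$strand == "." || gene$strand == ".") {
    stop("classify_relation is strand-aware; unstranded input not allowed",
         call. = FALSE)
  }
  if (lnc$chrom != gene$chrom) {
    return(list(relation = "none", overlap_bp = 0L, distance_bp = NA_integer_))
  }
  ov <- min(lnc$end, gene$end) - max(lnc$start, gene$start)
  same <- lnc$strand == gene$strand
  if (ov >= 1L) {
    rel <- if (same) {
      if (lnc$start >= gene$start && lnc$end <= gene$end) {
        "sense_full_overlap"
      } else {
        "sense_intersecting"
      }
    } else {
      "antisense_intersecting"
    }
    return(list(relation = rel, overlap_bp = as.integer(ov),
                distance_bp = 0L))
  }
  # disjoint: gap between closest boundaries
  if (lnc$end <= gene$start) {
    gap <- gene$start - lnc$end
    left_of_gene <- TRUE
  } else {
    gap <- lnc$start - gene$end
    left_of_gene <- FALSE
  }
  if (gap <= flank) {
    # sign in gene-strand orientation: upstream of gene start is negative
    upstream <- if (gene$strand == "+") left_of_gene else !left_of_gene
    dist <- if (upstream) -as.integer(gap) else as.integer(gap)
    rel <- if (same) "flanking_sense" else "flanking_antisense"
    return(list(relation = rel, overlap_bp = 0L, distance_bp = dist))
  }
  list(relation = "none", overlap_bp = 0L, distance_bp = NA_integer_)
}

#' Assign the positional category of a lncRNA against a gene set
#'
#' Precedence: `sense_exonic` (same-strand overlap with at least one exon of
#' any gene) > `sense_non_exonic` (same-strand overlap with a gene body but
#' no exon) > `antisense` (opposite-strand overlap) > `intergenic` (no
#' overlap with any gene but within `flank` bp of at least one) >
#' `unassociated`.
#'
#' @inheritParams classify_relation
#' @param genes list of [gene_model()] objects
#' @param use_exon_union if TRUE, gene-body overlap is assessed against the
#'   union of exons rather than the full gene span (surfacing the choice of
#'   span vs exon-union intersection substrate)
#' @return single category string
#' @export
assign_category <- function(lnc, genes, flank = 5000,
                            use_exon_union = FALSE) {
  if (lnc$strand == ".") {
    stop("assign_category is strand-aware; unstranded lncRNA not allowed",
         call. = FALSE)
  }
  best <- "unassociated"
  rank <- function(cat) match(cat, CATEGORY_LEVELS)
  for (gene in genes) {
    if (gene$chrom != lnc$chrom) next
    body_ov <- if (use_exon_union) {
      any(pmin(lnc$end, gene$exons$end) -
            pmax(lnc$start, gene$exons$start) >= 1L)
    } else {
      min(lnc$end, gene$end) - max(lnc$start, gene$start) >= 1L
    }
    same <- lnc$strand == gene$strand
    cat <- if (body_ov) {
      if (same) {
        exon_ov <- any(pmin(lnc$end, gene$exons$end) -
                         pmax(lnc$start, gene$exons$start) >= 1L)
        if (exon_ov) "sense_exonic" else "sense_non_exonic"
      } else {
        "antisense"
      }
    } else {
      gap <- if (lnc$end <= gene$start) {
        gene$start - lnc$end
      } else if (lnc$start >= gene$end) {
        lnc$start - gene$end
      } else {
        0L  # overlap with span but not exon union under use_exon_union
      }
      if (gap <= flank) "intergenic" else "unassociated"
    }
    if (rank(cat) < rank(best)) best <- cat
  }
  best
}

#' Build the full lncRNA-gene association table with regime summary counts
#'
#' One record per (lncRNA, gene) pair whose relation is not `none`, computed
#' with GenomicRanges interval overlap (equivalent to a brute-force all-pairs
#' scan). Summary counts report, per regime, the number of distinct lncRNA
#' genes and distinct candidate genes; `sense_intersecting` counts include
#' `sense_full_overlap` pairs (the nesting regime), which are also counted
#' separately.
#'
#' @param lncs list of [lncrna_gene()] objects
#' @param genes list of [gene_model()] objects
#' @param flank flanking window in bp
#' @return list with `records` (data.frame: lnc_id, gene_id, relation,
#'   overlap_bp, distance_bp) and `summary` (data.frame: regime, n_lnc,
#'   n_gene)
#' @export
build_association_table <- function(lncs, genes, flank = 5000) {
  empty <- data.frame(lnc_id = character(0), gene_id = character(0),
                      relation = character(0), overlap_bp = integer(0),
                      distance_bp = integer(0))
  if (!length(lncs) || !length(genes)) {
    return(list(records = empty,
                summary = regime_summary(empty)))
  }
  lgr <- genes_to_granges(lncs)
  ggr <- genes_to_granges(genes)
  # candidate pairs within flank, strand-agnostic at this stage
  # disjoint chromosome sets are a valid no-overlap case, not a warning
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(lgr, ggr, maxgap = flank,
                                ignore.strand = TRUE))
  li <- S4Vectors::queryHits(hits)
  gi <- S4Vectors::subjectHits(hits)
  rec <- lapply(seq_along(li), function(k) {
    r <- classify_relation(lncs[[li[k]]], genes[[gi[k]]], flank)
    if (r$relation == "none") return(NULL)
    data.frame(lnc_id = lncs[[li[k]]]$gene_id,
               gene_id = genes[[gi[k]]]$gene_id,
               relation = r$relation, overlap_bp = r$overlap_bp,
               distance_bp = r$distance_bp)
  })
  rec <- rec[!vapply(rec, is.null, logical(1))]
  records <- if (length(rec)) do.call(rbind, rec) else empty
  records <- records[order(records$lnc_id, records$gene_id), , drop = FALSE]
  rownames(records) <- NULL
  list(records = records, summary = regime_summary(records))
}

#' Per-regime distinct lncRNA / gene counts
#' @keywords internal
regime_summary <- function(records) {
  count <- function(keep) {
    c(n_lnc = length(unique(records$lnc_id[keep])),
      n_gene = length(unique(records$gene_id[keep])))
  }
  sense_any <- records$relation %in% c("sense_intersecting",
                                       "sense_full_overlap")
  rows <- rbind(
    sense_intersecting = count(sense_any),
    sense_full_overlap = count(records$relation == "sense_full_overlap"),
    antisense_intersecting = count(records$relation ==
                                     "antisense_intersecting"),
    flanking_sense = count(records$relation == "flanking_sense"),
    flanking_antisense = count(records$relation == "flanking_antisense")
  )
  data.frame(regime = rownames(rows), n_lnc = rows[, "n_lnc"],
             n_gene = rows[, "n_gene"], row.names = NULL)
}

#' Write an association table (records and summary) as TSV
#' @param assoc result of [build_association_table()]
#' @param records_path,summary_path output paths (NULL to skip)
#' @export
write_association_table <- function(assoc, records_path = NULL,
                                    summary_path = NULL) {
  if (!is.null(records_path)) {
    write.table(assoc$records, records_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  if (!is.null(summary_path)) {
    write.table(assoc$summary, summary_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(assoc)
}
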