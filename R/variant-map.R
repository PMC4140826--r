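# Nominal-significance filtering of GWAS variants and mapping into lncRNA
# genes, with spliced-transcript offsets for exonic hits.

#' Filter variants at nominal significance for one disease
#'
#' Keeps variants whose association p-value for `disease` is strictly below
#' `alpha` (the nominal cut-off p < 0.01). Variants lacking a p-value for the
#' disease are dropped.
#'
#' @param variants list of [variant()] objects
#' @param disease disease label to filter on
#' @param alpha significance cut-off in (0, 1]; comparison is strict
#' @return filtered list of variants
#' @export
filter_nominal <- function(variants, disease, alpha = 0.01) {
  check_prob_open_closed(alpha, "alpha")
  stop_if_not_scalar_string(disease, "disease")
  Filter(function(v) {
    disease %in% names(v$assoc_p) && v$assoc_p[[disease]] < alpha
  }, variants)
}

#' Map variants into lncRNA genes
#'
#' Produces one assignment for every (variant, lncRNA) pair with the variant
#' position inside the lncRNA span `[start, end)`. `inside_exon` is TRUE iff
#' the position falls in an exon; for exonic hits with a transcript sequence
#' available, `offset_in_transcript` is the 0-based position in the spliced
#' transcript, strand-aware (minus-strand offsets count from the 3' genomic
#' end). Intronic assignments are retained and flagged, not dropped.
#'
#' @param variants list of [variant()] objects
#' @param lncs list of [lncrna_gene()] objects
#' @return data.frame with columns `variant_id`, `lnc_id`, `inside_exon`,
#'   `offset_in_transcript` (NA when absent)
#' @export
map_variants <- function(variants, lncs) {
  empty <- data.frame(variant_id = character(0), lnc_id = character(0),
                      inside_exon = logical(0),
                      offset_in_transcript = integer(0))
  if (!length(variants) || !length(lncs)) return(empty)
  vgr <- variants_to_granges(variants)
  lgr <- genes_to_granges(lncs)
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(vgr, lgr, ignore.strand = TRUE))
  vi <- S4Vectors::queryHits(hits)
  li <- S4Vectors::subjectHits(hits)
  if (!length(vi)) return(empty)
  rows <- lapply(seq_along(vi), function(k) {
    v <- variants[[vi[k]]]
    l <- lncs[[li[k]]]
    off <- transcript_offset(l, v$pos)
    data.frame(variant_id = v$id, lnc_id = l$gene_id,
               inside_exon = !is.na(off),
               offset_in_transcript = if (!is.na(off) &&
                                          !is.null(l$transcript_seq)) {
                 off
               } else {
                 NA_integer_
               })
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$variant_id, out$lnc_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' 0-based spliced-transcript offset of a genomic position within a lncRNA
#'
#' Returns NA for intronic (or out-of-exon) positions. For minus-strand
#' genes the offset counts from the 3' genomic end (i.e. transcript 5' end).
#'
#' @param lnc an [lncrna_gene()]
#' @param pos 0-based genomic position
#' @return integer offset or NA
#' @export
transcript_offset <- function(lnc, pos) {
  ex <- lnc$exons
  hit <- which(pos >= ex$start & pos < ex$end)
  if (!length(hit)) return(NA_integer_)
  before <- if (hit > 1) sum(ex$end[seq_len(hit - 1)] -
                               ex$start[seq_len(hit - 1)]) else 0L
  plus_off <- before + (pos - ex$start[hit])
  total <- sum(ex$end - ex$start)
  if (lnc$strand == "-") {
    as.integer(total - 1L - plus_off)
  } else {
    as.integer(plus_off)
  }
}

#' Variant ids shared between two assignment sets
#'
#' Deduplicated and sorted lexicographically (C locale), mirroring the
#' cross-disease shared-variant comparison.
#'
#' @param set_a,set_b assignment data.frames from [map_variants()] (or
#'   anything with a `variant_id` column), or character vectors of ids
#' @return sorted character vector of shared ids
#' @export
shared_variants <- function(set_a, set_b) {
  ids <- function(x) {
    if (is.data.frame(x)) unique(x$variant_id) else unique(as.character(x))
  }
  sort(intersect(ids(set_a), ids(set_b)), method = "radix")
}
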