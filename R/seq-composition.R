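# Length, GC and repeat-class composition of lncRNA sets with the comparison
# statistics: Welch two-sample t, chi-square goodness of fit against
# background proportions, and adjusted standardized residuals.

#' GC content of a sequence
#'
#' `(#G + #C) / (#A + #C + #G + #T/U)`, case-insensitive; ambiguity codes
#' are excluded from both the counts and the denominator. Invariant under
#' reverse complement.
#'
#' @param seq non-empty sequence string (DNA or RNA)
#' @return fraction in `[0, 1]`
#' @export
gc_content <- function(seq) {
  if (!is.character(seq) || length(seq) != 1 || !nzchar(seq)) {
    stop("seq must be a non-empty string", call. = FALSE)
  }
  ch <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  gc <- sum(ch %in% c("G", "C"))
  denom <- sum(ch %in% c("A", "C", "G", "T", "U"))
  if (denom == 0) stop("sequence has no unambiguous bases", call. = FALSE)
  gc / denom
}

#' Welch two-sample t-test
#'
#' `t = (mean(x) - mean(y)) / sqrt(var(x)/nx + var(y)/ny)` with
#' Welch-Satterthwaite degrees of freedom and a two-sided p-value from the
#' Student-t distribution.
#'
#' @param x,y numeric samples, each of size >= 2 with nonzero variance
#' @return list with `statistic`, `df`, `p_value`
#' @export
welch_t_test <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) {
    stop("each sample needs at least 2 observations", call. = FALSE)
  }
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx == 0 && vy == 0) {
    stop("degenerate samples: both variances are zero", call. = FALSE)
  }
  nx <- length(x); ny <- length(y)
  se2 <- vx / nx + vy / ny
  t_stat <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  p <- 2 * pt(-abs(t_stat), df)
  list(statistic = t_stat, df = df, p_value = p)
}

#' Repeat-class composition of a lncRNA set
#'
#' A repeat counts toward a lncRNA when they overlap by at least 1 bp,
#' strand-agnostic (genomic repeats are annotated irrespective of transcript
#' strand). Class percentages are computed over the distinct repeat records
#' that overlap at least one lncRNA (each repeat counted once even when it
#' overlaps several lncRNAs).
#'
#' @param repeats data.frame as returned by
#'   `read_table(format = "repeatmasker")`: columns `chrom`, `start`, `end`,
#'   `repeat_class` (0-based half-open)
#' @param lncs list of [lncrna_gene()] objects
#' @return list with `class_counts` (named integer vector over the class
#'   vocabulary), `class_fractions`, `harboring_fraction` (fraction of
#'   lncRNAs with >= 1 repeat), `n_lnc_with_repeat`
#' @export
repeat_composition <- function(repeats, lncs) {
  classes <- c("SINE", "LINE", "LTR", "DNA", "Simple", "Low_complexity",
               "Other")
  counts <- setNames(integer(length(classes)), classes)
  if (!length(lncs) || !nrow(repeats)) {
    return(list(class_counts = counts,
                class_fractions = counts / max(1L, sum(counts)),
                harboring_fraction = 0, n_lnc_with_repeat = 0L))
  }
  rgr <- GenomicRanges::GRanges(
    seqnames = repeats$chrom,
    ranges = IRanges::IRanges(start = repeats$start + 1L, end = repeats$end))
  lgr <- genes_to_granges(lncs)
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(rgr, lgr, ignore.strand = TRUE))
  rep_hit <- unique(S4Vectors::queryHits(hits))
  lnc_hit <- unique(S4Vectors::subjectHits(hits))
  tab <- table(factor(repeats$repeat_class[rep_hit], levels = classes))
  counts[] <- as.integer(tab)
  list(class_counts = counts,
       class_fractions = counts / max(1L, sum(counts)),
       harboring_fraction = length(lnc_hit) / length(lncs),
       n_lnc_with_repeat = length(lnc_hit))
}

#' Chi-square goodness-of-fit enrichment test against background proportions
#'
#' Expected counts are `E_i = N * p_i` with `p_i` taken from the background
#' proportions; `X^2 = sum((O_i - E_i)^2 / E_i)` on `k - 1` degrees of
#' freedom. Residuals are adjusted standardized residuals
#' `r_i = (O_i - E_i) / sqrt(E_i * (1 - p_i))` by default (the simple
#' Pearson residual `(O_i - E_i)/sqrt(E_i)` is available via
#' `residual_type`); classes with `|r_i| > z_crit` are flagged enriched
#' (positive) or depleted (negative).
#'
#' @param observed named per-class counts (>= 2 classes, N > 0)
#' @param background named per-class counts, all > 0, same classes
#' @param residual_type `"adjusted"` (default) or `"pearson"`
#' @param z_crit residual flag threshold (default 1.96)
#' @return list with `statistic`, `df`, `p_value`, `residuals`, `expected`,
#'   `flagged` (named character: "enriched"/"depleted"/"none")
#' @export
chisq_enrichment <- function(observed, background,
                             residual_type = c("adjusted", "pearson"),
                             z_crit = 1.96) {
  residual_type <- match.arg(residual_type)
  if (length(observed) < 2) stop("need at least 2 classes (df = k - 1 > 0)",
                                 call. = FALSE)
  if (!is.null(names(background)) && !is.null(names(observed))) {
    background <- background[names(observed)]
  }
  if (length(background) != length(observed) || anyNA(background)) {
    stop("observed and background must cover the same classes",
         call. = FALSE)
  }
  if (any(background <= 0)) stop("all background counts must be > 0",
                                 call. = FALSE)
  N <- sum(observed)
  if (N <= 0) stop("sum of observed counts must be > 0", call. = FALSE)
  p <- background / sum(background)
  E <- N * p
  X2 <- sum((observed - E)^2 / E)
  df <- length(observed) - 1
  pv <- pchisq(X2, df, lower.tail = FALSE)
  r <- if (residual_type == "adjusted") {
    (observed - E) / sqrt(E * (1 - p))
  } else {
    (observed - E) / sqrt(E)
  }
  flagged <- ifelse(abs(r) > z_crit, ifelse(r > 0, "enriched", "depleted"),
                    "none")
  if (!is.null(names(observed))) names(flagged) <- names(observed)
  list(statistic = X2, df = df, p_value = max(pv, .Machine$double.xmin),
       residuals = r, expected = E, flagged = flagged)
}

#' Per-set composition summary (n, mean length, mean GC)
#'
#' Length is the genomic span; GC is computed per gene from the transcript
#' sequence where available (unweighted per-gene average).
#'
#' @param lncs list of [lncrna_gene()] objects
#' @return data.frame with one row: `n`, `mean_length`, `mean_gc`
#' @export
composition_summary <- function(lncs) {
  lens <- vapply(lncs, function(g) g$end - g$start, integer(1))
  gcs <- vapply(lncs, function(g) {
    if (is.null(g$transcript_seq)) NA_real_ else gc_content(g$transcript_seq)
  }, numeric(1))
  data.frame(n = length(lncs),
             mean_length = if (length(lens)) mean(lens) else NA_real_,
             mean_gc = if (any(!is.na(gcs))) mean(gcs, na.rm = TRUE)
                       else NA_real_)
}
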