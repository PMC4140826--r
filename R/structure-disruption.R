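# Secondary-structure disruption scoring: fold +/-200 nt windows around each
# exonic variant, compare wild-type vs mutant base-pair probabilities over
# local regions by length-normalized Euclidean distance, and attach empirical
# p-values from a background of random single-nucleotide substitutions.

#' Base-pair probability matrix of an RNA sequence
#'
#' Equilibrium pair probabilities over the ensemble of secondary structures
#' under a simple nearest-pair energy model: every canonical or wobble pair
#' (AU, UA, GC, CG, GU, UG) contributes the same Boltzmann factor
#' `pair_weight`, hairpin loops contain at least `min_loop` unpaired bases,
#' and there are no stacking or loop-type terms. Computed by a
#' McCaskill-style inside-outside partition function (O(n^3)); deterministic.
#' A full thermodynamic engine can be substituted behind the same contract
#' without changing interfaces or invariants.
#'
#' @param seq RNA string over `{A,C,G,U}`, length 1..2000 (`T` accepted)
#' @param pair_weight Boltzmann factor per pair (> 0); the default `exp(3.5)`
#'   corresponds to roughly -2.2 kcal/mol per pair at 37 C, within the range of real helix stacking energies
#' @param min_loop minimum hairpin loop length (default 3)
#' @return symmetric n x n matrix with entries in `[0,1]`, zero for
#'   non-pairable bases and for `|i - j| <= min_loop`; row sums at most 1
#' @export
base_pair_probabilities <- function(seq, pair_weight = exp(3.5), min_loop = 3) {
  seq <- dna_to_rna(seq)
  n <- nchar(seq)
  if (n < 1 || n > 2000) {
    stop("sequence length must be in 1..2000", call. = FALSE)
  }
  if (!is.numeric(pair_weight) || pair_weight <= 0) {
    stop("pair_weight must be positive", call. = FALSE)
  }
  codes <- match(strsplit(seq, "")[[1]], RNA_BASES) - 1L
  if (anyNA(codes)) {
    stop("sequence contains characters outside {A,C,G,U}", call. = FALSE)
  }
  bpp_matrix_cpp(codes, pair_weight, as.integer(min_loop))
}

#' Extract wild-type and mutant folding windows around a variant
#'
#' The window spans `[offset - radius, offset + radius]` on the spliced
#' transcript, clipped (not discarded) at the transcript ends. The transcript
#' base at the variant offset must equal the reference allele after
#' strand-aware complementation for minus-strand genes; the mutant window
#' differs from the wild type at exactly the variant position.
#'
#' @param lnc an [lncrna_gene()] with `transcript_seq`
#' @param assignment one row of a [map_variants()] data.frame (exonic, with
#'   `offset_in_transcript`)
#' @param variant the corresponding [variant()] (for ref/alt alleles)
#' @param radius window radius in nt (default 200)
#' @return list with `wt`, `mut` (RNA strings), `snp_offset` (0-based within
#'   the window), `window_start` (0-based transcript offset of window start)
#' @export
extract_window <- function(lnc, assignment, variant, radius = 200) {
  if (is.null(lnc$transcript_seq)) {
    stop("lncRNA ", lnc$gene_id, " has no transcript sequence", call. = FALSE)
  }
  if (!isTRUE(assignment$inside_exon) ||
      is.na(assignment$offset_in_transcript)) {
    stop("variant ", variant$id, " is not scoreable: intronic or no ",
         "transcript offset", call. = FALSE)
  }
  off <- as.integer(assignment$offset_in_transcript)
  tx <- lnc$transcript_seq
  L <- nchar(tx)
  if (off < 0 || off >= L) stop("offset outside transcript", call. = FALSE)
  minus <- lnc$strand == "-"
  ref_tx <- if (minus) complement_base(variant$ref) else dna_to_rna(variant$ref)
  alt_tx <- if (minus) complement_base(variant$alt) else dna_to_rna(variant$alt)
  have <- substr(tx, off + 1L, off + 1L)
  if (have != ref_tx) {
    stop("reference mismatch for ", variant$id, ": transcript has ", have,
         " but expected ", ref_tx, " at offset ", off, call. = FALSE)
  }
  w_start <- max(0L, off - as.integer(radius))
  w_end <- min(L - 1L, off + as.integer(radius))  # inclusive
  wt <- substr(tx, w_start + 1L, w_end + 1L)
  snp_off <- off - w_start
  mut <- wt
  substr(mut, snp_off + 1L, snp_off + 1L) <- alt_tx
  list(wt = wt, mut = mut, snp_offset = snp_off, window_start = w_start)
}

#' Local region of maximal base-pair probability change
#'
#' Over all regions `[i, j]` (0-based, inclusive) containing the variant
#' position with length at least `min_region`, computes the
#' length-normalized Euclidean distance
#' `d(i,j) = sqrt(sum_(i<=u<v<=j) (P_wt[u,v] - P_mut[u,v])^2) / (j - i + 1)`
#' and returns the maximizing region. Ties are broken by smallest `i`, then
#' smallest `j`. `min_region` is clamped to the window length for short
#' windows.
#'
#' @param p_wt,p_mut base-pair probability matrices of equal dimension
#' @param snp_offset 0-based variant position within the window
#' @param min_region minimum region length (default 50)
#' @return list with `region` (integer c(i, j), 0-based inclusive) and `d`
#' @export
disruption_score <- function(p_wt, p_mut, snp_offset, min_region = 50) {
  n <- nrow(p_wt)
  if (!identical(dim(p_wt), dim(p_mut))) {
    stop("matrix dimension mismatch", call. = FALSE)
  }
  if (snp_offset < 0 || snp_offset >= n) {
    stop("snp_offset outside window", call. = FALSE)
  }
  min_region <- min(as.integer(min_region), n)
  diff2 <- (p_wt - p_mut)^2
  diff2[lower.tri(diff2, diag = TRUE)] <- 0
  # 2D prefix sums: S[a+1, b+1] = sum of diff2[1..a, 1..b]
  S <- matrix(0, n + 1L, n + 1L)
  S[-1L, -1L] <- t(apply(apply(diff2, 2L, cumsum), 1L, cumsum))
  s0 <- as.integer(snp_offset)
  # enumerate admissible regions [i, j], i ascending then j ascending, so
  # which.max realizes the smallest-i-then-smallest-j tie-break
  is <- 0:s0
  j_lo <- pmax(s0, is + min_region - 1L)
  keep <- j_lo <= n - 1L
  is <- is[keep]
  j_lo <- j_lo[keep]
  if (!length(is)) stop("no admissible region", call. = FALSE)
  counts <- n - j_lo
  I <- rep.int(is, counts)
  J <- sequence(counts, from = j_lo, by = 1L)
  Sv <- as.vector(S)
  lin <- function(r, c) r + (n + 1L) * (c - 1L)
  box <- Sv[lin(J + 2L, J + 2L)] - Sv[lin(I + 1L, J + 2L)] -
    Sv[lin(J + 2L, I + 1L)] + Sv[lin(I + 1L, I + 1L)]
  d_all <- sqrt(pmax(box, 0)) / (J - I + 1L)
  k <- which.max(d_all)
  list(region = c(I[k], J[k]), d = d_all[k])
}

#' Empirical p-value of an observed disruption distance
#'
#' Draws `n_background` random single-nucleotide substitutions (position
#' uniform over the window, alternate allele uniform over the three
#' non-reference bases), scores each against the wild type with
#' [disruption_score()], and returns the add-one-smoothed tail probability
#' `p = (1 + #(background d >= d_obs)) / (n_background + 1)`. Windows with
#' no pairing potential simply yield all-zero background distances.
#'
#' @param d_obs observed distance
#' @param wt_window wild-type RNA string
#' @param snp_offset 0-based variant position (used only to mirror the
#'   observed scoring configuration; background positions are uniform)
#' @param n_background number of background draws (>= 19)
#' @param seed integer seed for reproducibility
#' @param min_region,pair_weight passed through to the scoring components
#' @return p-value in `[1/(n_background+1), 1]`
#' @export
empirical_pvalue <- function(d_obs, wt_window, snp_offset = NULL,
                             n_background = 1000, seed = 1,
                             min_region = 50, pair_weight = exp(3.5)) {
  if (n_background < 19) stop("n_background must be >= 19", call. = FALSE)
  wt_window <- dna_to_rna(wt_window)
  n <- nchar(wt_window)
  p_wt <- base_pair_probabilities(wt_window, pair_weight)
  d_bg <- with_seed(as.integer(seed), {
    vapply(seq_len(n_background), function(b) {
      pos <- sample.int(n, 1L) - 1L
      ref <- substr(wt_window, pos + 1L, pos + 1L)
      alt <- sample(setdiff(RNA_BASES, ref), 1L)
      mut <- wt_window
      substr(mut, pos + 1L, pos + 1L) <- alt
      p_mut <- base_pair_probabilities(mut, pair_weight)
      disruption_score(p_wt, p_mut, pos, min_region)$d
    }, numeric(1))
  })
  (1 + sum(d_bg >= d_obs)) / (n_background + 1)
}

#' Score one mapped variant for structure disruption
#'
#' Composes [extract_window()], [base_pair_probabilities()] (wild type and
#' mutant), [disruption_score()] and [empirical_pvalue()]. A variant is
#' called significant when its empirical p-value is at most `p_threshold`
#' (default 0.2).
#'
#' @inheritParams extract_window
#' @param config list of tuning parameters: `radius` (200), `min_region`
#'   (50), `n_background` (1000), `p_threshold` (0.2), `pair_weight`
#'   (`exp(3.5)`), `seed` (1)
#' @return a `disruption_result` list: `variant_id`, `lnc_id`, `region`
#'   (0-based inclusive window coordinates), `d`, `p_value`, `significant`,
#'   `window_start`, `snp_offset`
#' @export
score_variant <- function(lnc, assignment, variant, config = list()) {
  cfg <- utils::modifyList(
    list(radius = 200, min_region = 50, n_background = 1000,
         p_threshold = 0.2, pair_weight = exp(3.5), seed = 1),
    config)
  win <- extract_window(lnc, assignment, variant, cfg$radius)
  p_wt <- base_pair_probabilities(win$wt, cfg$pair_weight)
  p_mut <- base_pair_probabilities(win$mut, cfg$pair_weight)
  sc <- disruption_score(p_wt, p_mut, win$snp_offset, cfg$min_region)
  pv <- empirical_pvalue(sc$d, win$wt, win$snp_offset,
                         n_background = cfg$n_background,
                         seed = derive_seed(cfg$seed,
                                            paste0(variant$id, lnc$gene_id)),
                         min_region = cfg$min_region,
                         pair_weight = cfg$pair_weight)
  structure(
    list(variant_id = variant$id, lnc_id = lnc$gene_id, region = sc$region,
         d = sc$d, p_value = pv, significant = pv <= cfg$p_threshold,
         window_start = win$window_start, snp_offset = win$snp_offset),
    class = "disruption_result"
  )
}

#' @export
print.disruption_result <- function(x, ...) {
  cat(sprintf(
    "<disruption_result> %s in %s: d = %.4g over [%d, %d], p = %.4g%s\n",
    x$variant_id, x$lnc_id, x$d, x$region[1], x$region[2], x$p_value,
    if (x$significant) " *" else ""))
  invisible(x)
}

#' Dot-plot-style matrix dump (upper triangle wild type, lower mutant)
#'
#' @param p_wt,p_mut base-pair probability matrices
#' @param path output TSV path
#' @export
write_dotplot_matrix <- function(p_wt, p_mut, path) {
  m <- p_wt
  m[lower.tri(m)] <- p_mut[lower.tri(p_mut)]
  write.table(format(m, digits = 6), path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
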