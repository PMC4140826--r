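# Independent oracles used across the suite. Each is deliberately written as
# a brute-force or reference computation, sharing no code path with the
# implementation it checks.

# --- exhaustive secondary-structure enumeration -----------------------------
# All nested structures with minimum hairpin loop `min_loop`, represented as
# two-column matrices of 1-based pair indices. Feasible to ~length 25.
enumerate_structures <- function(seq, min_loop = 3) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  ok_pair <- function(a, b) {
    paste0(ch[a], ch[b]) %in% c("AU", "UA", "GC", "CG", "GU", "UG")
  }
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (j - i < min_loop + 1) return(list(matrix(numeric(0), ncol = 2)))
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    out <- rec(i + 1, j)
    for (k in (i + min_loop + 1):j) {
      if (!ok_pair(i, k)) next
      for (s1 in rec(i + 1, k - 1)) {
        for (s2 in rec(k + 1, j)) {
          out[[length(out) + 1]] <- rbind(s1, s2, c(i, k))
        }
      }
    }
    memo[[key]] <- out
    out
  }
  if (n < min_loop + 2) return(list(matrix(numeric(0), ncol = 2)))
  rec(1, n)
}

# Boltzmann-weighted pair probabilities from exhaustive enumeration.
oracle_bpp <- function(seq, pair_weight = exp(3.5), min_loop = 3) {
  n <- nchar(seq)
  P <- matrix(0, n, n)
  Z <- 0
  for (s in enumerate_structures(seq, min_loop)) {
    wt <- pair_weight^nrow(s)
    Z <- Z + wt
    if (nrow(s)) {
      for (r in seq_len(nrow(s))) {
        P[s[r, 1], s[r, 2]] <- P[s[r, 1], s[r, 2]] + wt
      }
    }
  }
  P <- P / Z
  P + t(P)
}

# --- brute-force all-pairs relation classification --------------------------
# Vectorized re-statement of the overlap/flank rules straight from their
# definitions, with no interval index.
oracle_relations <- function(lncs, genes, flank = 5000) {
  g <- expand.grid(li = seq_along(lncs), gi = seq_along(genes))
  lc <- vapply(lncs, `[[`, character(1), "chrom")[g$li]
  gc_ <- vapply(genes, `[[`, character(1), "chrom")[g$gi]
  ls <- vapply(lncs, `[[`, integer(1), "start")[g$li]
  le <- vapply(lncs, `[[`, integer(1), "end")[g$li]
  gs <- vapply(genes, `[[`, integer(1), "start")[g$gi]
  ge <- vapply(genes, `[[`, integer(1), "end")[g$gi]
  lst <- vapply(lncs, `[[`, character(1), "strand")[g$li]
  gst <- vapply(genes, `[[`, character(1), "strand")[g$gi]
  ov <- pmin(le, ge) - pmax(ls, gs)
  gap <- ifelse(le <= gs, gs - le, ifelse(ls >= ge, ls - ge, 0L))
  same <- lst == gst
  rel <- rep("none", nrow(g))
  rel[lc == gc_ & ov >= 1 & same] <- "sense_intersecting"
  rel[lc == gc_ & ov >= 1 & same & ls >= gs & le <= ge] <-
    "sense_full_overlap"
  rel[lc == gc_ & ov >= 1 & !same] <- "antisense_intersecting"
  flk <- lc == gc_ & ov < 1 & gap <= flank
  rel[flk & same] <- "flanking_sense"
  rel[flk & !same] <- "flanking_antisense"
  data.frame(
    lnc_id = vapply(lncs, `[[`, character(1), "gene_id")[g$li],
    gene_id = vapply(genes, `[[`, character(1), "gene_id")[g$gi],
    relation = rel,
    overlap_bp = pmax(ov, 0L))
}

# --- brute-force variant-to-lncRNA assignment -------------------------------
oracle_assignments <- function(variants, lncs) {
  rows <- list()
  for (v in variants) {
    for (l in lncs) {
      if (v$chrom != l$chrom) next
      if (v$pos < l$start || v$pos >= l$end) next
      in_exon <- any(v$pos >= l$exons$start & v$pos < l$exons$end)
      rows[[length(rows) + 1]] <- data.frame(
        variant_id = v$id, lnc_id = l$gene_id, inside_exon = in_exon)
    }
  }
  if (!length(rows)) {
    return(data.frame(variant_id = character(0), lnc_id = character(0),
                      inside_exon = logical(0)))
  }
  out <- do.call(rbind, rows)
  out[order(out$variant_id, out$lnc_id), , drop = FALSE]
}

# Base-by-base walk along the spliced transcript to find the offset of a
# genomic position (independent of transcript_offset's arithmetic).
oracle_transcript_offset <- function(lnc, pos) {
  genomic <- unlist(lapply(seq_len(nrow(lnc$exons)), function(i) {
    seq.int(lnc$exons$start[i], lnc$exons$end[i] - 1L)
  }))
  if (lnc$strand == "-") genomic <- rev(genomic)
  hit <- which(genomic == pos)
  if (!length(hit)) NA_integer_ else hit - 1L
}

# --- ranking comparator oracle ----------------------------------------------
oracle_rank <- function(df, regulome_levels) {
  key <- function(i) {
    reg <- match(df$regulome_score[i], regulome_levels)
    if (is.na(reg)) reg <- length(regulome_levels) + 1
    c(reg, ifelse(df$n_eqtl[i] > 0, 0, 1),
      ifelse(df$under_selection[i], 0, 1))
  }
  ord <- order(vapply(seq_len(nrow(df)), function(i) key(i)[1], numeric(1)),
               vapply(seq_len(nrow(df)), function(i) key(i)[2], numeric(1)),
               vapply(seq_len(nrow(df)), function(i) key(i)[3], numeric(1)),
               df$p_value, df$chrom, df$pos, df$variant_id, method = "radix")
  df$variant_id[ord]
}

# --- average-rank Spearman oracle -------------------------------------------
oracle_spearman <- function(x, y) {
  avg_rank <- function(v) {
    r <- numeric(length(v))
    for (i in seq_along(v)) {
      r[i] <- sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
    }
    r
  }
  rx <- avg_rank(x); ry <- avg_rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# random gene/lncRNA fixtures for oracle-equivalence tests
random_gene <- function(id, chrom, max_pos = 2e5) {
  start <- sample.int(max_pos, 1)
  len <- sample(500:3000, 1)
  n_ex <- sample(1:3, 1)
  bounds <- sort(sample.int(len - 1, 2 * n_ex - 1))
  ex_start <- start + c(0, bounds[seq_len(n_ex - 1) * 2])
  ex_end <- start + c(bounds[seq_len(n_ex - 1) * 2 - 1], len)
  gene_model(id, chrom, start, start + len, sample(c("+", "-"), 1),
             exons = data.frame(start = ex_start, end = ex_end))
}

random_lnc <- function(id, chrom, max_pos = 2e5, with_seq = FALSE) {
  start <- sample.int(max_pos, 1)
  len <- sample(150:800, 1)
  lncrna_gene(id, chrom, start, start + len, sample(c("+", "-"), 1),
              transcript_seq = if (with_seq) {
                paste(sample(c("A", "C", "G", "U"), len, TRUE),
                      collapse = "")
              })
}
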