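# Domain types (genomic intervals, gene models, variants) and readers/writers
# for the plain-text formats every stage touches. All internal coordinates are
# 0-based half-open (BED convention); variant positions are 1-based on disk
# (VCF convention) and converted on read.

#' Construct a gene model
#'
#' A strand-aware genomic interval with ordered, non-overlapping exon blocks.
#' Coordinates are 0-based half-open; a gene of length L spans
#' `[start, start+L)`.
#'
#' @param gene_id gene identifier
#' @param chrom chromosome name (non-empty)
#' @param start,end 0-based half-open span; `0 <= start < end`
#' @param strand one of `"+"`, `"-"`, `"."` (unstranded)
#' @param exons data.frame with columns `start`, `end` (0-based half-open),
#'   sorted by start, non-overlapping, contained in `[start, end)`. Defaults
#'   to the single exon spanning the whole gene.
#' @param biotype one of `"protein_coding"`, `"lncRNA"`, `"pseudogene"`,
#'   `"other"`
#' @return an object of class `gene_model`
#' @export
gene_model <- function(gene_id, chrom, start, end, strand = ".",
                       exons = NULL, biotype = "protein_coding") {
  stop_if_not_scalar_string(gene_id, "gene_id")
  stop_if_not_scalar_string(chrom, "chrom")
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 0 || end <= start) {
    stop("invalid interval for gene ", gene_id, ": need 0 <= start < end",
         call. = FALSE)
  }
  if (!strand %in% c("+", "-", ".")) {
    stop("strand must be '+', '-' or '.'", call. = FALSE)
  }
  biotype <- match.arg(biotype,
                       c("protein_coding", "lncRNA", "pseudogene", "other"))
  if (is.null(exons)) {
    exons <- data.frame(start = start, end = end)
  }
  exons <- as.data.frame(exons)[, c("start", "end")]
  exons$start <- as.integer(exons$start)
  exons$end <- as.integer(exons$end)
  exons <- exons[order(exons$start), , drop = FALSE]
  rownames(exons) <- NULL
  if (any(exons$end <= exons$start)) {
    stop("gene ", gene_id, ": exon with end <= start", call. = FALSE)
  }
  if (any(exons$start < start) || any(exons$end > end)) {
    stop("gene ", gene_id, ": exon outside gene span", call. = FALSE)
  }
  if (nrow(exons) > 1 &&
      any(exons$start[-1] < exons$end[-nrow(exons)])) {
    stop("gene ", gene_id, ": overlapping exons", call. = FALSE)
  }
  structure(
    list(gene_id = gene_id, chrom = chrom, start = start, end = end,
         strand = strand, exons = exons, biotype = biotype),
    class = "gene_model"
  )
}

#' Construct a lncRNA gene
#'
#' A [gene_model()] with biotype `lncRNA` and an optional spliced transcript
#' sequence over `{A,C,G,U}` whose length must equal the summed exon lengths.
#' The transcript is given in sense orientation (5' to 3' of the lncRNA).
#'
#' @inheritParams gene_model
#' @param transcript_seq optional RNA string (`T` accepted, converted to `U`)
#' @return an object of class `c("lncrna_gene", "gene_model")`
#' @export
lncrna_gene <- function(gene_id, chrom, start, end, strand = ".",
                        exons = NULL, transcript_seq = NULL) {
  g <- gene_model(gene_id, chrom, start, end, strand, exons,
                  biotype = "lncRNA")
  if (!is.null(transcript_seq)) {
    transcript_seq <- dna_to_rna(transcript_seq)
    bad <- setdiff(strsplit(transcript_seq, "")[[1]], RNA_BASES)
    if (length(bad)) {
      stop("transcript of ", gene_id, " contains non-ACGU character(s): ",
           paste(bad, collapse = ","), call. = FALSE)
    }
    exon_len <- sum(g$exons$end - g$exons$start)
    if (nchar(transcript_seq) != exon_len) {
      stop("transcript of ", gene_id, " has length ", nchar(transcript_seq),
           " but exons sum to ", exon_len, call. = FALSE)
    }
  }
  g$transcript_seq <- transcript_seq
  class(g) <- c("lncrna_gene", "gene_model")
  g
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<%s> %s %s:%d-%d(%s) %d exon(s)\n",
              paste(class(x), collapse = "/"), x$gene_id, x$chrom,
              x$start, x$end, x$strand, nrow(x$exons)))
  invisible(x)
}

#' Construct a variant
#'
#' A single-nucleotide variant with per-disease association p-values. The
#' position is supplied 1-based (as read from input tables) and stored
#' 0-based internally; a 1 bp variant occupies `[pos, pos + 1)`.
#'
#' @param id rsID string
#' @param chrom chromosome name
#' @param pos 1-based position
#' @param ref,alt single DNA nucleotides, `ref != alt`
#' @param assoc_p named numeric vector mapping disease label to a p-value in
#'   (0, 1]
#' @return an object of class `variant` with element `pos` 0-based
#' @export
variant <- function(id, chrom, pos, ref, alt, assoc_p = numeric(0)) {
  stop_if_not_scalar_string(id, "id")
  stop_if_not_scalar_string(chrom, "chrom")
  pos <- as.integer(pos)
  if (is.na(pos) || pos < 1) stop("pos must be a positive 1-based integer",
                                  call. = FALSE)
  ref <- toupper(ref); alt <- toupper(alt)
  if (!ref %in% DNA_BASES || !alt %in% DNA_BASES) {
    stop("ref and alt must be single nucleotides in {A,C,G,T}", call. = FALSE)
  }
  if (ref == alt) stop("ref and alt must differ for variant ", id,
                       call. = FALSE)
  assoc_p <- unlist(assoc_p)
  if (length(assoc_p)) {
    if (is.null(names(assoc_p)) || any(!nzchar(names(assoc_p)))) {
      stop("assoc_p must be named by disease label", call. = FALSE)
    }
    check_prob_open_closed(assoc_p, paste0("assoc_p of ", id))
  }
  structure(
    list(id = id, chrom = chrom, pos = pos - 1L, ref = ref, alt = alt,
         assoc_p = assoc_p),
    class = "variant"
  )
}

#' @export
print.variant <- function(x, ...) {
  cat(sprintf("<variant> %s %s:%d %s>%s [%s]\n", x$id, x$chrom, x$pos + 1L,
              x$ref, x$alt,
              paste(sprintf("%s=%.3g", names(x$assoc_p), x$assoc_p),
                    collapse = ", ")))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Readers

#' Read gene models from a BED6 or BED12 file
#'
#' BED12 block fields populate exons; BED6 yields single-exon genes. A strand
#' column of `"."` maps to unstranded. Malformed lines raise an error naming
#' the line number.
#'
#' @param path file path
#' @param biotype biotype assigned to every record (`"lncRNA"` yields
#'   [lncrna_gene()] objects)
#' @return list of [gene_model()] (or [lncrna_gene()]) objects
#' @export
read_gene_bed <- function(path, biotype = "protein_coding") {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(trimws(lines[[i]]), "[ \t]+")[[1]]
    if (!length(f) %in% c(6L, 12L)) {
      stop("line ", i, ": expected 6 or 12 BED fields, got ", length(f),
           call. = FALSE)
    }
    start <- suppressWarnings(as.integer(f[2]))
    end <- suppressWarnings(as.integer(f[3]))
    if (is.na(start) || is.na(end)) {
      stop("line ", i, ": non-numeric coordinates", call. = FALSE)
    }
    if (end <= start) {
      stop("line ", i, ": end <= start", call. = FALSE)
    }
    exons <- NULL
    if (length(f) == 12L) {
      n_blocks <- suppressWarnings(as.integer(f[10]))
      sizes <- suppressWarnings(as.integer(strsplit(f[11], ",")[[1]]))
      starts <- suppressWarnings(as.integer(strsplit(f[12], ",")[[1]]))
      if (is.na(n_blocks) || length(sizes) != n_blocks ||
          length(starts) != n_blocks || anyNA(sizes) || anyNA(starts)) {
        stop("line ", i, ": malformed BED12 block fields", call. = FALSE)
      }
      exons <- data.frame(start = start + starts,
                          end = start + starts + sizes)
    }
    rec <- tryCatch(
      if (biotype == "lncRNA") {
        lncrna_gene(f[4], f[1], start, end, f[6], exons)
      } else {
        gene_model(f[4], f[1], start, end, f[6], exons, biotype)
      },
      error = function(e) stop("line ", i, ": ", conditionMessage(e),
                               call. = FALSE)
    )
    out[[i]] <- rec
  }
  out
}

#' Write gene models to BED12
#'
#' Inverse of [read_gene_bed()]: `read(write(x))` reproduces coordinates,
#' strand and exon blocks exactly.
#'
#' @param genes list of [gene_model()] objects
#' @param path output path
#' @export
write_gene_bed <- function(genes, path) {
  lines <- vapply(genes, function(g) {
    sizes <- g$exons$end - g$exons$start
    starts <- g$exons$start - g$start
    paste(g$chrom, g$start, g$end, g$gene_id, 0L, g$strand, g$start, g$end,
          "0,0,0", nrow(g$exons),
          paste0(paste(sizes, collapse = ","), ","),
          paste0(paste(starts, collapse = ","), ","),
          sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a variant table
#'
#' Tab-separated with header columns `id`, `chrom`, `pos`, `ref`, `alt` and
#' one p-value column per disease label. Positions are 1-based on disk and
#' converted to 0-based internally. Rows with a missing p-value for a disease
#' simply carry no entry for that label.
#'
#' @param path file path
#' @return list of [variant()] objects
#' @export
read_variant_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tab <- read.delim(path, header = TRUE, sep = "\t",
                    colClasses = "character", check.names = FALSE)
  required <- c("id", "chrom", "pos", "ref", "alt")
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    stop("variant table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  p_cols <- setdiff(names(tab), required)
  lapply(seq_len(nrow(tab)), function(i) {
    p <- vapply(p_cols, function(cn) {
      v <- tab[[cn]][i]
      if (is.na(v) || !nzchar(v) || v == "NA") NA_real_ else as.numeric(v)
    }, numeric(1))
    p <- p[!is.na(p)]
    variant(tab$id[i], tab$chrom[i], as.numeric(tab$pos[i]),
            tab$ref[i], tab$alt[i], p)
  })
}

#' Write a variant table
#'
#' Inverse of [read_variant_table()]; positions are written back 1-based.
#'
#' @param variants list of [variant()] objects
#' @param path output path
#' @export
write_variant_table <- function(variants, path) {
  labels <- unique(unlist(lapply(variants, function(v) names(v$assoc_p))))
  header <- c("id", "chrom", "pos", "ref", "alt", labels)
  rows <- vapply(variants, function(v) {
    p <- vapply(labels, function(l) {
      if (l %in% names(v$assoc_p)) format(v$assoc_p[[l]], digits = 15) else "NA"
    }, character(1))
    paste(c(v$id, v$chrom, v$pos + 1L, v$ref, v$alt, p), collapse = "\t")
  }, character(1))
  writeLines(c(paste(header, collapse = "\t"), rows), path)
  invisible(path)
}

#' Read a FASTA file into a named character vector of RNA sequences
#'
#' Sequence ids are the first whitespace-delimited token of each header.
#' `T` is accepted and transcribed to `U`. Duplicate ids and non-IUPAC
#' characters are errors.
#'
#' @param path file path
#' @return named character vector, one RNA string per record
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  seqs <- toupper(as.character(set))
  for (i in seq_along(seqs)) {
    bad <- setdiff(unique(strsplit(seqs[[i]], "")[[1]]), IUPAC_CODES)
    if (length(bad)) {
      stop("record ", ids[i], " contains non-IUPAC character(s): ",
           paste(bad, collapse = ","), call. = FALSE)
    }
  }
  setNames(dna_to_rna(seqs), ids)
}

#' Read a typed TSV (or RepeatMasker .out) table
#'
#' For `format = "tsv"` the file must carry a header; `schema` gives the
#' required columns and their types, e.g.
#' `c(variant_id = "character", ihs = "numeric")`. Unknown extra columns are
#' preserved as character. For `format = "repeatmasker"` the standard .out
#' dialect is parsed (3 header lines, whitespace-delimited) into columns
#' `chrom`, `start` (0-based), `end`, `strand`, `repeat_name`,
#' `repeat_class`, with the class collapsed to the vocabulary
#' SINE/LINE/LTR/DNA/Simple/Low_complexity/Other.
#'
#' @param path file path
#' @param schema named character vector of required column types (TSV only)
#' @param format `"tsv"` or `"repeatmasker"`
#' @return data.frame
#' @export
read_table <- function(path, schema = NULL, format = c("tsv", "repeatmasker")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (format == "repeatmasker") {
    lines <- readLines(path)
    if (length(lines) > 3) lines <- lines[-(1:3)] else lines <- character(0)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) {
      return(data.frame(chrom = character(0), start = integer(0),
                        end = integer(0), strand = character(0),
                        repeat_name = character(0),
                        repeat_class = character(0)))
    }
    f <- strsplit(trimws(lines), "\\s+")
    n_fields <- lengths(f)
    if (any(n_fields < 11)) {
      stop("RepeatMasker line ", which(n_fields < 11)[1],
           " has fewer than 11 fields", call. = FALSE)
    }
    get <- function(k) vapply(f, `[`, character(1), k)
    cls_raw <- get(11)
    cls <- vapply(strsplit(cls_raw, "/", fixed = TRUE), `[`, character(1), 1L)
    cls[cls == "Simple_repeat"] <- "Simple"
    cls[!cls %in% c("SINE", "LINE", "LTR", "DNA", "Simple",
                    "Low_complexity")] <- "Other"
    data.frame(
      chrom = get(5),
      start = as.integer(get(6)) - 1L,   # .out query begin is 1-based
      end = as.integer(get(7)),
      strand = ifelse(get(9) == "C", "-", "+"),
      repeat_name = get(10),
      repeat_class = cls
    )
  } else {
    tab <- read.delim(path, header = TRUE, sep = "\t",
                      colClasses = "character", check.names = FALSE)
    if (!is.null(schema)) {
      missing <- setdiff(names(schema), names(tab))
      if (length(missing)) {
        stop("table missing required column(s): ",
             paste(missing, collapse = ", "), call. = FALSE)
      }
      for (cn in names(schema)) {
        tab[[cn]] <- switch(schema[[cn]],
                            numeric = as.numeric(tab[[cn]]),
                            integer = as.integer(tab[[cn]]),
                            character = tab[[cn]],
                            stop("unknown schema type: ", schema[[cn]]))
      }
    }
    tab
  }
}

# ---------------------------------------------------------------------------
# Conversions to Bioconductor containers

#' Gene spans as a GRanges
#' @param genes list of gene_model objects
#' @return GRanges with `gene_id` metadata, IRanges 1-based internally
#' @keywords internal
genes_to_granges <- function(genes) {
  if (!length(genes)) {
    return(GenomicRanges::GRanges())
  }
  GenomicRanges::GRanges(
    seqnames = vapply(genes, `[[`, character(1), "chrom"),
    ranges = IRanges::IRanges(
      start = vapply(genes, `[[`, integer(1), "start") + 1L,
      end = vapply(genes, `[[`, integer(1), "end")),
    strand = vapply(genes, function(g) {
      if (g$strand == ".") "*" else g$strand
    }, character(1)),
    gene_id = vapply(genes, `[[`, character(1), "gene_id")
  )
}

#' Exons of a gene list as a GRanges
#' @keywords internal
exons_to_granges <- function(genes) {
  if (!length(genes)) return(GenomicRanges::GRanges())
  n_ex <- vapply(genes, function(g) nrow(g$exons), integer(1))
  starts <- unlist(lapply(genes, function(g) g$exons$start))
  ends <- unlist(lapply(genes, function(g) g$exons$end))
  GenomicRanges::GRanges(
    seqnames = rep(vapply(genes, `[[`, character(1), "chrom"), n_ex),
    ranges = IRanges::IRanges(start = starts + 1L, end = ends),
    strand = rep(vapply(genes, function(g) {
      if (g$strand == ".") "*" else g$strand
    }, character(1)), n_ex),
    gene_id = rep(vapply(genes, `[[`, character(1), "gene_id"), n_ex)
  )
}

#' Variants as a GRanges (1 bp ranges)
#' @keywords internal
variants_to_granges <- function(variants) {
  if (!length(variants)) return(GenomicRanges::GRanges())
  GenomicRanges::GRanges(
    seqnames = vapply(variants, `[[`, character(1), "chrom"),
    ranges = IRanges::IRanges(
      start = vapply(variants, `[[`, integer(1), "pos") + 1L, width = 1L),
    strand = "*",
    variant_id = vapply(variants, `[[`, character(1), "id")
  )
}
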