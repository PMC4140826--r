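# Shared helpers: alphabet handling, seed derivation, small validators.

DNA_BASES <- c("A", "C", "G", "T")
RNA_BASES <- c("A", "C", "G", "U")
IUPAC_CODES <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N")

#' Complement a vector of single bases (DNA or RNA alphabet)
#' @param x character vector of single upper-case bases
#' @param rna logical; if TRUE the complement of A is U, otherwise T
#' @return character vector of complements
#' @keywords internal
complement_base <- function(x, rna = TRUE) {
  map <- if (rna) {
    c(A = "U", C = "G", G = "C", U = "A", T = "A", N = "N")
  } else {
    c(A = "T", C = "G", G = "C", T = "A", U = "A", N = "N")
  }
  out <- unname(map[x])
  if (anyNA(out)) {
    stop("cannot complement base(s): ",
         paste(unique(x[is.na(out)]), collapse = ", "))
  }
  out
}

#' Reverse-complement an RNA sequence string
#' @param seq single character string over {A,C,G,U}
#' @return reverse complement string
#' @export
reverse_complement <- function(seq) {
  ch <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  paste(rev(complement_base(ch, rna = TRUE)), collapse = "")
}

#' Convert T to U and uppercase (DNA -> RNA at the FASTA boundary)
#' @param seq character vector of sequences
#' @return RNA sequences
#' @keywords internal
dna_to_rna <- function(seq) {
  gsub("T", "U", toupper(seq), fixed = TRUE)
}

#' Derive a stage-specific seed from a global seed
#'
#' A single global seed fans out to per-stage seeds by stable string hashing,
#' so adding one pipeline stage never perturbs another stage's random draws.
#' The result is always a positive 31-bit integer.
#'
#' @param seed integer global seed
#' @param label character stage label
#' @return integer seed for the stage
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1, length(label) == 1)
  m <- 2147483647  # 2^31 - 1; all products below stay exact in doubles
  h <- (abs(seed) %% m) * 69069 %% m
  for (ch in utf8ToInt(label)) h <- (h * 131 + ch) %% m
  h <- (h * 48271) %% m
  as.integer(h) + 1L
}

#' Evaluate an expression under a temporary RNG seed
#' @keywords internal
with_seed <- function(seed, code) {
  withr::with_seed(seed, code)
}

stop_if_not_scalar_string <- function(x, what) {
  if (!is.character(x) || length(x) != 1 || is.na(x) || !nzchar(x)) {
    stop(what, " must be a non-empty string", call. = FALSE)
  }
}

#' Validate that a probability lies in (0, 1]
#' @keywords internal
check_prob_open_closed <- function(p, what = "p-value") {
  if (!is.numeric(p) || anyNA(p) || any(p <= 0) || any(p > 1)) {
    stop(what, " must lie in (0, 1]", call. = FALSE)
  }
  invisible(p)
}
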