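# Low-level DNA string utilities shared across the package. Sequences are
# plain upper-case character scalars over {A,C,G,T,N}; the scan core works on
# an integer encoding A=0, C=1, G=2, T=3, N=4.

DNA_BASES <- c("A", "C", "G", "T")

# raw byte -> code lookup, built once
.dna_code <- local({
  m <- rep(NA_integer_, 256)
  set <- function(m, chars, val) {
    m[as.integer(charToRaw(paste(chars, collapse = ""))) + 1L] <- val
    m
  }
  for (i in seq_along(DNA_BASES)) {
    m <- set(m, c(DNA_BASES[i], tolower(DNA_BASES[i])), i - 1L)
  }
  m <- set(m, c("N", "n"), 4L)
  m
})

dna_encode <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  codes <- .dna_code[as.integer(charToRaw(x)) + 1L]
  if (anyNA(codes)) {
    stop("sequence contains characters outside {A,C,G,T,N}; run clean_residues() first",
         call. = FALSE)
  }
  codes
}

dna_decode <- function(codes) {
  paste(c(DNA_BASES, "N")[codes + 1L], collapse = "")
}

#' Sanitize a DNA string
#'
#' Upper-cases the input and maps any character outside `{A,C,G,T,N}`
#' (e.g. IUPAC ambiguity codes) to `N`, with a warning naming the record.
#' `N` never matches during repeat scanning, so ambiguous input is treated
#' conservatively rather than being given invented match semantics.
#'
#' @param x a DNA string.
#' @param id record identifier used in the warning.
#' @return cleaned upper-case DNA string.
#' @export
clean_residues <- function(x, id = "sequence") {
  x <- toupper(x)
  bad <- grepl("[^ACGTN]", x)
  if (bad) {
    n_bad <- nchar(gsub("[ACGTN]", "", x))
    warning(sprintf("%s: %d non-ACGTN character(s) mapped to N", id, n_bad),
            call. = FALSE)
    x <- gsub("[^ACGTN]", "N", x)
  }
  x
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

subseq_str <- function(x, start, end) substr(x, start, end)

# replace residues [start, end] of x with value (same length)
splice_str <- function(x, start, value) {
  stopifnot(start >= 1, start + nchar(value) - 1L <= nchar(x))
  paste0(substr(x, 1L, start - 1L), value,
         substr(x, start + nchar(value), nchar(x)))
}

count_base <- function(x, base) {
  lengths(regmatches(x, gregexpr(base, x, fixed = TRUE)))
}
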