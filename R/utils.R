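#' Null-coalescing operator
#' @param a,b values; `b` is returned when `a` is `NULL`
#' @return `a` unless it is `NULL`, else `b`
#' @export
#' @name null-coalesce
#' @rdname null-coalesce
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Random DNA sequence
#' @param n sequence length (bases)
#' @return a single character string over A/C/G/T
#' @keywords internal
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Reverse complement of character sequences
#' @param x character vector of DNA sequences
#' @return character vector of reverse complements
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Introduce independent per-base substitutions at the given rate. Each
# substituted base is replaced by one of the three other bases uniformly.
mutate_sequences <- function(seqs, rate) {
  if (rate <= 0 || length(seqs) == 0) return(seqs)
  widths <- nchar(seqs)
  n_err <- rbinom(length(seqs), widths, rate)
  hit <- which(n_err > 0)
  bases <- c("A", "C", "G", "T")
  for (i in hit) {
    s <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    pos <- sample.int(widths[i], n_err[i])
    for (p in pos) {
      s[p] <- sample(setdiff(bases, s[p]), 1L)
    }
    seqs[i] <- paste(s, collapse = "")
  }
  seqs
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
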