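#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA sequences (ACGTN).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' GC content of DNA strings
#'
#' @param x character vector of DNA sequences.
#' @return numeric vector of GC fractions in [0, 1].
#' @export
gc_content <- function(x) {
  if (length(x) == 0) return(numeric(0))
  s <- Biostrings::DNAStringSet(x)
  gc <- Biostrings::letterFrequency(s, letters = c("G", "C"))
  as.numeric(rowSums(gc)) / Biostrings::width(s)
}

# uniform random DNA sequences (uses the current RNG state)
random_dna <- function(n, len) {
  if (length(len) == 1) len <- rep(len, n)
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len[i], replace = TRUE),
          collapse = "")
  }, character(1))
}

# plus-strand canonical form: lexicographic min of a sequence and its
# reverse complement
canonical_seq <- function(x) {
  r <- revcomp(x)
  ifelse(x <= r, x, r)
}

# substitute `n_sub` random positions of a sequence (fixture divergence)
diverge_seq <- function(seq, n_sub) {
  if (n_sub <= 0) return(seq)
  chars <- strsplit(seq, NULL)[[1]]
  pos <- sample(length(chars), min(n_sub, length(chars)))
  for (p in pos) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
  }
  paste(chars, collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
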