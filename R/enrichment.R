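#' Build a k-mer locus index
#'
#' Indexes every length-k window of every barcode context sequence (both
#' strands, canonicalised to the lexicographic minimum of a k-mer and its
#' reverse complement) to its locus.  Windows containing non-ACGT bases are
#' skipped; references shorter than k are skipped with a warning.
#'
#' @param refdb a `reference_db`.
#' @param k odd k-mer length, at most 31.
#' @return a `locus_index`.
#' @export
build_locus_index <- function(refdb, k = 31) {
  stopifnot(k %% 2 == 1, k >= 5, k <= 31)
  b <- refdb$barcodes
  if (nrow(b) == 0) stop("cannot index an empty reference database")
  short <- nchar(b$context_seq) < k
  if (any(short)) {
    warning(sum(short), " reference(s) shorter than k = ", k, " skipped")
    b <- b[!short, , drop = FALSE]
  }
  if (nrow(b) == 0) stop("no reference reaches the k-mer length")
  loci <- sort(unique(b$locus))
  idx <- structure(
    list(k = as.integer(k), loci = loci, seqs = b$context_seq,
         locus_id = match(b$locus, loci), cache = new.env(parent = emptyenv())),
    class = "locus_index")
  locus_index_ptr(idx)  # build eagerly
  idx
}

# the external pointer does not survive serialization; rebuild on demand
locus_index_ptr <- function(index) {
  p <- index$cache$ptr
  if (is.null(p) || !xptr_valid_cpp(p)) {
    p <- kmer_index_build_cpp(index$seqs, as.integer(index$locus_id),
                              index$k)
    index$cache$ptr <- p
  }
  p
}

#' @export
print.locus_index <- function(x, ...) {
  cat("Locus k-mer index: k =", x$k, "|", length(x$seqs), "references |",
      format(kmer_index_size_cpp(locus_index_ptr(x)), big.mark = ","),
      "canonical k-mers |loci:", paste(x$loci, collapse = ", "), "\n")
  invisible(x)
}

#' Classify one read pair to a barcode locus
#'
#' Counts canonical k-mers matching each locus across both mates and
#' returns the locus with the highest count when that count reaches
#' `min_hits`.  Ties between loci are conservative and return `NA`.
#'
#' @param pair list with `seq1` and `seq2`.
#' @param index a [build_locus_index()] result.
#' @param min_hits minimum matching k-mer count.
#' @return locus name, or `NA_character_`.
#' @export
classify_read_pair <- function(pair, index, min_hits = 3) {
  classify_read_pairs(pair$seq1, pair$seq2, index, min_hits)
}

#' Classify many read pairs to barcode loci
#'
#' @param seq1,seq2 character vectors of mate sequences.
#' @param index a [build_locus_index()] result.
#' @param min_hits minimum matching k-mer count.
#' @return character vector of locus names (`NA` for unassigned pairs).
#' @export
classify_read_pairs <- function(seq1, seq2, index, min_hits = 3) {
  hit <- kmer_classify_cpp(locus_index_ptr(index), seq1, seq2, index$k,
                           length(index$loci), as.integer(min_hits))
  out <- rep(NA_character_, length(hit))
  out[hit > 0] <- index$loci[hit[hit > 0]]
  out
}

#' Enrich read pairs by barcode locus
#'
#' Splits a read-pair table into per-locus bins plus an unassigned stream,
#' the shotgun-metabarcoding stand-in for enrichment against a public
#' sequence database.
#'
#' @param pairs read-pair data.frame (pair_id, seq1, qual1, seq2, qual2).
#' @param index a [build_locus_index()] result.
#' @param min_hits minimum matching k-mer count.
#' @return list with `bins` (named list of per-locus read-pair tables),
#'   `unassigned`, and `tally` (data.frame locus / n_pairs).
#' @export
enrich_reads <- function(pairs, index, min_hits = 3) {
  locus <- classify_read_pairs(pairs$seq1, pairs$seq2, index, min_hits)
  bins <- lapply(setNames(index$loci, index$loci), function(l) {
    out <- pairs[!is.na(locus) & locus == l, , drop = FALSE]
    rownames(out) <- NULL
    out
  })
  tally <- data.frame(locus = index$loci,
                      n_pairs = vapply(bins, nrow, integer(1)),
                      stringsAsFactors = FALSE)
  rownames(tally) <- NULL
  unassigned <- pairs[is.na(locus), , drop = FALSE]
  rownames(unassigned) <- NULL
  list(bins = bins, unassigned = unassigned, tally = tally)
}
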