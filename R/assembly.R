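#' Assemble one locus bin with a de Bruijn mini-assembler
#'
#' Builds a de Bruijn graph over canonical k-mers with count at least
#' `min_kmer_count` and emits maximal non-branching paths (unitigs) of at
#' least k + 10 nt.  Short dead-end tips (< 2k nt) and bubble arms below
#' `bubble_frac` of the strongest parallel path are pruned before the final
#' threading, which removes most substitution-error artefacts.  Contigs are
#' reported in plus-strand canonical orientation and sorted, so assembly is
#' independent of read input order.
#'
#' @param reads character vector of read sequences (both mates of a bin).
#' @param k odd k-mer size, less than the read length, at most 31.
#' @param min_kmer_count k-mers seen fewer times are discarded.
#' @param bubble_frac bubble arms below this fraction of the dominant
#'   parallel path's coverage are removed.
#' @param rel_frac k-mers below this fraction of their strongest graph
#'   neighbour's count are removed before unitig building (low-coverage
#'   edge removal; errors duplicated at high depth form such branches,
#'   while genuinely low-abundance components have uniformly low counts
#'   and are untouched).
#' @param clean logical; disable to keep raw unitigs (used by graph-level
#'   tests).
#' @param locus optional locus label attached to the contigs.
#' @return data.frame of contigs: contig_id, locus, seq, k_used,
#'   mean_kmer_coverage.
#' @export
assemble_bin <- function(reads, k = 21, min_kmer_count = 2,
                         bubble_frac = 0.1, rel_frac = 0.05, clean = TRUE,
                         locus = NA) {
  if (length(reads) == 0) {
    return(data.frame(contig_id = character(0), locus = character(0),
                      seq = character(0), k_used = integer(0),
                      mean_kmer_coverage = numeric(0),
                      stringsAsFactors = FALSE))
  }
  res <- assemble_bin_cpp(reads, as.integer(k), as.integer(min_kmer_count),
                          bubble_frac, as.integer(2 * k),
                          as.integer(k + 10),
                          if (clean) 8L else 0L,
                          if (clean) rel_frac else 0)
  n <- length(res$seq)
  data.frame(
    contig_id = if (n > 0) sprintf("k%d_c%03d", k, seq_len(n)) else character(0),
    locus = rep(as.character(locus), n),
    seq = as.character(res$seq),
    k_used = rep(as.integer(k), n),
    mean_kmer_coverage = as.numeric(res$coverage),
    stringsAsFactors = FALSE
  )
}

#' Merge contig sets into unique contigs
#'
#' Union of two assemblies with duplicates removed, where a duplicate is an
#' identical sequence, the reverse complement of another contig, or an
#' exact substring of a longer contig.  The longest representative is
#' retained; ties break lexicographically.  The operation is idempotent and
#' commutative.
#'
#' @param setA,setB contig data.frames as returned by [assemble_bin()].
#' @return a deduplicated contig data.frame.
#' @export
merge_unique_contigs <- function(setA, setB) {
  all <- rbind(setA, setB)
  if (nrow(all) == 0) return(all)
  all$canon <- canonical_seq(all$seq)
  # drop exact (orientation-insensitive) duplicates first
  all <- all[order(-nchar(all$canon), all$canon), , drop = FALSE]
  all <- all[!duplicated(all$canon), , drop = FALSE]
  rcanon <- revcomp(all$canon)
  keep <- rep(TRUE, nrow(all))
  hay <- ""  # grows with every retained (longer) contig
  for (i in seq_len(nrow(all))) {
    if (nzchar(hay) &&
        (grepl(all$canon[i], hay, fixed = TRUE) ||
           grepl(rcanon[i], hay, fixed = TRUE))) {
      keep[i] <- FALSE
    } else {
      hay <- paste(hay, all$canon[i], sep = "#")
    }
  }
  out <- all[keep, setdiff(names(all), "canon"), drop = FALSE]
  out$seq <- canonical_seq(out$seq)
  out <- out[order(-nchar(out$seq), out$seq), , drop = FALSE]
  out$contig_id <- sprintf("u%03d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out
}

#' Dual-k assembly of a locus bin
#'
#' Assembles a bin at two k values and merges the results into unique
#' contigs, emulating a union of two assemblers followed by deduplication.
#'
#' @param reads read sequences of the bin.
#' @param k_values two odd k sizes (each at most 31).
#' @param ... passed to [assemble_bin()].
#' @param locus optional locus label.
#' @return a contig data.frame.
#' @export
assemble_dual_k <- function(reads, k_values = c(21, 31), locus = NA, ...) {
  a <- assemble_bin(reads, k = k_values[1], locus = locus, ...)
  b <- assemble_bin(reads, k = k_values[2], locus = locus, ...)
  out <- merge_unique_contigs(a, b)
  if (nrow(out) > 0) out$locus <- as.character(locus)
  out
}
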