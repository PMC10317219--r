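#' Default trimming parameters
#'
#' Conservative Trimmomatic-style settings: a 4-base sliding window cut at
#' mean Q15, leading/trailing trim at Q3, and a 50 nt minimum mate length.
#'
#' @param adapter_seq adapter to clip from read 3' ends.
#' @param window sliding-window length (nt).
#' @param window_min_q minimum mean Phred quality of a window.
#' @param min_len minimum surviving mate length; shorter pairs are dropped.
#' @param leading_q,trailing_q leading/trailing base quality floor.
#' @return a list of trimming parameters.
#' @export
trim_params <- function(adapter_seq = "AGATCGGAAGAGC", window = 4,
                        window_min_q = 15, min_len = 50, leading_q = 3,
                        trailing_q = 3) {
  stopifnot(window >= 0, window_min_q >= 0, min_len >= 0, leading_q >= 0,
            trailing_q >= 0)
  list(adapter_seq = adapter_seq, window = window,
       window_min_q = window_min_q, min_len = min_len,
       leading_q = leading_q, trailing_q = trailing_q)
}

#' Clip a 3' adapter from one read
#'
#' Removes the read suffix from the leftmost position where a prefix of the
#' adapter aligns with at least `min_overlap` bases and at most
#' `max_mismatch_rate` mismatches; qualities are clipped in lockstep.
#'
#' @param seq,qual read sequence and Phred+33 quality string.
#' @param adapter adapter sequence.
#' @param min_overlap minimum adapter prefix length considered.
#' @param max_mismatch_rate maximum mismatch fraction of the overlap.
#' @return list with clipped `seq` and `qual` (unchanged when no match).
#' @export
clip_adapter <- function(seq, qual, adapter, min_overlap = 8,
                         max_mismatch_rate = 0.1) {
  stopifnot(nchar(seq) == nchar(qual))
  keep <- clip_adapter_cpp(seq, adapter, as.integer(min_overlap),
                           max_mismatch_rate)
  list(seq = substr(seq, 1, keep), qual = substr(qual, 1, keep))
}

#' Quality-trim a read pair
#'
#' Per mate: clip the adapter, trim leading/trailing low-quality bases, then
#' cut before the first sliding window whose mean quality falls below the
#' threshold.  The pair is dropped (NULL) when either mate ends up shorter
#' than `min_len` — downstream stages are pair-oriented, so no orphan reads
#' are kept.
#'
#' @param pair list with `seq1`, `qual1`, `seq2`, `qual2`.
#' @param params a [trim_params()] list.
#' @return the trimmed pair, or `NULL` when dropped.
#' @export
quality_trim_pair <- function(pair, params = trim_params()) {
  out <- trim_read_pairs(data.frame(pair_id = "p", seq1 = pair$seq1,
                                    qual1 = pair$qual1, seq2 = pair$seq2,
                                    qual2 = pair$qual2,
                                    stringsAsFactors = FALSE), params)
  if (nrow(out$pairs) == 0) return(NULL)
  list(seq1 = out$pairs$seq1, qual1 = out$pairs$qual1,
       seq2 = out$pairs$seq2, qual2 = out$pairs$qual2)
}

#' Trim a table of read pairs
#'
#' Vectorised trimming of a read-pair table (columns pair_id, seq1, qual1,
#' seq2, qual2).
#'
#' @param pairs read-pair data.frame.
#' @param params a [trim_params()] list.
#' @return list with `pairs` (surviving, trimmed), `n_in`, `n_out`,
#'   `bases_removed`.
#' @export
trim_read_pairs <- function(pairs, params = trim_params()) {
  n_in <- nrow(pairs)
  if (n_in == 0) {
    return(list(pairs = pairs, n_in = 0L, n_out = 0L, bases_removed = 0L))
  }
  bases_in <- sum(nchar(pairs$seq1)) + sum(nchar(pairs$seq2))
  trim_mate <- function(seq, qual) {
    keep <- clip_adapter_cpp(seq, params$adapter_seq, 8L, 0.1)
    seq <- substr(seq, 1, keep)
    qual <- substr(qual, 1, keep)
    win <- quality_trim_cpp(qual, as.integer(params$window),
                            params$window_min_q,
                            as.integer(params$leading_q),
                            as.integer(params$trailing_q), 33L)
    list(seq = substr(seq, win[, 1], win[, 2]),
         qual = substr(qual, win[, 1], win[, 2]))
  }
  m1 <- trim_mate(pairs$seq1, pairs$qual1)
  m2 <- trim_mate(pairs$seq2, pairs$qual2)
  ok <- nchar(m1$seq) >= params$min_len & nchar(m2$seq) >= params$min_len
  out <- data.frame(pair_id = pairs$pair_id[ok], seq1 = m1$seq[ok],
                    qual1 = m1$qual[ok], seq2 = m2$seq[ok],
                    qual2 = m2$qual[ok], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  list(pairs = out, n_in = n_in, n_out = nrow(out),
       bases_removed = bases_in -
         (sum(nchar(out$seq1)) + sum(nchar(out$seq2))))
}
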