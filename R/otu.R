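#' Cluster barcode candidates into OTUs at 100% identity
#'
#' Candidates with identical sequences (after plus-strand canonicalisation)
#' collapse into one OTU, and a candidate that is an exact substring of a
#' longer candidate joins the longer one's OTU — mirroring how partial
#' barcodes of an ingredient are counted with the full-length one.  The
#' representative is the longest member (ties break lexicographically);
#' distinct sequences never merge.  The partition is independent of input
#' order and re-clustering the representatives is a fixed point.
#'
#' @param candidates barcode-candidate data.frame (all of one locus).
#' @return OTU data.frame: otu_id, locus, rep_seq, member_count, partial
#'   (TRUE when every member was a partial candidate), plus placeholder
#'   mean_depth/coverage/validated columns filled by [map_reads_to_otus()]
#'   and [filter_otus()].
#' @export
cluster_otus <- function(candidates) {
  empty <- data.frame(otu_id = character(0), locus = character(0),
                      rep_seq = character(0), member_count = integer(0),
                      partial = logical(0), mean_depth = numeric(0),
                      coverage = numeric(0), validated = logical(0),
                      stringsAsFactors = FALSE)
  if (is.null(candidates) || nrow(candidates) == 0) return(empty)
  locus <- unique(candidates$locus)
  stopifnot(length(locus) == 1)
  seqs <- canonical_seq(candidates$seq)
  part <- if ("partial" %in% names(candidates)) candidates$partial else
    rep(FALSE, length(seqs))
  ord <- order(-nchar(seqs), seqs)
  seqs <- seqs[ord]
  part <- part[ord]
  rep_seq <- character(0)
  members <- integer(0)
  all_partial <- logical(0)
  for (i in seq_along(seqs)) {
    s <- seqs[i]
    r <- revcomp(s)
    j <- which(vapply(rep_seq, function(L) {
      grepl(s, L, fixed = TRUE) || grepl(r, L, fixed = TRUE)
    }, logical(1)))[1]
    if (!is.na(j)) {
      members[j] <- members[j] + 1L
      all_partial[j] <- all_partial[j] && part[i]
    } else {
      rep_seq <- c(rep_seq, s)
      members <- c(members, 1L)
      all_partial <- c(all_partial, part[i])
    }
  }
  ord2 <- order(-members, rep_seq)
  n <- length(rep_seq)
  data.frame(
    otu_id = sprintf("%s_%03d", gsub("[^A-Za-z0-9]", "", locus), seq_len(n)),
    locus = locus, rep_seq = rep_seq[ord2], member_count = members[ord2],
    partial = all_partial[ord2], mean_depth = NA_real_, coverage = NA_real_,
    validated = NA, stringsAsFactors = FALSE)
}

#' Map reads to OTU representatives
#'
#' Seed-and-extend mapping of reads against every OTU representative: a
#' read maps where an exact `k_seed` match anchors an ungapped extension
#' with identity at least `min_identity` over the overlapping span.  Each
#' read maps to at most one OTU (best identity, then longer overlap, then
#' lexicographic otu_id).  Fills mean_depth (mapped bases per
#' representative position) and coverage (fraction of positions with depth
#' >= 1).
#'
#' @param reads character vector of read sequences.
#' @param otus OTU data.frame from [cluster_otus()] (may span loci).
#' @param k_seed exact seed length.
#' @param min_identity minimum identity over the overlap.
#' @return list with `otus` (depth/coverage filled), `pileups` (named list
#'   of per-base depth vectors), `read_otu` (per-read otu_id or NA), and
#'   `read_counts` (mapped reads per OTU).
#' @export
map_reads_to_otus <- function(reads, otus, k_seed = 15, min_identity = 0.95) {
  if (nrow(otus) == 0) {
    return(list(otus = otus, pileups = list(),
                read_otu = rep(NA_character_, length(reads)),
                read_counts = integer(0)))
  }
  ord <- order(otus$otu_id)
  otus <- otus[ord, , drop = FALSE]
  res <- map_reads_cpp(otus$rep_seq, reads, as.integer(k_seed), min_identity,
                       as.integer(k_seed))
  pileups <- setNames(res$pileups, otus$otu_id)
  otus$mean_depth <- vapply(pileups, function(p) sum(p) / length(p),
                            numeric(1))
  otus$coverage <- vapply(pileups, function(p) mean(p >= 1), numeric(1))
  read_otu <- rep(NA_character_, length(reads))
  read_otu[res$ref > 0] <- otus$otu_id[res$ref[res$ref > 0]]
  counts <- setNames(tabulate(res$ref, nbins = nrow(otus)), otus$otu_id)
  rownames(otus) <- NULL
  list(otus = otus, pileups = pileups, read_otu = read_otu,
       read_counts = counts)
}

#' Per-base pileup of reads on a single OTU
#'
#' Convenience single-reference wrapper around the mapper; returns the
#' per-base depth vector over the representative.
#'
#' @param reads read sequences.
#' @param otu one-row OTU data.frame.
#' @inheritParams map_reads_to_otus
#' @return integer vector of per-base depth.
#' @export
map_reads_to_otu <- function(reads, otu, k_seed = 15, min_identity = 0.95) {
  if (length(reads) == 0) {
    return(integer(nchar(otu$rep_seq)))
  }
  res <- map_reads_cpp(otu$rep_seq, reads, as.integer(k_seed), min_identity,
                       as.integer(k_seed))
  as.integer(res$pileups[[1]])
}

#' Validate OTUs by depth and coverage
#'
#' An OTU is validated when coverage >= `min_coverage` and mean depth >=
#' `min_depth` (both inclusive).  Failing OTUs are retained but flagged, so
#' reports can list them as low-reliability rather than silently dropping
#' them.  These thresholds are the most consequential undocumented
#' parameters of the workflow and are therefore surfaced in the run
#' configuration and provenance log.
#'
#' @param otus OTU data.frame with depth/coverage filled.
#' @param min_coverage minimum covered fraction of the representative.
#' @param min_depth minimum mean depth (reads per base).
#' @return the OTU data.frame with `validated` set.
#' @export
filter_otus <- function(otus, min_coverage = 0.8, min_depth = 5.0) {
  otus$validated <- otus$coverage >= min_coverage &
    otus$mean_depth >= min_depth
  otus
}
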