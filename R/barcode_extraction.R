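#' Default barcode primer set
#'
#' The field-standard primer pairs for the five loci: ITS2F/ITS3R (ITS2),
#' psbA/trnH (psbA-trnH), 1F/724R (rbcL), 3F_KIM/1R_KIM (matK) and
#' LCO1490/HCO2198 (COI, the Folmer region).  Primers are written 5'-3' on
#' their own strand; IUPAC degenerate codes are permitted.
#'
#' @return data.frame with columns locus, fwd_name, fwd, rev_name, rev.
#' @export
default_primer_set <- function() {
  ps <- data.frame(
    locus = c("ITS2", "psbA-trnH", "rbcL", "matK", "COI"),
    fwd_name = c("ITS2F", "psbA", "1F", "3F_KIM", "LCO1490"),
    fwd = c("ATGCGATACTTGGTGTGAAT",
            "GTTATGCATGAACGTAATGCTC",
            "ATGTCACCACAAACAGAAAC",
            "CGTACAGTACTTTTGTGTTTACGAG",
            "GGTCAACAAATCATAAAGATATTGG"),
    rev_name = c("ITS3R", "trnH", "724R", "1R_KIM", "HCO2198"),
    rev = c("GACGCTTCTCCAGACTACAAT",
            "CGCGCATGGTGGATTCACAATCC",
            "TCGCATGTACCTGCAGTAGC",
            "ACCCAGTCCATCTGGAAATCTTGGTTC",
            "TAAACTTCAGGGTGACCAAAAAATCA"),
    stringsAsFactors = FALSE
  )
  bad <- nchar(c(ps$fwd, ps$rev)) < 15 | nchar(c(ps$fwd, ps$rev)) > 30
  stopifnot(!any(bad))
  ps
}

#' Read or write a primer set as TSV
#'
#' @param path TSV path with columns locus, name, sequence, direction
#'   (fwd/rev).
#' @return a primer set data.frame in [default_primer_set()] layout.
#' @export
read_primer_set <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  fwd <- tab[tab$direction == "fwd", ]
  rev <- tab[tab$direction == "rev", ]
  m <- match(fwd$locus, rev$locus)
  data.frame(locus = fwd$locus, fwd_name = fwd$name, fwd = fwd$sequence,
             rev_name = rev$name[m], rev = rev$sequence[m],
             stringsAsFactors = FALSE)
}

#' @rdname read_primer_set
#' @param primer_set a primer set data.frame.
#' @export
write_primer_set <- function(primer_set, path) {
  long <- rbind(
    data.frame(locus = primer_set$locus, name = primer_set$fwd_name,
               sequence = primer_set$fwd, direction = "fwd"),
    data.frame(locus = primer_set$locus, name = primer_set$rev_name,
               sequence = primer_set$rev, direction = "rev"))
  write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Find primer sites on a contig
#'
#' Reports every position (both strands) where the primer matches with at
#' most `max_mismatch` mismatches under IUPAC-aware comparison (a
#' degenerate code matches any of its bases).  No indels are considered:
#' assembled contigs carry few.
#'
#' @param contig_seq contig sequence.
#' @param primer primer sequence, IUPAC codes allowed.
#' @param max_mismatch maximum mismatches.
#' @return data.frame with columns position (1-based start on the plus
#'   strand), strand (`"+"`/`"-"`), mismatches.  The minus strand means the
#'   primer matches the reverse complement of the contig at that region.
#' @export
find_primer_sites <- function(contig_seq, primer, max_mismatch = 3) {
  subject <- Biostrings::DNAString(contig_seq)
  scan <- function(pat, strand) {
    hits <- Biostrings::matchPattern(Biostrings::DNAString(pat), subject,
                                     max.mismatch = max_mismatch,
                                     fixed = FALSE)
    # with max.mismatch > 0 matches may overhang the contig ends; keep only
    # fully contained sites
    hits <- hits[Biostrings::start(hits) >= 1 &
                   Biostrings::end(hits) <= length(subject)]
    if (length(hits) == 0) {
      return(data.frame(position = integer(0), strand = character(0),
                        mismatches = integer(0)))
    }
    mm <- vapply(seq_along(hits), function(i) {
      w <- as.character(hits[[i]])
      sum(!iupac_match(strsplit(pat, NULL)[[1]], strsplit(w, NULL)[[1]]))
    }, integer(1))
    data.frame(position = Biostrings::start(hits), strand = strand,
               mismatches = mm, stringsAsFactors = FALSE)
  }
  out <- rbind(scan(primer, "+"), scan(revcomp_iupac(primer), "-"))
  out <- out[order(out$position, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# IUPAC helpers -------------------------------------------------------------

iupac_table <- c(A = "A", C = "C", G = "G", T = "T", R = "AG", Y = "CT",
                 S = "CG", W = "AT", K = "GT", M = "AC", B = "CGT",
                 D = "AGT", H = "ACT", V = "ACG", N = "ACGT")

# does each degenerate pattern base match the corresponding plain base?
iupac_match <- function(pattern_chars, subject_chars) {
  mapply(function(p, s) {
    grepl(s, iupac_table[[p]], fixed = TRUE)
  }, pattern_chars, subject_chars, USE.NAMES = FALSE)
}

revcomp_iupac <- function(x) {
  comp <- chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", x)
  paste(rev(strsplit(comp, NULL)[[1]]), collapse = "")
}

#' Extract the inter-primer barcode region from a contig
#'
#' Looks for a forward-primer site and a downstream reverse-complemented
#' reverse-primer site (on either contig strand) and returns the region
#' strictly between them, primers excluded, canonicalised to the plus
#' strand of the barcode.  When several pairings exist the longest
#' extractable region wins; ties go to the leftmost pairing.
#'
#' @param contig one row of a contig data.frame (or a list with `seq` and
#'   `contig_id`).
#' @param primer_pair one row of [default_primer_set()].
#' @param max_mismatch maximum primer mismatches.
#' @return one-row barcode-candidate data.frame, or `NULL` when no primer
#'   pairing exists.
#' @export
extract_interprimer <- function(contig, primer_pair, max_mismatch = 3) {
  extract_one <- function(seq) {
    f <- find_primer_sites(seq, primer_pair$fwd, max_mismatch)
    f <- f[f$strand == "+", , drop = FALSE]
    r <- find_primer_sites(seq, primer_pair$rev, max_mismatch)
    r <- r[r$strand == "-", , drop = FALSE]
    if (nrow(f) == 0 || nrow(r) == 0) return(NULL)
    best <- NULL
    flen <- nchar(primer_pair$fwd)
    for (i in seq_len(nrow(f))) {
      start <- f$position[i] + flen
      for (j in seq_len(nrow(r))) {
        end <- r$position[j] - 1
        if (end < start) next
        cand <- list(start = start, end = end, len = end - start + 1)
        if (is.null(best) || cand$len > best$len ||
            (cand$len == best$len && cand$start < best$start)) {
          best <- cand
        }
      }
    }
    if (is.null(best)) return(NULL)
    substr(seq, best$start, best$end)
  }
  seq <- contig$seq
  bc <- extract_one(seq)
  strand <- "+"
  if (is.null(bc)) {
    bc <- extract_one(revcomp(seq))
    strand <- "-"
  }
  if (is.null(bc) || nchar(bc) == 0) return(NULL)
  data.frame(locus = primer_pair$locus, seq = bc,
             source_contig_id = contig$contig_id %||% NA_character_,
             extraction_method = "primer", strand = strand, partial = FALSE,
             stringsAsFactors = FALSE)
}

# ITS2 flank profiles --------------------------------------------------------

# Conserved rDNA flank consensus used by the fixtures and the default
# profile: the 3' tail of 5.8S (ending in the ITS2F site) and the 5' head of
# 28S (starting with the reverse complement of the ITS3R site).
its2_flank_sequences <- function() {
  ps <- default_primer_set()
  its2 <- ps[ps$locus == "ITS2", ]
  list(
    five8S_tail = paste0("CAACG", its2$fwd),       # ...5.8S | ITS2F site
    two8S_head = paste0(revcomp(its2$rev), "GACC") # ITS3R site | 28S...
  )
}

#' Default ITS2 flank profile
#'
#' Two position-weight matrices over the conserved 3' end of 5.8S and 5'
#' start of 28S, with a log-odds score threshold (versus a uniform
#' background).  This is the profile-matching stand-in for HMM-based ITS2
#' annotation: the ITS2 region is whatever lies between the two rDNA
#' flanks.
#'
#' @param consensus_prob probability mass on the consensus base per column.
#' @param threshold minimum log2-odds window score for a flank hit.
#' @return a `flank_profile` list.
#' @export
default_flank_profile <- function(consensus_prob = 0.91, threshold = 20) {
  fl <- its2_flank_sequences()
  make_pwm <- function(seq) {
    chars <- strsplit(seq, NULL)[[1]]
    m <- matrix((1 - consensus_prob) / 3, nrow = 4, ncol = length(chars),
                dimnames = list(c("A", "C", "G", "T"), NULL))
    for (j in seq_along(chars)) m[chars[j], j] <- consensus_prob
    m
  }
  structure(list(five8S = make_pwm(fl$five8S_tail),
                 two8S = make_pwm(fl$two8S_head),
                 threshold = threshold),
            class = "flank_profile")
}

# log2-odds scores of a profile at every window start of seq (NA-free)
profile_scores <- function(seq, pwm) {
  n <- nchar(seq)
  w <- ncol(pwm)
  if (n < w) return(numeric(0))
  code <- match(strsplit(seq, NULL)[[1]], c("A", "C", "G", "T"))
  logodds <- log2(pwm / 0.25)
  nwin <- n - w + 1
  sc <- numeric(nwin)
  ok <- rep(TRUE, nwin)
  for (j in seq_len(w)) {
    b <- code[j:(j + nwin - 1)]
    bad <- is.na(b)
    ok <- ok & !bad
    b[bad] <- 1L
    sc <- sc + logodds[cbind(b, j)]
  }
  sc[!ok] <- -Inf
  sc
}

#' Annotate the ITS2 region of a contig
#'
#' Scores every window of the contig (both strands) against the 5.8S-tail
#' and 28S-head profiles.  When both flanks exceed the threshold in
#' consistent order and orientation, the enclosed region is returned.  When
#' only one flank is found and the contig end truncates where the other
#' flank would lie, a candidate flagged `partial` covering the region up to
#' the contig end is returned.
#'
#' @param contig one row of a contig data.frame.
#' @param flank_profile a [default_flank_profile()].
#' @param max_its2_len longest region considered (guards the partial rule).
#' @return one-row candidate data.frame, or `NULL`.
#' @export
annotate_its2 <- function(contig, flank_profile = default_flank_profile(),
                          max_its2_len = 500) {
  scan_strand <- function(seq, strand) {
    s5 <- profile_scores(seq, flank_profile$five8S)
    s2 <- profile_scores(seq, flank_profile$two8S)
    w5 <- ncol(flank_profile$five8S)
    w2 <- ncol(flank_profile$two8S)
    h5 <- which(s5 >= flank_profile$threshold)
    h2 <- which(s2 >= flank_profile$threshold)
    # full annotation: best-scoring consistent pair, 28S strictly after 5.8S
    best <- NULL
    for (i in h5) {
      after <- h2[h2 >= i + w5]
      for (j in after) {
        sc <- s5[i] + s2[j]
        if (is.null(best) || sc > best$score) {
          best <- list(start = i + w5, end = j - 1, score = sc)
        }
      }
    }
    if (!is.null(best)) {
      return(data.frame(locus = "ITS2",
                        seq = substr(seq, best$start, best$end),
                        strand = strand, partial = FALSE,
                        stringsAsFactors = FALSE))
    }
    # partial: 5.8S found, contig ends before a 28S flank could fit
    n <- nchar(seq)
    for (i in h5) {
      tail_len <- n - (i + w5) + 1
      if (tail_len > 0 && tail_len <= max_its2_len) {
        return(data.frame(locus = "ITS2",
                          seq = substr(seq, i + w5, n),
                          strand = strand, partial = TRUE,
                          stringsAsFactors = FALSE))
      }
    }
    # partial from the other side: 28S found near the start
    for (j in h2) {
      head_len <- j - 1
      if (head_len > 0 && head_len <= max_its2_len) {
        return(data.frame(locus = "ITS2", seq = substr(seq, 1, j - 1),
                          strand = strand, partial = TRUE,
                          stringsAsFactors = FALSE))
      }
    }
    NULL
  }
  out <- scan_strand(contig$seq, "+")
  if (is.null(out)) out <- scan_strand(revcomp(contig$seq), "-")
  if (is.null(out) || nchar(out$seq) == 0) return(NULL)
  out$source_contig_id <- contig$contig_id %||% NA_character_
  out$extraction_method <- "flank_profile"
  out[, c("locus", "seq", "source_contig_id", "extraction_method", "strand",
          "partial")]
}

#' Extract barcode candidates from assembled contigs
#'
#' Applies [annotate_its2()] to ITS2 contigs and [extract_interprimer()] to
#' the primer-extractable loci, then (optionally) screens bimeras:
#' candidates whose two halves best-hit different genera in the reference
#' database are discarded.
#'
#' @param contigs contig data.frame with a `locus` column.
#' @param refdb a `reference_db` (used by the bimera screen).
#' @param primer_set a primer set data.frame.
#' @param flank_profile a [default_flank_profile()].
#' @param max_mismatch maximum primer mismatches.
#' @param bimera_check logical; disable to keep all candidates.
#' @param min_len candidates shorter than this are discarded (fragments of
#'   a barcode too short to carry taxonomic signal).
#' @return a barcode-candidate data.frame.
#' @export
extract_barcodes <- function(contigs, refdb = NULL,
                             primer_set = default_primer_set(),
                             flank_profile = default_flank_profile(),
                             max_mismatch = 3, bimera_check = TRUE,
                             min_len = 50) {
  out <- list()
  for (i in seq_len(nrow(contigs))) {
    ctg <- contigs[i, ]
    cand <- if (identical(ctg$locus, "ITS2")) {
      annotate_its2(ctg, flank_profile)
    } else {
      pp <- primer_set[primer_set$locus == ctg$locus, , drop = FALSE]
      if (nrow(pp) == 1) extract_interprimer(ctg, pp, max_mismatch) else NULL
    }
    if (!is.null(cand)) out[[length(out) + 1]] <- cand
  }
  if (length(out) == 0) {
    return(data.frame(locus = character(0), seq = character(0),
                      source_contig_id = character(0),
                      extraction_method = character(0),
                      strand = character(0), partial = logical(0),
                      stringsAsFactors = FALSE))
  }
  cands <- do.call(rbind, out)
  cands <- cands[nchar(cands$seq) >= min_len, , drop = FALSE]
  rownames(cands) <- NULL
  if (bimera_check && !is.null(refdb)) {
    ok <- vapply(seq_len(nrow(cands)), function(i) {
      !is_bimera(cands$seq[i], cands$locus[i], refdb)
    }, logical(1))
    cands <- cands[ok, , drop = FALSE]
    rownames(cands) <- NULL
  }
  cands
}

# a candidate is flagged bimeric when its two halves best-hit references of
# different genera with both halves aligning well (any locus: a glued
# contig can join segments of different loci as well as different taxa)
is_bimera <- function(seq, locus, refdb, min_half = 40) {
  n <- nchar(seq)
  if (n < 2 * min_half) return(FALSE)
  refs <- refdb$barcodes
  if (nrow(refs) == 0) return(FALSE)
  half_genus <- function(s) {
    hits <- vapply(refs$barcode_seq, function(r) {
      a <- overlap_align_cpp(s, r, 1, -1, -2, -1)
      if (a[["aligned_span"]] < min_half) return(NA_real_)
      1 - a[["base_differences"]] / a[["aligned_span"]]
    }, numeric(1))
    if (all(is.na(hits)) || max(hits, na.rm = TRUE) < 0.9) return(NA_character_)
    tax <- refs$taxon_id[which.max(hits)]
    unclass(get_lineage(refdb, tax))[["genus"]]
  }
  g1 <- half_genus(substr(seq, 1, floor(n / 2)))
  g2 <- half_genus(substr(seq, floor(n / 2) + 1, n))
  !is.na(g1) && !is.na(g2) && g1 != g2
}
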