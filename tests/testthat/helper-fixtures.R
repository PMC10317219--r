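# Small fixtures and independent oracle implementations shared by tests.
# Oracles are deliberately written as plain, brute-force R so they stay
# independent of the package's compiled code paths.

rand_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

rc_chr <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), NULL)[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# a minimal three-taxon database built by hand (no fixture generator);
# with_seed keeps the caller's RNG stream untouched, so test sequences
# drawn afterwards share no pseudo-random subsequences with the database
tiny_refdb <- function() withr::with_seed(101, {
  ps <- default_primer_set()
  mk_ctx <- function(locus, bc) {
    p <- ps[ps$locus == locus, ]
    paste0(rand_dna(210), p$fwd, bc, rc_chr(p$rev), rand_dna(210))
  }
  b1 <- rand_dna(300); b2 <- rand_dna(350); b3 <- rand_dna(400)
  barcodes <- data.frame(
    taxon_id = c("tax_a", "tax_b", "tax_c"),
    locus = c("matK", "rbcL", "COI"),
    copy_weight = c(20, 20, 20),
    barcode_seq = c(b1, b2, b3),
    context_seq = c(mk_ctx("matK", b1), mk_ctx("rbcL", b2),
                    mk_ctx("COI", b3)),
    stringsAsFactors = FALSE)
  taxa <- data.frame(
    taxon_id = c("tax_a", "tax_b", "tax_c"),
    role = c("labeled_ingredient", "labeled_ingredient",
             "labeled_ingredient"),
    kingdom_class = c("plant", "plant", "animal"),
    kingdom = c("Viridiplantae", "Viridiplantae", "Metazoa"),
    phylum = c("Streptophyta", "Streptophyta", "Chordata"),
    class = c("Magnoliopsida", "Magnoliopsida", "Aves"),
    order = c("Apiales", "Fabales", "Galliformes"),
    family = c("Araliaceae", "Fabaceae", "Phasianidae"),
    genus = c("Panax", "Glycyrrhiza", "Gallus"),
    species = c("Panax alpha", "Glycyrrhiza beta", "Gallus gamma"),
    stringsAsFactors = FALSE)
  shotgunmb:::new_reference_db(taxa, barcodes)
})

# lineages used across LCA tests
lin_panax_q <- lineage(paste("Viridiplantae", "Streptophyta",
                             "Magnoliopsida", "Apiales", "Araliaceae",
                             "Panax", "Panax quinquefolius", sep = ";"))
lin_panax_g <- lineage(paste("Viridiplantae", "Streptophyta",
                             "Magnoliopsida", "Apiales", "Araliaceae",
                             "Panax", "Panax ginseng", sep = ";"))
lin_scroph_n <- lineage(paste("Viridiplantae", "Streptophyta",
                              "Magnoliopsida", "Lamiales",
                              "Scrophulariaceae", "Scrophularia",
                              "Scrophularia ningpoensis", sep = ";"))
lin_scroph_b <- lineage(paste("Viridiplantae", "Streptophyta",
                              "Magnoliopsida", "Lamiales",
                              "Scrophulariaceae", "Scrophularia",
                              "Scrophularia buergeriana", sep = ";"))
lin_gallus <- lineage(paste("Metazoa", "Chordata", "Aves", "Galliformes",
                            "Phasianidae", "Gallus", "Gallus gallus",
                            sep = ";"))

# brute-force longest-common-prefix LCA over rank vectors
oracle_lca <- function(lineages) {
  mat <- do.call(rbind, lapply(lineages, unclass))
  ranks <- colnames(mat)
  depth <- 0
  for (j in seq_len(ncol(mat))) {
    if (length(unique(mat[, j])) == 1) depth <- j else break
  }
  if (depth == 0) return(list(rank = "root", taxon = "cellular organisms"))
  list(rank = ranks[depth], taxon = unname(mat[1, depth]))
}

# enumerate distinct canonical k-mers of a sequence directly
oracle_canonical_kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  kmers <- substring(seq, 1:(n - k + 1), k:n)
  kmers <- kmers[!grepl("[^ACGT]", kmers)]
  unique(pmin(kmers, rc_chr(kmers)))
}

# brute-force per-base pileup from explicit read placements
oracle_pileup <- function(ref, reads) {
  depth <- integer(nchar(ref))
  placements <- list()
  for (rd in reads) {
    hit <- regexpr(rd, ref, fixed = TRUE)
    if (hit == -1) {
      hit <- regexpr(rc_chr(rd), ref, fixed = TRUE)
    }
    if (hit > -1) {
      span <- hit:(hit + nchar(rd) - 1)
      depth[span] <- depth[span] + 1L
      placements[[length(placements) + 1]] <- c(hit - 1L,
                                                hit + nchar(rd) - 1L)
    }
  }
  depth
}

# quadratic-time overlap alignment oracle with affine gaps (first gap
# column costs `open`, later columns `ext`); mirrors the documented scoring
# contract but is implemented independently in plain R
oracle_overlap_align <- function(a, b, match = 1, mismatch = -1,
                                 open = -2, ext = -1) {
  n <- nchar(a); m <- nchar(b)
  A <- strsplit(a, NULL)[[1]]; B <- strsplit(b, NULL)[[1]]
  NEG <- -1e15
  M <- matrix(NEG, n + 1, m + 1); X <- M; Y <- M
  M[1, ] <- 0; M[, 1] <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (A[i - 1] == B[j - 1]) match else mismatch
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      X[i, j] <- max(M[i - 1, j] + open, X[i - 1, j] + ext)
      Y[i, j] <- max(M[i, j - 1] + open, Y[i, j - 1] + ext)
    }
  }
  max(M[n + 1, ], X[n + 1, ], Y[n + 1, ], M[, m + 1], X[, m + 1],
      Y[, m + 1])
}

# exhaustive IUPAC-aware primer scan over every offset and strand
oracle_primer_scan <- function(contig, primer, max_mismatch) {
  iupac <- c(A = "A", C = "C", G = "G", T = "T", R = "AG", Y = "CT",
             S = "CG", W = "AT", K = "GT", M = "AC", B = "CGT", D = "AGT",
             H = "ACT", V = "ACG", N = "ACGT")
  match1 <- function(pat, win) {
    p <- strsplit(pat, NULL)[[1]]
    w <- strsplit(win, NULL)[[1]]
    sum(!mapply(function(pp, ww) grepl(ww, iupac[[pp]], fixed = TRUE),
                p, w))
  }
  rc_iupac <- function(x) {
    paste(rev(strsplit(chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", x),
                       NULL)[[1]]), collapse = "")
  }
  n <- nchar(contig); plen <- nchar(primer)
  out <- list()
  for (strand in c("+", "-")) {
    pat <- if (strand == "+") primer else rc_iupac(primer)
    for (pos in seq_len(n - plen + 1)) {
      mm <- match1(pat, substr(contig, pos, pos + plen - 1))
      if (mm <= max_mismatch) {
        out[[length(out) + 1]] <- data.frame(position = pos,
                                             strand = strand,
                                             mismatches = mm)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(position = integer(0), strand = character(0),
                      mismatches = integer(0)))
  }
  o <- do.call(rbind, out)
  o <- o[order(o$position, o$strand), ]
  rownames(o) <- NULL
  o
}
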