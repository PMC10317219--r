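test_that("primer sites are found exactly and IUPAC codes match their bases", {
  set.seed(81)
  primer <- "ACGTACGTACGTACGTACGT"
  contig <- paste0(rand_dna(11), primer, rand_dna(40))
  hits <- find_primer_sites(contig, primer, max_mismatch = 0)
  expect_equal(hits$position[hits$strand == "+"], 12)
  expect_equal(hits$mismatches[hits$strand == "+"], 0)
  # degenerate R matches both A and G at that position
  deg <- "ACGTRCGTACGTACG"
  win_a <- sub("R", "A", deg)
  win_g <- sub("R", "G", deg)
  for (w in c(win_a, win_g)) {
    ctg <- paste0(rand_dna(10), w, rand_dna(10))
    h <- find_primer_sites(ctg, deg, max_mismatch = 0)
    expect_true(11 %in% h$position[h$strand == "+"])
  }
})

test_that("primer scanning equals the exhaustive offset/strand oracle", {
  set.seed(82)
  for (i in 1:10) {
    contig <- rand_dna(300)
    primer <- rand_dna(20)
    # plant the primer (possibly mutated) at a couple of places
    p1 <- sample(250, 1)
    contig <- paste0(substr(contig, 1, p1 - 1), primer,
                     substr(contig, p1 + 20, 300))
    got <- find_primer_sites(contig, primer, max_mismatch = 3)
    want <- oracle_primer_scan(contig, primer, max_mismatch = 3)
    expect_equal(got$position, want$position)
    expect_equal(got$strand, want$strand)
    expect_equal(got$mismatches, want$mismatches)
  }
})

test_that("inter-primer extraction returns the enclosed barcode", {
  set.seed(83)
  ps <- default_primer_set()
  pp <- ps[ps$locus == "matK", ]
  barcode <- rand_dna(300)
  contig <- list(contig_id = "c1",
                 seq = paste0(rand_dna(60), pp$fwd, barcode, rc_chr(pp$rev),
                              rand_dna(60)))
  out <- extract_interprimer(contig, pp)
  expect_equal(out$seq, barcode)
  expect_equal(out$extraction_method, "primer")
  # extraction is orientation-invariant
  out_rc <- extract_interprimer(list(contig_id = "c1",
                                     seq = rc_chr(contig$seq)), pp)
  expect_equal(out_rc$seq, barcode)
  # the extracted barcode no longer contains its own primer sites
  expect_equal(nrow(find_primer_sites(out$seq, pp$fwd, 3)) +
                 nrow(find_primer_sites(out$seq, pp$rev, 3)), 0)
  # missing reverse site -> NONE
  no_rev <- list(contig_id = "c2",
                 seq = paste0(rand_dna(60), pp$fwd, barcode, rand_dna(60)))
  expect_null(extract_interprimer(no_rev, pp))
})

test_that("multiple primer pairings resolve to the longest, leftmost region", {
  set.seed(84)
  ps <- default_primer_set()
  pp <- ps[ps$locus == "rbcL", ]
  bc1 <- rand_dna(120)
  bc2 <- rand_dna(260)
  # two reverse sites downstream of one forward site
  contig <- list(contig_id = "c3",
                 seq = paste0(rand_dna(30), pp$fwd, bc1, rc_chr(pp$rev),
                              rand_dna(20), rc_chr(pp$rev), rand_dna(30)))
  out <- extract_interprimer(contig, pp)
  # brute force over all pairings by the stated rule
  f <- find_primer_sites(contig$seq, pp$fwd, 3)
  f <- f[f$strand == "+", ]
  r <- find_primer_sites(contig$seq, pp$rev, 3)
  r <- r[r$strand == "-", ]
  best <- NULL
  for (i in seq_len(nrow(f))) {
    for (j in seq_len(nrow(r))) {
      s <- f$position[i] + nchar(pp$fwd)
      e <- r$position[j] - 1
      if (e < s) next
      len <- e - s + 1
      if (is.null(best) || len > best$len ||
          (len == best$len && s < best$s)) best <- list(s = s, e = e,
                                                        len = len)
    }
  }
  expect_equal(out$seq, substr(contig$seq, best$s, best$e))
})

test_that("ITS2 flank profiles locate the planted region", {
  set.seed(85)
  fl <- shotgunmb:::its2_flank_sequences()
  its2 <- rand_dna(240)
  contig <- list(contig_id = "c4",
                 seq = paste0(rand_dna(80), fl$five8S_tail, its2,
                              fl$two8S_head, rand_dna(80)))
  out <- annotate_its2(contig)
  expect_equal(out$seq, its2)
  expect_false(out$partial)
  expect_equal(out$extraction_method, "flank_profile")
  # orientation invariance
  out_rc <- annotate_its2(list(contig_id = "c4", seq = rc_chr(contig$seq)))
  expect_equal(out_rc$seq, its2)
  # truncated 28S flank -> partial candidate covering the planted prefix
  trunc <- list(contig_id = "c5",
                seq = paste0(rand_dna(80), fl$five8S_tail,
                             substr(its2, 1, 150)))
  pout <- annotate_its2(trunc)
  expect_true(pout$partial)
  expect_equal(pout$seq, substr(its2, 1, 150))
})

test_that("random contigs are almost never annotated as ITS2", {
  set.seed(86)
  n <- 1000
  hits <- 0L
  prof <- default_flank_profile()
  for (i in seq_len(n)) {
    out <- annotate_its2(list(contig_id = "r", seq = rand_dna(600)), prof)
    if (!is.null(out)) hits <- hits + 1L
  }
  expect_gte((n - hits) / n, 0.99)
})

test_that("extract_barcodes keeps exact planted barcodes and screens bimeras", {
  set.seed(87)
  db <- tiny_refdb()
  ps <- default_primer_set()
  ctg <- data.frame(contig_id = c("a", "b"),
                    locus = c("matK", "rbcL"),
                    seq = c(db$barcodes$context_seq[1],
                            db$barcodes$context_seq[2]),
                    k_used = 21L, mean_kmer_coverage = 50,
                    stringsAsFactors = FALSE)
  cands <- extract_barcodes(ctg, db)
  expect_setequal(cands$seq, db$barcodes$barcode_seq[1:2])
  # a contig gluing the halves of two different-genus references is
  # discarded by the bimera screen
  b1 <- db$barcodes$barcode_seq[1]
  b2 <- db$barcodes$barcode_seq[2]
  pp <- ps[ps$locus == "matK", ]
  chimera <- paste0(substr(b1, 1, 150), substr(b2, 180, 350))
  ctg2 <- data.frame(contig_id = "x", locus = "matK",
                     seq = paste0(rand_dna(30), pp$fwd, chimera,
                                  rc_chr(pp$rev), rand_dna(30)),
                     k_used = 21L, mean_kmer_coverage = 50,
                     stringsAsFactors = FALSE)
  expect_equal(nrow(extract_barcodes(ctg2, db, bimera_check = TRUE)), 0)
  expect_equal(nrow(extract_barcodes(ctg2, db, bimera_check = FALSE)), 1)
})
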