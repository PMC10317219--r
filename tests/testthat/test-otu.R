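cand_df <- function(seqs, partial = FALSE) {
  data.frame(locus = rep("ITS2", length(seqs)), seq = seqs,
             source_contig_id = sprintf("c%d", seq_along(seqs)),
             extraction_method = rep("flank_profile", length(seqs)),
             strand = rep("+", length(seqs)),
             partial = rep_len(partial, length(seqs)),
             stringsAsFactors = FALSE)
}

test_that("clustering at 100% identity collapses only identical/contained", {
  set.seed(91)
  x <- rand_dna(200)
  y_chars <- strsplit(x, NULL)[[1]]
  y_chars[77] <- setdiff(c("A", "C", "G", "T"), y_chars[77])[1]
  y <- paste(y_chars, collapse = "")
  o1 <- cluster_otus(cand_df(c(x, x, x)))
  expect_equal(nrow(o1), 1)
  expect_equal(o1$member_count, 3)
  # Hamming distance 1 keeps sequences apart
  o2 <- cluster_otus(cand_df(c(x, y)))
  expect_equal(nrow(o2), 2)
  # containment joins the longer candidate's OTU, longest is representative
  o3 <- cluster_otus(cand_df(c(substr(x, 20, 150), x, rc_chr(x))))
  expect_equal(nrow(o3), 1)
  expect_equal(o3$member_count, 3)
  expect_equal(nchar(o3$rep_seq), 200)
  expect_equal(nrow(cluster_otus(cand_df(character(0)))), 0)
})

test_that("clustering equals a brute-force all-pairs partition", {
  set.seed(92)
  base <- vapply(1:12, function(i) rand_dna(sample(80:160, 1)), "")
  cands <- character(0)
  for (b in base) {
    n_copies <- sample(1:3, 1)
    for (j in seq_len(n_copies)) {
      form <- sample(c("same", "rc", "sub"), 1)
      cands <- c(cands, switch(form,
        same = b,
        rc = rc_chr(b),
        sub = substr(b, sample(1:10, 1), nchar(b) - sample(0:10, 1))))
    }
  }
  cands <- c(cands, vapply(1:8, function(i) rand_dna(100), ""))
  got <- cluster_otus(cand_df(cands))
  expect_equal(sum(got$member_count), length(cands))
  # oracle: assign every candidate to the longest candidate containing it
  # (all-pairs comparison on the containment relation)
  canon <- pmin(cands, rc_chr(cands))
  contained <- function(a, b) {
    grepl(a, b, fixed = TRUE) || grepl(rc_chr(a), b, fixed = TRUE)
  }
  ord <- order(-nchar(canon), canon)
  reps <- character(0)
  sizes <- integer(0)
  for (i in ord) {
    host <- NA_integer_
    for (j in seq_along(reps)) {
      if (contained(canon[i], reps[j])) { host <- j; break }
    }
    if (is.na(host)) {
      reps <- c(reps, canon[i])
      sizes <- c(sizes, 1L)
    } else {
      sizes[host] <- sizes[host] + 1L
    }
  }
  expect_equal(sort(got$member_count), sort(sizes))
})

test_that("clustering is input-order invariant and idempotent", {
  set.seed(93)
  x <- rand_dna(150)
  cands <- c(x, substr(x, 10, 120), rand_dna(150), rc_chr(x), rand_dna(90))
  a <- cluster_otus(cand_df(cands))
  b <- cluster_otus(cand_df(rev(cands)))
  expect_equal(a$rep_seq, b$rep_seq)
  expect_equal(a$member_count, b$member_count)
  again <- cluster_otus(cand_df(a$rep_seq))
  expect_equal(sort(again$rep_seq), sort(a$rep_seq))
})

test_that("pileups match direct per-base counting", {
  set.seed(94)
  rep_seq <- rand_dna(400)
  otu <- data.frame(otu_id = "OTU_1", locus = "matK", rep_seq = rep_seq,
                    member_count = 1L, partial = FALSE,
                    mean_depth = NA_real_, coverage = NA_real_,
                    validated = NA, stringsAsFactors = FALSE)
  # zero reads -> zero pileup
  expect_equal(map_reads_to_otu(character(0), otu), integer(400))
  # error-free tiling reads: coverage 1, mean depth equals mapped bases/len
  starts <- seq(1, 321, by = 16)
  reads <- substring(rep_seq, starts, starts + 79)
  reads[seq(2, length(reads), 2)] <-
    rc_chr(reads[seq(2, length(reads), 2)])
  res <- map_reads_to_otus(reads, otu)
  expect_equal(res$otus$coverage, 1)
  expect_equal(res$otus$mean_depth, length(reads) * 80 / 400)
  expect_equal(as.integer(res$pileups[["OTU_1"]]),
               oracle_pileup(rep_seq, reads))
  # depth conservation: sum of pileup equals total mapped bases
  expect_equal(sum(res$pileups[["OTU_1"]]), length(reads) * 80)
  # a read with ~20% mismatches stays unmapped
  bad <- strsplit(substr(rep_seq, 50, 149), NULL)[[1]]
  idx <- seq(1, 100, by = 5)
  bad[idx] <- vapply(bad[idx], function(c) {
    setdiff(c("A", "C", "G", "T"), c)[1]
  }, "")
  res2 <- map_reads_to_otus(paste(bad, collapse = ""), otu)
  expect_equal(sum(res2$pileups[["OTU_1"]]), 0)
})

test_that("reads are assigned uniquely to the best-identity OTU", {
  set.seed(95)
  a <- rand_dna(300)
  b_chars <- strsplit(a, NULL)[[1]]
  b_chars[c(100, 150, 200, 250, 260, 270)] <-
    vapply(b_chars[c(100, 150, 200, 250, 260, 270)], function(c) {
      setdiff(c("A", "C", "G", "T"), c)[1]
    }, "")
  b <- paste(b_chars, collapse = "")
  otus <- data.frame(otu_id = c("OTU_a", "OTU_b"), locus = "ITS2",
                     rep_seq = c(a, b), member_count = 1L, partial = FALSE,
                     mean_depth = NA_real_, coverage = NA_real_,
                     validated = NA, stringsAsFactors = FALSE)
  read_a <- substr(a, 90, 239)
  res <- map_reads_to_otus(read_a, otus)
  expect_equal(unname(res$read_otu), "OTU_a")
  expect_equal(unname(res$read_counts["OTU_b"]), 0L)
})

test_that("reliability filtering is inclusive at the boundary", {
  otus <- data.frame(otu_id = c("o1", "o2", "o3"), locus = "ITS2",
                     rep_seq = c("ACGT", "ACGT", "ACGT"),
                     member_count = 1L, partial = FALSE,
                     mean_depth = c(30, 4.9, 5.0),
                     coverage = c(1.0, 0.3, 0.8),
                     validated = NA, stringsAsFactors = FALSE)
  out <- filter_otus(otus)
  expect_equal(out$validated, c(TRUE, FALSE, TRUE))
  # failing OTUs are retained, only flagged
  expect_equal(nrow(out), 3)
})
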