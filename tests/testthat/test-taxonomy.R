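mk_otu <- function(seq, locus = "matK", id = "OTU_x") {
  data.frame(otu_id = id, locus = locus, rep_seq = seq, member_count = 1L,
             partial = FALSE, mean_depth = 30, coverage = 1,
             validated = TRUE, stringsAsFactors = FALSE)
}

test_that("alignment identities and base differences behave as documented", {
  db <- tiny_refdb()
  ref <- db$barcodes$barcode_seq[db$barcodes$locus == "matK"]
  hits <- align_otu(mk_otu(ref), db)
  expect_equal(hits$identity[1], 1)
  expect_equal(hits$base_differences[1], 0)
  # four substitutions -> four base differences
  chars <- strsplit(ref, NULL)[[1]]
  pos <- c(40, 90, 140, 190)
  chars[pos] <- vapply(chars[pos], function(c) {
    setdiff(c("A", "C", "G", "T"), c)[1]
  }, "")
  hits4 <- align_otu(mk_otu(paste(chars, collapse = "")), db)
  expect_equal(hits4$base_differences[1], 4)
  expect_equal(hits4$identity[1], 1 - 4 / hits4$aligned_span[1])
  # reverse-complement representative aligns identically
  hits_rc <- align_otu(mk_otu(rc_chr(ref)), db)
  expect_equal(hits_rc$identity[1], 1)
  # no same-locus references -> empty hit list
  expect_equal(nrow(align_otu(mk_otu(ref, locus = "ITS2"), db)), 0)
})

test_that("alignment scores equal an independent DP oracle", {
  set.seed(101)
  for (i in 1:50) {
    a <- rand_dna(sample(60:200, 1))
    b <- if (i %% 3 == 0) {
      rand_dna(sample(60:200, 1))
    } else {
      # related sequence: mutate and indel the first
      chars <- strsplit(a, NULL)[[1]]
      n_mut <- sample(0:8, 1)
      if (n_mut > 0) {
        p <- sample(length(chars), n_mut)
        chars[p] <- vapply(chars[p], function(c) {
          sample(setdiff(c("A", "C", "G", "T"), c), 1)
        }, "")
      }
      if (i %% 2 == 0) chars <- chars[-sample(length(chars), 2)]
      paste(chars, collapse = "")
    }
    got <- shotgunmb:::overlap_align_cpp(a, b, 1, -1, -2, -1)
    expect_equal(unname(got[["score"]]), oracle_overlap_align(a, b))
  }
})

test_that("top-percent LCA assignment follows the documented rules", {
  db <- generate_reference_fixtures(42)
  mk_hits <- function(taxa, idents) {
    data.frame(otu_id = "OTU_x", taxon_id = taxa, identity = idents,
               base_differences = 0L, aligned_span = 200L, score = 200,
               stringsAsFactors = FALSE)
  }
  # single perfect hit -> that species
  a1 <- assign_taxon(mk_hits("panax_quinquefolius", 1.0), db)
  expect_equal(a1$rank, "species")
  expect_equal(a1$taxon, "Panax quinquefolius")
  # equal-identity congeners -> genus
  a2 <- assign_taxon(mk_hits(c("scrophularia_ningpoensis",
                               "scrophularia_buergeriana"), c(1, 1)), db)
  expect_equal(a2$rank, "genus")
  expect_equal(a2$taxon, "Scrophularia")
  # hits at 0.999 and 0.985 with a 1-point window: only the first is kept
  a3 <- assign_taxon(mk_hits(c("panax_quinquefolius", "panax_ginseng"),
                             c(0.999, 0.985)), db)
  expect_equal(a3$n_hits_used, 1)
  expect_equal(a3$taxon, "Panax quinquefolius")
  # brute-force filter + LCA oracle over random hit tables
  set.seed(102)
  pool <- c("panax_quinquefolius", "panax_ginseng",
            "scrophularia_ningpoensis", "zea_mays")
  for (i in 1:20) {
    taxa <- sample(pool, sample(2:4, 1))
    idents <- round(runif(length(taxa), 0.85, 1), 3)
    ord <- order(-idents)
    taxa <- taxa[ord]
    idents <- idents[ord]
    got <- assign_taxon(mk_hits(taxa, idents), db)
    keep <- idents >= 0.90
    taxa_k <- taxa[keep]; id_k <- idents[keep]
    if (length(taxa_k) == 0) {
      expect_equal(got$rank, "unassigned")
    } else {
      kept <- taxa_k[id_k >= max(id_k) - 0.01]
      res <- oracle_lca(lapply(kept, get_lineage, refdb = db))
      if (res$rank == "species" && max(id_k) < 0.99) {
        res <- list(rank = "genus",
                    taxon = unclass(get_lineage(db, kept[1]))[["genus"]])
      }
      expect_equal(got$rank, res$rank)
      expect_equal(got$taxon, res$taxon)
    }
  }
})

test_that("species calls demote to genus below the species-identity floor", {
  db <- generate_reference_fixtures(42)
  hits <- data.frame(otu_id = "OTU_x", taxon_id = "panax_quinquefolius",
                     identity = 0.97, base_differences = 6L,
                     aligned_span = 200L, score = 180,
                     stringsAsFactors = FALSE)
  a <- assign_taxon(hits, db)
  expect_equal(a$rank, "genus")
  expect_equal(a$taxon, "Panax")
  # raising min_identity never deepens an assignment
  rank_depth <- function(r) {
    match(r, c("unassigned", "root", "kingdom", "phylum", "class", "order",
               "family", "genus", "species"))
  }
  set.seed(103)
  pool <- c("panax_quinquefolius", "panax_ginseng", "zea_mays")
  for (i in 1:15) {
    taxa <- sample(pool, 3, replace = TRUE)
    idents <- sort(round(runif(3, 0.88, 1), 3), decreasing = TRUE)
    h <- data.frame(otu_id = "o", taxon_id = taxa, identity = idents,
                    base_differences = 0L, aligned_span = 200L,
                    score = 200, stringsAsFactors = FALSE)
    lo <- assign_taxon(h, db, min_identity = 0.88)
    hi <- assign_taxon(h, db, min_identity = 0.95)
    expect_lte(rank_depth(hi$rank), rank_depth(lo$rank))
  }
})

test_that("detection matrix statuses follow locus presence and assignments", {
  db <- generate_reference_fixtures(42)
  asn <- data.frame(
    otu_id = c("ITS2_001", "COI_001"), rank = "species",
    taxon = c("Wolfiporia cocos", "Gallus gallus"), best_identity = 1,
    n_hits_used = 1L, locus = c("ITS2", "COI"), member_count = 1L,
    partial = FALSE, mean_depth = 30, coverage = 1, validated = TRUE,
    stringsAsFactors = FALSE)
  taxa <- c("wolfiporia_cocos", "gallus_gallus", "terminalia_chebula")
  dm <- build_detection_matrix(list(S1 = asn), list(S1 = taxa), taxa, db)
  get <- function(t, l) dm$status[dm$taxon_id == t & dm$locus == l]
  # the animal ingredient: plant loci are absent from the genome
  for (l in c("ITS2", "psbA-trnH", "matK", "rbcL")) {
    expect_equal(get("gallus_gallus", l), "locus_absent")
  }
  expect_equal(get("gallus_gallus", "COI"), "detected")
  expect_equal(get("wolfiporia_cocos", "ITS2"), "detected")
  expect_equal(get("wolfiporia_cocos", "matK"), "locus_absent")
  # no OTU for a (taxon, locus) present in the database -> not_detected
  expect_equal(get("terminalia_chebula", "rbcL"), "not_detected")
  # partial/unvalidated OTUs do not count as detections
  asn2 <- asn
  asn2$partial[1] <- TRUE
  dm2 <- build_detection_matrix(list(S1 = asn2), list(S1 = taxa), taxa, db)
  expect_equal(dm2$status[dm2$taxon_id == "wolfiporia_cocos" &
                            dm2$locus == "ITS2"], "not_detected")
  # symbol rendering uses the conventional legend
  sym <- format_detection_matrix(dm)
  expect_equal(sym$COI[sym$species == "Gallus gallus"], "√")
  expect_equal(sym$matK[sym$species == "Gallus gallus"], "/")
})

test_that("community report computes fungal shares and the unlabeled ratio", {
  db <- generate_reference_fixtures(42)
  asn <- data.frame(
    otu_id = c("o1", "o2", "o3", "o4"),
    rank = "species",
    taxon = c("Schwanniomyces occidentalis", "Fusarium oxysporum",
              "Glycyrrhiza uralensis", "Zea mays"),
    best_identity = 1, n_hits_used = 1L,
    locus = "ITS2", member_count = 1L, partial = FALSE, mean_depth = 30,
    coverage = 1, validated = TRUE, stringsAsFactors = FALSE)
  counts <- c(o1 = 215, o2 = 785, o3 = 10000, o4 = 137)
  rep <- community_report(asn, counts, db)
  expect_equal(rep$fungal$pct[rep$fungal$genus == "Schwanniomyces"], 21.5)
  expect_equal(sum(rep$fungal$reads), 1000)
  expect_equal(rep$unlabeled_ratio, 100 * 137 / 10000)
  # no fungal OTUs -> empty genus table; no labeled reads -> NA ratio
  plant_only <- asn[3:4, ]
  rep2 <- community_report(plant_only, counts, db)
  expect_equal(nrow(rep2$fungal), 0)
  rep3 <- community_report(asn[1:2, ], counts, db)
  expect_true(is.na(rep3$unlabeled_ratio))
})
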