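test_that("fixture generation is deterministic and congeners differ", {
  db1 <- generate_reference_fixtures(7)
  db2 <- generate_reference_fixtures(7)
  expect_identical(db1$barcodes, db2$barcodes)
  expect_identical(db1$organelles[[1]]$seq, db2$organelles[[1]]$seq)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- write_reference_db(db1, d1)
  p2 <- write_reference_db(db2, d2)
  expect_identical(readBin(p1[["fasta"]], "raw", 2e6),
                   readBin(p2[["fasta"]], "raw", 2e6))
  # congeneric ITS2 fixtures differ at >= 1 position (direct comparison)
  its2 <- function(t) get_barcodes(db1, taxon_id = t, locus = "ITS2")$barcode_seq
  a <- strsplit(its2("panax_quinquefolius"), NULL)[[1]]
  b <- strsplit(its2("panax_ginseng"), NULL)[[1]]
  expect_equal(length(a), length(b))
  expect_gte(sum(a != b), 1)
})

test_that("fixture contexts embed primer sites and rDNA flanks exactly", {
  db <- generate_reference_fixtures(3)
  ps <- default_primer_set()
  b <- get_barcodes(db, taxon_id = "canarium_album", locus = "matK")
  p <- ps[ps$locus == "matK", ]
  expect_true(grepl(paste0(p$fwd, b$barcode_seq, rc_chr(p$rev)),
                    b$context_seq, fixed = TRUE))
  fl <- shotgunmb:::its2_flank_sequences()
  i <- get_barcodes(db, taxon_id = "wolfiporia_cocos", locus = "ITS2")
  expect_true(grepl(paste0(fl$five8S_tail, i$barcode_seq, fl$two8S_head),
                    i$context_seq, fixed = TRUE))
})

test_that("positive-control spiking copies the reference proportion", {
  db <- generate_reference_fixtures(42)
  d <- default_mock_design(db, "M")
  sp <- spike_positive_control(d, "panax_quinquefolius", "wolfiporia_cocos",
                               db)
  comp <- sp$components
  expect_equal(sum(comp$mass_proportion), 1, tolerance = 1e-12)
  expect_equal(
    comp$mass_proportion[comp$taxon_id == "panax_quinquefolius"],
    comp$mass_proportion[comp$taxon_id == "wolfiporia_cocos"])
  # control already present -> error; empty design -> error
  expect_error(spike_positive_control(sp, "panax_quinquefolius",
                                      "wolfiporia_cocos", db),
               "already present")
  empty <- d
  empty$components <- d$components[0, ]
  expect_error(spike_positive_control(empty, "panax_quinquefolius",
                                      "wolfiporia_cocos", db),
               "empty")
})

test_that("design validation enforces proportions and known taxa", {
  db <- tiny_refdb()
  expect_error(mixture_design("S", data.frame(taxon_id = "tax_a",
                                              mass_proportion = 0.9), db),
               "sum to 1")
  expect_error(mixture_design("S", data.frame(taxon_id = "nobody",
                                              mass_proportion = 1), db),
               "nobody")
})

test_that("simulated read share follows mass x copy weight", {
  # one taxon, ITS2 copy weight 100 vs matK weight 1: read-count ratio
  # approximately 100:1 within 3 binomial SDs
  set.seed(5)
  ps <- default_primer_set()
  mk <- function(locus, w) {
    p <- ps[ps$locus == locus, ]
    bc <- rand_dna(300)
    data.frame(taxon_id = "solo", locus = locus, copy_weight = w,
               barcode_seq = bc,
               context_seq = paste0(rand_dna(210), p$fwd, bc,
                                    rc_chr(p$rev), rand_dna(210)),
               stringsAsFactors = FALSE)
  }
  taxa <- data.frame(taxon_id = "solo", role = "labeled_ingredient",
                     kingdom_class = "plant", kingdom = "Viridiplantae",
                     phylum = "Streptophyta", class = "Magnoliopsida",
                     order = "Apiales", family = "Araliaceae",
                     genus = "Panax", species = "Panax solo",
                     stringsAsFactors = FALSE)
  db <- shotgunmb:::new_reference_db(taxa, rbind(mk("ITS2", 100),
                                                 mk("matK", 1)))
  db$barcodes$copy_weight <- c(100, 1)
  d <- mixture_design("S", data.frame(taxon_id = "solo",
                                      mass_proportion = 1), db,
                      contaminant_fraction = 0, background_fraction = 0)
  cfg <- simulation_config(n_read_pairs = 100000, seed = 9)
  sim <- simulate_sample(d, cfg, db)
  n_its2 <- sum(sim$truth$origin == "ITS2")
  n_matk <- sum(sim$truth$origin == "matK")
  p <- 1 / 101
  expect_equal(n_its2 + n_matk, 100000)
  sd3 <- 3 * sqrt(100000 * p * (1 - p))
  expect_lt(abs(n_matk - 100000 * p), sd3)
})

test_that("zero-proportion taxa emit no reads and bad configs error", {
  db <- tiny_refdb()
  d <- mixture_design("S", data.frame(
    taxon_id = c("tax_a", "tax_b"), mass_proportion = c(1, 0)), db,
    contaminant_fraction = 0, background_fraction = 0)
  cfg <- simulation_config(n_read_pairs = 2000, seed = 1)
  sim <- simulate_sample(d, cfg, db)
  expect_equal(sum(sim$truth$taxon_id == "tax_b"), 0)
  expect_error(simulate_sample(d, simulation_config(n_read_pairs = 0), db),
               "positive")
  expect_error(simulation_config(insert_mean = 100, read_length = 150))
})

test_that("error-free reads are exact substrings of their origin", {
  db <- tiny_refdb()
  d <- mixture_design("S", data.frame(taxon_id = c("tax_a", "tax_b"),
                                      mass_proportion = c(0.5, 0.5)), db,
                      contaminant_fraction = 0, background_fraction = 0.2)
  cfg <- simulation_config(n_read_pairs = 300, substitution_rate = 0,
                           seed = 4)
  sim <- simulate_sample(d, cfg, db)
  src_seq <- c(setNames(db$barcodes$context_seq,
                        paste(db$barcodes$taxon_id, db$barcodes$locus)))
  for (i in seq_len(nrow(sim$truth))) {
    tr <- sim$truth[i, ]
    origin <- if (tr$origin == "genomic") NULL else
      src_seq[[paste(tr$taxon_id, tr$origin)]]
    if (is.null(origin)) next
    r1 <- sim$pairs$seq1[i]
    expect_true(grepl(r1, origin, fixed = TRUE) ||
                  grepl(rc_chr(r1), origin, fixed = TRUE))
    # and the truth coordinates delimit the fragment
    frag <- substr(origin, tr$start + 1, tr$end)
    if (tr$strand == "-") frag <- rc_chr(frag)
    expect_identical(substr(frag, 1, 150), r1)
  }
})

test_that("empirical error rate matches the configured mean within 10%", {
  db <- tiny_refdb()
  d <- mixture_design("S", data.frame(taxon_id = "tax_a",
                                      mass_proportion = 1), db,
                      contaminant_fraction = 0, background_fraction = 0)
  rate <- 0.005
  n <- 4000  # 4000 pairs x 300 nt = 1.2e6 simulated bases
  cfg <- simulation_config(n_read_pairs = n, substitution_rate = rate,
                           seed = 12)
  sim <- simulate_sample(d, cfg, db)
  ctx <- db$barcodes$context_seq[db$barcodes$taxon_id == "tax_a"]
  mism <- 0L
  total <- 0L
  for (i in seq_len(n)) {
    tr <- sim$truth[i, ]
    frag <- substr(ctx, tr$start + 1, tr$end)
    if (tr$strand == "-") frag <- rc_chr(frag)
    truth1 <- substr(frag, 1, 150)
    truth2 <- rc_chr(substr(frag, nchar(frag) - 149, nchar(frag)))
    for (pair in list(c(truth1, sim$pairs$seq1[i]),
                      c(truth2, sim$pairs$seq2[i]))) {
      a <- strsplit(pair[1], NULL)[[1]]
      b <- strsplit(pair[2], NULL)[[1]]
      mism <- mism + sum(a != b)
      total <- total + length(a)
    }
  }
  expect_gt(total, 1e6)
  expect_lt(abs(mism / total - rate), 0.1 * rate)
})

test_that("truth-table marginals match the design (chi-square GOF)", {
  db <- generate_reference_fixtures(42)
  d <- default_mock_design(db, "GOF")
  cfg <- simulation_config(n_read_pairs = 100000, seed = 21)
  sim <- simulate_sample(d, cfg, db)
  # expected probabilities recomputed from first principles
  comp <- d$components
  w <- list()
  for (i in seq_len(nrow(comp))) {
    t <- comp$taxon_id[i]
    b <- get_barcodes(db, taxon_id = t)
    for (j in seq_len(nrow(b))) {
      w[[paste(t, b$locus[j])]] <- comp$mass_proportion[i] * b$copy_weight[j]
    }
    for (o in db$organelles) {
      if (o$taxon_id == t) {
        w[[paste(t, paste0("organelle:", o$genome_kind))]] <-
          comp$mass_proportion[i] * 20
      }
    }
  }
  wv <- unlist(w)
  main_p <- (1 - d$contaminant_fraction - d$background_fraction) *
    wv / sum(wv)
  cont_p <- d$contaminant_fraction * d$contaminant_weights *
    100 / (100 * sum(d$contaminant_weights))
  names(cont_p) <- paste(names(d$contaminant_weights), "ITS2")
  probs <- c(main_p, cont_p, genomic = d$background_fraction)
  key <- ifelse(sim$truth$origin == "genomic", "genomic",
                paste(sim$truth$taxon_id, sim$truth$origin))
  obs <- table(factor(key, levels = names(probs)))
  gof <- suppressWarnings(chisq.test(obs, p = probs))
  expect_gt(gof$p.value, 0.001)
})

test_that("simulation is deterministic under a fixed seed", {
  db <- tiny_refdb()
  d <- mixture_design("S", data.frame(taxon_id = "tax_a",
                                      mass_proportion = 1), db,
                      contaminant_fraction = 0, background_fraction = 0.3)
  cfg <- simulation_config(n_read_pairs = 500, seed = 33)
  s1 <- simulate_sample(d, cfg, db)
  s2 <- simulate_sample(d, cfg, db)
  expect_identical(s1$pairs, s2$pairs)
  expect_identical(s1$truth, s2$truth)
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  f1 <- write_fastq_pair(s1, dir1, gzip = FALSE)
  f2 <- write_fastq_pair(s2, dir2, gzip = FALSE)
  expect_identical(readBin(f1[["r1"]], "raw", 1e7),
                   readBin(f2[["r1"]], "raw", 1e7))
  # FASTQ round-trips
  back <- read_fastq_pair(f1[["r1"]], f1[["r2"]])
  expect_identical(back$seq1, s1$pairs$seq1)
  expect_identical(back$qual2, s1$pairs$qual2)
})
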