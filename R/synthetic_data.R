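#' Simulation configuration
#'
#' Defaults emulate a PCR-free Illumina library: 150 nt paired reads,
#' 350 bp mean insert (SD 35, truncated at the read length), and a
#' substitution-only error model whose per-base rate ramps linearly to
#' twice the mean at the read 3' end.
#'
#' @param read_length read length (nt).
#' @param insert_mean,insert_sd Gaussian insert-size parameters (nt).
#' @param substitution_rate mean per-base substitution probability.
#' @param n_read_pairs number of read pairs to emit.
#' @param seed RNG seed; every random choice of the simulator derives from
#'   it.
#' @return a list of simulation parameters.
#' @export
simulation_config <- function(read_length = 150, insert_mean = 350,
                              insert_sd = 35, substitution_rate = 0.002,
                              n_read_pairs = 200000, seed = 42) {
  stopifnot(insert_mean >= read_length,
            substitution_rate >= 0, substitution_rate <= 0.1)
  list(read_length = as.integer(read_length),
       insert_mean = insert_mean, insert_sd = insert_sd,
       substitution_rate = substitution_rate,
       n_read_pairs = as.integer(n_read_pairs), seed = as.integer(seed))
}

#' Mixture design for a simulated sample
#'
#' @param sample_id sample identifier.
#' @param components data.frame with taxon_id and mass_proportion columns;
#'   proportions must sum to 1 (tolerance 1e-9) and every taxon must exist
#'   in the reference database.
#' @param refdb a `reference_db` used for validation.
#' @param contaminant_fraction read share drawn from contaminant fungi
#'   (taxa with role `"contaminant"`).
#' @param background_fraction read share drawn from a non-barcode genomic
#'   decoy sequence.
#' @param contaminant_weights optional named weights splitting the
#'   contaminant share between contaminant taxa; defaults to a 5:3:2:...
#'   dominance series over the database's contaminant taxa.
#' @return a `mixture_design` list.
#' @export
mixture_design <- function(sample_id, components, refdb,
                           contaminant_fraction = 0.02,
                           background_fraction = 0.3,
                           contaminant_weights = NULL) {
  stopifnot(is.data.frame(components),
            all(c("taxon_id", "mass_proportion") %in% names(components)))
  if (abs(sum(components$mass_proportion) - 1) > 1e-9) {
    stop("mass proportions must sum to 1")
  }
  unknown <- setdiff(components$taxon_id, refdb$taxa$taxon_id)
  if (length(unknown) > 0) {
    stop("taxa absent from the reference database: ",
         paste(unknown, collapse = ", "))
  }
  contam <- refdb$taxa$taxon_id[refdb$taxa$role == "contaminant"]
  if (is.null(contaminant_weights)) {
    if (length(contam) > 0) {
      w <- c(5, 3, rep(2, max(0, length(contam) - 2)))[seq_along(contam)]
      contaminant_weights <- setNames(w / sum(w), contam)
    } else {
      contaminant_weights <- numeric(0)
      contaminant_fraction <- 0
    }
  }
  structure(list(sample_id = sample_id, components = components,
                 contaminant_fraction = contaminant_fraction,
                 background_fraction = background_fraction,
                 contaminant_weights = contaminant_weights),
            class = "mixture_design")
}

#' Default ten-ingredient mock design
#'
#' Equal mass proportions across the labeled ingredients (eight plants, one
#' fungus, one animal), 2% contaminant-fungus reads and 30% genomic decoy
#' reads.
#'
#' @param refdb a `reference_db` from [generate_reference_fixtures()].
#' @param sample_id sample identifier.
#' @param ... passed to [mixture_design()].
#' @return a `mixture_design`.
#' @export
default_mock_design <- function(refdb, sample_id = "MOCK_A", ...) {
  lab <- refdb$taxa$taxon_id[refdb$taxa$role == "labeled_ingredient"]
  mixture_design(sample_id,
                 data.frame(taxon_id = lab,
                            mass_proportion = rep(1 / length(lab),
                                                  length(lab)),
                            stringsAsFactors = FALSE),
                 refdb, ...)
}

#' Pharmaceutical-style design with trace unlabeled plants
#'
#' The labeled ingredients in equal mass, plus unlabeled plant taxa whose
#' combined mass is `unlabeled_ratio` times the labeled-plant mass —
#' emulating the trace off-label plant material observed in commercial
#' products.
#'
#' @param refdb a `reference_db`.
#' @param sample_id sample identifier.
#' @param unlabeled_taxa taxon_ids of the unlabeled plants to spike.
#' @param unlabeled_ratio combined unlabeled mass as a fraction of the
#'   labeled-plant mass.
#' @param ... passed to [mixture_design()].
#' @return a `mixture_design`.
#' @export
default_pharma_design <- function(refdb, sample_id = "PHARM_A",
                                  unlabeled_taxa = c("zea_mays",
                                                     "cullen_corylifolium"),
                                  unlabeled_ratio = 0.0137, ...) {
  lab <- refdb$taxa$taxon_id[refdb$taxa$role == "labeled_ingredient"]
  kc <- setNames(refdb$taxa$kingdom_class, refdb$taxa$taxon_id)
  m <- rep(1, length(lab))
  plant_mass <- sum(m[kc[lab] == "plant"])
  u <- rep(unlabeled_ratio * plant_mass / length(unlabeled_taxa),
           length(unlabeled_taxa))
  comp <- data.frame(taxon_id = c(lab, unlabeled_taxa),
                     mass_proportion = c(m, u) / sum(c(m, u)),
                     stringsAsFactors = FALSE)
  mixture_design(sample_id, comp, refdb, ...)
}

#' Spike a positive-control taxon into a design
#'
#' Adds `taxon_id` at exactly the proportion of `reference_taxon_id` and
#' renormalises all proportions to 1 — the "same proportion as the fungal
#' ingredient" convention for monitoring pipeline sensitivity.
#'
#' @param design a `mixture_design`.
#' @param taxon_id control taxon to add (must not already be present).
#' @param reference_taxon_id existing taxon whose proportion is copied.
#' @param refdb a `reference_db` for validation.
#' @param sample_id identifier of the spiked sample.
#' @return a new `mixture_design`.
#' @export
spike_positive_control <- function(design, taxon_id, reference_taxon_id,
                                   refdb, sample_id = NULL) {
  comp <- design$components
  if (nrow(comp) == 0) stop("cannot spike into an empty design")
  if (taxon_id %in% comp$taxon_id) {
    stop("taxon already present in the design: ", taxon_id)
  }
  i <- match(reference_taxon_id, comp$taxon_id)
  if (is.na(i)) stop("reference taxon not in design: ", reference_taxon_id)
  comp <- rbind(comp, data.frame(taxon_id = taxon_id,
                                 mass_proportion = comp$mass_proportion[i],
                                 stringsAsFactors = FALSE))
  comp$mass_proportion <- comp$mass_proportion / sum(comp$mass_proportion)
  mixture_design(sample_id %||% paste0(design$sample_id, "_PC"), comp, refdb,
                 contaminant_fraction = design$contaminant_fraction,
                 background_fraction = design$background_fraction,
                 contaminant_weights = design$contaminant_weights)
}

# fixture construction -------------------------------------------------------

.fixture_barcode_len <- c("ITS2" = 230, "psbA-trnH" = 374, "matK" = 881,
                          "rbcL" = 702, "COI" = 658)
.fixture_copy_weight <- c("ITS2" = 100, "psbA-trnH" = 20, "matK" = 20,
                          "rbcL" = 20, "COI" = 20)
.organelle_copy_weight <- 20
.fixture_flank <- 220

#' Generate the reference fixtures
#'
#' Builds a reference database emulating a ten-ingredient herbal mixture:
#' eight labeled plants (four loci each), one labeled fungus (ITS2 only,
#' plus a toy mitochondrion with named gene features including COX1), one
#' labeled animal (COI only), one positive-control plant, four unlabeled
#' plants (two of them congeners of in-database species, differing at
#' controlled positions) and three contaminant fungi.  One labeled plant
#' carries a toy chloroplast with features including psbA and rpl2.
#' Barcode contexts embed the exact primer sites of
#' [default_primer_set()]; ITS2 contexts embed the conserved rDNA flanks
#' scored by [default_flank_profile()].  Deterministic given `seed`.
#'
#' @param seed RNG seed.
#' @param congener_divergence substitutions per barcode base separating
#'   congeneric species (at least 1 substitution).
#' @return a `reference_db`.
#' @export
generate_reference_fixtures <- function(seed = 42,
                                        congener_divergence = 0.025) {
  set.seed(seed)
  plant_loci <- c("ITS2", "psbA-trnH", "matK", "rbcL")
  spec <- list(
    list("ophiopogon_japonicus", "labeled_ingredient", "plant",
         "Viridiplantae;Streptophyta;Magnoliopsida;Asparagales;Asparagaceae;Ophiopogon;Ophiopogon japonicus", plant_loci),
    list("platycodon_grandiflorus", "labeled_ingredient", "plant",
         "Viridiplantae;Streptophyta;Magnoliopsida;Asterales;Campanulaceae;Platycodon;Platycodon grandiflorus", plant_loci),
    list("canarium_album", "labeled_ingredient", "plant",
         "Viridiplantae;Streptophyta;Magnoliopsida;Sapindales;Burseraceae;Canarium;Canarium album", plant_loci),
    list("scrophularia_ningpoensis", "labeled_ingredient", "plant",
         "Viridiplantae;Streptophyta;Magnoliopsida;Lamiales;Scrophulariaceae;Scrophularia;Scrophularia ningpoensis", plant_loci),
    list("fritillaria_thunbergii", "labeled_ingredient", "plant",
         "Viridiplantae;Streptophyta;Magnoliopsida;Liliales;Liliaceae;Fritillaria;Fritillaria thunbergii", plant_loci),
    list("trichosanthes_kirilowii", "labeled_ingredient", "plant",
         "Viridiplantae;Streptophyta;Magnoliopsida;Cucurbitales;Cucurbitaceae;Trichosanthes;Trichosanthes kirilowii", plant_loci),
    list("glycyrrhiza_uralensis", "labeled_ingredient", "plant",
         "Viridiplantae;Streptophyta;Magnoliopsida;Fabales;Fabaceae;Glycyrrhiza;Glycyrrhiza uralensis", plant_loci),
    list("terminalia_chebula", "labeled_ingredient", "plant",
         "Viridiplantae;Streptophyta;Magnoliopsida;Myrtales;Combretaceae;Terminalia;Terminalia chebula", plant_loci),
    list("wolfiporia_cocos", "labeled_ingredient", "fungus",
         "Fungi;Basidiomycota;Agaricomycetes;Polyporales;Polyporaceae;Wolfiporia;Wolfiporia cocos", "ITS2"),
    list("gallus_gallus", "labeled_ingredient", "animal",
         "Metazoa;Chordata;Aves;Galliformes;Phasianidae;Gallus;Gallus gallus", "COI"),
    list("panax_quinquefolius", "positive_control", "plant",
         "Viridiplantae;Streptophyta;Magnoliopsida;Apiales;Araliaceae;Panax;Panax quinquefolius", plant_loci),
    list("panax_ginseng", "unlabeled_plant", "plant",
         "Viridiplantae;Streptophyta;Magnoliopsida;Apiales;Araliaceae;Panax;Panax ginseng", plant_loci),
    list("scrophularia_buergeriana", "unlabeled_plant", "plant",
         "Viridiplantae;Streptophyta;Magnoliopsida;Lamiales;Scrophulariaceae;Scrophularia;Scrophularia buergeriana", plant_loci),
    list("zea_mays", "unlabeled_plant", "plant",
         "Viridiplantae;Streptophyta;Magnoliopsida;Poales;Poaceae;Zea;Zea mays", plant_loci),
    list("cullen_corylifolium", "unlabeled_plant", "plant",
         "Viridiplantae;Streptophyta;Magnoliopsida;Fabales;Fabaceae;Cullen;Cullen corylifolium", plant_loci),
    list("schwanniomyces_occidentalis", "contaminant", "fungus",
         "Fungi;Ascomycota;Saccharomycetes;Saccharomycetales;Debaryomycetaceae;Schwanniomyces;Schwanniomyces occidentalis", "ITS2"),
    list("diaporthe_eres", "contaminant", "fungus",
         "Fungi;Ascomycota;Sordariomycetes;Diaporthales;Diaporthaceae;Diaporthe;Diaporthe eres", "ITS2"),
    list("fusarium_oxysporum", "contaminant", "fungus",
         "Fungi;Ascomycota;Sordariomycetes;Hypocreales;Nectriaceae;Fusarium;Fusarium oxysporum", "ITS2")
  )
  taxa <- do.call(rbind, lapply(spec, function(s) {
    lin <- unclass(lineage(s[[4]]))
    cbind(data.frame(taxon_id = s[[1]], role = s[[2]], kingdom_class = s[[3]],
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(lin), stringsAsFactors = FALSE))
  }))

  # congeners share a genus-level backbone barcode, then diverge
  genus_of <- setNames(taxa$genus, taxa$taxon_id)
  genus_barcodes <- list()
  barcode_for <- function(taxon, locus) {
    g <- genus_of[[taxon]]
    len <- .fixture_barcode_len[[locus]]
    key <- paste(g, locus)
    if (is.null(genus_barcodes[[key]])) {
      genus_barcodes[[key]] <<- random_dna(1, len)
    }
    n_div <- max(1L, round(congener_divergence * len))
    diverge_seq(genus_barcodes[[key]], n_div)
  }
  ps <- default_primer_set()
  fl <- its2_flank_sequences()
  rows <- list()
  for (s in spec) {
    taxon <- s[[1]]
    for (locus in s[[5]]) {
      bc <- barcode_for(taxon, locus)
      # re-draw until congeners differ at >= 1 position (controlled, rare)
      while (any(vapply(rows, function(r) {
        r$locus == locus && r$barcode_seq == bc
      }, logical(1)))) {
        bc <- barcode_for(taxon, locus)
      }
      ctx <- if (locus == "ITS2") {
        paste0(random_dna(1, .fixture_flank), fl$five8S_tail, bc,
               fl$two8S_head, random_dna(1, .fixture_flank))
      } else {
        p <- ps[ps$locus == locus, ]
        paste0(random_dna(1, .fixture_flank), p$fwd, bc, revcomp(p$rev),
               random_dna(1, .fixture_flank))
      }
      rows[[length(rows) + 1]] <- data.frame(
        taxon_id = taxon, locus = locus,
        copy_weight = .fixture_copy_weight[[locus]],
        barcode_seq = bc, context_seq = ctx, stringsAsFactors = FALSE)
    }
  }
  barcodes <- do.call(rbind, rows)

  toy_genome <- function(genes) {
    # genes: named vector of gene lengths; intergenic spacers fill the gaps
    feats <- list()
    seqs <- character(0)
    pos <- 0L
    gnames <- names(genes)
    for (i in seq_along(genes)) {
      spacer <- 250L
      seqs <- c(seqs, random_dna(1, spacer))
      if (i > 1) {
        feats[[length(feats) + 1]] <- data.frame(
          name = paste0(gnames[i - 1], "-", gnames[i]), start = pos,
          end = pos + spacer, kind = "intergenic", stringsAsFactors = FALSE)
      }
      pos <- pos + spacer
      seqs <- c(seqs, random_dna(1, genes[i]))
      feats[[length(feats) + 1]] <- data.frame(
        name = gnames[i], start = pos, end = pos + genes[i], kind = "gene",
        stringsAsFactors = FALSE)
      pos <- pos + genes[i]
    }
    list(seq = paste(seqs, collapse = ""), features = do.call(rbind, feats))
  }
  mito <- toy_genome(c(nad1 = 600L, orf5 = 400L, nad2 = 700L, COX1 = 900L,
                       atp8 = 300L, orf30 = 350L))
  chlo <- toy_genome(c(psbA = 1062L, ndhK = 800L, ndhB = 1500L, ycf2 = 2000L,
                       rpl2 = 900L))
  organelles <- list(
    "wolfiporia_cocos|mitochondrion" = organelle_reference(
      "wolfiporia_cocos", "mitochondrion", mito$seq, mito$features),
    "terminalia_chebula|chloroplast" = organelle_reference(
      "terminalia_chebula", "chloroplast", chlo$seq, chlo$features))
  new_reference_db(taxa, barcodes, organelles)
}

# simulation ------------------------------------------------------------------

# expand a design into the weighted source table the sampler draws from
simulation_sources <- function(design, refdb, decoy_len = 50000L) {
  comp <- design$components
  rows <- list()
  for (i in seq_len(nrow(comp))) {
    t <- comp$taxon_id[i]
    mass <- comp$mass_proportion[i]
    b <- get_barcodes(refdb, taxon_id = t)
    for (j in seq_len(nrow(b))) {
      rows[[length(rows) + 1]] <- data.frame(
        taxon_id = t, origin = b$locus[j], seq = b$context_seq[j],
        weight = mass * b$copy_weight[j], category = "component",
        stringsAsFactors = FALSE)
    }
    for (o in refdb$organelles) {
      if (o$taxon_id == t) {
        rows[[length(rows) + 1]] <- data.frame(
          taxon_id = t, origin = paste0("organelle:", o$genome_kind),
          seq = o$seq, weight = mass * .organelle_copy_weight,
          category = "component", stringsAsFactors = FALSE)
      }
    }
  }
  for (t in names(design$contaminant_weights)) {
    b <- get_barcodes(refdb, taxon_id = t)
    for (j in seq_len(nrow(b))) {
      rows[[length(rows) + 1]] <- data.frame(
        taxon_id = t, origin = b$locus[j], seq = b$context_seq[j],
        weight = design$contaminant_weights[[t]] * b$copy_weight[j],
        category = "contaminant", stringsAsFactors = FALSE)
    }
  }
  src <- do.call(rbind, rows)
  cf <- design$contaminant_fraction
  bf <- design$background_fraction
  is_comp <- src$category == "component"
  p <- numeric(nrow(src))
  wsum <- sum(src$weight[is_comp])
  p[is_comp] <- (1 - cf - bf) * src$weight[is_comp] / wsum
  if (any(!is_comp)) {
    p[!is_comp] <- cf * src$weight[!is_comp] / sum(src$weight[!is_comp])
  }
  decoy <- data.frame(taxon_id = NA_character_, origin = "genomic",
                      seq = random_dna(1, decoy_len), weight = bf,
                      category = "background", stringsAsFactors = FALSE)
  src <- rbind(src, decoy)
  src$prob <- c(p, bf)
  src
}

# Phred+33 quality string matching the ramped error model
quality_string <- function(read_length, rate) {
  if (rate <= 0) {
    q <- rep(40L, read_length)
  } else {
    i <- seq_len(read_length) - 1
    p <- rate * (2 / 3) * (1 + i / max(1, read_length - 1))
    q <- pmin(40L, pmax(2L, as.integer(round(-10 * log10(p)))))
  }
  intToUtf8(q + 33L)
}

#' Simulate paired-end shotgun sequencing of a mixture
#'
#' Draws read pairs from the design's barcode contexts, organelle genomes,
#' contaminant contexts and a genomic decoy, with expected read share of a
#' (taxon, source) proportional to mass proportion times copy weight.
#' Fragments get Gaussian insert sizes (truncated at the read length),
#' random strand, a ramped substitution error model and Phred+33 qualities
#' consistent with it.  A truth table records the origin of every pair.
#'
#' @param design a `mixture_design`.
#' @param config a [simulation_config()].
#' @param refdb a `reference_db`.
#' @return list with `sample_id`, `pairs` (pair_id, seq1, qual1, seq2,
#'   qual2), `truth` (pair_id, taxon_id, origin, start, end, strand;
#'   0-based half-open coordinates on the origin sequence), `design`,
#'   `config`.
#' @export
simulate_sample <- function(design, config, refdb) {
  if (config$n_read_pairs <= 0) stop("n_read_pairs must be positive")
  # scramble the seed so the simulator's RNG stream is unrelated to that of
  # a reference database generated from the same nominal seed (overlapping
  # Mersenne-Twister streams would leak reference subsequences into the
  # decoy background)
  set.seed((config$seed * 69069 + 12345) %% 2147483647L)
  src <- simulation_sources(design, refdb)
  n <- config$n_read_pairs
  rl <- config$read_length
  counts <- as.vector(rmultinom(1, n, src$prob))
  seq1 <- character(n); seq2 <- character(n)
  taxon <- character(n); origin <- character(n)
  fstart <- integer(n); fend <- integer(n); strand <- character(n)
  at <- 0L
  for (i in seq_len(nrow(src))) {
    k <- counts[i]
    if (k == 0) next
    slen <- nchar(src$seq[i])
    ins <- as.integer(round(rnorm(k, config$insert_mean, config$insert_sd)))
    ins <- pmax(rl, pmin(ins, slen))
    pos <- 1L + as.integer(floor(runif(k) * (slen - ins + 1)))
    frag <- substring(src$seq[i], pos, pos + ins - 1L)
    minus <- runif(k) < 0.5
    frag[minus] <- revcomp(frag[minus])
    r1 <- substr(frag, 1L, rl)
    r2 <- revcomp(substring(frag, ins - rl + 1L, ins))
    idx <- (at + 1L):(at + k)
    seq1[idx] <- r1; seq2[idx] <- r2
    taxon[idx] <- src$taxon_id[i]; origin[idx] <- src$origin[i]
    fstart[idx] <- pos - 1L; fend[idx] <- pos + ins - 1L
    strand[idx] <- ifelse(minus, "-", "+")
    at <- at + k
  }
  perm <- sample.int(n)
  seq1 <- seq1[perm]; seq2 <- seq2[perm]
  taxon <- taxon[perm]; origin <- origin[perm]
  fstart <- fstart[perm]; fend <- fend[perm]; strand <- strand[perm]
  if (config$substitution_rate > 0) {
    seq1 <- mutate_reads_cpp(seq1, config$substitution_rate)
    seq2 <- mutate_reads_cpp(seq2, config$substitution_rate)
  }
  qual <- quality_string(rl, config$substitution_rate)
  pair_id <- sprintf("%s_%07d", design$sample_id, seq_len(n))
  list(sample_id = design$sample_id,
       pairs = data.frame(pair_id = pair_id, seq1 = seq1,
                          qual1 = rep(qual, n), seq2 = seq2,
                          qual2 = rep(qual, n), stringsAsFactors = FALSE),
       truth = data.frame(pair_id = pair_id, taxon_id = taxon,
                          origin = origin, start = fstart, end = fend,
                          strand = strand, stringsAsFactors = FALSE),
       design = design, config = config)
}

#' Write a simulated sample to FASTQ (and its truth table to TSV)
#'
#' @param sim a [simulate_sample()] result.
#' @param dir output directory.
#' @param gzip write gzipped FASTQ.
#' @return invisibly, the paths written (r1, r2, truth).
#' @export
write_fastq_pair <- function(sim, dir, gzip = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (gzip) ".fastq.gz" else ".fastq"
  p1 <- file.path(dir, paste0(sim$sample_id, "_R1", ext))
  p2 <- file.path(dir, paste0(sim$sample_id, "_R2", ext))
  pt <- file.path(dir, paste0(sim$sample_id, "_truth.tsv"))
  wr <- function(path, ids, seqs, quals) {
    con <- if (gzip) gzfile(path, "wb") else file(path, "wb")
    on.exit(close(con))
    writeLines(paste0("@", ids, "\n", seqs, "\n+\n", quals), con)
  }
  wr(p1, sim$pairs$pair_id, sim$pairs$seq1, sim$pairs$qual1)
  wr(p2, sim$pairs$pair_id, sim$pairs$seq2, sim$pairs$qual2)
  write.table(sim$truth, pt, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(r1 = p1, r2 = p2, truth = pt))
}

#' Read a FASTQ pair into a read-pair table
#'
#' @param r1_path,r2_path FASTQ paths (gzip-aware).
#' @return read-pair data.frame (pair_id, seq1, qual1, seq2, qual2).
#' @export
read_fastq_pair <- function(r1_path, r2_path) {
  rd <- function(path) {
    s <- Biostrings::readDNAStringSet(path, format = "fastq",
                                      with.qualities = TRUE)
    list(id = sub("\\s.*$", "", names(s)), seq = as.character(s),
         qual = as.character(S4Vectors::mcols(s)$qualities))
  }
  a <- rd(r1_path)
  b <- rd(r2_path)
  stopifnot(identical(a$id, b$id))
  data.frame(pair_id = a$id, seq1 = a$seq, qual1 = a$qual, seq2 = b$seq,
             qual2 = b$qual, stringsAsFactors = FALSE)
}
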