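#' Default pipeline parameters
#'
#' Every tunable of the pipeline in one place, so runs can log them all in
#' the provenance record (the OTU reliability thresholds and the LCA
#' top-percent window are deliberately surfaced — they are the most
#' consequential parameters with no community-standard value).
#'
#' @param ... overrides of the defaults.
#' @return named list of parameters.
#' @export
pipeline_params <- function(...) {
  p <- list(
    trim = trim_params(),
    enrich_k = 31L, enrich_min_hits = 3L,
    assembly_k = c(21L, 31L), min_kmer_count = 2L, bubble_frac = 0.1,
    primer_max_mismatch = 3L, bimera_check = TRUE,
    map_k_seed = 15L, map_min_identity = 0.95,
    min_coverage = 0.8, min_depth = 5.0,
    top_percent = 1.0, min_identity = 0.90, species_identity = 0.99,
    organelle_min_regions = 2L, organelle_min_region_coverage = 0.5
  )
  dots <- list(...)
  p[names(dots)] <- dots
  p
}

#' Process one sample end to end
#'
#' Runs trimming, locus enrichment, dual-k assembly, barcode extraction,
#' OTU clustering with depth/coverage validation, taxonomic assignment and
#' the organelle fallback on an in-memory read-pair table.
#'
#' @param pairs read-pair data.frame (pair_id, seq1, qual1, seq2, qual2).
#' @param refdb a `reference_db`.
#' @param params a [pipeline_params()] list.
#' @return list with the per-stage outputs: `trim_stats`, `tally`,
#'   `contigs`, `candidates`, `otus`, `pileups`, `read_counts`,
#'   `assignments`, `organelle`, `summary`.
#' @export
process_sample <- function(pairs, refdb, params = pipeline_params()) {
  tr <- trim_read_pairs(pairs, params$trim)
  index <- build_locus_index(refdb, k = params$enrich_k)
  enr <- enrich_reads(tr$pairs, index, min_hits = params$enrich_min_hits)
  contigs <- list()
  for (locus in names(enr$bins)) {
    bin <- enr$bins[[locus]]
    reads <- c(bin$seq1, bin$seq2)
    contigs[[locus]] <- assemble_dual_k(
      reads, k_values = params$assembly_k, locus = locus,
      min_kmer_count = params$min_kmer_count,
      bubble_frac = params$bubble_frac)
  }
  contigs <- do.call(rbind, contigs)
  rownames(contigs) <- NULL
  candidates <- extract_barcodes(contigs, refdb,
                                 max_mismatch = params$primer_max_mismatch,
                                 bimera_check = params$bimera_check)
  otus <- do.call(rbind, lapply(split(candidates, candidates$locus),
                                cluster_otus))
  if (is.null(otus)) otus <- cluster_otus(candidates)
  rownames(otus) <- NULL
  all_reads <- c(tr$pairs$seq1, tr$pairs$seq2)
  mp <- map_reads_to_otus(all_reads, otus, k_seed = params$map_k_seed,
                          min_identity = params$map_min_identity)
  otus <- filter_otus(mp$otus, min_coverage = params$min_coverage,
                      min_depth = params$min_depth)
  assignments <- assign_otus(otus, refdb,
                             top_percent = params$top_percent,
                             min_identity = params$min_identity,
                             species_identity = params$species_identity)
  org <- organelle_scan(
    all_reads, refdb, k_seed = params$map_k_seed,
    min_identity = params$map_min_identity,
    min_regions = params$organelle_min_regions,
    min_region_coverage = params$organelle_min_region_coverage)
  list(trim_stats = tr[c("n_in", "n_out", "bases_removed")],
       tally = enr$tally, contigs = contigs, candidates = candidates,
       otus = otus, pileups = mp$pileups, read_counts = mp$read_counts,
       assignments = assignments, organelle = org,
       summary = summarize_run(contigs, candidates, otus))
}

#' Per-locus run summary
#'
#' The run-level statistics table: per locus, the number of unique contigs,
#' barcodes surviving annotation and the chimera screen, validated OTUs,
#' average validated-OTU length and GC content (one decimal each; NA when
#' a locus has no validated OTU).
#'
#' @param contigs contig data.frame.
#' @param candidates barcode-candidate data.frame.
#' @param otus OTU data.frame with `validated` filled.
#' @return summary data.frame, one row per locus.
#' @export
summarize_run <- function(contigs, candidates, otus) {
  rows <- lapply(.barcode_loci, function(l) {
    v <- otus[otus$locus == l & otus$validated %in% TRUE, , drop = FALSE]
    data.frame(
      locus = l,
      n_unique_contigs = sum(contigs$locus == l),
      n_barcodes = sum(candidates$locus == l),
      n_otus = nrow(v),
      mean_otu_length = if (nrow(v) > 0)
        round(mean(nchar(v$rep_seq)), 1) else NA_real_,
      gc_percent = if (nrow(v) > 0)
        round(100 * mean(gc_content(v$rep_seq)), 1) else NA_real_,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Assemble a run configuration
#'
#' @param refdb_dir directory holding a serialized reference database
#'   (see [write_reference_db()]).
#' @param manifest data.frame with sample_id, r1, r2 (FASTQ paths).
#' @param outdir output directory.
#' @param seed seed recorded in provenance.
#' @param params a [pipeline_params()] list.
#' @return a `run_config` list.
#' @export
run_config <- function(refdb_dir, manifest, outdir, seed = 42,
                       params = pipeline_params()) {
  structure(list(refdb_dir = refdb_dir, manifest = manifest,
                 outdir = outdir, seed = seed, params = params),
            class = "run_config")
}

validate_run_config <- function(config) {
  stopifnot(inherits(config, "run_config"))
  need <- c(file.path(config$refdb_dir, "barcodes.fasta"),
            file.path(config$refdb_dir, "lineages.tsv"),
            config$manifest$r1, config$manifest$r2)
  missing <- need[!file.exists(need)]
  if (length(missing) > 0) {
    stop("missing input file(s): ", paste(missing, collapse = ", "))
  }
  invisible(TRUE)
}

write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the pipeline over a sample manifest
#'
#' Validates the configuration before any stage runs, processes every
#' sample, and writes per-sample TSV/FASTA outputs, the detection matrix
#' over all samples, and a JSON provenance record (parameters, seed,
#' per-stage counts).  Outputs are deterministic given identical
#' configuration and input files.
#'
#' @param config a [run_config()].
#' @return invisibly, the per-sample results plus the detection matrix.
#' @export
run_pipeline <- function(config) {
  validate_run_config(config)
  ofa <- file.path(config$refdb_dir, "organelles.fasta")
  refdb <- load_reference_db(
    file.path(config$refdb_dir, "barcodes.fasta"),
    file.path(config$refdb_dir, "lineages.tsv"),
    organelle_fasta_path = if (file.exists(ofa)) ofa else NULL,
    organelle_feature_path = file.path(config$refdb_dir,
                                       "organelle_features.tsv"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  results <- list()
  provenance <- list(seed = config$seed, params = config$params,
                     samples = list())
  for (i in seq_len(nrow(config$manifest))) {
    sid <- config$manifest$sample_id[i]
    pairs <- read_fastq_pair(config$manifest$r1[i], config$manifest$r2[i])
    res <- tryCatch(
      process_sample(pairs, refdb, config$params),
      error = function(e) {
        stop("stage failure in sample ", sid, ": ", conditionMessage(e))
      })
    sdir <- file.path(config$outdir, sid)
    dir.create(sdir, showWarnings = FALSE, recursive = TRUE)
    write_tsv(res$tally, file.path(sdir, "locus_tally.tsv"))
    write_tsv(res$summary, file.path(sdir, "run_summary.tsv"))
    write_tsv(res$assignments, file.path(sdir, "assignments.tsv"))
    ot <- res$otus
    ot$length <- nchar(ot$rep_seq)
    ot$gc_percent <- round(100 * gc_content(ot$rep_seq), 1)
    write_tsv(ot[, c("otu_id", "locus", "length", "gc_percent",
                     "member_count", "mean_depth", "coverage", "partial",
                     "validated")],
              file.path(sdir, "otu_table.tsv"))
    if (nrow(res$otus) > 0) {
      reps <- Biostrings::DNAStringSet(res$otus$rep_seq)
      names(reps) <- res$otus$otu_id
      Biostrings::writeXStringSet(reps, file.path(sdir, "otu_reps.fasta"),
                                  width = 80)
    }
    if (nrow(res$contigs) > 0) {
      ctg <- Biostrings::DNAStringSet(res$contigs$seq)
      names(ctg) <- paste(res$contigs$contig_id, res$contigs$locus,
                          res$contigs$k_used,
                          round(res$contigs$mean_kmer_coverage, 1),
                          sep = "|")
      Biostrings::writeXStringSet(ctg, file.path(sdir, "contigs.fasta"),
                                  width = 80)
    }
    org <- do.call(rbind, lapply(res$organelle, function(o) {
      cbind(o$regions,
            data.frame(genome_kind = o$genome_kind,
                       detected = o$call$detected, rule = o$call$rule,
                       stringsAsFactors = FALSE))
    }))
    if (!is.null(org)) {
      write_tsv(org, file.path(sdir, "organelle_regions.tsv"))
    }
    provenance$samples[[sid]] <- list(
      pairs_in = res$trim_stats$n_in, pairs_trimmed = res$trim_stats$n_out,
      pairs_dropped = res$trim_stats$n_in - res$trim_stats$n_out,
      enriched = sum(res$tally$n_pairs), contigs = nrow(res$contigs),
      candidates = nrow(res$candidates), otus = nrow(res$otus),
      validated_otus = sum(res$otus$validated))
    results[[sid]] <- res
  }
  label_taxa <- refdb$taxa$taxon_id[refdb$taxa$role %in%
                                      c("labeled_ingredient",
                                        "positive_control")]
  sample_taxa <- lapply(results, function(r) label_taxa)
  if (!is.null(config$manifest$design_taxa)) {
    sample_taxa <- setNames(config$manifest$design_taxa,
                            config$manifest$sample_id)
  }
  detmat <- build_detection_matrix(
    lapply(results, function(r) r$assignments), sample_taxa, label_taxa,
    refdb)
  write_tsv(detmat, file.path(config$outdir, "detection_matrix.tsv"))
  write_tsv(format_detection_matrix(detmat),
            file.path(config$outdir, "detection_matrix_symbols.tsv"))
  jsonlite::write_json(provenance,
                       file.path(config$outdir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(samples = results, detection_matrix = detmat,
                 refdb = refdb))
}
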