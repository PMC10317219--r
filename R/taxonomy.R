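#' Align an OTU representative against same-locus references
#'
#' Overlap (end-gap-free) alignment of the representative against every
#' reference of the same locus, scored match +1, mismatch -1, gap open -2,
#' gap extend -1.  Both orientations of the representative are tried and
#' the better one kept.  `base_differences` counts mismatch plus gap
#' columns inside the aligned overlap; `identity` is
#' `1 - base_differences / aligned_span`.
#'
#' @param otu one-row OTU data.frame (or list with `otu_id`, `rep_seq`,
#'   `locus`).
#' @param refdb a `reference_db`.
#' @param min_span_frac hits whose aligned overlap covers less than this
#'   fraction of the representative are dropped — a short perfect overlap
#'   between sequence ends carries no taxonomic signal.
#' @return data.frame of hits sorted by identity (otu_id, taxon_id,
#'   identity, base_differences, aligned_span, score); zero rows when the
#'   locus has no references.
#' @export
align_otu <- function(otu, refdb, min_span_frac = 0.5) {
  refs <- get_barcodes(refdb, locus = otu$locus)
  if (nrow(refs) == 0) {
    return(data.frame(otu_id = character(0), taxon_id = character(0),
                      identity = numeric(0), base_differences = integer(0),
                      aligned_span = integer(0), score = numeric(0),
                      stringsAsFactors = FALSE))
  }
  rep_f <- otu$rep_seq
  rep_r <- revcomp(rep_f)
  rows <- lapply(seq_len(nrow(refs)), function(i) {
    af <- overlap_align_cpp(rep_f, refs$barcode_seq[i], 1, -1, -2, -1)
    ar <- overlap_align_cpp(rep_r, refs$barcode_seq[i], 1, -1, -2, -1)
    a <- if (ar[["score"]] > af[["score"]]) ar else af
    span <- a[["aligned_span"]]
    data.frame(otu_id = otu$otu_id, taxon_id = refs$taxon_id[i],
               identity = if (span > 0) 1 - a[["base_differences"]] / span else 0,
               base_differences = as.integer(a[["base_differences"]]),
               aligned_span = as.integer(span), score = a[["score"]],
               stringsAsFactors = FALSE)
  })
  hits <- do.call(rbind, rows)
  hits <- hits[hits$aligned_span >= min_span_frac * nchar(rep_f), ,
               drop = FALSE]
  hits <- hits[order(-hits$identity, -hits$aligned_span, hits$taxon_id), ,
               drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Assign a taxon to an OTU by top-percent LCA
#'
#' Hits below `min_identity` are discarded; of the rest, hits within
#' `top_percent` percentage points of the best identity are kept and the
#' assignment is the lowest common ancestor of their lineages.  A
#' species-rank result is demoted to genus when the best identity is below
#' `species_identity`, which keeps near-identical congeners (e.g.
#' Scrophularia ningpoensis vs S. buergeriana) from being overcalled.
#'
#' @param hits hit data.frame from [align_otu()], sorted by identity.
#' @param refdb a `reference_db` (for lineages).
#' @param top_percent identity window (percentage points) below the best.
#' @param min_identity minimum identity for a hit to be used.
#' @param species_identity identity needed for a species-rank call.
#' @return data.frame: otu_id, rank, taxon, best_identity, n_hits_used.
#' @export
assign_taxon <- function(hits, refdb, top_percent = 1.0, min_identity = 0.90,
                         species_identity = 0.99) {
  otu_id <- if (nrow(hits) > 0) hits$otu_id[1] else NA_character_
  hits <- hits[hits$identity >= min_identity, , drop = FALSE]
  if (nrow(hits) == 0) {
    return(data.frame(otu_id = otu_id, rank = "unassigned",
                      taxon = NA_character_, best_identity = NA_real_,
                      n_hits_used = 0L, stringsAsFactors = FALSE))
  }
  best <- max(hits$identity)
  kept <- hits[hits$identity >= best - top_percent / 100, , drop = FALSE]
  res <- lca(lapply(kept$taxon_id, function(t) get_lineage(refdb, t)))
  if (res$rank == "species" && best < species_identity) {
    lin <- get_lineage(refdb, kept$taxon_id[1])
    res <- list(rank = "genus", taxon = unclass(lin)[["genus"]])
  }
  data.frame(otu_id = otu_id, rank = res$rank, taxon = res$taxon,
             best_identity = best, n_hits_used = nrow(kept),
             stringsAsFactors = FALSE)
}

#' Assign taxa to a table of OTUs
#'
#' @param otus OTU data.frame.
#' @param refdb a `reference_db`.
#' @param ... passed to [assign_taxon()].
#' @return assignment data.frame with one row per OTU, carrying locus,
#'   validated and partial flags alongside the taxon call.
#' @export
assign_otus <- function(otus, refdb, ...) {
  rows <- lapply(seq_len(nrow(otus)), function(i) {
    a <- assign_taxon(align_otu(otus[i, ], refdb), refdb, ...)
    a$otu_id <- otus$otu_id[i]
    cbind(a, otus[i, c("locus", "member_count", "partial", "mean_depth",
                       "coverage", "validated")])
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(otu_id = character(0), rank = character(0),
                      taxon = character(0), best_identity = numeric(0),
                      n_hits_used = integer(0), locus = character(0),
                      member_count = integer(0), partial = logical(0),
                      mean_depth = numeric(0), coverage = numeric(0),
                      validated = logical(0), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Build the per-sample detection matrix
#'
#' A (sample, taxon, locus) cell is `detected` when some validated,
#' non-partial OTU of that locus in that sample is assigned at species rank
#' to that taxon — or at genus rank when the taxon is the only member of
#' its genus in the database.  Cells are `locus_absent` where the database
#' lacks that (taxon, locus) — a fungus has no plastid loci, the animal
#' ingredient carries only COI — and `not_in_sample` for taxa outside the
#' sample's design.
#'
#' @param assignments named list (by sample id) of [assign_otus()] tables.
#' @param samples named list (by sample id) of taxon_id vectors present in
#'   each sample's design.
#' @param label_taxa taxon_ids to report rows for.
#' @param refdb a `reference_db`.
#' @return long data.frame: sample, taxon_id, species, locus, status.
#' @export
build_detection_matrix <- function(assignments, samples, label_taxa, refdb) {
  loci <- .barcode_loci
  taxa <- refdb$taxa
  genus_count <- table(taxa$genus)
  rows <- list()
  for (s in names(assignments)) {
    asn <- assignments[[s]]
    ok <- asn[asn$validated & !asn$partial, , drop = FALSE]
    for (t in label_taxa) {
      lin <- unclass(get_lineage(refdb, t))
      sp <- lin[["species"]]
      gen <- lin[["genus"]]
      has_locus <- get_barcodes(refdb, taxon_id = t)$locus
      for (l in loci) {
        status <- if (!(l %in% has_locus)) {
          "locus_absent"
        } else if (!(t %in% samples[[s]])) {
          "not_in_sample"
        } else {
          hit <- any(ok$locus == l & ok$rank == "species" & ok$taxon == sp) ||
            (genus_count[[gen]] == 1 &&
               any(ok$locus == l & ok$rank == "genus" & ok$taxon == gen))
          if (hit) "detected" else "not_detected"
        }
        rows[[length(rows) + 1]] <- data.frame(
          sample = s, taxon_id = t, species = sp, locus = l,
          status = status, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Render a detection matrix with the conventional symbols
#'
#' Wide per-sample table using the field's symbols: a check mark for
#' detected, a dash for not detected, and `/` where the locus is absent
#' from the taxon or the taxon was not added to the sample.
#'
#' @param detmat long detection matrix from [build_detection_matrix()].
#' @return data.frame, one row per (species, sample), one column per locus.
#' @export
format_detection_matrix <- function(detmat) {
  sym <- c(detected = "√", not_detected = "-", locus_absent = "/",
           not_in_sample = "/")
  detmat$symbol <- sym[detmat$status]
  wide <- stats::reshape(
    detmat[, c("sample", "species", "locus", "symbol")],
    idvar = c("sample", "species"), timevar = "locus", direction = "wide")
  names(wide) <- sub("^symbol\\.", "", names(wide))
  rownames(wide) <- NULL
  wide
}

#' Fungal community table and labeled/unlabeled read ratio
#'
#' Summarises, from OTU assignments and per-OTU mapped-read counts, the
#' fungal community at genus level (read count and percentage of
#' fungal-community reads) and the ratio of reads assigned to unlabeled
#' plant taxa to reads assigned to labeled plant ingredients, in percent.
#'
#' @param assignments an [assign_otus()] table (validated and partial OTUs
#'   both contribute reads, as mapping counts are per-OTU).
#' @param read_counts named vector of mapped-read counts per otu_id.
#' @param refdb a `reference_db`.
#' @return list with `fungal` (genus, reads, pct) and `unlabeled_ratio`
#'   (percent, `NA` when no labeled plant reads exist).
#' @export
community_report <- function(assignments, read_counts, refdb) {
  asn <- assignments[!is.na(assignments$taxon), , drop = FALSE]
  asn$reads <- as.numeric(read_counts[asn$otu_id])
  asn$reads[is.na(asn$reads)] <- 0
  info <- refdb$taxa
  # genus-level kingdom lookup (assignments may be at genus rank)
  genus_kingdom <- setNames(info$kingdom, info$genus)
  species_genus <- setNames(info$genus, info$species)
  asn$genus <- ifelse(asn$rank == "genus", asn$taxon,
                      ifelse(asn$rank == "species",
                             species_genus[asn$taxon], NA))
  asn$kingdom <- genus_kingdom[asn$genus]
  fungal <- asn[!is.na(asn$kingdom) & asn$kingdom == "Fungi", , drop = FALSE]
  if (nrow(fungal) == 0) {
    ftab <- data.frame(genus = character(0), reads = numeric(0),
                       pct = numeric(0), stringsAsFactors = FALSE)
  } else {
    agg <- stats::aggregate(reads ~ genus, data = fungal, FUN = sum)
    agg$pct <- 100 * agg$reads / sum(agg$reads)
    ftab <- agg[order(-agg$reads), , drop = FALSE]
    rownames(ftab) <- NULL
  }
  role <- setNames(info$role, info$species)
  kclass <- setNames(info$kingdom_class, info$species)
  sp <- asn[asn$rank == "species", , drop = FALSE]
  labeled <- sum(sp$reads[kclass[sp$taxon] == "plant" &
                            role[sp$taxon] %in% c("labeled_ingredient",
                                                  "positive_control")],
                 na.rm = TRUE)
  unlabeled <- sum(sp$reads[kclass[sp$taxon] == "plant" &
                              role[sp$taxon] == "unlabeled_plant"],
                   na.rm = TRUE)
  ratio <- if (labeled > 0) 100 * unlabeled / labeled else NA_real_
  list(fungal = ftab, unlabeled_ratio = ratio)
}
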