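#' Construct a seven-rank lineage
#'
#' Lineages use a fixed rank schema (kingdom, phylum, class, order, family,
#' genus, species).  They may be given as a single `;`-separated string or
#' as seven taxon names.
#'
#' @param x a `;`-separated lineage string, or a character vector of seven
#'   taxon names ordered from kingdom to species.
#' @return a named character vector of class `lineage`.
#' @examples
#' lineage("Viridiplantae;Streptophyta;Magnoliopsida;Apiales;Araliaceae;Panax;Panax quinquefolius")
#' @export
lineage <- function(x) {
  if (length(x) == 1 && grepl(";", x)) {
    x <- strsplit(x, ";", fixed = TRUE)[[1]]
  }
  x <- trimws(x)
  if (length(x) != length(.lineage_ranks)) {
    stop("a lineage needs exactly ", length(.lineage_ranks),
         " ranks (kingdom..species), got ", length(x))
  }
  if (any(!nzchar(x))) stop("lineage contains an empty taxon name")
  structure(setNames(x, .lineage_ranks), class = "lineage")
}

#' Lowest common ancestor of a set of lineages
#'
#' Returns the deepest rank at which all lineages agree.  Lineages that
#' disagree already at kingdom level fall back to the taxonomy root.
#'
#' @param lineages non-empty list of [lineage()] objects.
#' @return a list with elements `rank` and `taxon`; `("root",
#'   "cellular organisms")` when the lineages share no rank.
#' @examples
#' a <- lineage("Viridiplantae;Streptophyta;Magnoliopsida;Lamiales;Scrophulariaceae;Scrophularia;Scrophularia ningpoensis")
#' b <- lineage("Viridiplantae;Streptophyta;Magnoliopsida;Lamiales;Scrophulariaceae;Scrophularia;Scrophularia buergeriana")
#' lca(list(a, b))  # genus Scrophularia
#' @export
lca <- function(lineages) {
  if (length(lineages) == 0) stop("lca of an empty lineage set is undefined")
  mat <- do.call(rbind, lapply(lineages, unclass))
  deepest <- 0L
  for (j in seq_along(.lineage_ranks)) {
    if (all(mat[, j] == mat[1, j])) deepest <- j else break
  }
  if (deepest == 0L) {
    list(rank = "root", taxon = "cellular organisms")
  } else {
    list(rank = .lineage_ranks[deepest], taxon = unname(mat[1, deepest]))
  }
}

# internal constructor used by the loader and the fixture generator
new_reference_db <- function(taxa, barcodes, organelles = list()) {
  stopifnot(all(c("taxon_id", "kingdom_class", "role") %in% names(taxa)),
            all(c("taxon_id", "locus", "copy_weight", "barcode_seq",
                  "context_seq") %in% names(barcodes)))
  key <- paste(barcodes$taxon_id, barcodes$locus)
  dup <- key[duplicated(key)]
  if (length(dup) > 0) {
    stop("duplicate (taxon, locus) reference: ", paste(dup, collapse = ", "))
  }
  bad <- !mapply(grepl, barcodes$barcode_seq, barcodes$context_seq,
                 MoreArgs = list(fixed = TRUE))
  if (any(bad)) {
    stop("barcode_seq not contained in context_seq for: ",
         paste(key[bad], collapse = ", "))
  }
  structure(list(taxa = taxa, barcodes = barcodes, organelles = organelles),
            class = "reference_db")
}

#' @export
print.reference_db <- function(x, ...) {
  cat("Barcode reference database\n")
  cat("  taxa:      ", nrow(x$taxa), "\n")
  cat("  barcodes:  ", nrow(x$barcodes), " (",
      paste(sort(unique(x$barcodes$locus)), collapse = ", "), ")\n", sep = "")
  cat("  organelles:", length(x$organelles), "\n")
  invisible(x)
}

#' Look up barcode references
#'
#' @param refdb a `reference_db`.
#' @param taxon_id optional taxon filter.
#' @param locus optional locus filter.
#' @return data.frame of matching barcode reference rows.
#' @export
get_barcodes <- function(refdb, taxon_id = NULL, locus = NULL) {
  b <- refdb$barcodes
  if (!is.null(taxon_id)) b <- b[b$taxon_id %in% taxon_id, , drop = FALSE]
  if (!is.null(locus)) b <- b[b$locus %in% locus, , drop = FALSE]
  b
}

#' Lineage of a taxon in the database
#'
#' @param refdb a `reference_db`.
#' @param taxon_id taxon identifier.
#' @return a [lineage()].
#' @export
get_lineage <- function(refdb, taxon_id) {
  i <- match(taxon_id, refdb$taxa$taxon_id)
  if (is.na(i)) stop("unknown taxon: ", taxon_id)
  lineage(unlist(refdb$taxa[i, .lineage_ranks], use.names = FALSE))
}

#' Load a barcode reference database
#'
#' Reads barcode context sequences from FASTA (identifiers of the form
#' `taxon_id|locus`) and a tab-separated sidecar with columns `taxon_id`,
#' `locus`, `lineage` (a `;`-separated seven-rank string), `copy_weight`,
#' `barcode_start`, `barcode_end` (0-based half-open coordinates of the
#' inter-primer barcode within the context sequence) and optionally `role`
#' and `kingdom_class`.
#'
#' @param fasta_path FASTA of context sequences.
#' @param lineage_table_path tab-separated sidecar table.
#' @param organelle_fasta_path,organelle_feature_path optional organelle
#'   genome FASTA (ids `taxon_id|kind`) and BED-like feature table with
#'   columns chrom (`taxon_id|kind`), start, end, name, kind.
#' @return a `reference_db`.
#' @export
load_reference_db <- function(fasta_path, lineage_table_path,
                              organelle_fasta_path = NULL,
                              organelle_feature_path = NULL) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  tab <- read.delim(lineage_table_path, stringsAsFactors = FALSE,
                    check.names = FALSE)
  need <- c("taxon_id", "locus", "lineage", "copy_weight",
            "barcode_start", "barcode_end")
  if (!all(need %in% names(tab))) {
    stop("lineage table must have columns: ", paste(need, collapse = ", "))
  }
  ids <- sub("\\s.*$", "", names(seqs))
  tab_key <- paste(tab$taxon_id, tab$locus, sep = "|")
  missing <- setdiff(ids, tab_key)
  if (length(missing) > 0) {
    stop("FASTA id(s) missing from the lineage table: ",
         paste(missing, collapse = ", "))
  }
  if (anyDuplicated(tab_key)) {
    stop("duplicate (taxon, locus) rows in lineage table: ",
         paste(unique(tab_key[duplicated(tab_key)]), collapse = ", "))
  }
  m <- match(ids, tab_key)
  ctx <- as.character(seqs)
  barcodes <- data.frame(
    taxon_id = tab$taxon_id[m],
    locus = tab$locus[m],
    copy_weight = tab$copy_weight[m],
    barcode_seq = substr(ctx, tab$barcode_start[m] + 1, tab$barcode_end[m]),
    context_seq = ctx,
    stringsAsFactors = FALSE
  )
  lin <- do.call(rbind, lapply(tab$lineage[m], function(s) {
    as.data.frame(as.list(unclass(lineage(s))), stringsAsFactors = FALSE)
  }))
  taxa <- cbind(
    data.frame(taxon_id = tab$taxon_id[m],
               role = if ("role" %in% names(tab)) tab$role[m] else "labeled_ingredient",
               kingdom_class = if ("kingdom_class" %in% names(tab)) {
                 tab$kingdom_class[m]
               } else {
                 c(Viridiplantae = "plant", Fungi = "fungus",
                   Metazoa = "animal")[lin$kingdom]
               },
               stringsAsFactors = FALSE),
    lin
  )
  taxa <- taxa[!duplicated(taxa$taxon_id), , drop = FALSE]
  rownames(taxa) <- NULL
  if (anyDuplicated(taxa$species)) {
    stop("species names must be unique within a database")
  }
  organelles <- list()
  if (!is.null(organelle_fasta_path)) {
    oseq <- Biostrings::readDNAStringSet(organelle_fasta_path)
    feats <- read.delim(organelle_feature_path, stringsAsFactors = FALSE)
    for (i in seq_along(oseq)) {
      id <- sub("\\s.*$", "", names(oseq)[i])
      parts <- strsplit(id, "|", fixed = TRUE)[[1]]
      f <- feats[feats$chrom == id, c("start", "end", "name", "kind")]
      organelles[[id]] <- organelle_reference(
        taxon_id = parts[1], genome_kind = parts[2],
        seq = as.character(oseq[[i]]),
        features = data.frame(name = f$name, start = f$start, end = f$end,
                              kind = f$kind, stringsAsFactors = FALSE))
    }
  }
  new_reference_db(taxa, barcodes, organelles)
}

#' Construct an organelle genome reference
#'
#' @param taxon_id taxon identifier.
#' @param genome_kind `"chloroplast"` or `"mitochondrion"`.
#' @param seq genome sequence.
#' @param features data.frame with columns name, start, end (0-based
#'   half-open), kind (`"gene"` or `"intergenic"`).
#' @return an `organelle_reference`.
#' @export
organelle_reference <- function(taxon_id, genome_kind, seq, features) {
  stopifnot(genome_kind %in% c("chloroplast", "mitochondrion"))
  len <- nchar(seq)
  if (any(features$start < 0) || any(features$end > len) ||
      any(features$end <= features$start)) {
    stop("organelle features must lie within [0, genome length)")
  }
  g <- features[features$kind == "gene", , drop = FALSE]
  if (nrow(g) > 1) {
    g <- g[order(g$start), , drop = FALSE]
    if (any(g$start[-1] < g$end[-nrow(g)])) {
      stop("gene features must not overlap")
    }
  }
  structure(list(taxon_id = taxon_id, genome_kind = genome_kind, seq = seq,
                 features = features), class = "organelle_reference")
}

#' Serialize a reference database
#'
#' Writes the barcode contexts as 80-column FASTA plus the tab-separated
#' lineage sidecar, and (when present) organelle genomes with a BED-like
#' feature table.  [load_reference_db()] on the written files reproduces
#' the database; writing again reproduces the files byte-identically.
#'
#' @param refdb a `reference_db`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_reference_db <- function(refdb, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "barcodes.fasta")
  tsv <- file.path(dir, "lineages.tsv")
  b <- refdb$barcodes
  t_i <- match(b$taxon_id, refdb$taxa$taxon_id)
  seqs <- Biostrings::DNAStringSet(b$context_seq)
  names(seqs) <- paste(b$taxon_id, b$locus, sep = "|")
  Biostrings::writeXStringSet(seqs, fa, width = 80)
  bc_start <- mapply(function(ctx, bc) regexpr(bc, ctx, fixed = TRUE)[1] - 1L,
                     b$context_seq, b$barcode_seq, USE.NAMES = FALSE)
  tab <- data.frame(
    taxon_id = b$taxon_id, locus = b$locus,
    lineage = apply(refdb$taxa[t_i, .lineage_ranks], 1, paste,
                    collapse = ";"),
    copy_weight = b$copy_weight,
    barcode_start = bc_start,
    barcode_end = bc_start + nchar(b$barcode_seq),
    role = refdb$taxa$role[t_i],
    kingdom_class = refdb$taxa$kingdom_class[t_i],
    stringsAsFactors = FALSE
  )
  write.table(tab, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(fasta = fa, lineage_table = tsv)
  if (length(refdb$organelles) > 0) {
    ofa <- file.path(dir, "organelles.fasta")
    obed <- file.path(dir, "organelle_features.tsv")
    oseq <- Biostrings::DNAStringSet(
      vapply(refdb$organelles, function(o) o$seq, character(1)))
    names(oseq) <- vapply(refdb$organelles, function(o) {
      paste(o$taxon_id, o$genome_kind, sep = "|")
    }, character(1))
    Biostrings::writeXStringSet(oseq, ofa, width = 80)
    feats <- do.call(rbind, lapply(refdb$organelles, function(o) {
      data.frame(chrom = paste(o$taxon_id, o$genome_kind, sep = "|"),
                 start = o$features$start, end = o$features$end,
                 name = o$features$name, kind = o$features$kind,
                 stringsAsFactors = FALSE)
    }))
    rownames(feats) <- NULL
    write.table(feats, obed, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, organelle_fasta = ofa, organelle_features = obed)
  }
  invisible(paths)
}
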