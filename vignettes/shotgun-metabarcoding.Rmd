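---
title: "Shotgun metabarcoding of multi-ingredient herbal products"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shotgun metabarcoding of multi-ingredient herbal products}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shotgunmb)
```

## The problem

Compound herbal products mix plant, fungal and animal material in one
pill.  Conventional amplicon metabarcoding struggles here: PCR primers are
kingdom-biased, amplification introduces abundance distortion and
chimeras, and heavily processed material yields fragmented DNA.  *Shotgun
metabarcoding* sidesteps PCR entirely: whole-genome shotgun reads of the
product are searched for the small fraction that covers one of five
standard DNA barcodes — ITS2 (nuclear ribosomal, plants and fungi),
psbA-trnH, matK and rbcL (plastid, plants only) and COI (mitochondrial,
the animal barcode) — and those reads are assembled back into barcode
sequences that identify each ingredient.

shotgunmb implements this workflow end to end, together with a read
simulator that emulates the study design the method is validated on: a
ten-ingredient mixture (eight plants, one fungus, one animal), a
positive-control plant spiked into one replicate at the same mass
proportion as the fungal ingredient, trace contaminant fungi, and a
pharmaceutical-style sample carrying trace unlabeled plant species.

## Pipeline stages and their models

1. **Trimming** (`trim_read_pairs`): adapter clipping by suffix/prefix
   alignment (minimum 8 nt overlap, 10% mismatches) and quality trimming
   with leading/trailing floors (Q3) plus a 4-base sliding window cut at
   mean Q15; pairs with a mate under 50 nt are dropped whole, because all
   downstream stages are pair-oriented.  The upstream tool this stands in
   for is configured by a parameter string that has no community-standard
   value; these defaults are deliberately conservative ("gentle") and are
   all exposed in `trim_params()`.
2. **Locus enrichment** (`build_locus_index`, `enrich_reads`): every
   31-mer of every reference *context* sequence (barcode plus primer
   sites plus ≥200 nt of genomic flank) is indexed under its locus,
   canonicalised over strands.  A read pair is recruited to the locus
   with the most matching k-mers if that count reaches `min_hits = 3`;
   ties are left unassigned so bins stay disjoint.  k = 31 makes random
   150 nt reads essentially never match (verified at <1% on decoy reads),
   while 3 hits tolerate a couple of sequencing errors per read.
3. **Assembly** (`assemble_dual_k`): a de Bruijn graph over canonical
   k-mers, unitigs emitted deterministically (nodes iterated in
   lexicographic order), run at k = 21 and k = 31 and unioned with
   exact/reverse-complement/containment deduplication — emulating the
   union of two assemblers followed by a uniqueness pass.  Cleaning is
   three-fold: k-mers seen once are dropped; k-mers below 5% of their
   component's *coverage-weighted median* count are dropped (at high
   depth, recurring sequencing errors produce k-mers whose counts scale
   with depth — a plain median fails because such error k-mers outnumber
   genuine ones, while the weighted median tracks where the coverage mass
   sits); then short dead-end tips (<2k) and bubble arms below 10% of the
   dominant parallel path are pruned iteratively.  The weighted-median
   rule is safe for genuinely low-abundance taxa because their components
   carry uniformly moderate counts, and any component merged with
   high-depth taxa through shared conserved sequence at k = 21 is
   recovered by the k = 31 pass, where those short shared stretches no
   longer produce shared k-mers.
4. **Barcode extraction** (`extract_barcodes`): for psbA-trnH, matK,
   rbcL and COI, the region strictly between a forward primer site and a
   downstream reverse-complemented reverse primer site (IUPAC-aware
   matching, ≤3 mismatches, no indels — assembled contigs carry few);
   the longest extractable region wins, ties leftmost.  ITS2 is located
   between two position-weight profiles over the conserved 3' end of
   5.8S and 5' start of 28S, scored as log-odds against a uniform
   background — a profile-matching stand-in for HMM-based rDNA
   annotation that preserves the observable contract (find the region
   between the two conserved flanks) without indel states.  A contig
   whose end truncates one flank yields a candidate flagged *partial*.
   Candidates whose two halves best-hit different genera are discarded
   as bimeras (configurable off); candidates under 50 nt are discarded
   as uninformative.
5. **OTUs** (`cluster_otus`, `map_reads_to_otus`, `filter_otus`):
   clustering at 100% identity — identical sequences collapse, and an
   exact substring joins the longer candidate's OTU, so partial barcodes
   of an ingredient are counted with the full-length one.  All trimmed
   reads are then mapped back (15 nt exact seed, ungapped extension,
   ≥95% identity over the overlap, each read to its single best OTU) to
   obtain per-base depth and coverage.  An OTU is *validated* when
   coverage ≥0.8 and mean depth ≥5 — both inclusive; these reliability
   thresholds are the single most consequential parameters with no
   published value, so they are surfaced in the run configuration and
   the provenance record rather than buried.
6. **Taxonomy** (`align_otu`, `assign_taxon`): exact overlap
   (end-gap-free) alignment against every same-locus reference (match
   +1, mismatch −1, gap open −2, extend −1) — with small reference sets,
   exact dynamic programming is affordable and testable against an
   independent oracle, so no heuristic seeding is used.  Hits below 90%
   identity are dropped, hits within 1 percentage point of the best are
   kept, and the assignment is the lowest common ancestor of their
   lineages over a fixed seven-rank schema.  A species-rank call is
   demoted to genus when the best identity is below 99%, which prevents
   overcalling between near-identical congeners (the Scrophularia
   problem).  Overlaps covering less than half the representative are
   ignored: a short perfect overlap between sequence ends carries no
   signal.
7. **Organelle fallback** (`organelle_scan`): ingredients whose barcodes
   fail to assemble are recovered by recruiting all reads to their whole
   chloroplast/mitochondrial genome and summarising per-feature read
   counts, coverage and depth.  The underlying studies report such
   mappings descriptively without a decision rule; this package makes
   the rule explicit and configurable — detected when ≥2 annotated
   regions reach ≥50% coverage — and records it in every report.
   Reads already recruited to barcode bins stay eligible, since the COI
   barcode lies inside the mitochondrial COX1 gene.

## What the simulator emulates — and what it does not

`simulate_sample()` draws read pairs from barcode contexts, organelle
genomes, contaminant contexts and a 50 kb genomic decoy, with the
expected read share of a (taxon, source) proportional to mass proportion
× copy weight.  Defaults: 150 nt paired reads; Gaussian 350 ± 35 nt
inserts truncated at the read length (the library is PCR-free, so no
amplification bias is modelled); substitution-only errors at mean rate
0.002 per base, ramping linearly to twice that at the read 3' end, with
Phred+33 qualities consistent with the ramp; no indels (negligible for
the emulated platform at this scale).  Copy weights default to ITS2 =
100 and plastid/mitochondrial loci = 20, chosen so the simulated
per-locus read-count imbalance qualitatively reproduces the strong skew
observed in real shotgun data toward ribosomal and organellar loci; they
are configurable per reference.  The mock design uses equal mass
proportions across the ten labeled ingredients (the source prescription's
exact proportions are not published in the text), 2% contaminant reads
split 5:3:2 across three fixture fungi in the dominance order seen in
real products, and 30% decoy.  The pharmaceutical-style design adds two
unlabeled plants at a combined 1.37% of the labeled-plant mass, the
trace level at which off-label plant reads are reported in commercial
products.

Fixture reference sequences are uniform random DNA with exact primer
sites and conserved rDNA flanks embedded, congeners separated by a
controlled 2.5% divergence.  Real barcodes have phylogenetic structure,
conserved cores and length variation that random fixtures lack, so
passing tests demonstrate the pipeline's logic — binning, assembly,
extraction, clustering, LCA behaviour, fallback — not classification
accuracy against real reference databases.  Likewise the error model
omits indels and quality-dependent miscalls, so trimming is exercised
mostly by constructed cases rather than by the simulated mock.

Simulator RNG streams are decoupled from the seed used to generate the
reference database: two equal nominal seeds would otherwise replay
overlapping Mersenne–Twister streams and leak reference subsequences
into the decoy background.

## Numerical and degenerate-input conventions

Coordinates are 0-based half-open internally and 1-based closed only in
human-readable reports.  Contigs, OTU representatives and candidates are
canonicalised to the lexicographically smaller of a sequence and its
reverse complement, which — together with lexicographic node iteration
and explicit tie-breaks (longest, then leftmost, then lexicographic) —
makes every stage independent of input order and reproducible
byte-for-byte under a fixed seed.  Empty bins assemble to empty contig
sets rather than erroring; empty candidate sets cluster to empty OTU
tables; a locus with no validated OTUs reports NA length and GC.  OTU
validation boundaries are inclusive.  At source termini, fragment
placement thins out, so the outermost bases of a context are not
guaranteed to assemble; the primer-to-primer region sits ≥200 nt inside
its context and is unaffected.

Problem sizes: the validation suite simulates 200,000 read pairs per
mock sample (unspiked, spiked and pharmaceutical-style), which gives
per-taxon barcode depths in the hundreds-to-thousands — the regime in
which OTU validation, error-path cleaning and the trace-level
(1.37%) unlabeled signal are all meaningfully exercised on one CPU in a
few minutes.

## Design choices made where the design was open

* The dual-assembler union is emulated by one assembler at two k values
  (21 and 31); k-mers are packed two bits per base into 64-bit words, so
  k ≤ 31.  The observable contract — union of two assemblies, then
  containment-aware deduplication — is what downstream stages consume.
* How multiple reference databases would be reconciled into one
  assignment is deliberately not guessed: the package exposes a single
  merged local database.
* "Detected" requires a validated, non-partial OTU assigned at species
  rank (or genus rank when the taxon is its genus's only member in the
  database); partial OTUs are reported separately rather than counted.
* The organelle detection rule (≥2 regions at ≥50% coverage) is the
  package's own, labelled as such in outputs, because background
  cross-mapping of a handful of reads must not count as a detection.

## Known limitations

Ungapped OTU mapping under-counts reads over indel-bearing
representatives (none arise from the substitution-only simulator, and
representatives derive from the same reads).  The bimera screen is a
two-half best-hit heuristic, not a full chimera model.  The LCA operates
on a fixed seven-rank schema; intermediate ranks are not represented.
Primer matching allows no indels.  None of these affect the synthetic
validation, and each is confined behind a module boundary where a more
elaborate implementation could be swapped in.
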