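---
title: "Designing intron-targeting markers for an alien chromosome arm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing intron-targeting markers for an alien chromosome arm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(intronIT)
```

## The problem and the model

Wheat breeding programs introgress chromatin from wild relatives — here the
short arm 4VS of *Haynaldia villosa*, which carries a disease-resistance
locus — into hexaploid wheat, and then need cheap PCR assays that detect the
alien segment against the three homoeologous wheat arms (4AL, 4BS, 4DS).
Exons of homoeologous genes are strongly conserved, while intron *lengths*
drift quickly. An intron-targeting (IT) marker exploits this: a primer pair
anchored in the conserved exons flanking one intron amplifies a product from
every genome, and the product *sizes* differ by each genome's intron length.
If the alien intron's size differs enough from all three wheat introns, the
alien band separates on a gel and the marker diagnoses the presence of alien
chromatin — codominantly, since the wheat bands remain visible.

The pipeline turns that idea into a design procedure:

1. **Gene set** (`merge_gene_sets`, `find_redundant_pairs`,
   `window_filter`): assemble a non-redundant set of query genes from two
   annotation sources. A pair of transcripts is redundant when a local
   alignment (blastn-like scoring: match +1, mismatch −2, gap open 5, gap
   extend 2) reaches e-value ≤ `dedup_evalue_cutoff` (default `1e-5`, the
   conventional nucleotide-homology cutoff) with aligned coverage >
   `dedup_coverage_cutoff` (default 0.80) of the reference transcript.
   E-values use the ungapped Karlin–Altschul form `K m n exp(−λ S)` with
   λ = 1.28, K = 0.46, the standard constants for this scoring scheme. The
   coverage reference is the *shorter* transcript by default
   (`dedup_coverage_denominator = "shorter"`): this is the conservative
   choice — it removes a fragment that is wholly contained in a longer gene
   — and `"longer"` is available where symmetric containment is wanted.
2. **Spliced mapping** (`map_genes_to_panels`, `find_exon_blocks`): map each
   spliced transcript onto each of the four arm assemblies with an exact
   15-mer seed → collinear chain → boundary-refinement aligner (below).
   Genomic gaps between adjacent exon blocks are the inferred introns.
3. **Intron matching** (`match_homologous_introns`): exon–exon junctions are
   matched across arms by transcript position within `junction_tol_bp`
   (default 12 bp), giving one (A, B, D, V) intron-size quartet per
   junction present on all four arms.
4. **Polymorphism filter** (`filter_targeted_introns`): a quartet is a
   *targeted intron* when the V size differs by at least
   `polymorphism_threshold` (default 0.10) from **every** wheat arm's size,
   relative to the wheat size (`|V − w| / w`). One intron is selected per
   gene — the one with the largest worst-case difference
   (`select_marker_intron`) — so each gene yields at most one marker.
5. **Primer design** (`design_all`, `melting_temperature`): primer windows
   are enumerated in the two exons flanking the selected intron on the
   V-genome template and scored against melting-temperature, length, GC,
   homopolymer and self-complementarity constraints (defaults below).
6. **In-silico validation** (`call_specific_markers`, `simulate_pcr`): each
   pair is amplified computationally against all four assemblies, products
   are clustered into gel bands, and the band pattern is classified; a
   marker is *specific* when the V product forms its own band.

## The spliced aligner

Transcript-to-genome mapping must open intron-sized gaps in the genome but
none in the transcript. The aligner seeds exact `seed_k`-mers (default 15:
long enough that random hits are rare at the scales involved, short enough
to tolerate occasional substitutions), groups seeds by diagonal into blocks,
and chains collinear blocks with a dynamic program that allows genomic gaps
up to 5× the maximum PCR product and transcript gaps up to 60 bp. Inter-block
transcript gaps are then redistributed across the flanking exon boundaries by
maximizing matched bases, and genomic gaps shorter than `min_intron_bp`
(default 40 bp, below the eukaryotic minimum spliceosomal intron size) are
fused as alignment artifacts rather than called as introns. Both transcript
orientations are tried; ties between equally scoring placements resolve
deterministically (score, then query coverage, then scaffold id, then
strand). Arms where the best chain covers less than `min_query_cov`
(default 0.5) of the transcript are treated as having no hit.

The test suite checks this aligner against an independent quadratic dynamic
program (global in the transcript, free intron jumps ≥ `min_intron_bp` in
the genome) on hundreds of randomized instances: the chain the mapper finds
must achieve exactly the DP-optimal score, and its intron sizes must equal
the generating truth.

## Primer and product constraints

- **Tm** (`tm_min`/`tm_opt`/`tm_max` = 55/60/65 °C): nearest-neighbor
  thermodynamics with the unified duplex parameter set, entropy salt
  correction `0.368 (N−1) ln[Na+]` at `monovalent_mM` = 50, and duplex
  concentration CT/4 for `oligo_nM` = 250 nM total oligonucleotide. The
  implementation is frozen against an independent reference implementation
  to ~10⁻⁵ °C in the tests. A Wallace-rule fallback exists for quick
  estimates.
- **Length** 18–25 nt (optimum 20), **GC** 0.30–0.70, homopolymer runs
  ≤ 4, self-complementary stretches ≤ 8 bp (hairpin/self-dimer proxy) —
  standard PCR-design practice.
- **Product size**: the V product must exceed the targeted intron by at
  least `product_overhead_bp` (default 50 bp) so both primers sit strictly
  in exons with usable footprints; a soft optimum keeps products compact.
  Primer windows are searched within `max_flank_bp` (150 bp) of the intron
  so products stay in the resolvable gel range.

## In-silico PCR and band classification

A primer binds where at most `epcr_max_mismatch` (2) mismatches occur and
the `epcr_3prime_exact_bp` (5) 3′-terminal bases match exactly — the 3′ end
is what the polymerase extends, so mismatches there are disqualifying while
5′ mismatches mostly are not. Convergent site pairs on one scaffold with a
product ≤ `epcr_max_product_bp` (3000 bp, a practical ceiling for standard
PCR and gel resolution) yield amplicons; the tests compare this against an
exhaustive position-by-position scan.

Two products co-migrate (one band) when they differ by at most
`max(comigration_abs_bp, comigration_rel × mean size)` — an absolute floor
of 4 bp plus a 1% relative term, calibrated so that the shipped reference
markers' published band patterns are reproduced: with it, the
three-band reference marker whose wheat products differ by 3 bp merges
exactly those two, while 6-bp-apart products at the same size still resolve.
Band patterns with a distinct V band are classified by what co-migrates:
four bands (type `I`), one wheat pair merged (`II` = A+B, `III` = A+D,
`IV/VI` = B+D — two published labels cover the same B+D pattern, so both are
reported as one alias), all wheat merged (`V/VII`). A V band that co-migrates
with wheat is not specific; a missing V product is `no-V`. `assign_bins`
places validated markers into physical bins from presence/absence across
nested translocation lines.

## Synthetic panels and ground truth

`generate_panel` builds four homoeologous arm assemblies with fully known
structure: each gene family draws an ancestral exon/intron layout, realizes
wheat arms with small independent intron-size jitter (±4%) and the alien arm
with either large (`targeted_divergence`, 18–45%) or small
(`background_divergence`, 0–8%) size changes, then verifies every junction's
intended targeted/background class against the realized sizes with the
actual filter rule — so the truth table is exact by construction, not by
intention. Exonic substitutions (default 2% per arm) spare primer-sized
windows at the exon ends; families are embedded on random strands in
composition-matched random background with ≥ 2 kb spacing, several families
per scaffold. The generator is deliberately idealized — no segmental
duplications, no repeat families, no indel drift in exons by default — which
is what makes exact recall/precision assertions meaningful; raising
`substitution_rate` or `background_divergence` degrades realism gracefully
for robustness testing.

## A worked example

```{r example}
clean <- family_params(substitution_rate = 0)   # noise-free: exact truth
bundle <- generate_panel(n_families = 10, fraction_targeted = 0.4,
                         fraction_intronless = 0.2, seed = 7,
                         params = clean)
bundle

res <- suppressMessages(run_marker_pipeline(bundle$genes, bundle$panels))
res$funnel
res$markers[, c("marker_id", "gene_id", "intron_V", "product_V",
                "type", "is_specific")]
```

Every specific marker above belongs to a family the generator made targeted,
and every targeted family yields one:

```{r check}
setdiff(unique(bundle$truth$gene_id[bundle$truth$is_targeted]),
        res$markers$gene_id[res$markers$is_specific])
```

The same pipeline runs from files via `run_pipeline()` (FASTA + GFF3 in,
TSV/JSON out, with a checksum manifest making reruns idempotent) or the
`inst/cli/intronit.R` script. At the scales used throughout the tests —
up to 100 families, scaffolds of tens of kilobases, four arms — the full
chain runs in about a minute on one core; the mapper indexes each scaffold's
k-mers once per run, so cost grows roughly linearly in panel size times
gene count.
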