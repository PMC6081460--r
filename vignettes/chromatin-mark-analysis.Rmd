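---
title: "Comparative chromatin-mark analysis: models, thresholds and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative chromatin-mark analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem this package addresses

Histone H3.3 G34R is an oncohistone substitution two residues away from
lysine 36. Rather than acting through the mutated nucleosome alone, G34R
behaves as a dominant inhibitor of the KDM4 family of H3K9me3/H3K36me3
demethylases, so mutant cells accumulate both marks at the genomic sites
where KDM4 normally acts — a molecular "genocopy" of a KDM4 A/B/C triple
knockout. Detecting that phenotype from sequencing data requires a chain of
small, exactly specified decisions: how reads become bin counts, how two
libraries are made comparable, what counts as an enriched region, how
regions are stratified by factor occupancy, and how fold changes against an
independent knockout cohort are classified. `oncomark` implements that chain
as a tested, reusable package, together with seeded synthetic-data
generators that plant a known truth so every stage can be verified without
any external download.

## Quantitation and normalization

Reads are counted over a fixed grid of half-open bins (`bin_genome`,
default width 200 bp; the last bin of each chromosome is truncated and bins
never cross chromosomes). Each retained read increments exactly one bin —
the bin containing its 5' start, taking strand into account (for a
minus-strand read the 5' end is its rightmost base). This single-bin rule
makes the counting conservation law exact:

```
retained + skipped (off-grid) + duplicates removed = input reads.
```

PCR duplicates are reads identical in (chromosome, start, end, strand), the
standard duplicate-marking semantics for single-end reads. An
overlap-fraction assignment (each read contributes `overlap/width` to every
bin it touches) is available behind a flag for users who prefer smoother
tracks; it is not the default because it breaks the integer conservation
law.

Two normalizations are applied in sequence. Per-million scaling
(`v * 1e6 / total_reads`) removes library-size differences and preserves
between-bin ratios exactly. Distribution matching (`match_distributions`)
then removes differences in signal-to-noise shape: both tracks are mapped
rank-wise onto their common reference distribution, the element-wise mean of
the two sorted value vectors. Within-track rank order is preserved, so every
downstream per-track percentile threshold is invariant to matching.

**Ties.** Tied values receive the mean reference value over their tied
ranks — the canonical quantile-normalization tie treatment (as in
`limma::normalizeQuantiles`). A consequence worth stating plainly: with
ties, the two output multisets are close but not identical (ties sit at
different rank positions in the two tracks), so the exact multiset-equality
contract, tested at 1e-9, holds for tie-free inputs. Integer count tracks
always carry ties; their matched values still agree in total mass and rank
structure.

## Region calling

The calling chain follows a percentile philosophy rather than a background
model — every threshold is relative to the dataset at hand:

1. **Genic restriction.** Only bins overlapping an annotated gene by at
   least 1 bp participate.
2. **Selection.** A genic bin is selected if its value strictly exceeds the
   95th percentile of genic-bin values in *either* condition; thresholds are
   computed per track, over genic bins only.
3. **Merging.** Selected bins within 100 bp are merged; the merged score is
   the mean of member-bin scores (MergeBed `-d 100 -o mean` semantics).
4. **Exclusions.** Merged regions longer than 500 bp are excluded, then the
   top `floor(n * 1e-4)` regions by score (extreme read counts, typically
   artifact regions). Every exclusion is retained with a reason code.

**Percentile conventions.** Thresholding uses the nearest-rank percentile
(the value at rank `ceiling(p/100 * n)` of the sorted vector) with strict
`>` / `<` comparisons — reproducible on integer-valued counts, and the
reading under which "values 1..100, 95th percentile" selects exactly the
five values 96..100. The descriptive `quantile_summary` (10/25/50/75/90)
uses linear interpolation (`stats::quantile` type 7), matching box-plot
conventions. These are deliberately different tools for different jobs.

**Why floor, not ceiling, for the extreme filter.** A ceiling rule removes
at least one region from any non-empty set, which is absurd for small sets
(it would empty a set of one) and contradicts the worked behaviour of the
merge filter on toy inputs. `floor(n * fraction)` leaves sets smaller than
`1/fraction` untouched and removes exactly one region per 10,000 at the
default fraction — indistinguishable from ceiling at realistic set sizes.

**Factor stratification.** A region's factor score is the length-weighted
mean of factor-track values over its span. Within the region set, scores
strictly above the enriched percentile (75th for demethylase tracks, 90th
for variant-histone tracks) are `enriched`, strictly below the 25th are
`depleted`, the rest `neither`. Fewer than four regions is an error —
percentiles of three values are not meaningful. Venn-style overlap counts
(`overlap_classes`) are exclusive cells: a region counts for a factor
combination if it is enriched for every factor in it, enriched for none
outside it, and depleted for none in it (depletion as an exclusion
criterion).

**Scaled profiles.** `scaled_region_matrix` re-grids each region body onto
`ceiling(500/bin)` columns by linear interpolation of member-bin values at
their centers, appends 1 kb flanks at native resolution (off-chromosome
positions contribute 0), and removes blacklist-overlapping regions first.
A region shorter than one bin contributes its single bin value to all body
columns.

## The knockout-cohort comparison

`harmonize_cohorts` keeps reference-cohort regions that are also enriched in
the query cohort: the region's query score must strictly exceed the 90th
(H3K9me3) or 75th (H3K36me3) percentile, computed within the region set, in
at least one query condition. `classify_fold_change` then labels each
region by its reference ratio `ko/wt`: `gained` above 1.5, `unchanged` in
the closed interval [0.8, 1], `other` elsewhere. "Between 0.8 and 1" is
ambiguous about its endpoints; both are included and the choice is
configurable. Zero denominators are flagged rather than propagated: `wt = 0,
ko > 0` is a gain with an infinite-ratio flag, `wt = ko = 0` is `other`
with a zero flag. `mirror_comparison` reports, per reference label, the
distribution of `log2(query_mut/query_wt)` — the genocopy readout: if the
mutant phenocopies the knockout, the reference-gained class shows elevated
query ratios while the reference-unchanged class sits near zero.

Ratios are computed on matched-normalized scores within each cohort; the
cross-cohort link is only through region identity, never through shared
normalization.

## Expression and allele readouts

RPKM follows the strict rule set: isoforms merged into union exons per gene;
a read assigned by its 5' start falling in a union exon with compatible
strand (default reverse/dUTP protocol); reads assignable to more than one
gene left unassigned and tallied (fractional assignment is configurable);
`rpkm = count * 1e9 / (union_exon_length * total_assigned)`; genes with zero
counts in every sample dropped. Gene-set comparisons report per-gene
`log2(mut/wt)` sorted ascending against a size-matched uniform random
control drawn without replacement from non-set genes under a mandatory
seed; zero-RPKM genes are excluded without pseudocounts and reported.

Allele classification at codon 34 works on a three-sequence library (mutant
transgene, the two wild-type genes) that is positionally aligned and
near-identical. The diagnostic positions are the positions where the three
sequences are not all identical, within the window a codon-34-spanning read
can reach. After collapsing exact-sequence duplicates, each read is placed
ungapped (best placement, both orientations) against each sequence and
assigned to the unique sequence it matches at every diagnostic position
with at most 2 mismatches elsewhere; anything else is uninformative. With a
valid library no read can match two sequences at all diagnostic positions,
so ambiguity is tallied only defensively.

## Methylation-state readout

The expected mass ladder is `base + k * 14.015650` Da (monoisotopic CH2)
for me0..me3, assuming singly charged species (the MALDI-TOF convention;
charge configurable). The peptide base mass is a required input — the
assay peptides are proprietary and no mass is hard-coded. Peak picking is
deliberately simple: local maxima above `median + 3 * MAD` of the
intensities; each state takes the nearest such peak within 200 ppm
(externally calibrated reflector instrument) and abundances are apex
intensities normalized to sum to one. Matching against apexes makes the
profile equivariant under a common shift of spectrum and base mass, which
is the property the readout is tested on.

## The synthetic stated world

The generators are first-class, seeded, and serialize their planted truth.
Their defaults are frozen; the notable choices and why:

* **ChIP genome and depth.** 2 chromosomes x 2 Mb at 200 bp bins, 60 genes
  of 10–50 kb (~45% genic), background 20 reads per bin (~4M reads per
  track — a realistic desk-scale reduction), negative-binomial counts with
  dispersion 0.2 (Poisson as the dispersion-0 limit), 200 planted domains
  enriched 8-fold, half of them factor-binding sites that additionally gain
  2-fold in the mutant, with the factor track elevated 8-fold at its sites.
* **Whole-bin domains.** Planted domains occupy whole quantitation bins
  (1–2 bins, i.e. 200/400 bp, from `round(U(100,500)/200)`). This is the
  one place where generator geometry had to be chosen with care: the
  analysis inherits a hard ">500 bp merged regions are excluded" rule, and
  a domain straddling three bins merges to 600 bp and is discarded no
  matter how real its signal. A design simulation showed arbitrary-phase
  100–500 bp domains are structurally capped near 70% recovery by this rule
  alone — not a property of the caller but of grid phase. Whole-bin domains
  isolate what the recovery test is meant to verify (statistical behaviour
  of selection, merging and exclusion) from that geometric artifact;
  `align_to_grid = FALSE` restores arbitrary phase for users who want to
  study the artifact itself.
* **Read emission.** Each read is emitted with its 5' end at the sampled
  in-bin position (minus-strand reads extend leftward), so 5'-start
  counting reproduces the intensities the counts were drawn from;
  otherwise minus-strand reads spill into the next bin and create domain
  shoulders.
* **RNA world.** 300 genes (1–3 exons, lognormal expression), a 30-gene
  down-regulated set at effect 0.5 — a ~10% set share, so that RPKM's
  per-million renormalization does not visibly shift the control
  distribution (at a one-third share the composition effect moves both
  medians by ~0.36 log2 units; that is a property of RPKM, not a bug, but
  it is not what the set-recovery check is about).
* **Allele trio.** A synthetic 408-nt CDS stand-in with codon 34 at
  nt 100–102; the transgene differs only by the codon-34 substitution, the
  second wild-type gene by synonymous third-codon changes flanking the
  codon plus distant synonymous sites. Reads take distinct
  (start, orientation) placements where possible, and planted duplicates
  are appended as exact copies, so the generator knows the exact duplicate
  count the classifier must remove. Per-base errors use
  common-random-numbers coupling (fixed RNG consumption per base): under
  one seed the error set at a higher rate is a superset of the set at a
  lower rate, making accuracy degradation exactly monotone in the rate.
* **Spectrum.** Gaussian peaks (sd 0.1 Da) on a 0.05 Da grid over the
  1200–3500 Da window, apex scale 1000, flat baseline 5, noise sd 2 — a
  clean reflector-mode spectrum. The synthetic base mass (2000 Da) is a
  stand-in and is labelled as such.

**What a green test establishes — and does not.** The planted world has
independent bins, no mappability structure, no copy-number variation, no
input-chromatin bias, symmetric noise and literal duplicates. Recovery and
false-call rates verified here establish that the implementation applies
its stated rules correctly at realistic signal-to-noise; they do not
establish peak-calling performance on real chromatin, where the percentile
approach inherits all of the above confounders.

## Numerical choices, degenerate inputs, tie-breaks

* Value-equality tolerance 1e-9 (relative) wherever matching contracts are
  asserted; all thresholding is on exact comparisons of doubles produced by
  identical code paths.
* Empty inputs: empty read sets count to zero; empty bin sets merge to
  empty region sets; empty region sets harmonize to empty with a warning.
  Errors are reserved for meaningless requests (percentiles of an empty
  vector, classification of fewer than four regions, per-million scaling of
  an empty library).
* Region score ties in the extreme filter are broken by sort order
  (`order(score, decreasing = TRUE)`), i.e. earlier regions are removed
  first; at the default fraction this affects at most one region per
  10,000.
* The label partition in `classify_fold_change` is total by construction:
  flags, not NA labels, mark zero-denominator regions.

## Known limitations

* No replicate-aware differential statistics — the upstream design has no
  replicates, and the package deliberately reports classifications and
  distributions, not p-values.
* No local-background peak model; the percentile approach requires the
  two conditions to be match-normalized and inherits genome-wide biases.
* The allele classifier assumes a positionally aligned, equal-length
  library (true for the intended three-CDS design); it does not handle
  indels.
* mzML spectra are not parsed; spectra arrive as two-column tables.
* Mappability and blacklist generation are out of scope; blacklists are
  consumed, not derived.
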