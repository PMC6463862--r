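---
title: "Methods: polymorphism and selection analysis of a multigene family"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: polymorphism and selection analysis of a multigene family}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(askpoly)
```

This vignette is the package's own account of the statistical machinery it
implements: the models, their assumptions, the tunable parameters, the
numerical choices, and — importantly — what the built-in simulators do and do
not establish about real data.

## The analysis in one paragraph

The pipeline quantifies evolutionary constraint on the members of a gene
family (the motivating case is the *Arabidopsis* Skp1-like family) from two
directions. *Within species*, per-accession allelic sequences are rebuilt
from quality-filtered SNP calls over three regions per gene — 500 bp upstream
of the start codon, the CDS, 500 bp downstream of the stop codon — and
summarised by segregating sites, nucleotide diversity π, Watterson's
θ~W~, Tajima's D, and the minor-allele-frequency spectrum. *Between
species*, each ortholog CDS pair is fitted under a GY94 codon substitution
model with the dN/dS ratio ω fixed at 1 and again with ω free; twice the
log-likelihood difference is compared to 2.71, the 5% critical value of
χ²~1~, to call each gene *Neutral* or *Non-neutral*. Sliding-window π scans
with latitude- or expression-defined accession groups link promoter
polymorphism to expression variation, and genes are clustered on their
per-region D profiles (Manhattan distance, ward.D linkage, k = 3).

## Allele assembly

SNP records carry a Phred quality; records below `qual_min = 25` are
discarded before substitution (Phred 25 ≈ 0.3% error probability — the
conventional threshold for resequencing SNP matrices). Two sequences are
rebuilt per accession and region: the *variant allele* (alternate alleles
substituted into the reference) and a *reference reconstruction* (the
records' stated reference alleles substituted). The assembly is accepted
only when the reconstruction is 100% identical to the reference — any
mismatch indicates a coordinate or assembly-version error, and the mismatch
positions are reported.

Two conventions needed a decision the data sources leave open:

- **Accessions without a record at a polymorphic site** are assigned the
  reference allele (`mask_missing = FALSE`): variant-only SNP matrices do
  not distinguish "reference call" from "no call", and reference-fill is the
  convention such matrices assume. Setting `mask_missing = TRUE` N-masks
  those cells instead; all diversity statistics then use pairwise deletion,
  so the option mainly trades bias (reference-fill understates diversity if
  no-calls hide variants) against variance.
- **Heterozygous VCF genotypes** take the alternate allele and are counted
  in the skip log. The accession panels this pipeline targets are inbred
  (effectively haploid), so heterozygous calls are rare artefacts rather
  than genuine diplotypes.

Outgroup CDS sequences are projected into reference coordinates via a global
protein alignment (Needleman–Wunsch, match 1 / mismatch −1 / gap −2, ties
broken deterministically: substitution step, then gap in the first sequence,
then gap in the second). Columns where the *reference* protein is gapped are
removed outright; columns where the *outgroup* is gapped become `---`
placeholders, so the projected sequence always has the reference CDS length.
Whether outgroup-deletion columns should be gap-filled or dropped entirely
is not determined by the procedure description we follow; gap-fill was
chosen because it preserves the reference coordinate system, and the gap
codons are excluded pairwise downstream anyway.

## Diversity statistics

For an alignment of n sequences and L sites:

- **S** counts columns with ≥ 2 distinct non-N alleles (missing data do not
  disqualify a column);
- **π** is the mean number of pairwise differences, each pair compared over
  its mutually non-missing sites (pairwise deletion), reported per locus and
  per site;
- **θ~W~ = S/a₁**, a₁ = Σ 1/i;
- **Tajima's D** uses the classical constants a₁…e₂; it is undefined at
  S = 0. A genuine degenerate corner: for n = 3 every biallelic column
  contributes equally to π and θ~W~ *and* the variance constants c₁ = c₂ =
  0, so D is 0/0. The implementation returns `NaN` there; analyses should
  use n ≥ 4, where the statistic is well defined.
- **Significance of D** uses the beta-distribution approximation to the
  neutral null: D is treated as a generalised beta variable with mean 0 and
  variance 1 on [D~min~, D~max~], the all-singleton and balanced-site
  extremes implied by the sample size. The bounds are computed at runtime
  from n (no table lookup); the test suite verifies the quantiles against a
  direct numerical integration of the density.
- **MAF spectra** count the *minor* allele (min of alternate and reference
  counts under the roster), not the derived allele; a singleton is minor
  count 1. Sites that are monomorphic across the roster are excluded and
  counted.

## Sliding windows and group comparisons

Windows (default 200 bp, 100 bp slide) are anchored at the 3′ end of the
region, so the last column sits at offset −1 from the anchor (e.g. the
transcription start site) and a 2.5 kb promoter yields 24 windows starting
at −2500, −2400, …, −200. Per-window π is per site.

The group comparison (`compare_window_profiles`) needed a genuine design
decision: when two accession groups are compared window by window, what is
the unit of replication? Two modes are provided.

- **`mode = "resample"`** (default): each group's windowed π profile is
  recomputed on `n_resample = 100` half-size subsamples of its accessions,
  and per window the focal group's resample distribution is compared to each
  other group's by rank-sum test. Resample index sets are drawn once per
  group *size* and shared between equally-sized groups, which makes the
  comparison paired and guarantees that identical groups compare as
  identical (p = 1). The caveat: resample values are not independent
  replicates, so the p-values quantify the stability of the contrast under
  subsampling, not a population-level error rate.
- **`mode = "windows"`**: within a stated band (e.g. offsets −1600..−500),
  the groups' full-panel per-window π values are compared across windows —
  one test per group pair, windows as replication units. Coarser, but free
  of the resampling caveat.

No multiple-testing correction is applied across windows by default
(`adjust = "BH"` enables Benjamini–Hochberg), matching the descriptive use
of these scans.

The rank-sum test itself is `stats::wilcox.test` behind a fixed policy:
exact enumeration when the smaller sample has ≤ 8 observations and there are
no ties, otherwise the normal approximation with tie and continuity
corrections; two all-identical samples return p = 1. The suite checks the
exact branch against full enumeration of all labelings for every sample-size
split with n ≤ 10.

Latitude bins are left-closed right-open ([40,45), [45,50)) with the last
bin closed ([50,60]); expression groups split RPKM at 137 and 170 within an
overall 50–480 range, same convention.

## The codon-model neutrality test

The GY94 model places a continuous-time Markov chain on the 61 sense codons
of the universal code. Instantaneous rates are zero for multi-nucleotide
changes and otherwise proportional to the target codon's stationary
frequency π~j~, multiplied by κ for transitions and ω for nonsynonymous
changes. Q is scaled to one expected substitution per codon per unit branch
length t. The two-sequence log-likelihood is Σ log(π~c1~ [e^{Qt}]~c1,c2~),
which is root-invariant by reversibility (verified numerically in the
suite, along with agreement of the eigendecomposition-based e^{Qt} with a
plain series expansion to 10⁻⁶).

Fitting maximises over (t, κ) with ω either fixed at 1 or free:

- branch length t is *profiled*: for each (κ, ω) candidate the rate matrix
  is decomposed once and t optimised in one dimension (bounds 10⁻⁶–20,
  log scale), making each outer evaluation cheap;
- the outer search is Nelder–Mead on log parameters from a fixed start grid
  (ω ∈ {0.3, 1, 1.5}, κ = 2; bounds κ ∈ [0.01, 50], ω ∈ [10⁻⁴, 20]),
  deterministic by construction. The free fit additionally starts from the
  fixed fit's solution with ω = 1, which enforces the nesting lnML2 ≥ lnML1
  in practice; `neutrality_test` falls back to the fixed solution should the
  free optimum ever come out lower.
- codon frequencies default to F3x4 (position-specific nucleotide
  frequencies pooled over both sequences, floored at 10⁻⁶), the common
  default of ML codon-model software; equal frequencies are available.

The LRT statistic 2ΔlnML = 2(lnML2 − lnML1) is compared to 2.71, the 5%
critical value of χ²~1~ (`qchisq(0.90, 1)` to two decimals). Model-based dN
and dS follow the standard branch-length decomposition: the nonsynonymous
and synonymous flux proportions under the fitted parameters, divided by the
corresponding mutational-opportunity proportions at ω = 1, times t/3 — so
dN/dS equals the fitted ω identically.

**Calibration.** On data simulated under the model itself, the LRT's
rejection rate at the 2.71 cutoff is asymptotically exactly 10% (ω = 1 is an
interior point, so 2ΔlnML is plain χ²~1~, and 2.71 is its 90th percentile —
the cutoff is *not* conservative for this one-parameter comparison). At 500
codons and t = 0.3 the suite measures mild finite-sample inflation (on the
order of 11–12% over a few hundred replicates, falling to ~6% at 2000
codons); the acceptance suite asserts a ≤ 10% bound at 500 codons and
therefore documents this as a known, understood failure rather than widening
the bound.

The NG86 counting estimator is implemented as an independent cross-check:
synonymous site counts per codon (averaged over both sequences), differences
averaged over all minimal mutation pathways with equal weights — pathways
through stop codons are excluded; if every pathway is blocked, all are used
with the stop steps counted as nonsynonymous — and Jukes–Cantor correction
d = −(3/4)log(1 − 4p/3), undefined at p ≥ 3/4 (flagged). Changes *to* stop
codons count as nonsynonymous opportunities in the site tally. The suite
checks rank agreement (Spearman > 0.8) between NG86 and ML ω across a
simulation grid.

## Structural annotation

Upstream/downstream regions are defined relative to the *coding strand*
(mirrored and reverse-complemented for minus-strand genes): promoter-side
analyses are only meaningful in transcription orientation. Regions running
off a chromosome end are truncated, never padded, and flagged. Intron count
is simply exons − 1.

Tandem duplication requires *both* conditions: at most 5 annotated genes of
any family strictly between the pair, and ≤ 10 kb between their nearest
boundaries (start of the downstream gene minus end of the upstream gene).
Whether such distances should be measured boundary-to-boundary or
start-to-start is ambiguous in common usage; boundary gap is the default and
`distance_mode = "start"` switches the convention.

## Clustering

Per-gene statistic profiles (e.g. Tajima's D for up/CDS/down) are clustered
with Manhattan distances and ward.D linkage — R's `dist`/`hclust` machinery,
i.e. the Lance–Williams ward update applied to the *unsquared* distances,
the same convention the original heatmap-based analyses of such profiles
used. Rows with undefined cells are dropped with a warning rather than
imputed. Raw values are clustered by default; `scale_rows = TRUE` z-scales
first (the choice matters when features are on different scales, which D
profiles are not). The default cut k = 3 reflects the three
constraint classes such profiles typically separate into; it is a parameter,
not a constant.

## The synthetic-data generators

The generators define the study conditions under which the pipeline is
validated:

- **`simulate_coalescent_snps`**: Kingman coalescent (exponential waiting
  times with rate k(k−1)/2, uniform pair merges), infinite-sites mutations
  placed as a Poisson process of total rate θL/2 per unit coalescent time,
  each at a distinct uniform site. This gives the analytic oracle
  E[S] = θLa₁ against which the simulator itself is tested, and known-truth
  input for every downstream stage. Phred qualities: 95% of records uniform
  on [25, 60], 5% uniform on [0, 24.9] — a caricature of a quality
  distribution whose only load-bearing feature is that a known subset falls
  below the 25 threshold.
- **`simulate_codon_pair`**: stationary ancestor, descendant drawn per codon
  from e^{Qt} — exactly the GY94 model used for fitting, with independent
  codons and no rate variation.
- **`simulate_expression`**: log-normal RPKM around group means
  (`noise_sd = 0` returns the means exactly).
- **`generate_gene_table`**: deterministic gene layouts with exact boundary
  gaps, for the tandem-duplication rule.

What they deliberately do *not* emulate — and hence what green tests do not
establish about real data: recombination and linkage (each simulated region
is one genealogy), population structure and sampling bias in the accession
panel, selection within species, sequencing error beyond the quality flag,
alignment error in ortholog pairs, codon-rate heterogeneity, and
multi-nucleotide mutations. Calibration results transfer to real data only
to the degree these assumptions hold there.

Problem sizes in the test and acceptance runs (1000 coalescent replicates at
n = 20, θL = 10; 50 recovery and 200 null codon-pair fits at 500 codons; 20
seeds for the window-band scan) were chosen as the smallest runs at which
the Monte-Carlo standard errors are well below the tolerances being
asserted.

## Reproducibility and numerical notes

- Every generator takes an explicit integer seed and restores the caller's
  RNG state; identical (parameters, seed) give bit-identical output.
- The codon-model fit is deterministic: fixed start grid, fixed ordering,
  no stochastic restarts.
- e^{Qt} is computed by symmetrised eigendecomposition (the chain is
  reversible, so D^{1/2}QD^{−1/2} is symmetric); tiny negative entries from
  round-off are clamped at zero, and probabilities are floored at 10⁻³⁰⁰
  inside logs.
- The LRT clamps small negative 2ΔlnML (< 10⁻⁴, optimisation round-off) to
  zero and errors on anything larger, since a materially negative value can
  only mean the free-model optimiser failed.

## Known limitations

- Pairwise (two-taxon) codon likelihood only; no site/branch models, no
  synonymous rate variation.
- The beta approximation for Tajima's D significance is an approximation;
  at very small n or S its tail behaviour is rough.
- `read_snps` consumes biallelic SNPs only; indels and multi-allelic sites
  are counted and skipped by design.
- The resample-mode window comparison quantifies subsampling stability, not
  a population error rate (see above); treat its per-window flags as
  descriptive.
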