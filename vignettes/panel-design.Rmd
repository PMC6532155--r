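---
title: "Designing and evaluating a medium-density SNP panel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and evaluating a medium-density SNP panel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snpanel)
library(dplyr)
```

`snpanel` implements the design procedure behind medium-density
livestock genotyping arrays of the kind used for Chinese local chicken
breeds: candidate markers are gathered from four sources, placed on the
genome with a windowed even-spacing rule, and the finished panel is
evaluated with the usual array-validation statistics. This vignette
explains the model behind each step, the tunable parameters and their
defaults, what the synthetic-data generators do and do not emulate, and
the numerical conventions the implementation commits to.

## The selection model

### Candidate sources and priority tiers

Markers enter the design from five sources, in two priority tiers plus a
background:

* **Priority 1** — markers with direct evidence of trait relevance:
  GWAS top-fraction hits (`select_gwas_candidates()`), consequence-ranked
  markers in candidate genes (`select_gene_candidates()`), markers
  differentiated between divergent feed-efficiency lines
  (`select_rfi_candidates()`), and a small whitelist of special-interest
  indels.
* **Priority 2** — markers whose allele frequencies separate local
  breeds from commercial lines (`select_resequencing_candidates()`).
* **Background** — database (SNPdb) markers used only to fill windows
  the first two tiers leave empty, with assay-validated markers
  preferred.

`assemble_candidates()` merges the sources, deduplicating positions with
precedence P1 > P2 > background and keeping the losing sources in an
`other_groups` column so provenance survives the merge.

### The frequency-differential screen

For a focal breed with pooled alternate-allele frequency $f_b$ and its
control line with $f_c$, the default screen folds both to minor allele
frequencies and takes the signed difference
$\Delta F = \min(f_b, 1-f_b) - \min(f_c, 1-f_c)$, keeping loci with
focal MAF at least `maf_min` (0.05) and $\Delta F$ at or above the
role's threshold. Local breeds are screened against a commercial
control and commercial lines against a reference local breed, so both
directions of differentiation are represented.

The default thresholds (0.609 for local breeds, 0.731 for commercial
lines) are the values used for the chicken 55K design. On the folded
scale the difference of two MAFs is bounded by 0.5, so these thresholds
can only be met on the unfolded scale; `design_config(delta_f_mode =
"absolute")` switches the screen to $|f_b - f_c|$ on alternate-allele
frequencies (range $[0, 1]$), which is the scale on which thresholds
above 0.5 are attainable. The folded signed difference remains the
default because the screen is described in MAF terms; the mode switch
makes the choice explicit rather than silent. Both modes drop
chromosome-W loci and all indels except whitelist members.

### Gene-based capping

Markers within `gene_flank` (5 kb) of a candidate gene compete within
that gene under a consequence ranking — missense/splice-region, then
splicing, start/stop changes, UTRs, synonymous, 1 kb up/downstream,
introns, everything else — and at most `gene_cap` (5) survive per gene,
with ascending position breaking rank ties. The ranking extends the
stated preference for exonic, splicing and UTR variation to a total
order; beyond the first four ranks the order is a package convention.
A locus inside two flanked genes competes in both and is emitted once.

### The feed-efficiency screen

The published procedure excludes markers below the 5% Fst tail and
those with mean $\Delta F < 0.35$ between divergent lines. We read the
Fst rule as *keeping the top 5%* of the empirical Fst distribution
(`rfi_fst_quantile = 0.95`): this is the only reading consistent with
the reduction from millions of sequenced variants to a few thousand
survivors. When every Fst value is identical the quantile is
degenerate; the function warns and applies only the differential
filter. The bundled `wc_fst()` is the two-population Weir–Cockerham
moment estimator from allele counts, the form suited to pooled
sequencing where genotypes are unavailable; raw (possibly negative)
estimates are preserved, with clamping to $[0,1]$ available for
reporting.

## The placement algorithm

Each chromosome is partitioned left to right into windows of
`window_length` (22 kb). Within a window holding the start $S$ and end
$E$, the placement score of chosen positions is the population variance
of the point set:

$$SD^2 \;=\; \frac{(S-\bar x)^2 + (N_i-\bar x)^2 + (N_j-\bar x)^2 +
(E-\bar x)^2}{4}$$

with divisor equal to the point-set size (4 for a pair, 3 for a single
choice). The rules per window are: zero priority-1 candidates — the
window is reserved empty; one or two — all retained; three or more —
the pair minimising $SD^2$ is retained, found by exhaustive search over
all pairs. Whitelisted indels are always retained and count toward the
two-marker occupancy.

Two conventions deserve comment:

* **Window advancement.** After a window that retained markers, the
  next window starts at the rightmost retained position; after an empty
  window, at the previous window's end. This keeps the spacing between
  a retained marker and the next window's candidates bounded by one
  window length. All candidates falling inside a processed window are
  consumed whether retained or not, so a rejected candidate cannot
  reappear in a later overlapping window, and a window that rejected
  candidates in the first pass is not eligible for the fill passes —
  only truly empty windows are.
* **Midpoint preference.** Minimising the printed criterion prefers one
  or two positions near the window midpoint over a maximally spread
  pair (for candidates at 5.5/11/16.5 kb in a 22 kb window the optimum
  is the 5.5/11 pair, not 5.5/16.5). The implementation follows the
  printed formula exactly, with a brute-force minimiser as the test
  oracle; ties are broken toward the lexicographically smallest
  positions so results are deterministic.

The second pass fills each still-empty window with the single
priority-2 candidate minimising $SD^2$ (equivalently, nearest the
midpoint; lower position on ties). The background pass fills remaining
empty windows with one database marker each, ordered by validated
status, then midpoint proximity, then position. Terminal partial
windows are treated like any other; their end is the chromosome end.

`design_panel()` returns the manifest plus a complete window ledger
(per-window bounds, occupancy per pass, final state), and is
deterministic: identical inputs give byte-identical manifests through
`write_panel_manifest()`.

## Evaluation statistics

* **Quality control** (`qc_filter()`): samples with more than
  `sample_missing_max` (10%) missing genotypes are removed first, so
  that marker statistics reflect the retained cohort; markers then fail
  on call rate (< 0.95), MAF (< 0.05) or the exact Hardy–Weinberg test
  (p < 0.001), with exactly one primary reason recorded per removal in
  that order of precedence. When population labels are present the HWE
  test runs within each population and the smallest p-value is
  thresholded, so genuine population structure is not mistaken for
  typing error. Polymorphism reporting uses the strict rule MAF > 0.05,
  while QC removal uses MAF < 0.05; both conventions are honoured where
  they apply.
* **Exact HWE test** (`hwe_exact_p()`): the standard exact conditional
  test — given sample size and minor-allele count, sum the
  probabilities of all heterozygote counts no more probable than the
  observed one, without mid-p correction. Monomorphic markers return 1.
* **Population structure**: `ibs_distance()` computes identity-by-state
  distances (mean per-locus allele sharing over mutually called loci)
  and `classical_mds()` embeds them by metric MDS (double-centring and
  eigendecomposition, delegated to `stats::cmdscale`). Genotype-derived
  IBS matrices are generally non-Euclidean; negative eigenvalues are
  truncated to zero with a warning.
* **Linkage disequilibrium**: `r2_pair()` is the composite
  (dosage-correlation) estimator — the squared Pearson correlation of
  dosage vectors — chosen because validation genotypes are unphased and
  this matches common array-QC practice; EM haplotype-based r² is out
  of scope. Pairs undefined because a column is constant are excluded
  from bin means rather than zero-filled. `ld_decay_profile()` bins
  intra-chromosome pairs to 40 kb in 5 kb bins by default.

## Synthetic data: what it does and does not emulate

The generators in `sim_config()` exist so every pipeline stage can be
exercised and property-tested without external data.

* **Differentiation** follows the Balding–Nichols model: ancestral
  frequencies uniform on $[0.05, 0.95]$, breed frequencies Beta-drawn
  with differentiation parameter `target_fst` (default 0.10, a typical
  between-breed value for chicken), pool estimates with binomial noise
  at $2 \times$ `pool_size` draws (default 48 diploid individuals per
  breed, matching a pooled-resequencing cohort of three 16-bird pools).
  The model is standard and gives analytic control of the expected
  Fst, which the parameter-recovery tests rely on.
* **Linkage** is first-order haplotype copying: each allele copies its
  left neighbour with probability `ld_copy_rate` (default 0.9), else is
  drawn fresh. This is the cheapest model with monotone distance-decay
  of r² — sufficient to exercise the decay profile — but it has no
  recombination map, no coalescent depth and no allele-frequency
  coupling between loci.
* **Missingness** is uniform at `missing_rate` (default 0.02, matching
  array call rates around 98%); real missingness is clustered by marker
  and sample.
* **Genotyped cohorts** default to `samples_per_pop = 20`, the scale of
  a per-breed validation sample.

Passing tests therefore show that the algorithms recover parameters and
orderings under these controlled conditions — they do not certify
behaviour under ascertainment bias, clustered missingness or real
linkage structure.

Default problem sizes used by the test suite and the acceptance script
— 10,000 loci for Fst recovery, 2,000 loci and 3 populations of 20 for
MDS recovery, 10,000 replicates of n = 500 for the HWE size check,
300-locus chromosomes for LD profiles — are desk-scale choices that
keep the full suite in well under a minute of compute while leaving
sampling error far inside the asserted tolerances.

## Numerical conventions

* Coordinates are 1-based inclusive everywhere inside the package; BED
  export (`export_bed()`) is the only 0-based, half-open surface.
* Missing genotypes are an explicit `NA`, never conflated with dosage
  0; call rates depend on the distinction.
* Printed percentages and kb distances round half away from zero
  (`2.5 -> 3`), matching how array summary tables are conventionally
  printed; base R's round-half-to-even would disagree on boundary
  values.
* In the exact HWE test, heterozygote configurations are included in
  the p-value when their probability is within a relative $10^{-9}$ of
  the observed configuration's, so mathematically tied configurations
  (which arise routinely from symmetry) are never split by floating
  point.
* $SD^2$ tie-breaks are lexicographic toward lower positions; window
  starts are strictly increasing, with a guard that advances to the
  window end if the rightmost retained position equals the window
  start.
* The manifest column set, column order and (chromosome order,
  position) sort are fixed, making byte-identity across runs a testable
  contract.

## Known limitations

* The panel-level reports reproduce published summary arithmetic
  exactly, but panel *contents* from synthetic fixtures are not
  comparable to any real array — candidate positions are random.
* `qc_filter()` recomputes sample missingness only once; after marker
  removal a sample's missing fraction over the retained markers could
  in principle exceed the threshold again. In practice one pass is the
  convention, and the suite verifies idempotence on its outputs in the
  tested regimes.
* Multi-allelic VCF records, phasing information and binary PLINK files
  are out of scope; the VCF reader consumes diploid GT fields only.
* The placement algorithm optimises the printed criterion per window;
  it is not a global spacing optimiser and does not revisit earlier
  windows.
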