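# snpanel

Design and evaluation of medium-density SNP genotyping panels for
livestock, modelled on the design of the chicken 55K array (IASCHICK).

Breeding programmes for local chicken breeds need genotyping arrays that
are cheap, informative for the breeds actually being improved, and evenly
spread across the genome. `snpanel` implements the complete design
pipeline for such an array and the statistics used to validate the
finished product, for geneticists building or evaluating marker panels
from multi-population resequencing data.

## What it implements

**Candidate screening** — four sources of candidate markers:

1. *Resequencing candidates*: pooled allele frequencies per breed are
   screened by minor allele frequency (MAF ≥ 0.05) and by the
   allele-frequency differential ΔF between each focal breed and a
   control line (local breeds vs a commercial control, commercial lines
   vs a local control), with chromosome-W removal and a special-interest
   indel whitelist.
2. *Association candidates*: per trait, the top 1% smallest GWAS
   p-values, unioned over traits.
3. *Gene-based candidates*: markers within ±5 kb of candidate genes,
   ranked by predicted consequence (missense/splice region first, then
   splicing, start/stop changes, UTRs, synonymous, 1 kb up/downstream,
   introns), capped at 5 per gene.
4. *Feed-efficiency (RFI) candidates*: markers in the top 5% of the
   empirical Fst distribution between divergent lines with mean ΔF ≥
   0.35. A two-population Weir–Cockerham estimator from allele counts
   (`wc_fst()`) is included.

**Panel design** — the core placement algorithm. Each chromosome is
walked in 22 kb windows; for one or two priority-1 candidates in a
window both are kept, for three or more the pair (N_i, N_j) minimising
the positional variance criterion

    SD² = [ (S − x̄)² + (N_i − x̄)² + (N_j − x̄)² + (E − x̄)² ] / 4

is kept, where S and E are the window bounds and x̄ the mean of the four
points. After a retaining window the next window starts at the rightmost
retained position. Still-empty windows are filled by the best single
priority-2 candidate, and finally by one database (SNPdb) marker each,
assay-validated markers first.

**Evaluation** — marker/sample quality control (call rate, MAF, exact
Hardy–Weinberg test, sample missingness), per-population polymorphism
summaries, identity-by-state distances with classical MDS for population
structure, and LD-decay profiles from dosage-correlation r².

**Synthetic data** — seeded Balding–Nichols generators for pooled
frequencies, genotype matrices with first-order linkage and missingness,
and complete design-input bundles, so the whole pipeline runs without
external data.

## Worked example

```r
library(snpanel)

cfg <- sim_config(seed = 7)
fx  <- make_design_fixture(cfg)
cand  <- assemble_candidates(fx$candidates, snpdb = fx$snpdb)
panel <- design_panel(fx$genome, cand)
panel
#> <snp_panel> 254 markers on 2 chromosome(s), 179 windows
#>   background     12
#>   priority1     208
#>   priority2      34
#>   empty windows: 2 of 179
glance(panel)
#> # A tibble: 1 × 7
#>   n_snps n_priority1 n_priority2 n_background n_windows n_empty_windows ...
#> 1    254         208          34           12       179               2
```

254 markers were placed: 208 in the trait-linked first pass (at most two
per 22 kb window), 34 breed-differential markers filling empty windows,
and 12 database markers closing the remaining gaps; 2 windows had no
candidate at all. `tidy(panel)` returns the manifest tibble,
`write_panel_manifest()` / `export_bed()` write it, and
`per_chromosome_summary()`, `group_composition()`,
`annotation_summary()` and `panel_overlap()` reproduce the standard
descriptive tables. For a genotyped validation cohort:

```r
gm  <- simulate_genotypes(cfg, simulate_population_frequencies(cfg, 3))
res <- qc_filter(gm)                  # samples, then markers
polymorphism_summary(res$genotypes)   # call rate, polymorphic loci, MAF
mds <- classical_mds(ibs_distance(gm), k = 2)
autoplot(mds, populations = gm$samples$population)
plot_ld_decay(ld_decay_profile(gm))
```

A thin command-line wrapper with subcommands `simulate`, `prep`,
`design`, `report`, `overlap`, `qc`, `mds` and `ld` is installed at
`inst/cli/snpanel.R`.

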