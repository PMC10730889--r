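# chromkinetics

Kinetic analysis of histone-mark and chromatin-accessibility time courses
after acute protein degradation.

## What problem this solves

Degron (PROTAC) systems remove a chromatin regulator within minutes, so the
interesting question shifts from *whether* a mark depends on it to *how
fast* each locus responds and in what order downstream states follow. The
motivating setting is acute loss of the COMPASS/KMT2 core subunit ASH2L in
fibroblasts: promoters lose H3K4me3 with locus-specific half-lives, then
gain H3K4me1, then lose H3K27ac, while H3K27me3 appears late and sparsely
and promoter accessibility slowly declines. `chromkinetics` provides the
downstream statistics of such an experiment for analysts working from peak
sets, count tables and fragment files (post-alignment, post-peak-calling):

- **Normalization** — minimum-coverage scaling for ChIP/ATAC
  (`size_factors_min_coverage()`), ERCC spike-in median-of-ratios for RNA
  (`size_factors_spike_in()`).
- **Differential signal** — a self-contained per-site negative-binomial
  Wald test with fixed dispersion and per-contrast Benjamini–Hochberg
  correction (`nb_wald_test()`, `differential_timecourse()`). A site is
  called changed when `q < 0.05` and `|log2FC| > 0.58` (both strict).
- **Annotation** — signed midpoint distance to the nearest TSS, promoter
  attribution within ±1 kb, CpG-island promoters, intergenic filtering
  (>3 kb), all on BED-convention half-open coordinates.
- **Kinetic classes** — *fast* promoters lose H3K4me3 significantly by the
  2 h contrast; *slow* ones first at 16 h with no earlier loss
  (`classify_fast_slow()`); intensity tertiles high/medium/low
  (`tertile_split()`); per-class trajectory and expression summaries.
- **Enhancers** — merged triple intersection of H3K4me1, H3K27ac and ATAC
  peaks, excluding TSS ±1 kb windows (`define_enhancers()`), with overlap
  summaries for changed intergenic sites.
- **ATAC fragment structure** — nucleosome-free (<120 bp) vs
  mono-nucleosome (130–200 bp) partitioning (`partition_fragments()`) and
  CPM-scaled TSS/enhancer metaprofiles (`tss_metaprofile()`).
- **Synthetic data** — `simulate_experiment()` generates a full annotated
  genome, per-mark count time courses with exponential H3K4me3 decay
  (bimodal half-lives 1.5 h / 12 h, 10% residual plateau), delayed
  H3K4me1/H3K27ac responses, ATAC fragments and spike-in RNA, plus ground
  truth for every label — so the whole pipeline is testable end to end.

The statistical core, the two-group NB model with log link and fixed
dispersion α, tests H₀: β = 0 in
`log μ_ij = log s_j + β₀ + β x_j`, `Var(y) = μ + αμ²`,
by Wald z against N(0,1); see `vignette("methods")` for why this replaces
a DESeq2 call here and how the dispersion is pooled.

## Worked example

```r
library(chromkinetics)

cfg <- simulation_config(seed = 1, n_promoters = 500, n_enhancers = 80,
                         chrom_length = 5e6)
run <- run_pipeline(cfg)
run
#> chromkinetics run report (seed 1 )
#>   H3K4me3: 2342 changed site-contrasts over 8 timepoints
#>   H3K4me1: 1159 changed site-contrasts over 8 timepoints
#>   H3K27ac: 1470 changed site-contrasts over 8 timepoints
#>   H3K27me3: 1 changed site-contrasts over 8 timepoints
#>   ATAC: 534 changed site-contrasts over 8 timepoints
#>   kinetic classes: fast=212, slow=134, other=154
#>   enhancers: 80

head(run$classes)
#>   promoter_id speed_class tertile
#> 1   prom_0001       other    high
#> 2   prom_0002        fast  medium
#> 3   prom_0003        fast     low

run$cgi_stratification
#>   direction n_cgi n_non_cgi n_total fraction_cgi
#> 1      gain     0         0       0          NaN
#> 2      loss   385       100     485    0.7938144

subset(run$trajectories$H3K4me3, timepoint_h %in% c(2, 16))
#>    class timepoint_h   n      median         q1          q3
#> 3   fast           2 212 -1.17461750 -1.3770147 -0.98767617
#> 6   fast          16 212 -3.28000766 -3.5522456 -2.97983985
#> 11  slow           2 134 -0.06299617 -0.2877763  0.09295661
#> 14  slow          16 134 -1.13955617 -1.3409719 -0.94731974
```

Reading this: of 500 simulated promoters, 212 lose H3K4me3 significantly
already at 2 h (fast) and 134 first at 16 h (slow). 79% of the promoters
with H3K4me3 loss at 16 h are CGI promoters. The trajectory table shows
the kinetic separation: at 2 h the fast class has already lost more than
half its signal (median log2FC −1.17) while the slow class is flat
(−0.06); by 16 h the slow class reaches the level the fast class had at
2 h. H3K27me3 barely changes, as intended — it responds late and only at
a sparse promoter subset.

The same analysis runs from the shell:

```sh
Rscript inst/scripts/chromkinetics all --seed 1 --out results/
# writes results/report.json, kinetic_classes.tsv, enhancers.bed,
# per-mark differential tables, and the simulated input files
```

Real data enter through the readers instead of the generator:
`read_bed()`, `read_narrowpeak()`, `read_cpg_islands()` (UCSC
cpgIslandExt, with or without the bin column), `read_counts()` (counts TSV
plus sample sheet), `read_tss()`.

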