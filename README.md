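# homoeologr

Duplicate-gene expression analysis for a resynthesized allopolyploid and
its two diploid parents. When an A-genome and a C-genome diploid merge
into an AACC allotetraploid (the resynthesized *Brassica napus* model),
every gene becomes a homoeolog pair; `homoeologr` classifies what happens
to each pair's expression, from replicate FPKM tables alone:

* **Differential expression** between each subgenome and its parent
  (Student's t-test on log2(FPKM+1), Benjamini–Hochberg FDR ≤ 0.05,
  |log2FC| ≥ 1), after the conventional FPKM ≥ 1 expression filter.
* **Homoeolog expression bias**: ternary t-test calls (P ≤ 0.05) on
  `A_r` vs `C_o` (parents) and `A_n` vs `C_n` (progeny), with
  maintained / novel / reverted / switched transitions.
* **Expression level dominance (ELD)**: the twelve-category decision
  table on `S = A_n + C_n` versus each parent — no change, ELD toward
  either parent (higher- or lower-expressing), additivity, and
  transgressive expression up/down oriented by the parents' comparison.
* **ELD explanation**: per-homoeolog changes (`A_n` vs `A_r`, `C_n` vs
  `C_o`) and mechanism labels (dominant homoeolog down, nondominant up,
  nondominant down, both down), with the cross-tabulations and overlapping
  mechanism sums used in the allopolyploid literature.
* **Term enrichment**: one-sided hypergeometric tests over GMT gene sets,
  BH-adjusted, enriched at FDR ≤ 0.001.
* **Chromosome integrity**: 10-kb window mean-depth ratios between
  polyploid and parent resequencing tracks (samtools-depth dialect).
* **Synthetic data**: a template-based simulator with lognormal replicate
  noise and exact-mean ground-truth labels for every pair, so the whole
  pipeline is testable without sequencing data.

Everything is tidyverse-native: data frames in, tibbles out, `tidy()` /
`glance()` / `autoplot()` on the pipeline result.

## Worked example

```r
library(homoeologr)

ds  <- simulate_expression(sim_config(n_pairs = 2000, seed = 1))
res <- analyze_homoeologs(ds$pair_map, ds$expr_parentA, ds$expr_parentC,
                          ds$expr_polyploid)
res
#> <homoeolog_analysis> 1918 of 2000 pairs expressed (FPKM >= 1), alpha = 0.05
#>   ELD groups: NoChange 839 (43.7%), ELD_A 424 (22.1%), ELD_C 406 (21.2%),
#>     Additivity 89 (4.6%), TransUp 136 (7.1%), TransDown 24 (1.3%)
#>   progeny bias: A_biased 356 (18.6%), C_biased 352 (18.4%), no_bias 1210 (63.1%)
```

1,918 of the 2,000 simulated pairs pass the FPKM ≥ 1 filter (the simulator
plants a below-cutoff template on purpose). Of those, 43.7% show no
dominance, 43.3% show ELD toward one of the parents, and additivity and
transgressive expression make up the rest; 36.9% of pairs are biased
toward one homoeolog in the progeny. Per-pair calls and ground truth line
up like this:

```r
tidy(res)[1:3, c("pair_id", "transition", "category", "group", "mechanism")]
#> # A tibble: 3 x 5
#>   pair_id   transition category group    mechanism
#>   <chr>     <chr>      <chr>    <chr>    <chr>
#> 1 pair00001 maintained II       ELD_C    other
#> 2 pair00002 maintained NoChange NoChange <NA>
#> 3 pair00003 reverted   II       ELD_C    nondominant_up

truth <- ds$truth[match(res$eld$pair_id, ds$truth$pair_id), ]
mean(res$eld$category == truth$truth_category)
#> [1] 0.9124088
```

At the default study conditions (3 replicates, CV 0.2, 4-fold templates)
the pipeline recovers ~91% of true categories; with `cv = 0` it recovers
100% of them exactly.

## Layout

| path | contents |
|------|----------|
| `R/` | simulator, IO, statistical primitives, DEG calling, pair classification, summaries/enrichment, coverage, pipeline wrapper and plots |
| `inst/extdata/` | published reference counts used by the arithmetic identities |
| `tests/testthat/` | unit, property and acceptance suites |
| `scripts/acceptance.R` | headline-number reproduction |
| `vignettes/homoeolog-expression.Rmd` | methods: models, decision tables, defaults, simulator scope and limitations |
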