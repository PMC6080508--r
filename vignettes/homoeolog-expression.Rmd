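---
title: "Classifying duplicate-gene expression in a resynthesized allopolyploid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying duplicate-gene expression in a resynthesized allopolyploid}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(homoeologr)
library(dplyr)
```

## The biological question

When two diploid species hybridise and double their genomes, the resulting
allopolyploid carries two complete parental gene sets. For the Brassica
model considered here, an A-genome parent (*B. rapa* type) and a C-genome
parent (*B. oleracea* type) merge into an AACC allotetraploid resembling
resynthesized *B. napus*. Each gene is now present as a homoeolog pair: an
A-subgenome copy and a C-subgenome copy. Two questions dominate the first
generations after the merger:

1. **Homoeolog expression bias** — within the allopolyploid, do the two
   copies contribute equally (`A_n` vs `C_n`), and how does that compare
   with the relative expression of the orthologs in the parents
   (`A_r` vs `C_o`)?
2. **Expression level dominance (ELD)** — does the *total* expression of
   the pair in the allopolyploid, `S = A_n + C_n`, resemble one parent, sit
   between them (additivity), or exceed both (transgressive expression)?

`homoeologr` implements the complete decision pipeline for these questions
over replicate FPKM tables, together with differential-expression calling
between each subgenome and its parent, hypergeometric term enrichment for
the resulting gene lists, and a window-based coverage-depth check of
chromosome integrity. A synthetic-data generator with exact ground truth
makes every stage testable without sequencing data.

## The comparison atom

Every classification is assembled from one primitive: a two-sample
Student's t-test on replicate expression values turned into a ternary call
(`LT` / `EQ` / `GT`) at a significance level `alpha = 0.05`. `EQ` means
"not distinguishable at `alpha`", which matches how such pair analyses are
conventionally run: a raw per-pair threshold of P <= 0.05, with no
multiple-testing correction across pairs (the DEG and enrichment modules,
by contrast, do correct with Benjamini–Hochberg, at FDR 0.05 and 0.001
respectively). The tests for bias and ELD run on raw FPKM replicate values;
DEG calling tests `log2(FPKM + 1)` values, the usual variance-stabilising
convention for fold-change-oriented comparisons.

Two deliberate conventions make noise-free data classify exactly:

* **Degenerate variance.** If the pooled variance is zero, the test is
  undefined; we set `p = 1` when the two means are equal and `p = 0`
  otherwise. With zero simulated noise the pipeline therefore reproduces
  the exact-mean classification, which is the basis of the oracle tests.
* **Numerical equality tolerance.** "Equal" in the degenerate branch (and
  in the exact-mean oracle) means equal to a *relative* tolerance of 1e-9.
  Pair totals such as `0.7m + 0.3m` differ from `1.0m` at the last floating
  point bit; a strict `==` would turn rounding noise into spurious
  dominance calls. Similarly, a standard error below 1e-9 relative to the
  means is treated as zero, since replicate vectors of identical values can
  acquire rounding-level variance through the mean computation. Real
  replicate data never sits within 1e-9 of exact equality, so the tolerance
  is invisible outside the noise-free regime.

## The decision tables

With `d1 = dir(S vs A_r)`, `d2 = dir(S vs C_o)` and `dAC = dir(A_r vs C_o)`:

| `d1` | `d2` | category | group |
|------|------|----------|-------|
| EQ | EQ | NoChange | NoChange |
| EQ | GT | IV | ELD_A (higher parent) |
| EQ | LT | IX | ELD_A (lower parent) |
| GT | EQ | II | ELD_C (higher parent) |
| LT | EQ | XI | ELD_C (lower parent) |
| GT | LT | I | Additivity (A_r < S < C_o) |
| LT | GT | XII | Additivity (C_o < S < A_r) |
| GT | GT | V / VI / VIII | TransUp, split by `dAC` = LT / EQ / GT |
| LT | LT | III / VII / X | TransDown, split by `dAC` = LT / EQ / GT |

Only the two S-versus-parent comparisons decide dominance and additivity;
the parents' own comparison `dAC` is used to orient the transgressive
subclasses and to set a `consistent` flag. The flag is lowered when `dAC`
*significantly contradicts* the geometry a category implies (e.g. category
IV implies `A_r > C_o`, so an observed significant `A_r < C_o` is
contradictory); a non-significant `EQ` is not treated as a contradiction,
because failing to reject is weak evidence. Pairs whose total is
indistinguishable from both parents are always filed as NoChange, even if
the parents differ from each other — the flag, not the category, records
the tension. The Roman numerals follow the twelve-state layout convention
of the cotton allopolyploid literature; the group labels are the
authoritative output.

Bias works on the same atom: `A_r` vs `C_o` gives the parental state,
`A_n` vs `C_n` the progeny state (each `A_gt` / `EQ` / `C_gt`), and the
transition is `maintained` (same state), `novel` (parents equal, progeny
biased), `reverted` (parents biased, progeny equal) or `switched` (bias
flipping subgenome). For three-way summaries in the conventional style,
`switched` is folded into `novel` — both are newly arisen progeny states —
while the four-way table is kept alongside.

For ELD pairs, the *explanation* stage compares each homoeolog with its
own parent (`A_n` vs `A_r`, `C_n` vs `C_o`). Calling the homoeolog from
the matched parent "dominant": higher-parent dominance can arise from the
dominant homoeolog going down (`dominant_down`), the nondominant one going
up (`nondominant_up`) or both at once; lower-parent dominance from the
nondominant homoeolog going down alone (`nondominant_down`) or both going
down (`both_down`). A pure `nondominant_up` with an unchanged dominant
homoeolog is geometrically impossible for an exact-mean pair (the total
would exceed the matched parent), which is why the simulator's
"nondominant up" template also moves the dominant copy down — the
mechanism *totals* reported by `summarize_explain()` count overlapping
sums, exactly as such cross-tabulations are conventionally reported.

## Thresholds and defaults

| parameter | default | meaning |
|-----------|---------|---------|
| `alpha` | 0.05 | per-pair ternary t-tests |
| `expr_cutoff` | 1 FPKM | replicate-mean expression filter |
| `fdr_cutoff` (DEG) | 0.05 | BH threshold per subgenome comparison |
| `lfc_cutoff` | 1 bit | absolute log2 fold change for DEG status |
| `pseudocount` | 1 FPKM | log2 fold change stabiliser |
| `fdr_cutoff` (enrichment) | 0.001 | BH threshold for term enrichment |
| `window_size` | 10 kb | coverage windows |
| `low_cutoff` | 0.25 | depth-ratio "low" flag |

A pair counts as expressed when any of the three species reaches the
cutoff; at the polyploid level the per-replicate *pair total* `A_n + C_n`
is used, the same quantity the ELD comparison tests, so a pair whose two
homoeologs individually sit just below the cutoff but jointly above it is
retained. "Expressed" for a single table is the replicate mean reaching
the cutoff — the common FPKM convention when per-replicate rules are not
stated. BH correction for DEGs is applied separately within each
subgenome-versus-parent comparison, since the two comparisons are separate
experiments with separate gene universes.

## The synthetic-data generator

`simulate_expression()` draws, for each pair, a *template* — a quadruple
of true means `(A_r, C_o, A_n, C_n)` whose exact-mean classification is
the pair's ground truth — then a base expression level `m` log-uniform on
[2, 500] FPKM, and finally per-replicate values
`true mean * exp(N(0, sigma^2))` with `sigma = sqrt(log(1 + cv^2))`, i.e.
multiplicative lognormal noise with coefficient of variation `cv`. The
defaults are three biological replicates, `cv = 0.2` and a template fold
change of 4. Replicate dispersion of FPKM data is not something the
classification thresholds pin down, so `cv = 0.2` is a convention — a
typical magnitude for bulk RNA-seq biological replicates — not a measured
value; the same applies to the fold change inside templates.

The default template mix mirrors the category composition observed in a
resynthesized *B. napus* allotetraploid (about 46% of expressed pairs
unchanged, 40% ELD, 5% additive, 9% transgressive and almost none
transgressive-down), with small slices for novel- and switched-bias
geometries and a below-cutoff `low_expression` template that exercises the
expression filter. Truth labels are never asserted by hand: every template
stores the output of the exact-mean oracle `truth_label()`, and a test
recomputes them.

What the generator does *not* emulate: count-based overdispersion
(negative binomial mean–variance coupling), mapping or homoeolog-assignment
errors, correlated replicates, and length/library-size effects hidden
inside FPKM. Passing the recovery tests therefore demonstrates that the
decision logic is correct and well calibrated under clean lognormal
replicate noise — not that any particular recovery rate will be achieved
on real sequencing data, where assignment error and dispersion are larger
and structured.

```{r}
ds <- simulate_expression(sim_config(n_pairs = 2000, seed = 1))
res <- analyze_homoeologs(ds$pair_map, ds$expr_parentA, ds$expr_parentC,
                          ds$expr_polyploid)
res
```

```{r}
truth <- ds$truth[match(res$eld$pair_id, ds$truth$pair_id), ]
mean(res$eld$category == truth$truth_category)
```

At the default conditions the pipeline recovers roughly 90% of true
categories; with `cv = 0` it recovers all of them (the oracle-equivalence
test). Misclassification concentrates where it should: EQ calls are
non-rejections, so each truly-equal comparison is misread with probability
`alpha`, and the additivity categories — whose totals sit closest to the
parents — lose the most power at 3 replicates.

## Coverage windows

`simulate_depth()` draws independent per-base Poisson depths;
`window_means()` tiles each chromosome with half-open 10-kb windows
(0-based internally; the on-disk track is 1-based, headerless,
samtools-depth style), counting absent bases as zero and averaging the
final partial window over its real width. `depth_ratio()` reports the
window-wise ratio between two tracks — allopolyploid over parent — with
`missing_num` / `missing_den` flags rather than silent drops when a window
has zero coverage, and an optional library-size normalisation that is off
by default because the integrity statistic is a plain ratio. Poisson
sampling reproduces the shot-noise component of real resequencing depth
but none of its mappability or GC structure, which is all the integrity
check needs: a present chromosome scatters around a constant, a missing
one collapses to zero.

## Problem sizes used by the test suite

The shipped tests run the oracle-equivalence comparison on 5,000
noise-free pairs over every default template, category recovery on 10,000
pairs at the default conditions, null calibration on ten simulations of
5,000 pairs (bias) and 2,000 genes (DEGs), mirror-symmetry on 1,000 random
pairs, and exhaustive brute-force cross-checks of the statistical
primitives; the whole suite completes in well under a minute. These sizes
give Monte-Carlo standard errors a few times smaller than the margins
being tested while keeping the suite quick.

## Known limitations

* The t-test machinery deliberately replaces heavier count-model DE
  pipelines; with three replicates its power profile, not the FDR control,
  is the binding constraint.
* FPKM input is taken at face value: no re-normalisation across species,
  which mirrors the conventional workflow but inherits its compositional
  caveats.
* Enrichment treats the gene–term map as given (no ontology propagation or
  redundancy reduction); a term blacklist can be applied upstream by
  filtering the map.
* The twelve-category table is a classification of point comparisons, not
  a generative model; pairs near thresholds flip categories under
  resampling, which is why summaries should be read at the cohort level.
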