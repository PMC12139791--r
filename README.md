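# cpmshift

Quantifying how a within-subject pharmacological manipulation shifts
connectome-based network signatures.

## The problem

Connectome-based predictive modeling (CPM) summarises a functional
connectome through fixed, published binary edge masks: *network strength* is
the mean Fisher z-transformed correlation over a mask's edges, e.g. the
high- and low-attention networks of the sustained-attention CPM. In a
placebo-controlled crossover design, every subject is scanned under both a
drug (MA) and a placebo (PL) condition, and the questions are:

* does the drug shift network strength within subjects
  (paired t-tests, Cohen's *d* = mean(Δ)/sd(Δ))?
* are the shifts selective, compared against an 8×8 grid of canonical
  resting-state network pairs, Bonferroni-corrected at α = 0.05/64?
* can a linear SVM tell the two conditions apart from the edge vectors,
  with paired leave-one-subject-out cross-validation and a label-flip
  permutation null?
* do the classifier's top-weight edges overlap published attention/arousal
  networks more than chance, under the hypergeometric tail test
  P(X ≥ x) with M = 268·267/2 = 35,778 possible edges?

`cpmshift` implements this pipeline end to end for parcellated node time
series, plus signal-detection scoring (d′) of the go/no-go sustained
attention task, run-level motion QC, and a synthetic-data generator that
plants condition effects on designated mask edges so the entire chain is
testable without any scanner data.

## Worked example

Simulate a 20-subject crossover cohort at 40 nodes with the default planted
effect (calibrated to a within-subject Cohen's *d* ≈ 1), then run the whole
pipeline:

```r
library(cpmshift)

cfg <- synth_config(n_subjects = 20, n_nodes = 40, seed = 42)
dataset <- gen_condition_dataset(cfg)
out <- run_pipeline(dataset, n_perm = 99, seed = 42)

out$tests
#>   measure   estimate         t df            p  cohens_d  n
#> 1    high  0.1483501  6.891357 19 1.425299e-06  1.540954 20
#> 2     low -0.1646056 -8.526626 19 6.419567e-08 -1.906611 20
#> 3    diff  0.3129557  7.799104 19 2.440108e-07  1.743933 20

out$classifier
#> <classifier_report> 20 subjects, 40 held-out scans, accuracy 85.00%
#>   permutation null: 99 draws, p = 0.01
```

High-attention strength rises and low-attention strength falls under the
drug (t(19) = 6.9 and −8.5), the difference score shifts by 0.31 Fisher-z
units, and the paired leave-one-subject-out SVM separates the conditions at
85% accuracy with the smallest attainable add-one permutation p
(1/(1+99) = 0.01). The overlap table (`out$overlap`) then tests the selected
edges against the planted attention and arousal masks, e.g.:

```r
head(out$overlap, 2)
#> # A tibble: 2 × 7
#>   pair             network_1          K network_2     n     x        p
#>   <chr>            <chr>          <int> <chr>     <int> <int>    <dbl>
#> 1 high_vs_positive high_attention    17 positive     19    11 5.82e-16
#> 2 low_vs_negative  low_attention     14 negative     19    12 4.64e-20
```

The classifier's top-weight edges recover the planted masks: 11 of the 19
selected positive edges fall in the 17-edge high-attention mask (chance
would put ~0.04 there), so the enrichment tail is vanishingly small.

The published-scale worked example of the overlap test is a one-liner — the
probability that a 757-edge network shares at least 5 edges with a 135-edge
network by chance:

```r
hypergeom_overlap_p(x = 5, K = 757, n = 135, M = total_edges(268))
#> [1] 0.1588896
```

A thin command-line dispatcher over the same functions lives at
`inst/cli/cpmshift.R` (subcommands `simulate`, `fc`, `strength`, `compare`,
`classify`, `overlap`).

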