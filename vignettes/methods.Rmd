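---
title: "Methods: paired-condition shifts in connectome-based network signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired-condition shifts in connectome-based network signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpmshift)
```

## The analysis problem

Within-subject pharmacological designs ask whether a drug shifts a subject's
whole-brain functional organisation relative to a placebo session of the same
person. `cpmshift` implements the network-level toolchain for such designs
when the connectome is summarised through *connectome-based predictive
modeling* (CPM): fixed, published binary edge masks (for example the high-
and low-attention networks of the sustained-attention CPM) are applied to
each subject's functional connectome, and the mean connectivity over each
mask — the *network strength* — becomes the unit of inference.

The pipeline covers five stages:

1. **Connectome construction.** Functional connectivity between two
   parcellation nodes is the Fisher z-transformed Pearson correlation of
   their time series, $z_{ij} = \operatorname{atanh}(r_{ij})$, computed per
   run and session. Runs failing motion quality control are excluded; for
   two-run tasks the usable runs are averaged.
2. **Network strength and difference scores.** For a mask $E$ with edge set
   on the upper triangle, strength is $\bar z_E = |E|^{-1} \sum_{(i,j) \in E}
   z_{ij}$. The attention *difference score* is high-mask strength minus
   low-mask strength; a fixed linear model (coefficient and offset shipped
   with the published masks) maps it to a predicted task sensitivity.
3. **Paired inference.** Per-measure paired t-tests (one-sample on
   within-subject differences, two-tailed, Cohen's
   $d = \bar\Delta / s_\Delta$), plus a canonical-network grid contrast:
   an 8×8 grid of mean connectivity per network pair, cellwise paired
   t-tests, Bonferroni-corrected at $\alpha = 0.05/64$.
4. **Condition classification.** A linear soft-margin SVM on vectorised
   upper-triangle edges with paired leave-one-subject-out cross-validation
   (both of a subject's scans held out together), a pair-flip permutation
   null for the accuracy, fold-averaged primal weights, and extraction of
   the top positive/negative weighted edges as masks.
5. **Edge-set overlap.** Hypergeometric tail tests of whether two edge sets
   share more edges than chance given $M = \binom{268}{2} = 35{,}778$
   possible edges.

Behavioural sustained attention is scored from go/no-go trial tables with
signal-detection sensitivity $d' = \Phi^{-1}(\text{hit rate}) -
\Phi^{-1}(\text{false-alarm rate})$.

## Statistical conventions and why

**Hypergeometric tail convention.** For overlap $x$ between sets of $K$ and
$n$ edges out of $M$, the package reports the enrichment tail
$P(X \ge x) = 1 - F(x-1)$ by default. The alternative strict tail
$P(X > x) = 1 - F(x)$ is exposed via `convention = "greater"`. The default
is the convention under which published worked examples of this test are
internally consistent: for instance $(K, n, x) = (757, 135, 5)$ gives
$P(X \ge 5) = 0.159$ while $P(X > 5) = 0.068$.

```{r}
hypergeom_overlap_p(5, 757, 135, total_edges(268))
```

**QC boundaries are strict.** A run is excluded when maximum censored
displacement *exceeds* 3 mm, mean censored motion *exceeds* 0.15 mm, or
*more than* 50% of frames are censored; a run exactly at a bound is kept.
Whether missing parcellation nodes exclude a whole run or only those nodes
is design-dependent, so both behaviours exist (`strict_nodes`); the default
keeps the run and drops NaN edges from mask means, with the usable edge
count reported alongside every strength.

**Degenerate correlations.** $r = \pm 1$ has infinite Fisher z; correlations
are clipped to $\pm(1 - 10^{-7})$ before `atanh`, keeping downstream
averages finite while leaving ordinary values untouched (the clip moves
nothing below $|r| < 1 - 10^{-7}$).

**Undefined strengths stay undefined.** A mask whose usable edges are all
missing yields `NA`, never silently 0, because small masks can be emptied by
missing nodes.

**Paired t-tests** use $df = n - 1$ and two-tailed p-values throughout, with
the paired-design effect size $d = \bar\Delta / s_\Delta$ (so $t = d\sqrt
n$). The grid contrast deliberately corrects over the full 64-cell family,
symmetric duplicates included, mirroring the conventional 8×8 presentation
of such grids rather than the 36 unique cells.

**Extreme-rate correction** for $d'$ uses the standard 1/(2N) rule: a hit or
false-alarm rate of 0 becomes $1/(2N)$ and a rate of 1 becomes $1 - 1/(2N)$
with $N$ the trial count of that type. Median splits send subjects strictly
above the median to the high group and ties at the median to the low group —
a deterministic, documented convention.

**Classifier choices.** Linear kernel, $C = 1$ by default, no feature
standardisation (Fisher-z edges already share a scale), all exposed as
arguments. Fold weight vectors are averaged as-is without sign alignment;
with a fixed label orientation (positive decision = drug condition) the
primal weights of different folds are directly comparable. The permutation
scheme flips each subject's label pair independently with probability 1/2,
which preserves the exchangeability structure of a paired design; a full
label reshuffle is available as an option. The permutation p-value uses the
add-one estimator $(1 + \#\{A_{perm} \ge A_{obs}\})/(1 + B)$ and is
therefore never exactly zero.

**Edge selection** supports the two rules seen in practice: absolute weight
cutoffs (e.g. $> 0.0020$ and $< -0.0023$) and a percentile rule taking
$\lfloor q\% \cdot n_{\text{finite}} \rfloor$ edges per side. The two rules
generally produce very different edge counts (2.5% of 35,778 edges is 894
per side); both are first-class because published analyses describe
selections in both vocabularies, and the absolute rule is what printed edge
counts can be reproduced from.

## The synthetic-data generator

No raw fMRI is shipped or downloaded: every downstream stage is exercised on
synthetic cohorts with planted effects, generated by `gen_condition_dataset()`.

The generative model:

* A base correlation matrix $R_0$ shared by all subjects, from a rank-3
  factor model $\mathrm{cov2cor}(LL^\top + I)$ with loadings
  $\mathcal N(0, 0.35^2)$ — mild, mixed-sign correlations typical of
  parcellated BOLD data.
* Disjoint high/low attention masks drawn uniformly at random (published
  268-node sizes 757/630, scaled proportionally to $\binom{n}{2}$ at other
  node counts), plus independently drawn arousal (469/555) and valence
  mask pairs whose overlap with the attention masks is therefore itself
  hypergeometric.
* In the drug condition, correlations on high-mask edges are raised and on
  low-mask edges lowered by $e \cdot m_s$, where $e$ is `effect_size` and
  $m_s \sim \mathcal N(1, h^2)$ is a subject-level multiplier with $h$ =
  `heterogeneity`. $m_s$ is drawn once per subject and shared across run
  types, which is what makes drug-induced changes correlate across rest and
  task contexts. Entries are clipped to $\pm 0.97$ and the matrix is
  repaired to the nearest positive-definite correlation matrix only when a
  Cholesky check fails.
* Node time series are $T \times n$ Gaussian draws coloured by the Cholesky
  factor; the default $T = 210$ emulates a 7-minute run at a 2-second
  sampling interval. Go/no-go trials come from an equal-variance
  signal-detection observer (hit probability $\Phi(d'/2 - c)$, false-alarm
  probability $\Phi(-d'/2 - c)$) over 750 trials with 10% no-go.

**Calibration.** Because strengths average hundreds of edges, estimation
noise in the difference score is small and the paired effect size is
governed almost entirely by the subject multiplier: $d \approx 1/h$. The
defaults `effect_size = 0.11`, `heterogeneity = 1.0` were fixed once by
simulating the generator itself so that the within-subject high-minus-low
contrast lands at Cohen's $d \approx 1$ with 40 subjects at the package's
40-node test scale — a realistic magnitude for a strong pharmacological
network effect — and were not revisited afterwards. With `effect_size = 0`
the generator is an exact null (both conditions share one covariance), which
is what the type-I-error and classifier-calibration checks rely on.

**What the generator does not emulate.** Haemodynamics, autocorrelated BOLD
noise, motion artefacts (QC metrics are planted metadata, not derived from
the signals), spatial structure of the parcellation, scanner drift, and
individually distinct connectomes beyond a scalar effect multiplier. Passing
tests therefore certify the statistical machinery — estimator correctness,
calibration under a true null, power under a planted alternative — not
performance on real fMRI.

## Problem sizes used by the test suite

Simulation-backed checks run at desk scale, chosen so the full suite stays
in the tens of minutes on one core: power and type-I calibration at 40
subjects × 40 nodes (200 and 500 replicates), classifier calibration at 20
subjects × 40 nodes (200 null replicates), the permutation-uniformity study
at 12 subjects × 16 nodes with 99 permutations × 200 replicates, and d′
recovery over 500 simulated 750-trial runs. Full 268-node generation is
supported but exercised only where cheap (mask generation, selection
counting).

## Known limitations

* The uniformity of permutation p-values is approximate at small sample
  sizes: cross-validated accuracy takes few distinct values, ties between
  observed and permuted accuracies are common, and the add-one estimator is
  deliberately conservative, so the null p-value distribution is slightly
  super-uniform. This is a property of the estimator, not a defect; the
  test suite checks approximate uniformity at a scale where the
  discreteness is tolerable.
* The published linear model mapping difference scores to predicted d′
  ships its constants with the published masks, not with this package;
  `sacpm_model()` defaults are placeholders and real analyses must supply
  the published coefficient and offset.
* Classifier fold weights are averaged without sign alignment. With a fixed
  label orientation this is well-defined, but fold weight instability in
  near-null data makes the averaged map noisy — the same caveat applies to
  any fold-averaged linear weight map.
* `combine_doors()` averages Fisher-z matrices elementwise; it does not
  weight by run length, matching the convention of averaging two runs of
  equal design length.
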