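---
title: "Finding MTI-supported tissues by correlation loss minimisation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Finding MTI-supported tissues by correlation loss minimisation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tissuescope)
```

## The problem

MicroRNAs suppress their target mRNAs through translational repression or
degradation, so the expression of a miRNA and a validated target should be
negatively correlated. Across a heterogeneous tissue panel, however, the
correlations of experimentally validated miRNA–target interactions (MTIs)
cluster around zero: down-regulation is not equally active everywhere. The
working model of this package is that each miRNA has a set of *MTI-supported
tissues* — a tissue subset in which it actively down-regulates its validated
targets — and that this subset can be recovered from paired miRNA/mRNA
expression matrices as the subset on which the miRNA–target correlations are
strongly and consistently negative.

## The selection criterion

For a miRNA $m$ with $N_m$ validated targets and a tissue subset $A$ of size
$k$, let $\rho(m, y; A)$ be the Pearson correlation of $m$ and target $y$
across the samples in $A$, $\bar r_A$ the mean of the $N_m$ correlations, and
$p_{neg}$ the proportion of strictly negative correlations. The selection
loss is

$$L_a(A) = a\,\bar r_A + (1 - a)\,(1 - p_{neg}), \qquad 0 < a < 1 .$$

$L_a$ lies in $[-a, 1]$; it is minimised when the correlations are uniformly
$-1$ and maximised when $\bar r_A = 1$ with no negative correlation. The two
terms are deliberately distinct: a strongly negative mean can be produced by
a few extreme targets, while a large $p_{neg}$ requires the *majority* of
targets to respond. Zero correlations count as non-negative.

The weight defaults to $a = 0.4$. Values below $0.5$ put more weight on the
negative-proportion term, which is the more robust of the two summaries; in
our experience values in $0.3$–$0.5$ select very similar subsets, and the
weight is a first-class, always-reported parameter (`loss_config(a = )`).
For a new data set the weight can be tuned on training data.

## The search

Direct minimisation over all subsets of all sizes is hopeless
($\sum_k \binom{89}{k}$ explodes), so the search relaxes the problem in two
ways, following the correlation loss function algorithm:

1. **Per size**: for each subset size $k$, draw $M$ subsets of the candidate
   universe uniformly at random (partial Fisher–Yates; independent draws,
   duplicates allowed), evaluate $L_a$ on each, and keep the minimiser
   $A^*_k$. When $\binom{n}{k} \le M$ the search switches to exhaustive
   enumeration automatically, making the per-size minimum exact.
2. **Over sizes**: repeat for $k = k_{min}, \dots, k_{max}$ (defaults 3–15;
   a single tissue admits no correlation, and beyond ~15 tissues the
   attainable loss increases) and report the global minimiser along with the
   full loss-versus-$k$ profile.

The candidate universe for a miRNA is the set of tissues where its log2
expression is strictly above the detection cutoff (default 7.25, a standard
microarray detection threshold for these data): tissues in which the miRNA
is not detected can only contribute noise correlations. `M` defaults to
100,000 draws per size. A *seeded* mode restricts all draws to supersets of
tissues already believed to be involved, pruning the space when prior
knowledge exists.

Two determinism rules make results reproducible across platforms: a run is a
pure function of (data, configuration, seed), and equal-loss ties are broken
by the lexicographically smallest sorted sample-id tuple.

### Ranking instead of a single winner

Because the per-size minima are near-ties in well-supported regions, the
package also ranks tissues by their occurrence across the per-size best
subsets (`rank_tissues()`): a tissue that reappears at most sizes is more
credibly MTI-supported than one picked once. Ties in occurrence are ordered
lexicographically and receive distinct ordinal ranks. Counts always sum to
the total size of the per-size best subsets, which is asserted in the tests.

### Organ extension

Selected subsets can contain single samples of an organ, which may reflect
extreme individual profiles. `extend_to_organs()` enlarges a selection to
every sample sharing an (organ, tumor/normal) class with a selected sample
and then re-applies the expression cutoff. The extension reports both the
pre-cutoff class universe and the retained set, so the two counts can be
compared.

## Preprocessing

* Genes with any missing value are removed (`drop_incomplete_genes()`);
  missing entries are represented as `NA` from load to save, never zero.
* Normalization is configurable: quantile (default, via limma), median
  centring, or none for pre-normalized inputs. The original preprocessing of
  the public tissue panel this design targets is not fully specified, so the
  method here is an explicit, documented choice rather than an attempted
  reconstruction.
* A miRNA is analysable when it has at least `min_targets` (default 10)
  validated targets present in the mRNA matrix and at least
  `min_expressed_tissues` (default 30) tissues above the cutoff. The second
  threshold separates broadly expressed miRNAs from ones detected in only a
  handful of tissues; published analyses of this kind excluded miRNAs with
  up to 17 expressed tissues and retained ones with 42 or more without
  stating the boundary, so the default sits in that gap and is deliberately
  configurable. Diagnostics name the excluded candidates and the reason.
* Catalog/matrix id matching is case-insensitive exact matching after
  trimming, with an optional literal prefix strip
  (`strip_mirna_prefix()`); fuzzy matching is intentionally absent because
  it produces irreproducible joins.

### Undefined correlations

Detection-floor data produce constant vectors over small subsets, whose
Pearson correlation is undefined. The default policy (`undefined = "skip"`)
drops such targets from the profile and reduces the denominator of
$p_{neg}$, recording the skipped targets; a `"fail"` policy is available.
Silent `NaN` propagation is never an option.

## Evaluation

* `improvement()` reports $A$ (mean correlation over all tissues), $S$ (over
  the selected subset) and $S - A$; a strongly negative difference is the
  headline effect of a successful selection.
* `permutation_test()` compares the selected subset's loss with $B$ (default
  1,000) uniformly resampled subsets of the same size from the same candidate
  universe — tissue-set resampling, not expression relabelling — and reports
  the +1-corrected empirical p-value $(1 + \#\{L_{null} \le
  L_{obs}\})/(B+1)$. **Caveat:** when the subset was itself chosen by
  minimising the same loss on the same data, selection and test share data
  and this p-value is optimistically biased; every report carries a note
  labelling it a diagnostic of how deep in the null tail the selection sits,
  not an inference.
* `density_comparison()` overlays Gaussian-kernel densities of correlation
  sets on a fixed 512-point grid over $[-1.1, 1.1]$ (Silverman bandwidth)
  and reports each set's skewness, so "the selected-tissue density is
  right-skewed" is a sign check rather than a visual impression.

## The synthetic generator

`synth_generate()` produces paired matrices over an 11-organ census
(89 samples, 68 tumor / 21 normal by default) with sample ids in
`T|N_organ_k` form. Each miRNA is $\mathcal N(\mu_0, 1)$ everywhere
($\mu_0 = 9$, comfortably above the 7.25 cutoff). Inside that miRNA's
planted subset, each non-decoy target follows

$$y = \mu_0 - \beta\,(m - \mu_0) + \varepsilon, \qquad
  \varepsilon \sim \mathcal N(0, \sigma^2),$$

and outside it (and for decoy targets everywhere) $y = \mu_0 + \varepsilon$
independent of $m$. The within-subset correlation has the closed form
$\rho = -\beta/\sqrt{\beta^2 + \sigma^2}$; the defaults $\beta = 2$,
$\sigma = 0.5$ give $\rho \approx -0.97$, and $\beta = 0$ is the null.
Decoy targets (default 10%) emulate validated interactions with no
expression-level response — regulation at the protein level only, or
dominance of other regulators — and exercise the $p_{neg}$ term separately
from $\bar r$. The acceptance checks verify the closed form by Monte Carlo
over independent miRNA–target pairs, applying the Olkin–Pratt small-sample
correction to the sample correlations so the Monte-Carlo mean estimates
$\rho$ itself rather than the downward-biased expectation of $r$.

What the generator does **not** emulate: probe-level noise physics,
saturation, batch structure, correlated targets (each target has independent
noise), or organ-level expression differences. Passing the planted-recovery
tests therefore demonstrates that the search machinery optimises the loss
correctly under the model's assumptions — not that real tissue panels
satisfy those assumptions.

## Known limitations

Two structural properties of the loss matter when interpreting results, and
both are visible in this package's own simulation studies:

* **Exact subset identity is not identifiable under a centred plant.** The
  planted regression line passes through the centre of the null cloud
  ($(\mu_0, \mu_0)$), so a null tissue whose miRNA value happens to fall
  near $\mu_0$ has almost no leverage on any target's correlation: swapping
  it for a planted tissue changes the loss by nearly nothing, and with tens
  of null tissues some always land near the centre. Exhaustive search then
  returns a subset that overlaps the planted one but is rarely *equal* to
  it. Recovery should be scored with the Jaccard index
  (`score_recovery()`), and tissue membership claims should rest on
  the occurrence ranking rather than on a single best subset.
* **The loss is not complexity-penalised, so smaller $k$ wins.** At smaller
  subset sizes the minimum over many subsets exploits sampling variability
  more easily, and the attainable loss decreases; the global minimiser over
  $k$ therefore sits at or near $k_{min}$ under the generator's conditions.
  This is a property of minimising $L_a$ itself, consistent with the
  observation that losses grow for large subset sizes. The per-$k$ loss
  profile and the occurrence ranking are the tools for judging subset size,
  not the global argmin alone.

The permutation p-value's selection bias (above) is the third caveat; the
three together are why the package reports rankings, loss profiles and
improvement metrics rather than a single point answer.

## Simulation sizes used by the test suite

The packaged checks run, per fixed seed: 21 oracle-equivalence instances
(10–12 candidates, $k \in \{3,4,5\}$, random $M = 10\binom{n}{k}$ vs
exhaustive); 100 recovery replicates at 30 tissues, planted size 5, 10
targets, $\beta = 2$, $\sigma = 0.5$ (exhaustive at $k = 5$; size selection
over $k = 3..8$ with $M = 20{,}000$ per size); 200 null-calibration
replicates with $B = 199$ permutation draws; and 1,000 independent pairs for
the closed-form check. These sizes are the package's standing simulation
study; the acceptance script (`scripts/acceptance.R`) recomputes the same
quantities from scratch for any seed.
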