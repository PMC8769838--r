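---
title: "Phylogenetic clustering of therapeutic efficacy: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogenetic clustering of therapeutic efficacy: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ethnophylo)
```

## The question and the model

Ethnomedicinal traditions record, for each plant species, the ailments it is
used against. If the chemistry behind a therapeutic use is phylogenetically
conserved — alkaloid classes confined to particular clades, say — then the
species sharing a use should be *more closely related* than a random draw
from the regional flora. ethnophylo quantifies this, one disease category at
a time, with the two standard community-phylogenetics indices:

* **NRI** (net relatedness index), the sign-flipped standardized effect size
  of the **mean pairwise distance** (MPD): for a community $S$ of $k$
  species on a tree with patristic distance $d$,
  $\mathrm{MPD}(S) = \binom{k}{2}^{-1}\sum_{\{i,j\}\subset S} d(i,j)$ and
  $$\mathrm{NRI} = -\,\frac{\mathrm{MPD}_{obs} -
  \overline{\mathrm{MPD}}_{null}}{\mathrm{sd}(\mathrm{MPD}_{null})}.$$
  Sensitive to tree-wide (basal) clustering.
* **NTI** (nearest taxon index), the same standardization applied to the
  **mean nearest-taxon distance**
  $\mathrm{MNTD}(S) = k^{-1}\sum_{i \in S}\min_{j \in S,\, j\neq i} d(i,j)$.
  Sensitive to clustering near the tips.

Positive values mean clustering (the observed distance is smaller than
expected), negative values overdispersion.

The null model is the **taxa-label shuffle**: the tip labels of the pool's
distance matrix are permuted uniformly while the community size $k$ is held
fixed, which is equivalent to drawing $k$ labels from the pool without
replacement in every run (999 runs by default). The reported p-value is the
one-tailed lower rank statistic $p = \mathrm{rank}/(\mathrm{runs}+1)$, where
the rank of the observed value among observed-plus-null values uses
**midranks** for ties. The floor is therefore $1/(\mathrm{runs}+1)$ (0.001
at 999 runs) and an extremely overdispersed community reports $p$ near 1.
Significance is flagged at $p < 0.05$ per test, uncorrected — each category
is treated as its own hypothesis, and summary tables always carry all 15
categories so the multiplicity is visible to the reader.

### Numerical conventions and degenerate inputs

* Ties at the observed value take midranks. This matters: a community whose
  observed metric coincides with a positive fraction $q$ of the null mass
  (e.g. one cherry of a small balanced tree) has limiting p-value $q/2$
  regardless of the number of runs, so "significant" verdicts cannot be
  manufactured by adding runs.
* A community equal to the whole pool (or any configuration with zero null
  standard deviation) is returned as `degenerate = TRUE` with `ses = NA` —
  never an error, never a fabricated z-score.
* Categories with fewer than two species in scope produce a row of `NA`
  metrics with the true count, keeping the 15-row table shape.
* Branch lengths must be present; a tree without them is a hard error unless
  the caller explicitly opts into unit branch lengths. Zero-length edges are
  accepted (they occur in large supertrees).
* Every permutation consumes a caller-controlled seed; the pipeline derives
  one seed per (category, metric) from its base seed, so tables are
  reproducible bit-for-bit and independent of evaluation order.

## Pool choice

Which species constitute the null pool is a scientific decision, not a
computational one, so `run_scope()` exposes it:

* `all_tree_tips` (default): the pool is the scope's whole pruned subtree —
  all congeners, medicinal or not. Clustering then means "uses concentrate
  in particular clades of the flora".
* `medicinal_only`: the pool is the medicinal species themselves.
  Clustering then means "this use concentrates within the medicinal set".

Published order-level analyses of this kind do not always state which pool
their null received, and the two give different baselines; both are
supported and the choice is recorded in every result's attributes and the
run manifest. Family-level runs re-prune the tree to the family's subtree,
so the family scope's null pool is the family, not the order.

## The synthetic study generator

Real compiled efficacy dictionaries cannot be redistributed, so calibration
and power analysis run on synthetic studies whose structure is known by
construction:

* **Trees** come from a forward Yule (pure-birth) simulation: with $k$
  lineages the next split arrives after an $\mathrm{Exp}(k\lambda)$ waiting
  time; at $n$ tips the simulation adds one final $\mathrm{Exp}(n\lambda)$
  interval, so trees are ultrametric with expected height
  $\lambda^{-1}(\sum_{k=2}^{n-1} 1/k + 1/n)$ — the exact oracle the tests
  check against. Pure birth was chosen over birth–death because clade
  structure (the "families") comes free from the process and no extra
  parameters need defending.
* **Family analogues**: the tree is partitioned into monophyletic groups by
  repeatedly splitting the largest clade at its root until the configured
  number of clades exists. Realized sizes are emergent from the topology;
  configured weights order the family labels by size rather than force
  exact counts, which would require rejection sampling for no analytic
  benefit.
* **Communities** (category member sets) are drawn in one of three modes:
  `null` (uniform), `clustered` (members confined to one internal node's
  clade), `overdispersed` (greedy max–min patristic spread). A `strength`
  parameter interpolates linearly toward uniform by controlling the number
  of members placed by the structured rule. Clade-membership was chosen
  over a Brownian-threshold trait model because it directly instantiates
  the aggregation the NRI detects and gives every category an unambiguous
  truth label for recovery tests. For the clustered mode the qualifying
  clade (size $\ge k$) is drawn preferring clades of at most $3k$ tips when
  any exist: a "clustered" community planted in a near-root clade spanning
  most of the pool would be indistinguishable from null, defeating the
  purpose of a planted signal.
* **Default study conditions** mirror the compiled Ranunculales survey this
  package was built around: 551 species in five clades with relative sizes
  300/69/42/14/126, and 15 categories at the published per-category
  prevalences (13.2%–78.9%). The default per-category mode is `null` — the
  generator's baseline is the no-signal hypothesis, and structure is
  planted explicitly by the caller. Species left all-zero by the draws
  receive one positive category (probability proportional to prevalence),
  since a recorded medicinal species must treat something; this only adds
  isolated positives and leaves null categories null.

What the generator does **not** emulate: non-ultrametric branch lengths,
correlated categories (real uses co-occur: a species used for wounds is
often also used for skin disease), imperfect name matching, and
polytomy-rich supertree topology. Passing calibration and power tests on
synthetic data therefore demonstrates the statistical machinery is correct
and well-calibrated, not that any particular empirical clustering claim is
right — on real data the verdicts inherit the tree's and the dictionary's
error structure.

## Statistical acceptance surface

The test suite asserts, at fixed seeds (problem sizes chosen to keep the
default run within a normal CI budget):

* MPD/MNTD equal brute-force enumeration on 200 random (tree, subset)
  instances, and the exact subset-enumeration null on an 8-tip pool matches
  the sampled null within 3 Monte-Carlo standard errors.
* Null calibration: 200 uniform communities (pool 64, $k = 8$, 999 runs)
  give mean NRI within $[-0.15, 0.15]$ (the estimator's SE is ~0.07, since
  sd(NRI) ≈ 1) and a p-value distribution indistinguishable from uniform
  (KS $p > 0.01$).
* Power: planted clustered communities ($n = 300$, $k = 30$, strength 1)
  are recovered with NRI > 0 and $p < 0.05$ in at least 90 of 100 seeds;
  planted max–min overdispersed communities give NRI < 0 in at least 90.
  (The MPD overdispersion signal is intrinsically weak on ultrametric Yule
  trees — most pairwise distances already span the root — so the sign test,
  not a significance test, is the appropriate assertion there.)
* Type-I control: on all-null 15-category studies (pool 64), category NRI
  tests flag close to the nominal 5% across 100 seeds.
* The independent reference implementation in picante reproduces our
  observed MPD/MNTD exactly and our standardized effect sizes within
  Monte-Carlo error of its own permutation stream.

Two further checks require external inputs (the full species-by-category
survey matrix and the 26,978-tip national angiosperm phylogeny) that are
not redistributable with the package; the corresponding tests run the full
pipeline when those files are supplied and report an honest failure when
they are absent.

## Known limitations

* Only the taxa-label null is implemented; richness, frequency and
  independent-swap nulls, and abundance-weighted metrics, are out of scope.
* No multiple-testing correction is applied across categories (by design,
  to match the field's reporting convention); users comparing many clades
  should correct downstream.
* Name reconciliation is rule-based normalization only (no synonym
  resolution); unmatched names are dropped with a report by default, and
  infraspecific fallback merging is opt-in.
* iTOL colors and symbol shapes are fixed documented constants; the export
  targets iTOL's `DATASET_BINARY` and `TREE_COLORS` formats only.
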