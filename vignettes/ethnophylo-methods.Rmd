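---
title: "Phylogenetic dispersion and hotnode analysis of ethnomedicinal use: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogenetic dispersion and hotnode analysis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ethnophylo)
```

## The scientific problem

Ethnobotanical surveys record which plant species of a flora are used in
traditional medicine, how often each use is reported, and how much
pharmacological or phytochemical research each species has attracted.
Two questions recur in such studies. First, are the used species spread
across the phylogeny of the flora at random, concentrated in a few
lineages (phylogenetic clustering), or spread more evenly than random
(overdispersion)? Second, do lineages rich in ethnomedicinal species —
"hotnode clades" — also concentrate traditional-use intensity and
research effort? `ethnophylo` implements the full analysis chain for
these questions: preparing a species-level ultrametric tree from a
genus-level backbone, computing dispersion statistics with a
permutation null, detecting hotnode clades, and producing
inside/outside-clade summaries with rank-based tests. A synthetic-data
generator with known phylogenetic structure makes every stage testable
and provides calibration and power results where real survey data are
unavailable.

## Dispersion metrics and the permutation null

For a focal set $S$ of $k$ tips on a tree with patristic distance
matrix $d$, the mean pairwise distance and mean nearest taxon distance
are

$$\mathrm{MPD}(S) = \binom{k}{2}^{-1} \sum_{i<j \in S} d_{ij},
\qquad
\mathrm{MNTD}(S) = \frac{1}{k}\sum_{i \in S} \min_{j \in S,\, j \neq i} d_{ij}.$$

Both are presence-only (unweighted): the analysis asks where the used
species sit on the tree, not how often they are used. The null model
shuffles tip labels across the whole distance matrix — equivalent to
drawing $k$ tips uniformly without replacement — and recomputes the
metric `runs` times (default 999). The standardized effect size is
$\mathrm{SES} = (\mathrm{obs} - \bar{x}_{\mathrm{null}}) /
s_{\mathrm{null}}$ with the sample ($n-1$) standard deviation, and the
community-phylogenetics indices are the negations: NRI $= -$SES(MPD),
NTI $= -$SES(MNTD). Positive index values mean the focal tips are
closer together than random draws (clustering), negative values mean
they are more spread out (overdispersion). NRI responds mainly to deep
(basal) structure, NTI to terminal structure, so their sign pattern
distinguishes four scenarios plus "random", implemented in
`classify_structure()`.

Permutation p-values use the $+1$ correction,
$p_{\mathrm{lower}} = (\#\{x_{\mathrm{null}} \le \mathrm{obs}\} + 1) /
(\mathrm{runs}+1)$, so no p-value is ever exactly zero, and the
two-tailed value is twice the smaller tail, capped at 1. When the
focal set contains every tip the null distribution is a point mass; the
result is flagged `degenerate` with SES fixed at 0 and p at 1 rather
than raising an error, because saturated categories do occur in real
category-wise analyses. Each `ses_dispersion()` call uses a single
seeded generator and records the seed, so any reported value can be
reproduced exactly.

A note on sign conventions: descriptions of these indices sometimes
phrase clustering and overdispersion in terms of "MPD/MNTD positive or
negative", meaning the SES of those metrics, which has the opposite
sign to NRI/NTI. This package standardizes on NRI/NTI signs (positive =
clustering) everywhere.

## Hotnode detection

`nodesig()` tests every internal node except the root: the observed
count of focal tips descending from the node is compared with its
distribution under the same tip-shuffling null. One relabeling per run
is evaluated at every node simultaneously, which is cheaper than
per-node permutation and gives a valid joint null. The test is
one-tailed for over-representation — only enrichment is interpreted as
a "hotnode" — with under-representation reported but never flagged.
Under the null the count is hypergeometric, and the permutation
p-values are checked against that closed form in the test suite. No
multiple-testing correction is applied by default, following the
convention of the original node-significance method; a
Benjamini–Hochberg option is available (`p_adjust = "BH"`).

`hotnode_clades()` keeps the significant nodes with no significant
ancestor. Because ancestors of an enriched clade are themselves
enriched, this "maximal node" rule yields a small set of disjoint
clades and a clean inside/outside bipartition of the tips, which is
what the downstream summaries consume. Listing every significant node
instead (`maximal_only = FALSE`) changes the node list but not the
partition.

## Tree preparation

Backbone phylogenies are typically genus-level; survey data are
species-level. `graft_species()` adds unsampled species as polytomies:
at the genus MRCA for genera with two or more tips (pendant length
equal to the node's height above its tips, so an ultrametric tree stays
ultrametric), or, for monotypic genera, at a new node placed
`split_fraction` (default 0.5) along the terminal branch. The default
of one half is the neutral choice when nothing is known about the
within-genus divergence time; it is configurable. Grafting is exact
edge-matrix surgery: existing pairwise distances are preserved
bit-for-bit, which the test suite asserts. Genus identity is read from
tip labels using the `Genus_species` underscore convention (separator
configurable); non-monophyletic genera are attached at their MRCA with
a warning.

`make_ultrametric()` uses deterministic mean-path-length smoothing:
each node's age is the mean path length to its descendant tips, parent
ages are clamped above child ages, and branch lengths are rewritten as
age differences. Rate-smoothing methods based on penalized likelihood
need a model and smoothing parameter and can return different
chronograms for different settings; for the relative-distance metrics
computed here only a consistent ultrametric scaling matters, so the
package prefers the reproducible, parameter-free transform. The exact
branch lengths of any particular published chronogram are not
recoverable by either route.

## The synthetic-data generator

`simulate_dataset()` produces a tree plus a species table with known
structure. Its defaults are the package's reference study conditions
and are not adjusted per analysis:

* **Tree**: forward pure-birth (Yule) simulation from two lineages,
  depth rescaled to 1, with genera assigned by recursively splitting
  the largest clade until the requested number of monophyletic genus
  blocks exists (default: about one genus per 13 species, the ratio
  typical of a large legume flora).
* **Use prevalence** 0.10 — roughly one species in ten of the flora
  has recorded ethnomedicinal use.
* **Scenarios**: `random` (independent Bernoulli); `clustered` — the
  clade closest in size to `prevalence * n_tips` gets an elevated
  per-tip use probability with ratio `p_in/p_out = 8`, overall
  prevalence preserved; `overdispersed` — deterministic greedy maximin
  selection seeded with the tree's diameter pair, ties broken by
  lowest label, so the selection depends only on the tree.
* **Counts**: use reports are $1 + \mathrm{NegBin}$ (mean 6,
  dispersion 0.5 — a long-tailed distribution in which a few species
  carry many reports); study counts come from a Gaussian copula
  against the report counts with target Spearman $\rho = 0.36$, with
  half of the used species mapped to zero studies (the zero-inflation
  is the lowest copula grade, so "never studied" is informatively the
  low end of the association, matching the observation that about half
  of used species are unstudied). The latent copula correlation is
  calibrated by bisection against a fixed-seed Monte-Carlo table of
  the same discrete margins, so tie- and zero-induced attenuation is
  accounted for; the realized rank correlation recovers the target
  within about $\pm 0.05$ at $n = 286$.
* **Unused species** get zero use reports and independent, mostly-zero
  study counts (5% have any), reflecting that some never-used genera
  are nevertheless studied.

What the generator does *not* emulate: real floras have genus sizes
with much heavier tails than Yule clade splits, spatially and
culturally structured sampling effort, and use-report counts that are
correlated within genera. Passing calibration and recovery tests on
synthetic data therefore demonstrates the statistical machinery is
correct and calibrated, not that any particular empirical flora will
show a given power.

## Calibration and power at the reference conditions

The acceptance suite runs the pipeline at fixed reference conditions
(64 tips, prevalence 0.15, enrichment ratio 8, 199 permutation runs;
100–500 replicates; problem sizes chosen so the whole suite runs in
well under a minute). Measured behaviour:

* Type-I error: under the random scenario the lower-tail SES rejection
  rate at $\alpha = 0.05$ falls in $[0.03, 0.07]$, and per-node
  hotnode false-positive rates match the attainable discrete level of
  the hypergeometric null (which is below $\alpha$ for small nodes —
  an inherent feature of discrete permutation tests, not a defect).
* The planted clustered clade is flagged by `nodesig()` in roughly
  nine replicates out of ten.
* The copula recovers $\rho = 0.36$ within $\pm 0.08$.
* Power of the *NRI index itself* is more limited: about half the
  clustered replicates and roughly three quarters to four fifths of
  the overdispersed replicates reach one-tailed significance. This is
  a real property of SES(MPD) at these sample sizes: with ~10 focal
  tips of which only ~60% sit in the enriched clade, the MPD shift is
  modest relative to its null spread. The per-node test, which looks
  exactly where the signal is, is the more powerful instrument for
  clade-level enrichment, and the package's tests record both rates
  honestly rather than tuning the generator until the weaker statistic
  passes.

## Numerical and design choices

* Null sd uses the $n-1$ denominator; p-values use the $+1$-corrected
  permutation quantile.
* Rank tests: Spearman's $\rho$ is the Pearson correlation of
  mid-ranks; its p-value is exact (full $n!$ enumeration) for
  $n \le 8$ and a $t$ approximation otherwise. The Mann–Whitney test
  enumerates all $\binom{n_1+n_2}{n_1}$ assignments when
  $n_1 + n_2 \le 12$ and otherwise uses the normal approximation with
  tie and continuity corrections. Two-tailed p-values are the default
  throughout; zero counts are data, not missing values.
* Summary percentages are reported with explicit numerators and
  denominators, both raw and display-rounded (round-half-up), because
  shares such as "used species studied" (denominator: used species)
  and "unused genera studied" (denominator: unused genera) are easy to
  conflate and published roundings are inconsistent. A genus is "used"
  or "studied" if any of its species is.
* The packaged `synthetic_flora()` fixture reproduces the count
  structure of a large legume ethnoflora (2837 species, 222 genera,
  286 used, 143 studied, 454 species in hotnode clades, 14
  drug-yielding genera of which 11 used and 2 in hotnodes) with
  internally consistent totals; published tables of this kind often
  contain small internal inconsistencies, and the fixture resolves
  them in favour of additivity so that inside + outside always equals
  the total.
* Degenerate inputs: zero-depth trees are rejected by
  `make_ultrametric()`; trees without branch lengths parse with a
  warning and zero lengths; saturated SES samples and constant
  vectors in `spearman_test()` yield flagged results, not errors.

## Known limitations

The pipeline consumes a tree; it does not infer one, align sequences,
or standardize taxon names. Only the tip-shuffling null is provided
(no phylogeny-pool or independent-swap nulls), matching the analysis
it implements. Dispersion metrics are unweighted by abundance or
report counts. Hotnode maximality is a hard rule; fuzzy clade
boundaries and branch-length-weighted enrichment are out of scope.
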