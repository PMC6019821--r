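# ethnophylo

Phylogenetic dispersion and hotnode analysis of ethnomedicinal plant
use.

Ethnobotanical surveys of a flora record which species are used in
traditional medicine, how many use reports each species has, and how
much pharmacological or phytochemical research each has attracted.
`ethnophylo` answers the two questions such data raise: **are the used
species phylogenetically clustered, overdispersed, or random** within
the flora, and **do the lineages rich in used species ("hotnode
clades") also concentrate use intensity and research effort?**

The package is aimed at ethnobotanists and community-phylogenetics
practitioners who have a backbone phylogeny (newick) and a species
table (CSV) and want a reproducible, tested pipeline from those inputs
to dispersion indices, hotnode clades, and inside/outside summaries.

## The statistics at its core

For a focal tip set *S* of size *k* with patristic distances *d*:

* **MPD** — mean of *d(i, j)* over all pairs in *S*; **MNTD** — mean
  over *i* of the distance to *i*'s nearest neighbour in *S*.
* The **taxa-labels null** shuffles tip labels on the distance matrix
  (equivalently: draws *k* tips uniformly), recomputing the metric
  `runs` times (default 999).
* **SES = (obs − null mean) / null sd**, and the indices are
  **NRI = −SES(MPD)**, **NTI = −SES(MNTD)**: positive means
  clustering, negative overdispersion; NRI reflects deep structure,
  NTI terminal structure. Permutation p-values use the +1 correction,
  `p = (#{null ≤ obs} + 1) / (runs + 1)`.
* The **hotnode test** (`nodesig`) compares, for every non-root
  internal node, the number of focal tips descending from it against
  the same shuffling null (one-tailed, enrichment only; the null count
  is hypergeometric and the permutation p is validated against that
  closed form). Significant nodes with no significant ancestor are
  merged into a disjoint set of **hotnode clades**, partitioning the
  tips into "inside" and "outside".
* Use-vs-effort associations use mid-rank **Spearman correlation** and
  the **Mann–Whitney rank-sum test**, with exact enumeration p-values
  for small samples (n ≤ 8, n1+n2 ≤ 12) and standard approximations
  otherwise.

Tree preparation utilities graft unsampled species onto a genus-level
backbone as polytomies (exact edge surgery, distances preserved
bit-for-bit) and make trees ultrametric by deterministic
mean-path-length smoothing. A synthetic-data module simulates Yule
trees with monophyletic genera, random/clustered/overdispersed use
scenarios, and count data whose rank correlation is calibrated by a
Gaussian copula — so every stage of the pipeline is testable with
known truth.

## Worked example

```r
library(ethnophylo)

# a synthetic flora: 128 species, ~12% used, use enriched in one clade
bundle <- simulate_dataset(
  sim_config(n_tips = 128, prevalence = 0.12, scenario = "clustered"),
  seed = 54)
dm   <- patristic_matrix(bundle$tree)
used <- bundle$dataset$species[bundle$dataset$used]

ses_dispersion(used, dm, "mpd",  runs = 999, seed = 1)
#> MPD: obs = 1.368, null = 1.512 (sd 0.07958), NRI = 1.809, two-tailed p = 0.096
ses_dispersion(used, dm, "mntd", runs = 999, seed = 2)
#> MNTD: obs = 0.7805, null = 0.8045 (sd 0.1045), NTI = 0.230, two-tailed p = 0.756

ns <- nodesig(bundle$tree, used, runs = 999, seed = 3)
hs <- hotnode_clades(ns, bundle$tree)
hs
#> hotnode set: 1 maximal clade(s), 22 tips inside, 106 outside

rep <- summarize_use(bundle$dataset, hs$inside)
rep$partitions[, c("partition", "n_species", "n_species_used",
                   "sum_use_reports", "sum_studies_used")]
#>  partition n_species n_species_used sum_use_reports sum_studies_used
#>     inside        22             11              31               40
#>    outside       106              9              74              252
#>      total       128             20             105              292

used_df <- bundle$dataset[bundle$dataset$used, ]
spearman_test(used_df$n_use_reports, used_df$n_studies)
#> spearman_rho = 0.5003 (n = 20, approximate, two.sided): p = 0.02468
```

Reading the output: the NRI of 1.81 points toward clustering of the
used species but does not reach two-tailed significance at this sample
size (the SES indices have limited power with ~20 focal tips). The
per-node test, which looks exactly where the enrichment is, flags one
hotnode clade of 22 species holding 11 of the 20 used species — over
half the used flora in a sixth of the species. Species with more use
reports attract significantly more studies (Spearman rho 0.50,
p 0.025). `classify_structure()` combines the two indices into a
scenario label, and `write_membership()` / `summarize_use()` carry the
inside/outside partition into Table-style reports. `drug_overlap()`
intersects a list of drug-yielding genera with the used and hotnode
genera. The same steps are scriptable through the bundled CLI
(`inst/cli/ethnophylo.R`, subcommands `simulate`, `graft`,
`ultrametric`, `ses`, `hotnodes`, `correlate`, `summarize`).

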