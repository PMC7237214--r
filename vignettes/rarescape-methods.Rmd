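---
title: "Methods: rarity and phylogenetic rarity as land-use indicators"
author: "rarescape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rarity and phylogenetic rarity as land-use indicators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific problem

Soil invertebrates are the most diverse animal component of terrestrial
ecosystems, and DNA metabarcoding (here, COI amplicons clustered into
OTUs at 97% identity) makes it possible to census them across many taxa
at once. The question this package addresses is *which biodiversity
metric most reliably registers the impact of land use* on such
communities. Species richness — the default measure — says nothing about
how restricted species are; two landscapes can have identical per-site
richness while one is a mosaic of distinct specialist assemblages and
the other a single homogenized generalist pool. Occurrence-weighted
rarity and its phylogenetic counterpart are designed to see exactly that
difference.

`rarescape` implements the full analysis chain for a survey of sites in
five land-use categories — natural forest, planted forest, low-producing
grassland, high-producing grassland, perennial cropland — with replicate
sites per category and negative controls, from the decontaminated OTU
table to the bootstrap comparison of metric sensitivity, together with a
synthetic-community generator that plants known land-use structure so
every stage can be validated against ground truth.

# The six metrics

For sample $j$ with OTU set $S_j$ (presence/absence taken from positive
read counts), and a rooted, branch-lengthed phylogeny over all OTUs:

* **Richness** $S = |S_j|$.
* **Effective species numbers** $D = \exp(-\sum_k p_k \ln p_k)$, the
  Hill number of order 1, with $p_k$ the within-sample relative read
  abundances. Reads are used as the abundance proxy directly; no
  rarefaction or depth normalization is applied by default (a
  deliberate choice — the upstream pipeline gives no depth-standardized
  counts, and presence-based metrics dominate the analysis; see *Open
  choices*).
* **Rarity** (endemism richness) $R = \sum_{i \in S_j} 1/n_i$, where
  $n_i$ is OTU $i$'s occurrence across *all* samples regardless of land
  use: a single-site OTU contributes 1, a ubiquitous one almost
  nothing.
* **Faith phylogenetic diversity** $PD = \sum_{b \in B_j} L_b$, the
  total branch length on paths from the present tips to the root. The
  root connection is included by default (`includeRoot`), so a
  single-tip sample has positive PD; both behaviours are tested.
* **Phylogenetic endemism / phylogenetic rarity**
  $PE = \sum_{b \in B_j} L_b / m_b$, with $m_b$ the number of samples
  containing any tip below branch $b$. The weighted ($1/m_b$) form is
  the default; strict endemism (only $m_b = 1$ branches) is available
  behind a flag. PE conserves branch length: summed over all samples it
  equals the total branch length present anywhere, just as rarity sums
  to the number of OTUs present anywhere — both identities are tested.
* **Mean pairwise distance** $MPD$, the presence-based mean patristic
  distance between the OTUs of a sample; undefined (flagged missing)
  below two OTUs. Abundance weighting is off, consistent with every
  other metric being presence-based.

Occurrence counts $n_i$ and branch occurrences $m_b$ are always computed
on the full post-filter sample set; per-analysis sample exclusions only
affect which rows are reported.

# Decontamination: the tag-jump model

Index hopping moves a small fraction of an abundant OTU's reads into
other samples of the same run. Negative controls measure it: for every
OTU with reads in any control, pairs $(x, y)$ are formed with $x$ the
OTU's maximum count over all non-control samples and $y$ its count in
each control, and a *through-origin* quantile regression
$y \sim \beta x$ is fitted at $\tau = 0.90$ by exact minimization of the
check loss (the loss is piecewise linear and convex in $\beta$, so the
minimizer lies at one of the observed slopes $y/x$; ties resolve to the
smallest slope). Through the origin because an OTU absent from the run
cannot contaminate anything. The correction subtracts
$\lceil \beta M_{i,-j} \rceil$ reads of OTU $i$ from sample $j$, where
$M_{i,-j}$ is the maximum over all *other* samples — a sample's dominant
OTU is not penalized by its own count, and the ceiling is conservative
(whether the original procedure rounded, truncated or took the ceiling
is not stated; the ceiling removes every single-read contaminant).
Applying the correction twice never increases a count.

# Null models and standardized effect sizes

SES values for PD, PE and MPD compare each sample's observed value to
999 randomizations under a *regional null*: every sample independently
receives a uniform random subset of the regional (whole-dataset,
per-group) species pool of the same size as its observed richness.
Richness is preserved; OTU identities and the occurrence structure are
randomized — for PE the branch occurrences $m_b$ are recomputed inside
every randomized table, since the null randomizes exactly the structure
PE depends on. The precise algorithm behind a "regional null" is not
uniquely defined in the literature this follows; the equal-probability
richness-preserving draw is the declared default, with
occupancy-preserving and swap-family alternatives behind a flag. SES is
positive when the observation exceeds the null mean. Degenerate nulls
(zero variance, e.g. PD on a star tree at fixed richness) yield flagged
missing values rather than divisions by zero.

Discreteness matters for rank-based tests on small pools: null values
tie with the observation, and the naive rank test is anticonservative
(we measured ~9% rejection at nominal 5% on 10-tip fixtures). The SES
records therefore carry both `null_rank` ($1 + \#\{null < obs\}$) and
`null_ties`; the exact two-sided test spreads the observation uniformly
over its tie range, which restores the nominal level and is what the
calibration tests use.

Null streams are seeded per (group, metric) from the root seed, so
adding or removing a group never perturbs another group's nulls.

# Community structure and homogenization

Compositional analyses use binary Jaccard distances on presence/absence
data, and unweighted UniFrac for their phylogenetic counterpart (the
fraction of jointly spanned branch length unique to one of two samples;
on a star tree with equal branch lengths it reduces exactly to Jaccard,
which is tested). Samples whose within-group read total falls below 5%
of the group's mean per-sample total are excluded from ordination input;
a manual exclusion flag exists for samples that render an ordination
uninterpretable. NMDS uses Kruskal stress-1 with monotone regression on
distance ranks (weak ties), 20 random restarts, 300 iterations.
PERMANOVA partitions the Gower-centred inner-product matrix by land use
with free sample-label permutation (single-factor design, no strata) and
the inclusive ($\ge$) tie convention in the permutation count.
Homogenization is tested two ways: multivariate dispersion (distances to
group centroids in principal-coordinates space, negative eigenvalues
retained, imaginary parts truncated at zero) compared by one-way ANOVA;
and mean pairwise (phylogenetic) beta diversity per land use, compared
by ANOVA with Tukey HSD. The pairwise-beta ANOVA knowingly treats
pairwise distances as independent observations, replicating the
conventional procedure; the caveat travels in the result object.

# Inference and the metric-sensitivity bootstrap

Per (taxonomic group, metric), one-way ANOVA against land use screens
for significant effects; land use is treated as an unordered factor.
Tukey HSD (Tukey–Kramer for unequal $n$) identifies pairwise contrasts;
with two groups it reduces to the pooled t-test to $10^{-6}$ in p. The
derived land-use rank (DLUR, 1–5 in the order natural forest →
perennial cropland) supports a linear trend test, and sequential
(Type-I) fixed-effects models ask whether land-use category explains
anything beyond DLUR, or beyond spatial/soil-chemistry principal
components (correlation-matrix PCA, constant variables dropped,
casewise deletion of incomplete samples). The "mixed-model" test of the
source analysis is implemented as a fixed-effects sequential model — no
random terms are named there, and the sequential decomposition is the
documented interpretation.

The headline comparison (which metric explains most land-use variance)
bootstraps $\eta^2 = SS_{landuse}/SS_{total}$ per eligible (group,
metric) combination — eligible meaning screening $p < 0.05$; a metric
with no significant group falls back to all groups, so every metric
receives a (then necessarily small) estimate. Each of 999 replicates
resamples, within each taxonomic group, that group's samples with
replacement *preserving per-land-use counts*, so no replicate loses a
cell and every ANOVA stays defined. A metric's replicate value is the
mean $\eta^2$ over its eligible groups, keeping one distribution per
metric; a pooled mode (every combination a separate value) exists. The
reported headline `obs_mean` is the *observed* mean $\eta^2$; the
bootstrap supplies 2.5/97.5 percentile confidence limits (percentile,
not BCa — the simplest defensible match to "95% confidence interval
limits"). This matters for calibration: on pure noise with $k$ groups of
$n$ samples the observed $\eta^2$ has expectation $(k-1)/(n-1)$ — $4/74
\approx 0.054$ for the 5 × 15 design, which the acceptance suite
verifies — whereas bootstrap-replicate means are inflated roughly
twofold by resampling noise, so the replicate mean is reported
separately (`boot_mean`) and never used as the headline. Metric
distributions are compared with a tie-corrected Kruskal–Wallis test and
Holm-adjusted pairwise Wilcoxon post-hocs.

# The synthetic-community generator

The generator is the package's ground truth: it emulates the
*statistical* structure of the national survey — 5 land uses × 15 sites
plus negative controls, ~4500 OTUs in 17 taxonomic groups (matching the
survey's terrestrial OTU count and roughly its group proportions), many
single-site OTUs, specialist-rich heterogeneous forest communities
grading into homogenized generalist-dominated agricultural ones,
negative-binomial read depth (mean 30,000, size 8) over a lognormal
rank-abundance curve (sdlog 1.5, one read reserved per present OTU so
designed incidence survives the count draw), and binomial tag-jump
contamination at a realistic total rate of 0.2% split across the
controls.

Mechanics and the reasoning behind them:

* Every OTU is homed to one land use; home assignment is a fixed
  (largest-remainder) apportionment so group sizes are deterministic
  given the design. The apportionment weights solve a small linear
  system so that *expected per-site richness is equal across land
  uses*: richness is flat by construction while the occupancy structure
  varies — the configuration in which richness-based and
  occurrence-based metrics genuinely disagree.
* Within a land use, a fraction $h$ (homogenization, 0.05 → 0.75 in
  even steps along DLUR) of its OTUs is *shared* — present at every
  site, the homogenized core that drives low dispersion and low rarity
  in intensive land uses. Of the rest, a fraction $\sigma$ (0.90 → 0.10)
  are *specialists* occupying $1 + \mathrm{Binomial}(2, 0.15)$ home
  sites (72% single-site); the remainder are *generalists* present at
  each home site with probability 0.45 and spilling into each foreign
  site with probability 0.08.
* The phylogeny is a pure-birth tree whose tips are assigned so that
  groups, and home land uses within them, occupy contiguous clades, and
  phylogenetically adjacent specialists preferentially share a home
  site (`radiation_cohesion = 0.5`): local clade radiations confine
  whole subclades, internal branches included, to single sites. This
  geographic–phylogenetic correlation is what real soil faunas with
  deep endemic lineages exhibit, and it is the mechanism through which
  phylogenetic rarity overtakes non-phylogenetic rarity here (the
  phylogenetic distance structure also sharpens MPD's land-use
  contrast in these simulations). Two
  alternatives probed during design did *not* produce that behaviour
  and are documented as such: stretching endemic terminal branches
  inflates within-land-use PE variance and weakens the signal (the
  knob remains, off by default), and raising specialist occupancy
  helps only marginally.
* Soil chemistry and altitude follow linear DLUR trends with noise
  (e.g. pH rising, carbon falling toward cropland), so the covariate
  PCA models have realistic confounded structure; latitude is
  uninformative by design.

What the generator does **not** emulate: sequence-level error (chimeras,
clustering artefacts), spatial autocorrelation between sites, taxon-
specific read-depth biases, or abundance-occupancy correlations beyond
the lognormal weights. Passing the planted-structure tests therefore
shows the pipeline recovers the designed occupancy/phylogeny structure
from realistic count data — not that real communities behave this way.

# Numerical choices and degenerate inputs

Exact check-loss enumeration (not golden-section search) fits the
tag-jump slope, with a brute-force grid oracle in the tests; the
subtraction never drives counts negative and is idempotent-safe. Metric
implementations are vectorized over a sparse tips × branches incidence
matrix, which is what makes 999 randomizations over thousands-of-tip
trees affordable; they are verified to $10^{-9}$ against independent
recursive branch-enumeration oracles on 200 random fixtures, and
against the standard field implementations (`picante::pd`,
`picante::mpd`, `picante::unifrac`) where those exist. Both-empty
sample pairs get Jaccard distance 0 with a warning; empty samples give
missing tree metrics; all-identical ANOVA inputs return $F = 0, p = 1$
rather than 0/0. All randomized stages take explicit seeds, and the
problem sizes used by the test suite (8-tip oracle fixtures; a ~260-OTU
five-group survey for pipeline tests; 199–999 randomizations;
100–500-replicate calibration loops; the full ~4500-OTU default design
for the end-to-end planted-structure check) were chosen to give each
statistical check adequate power while keeping the whole suite fast.

# Open choices, made and documented

* No rarefaction by default; a depth-normalization switch exists.
* PD includes the root path by default; both variants tested.
* Weighted (not strict) phylogenetic endemism, matching the cited
  method's default.
* Regional null = equal-probability richness-preserving draws;
  alternatives behind flags.
* Gastrotricha and Onychophora remain in the overall community but
  belong to no group-level analysis; the 17 groups plus `Excluded`
  partition all OTUs.
* Mites are identified as Acari (subclass or order) under Arachnida;
  myriapods pool Chilopoda, Diplopoda, Symphyla, Pauropoda — the rules
  are explicit and configurable because the source names groups, not
  rank rules.
* Bootstrap pooling across eligible groups uses the per-metric mean;
  the pooled-values mode is available.

# Known limitations

Pairwise-beta ANOVA inherits the non-independence of pairwise
distances; the sequential models are fixed-effects only; the bootstrap
CI is percentile-based; UniFrac is unweighted only; and the synthetic
ground truth, however carefully structured, is not field data — claims
proven here are claims about the pipeline, not about soil ecosystems.
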