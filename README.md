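# rarescape

Land-use impacts on soil invertebrate communities, measured by DNA
metabarcoding and six biodiversity metrics — with an emphasis on
occurrence-weighted **rarity** and **phylogenetic rarity** as indicators
that see what species richness misses: the replacement of distinct
specialist assemblages by a homogenized pool of generalists.

The package is written for community ecologists analysing OTU-by-sample
COI metabarcoding tables from replicated land-use surveys (natural
forest, planted forest, low-/high-producing grassland, perennial
cropland), and for methodologists who want a fully testable version of
that analysis chain.

## What it computes

For sample *j* with OTU set *S<sub>j</sub>* on a rooted phylogeny with
branch lengths *L<sub>b</sub>*:

| metric | definition |
|---|---|
| `S_richness` | number of OTUs present |
| `D_effective` | exp(Shannon entropy) of relative read abundances (Hill q = 1) |
| `R_rarity` | Σ 1/*n<sub>i</sub>* over present OTUs; *n<sub>i</sub>* = occurrence across **all** samples |
| `PD` | total branch length spanned by the present tips (Faith) |
| `PE` | Σ *L<sub>b</sub>*/*m<sub>b</sub>* over present branches; *m<sub>b</sub>* = branch occurrence across samples |
| `MPD` | mean pairwise patristic distance among present OTUs |

Around the metrics sit the full pipeline stages: tag-jump (index
hopping) decontamination via through-origin 90th-quantile regression of
control counts on cross-sample maxima; terrestrial filtering and
assignment to 17 taxonomic groups; standardized effect sizes for the
phylogenetic metrics against a regional null (999 randomizations);
Jaccard / unweighted-UniFrac community structure with NMDS, PERMANOVA,
multivariate dispersion and mean pairwise beta diversity; land-use
ANOVAs with Tukey HSD, derived-land-use-rank trends and sequential
covariate models; and a taxonomic-group-stratified bootstrap comparing
the proportion of land-use variance (η²) each metric explains. A
synthetic-survey generator with planted land-use structure provides
ground truth for all of it.

## Worked example

Simulate a survey with the default design (5 land uses × 15 sites, 3
negative controls, ~4500 OTUs in 17 groups, planted specialist→
generalist gradient), decontaminate, and compare metrics:

```r
library(rarescape)

x <- simulateSurvey(simDesign(seed = 42))
x
#> RarescapeExperiment with 4500 OTUs x 78 samples
#>   total reads: 2250752
#>   controls: CTRL01, CTRL02, CTRL03
#>   tree: 4500 tips
#>   taxonomy ranks: kingdom, phylum, class, subclass, order
#>   land uses: HighProducingGrassland=15, LowProducingGrassland=15, ...

dec <- decontaminate(x)          # fit + subtract tag jumps
dec$model
#> TagJumpModel: beta = 0.00292398 at tau = 0.9 ( 1803 pairs )

xf <- filterTerrestrial(dec$x)
mt <- metricTable(xf)            # sample x group x metric, long format
```

Mean per-site values of the overall community along the derived
land-use rank show the designed contrast — richness flat, rarity and
phylogenetic rarity collapsing from forest to cropland:

```
               land_use value.PE value.R_rarity value.S_richness
          NaturalForest   137.58         137.78            392.1
          PlantedForest    58.98          59.73            390.3
  LowProducingGrassland    39.63          40.48            388.2
 HighProducingGrassland    34.71          32.59            390.5
      PerennialCropland    31.42          29.15            389.2
```

The stratified bootstrap then ranks the metrics by the proportion of
land-use variance they explain (observed mean η² over eligible groups,
with 95% percentile CIs from 199 replicates here):

```r
boot <- bootstrapVarianceExplained(mt, sampleData(xf), nBoot = 199, seed = 43)
boot$summary
#>       metric obs_mean ci_low ci_high n_groups
#>          MPD    0.596  0.589   0.646       17
#>           PE    0.565  0.549   0.613       17
#>     R_rarity    0.519  0.514   0.569       17
#>  D_effective    0.413  0.402   0.485       14
#>           PD    0.391  0.381   0.460       15
#>   S_richness    0.179  0.104   0.481        1
```

Rarity-type metrics explain roughly three times the land-use variance
that richness does, on data where per-site richness is equal across
land uses *by construction* — the homogenization signal is carried
entirely by occurrence and phylogenetic structure. `sesTable()` adds
null-model SES values, `betaStructure()` the PERMANOVA / dispersion /
beta-diversity tests, and `compareMetricSensitivity()` the
Kruskal–Wallis comparison of the bootstrap distributions.

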