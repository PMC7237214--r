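#' Run the full analysis pipeline
#'
#' Chains the pipeline end to end, typically on a simulated survey:
#' tag-jump decontamination on the negative controls, terrestrial
#' filtering, the per-sample / per-group metric table, the overall-
#' community beta-structure tests, land-use ANOVAs with Tukey HSD and
#' derived-land-use-rank trends, and the stratified bootstrap comparison
#' of how much land-use variance each metric explains.
#'
#' @param x a [RarescapeExperiment-class]; default: a fresh
#'   [simulateSurvey()] of the default design with `seed`.
#' @param seed root integer seed for all randomized stages.
#' @param nPerm PERMANOVA permutations.
#' @param nBoot bootstrap replicates.
#' @param alpha significance level for screening and reporting.
#' @param tau tag-jump regression quantile.
#' @return list with components `x` (processed object), `tagjump`,
#'   `metrics`, `beta`, `anova` (per group x metric), `tukey_overall`,
#'   `trend_overall`, `bootstrap`, `sensitivity`.
#' @export
runPipeline <- function(x = NULL, seed = 1L, nPerm = 999, nBoot = 999,
                        alpha = 0.05, tau = 0.90) {
  if (is.null(x)) x <- simulateSurvey(simDesign(seed = seed))
  dec <- decontaminate(x, tau = tau)
  x <- filterTerrestrial(dec$x)
  meta <- sampleData(x)
  mt <- metricTable(x)
  beta <- betaStructure(x, nPerm = nPerm, seed = seed + 1L)
  anova <- groupMetricAnova(mt, meta, includeOverall = TRUE)
  ovRar <- mt[mt$group == "Overall" & mt$metric == "R_rarity", ]
  lu <- meta[ovRar$sample_id, "land_use"]
  tukey <- tukeyPairwise(ovRar$value, lu)
  trend <- dlurTrend(ovRar$value, meta[ovRar$sample_id, "dlur"])
  boot <- bootstrapVarianceExplained(mt, meta, alpha = alpha,
                                     nBoot = nBoot, seed = seed + 2L)
  sens <- compareMetricSensitivity(boot)
  list(x = x, tagjump = dec$model, metrics = mt, beta = beta,
       anova = anova, tukey_overall = tukey, trend_overall = trend,
       bootstrap = boot, sensitivity = sens)
}
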