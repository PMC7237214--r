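#' Binary Jaccard distances
#'
#' Pairwise presence/absence Jaccard dissimilarity,
#' `d_ij = 1 - |intersection| / |union|` over OTU sets. A pair of samples
#' that are both empty gets distance 0 with a warning.
#'
#' @param pa presence/absence matrix, OTUs x samples.
#' @return symmetric distance `matrix` with zero diagonal.
#' @export
jaccardDistance <- function(pa) {
  pa <- (as.matrix(pa) > 0) + 0
  if (ncol(pa) < 2L) stop("at least 2 samples are required")
  inter <- t(pa) %*% pa
  sz <- colSums(pa)
  un <- outer(sz, sz, "+") - inter
  d <- ifelse(un > 0, 1 - inter / un, 0)
  if (any(sz == 0)) {
    warning("empty sample(s): ", paste(colnames(pa)[sz == 0], collapse = ", "),
            "; pairs of empty samples get distance 0")
  }
  diag(d) <- 0
  dimnames(d) <- list(colnames(pa), colnames(pa))
  d
}

#' Non-metric multidimensional scaling
#'
#' Kruskal NMDS of a distance matrix: iterative minimization of stress-1
#' with monotone regression on the distance ranks (weak/primary tie
#' treatment), best of `nRestarts` random starts, via
#' [vegan::metaMDS()] on the precomputed distances.
#'
#' @param d distance `matrix` or `dist`.
#' @param k embedding dimension (default 2); must be `< n` samples.
#' @param nRestarts random starts (default 20).
#' @param seed integer seed for reproducible configurations.
#' @param maxit maximum iterations per start.
#' @return list: `points` (n x k coordinates), `stress` (Kruskal stress-1,
#'   in `[0, 1]`), `converged` flag.
#' @export
nmdsOrdination <- function(d, k = 2, nRestarts = 20, seed = NULL,
                           maxit = 300) {
  d <- stats::as.dist(d)
  n <- attr(d, "Size")
  if (n <= k) stop("need more samples than embedding dimensions")
  if (!is.null(seed)) set.seed(seed)
  fit <- vegan::metaMDS(d, k = k, try = nRestarts, trymax = nRestarts,
                        maxit = maxit, trace = 0, autotransform = FALSE,
                        wascores = FALSE)
  list(points = fit$points, stress = fit$stress,
       converged = isTRUE(fit$converged) || fit$stress < 1e-3)
}

#' PERMANOVA on a distance matrix
#'
#' Permutational multivariate ANOVA: partitions the Gower-centred
#' inner-product matrix by group membership, yielding a pseudo-F and an
#' `R2 = SS_between / SS_total`; the p-value is
#' `(1 + #permuted F >= observed F) / (nPerm + 1)` under free whole-sample
#' label permutation (ties counted inclusively). Backed by
#' [vegan::adonis2()].
#'
#' @param d distance `matrix` or `dist`.
#' @param groups factor of group labels, one per sample; every group must
#'   have at least 2 samples.
#' @param nPerm number of permutations (default 999).
#' @param seed integer seed.
#' @return list: `F`, `df_between`, `df_within`, `R2`, `p_perm`, `n_perm`,
#'   and the underlying `table`.
#' @export
permanovaTest <- function(d, groups, nPerm = 999, seed = NULL) {
  d <- stats::as.dist(d)
  groups <- factor(groups)
  tb <- table(groups)
  if (length(tb) < 2L) stop("at least 2 groups are required")
  if (any(tb < 2L)) {
    stop("group(s) with a single sample: ",
         paste(names(tb)[tb < 2L], collapse = ", "))
  }
  if (!is.null(seed)) set.seed(seed)
  df <- data.frame(groups = groups)
  fit <- vegan::adonis2(d ~ groups, data = df, permutations = nPerm)
  list(F = fit$F[1L], df_between = fit$Df[1L], df_within = fit$Df[2L],
       R2 = fit$R2[1L], p_perm = fit$`Pr(>F)`[1L], n_perm = nPerm,
       table = as.data.frame(fit))
}

#' Multivariate homogeneity of group dispersions
#'
#' Embeds the distance matrix in principal-coordinates space (retaining
#' negative eigenvalues), computes each sample's distance to its group
#' centroid as `sqrt(max(0, d_real^2 - d_imag^2))`, and compares mean
#' dispersion across groups with a one-way ANOVA. Backed by
#' [vegan::betadisper()] with centroid type.
#'
#' @inheritParams permanovaTest
#' @return list: `distances` (per sample), `group_means`, `F`, `p`,
#'   `anova` table, and the `betadisper` fit.
#' @export
dispersionTest <- function(d, groups) {
  d <- stats::as.dist(d)
  groups <- factor(groups)
  fit <- vegan::betadisper(d, groups, type = "centroid")
  an <- stats::anova(fit)
  gm <- tapply(fit$distances, groups, mean)
  list(distances = fit$distances, group_means = gm,
       F = an$`F value`[1L], p = an$`Pr(>F)`[1L], anova = an, fit = fit)
}

#' Mean pairwise beta diversity by group
#'
#' Collects the within-group pairwise distances of each land-use category
#' as observations, reports group means, and compares groups with a
#' one-way ANOVA and post-hoc Tukey HSD over these pairwise values. (The
#' pairwise distances of a group are not independent observations; the
#' ANOVA deliberately follows the conventional procedure and the caveat
#' travels in the `note` element.)
#'
#' @inheritParams permanovaTest
#' @return list: `values` (data.frame of group, pair, distance),
#'   `group_means`, `anova` (or `NULL` for a single group), `tukey`,
#'   `note`.
#' @export
meanPairwiseBeta <- function(d, groups) {
  m <- as.matrix(d)
  groups <- factor(groups)
  vals <- do.call(rbind, lapply(levels(groups), function(g) {
    idx <- which(groups == g)
    if (length(idx) < 2L) return(NULL)
    pr <- utils::combn(idx, 2L)
    data.frame(group = g,
               pair = paste(rownames(m)[pr[1L, ]], rownames(m)[pr[2L, ]],
                            sep = ":"),
               distance = m[cbind(pr[1L, ], pr[2L, ])],
               stringsAsFactors = FALSE)
  }))
  gm <- tapply(vals$distance, vals$group, mean)
  an <- tk <- NULL
  if (length(unique(vals$group)) >= 2L) {
    fit <- stats::aov(distance ~ group, data = vals)
    an <- stats::anova(fit)
    tk <- as.data.frame(stats::TukeyHSD(fit)$group)
  }
  list(values = vals, group_means = gm, anova = an, tukey = tk,
       note = "within-group pairwise distances treated as independent observations")
}

#' Community-structure summary for one distance metric
#'
#' Convenience wrapper chaining low-abundance sample exclusion, distance
#' computation (`"jaccard"` or `"unifrac"`), NMDS, PERMANOVA, dispersion
#' and mean-pairwise-beta tests for a set of OTUs against the land-use
#' factor.
#'
#' @param x a [RarescapeExperiment-class].
#' @param otus OTU subset (default all).
#' @param distance `"jaccard"` or `"unifrac"`.
#' @param nPerm permutations for PERMANOVA.
#' @param seed integer seed.
#' @param lowAbundanceFraction threshold for [excludeLowAbundance()];
#'   `NULL` disables exclusion.
#' @param runNmds compute the NMDS embedding (slowest step).
#' @return list with `excluded`, `d`, `nmds`, `permanova`, `dispersion`,
#'   `beta`.
#' @export
betaStructure <- function(x, otus = NULL,
                          distance = c("jaccard", "unifrac"),
                          nPerm = 999, seed = NULL,
                          lowAbundanceFraction = 0.05, runNmds = FALSE) {
  distance <- match.arg(distance)
  real <- setdiff(colnames(x), controlSamples(x))
  meta <- sampleData(x)[real, ]
  pa <- presenceAbsence(x, dropControls = TRUE)
  if (is.null(otus)) otus <- rownames(pa)
  excl <- if (is.null(lowAbundanceFraction)) character() else
    excludeLowAbundance(x, otus = otus, fraction = lowAbundanceFraction)
  keep <- setdiff(real, excl)
  sub <- pa[otus, keep, drop = FALSE]
  d <- if (distance == "jaccard") jaccardDistance(sub) else
    unifracDistance(sub, otuTree(x))
  grp <- factor(meta[keep, "land_use"], levels = landUseLevels())
  list(
    excluded = excl,
    d = d,
    nmds = if (runNmds) nmdsOrdination(d, seed = seed) else NULL,
    permanova = permanovaTest(d, grp, nPerm = nPerm, seed = seed),
    dispersion = dispersionTest(d, grp),
    beta = meanPairwiseBeta(d, grp)
  )
}
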