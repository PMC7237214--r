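#' Occurrence counts and rarity weights
#'
#' For every OTU, its occurrence `n_i` — the number of samples in which it
#' is present, across *all* samples regardless of land use — and the
#' rarity weight `w_i = 1/n_i`: 1 for a single-sample OTU, approaching 0
#' for ubiquitous ones. OTUs absent everywhere get `n = 0` and a missing
#' weight.
#'
#' @param pa presence/absence (or count) matrix, OTUs x samples.
#' @return data.frame with columns `n` and `w`, row names = OTU ids.
#' @export
occurrenceProfile <- function(pa) {
  n <- rowSums(as.matrix(pa) > 0)
  w <- ifelse(n > 0, 1 / n, NA_real_)
  data.frame(n = n, w = w, row.names = rownames(pa))
}

#' Per-sample OTU richness
#'
#' @param pa presence/absence (or count) matrix, OTUs x samples (already
#'   restricted to the group of interest).
#' @return named integer vector of per-sample richness.
#' @export
otuRichness <- function(pa) {
  out <- colSums(as.matrix(pa) > 0)
  storage.mode(out) <- "integer"
  out
}

#' Effective species numbers
#'
#' Hill number of order 1: the exponential of the Shannon entropy of the
#' within-sample relative read abundances — the number of equally common
#' species that would give the same entropy. Computed on raw read
#' proportions (reads are the abundance proxy; no rarefaction). A sample
#' with a single OTU has `D = 1`; a sample with no reads is missing.
#'
#' @param counts count matrix, OTUs x samples (group subset), or a single
#'   count vector.
#' @return named numeric vector `D` per sample.
#' @export
effectiveSpecies <- function(counts) {
  if (is.null(dim(counts))) counts <- matrix(counts, ncol = 1)
  counts <- as.matrix(counts)
  H <- vegan::diversity(t(counts), index = "shannon")
  D <- exp(H)
  D[colSums(counts) == 0] <- NA_real_
  names(D) <- colnames(counts)
  D
}

#' Occurrence-weighted rarity (endemism richness)
#'
#' Per-sample sum of the rarity weights `w_i = 1/n_i` of the OTUs present:
#' the number of OTUs in the sample adjusted for how widely each occurs
#' across all samples. Equals richness exactly when every present OTU is
#' single-site.
#'
#' @param pa presence/absence matrix restricted to the group of interest,
#'   OTUs x samples.
#' @param occ occurrence profile from [occurrenceProfile()], computed over
#'   *all* samples (pass it explicitly when `pa` covers a sample subset).
#' @return named numeric vector `R` per sample.
#' @export
rarityIndex <- function(pa, occ = occurrenceProfile(pa)) {
  pa <- (as.matrix(pa) > 0) + 0
  w <- occ[rownames(pa), "w"]
  w[is.na(w)] <- 0
  r <- as.vector(t(pa) %*% w)
  names(r) <- colnames(pa)
  r
}

#' Per-sample, per-group biodiversity metric table
#'
#' Computes the six biodiversity metrics — richness `S_richness`,
#' effective species numbers `D_effective`, rarity `R_rarity`, Faith
#' phylogenetic diversity `PD`, phylogenetic endemism `PE`, and mean
#' pairwise distance `MPD` — for every non-control sample, for the overall
#' community and for each taxonomic analysis group present. Occurrence
#' weights and branch occurrences are always computed on the full
#' post-filter sample set; control samples are excluded from the reported
#' rows.
#'
#' Per-cell missing values are propagated: `MPD` is missing for
#' sample-group combinations with fewer than two OTUs, `D_effective` for
#' zero-read combinations, and all tree metrics for groups with fewer
#' than two OTUs overall.
#'
#' @param x a [RarescapeExperiment-class] (filtered, decontaminated).
#' @param groups group labels to report (default [analysisGroups()];
#'   groups with no OTUs are skipped). Group membership comes from
#'   [assignGroups()] on the object's taxonomy.
#' @param includeOverall include the `"Overall"` community rows.
#' @param dropSingletons remove single-site OTUs first (sensitivity
#'   rerun).
#' @param includeRootInPd passed to [faithPD()].
#' @return long data.frame: `sample_id`, `group`, `metric`, `value`.
#' @export
metricTable <- function(x, groups = analysisGroups(), includeOverall = TRUE,
                        dropSingletons = FALSE, includeRootInPd = TRUE) {
  if (dropSingletons) x <- dropSingleSiteOtus(x)
  real <- setdiff(colnames(x), controlSamples(x))
  cnt <- otuCounts(x)[, real, drop = FALSE]
  pa <- (cnt > 0) + 0
  occ <- occurrenceProfile(pa)
  tree <- otuTree(x)
  grp <- assignGroups(otuTaxonomy(x))
  units <- list()
  if (includeOverall) units[["Overall"]] <- rownames(cnt)
  for (g in groups) {
    ids <- names(grp)[grp == g]
    if (length(ids)) units[[g]] <- ids
  }
  res <- lapply(names(units), function(u) {
    ids <- units[[u]]
    subPa <- pa[ids, , drop = FALSE]
    subCnt <- cnt[ids, , drop = FALSE]
    S <- otuRichness(subPa)
    D <- effectiveSpecies(subCnt)
    R <- rarityIndex(subPa, occ = occ)
    if (!is.null(tree) && length(ids) >= 2L) {
      subTree <- ape::keep.tip(tree, ids)
      PD <- faithPD(subPa, subTree, includeRoot = includeRootInPd)
      PE <- phyloEndemism(subPa, subTree)
      MPD <- meanPairwiseDist(subPa, subTree)
    } else {
      PD <- PE <- MPD <- rep(NA_real_, length(S))
    }
    data.frame(
      sample_id = rep(colnames(subPa), 6L),
      group = u,
      metric = rep(c("S_richness", "D_effective", "R_rarity", "PD", "PE",
                     "MPD"), each = ncol(subPa)),
      value = c(S, D, R, PD, PE, MPD),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' @rdname metricTable
#' @export
metricNames <- function() {
  c("S_richness", "D_effective", "R_rarity", "PD", "PE", "MPD")
}
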