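#' Regional null-model randomization
#'
#' One draw of the regional null: every sample independently receives a
#' uniform random subset of the regional species pool (all OTUs of the
#' group present in at least one sample) of the same size as its observed
#' richness. Sample richness is preserved; OTU identities — and therefore
#' the occurrence structure — are randomized.
#'
#' @param pa presence/absence matrix, OTUs x samples.
#' @param seed optional integer seed.
#' @return a 0/1 matrix with the same dimnames as `pa`.
#' @export
randomizeRegional <- function(pa, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pa <- (as.matrix(pa) > 0) + 0L
  pool <- which(rowSums(pa) > 0)
  rich <- colSums(pa)
  if (any(rich > length(pool))) {
    stop("sample richness exceeds the regional pool size")
  }
  out <- matrix(0L, nrow(pa), ncol(pa), dimnames = dimnames(pa))
  for (j in seq_len(ncol(pa))) {
    if (rich[j] > 0) out[pool[sample.int(length(pool), rich[j])], j] <- 1L
  }
  out
}

# occupancy-preserving alternative: independent column shuffles keep each
# sample's identity structure destroyed but row sums are NOT preserved;
# the swap family (curveball trades) preserves both margins
.randomizeOccupancy <- function(pa) {
  out <- pa
  for (i in seq_len(nrow(pa))) out[i, ] <- pa[i, sample.int(ncol(pa))]
  out
}

.randomizeSwap <- function(pa, nSwaps = 10 * sum(pa)) {
  out <- (as.matrix(pa) > 0) + 0L
  ones <- which(out == 1L)
  for (k in seq_len(nSwaps)) {
    pick <- sample(length(ones), 2L)
    a <- arrayInd(ones[pick[1L]], dim(out))
    b <- arrayInd(ones[pick[2L]], dim(out))
    if (a[1L] != b[1L] && a[2L] != b[2L] &&
        out[a[1L], b[2L]] == 0L && out[b[1L], a[2L]] == 0L) {
      out[a[1L], a[2L]] <- 0L; out[b[1L], b[2L]] <- 0L
      out[a[1L], b[2L]] <- 1L; out[b[1L], a[2L]] <- 1L
      ones[pick[1L]] <- (b[2L] - 1L) * nrow(out) + a[1L]
      ones[pick[2L]] <- (a[2L] - 1L) * nrow(out) + b[1L]
    }
  }
  out
}

# metric evaluators over a precomputed context, used for both the
# observed and the randomized tables
.phyloContext <- function(pa, tree, metric, includeRoot = TRUE) {
  tree <- .pruneToTable(pa, tree)
  list(
    tree = tree,
    et = .edgeTipMatrix(tree),
    D = if (metric == "MPD") stats::cophenetic(tree) else NULL
  )
}

.evalPhyloMetric <- function(pa, ctx, metric, includeRoot = TRUE) {
  if (metric == "MPD") {
    return(meanPairwiseDist(pa, ctx$tree, distances = ctx$D))
  }
  pres <- .sampleEdgePresence(pa, ctx$tree, ctx$et)
  L <- ctx$tree$edge.length
  if (metric == "PD") {
    if (!includeRoot) {
      cnts <- as.matrix(
        Matrix::t(Matrix::Matrix((pa[ctx$tree$tip.label, , drop = FALSE] > 0) + 0,
                                 sparse = TRUE)) %*% ctx$et)
      rich <- colSums(pa > 0)
      use <- (cnts > 0) & (cnts < rich)
      v <- as.vector(use %*% L)
    } else {
      v <- as.vector(pres %*% L)
    }
  } else {  # PE: branch occurrence recomputed inside the randomized table
    m <- colSums(pres)
    w <- ifelse(m > 0, L / pmax(m, 1), 0)
    v <- as.vector(pres %*% w)
  }
  v[colSums(pa > 0) == 0L] <- NA_real_
  names(v) <- colnames(pa)
  v
}

#' Standardized effect sizes against the regional null
#'
#' For each sample, compares the observed value of a phylogenetic metric
#' (`PD`, `PE` or `MPD`) to its distribution over `nRand` regional-null
#' randomizations of the incidence matrix:
#' `ses = (obs - mean(null)) / sd(null)`. Positive SES means the observed
#' value exceeds the null expectation. For `PE`, branch occurrences are
#' recomputed inside every randomized table, since the null randomizes
#' exactly the occurrence structure PE depends on. A degenerate null
#' (`sd = 0`) yields a missing SES, flagged in the `degenerate` column.
#' `null_rank` is `1 + #\{null < obs\}` and `null_ties` the number of null
#' values tied with the observation: on discrete metrics an exact
#' two-sided rank test should spread the observation uniformly over
#' `null_rank ... null_rank + null_ties` (randomized tie-breaking).
#'
#' @param pa presence/absence matrix, OTUs x samples (one taxonomic
#'   group).
#' @param tree rooted `phylo` covering the OTUs.
#' @param metric one of `"PD"`, `"PE"`, `"MPD"`.
#' @param nRand number of randomizations (default 999).
#' @param seed optional integer seed.
#' @param nullModel `"regional"` (default), `"occupancy"` or `"swap"`.
#' @param includeRoot passed to the PD computation.
#' @return data.frame: `sample_id`, `metric`, `obs`, `null_mean`,
#'   `null_sd`, `ses`, `null_rank`, `n_rand`, `degenerate`.
#' @export
sesMetric <- function(pa, tree, metric = c("PD", "PE", "MPD"), nRand = 999,
                      seed = NULL,
                      nullModel = c("regional", "occupancy", "swap"),
                      includeRoot = TRUE) {
  metric <- match.arg(metric)
  nullModel <- match.arg(nullModel)
  if (!is.null(seed)) set.seed(seed)
  pa <- (as.matrix(pa) > 0) + 0L
  ctx <- .phyloContext(pa, tree, metric)
  obs <- .evalPhyloMetric(pa, ctx, metric, includeRoot)
  nulls <- matrix(NA_real_, nRand, ncol(pa))
  for (r in seq_len(nRand)) {
    rnd <- switch(nullModel,
                  regional = randomizeRegional(pa),
                  occupancy = .randomizeOccupancy(pa),
                  swap = .randomizeSwap(pa))
    nulls[r, ] <- .evalPhyloMetric(rnd, ctx, metric, includeRoot)
  }
  mu <- colMeans(nulls, na.rm = TRUE)
  sdv <- apply(nulls, 2L, stats::sd, na.rm = TRUE)
  degen <- !is.na(obs) & (is.na(sdv) | sdv < .Machine$double.eps^0.5)
  ses <- ifelse(degen, NA_real_, (obs - mu) / sdv)
  eps <- .Machine$double.eps^0.5
  rank <- vapply(seq_len(ncol(pa)), function(j) {
    if (is.na(obs[j])) return(NA_integer_)
    1L + sum(nulls[, j] < obs[j] - eps * max(1, abs(obs[j])), na.rm = TRUE)
  }, integer(1))
  ties <- vapply(seq_len(ncol(pa)), function(j) {
    if (is.na(obs[j])) return(NA_integer_)
    sum(abs(nulls[, j] - obs[j]) <= eps * max(1, abs(obs[j])), na.rm = TRUE)
  }, integer(1))
  data.frame(
    sample_id = colnames(pa), metric = metric, obs = obs, null_mean = mu,
    null_sd = sdv, ses = ses, null_rank = rank, null_ties = ties,
    n_rand = nRand, degenerate = degen, row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' SES table across groups and metrics
#'
#' Runs [sesMetric()] for each requested taxonomic group (plus the overall
#' community) and phylogenetic metric. Null randomization streams are
#' seeded per (group, metric) from the root seed, so adding or removing a
#' group never perturbs another group's null distribution.
#'
#' @param x a [RarescapeExperiment-class] with a tree.
#' @param groups group labels (default: the 17 analysis groups present).
#' @param metrics subset of `c("PD", "PE", "MPD")`.
#' @param nRand randomizations per null distribution.
#' @param seed root integer seed.
#' @param includeOverall include the overall community.
#' @inheritParams sesMetric
#' @return row-bound data.frame of [sesMetric()] results with a `group`
#'   column.
#' @export
sesTable <- function(x, groups = analysisGroups(),
                     metrics = c("PD", "PE", "MPD"), nRand = 999,
                     seed = NULL, includeOverall = TRUE,
                     nullModel = "regional", includeRoot = TRUE) {
  tree <- otuTree(x)
  if (is.null(tree)) stop("a phylogeny is required for SES metrics")
  pa <- presenceAbsence(x, dropControls = TRUE)
  grp <- assignGroups(otuTaxonomy(x))
  units <- list()
  if (includeOverall) units[["Overall"]] <- rownames(pa)
  for (g in groups) {
    ids <- names(grp)[grp == g]
    if (length(ids) >= 2L) units[[g]] <- ids
  }
  out <- lapply(seq_along(units), function(k) {
    ids <- units[[k]]
    sub <- pa[ids, , drop = FALSE]
    res <- lapply(seq_along(metrics), function(mi) {
      s <- if (is.null(seed)) NULL else seed + 131L * k + mi
      sesMetric(sub, tree, metric = metrics[mi], nRand = nRand, seed = s,
                nullModel = nullModel, includeRoot = includeRoot)
    })
    res <- do.call(rbind, res)
    cbind(group = names(units)[k], res, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
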