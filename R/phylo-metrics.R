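# Edge machinery shared by PD / PE / MPD / UniFrac.
#
# .edgeTipMatrix builds a sparse tips x edges incidence matrix (tip t
# descends from edge b); sample-level edge presence is then one sparse
# product away, which is what makes the 999-randomization null models
# affordable on trees with thousands of tips.

.edgeTipMatrix <- function(tree) {
  ntip <- length(tree$tip.label)
  edge <- tree$edge
  po <- ape::reorder.phylo(tree, "postorder")
  tipsOf <- vector("list", max(edge))
  for (t in seq_len(ntip)) tipsOf[[t]] <- t
  for (k in seq_len(nrow(po$edge))) {
    p <- po$edge[k, 1L]; ch <- po$edge[k, 2L]
    tipsOf[[p]] <- c(tipsOf[[p]], tipsOf[[ch]])
  }
  sizes <- vapply(edge[, 2L], function(ch) length(tipsOf[[ch]]), integer(1))
  Matrix::sparseMatrix(
    i = unlist(tipsOf[edge[, 2L]], use.names = FALSE),
    j = rep.int(seq_len(nrow(edge)), sizes),
    x = 1,
    dims = c(ntip, nrow(edge)),
    dimnames = list(tree$tip.label, NULL)
  )
}

# samples x edges presence (0/1 dense matrix) from an OTU x sample
# incidence matrix; rows of pa not among the tips are ignored (they were
# pruned away by the caller), absent tips count as not present
.sampleEdgePresence <- function(pa, tree, edgeTips = .edgeTipMatrix(tree),
                                requireCovered = FALSE) {
  tips <- tree$tip.label
  if (requireCovered) {
    miss <- setdiff(rownames(pa), tips)
    if (length(miss)) {
      stop(length(miss), " OTU(s) in the table are not tips of the tree")
    }
  }
  tipPa <- matrix(0, length(tips), ncol(pa),
                  dimnames = list(tips, colnames(pa)))
  common <- intersect(rownames(pa), tips)
  tipPa[common, ] <- (pa[common, , drop = FALSE] > 0) + 0
  P <- Matrix::t(Matrix::Matrix(tipPa, sparse = TRUE))
  as.matrix((P %*% edgeTips) > 0) + 0
}

.pruneToTable <- function(pa, tree) {
  extra <- setdiff(tree$tip.label, rownames(pa))
  if (length(extra)) tree <- ape::drop.tip(tree, extra)
  tree
}

#' Branch occurrence across samples
#'
#' For every branch of the tree, the number of samples `m_b` that contain
#' at least one tip descending from it, computed over *all* samples of the
#' incidence matrix. This is the occurrence structure that phylogenetic
#' endemism weights branch lengths by.
#'
#' @param pa presence/absence matrix, OTUs (tree tips) x samples.
#' @param tree rooted `phylo` with branch lengths; pruned to the table's
#'   OTUs first.
#' @return data.frame with one row per branch: `length` and occurrence
#'   `m`.
#' @export
branchOccurrence <- function(pa, tree) {
  tree <- .pruneToTable(pa, tree)
  pres <- .sampleEdgePresence(pa, tree)
  data.frame(length = tree$edge.length, m = colSums(pres))
}

#' Faith phylogenetic diversity
#'
#' Per-sample total branch length spanned by the OTUs present: the sum of
#' `L_b` over all branches on the paths from the present tips to the root.
#' With `includeRoot = FALSE` the branches ancestral to all present tips
#' are dropped, i.e. the tree is only spanned down to the most recent
#' common ancestor (a single-tip sample then has PD 0 instead of its
#' root-path length).
#'
#' @param pa presence/absence matrix, OTUs x samples.
#' @param tree rooted `phylo` with branch lengths.
#' @param includeRoot include the root connection (default `TRUE`).
#' @return named numeric vector per sample; `NA` where no tips are
#'   present.
#' @export
faithPD <- function(pa, tree, includeRoot = TRUE) {
  miss <- setdiff(rownames(pa), tree$tip.label)
  if (length(miss)) {
    stop(length(miss), " OTU(s) in the table are not tips of the tree")
  }
  tree <- .pruneToTable(pa, tree)
  et <- .edgeTipMatrix(tree)
  P <- Matrix::t(Matrix::Matrix((pa[tree$tip.label, , drop = FALSE] > 0) + 0,
                                sparse = TRUE))
  cnts <- as.matrix(P %*% et)
  rich <- colSums(pa > 0)
  use <- cnts > 0
  if (!includeRoot) use <- use & (cnts < rich)
  pd <- as.vector(use %*% tree$edge.length)
  pd[rich == 0L] <- NA_real_
  names(pd) <- colnames(pa)
  pd
}

#' Phylogenetic endemism (phylogenetic rarity)
#'
#' The branch length unique to each sample: every branch present in a
#' sample contributes its length divided by the branch's occurrence `m_b`
#' across all samples, so a branch found in only one sample contributes
#' its full length there, and widely shared branches are discounted. With
#' `strict = TRUE` only branches with `m_b = 1` contribute (strict
#' endemism); the default is the weighted form.
#'
#' Branch occurrences are taken over the samples of `paForOccurrence`
#' (default: the same matrix), so per-analysis sample exclusions can be
#' applied to the reported rows without changing the occurrence baseline.
#'
#' @inheritParams faithPD
#' @param strict use strict (single-sample branches only) endemism.
#' @param paForOccurrence incidence matrix over which `m_b` is computed.
#' @return named numeric vector per sample; `NA` where no tips are
#'   present.
#' @export
phyloEndemism <- function(pa, tree, strict = FALSE, paForOccurrence = pa) {
  tree <- .pruneToTable(paForOccurrence, tree)
  et <- .edgeTipMatrix(tree)
  occ <- .sampleEdgePresence(paForOccurrence, tree, et)
  m <- colSums(occ)
  w <- ifelse(m > 0, tree$edge.length / pmax(m, 1), 0)
  if (strict) w <- ifelse(m == 1, tree$edge.length, 0)
  pres <- .sampleEdgePresence(pa, tree, et)
  pe <- as.vector(pres %*% w)
  pe[colSums(pa > 0) == 0L] <- NA_real_
  names(pe) <- colnames(pa)
  pe
}

#' Mean pairwise phylogenetic distance
#'
#' Presence-based mean of the patristic distances (summed branch lengths
#' on the connecting path) between all unordered pairs of OTUs present in
#' a sample. Undefined — returned as `NA` — for samples with fewer than
#' two OTUs.
#'
#' @inheritParams faithPD
#' @param distances optional precomputed cophenetic matrix over the
#'   tree's tips (saves repeated O(n^2) work in null models).
#' @return named numeric vector per sample.
#' @export
meanPairwiseDist <- function(pa, tree, distances = NULL) {
  tree <- .pruneToTable(pa, tree)
  if (is.null(distances)) distances <- stats::cophenetic(tree)
  out <- vapply(seq_len(ncol(pa)), function(j) {
    ids <- rownames(pa)[pa[, j] > 0]
    ids <- intersect(ids, rownames(distances))
    if (length(ids) < 2L) return(NA_real_)
    sub <- distances[ids, ids]
    mean(sub[upper.tri(sub)])
  }, numeric(1))
  names(out) <- colnames(pa)
  out
}

#' Unweighted UniFrac distances
#'
#' Pairwise phylogenetic beta diversity: the fraction of the branch length
#' spanned by two samples jointly that is unique to one of them,
#' `d_ij = (union - shared) / union` over branch lengths. Entries lie in
#' `[0, 1]`; samples with no present tips give `NA` rows (with a
#' warning).
#'
#' @inheritParams faithPD
#' @return a symmetric `matrix` of distances with zero diagonal.
#' @export
unifracDistance <- function(pa, tree) {
  tree <- .pruneToTable(pa, tree)
  pres <- .sampleEdgePresence(pa, tree)
  L <- tree$edge.length
  PL <- pres * rep(L, each = nrow(pres))
  shared <- PL %*% t(pres)
  tot <- rowSums(PL)
  union <- outer(tot, tot, "+") - shared
  d <- ifelse(union > 0, 1 - shared / union, 0)
  empty <- colSums(pa > 0) == 0L
  if (any(empty)) {
    warning("sample(s) with no present tips: ",
            paste(colnames(pa)[empty], collapse = ", "))
    d[empty, ] <- NA_real_
    d[, empty] <- NA_real_
  }
  diag(d) <- 0
  dimnames(d) <- list(colnames(pa), colnames(pa))
  d
}
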