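# Brute-force oracles, independent of the package's edge-matrix
# machinery: explicit recursive enumeration of descendant tips per
# branch and of root paths per tip. Deliberately slow and simple.

oracle_edge_tips <- function(tree) {
  ntip <- length(tree$tip.label)
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  desc <- function(node) {
    if (node <= ntip) return(node)
    unlist(lapply(kids[[as.character(node)]], desc), use.names = FALSE)
  }
  lapply(seq_len(nrow(tree$edge)), function(k) sort(desc(tree$edge[k, 2])))
}

oracle_root_path <- function(tree, tipIdx) {
  parent <- integer(max(tree$edge))
  edgeOf <- integer(max(tree$edge))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  edgeOf[tree$edge[, 2]] <- seq_len(nrow(tree$edge))
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])
  path <- integer()
  node <- tipIdx
  while (node != root) {
    path <- c(path, edgeOf[node])
    node <- parent[node]
  }
  path
}

oracle_pd <- function(tips, tree, includeRoot = TRUE) {
  if (!length(tips)) return(NA_real_)
  idx <- match(tips, tree$tip.label)
  et <- oracle_edge_tips(tree)
  pres <- vapply(et, function(s) any(idx %in% s), logical(1))
  if (!includeRoot) {
    anc <- vapply(et, function(s) all(idx %in% s), logical(1))
    pres <- pres & !anc
  }
  sum(tree$edge.length[pres])
}

oracle_pe <- function(pa, tree) {
  et <- oracle_edge_tips(tree)
  tipIdx <- match(rownames(pa), tree$tip.label)
  inSample <- function(j) which(pa[, j] > 0)
  edgePres <- sapply(seq_len(ncol(pa)), function(j) {
    present <- tipIdx[inSample(j)]
    vapply(et, function(s) any(present %in% s), logical(1))
  })
  m <- rowSums(edgePres)
  w <- ifelse(m > 0, tree$edge.length / pmax(m, 1), 0)
  out <- colSums(edgePres * w)
  out[colSums(pa > 0) == 0] <- NA_real_
  stats::setNames(out, colnames(pa))
}

oracle_patristic <- function(tree, tipA, tipB) {
  pa <- oracle_root_path(tree, match(tipA, tree$tip.label))
  pb <- oracle_root_path(tree, match(tipB, tree$tip.label))
  sum(tree$edge.length[c(setdiff(pa, pb), setdiff(pb, pa))])
}

oracle_mpd <- function(tips, tree) {
  if (length(tips) < 2) return(NA_real_)
  pr <- utils::combn(tips, 2)
  mean(apply(pr, 2, function(p) oracle_patristic(tree, p[1], p[2])))
}

oracle_rarity <- function(pa) {
  n <- rowSums(pa > 0)
  sapply(seq_len(ncol(pa)), function(j) {
    ids <- which(pa[, j] > 0)
    sum(1 / n[ids])
  })
}

oracle_jaccard <- function(pa, i, j) {
  a <- which(pa[, i] > 0); b <- which(pa[, j] > 0)
  un <- union(a, b)
  if (!length(un)) return(0)
  1 - length(intersect(a, b)) / length(un)
}

oracle_unifrac <- function(pa, tree, i, j) {
  et <- oracle_edge_tips(tree)
  ta <- match(rownames(pa)[pa[, i] > 0], tree$tip.label)
  tb <- match(rownames(pa)[pa[, j] > 0], tree$tip.label)
  ea <- vapply(et, function(s) any(ta %in% s), logical(1))
  eb <- vapply(et, function(s) any(tb %in% s), logical(1))
  un <- sum(tree$edge.length[ea | eb])
  if (un == 0) return(0)
  sum(tree$edge.length[xor(ea, eb)]) / un
}

# Monte-Carlo band for the fitted tag-jump slope: refit the whole
# estimator (grid-search oracle, all control columns including zero-count
# pairs) on fresh binomial spills at the true per-control rate
oracle_tagjump_band <- function(M, rhoShare, nControls, tau = 0.9,
                                nSim = 30) {
  vapply(seq_len(nSim), function(i) {
    ys <- matrix(stats::rbinom(length(M) * nControls, M, rhoShare),
                 ncol = nControls)
    hit <- rowSums(ys) > 0
    oracle_qr_grid(rep(M[hit], nControls), as.vector(ys[hit, ]), tau)
  }, numeric(1))
}

# two-stage grid search for the through-origin tau-quantile regression,
# accurate to ~1e-7 of the slope scale
oracle_qr_grid <- function(x, y, tau) {
  loss <- function(b) {
    r <- y - b * x
    sum(r * (tau - (r < 0)))
  }
  hi <- max(y / x) * 1.2 + 1e-9
  g1 <- seq(0, hi, length.out = 4001)
  l1 <- vapply(g1, loss, numeric(1))
  b1 <- g1[which.min(l1)]
  g2 <- seq(max(0, b1 - hi / 4000), b1 + hi / 4000, length.out = 4001)
  l2 <- vapply(g2, loss, numeric(1))
  g2[which.min(l2)]
}
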