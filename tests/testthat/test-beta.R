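test_that("Jaccard distances match set arithmetic", {
  pa <- f1_pa()
  d <- jaccardDistance(pa)
  expect_equal(d["s1", "s2"], 1 - 2 / 3, tolerance = 1e-12)
  expect_equal(d["s1", "s4"], 1)              # disjoint
  expect_equal(diag(d), rep(0, 4), ignore_attr = TRUE)
  dup <- cbind(pa, s5 = pa[, "s1"])
  expect_equal(jaccardDistance(dup)["s1", "s5"], 0)  # identical samples

  empty <- pa; empty[, "s4"] <- 0L
  expect_warning(d2 <- jaccardDistance(empty), "empty")
  # both-empty pairs are defined as 0
  empty2 <- cbind(empty, s6 = 0L)
  expect_warning(d3 <- jaccardDistance(empty2), "empty")
  expect_equal(d3["s4", "s6"], 0)
})

test_that("UniFrac matches branch enumeration on the worked fixture", {
  d <- unifracDistance(f1_pa(), t1_tree())
  expect_equal(d["s1", "s4"], 6 / 7, tolerance = 1e-12)
  expect_equal(d["s1", "s1"], 0)
  # disjoint subtrees sharing no branches are at distance 1
  tr <- ape::read.tree(text = "((a1:1,a2:1):1,(b1:1,b2:1):1);")
  pa <- matrix(0L, 4, 2, dimnames = list(tr$tip.label, c("s1", "s2")))
  pa[c("a1", "a2"), 1] <- 1L; pa[c("b1", "b2"), 2] <- 1L
  expect_equal(unifracDistance(pa, tr)["s1", "s2"], 1)
})

test_that("UniFrac equals Jaccard on a star tree with equal branch lengths", {
  tr <- ape::read.tree(text = "(a:1,b:1,c:1,d:1,e:1);")
  set.seed(17)
  pa <- matrix(rbinom(5 * 6, 1, 0.5), 5, 6,
               dimnames = list(tr$tip.label, paste0("s", 1:6)))
  pa[, colSums(pa) == 0] <- 1L
  expect_equal(unifracDistance(pa, tr), jaccardDistance(pa),
               tolerance = 1e-12)
})

test_that("Jaccard and UniFrac are metrics and match oracles on random fixtures", {
  set.seed(18)
  for (rep in 1:40) {
    fx <- random_fixture()
    dj <- jaccardDistance(fx$pa)
    du <- unifracDistance(fx$pa, fx$tree)
    for (d in list(dj, du)) {
      expect_equal(d, t(d), tolerance = 1e-12)
      expect_true(all(d >= -1e-12 & d <= 1 + 1e-12))
      n <- ncol(d)
      for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
        expect_lte(d[i, k], d[i, j] + d[j, k] + 1e-9)
      }
    }
    i <- sample(ncol(fx$pa), 1); j <- sample(setdiff(seq_len(ncol(fx$pa)), i), 1)
    expect_equal(dj[i, j], oracle_jaccard(fx$pa, i, j), tolerance = 1e-9)
    expect_equal(du[i, j], oracle_unifrac(fx$pa, fx$tree, i, j),
                 tolerance = 1e-9)
  }
})

test_that("UniFrac agrees with the picante implementation", {
  skip_if_not_installed("picante")
  set.seed(19)
  for (rep in 1:5) {
    fx <- random_fixture(ntips = 10, nsamp = 5)
    ours <- unifracDistance(fx$pa, fx$tree)
    ref <- as.matrix(picante::unifrac(t(fx$pa), fx$tree))
    expect_equal(ours[rownames(ref), colnames(ref)], ref, tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
})

test_that("NMDS embeds exactly embeddable configurations with ~zero stress", {
  d3 <- matrix(1, 3, 3) - diag(3)
  dimnames(d3) <- list(paste0("s", 1:3), paste0("s", 1:3))
  fit <- suppressWarnings(nmdsOrdination(d3, k = 2, nRestarts = 5, seed = 1))
  expect_lt(fit$stress, 1e-4)  # equilateral triangle

  set.seed(2)
  pts <- matrix(rnorm(20), 10, 2)
  d <- as.matrix(dist(pts)); dimnames(d) <- list(paste0("s", 1:10),
                                                 paste0("s", 1:10))
  fit2 <- suppressWarnings(nmdsOrdination(d, k = 2, nRestarts = 10, seed = 3))
  expect_lt(fit2$stress, 0.01)
  expect_error(nmdsOrdination(d3, k = 3), "more samples")
})

test_that("PERMANOVA behaves under separation, reordering, and duplication", {
  # perfect separation: between-group distance 1, within 0
  n <- 6
  d <- matrix(1, n, n); d[1:3, 1:3] <- 0; d[4:6, 4:6] <- 0; diag(d) <- 0
  dimnames(d) <- list(paste0("s", 1:n), paste0("s", 1:n))
  g <- rep(c("a", "b"), each = 3)
  res <- permanovaTest(d, g, nPerm = 99, seed = 1)
  expect_equal(res$p_perm, 1 / 100, tolerance = 1e-12)
  expect_gt(res$F, 100)  # effectively infinite

  expect_error(permanovaTest(d, c("a", rep("b", 5)), nPerm = 9), "single sample")

  set.seed(4)
  pts <- matrix(rnorm(40), 8, 5)
  d <- as.matrix(dist(pts)); dimnames(d) <- list(paste0("s", 1:8),
                                                 paste0("s", 1:8))
  g <- rep(c("a", "b"), each = 4)
  base <- permanovaTest(d, g, nPerm = 99, seed = 5)
  # invariance to sample reordering
  perm <- sample(8)
  reord <- permanovaTest(d[perm, perm], g[perm], nPerm = 99, seed = 5)
  expect_equal(reord$F, base$F, tolerance = 1e-9)
  expect_equal(reord$R2, base$R2, tolerance = 1e-9)

  # duplicating every sample: R2 invariant and F scales by (2n-k)/(n-k)
  idx <- rep(1:8, 2)
  d2 <- d[idx, idx]
  dimnames(d2) <- list(paste0("r", 1:16), paste0("r", 1:16))
  dup <- permanovaTest(d2, g[idx], nPerm = 99, seed = 5)
  expect_equal(dup$R2, base$R2, tolerance = 1e-9)
  expect_equal(dup$F, base$F * (16 - 2) / (8 - 2), tolerance = 1e-9)
})

test_that("dispersion analysis recovers planted homogenization contrasts", {
  # a group with all-identical members has zero dispersion
  pa <- cbind(f1_pa(), s5 = f1_pa()[, "s1"], s6 = f1_pa()[, "s1"])
  d <- jaccardDistance(pa[, c("s1", "s5", "s6", "s2", "s3", "s4")])
  g <- c("same", "same", "same", "diff", "diff", "diff")
  res <- dispersionTest(d, g)
  expect_equal(unname(res$group_means["same"]), 0, tolerance = 1e-9)

  # Euclidean input: distances to centroid equal direct computation
  set.seed(6)
  pts <- matrix(rnorm(24), 12, 2)
  g <- rep(c("a", "b"), each = 6)
  d <- as.matrix(dist(pts)); dimnames(d) <- list(paste0("s", 1:12),
                                                 paste0("s", 1:12))
  res <- dispersionTest(d, g)
  direct <- unlist(lapply(split(seq_len(12), g), function(ii) {
    ctr <- colMeans(pts[ii, ])
    sqrt(rowSums((pts[ii, ] - rep(ctr, each = length(ii)))^2))
  }), use.names = FALSE)
  expect_equal(sort(unname(res$distances)), sort(direct), tolerance = 1e-6)

  # planted heterogeneous (h = 0) vs homogenized (h = 1) land uses
  dsg <- small_design(seed = 13,
                      specialist_fraction = c(1, 1, 0, 0, 0),
                      homogenization = c(0, 0, 1, 1, 1),
                      p_specialist_extra = 0)
  x <- simulateCommunities(dsg)
  pa2 <- presenceAbsence(x, dropControls = TRUE)
  meta <- sampleData(x)[colnames(pa2), ]
  dd <- jaccardDistance(pa2)
  res2 <- suppressWarnings(
    dispersionTest(dd, factor(meta$land_use, levels = landUseLevels())))
  expect_lt(res2$p, 0.001)
  expect_gt(res2$group_means[["NaturalForest"]],
            res2$group_means[["PerennialCropland"]])
})

test_that("mean pairwise beta diversity splits cleanly by group", {
  pa <- cbind(f1_pa(), s5 = f1_pa()[, "s1"], s6 = f1_pa()[, "s1"])
  d <- jaccardDistance(pa[, c("s1", "s5", "s6", "s2", "s3", "s4")])
  g <- c("same", "same", "same", "diff", "diff", "diff")
  res <- meanPairwiseBeta(d, g)
  expect_equal(unname(res$group_means["same"]), 0)

  # fixed within-group distances {0.1 x3} vs {0.9 x3}: huge F, p < 0.001
  dm <- matrix(0, 6, 6, dimnames = list(paste0("s", 1:6), paste0("s", 1:6)))
  dm[1:3, 1:3] <- 0.1; dm[4:6, 4:6] <- 0.9; diag(dm) <- 0
  res2 <- suppressWarnings(meanPairwiseBeta(dm, g))  # exact-fit notice
  expect_lt(res2$anova$`Pr(>F)`[1], 1e-3)
  expect_equal(unname(res2$group_means), c(0.9, 0.1),
               tolerance = 1e-12, ignore_attr = TRUE)

  # single group: means reported, no ANOVA
  res3 <- meanPairwiseBeta(dm[1:3, 1:3], rep("one", 3))
  expect_null(res3$anova)
  expect_equal(as.numeric(res3$group_means), 0.1)
})
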