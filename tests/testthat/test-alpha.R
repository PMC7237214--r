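test_that("richness, rarity and effective species match hand-derived values", {
  pa <- f1_pa()
  expect_equal(unname(otuRichness(pa)), c(3L, 2L, 2L, 1L))
  expect_equal(otuRichness(pa["A", , drop = FALSE])[["s4"]], 0L)

  occ <- occurrenceProfile(pa)
  expect_equal(occ[c("A", "B", "C", "D", "E"), "n"], c(3, 1, 2, 1, 1))
  expect_equal(occ["B", "w"], 1)
  r <- rarityIndex(pa)
  expect_equal(unname(r), c(1 / 3 + 1 + 1 / 2, 1 / 3 + 1 / 2, 1 / 3 + 1, 1),
               tolerance = 1e-12)
  # saturated table: R = S / n_samples for every sample
  full <- matrix(1L, 3, 3, dimnames = list(paste0("o", 1:3),
                                           paste0("s", 1:3)))
  expect_equal(unname(rarityIndex(full)), rep(3 / 3, 3))

  expect_equal(unname(effectiveSpecies(c(10, 10))), 2)
  expect_equal(unname(effectiveSpecies(c(8, 2))), exp(0.5004024), tolerance = 1e-6)
  expect_equal(unname(effectiveSpecies(c(8, 2))), 1.649385, tolerance = 1e-6)
  expect_equal(unname(effectiveSpecies(c(5, 0, 0))), 1)
  expect_true(is.na(effectiveSpecies(c(0, 0))))
})

test_that("PD, PE, MPD reproduce the worked tree fixture", {
  tr <- t1_tree()
  pa <- f1_pa()
  expect_equal(sum(tr$edge.length), 8)  # eight unit branches

  one <- function(tips) {
    m <- matrix(0L, 5, 1, dimnames = list(LETTERS[1:5], "x"))
    m[tips, 1] <- 1L
    m
  }
  expect_equal(faithPD(one(c("A", "B")), tr)[["x"]], 3)
  expect_equal(faithPD(one(LETTERS[1:5]), tr)[["x"]], 8)
  expect_equal(faithPD(one("A"), tr)[["x"]], 2)
  expect_equal(faithPD(one("A"), tr, includeRoot = FALSE)[["x"]], 0)
  expect_true(is.na(faithPD(one(character(0)), tr)[["x"]]))

  pe <- phyloEndemism(pa, tr)
  expect_equal(pe[["s4"]], 1 + 1 / 2 + 1 / 4)  # E + n3/2 + n2/4

  mpd <- meanPairwiseDist(pa, tr)
  expect_equal(mpd[["s2"]], 4)        # d(A, C)
  expect_equal(mpd[["s1"]], 10 / 3)   # {A,B,C}: 2 + 4 + 4 over 3 pairs
  expect_true(is.na(mpd[["s4"]]))     # single OTU
  two <- cbind(one(c("A", "B")))
  expect_equal(meanPairwiseDist(two, tr)[["x"]], 2)
})

test_that("identical samples give PE = PD / n_samples everywhere", {
  tr <- t1_tree()
  pa <- matrix(1L, 5, 4, dimnames = list(LETTERS[1:5], paste0("s", 1:4)))
  pa[c("D", "E"), ] <- 0L
  pe <- phyloEndemism(pa, tr)
  pd <- faithPD(pa, tr)
  expect_equal(pe, pd / 4)
})

test_that("alpha metrics agree with brute-force oracles on random fixtures", {
  set.seed(123)
  for (rep in 1:60) {
    fx <- random_fixture()
    tr <- fx$tree; pa <- fx$pa
    expect_equal(unname(rarityIndex(pa)), oracle_rarity(pa),
                 tolerance = 1e-9)
    pdWant <- vapply(seq_len(ncol(pa)), function(j) {
      oracle_pd(rownames(pa)[pa[, j] > 0], tr)
    }, numeric(1))
    expect_equal(unname(faithPD(pa, tr)), pdWant, tolerance = 1e-9)
    pdnWant <- vapply(seq_len(ncol(pa)), function(j) {
      oracle_pd(rownames(pa)[pa[, j] > 0], tr, includeRoot = FALSE)
    }, numeric(1))
    expect_equal(unname(faithPD(pa, tr, includeRoot = FALSE)), pdnWant,
                 tolerance = 1e-9)
    expect_equal(unname(phyloEndemism(pa, tr)), unname(oracle_pe(pa, tr)),
                 tolerance = 1e-9)
    mpdWant <- vapply(seq_len(ncol(pa)), function(j) {
      oracle_mpd(rownames(pa)[pa[, j] > 0], tr)
    }, numeric(1))
    expect_equal(unname(meanPairwiseDist(pa, tr)), mpdWant, tolerance = 1e-9)
  }
})

test_that("alpha metrics agree with the field implementations", {
  skip_if_not_installed("picante")
  set.seed(99)
  for (rep in 1:10) {
    fx <- random_fixture(ntips = 12, nsamp = 6)
    comm <- t(fx$pa)
    pd <- picante::pd(comm, fx$tree, include.root = TRUE)
    expect_equal(unname(faithPD(fx$pa, fx$tree)), pd$PD, tolerance = 1e-9)
    mpd <- picante::mpd(comm, stats::cophenetic(fx$tree))
    expect_equal(unname(meanPairwiseDist(fx$pa, fx$tree)), mpd,
                 tolerance = 1e-9)
  }
})

test_that("hill ordering, conservation and monotonicity invariants hold", {
  set.seed(321)
  for (rep in 1:20) {
    fx <- random_fixture(ntips = 10, nsamp = 6)
    pa <- fx$pa; tr <- fx$tree
    cnt <- pa * matrix(rpois(length(pa), 30) + 1L, nrow(pa))
    S <- otuRichness(pa)
    D <- effectiveSpecies(cnt)
    ok <- S > 0
    expect_true(all(D[ok] >= 1 - 1e-9 & D[ok] <= S[ok] + 1e-9))
    R <- rarityIndex(pa)
    expect_true(all(R <= S + 1e-9))
    PD <- faithPD(pa, tr); PE <- phyloEndemism(pa, tr)
    expect_true(all(PE[ok] <= PD[ok] + 1e-9))
    # conservation: summed PE equals total branch length present anywhere;
    # summed rarity equals the number of OTUs present anywhere
    bo <- branchOccurrence(pa, tr)
    expect_equal(sum(PE), sum(bo$length[bo$m > 0]), tolerance = 1e-9)
    expect_equal(sum(R), sum(rowSums(pa) > 0), tolerance = 1e-9)
  }

  # adding an OTU found nowhere else raises R by exactly 1 and PE by at
  # least its terminal branch length
  fx <- random_fixture(ntips = 8, nsamp = 5)
  pa <- fx$pa
  pa["t1", ] <- 0L
  pa2 <- pa; pa2["t1", 2] <- 1L
  expect_equal(rarityIndex(pa2)[[2]], rarityIndex(pa)[[2]] + 1,
               tolerance = 1e-12)
  term <- fx$tree$edge.length[fx$tree$edge[, 2] ==
                                which(fx$tree$tip.label == "t1")]
  expect_gte(phyloEndemism(pa2, fx$tree)[[2]] -
               phyloEndemism(pa, fx$tree)[[2]], term - 1e-9)
})

test_that("rarity equals richness exactly when all present OTUs are single-site", {
  pa <- diag(1L, 4); dimnames(pa) <- list(paste0("o", 1:4), paste0("s", 1:4))
  expect_equal(unname(rarityIndex(pa)), unname(otuRichness(pa)) + 0)
})

test_that("the metric table composes the per-metric computations", {
  x <- simulateCommunities(small_design(seed = 55))
  otuTree(x) <- simulatePhylogeny(nrow(x), seed = 56,
                                  tipLabels = rownames(x))
  mt <- metricTable(x)
  expect_setequal(unique(mt$metric), metricNames())
  real <- setdiff(colnames(x), controlSamples(x))
  expect_setequal(unique(mt$sample_id), real)
  expect_true(all(c("Overall", "Coleoptera", "Rotifera") %in% mt$group))

  # spot-check Overall rows against direct computation
  pa <- presenceAbsence(x, dropControls = TRUE)
  ov <- mt[mt$group == "Overall", ]
  direct <- rarityIndex(pa)
  got <- ov$value[ov$metric == "R_rarity"][match(real,
    ov$sample_id[ov$metric == "R_rarity"])]
  expect_equal(got, unname(direct[real]), tolerance = 1e-9)

  # permuting sample order leaves per-sample values unchanged
  perm <- sample(colnames(x))
  mt2 <- metricTable(x[, perm])
  key <- function(d) d[order(d$sample_id, d$group, d$metric), "value"]
  expect_equal(key(mt2), key(mt), tolerance = 1e-9)

  # group with zero OTUs in a sample: richness 0, D and tree metrics missing
  zeroRows <- mt[mt$value == 0 & mt$metric == "S_richness", ]
  if (nrow(zeroRows)) {
    k <- zeroRows[1, ]
    other <- mt[mt$sample_id == k$sample_id & mt$group == k$group, ]
    expect_true(is.na(other$value[other$metric == "D_effective"]))
  }
})
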