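# Worked fixtures used throughout the suite.
#
# F1: 5 OTUs (A-E) x 4 samples; occurrences n = (A=3, B=1, C=2, D=1, E=1).
# T1: ((A:1,B:1):1,(C:1,(D:1,E:1):1):1); — eight unit-length branches.

f1_pa <- function() {
  pa <- matrix(0L, 5, 4, dimnames = list(LETTERS[1:5], paste0("s", 1:4)))
  pa["A", c(1, 2, 3)] <- 1L
  pa["B", 1] <- 1L
  pa["C", c(1, 2)] <- 1L
  pa["D", 3] <- 1L
  pa["E", 4] <- 1L
  pa
}

t1_tree <- function() {
  ape::read.tree(text = "((A:1,B:1):1,(C:1,(D:1,E:1):1):1);")
}

# random tree + incidence fixture for property tests
random_fixture <- function(ntips = 8, nsamp = 5, p = 0.45) {
  tr <- ape::rphylo(ntips, birth = 1, death = 0)
  tr$tip.label <- paste0("t", seq_len(ntips))
  pa <- matrix(stats::rbinom(ntips * nsamp, 1L, p), ntips, nsamp,
               dimnames = list(tr$tip.label, paste0("s", seq_len(nsamp))))
  for (j in seq_len(nsamp)) {
    if (sum(pa[, j]) == 0L) pa[sample.int(ntips, 1L), j] <- 1L
  }
  list(tree = tr, pa = pa)
}

# a small but complete survey for pipeline-level tests (five groups,
# ~260 OTUs, 5 land uses x 6 sites): cheap enough to regenerate freely
small_design <- function(seed = 101L, ...) {
  simDesign(
    n_per_landuse = 6L, n_controls = 2L,
    groups = c(Coleoptera = 60L, Mites = 50L, Nematoda = 60L,
               Annelida = 40L, Rotifera = 50L),
    depth_mean = 8000, seed = seed, ...
  )
}

toy_experiment <- function() {
  cnt <- matrix(c(3L, 0L, 5L,
                  1L, 2L, 0L,
                  0L, 4L, 4L), 3, 3, byrow = TRUE,
                dimnames = list(c("A", "B", "C"), c("s1", "s2", "ctl")))
  tax <- data.frame(kingdom = "Animalia",
                    phylum = c("Arthropoda", "Nematoda", "Fungi"),
                    row.names = c("A", "B", "C"))
  meta <- data.frame(sample_id = c("s1", "s2", "ctl"),
                     land_use = c("natural_forest", "perennial_cropland", NA),
                     is_control = c(FALSE, FALSE, TRUE))
  RarescapeExperiment(cnt, taxonomy = tax, sampleData = meta,
                      controls = "ctl")
}
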