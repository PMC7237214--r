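#' Design of a synthetic soil-invertebrate survey
#'
#' Bundles the parameters of the community generator. The defaults emulate
#' the statistical structure of the national survey the package is built
#' for: 5 land-use categories x 15 replicate sites plus a few negative
#' controls, a couple of thousand OTUs spread over 17 taxonomic groups,
#' heterogeneous specialist-rich natural-forest communities grading into
#' homogenized generalist-dominated cropland communities, negative-binomial
#' per-site read depth over a lognormal rank-abundance curve, and low-rate
#' cross-sample tag-jump contamination.
#'
#' Each OTU is homed to one land use and is one of three kinds:
#' *shared* (present in every site of its home land use — the homogenized
#' core, a fraction `homogenization[lu]` of that land use's OTUs),
#' *specialist* (present in `1 + Binomial(2, p_specialist_extra)` home
#' sites — mostly single-site), or *generalist* (each home site with
#' probability `p_generalist`, each foreign site with probability
#' `p_spillover`). The specialist fraction of the non-shared OTUs is
#' `specialist_fraction[lu]`. Home land uses are apportioned
#' deterministically so that the *expected* per-site richness is equal
#' across land uses: richness is flat by construction while rarity and
#' phylogenetic rarity decline along the derived land-use rank.
#'
#' @param n_per_landuse replicate sites per land-use category.
#' @param n_controls number of negative-control samples (zero true reads).
#' @param groups named integer vector: OTUs per taxonomic group.
#' @param specialist_fraction,homogenization numeric length 5 in `[0,1]`,
#'   ordered as [landUseLevels()]: specialist fraction sigma and shared-pool
#'   (homogenization) fraction h per land use.
#' @param p_specialist_extra probability parameter of the specialist
#'   occupancy distribution `1 + Binomial(2, p)` (default 0.15: 72% of
#'   specialists are single-site).
#' @param p_generalist per-home-site presence probability of a generalist.
#' @param p_spillover per-foreign-site presence probability of a
#'   generalist.
#' @param depth_mean,depth_dispersion negative-binomial mean and size of
#'   per-site read depth.
#' @param abundance_sdlog sd(log) of the lognormal per-OTU abundance
#'   weights shaping within-site rank-abundance curves.
#' @param tagjump_rate total tag-jump rate rho: a control receives
#'   `Binomial(M_i, rho/n_controls)` reads of OTU i, where `M_i` is the
#'   OTU's maximum count over real samples.
#' @param birth_rate speciation rate of the pure-birth tree.
#' @param radiation_cohesion probability that a specialist OTU settles in
#'   the same site as the previous specialist of its block (default 0.5):
#'   phylogenetically adjacent endemics form local clade radiations, so
#'   whole subclades — internal branches included — are confined to
#'   single sites, the geographic-phylogenetic correlation that makes
#'   phylogenetic rarity the most sensitive land-use indicator. Set to 0
#'   for independent placement.
#' @param endemic_branch_scale optional factor (default 1, i.e. off) by
#'   which the terminal branches of specialist OTUs are stretched, for
#'   emulating relictual, deeply divergent endemic lineages.
#' @param seed integer seed consumed once by [simulateSurvey()].
#' @return a list of class `"simDesign"`.
#' @seealso [simulateSurvey()], [simulateCommunities()],
#'   [simulatePhylogeny()], [injectTagJumps()]
#' @export
simDesign <- function(n_per_landuse = 15L,
                      n_controls = 3L,
                      groups = defaultGroupSizes(),
                      specialist_fraction = c(0.90, 0.70, 0.50, 0.30, 0.10),
                      homogenization = c(0.05, 0.225, 0.40, 0.575, 0.75),
                      p_specialist_extra = 0.15,
                      p_generalist = 0.45,
                      p_spillover = 0.08,
                      depth_mean = 30000,
                      depth_dispersion = 8,
                      abundance_sdlog = 1.5,
                      tagjump_rate = 0.002,
                      birth_rate = 1,
                      radiation_cohesion = 0.5,
                      endemic_branch_scale = 1,
                      seed = NULL) {
  lus <- landUseLevels()
  specialist_fraction <- .namedByLu(specialist_fraction)
  homogenization <- .namedByLu(homogenization)
  stopifnot(
    n_per_landuse >= 1, n_controls >= 0,
    all(groups >= 0), sum(groups) > 0,
    all(specialist_fraction >= 0 & specialist_fraction <= 1),
    all(homogenization >= 0 & homogenization <= 1),
    p_specialist_extra >= 0, p_specialist_extra <= 1,
    p_generalist > 0, p_generalist <= 1,
    p_spillover >= 0, p_spillover <= 1,
    depth_mean > 0, depth_dispersion > 0, abundance_sdlog >= 0,
    tagjump_rate >= 0, tagjump_rate < 1, birth_rate > 0,
    radiation_cohesion >= 0, radiation_cohesion < 1,
    endemic_branch_scale >= 1
  )
  structure(list(
    n_per_landuse = as.integer(n_per_landuse),
    n_controls = as.integer(n_controls),
    groups = groups,
    specialist_fraction = specialist_fraction,
    homogenization = homogenization,
    p_specialist_extra = p_specialist_extra,
    p_generalist = p_generalist,
    p_spillover = p_spillover,
    depth_mean = depth_mean,
    depth_dispersion = depth_dispersion,
    abundance_sdlog = abundance_sdlog,
    tagjump_rate = tagjump_rate,
    birth_rate = birth_rate,
    radiation_cohesion = radiation_cohesion,
    endemic_branch_scale = endemic_branch_scale,
    seed = seed
  ), class = "simDesign")
}

.namedByLu <- function(v) {
  lus <- landUseLevels()
  if (is.null(names(v))) names(v) <- lus
  stopifnot(setequal(names(v), lus))
  v[lus]
}

#' @rdname simDesign
#' @export
defaultGroupSizes <- function() {
  # ~4500 OTUs over the 17 groups, proportioned roughly as in the
  # national survey (insect orders dominant; rotifers and nematodes rich)
  c(Coleoptera = 400L, Diptera = 520L, Hymenoptera = 360L,
    Lepidoptera = 320L, Hemiptera = 300L, OtherInsects = 240L,
    Collembola = 180L, Mites = 320L, NonMiteArachnida = 80L,
    Malacostraca = 40L, Myriapods = 50L, Annelida = 180L, Mollusca = 200L,
    Nematoda = 580L, Platyhelminthes = 40L, Rotifera = 660L,
    Tardigrada = 30L)
}

# expected per-OTU presence probability in a home site (e) and in a
# foreign site (g), per land use
.presenceRates <- function(design) {
  s <- design$specialist_fraction
  h <- design$homogenization
  ek <- (1 + 2 * design$p_specialist_extra) / design$n_per_landuse
  e <- h + (1 - h) * (s * ek + (1 - s) * design$p_generalist)
  g <- (1 - h) * (1 - s) * design$p_spillover
  list(e = e, g = g)
}

# home land-use apportionment weights that equalize expected per-site
# richness across land uses: n_lu proportional to 1 / (e_lu - g_lu)
.homeWeights <- function(design) {
  r <- .presenceRates(design)
  u <- r$e - r$g
  if (any(u <= 0)) stop("design gives foreign presence rate >= home rate")
  w <- 1 / u
  w / sum(w)
}

# deterministic largest-remainder apportionment of n among weights
.apportion <- function(n, weights) {
  q <- n * weights / sum(weights)
  fl <- floor(q)
  rem <- n - sum(fl)
  if (rem > 0) {
    idx <- order(q - fl, decreasing = TRUE)[seq_len(rem)]
    fl[idx] <- fl[idx] + 1
  }
  as.integer(fl)
}

#' Simulate a pure-birth phylogeny
#'
#' Rooted ultrametric Yule tree with positive branch lengths, used as the
#' synthetic stand-in for the marker-gene phylogeny of the OTUs.
#'
#' @param nTips number of tips (>= 2).
#' @param birthRate speciation rate.
#' @param seed optional integer seed (bit-reproducible output).
#' @param tipLabels optional character vector of tip labels, length
#'   `nTips`.
#' @return a `phylo` object.
#' @export
simulatePhylogeny <- function(nTips, birthRate = 1, seed = NULL,
                              tipLabels = NULL) {
  if (nTips < 2L) stop("a phylogeny needs at least 2 tips")
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rphylo(nTips, birth = birthRate, death = 0)
  if (!is.null(tipLabels)) {
    stopifnot(length(tipLabels) == nTips)
    tr$tip.label <- tipLabels
  }
  tr
}

# lineage rows consistent with assignGroups(), one per OTU of a group
.lineageFor <- function(group, n) {
  other_orders <- c("Blattodea", "Orthoptera", "Psocoptera", "Thysanoptera",
                    "Trichoptera", "Dermaptera", "Plecoptera")
  arach_other <- c("Araneae", "Opiliones", "Pseudoscorpiones")
  myri <- c("Chilopoda", "Diplopoda", "Symphyla", "Pauropoda")
  phylum <- class <- subclass <- ord <- rep(NA_character_, n)
  ins5 <- c("Coleoptera", "Diptera", "Hymenoptera", "Lepidoptera",
            "Hemiptera")
  if (group %in% ins5) {
    phylum[] <- "Arthropoda"; class[] <- "Insecta"; ord[] <- group
  } else if (group == "OtherInsects") {
    phylum[] <- "Arthropoda"; class[] <- "Insecta"
    ord <- sample(other_orders, n, replace = TRUE)
  } else if (group == "Collembola") {
    phylum[] <- "Arthropoda"; class[] <- "Collembola"
  } else if (group == "Mites") {
    phylum[] <- "Arthropoda"; class[] <- "Arachnida"; subclass[] <- "Acari"
    ord <- sample(c("Sarcoptiformes", "Trombidiformes", "Mesostigmata"),
                  n, replace = TRUE)
  } else if (group == "NonMiteArachnida") {
    phylum[] <- "Arthropoda"; class[] <- "Arachnida"
    ord <- sample(arach_other, n, replace = TRUE)
  } else if (group == "Malacostraca") {
    phylum[] <- "Arthropoda"; class[] <- "Malacostraca"
  } else if (group == "Myriapods") {
    phylum[] <- "Arthropoda"
    class <- sample(myri, n, replace = TRUE)
  } else {
    phylum[] <- group  # non-arthropod phyla carry their own label
  }
  data.frame(kingdom = "Animalia", phylum = phylum, class = class,
             subclass = subclass, order = ord, stringsAsFactors = FALSE)
}

#' Simulate land-use-structured communities
#'
#' Draws the OTU x sample count table, taxonomy, and sample metadata for a
#' [simDesign()]. See that help page for the occupancy model. Counts are
#' drawn per site: a negative-binomial total depth is allocated to the
#' present OTUs by a multinomial over lognormal abundance weights, with
#' one read reserved per present OTU so that designed incidence survives
#' the count draw. The returned object's `metadata()$truth` records every
#' OTU's home land use and kind (shared / specialist / generalist).
#'
#' @param design a [simDesign()].
#' @param seed optional integer seed; `NULL` continues the caller's RNG
#'   stream (as used by [simulateSurvey()]).
#' @return a [RarescapeExperiment-class] without a tree (see
#'   [simulatePhylogeny()]), controls included as all-zero columns.
#' @export
simulateCommunities <- function(design, seed = design$seed) {
  stopifnot(inherits(design, "simDesign"))
  if (!is.null(seed)) set.seed(seed)
  lus <- landUseLevels()
  nlu <- design$n_per_landuse
  siteLu <- rep(lus, each = nlu)
  codes <- c("NF", "PF", "LG", "HG", "PC")
  siteIds <- paste0(rep(codes, each = nlu), sprintf("%02d", seq_len(nlu)))
  nSites <- length(siteIds)

  homeP <- .homeWeights(design)
  groups <- design$groups
  nOtu <- sum(groups)
  if (nOtu == 0L) stop("design yields an empty table")
  otuIds <- sprintf("OTU%05d", seq_len(nOtu))

  group <- rep(names(groups), times = groups)
  home <- character(nOtu)
  kind <- character(nOtu)
  ptr <- 0L
  for (g in names(groups)) {
    ng <- groups[[g]]
    if (ng == 0L) next
    perLu <- .apportion(ng, homeP)
    hvec <- rep(lus, times = perLu)
    kv <- character(ng)
    off <- 0L
    for (k in seq_along(lus)) {
      nb <- perLu[k]
      if (nb == 0L) next
      nShared <- round(design$homogenization[k] * nb)
      rest <- nb - nShared
      nSpec <- round(design$specialist_fraction[k] * rest)
      kv[off + seq_len(nb)] <- rep(c("shared", "specialist", "generalist"),
                                   c(nShared, nSpec, rest - nSpec))
      off <- off + nb
    }
    home[ptr + seq_len(ng)] <- hvec
    kind[ptr + seq_len(ng)] <- kv
    ptr <- ptr + ng
  }

  pa <- matrix(0L, nOtu, nSites, dimnames = list(otuIds, siteIds))
  lastSpecSite <- NA_integer_
  lastSpecHome <- NA_character_
  for (i in seq_len(nOtu)) {
    homeSites <- which(siteLu == home[i])
    if (kind[i] == "shared") {
      pa[i, homeSites] <- 1L
    } else if (kind[i] == "specialist") {
      # local radiations: phylogenetically adjacent specialists of the
      # same land use tend to share a home site
      if (!is.na(lastSpecSite) && identical(lastSpecHome, home[i]) &&
          stats::runif(1L) < design$radiation_cohesion) {
        site1 <- lastSpecSite
      } else {
        site1 <- sample(homeSites, 1L)
      }
      k <- 1L + stats::rbinom(1L, 2L, design$p_specialist_extra)
      sites <- site1
      if (k > 1L) {
        sites <- c(site1, sample(setdiff(homeSites, site1),
                                 min(k - 1L, length(homeSites) - 1L)))
      }
      pa[i, sites] <- 1L
      lastSpecSite <- site1
      lastSpecHome <- home[i]
    } else {
      occHome <- stats::rbinom(length(homeSites), 1L, design$p_generalist)
      pa[i, homeSites] <- occHome
      foreign <- which(siteLu != home[i])
      if (design$p_spillover > 0) {
        pa[i, foreign] <- stats::rbinom(length(foreign), 1L,
                                        design$p_spillover)
      }
      if (!any(pa[i, ] > 0)) pa[i, sample(homeSites, 1L)] <- 1L
    }
  }

  lambda <- stats::rlnorm(nOtu, meanlog = 0, sdlog = design$abundance_sdlog)
  counts <- matrix(0L, nOtu, nSites, dimnames = dimnames(pa))
  depth <- stats::rnbinom(nSites, mu = design$depth_mean,
                          size = design$depth_dispersion)
  for (j in seq_len(nSites)) {
    idx <- which(pa[, j] > 0)
    if (!length(idx)) next
    dj <- max(depth[j], length(idx))
    extra <- stats::rmultinom(1L, dj - length(idx), prob = lambda[idx])[, 1L]
    counts[idx, j] <- 1L + extra
  }

  if (design$n_controls > 0L) {
    ctrlIds <- sprintf("CTRL%02d", seq_len(design$n_controls))
    counts <- cbind(counts, matrix(0L, nOtu, design$n_controls,
                                   dimnames = list(otuIds, ctrlIds)))
  } else {
    ctrlIds <- character()
  }

  tax <- do.call(rbind, lapply(names(groups), function(g) {
    .lineageFor(g, groups[[g]])
  }))
  rownames(tax) <- otuIds

  meta <- .simulateMetadata(siteIds, siteLu, ctrlIds)
  truth <- data.frame(otu_id = otuIds, group = group, home_landuse = home,
                      kind = kind, lambda = lambda,
                      stringsAsFactors = FALSE)

  x <- RarescapeExperiment(counts, taxonomy = tax, sampleData = meta,
                           controls = ctrlIds)
  S4Vectors::metadata(x)$truth <- truth
  S4Vectors::metadata(x)$design <- design
  x
}

# per-site environment with land-use trends along the derived rank; the
# soil-chemistry panel mirrors a standard agronomic soil test
.simulateMetadata <- function(siteIds, siteLu, ctrlIds) {
  d <- match(siteLu, landUseLevels())
  n <- length(siteIds)
  clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  C <- clip(10 - 1.3 * d + stats::rnorm(n, 0, 1.2), 0.5, 20)
  N <- clip(0.75 - 0.05 * d + stats::rnorm(n, 0, 0.08), 0.05, 2)
  env <- data.frame(
    sample_id = siteIds,
    land_use = siteLu,
    dlur = d,
    is_control = FALSE,
    latitude = stats::runif(n, -46.5, -34.5),
    altitude = clip(600 - 60 * d + stats::rnorm(n, 0, 150), 10, 1000),
    pH = clip(5.0 + 0.25 * d + stats::rnorm(n, 0, 0.25), 3.5, 8.5),
    C = C, N = N, CN = C / N,
    OlsenP = clip(4 + 7 * d + stats::rnorm(n, 0, 5), 1, 100),
    TotalP = clip(300 + 120 * d + stats::rnorm(n, 0, 80), 50, 2000),
    Ca = clip(2 + 1.8 * d + stats::rnorm(n, 0, 1), 0.2, 25),
    Mg = clip(1 + 0.25 * d + stats::rnorm(n, 0, 0.3), 0.1, 10),
    K = clip(0.3 + 0.1 * d + stats::rnorm(n, 0, 0.1), 0.05, 3),
    Na = clip(0.1 + 0.02 * d + stats::rnorm(n, 0, 0.03), 0.01, 1),
    CEC = clip(18 + stats::rnorm(n, 0, 4), 4, 40),
    BaseSat = clip(20 + 12 * d + stats::rnorm(n, 0, 8), 1, 100),
    stringsAsFactors = FALSE
  )
  if (length(ctrlIds)) {
    ctrl <- env[rep(NA_integer_, length(ctrlIds)), ]
    ctrl$sample_id <- ctrlIds
    ctrl$is_control <- TRUE
    env <- rbind(env, ctrl)
  }
  rownames(env) <- env$sample_id
  env
}

#' Inject tag-jump contamination
#'
#' Adds cross-sample index-hopping reads to the negative controls (and,
#' optionally, to real samples): each destination sample receives
#' `Binomial(M_i, rate * share)` reads of OTU i, where `M_i` is the OTU's
#' maximum count over all real samples and `share = 1/n_destinations`, so
#' the expected contaminant count is proportional to the OTU's
#' cross-sample maximum — the relationship the decontamination regression
#' assumes. Real-sample counts are otherwise unchanged.
#'
#' @param x a [RarescapeExperiment-class] with at least one control.
#' @param rate total jump rate rho in `[0, 1)`.
#' @param seed optional integer seed.
#' @param affectReal also spike real samples (default `FALSE`).
#' @return `x` with contaminated counts.
#' @export
injectTagJumps <- function(x, rate, seed = NULL, affectReal = FALSE) {
  if (rate < 0 || rate >= 1) stop("rate must lie in [0, 1)")
  ctrl <- controlSamples(x)
  if (!length(ctrl)) stop("no control samples present in the table")
  if (!is.null(seed)) set.seed(seed)
  cnt <- otuCounts(x)
  real <- setdiff(colnames(cnt), ctrl)
  M <- apply(cnt[, real, drop = FALSE], 1L, max)
  dest <- if (affectReal) colnames(cnt) else ctrl
  share <- 1 / length(dest)
  if (rate > 0) {
    for (j in dest) {
      cnt[, j] <- cnt[, j] + stats::rbinom(nrow(cnt), M, rate * share)
    }
  }
  SummarizedExperiment::assay(x, "counts") <- cnt
  validObject(x)
  x
}

#' Simulate a complete survey
#'
#' One-call generator chaining [simulateCommunities()], a matching
#' [simulatePhylogeny()] over the OTUs, and [injectTagJumps()] at the
#' design's `tagjump_rate`. All randomness is drawn from the design's
#' single seed, so the output is bit-reproducible.
#'
#' @param design a [simDesign()].
#' @param seed integer seed; defaults to `design$seed`.
#' @return a contaminated, tree-equipped [RarescapeExperiment-class]; the
#'   pre-contamination object is kept in `metadata()$clean`.
#' @export
simulateSurvey <- function(design = simDesign(), seed = design$seed) {
  if (!is.null(seed)) set.seed(seed)
  x <- simulateCommunities(design, seed = NULL)
  tr <- simulatePhylogeny(nrow(x), birthRate = design$birth_rate)
  # Tip labels are assigned so that taxonomic groups, and home land uses
  # within them, occupy contiguous clades: communities of a land use hold
  # related lineages, and habitat endemics form deep endemic clades (the
  # structure that makes phylogenetic rarity informative in real soil
  # faunas), rather than scattering ecology at random over the tree.
  truth <- S4Vectors::metadata(x)$truth
  key <- order(match(truth$group, names(design$groups)),
               match(truth$home_landuse, landUseLevels()),
               match(truth$kind, c("shared", "generalist", "specialist")))
  cl <- ape::reorder.phylo(tr, "cladewise")
  tipOrder <- cl$edge[cl$edge[, 2] <= nrow(x), 2]
  labels <- character(nrow(x))
  labels[tipOrder] <- truth$otu_id[key]
  tr$tip.label <- labels
  if (design$endemic_branch_scale > 1) {
    # habitat endemics are deeply divergent: stretch their terminal
    # branches (the assembled tree is therefore not ultrametric)
    spec <- truth$otu_id[truth$kind == "specialist"]
    edgeIdx <- match(match(spec, tr$tip.label), tr$edge[, 2L])
    tr$edge.length[edgeIdx] <- tr$edge.length[edgeIdx] *
      design$endemic_branch_scale
  }
  otuTree(x) <- tr
  clean <- x
  if (design$tagjump_rate > 0 && design$n_controls > 0L) {
    x <- injectTagJumps(x, design$tagjump_rate)
  }
  S4Vectors::metadata(x)$clean <- clean
  x
}
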