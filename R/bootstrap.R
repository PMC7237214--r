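#' Per-group, per-metric land-use ANOVAs
#'
#' One-way ANOVA of each (taxonomic group, metric) combination against
#' land use, the screening step that decides which combinations enter the
#' bootstrap variance comparison.
#'
#' @param mt long metric table from [metricTable()].
#' @param meta sample metadata with `land_use` (row names = sample ids).
#' @param includeOverall keep the `"Overall"` rows (default `FALSE`: the
#'   sensitivity comparison runs across the taxonomic groups).
#' @return data.frame: `group`, `metric`, `F`, `p`, `eta2`, `n`.
#' @export
groupMetricAnova <- function(mt, meta, includeOverall = FALSE) {
  if (!includeOverall) mt <- mt[mt$group != "Overall", , drop = FALSE]
  combos <- unique(mt[, c("group", "metric")])
  res <- lapply(seq_len(nrow(combos)), function(k) {
    sub <- mt[mt$group == combos$group[k] & mt$metric == combos$metric[k], ]
    lu <- meta[sub$sample_id, "land_use"]
    ok <- !is.na(sub$value) & !is.na(lu)
    if (sum(ok) < 4L || length(unique(lu[ok])) < 2L) {
      return(data.frame(group = combos$group[k], metric = combos$metric[k],
                        F = NA_real_, p = NA_real_, eta2 = NA_real_,
                        n = sum(ok)))
    }
    a <- oneWayAnova(sub$value[ok], lu[ok])
    data.frame(group = combos$group[k], metric = combos$metric[k],
               F = a$F, p = a$p, eta2 = a$eta2, n = a$n)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Bootstrap comparison of land-use variance explained per metric
#'
#' Estimates, for each biodiversity metric, the proportion of sample
#' variance attributable to land use (`eta2 = SS_landuse / SS_total` from
#' one-way ANOVAs), with non-parametric bootstrap confidence intervals
#' stratified by taxonomic group.
#'
#' Eligibility: a (group, metric) combination enters if its screening
#' ANOVA has `p < alpha`. If a metric has no significant group at all, it
#' falls back to all groups (`fallbackAll = TRUE`, the default), so every
#' metric still receives a — then necessarily small — variance estimate.
#'
#' Each bootstrap replicate resamples, within every taxonomic group
#' (stratum), that group's samples with replacement *preserving the
#' per-land-use sample counts*, so no replicate can lose a land-use cell
#' and every ANOVA stays well defined. A metric's replicate value is the
#' mean `eta2` over its eligible groups (`pooling = "mean"`, one
#' distribution per metric); `pooling = "pooled"` instead keeps every
#' (group, metric) `eta2` as a separate replicate value. The reported
#' `obs_mean` is the observed (non-bootstrap) mean `eta2` over the
#' eligible groups; `ci_low`/`ci_high` are 2.5/97.5 bootstrap
#' percentiles.
#'
#' @param mt long metric table from [metricTable()].
#' @param meta sample metadata with `land_use`.
#' @param metrics metrics to compare (default [metricNames()]).
#' @param alpha screening significance level (default 0.05).
#' @param nBoot bootstrap replicates (default 999).
#' @param seed integer seed.
#' @param pooling `"mean"` or `"pooled"` (see above).
#' @param fallbackAll fall back to all groups for metrics with no
#'   significant group.
#' @return list of class `"varianceBootstrap"`: `summary` (per metric:
#'   `obs_mean`, `boot_mean`, `ci_low`, `ci_high`, `n_boot`,
#'   `n_groups`, `fallback`), `replicates` (long data.frame of `metric`,
#'   `replicate`, `eta2`), `eligible` (the screening table used).
#' @export
bootstrapVarianceExplained <- function(mt, meta, metrics = metricNames(),
                                       alpha = 0.05, nBoot = 999,
                                       seed = NULL, pooling = c("mean",
                                                                "pooled"),
                                       fallbackAll = TRUE) {
  pooling <- match.arg(pooling)
  if (!is.null(seed)) set.seed(seed)
  mt <- mt[mt$group != "Overall" & mt$metric %in% metrics, , drop = FALSE]
  mt$land_use <- meta[mt$sample_id, "land_use"]
  mt <- mt[!is.na(mt$land_use), , drop = FALSE]
  screen <- groupMetricAnova(mt, meta)
  eligible <- lapply(metrics, function(m) {
    sc <- screen[screen$metric == m & !is.na(screen$p), ]
    sig <- sc$group[sc$p < alpha]
    if (!length(sig) && fallbackAll) {
      list(groups = sc$group, fallback = TRUE)
    } else {
      list(groups = sig, fallback = FALSE)
    }
  })
  names(eligible) <- metrics
  keepMetrics <- metrics[vapply(eligible, function(e) length(e$groups) > 0,
                                logical(1))]
  if (!length(keepMetrics)) stop("no eligible (group, metric) combination")

  allGroups <- unique(unlist(lapply(eligible[keepMetrics],
                                    function(e) e$groups)))
  # cache per (group, metric): values and land-use factor aligned to the
  # group's sample set
  cells <- list()
  strata <- list()
  for (g in allGroups) {
    sub <- mt[mt$group == g, ]
    ids <- unique(sub$sample_id)
    lu <- factor(meta[ids, "land_use"], levels = landUseLevels())
    strata[[g]] <- split(seq_along(ids), lu, drop = TRUE)
    for (m in keepMetrics) {
      v <- sub$value[sub$metric == m][match(ids, sub$sample_id[sub$metric == m])]
      cells[[paste(g, m, sep = "\r")]] <- list(ids = ids, lu = lu, v = v)
    }
  }
  eta2Of <- function(v, lu) {
    ok <- !is.na(v)
    if (length(unique(lu[ok])) < 2L) return(NA_real_)
    tryCatch(oneWayAnova(v[ok], lu[ok])$eta2, error = function(e) NA_real_)
  }
  obs <- vapply(keepMetrics, function(m) {
    mean(vapply(eligible[[m]]$groups, function(g) {
      cl <- cells[[paste(g, m, sep = "\r")]]
      eta2Of(cl$v, cl$lu)
    }, numeric(1)), na.rm = TRUE)
  }, numeric(1))

  reps <- vector("list", nBoot)
  for (b in seq_len(nBoot)) {
    # one stratified resampling per replicate, shared across metrics
    idxMap <- lapply(strata, function(cellIdx) {
      unlist(lapply(cellIdx, function(ii) {
        ii[sample.int(length(ii), length(ii), replace = TRUE)]
      }), use.names = FALSE)
    })
    vals <- lapply(keepMetrics, function(m) {
      per <- vapply(eligible[[m]]$groups, function(g) {
        cl <- cells[[paste(g, m, sep = "\r")]]
        take <- idxMap[[g]]
        eta2Of(cl$v[take], cl$lu[take])
      }, numeric(1))
      if (pooling == "mean") mean(per, na.rm = TRUE) else per
    })
    names(vals) <- keepMetrics
    reps[[b]] <- vals
  }
  repDf <- do.call(rbind, lapply(seq_len(nBoot), function(b) {
    do.call(rbind, lapply(keepMetrics, function(m) {
      data.frame(metric = m, replicate = b, eta2 = reps[[b]][[m]],
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(repDf) <- NULL
  summ <- do.call(rbind, lapply(keepMetrics, function(m) {
    v <- repDf$eta2[repDf$metric == m]
    data.frame(metric = m, obs_mean = obs[[m]], boot_mean = mean(v),
               ci_low = unname(stats::quantile(v, 0.025, na.rm = TRUE)),
               ci_high = unname(stats::quantile(v, 0.975, na.rm = TRUE)),
               n_boot = nBoot, n_groups = length(eligible[[m]]$groups),
               fallback = eligible[[m]]$fallback,
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  structure(list(summary = summ, replicates = repDf, eligible = screen),
            class = "varianceBootstrap")
}

#' @export
print.varianceBootstrap <- function(x, ...) {
  cat("Stratified bootstrap of land-use variance explained\n")
  print(x$summary, digits = 3)
  invisible(x)
}
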