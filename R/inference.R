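#' One-way ANOVA of a metric across land uses
#'
#' Standard between/within sums-of-squares decomposition with casewise
#' deletion of missing values. Degenerate input (all values identical)
#' returns `F = 0`, `p = 1` rather than 0/0.
#'
#' @param values numeric vector of per-sample metric values.
#' @param groups factor of land-use (or other) labels, same length.
#' @return list: `SS_between`, `SS_within`, `SS_total`, `df_between`,
#'   `df_within`, `F`, `p`, `eta2` (`SS_between / SS_total`), `n`.
#' @export
oneWayAnova <- function(values, groups) {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  groups <- droplevels(factor(groups[keep]))
  tb <- table(groups)
  if (length(tb) < 2L) {
    stop("fewer than 2 groups with data (", paste(names(tb), collapse = ", "),
         ")")
  }
  if (any(tb < 1L)) {
    stop("group(s) empty after dropping missing values: ",
         paste(names(tb)[tb < 1L], collapse = ", "))
  }
  n <- length(values)
  gm <- tapply(values, groups, mean)
  grand <- mean(values)
  ssb <- sum(tb * (gm - grand)^2)
  sst <- sum((values - grand)^2)
  ssw <- sst - ssb
  dfb <- length(tb) - 1L
  dfw <- n - length(tb)
  if (sst < .Machine$double.eps) {
    return(list(SS_between = 0, SS_within = 0, SS_total = 0,
                df_between = dfb, df_within = dfw, F = 0, p = 1,
                eta2 = 0, n = n))
  }
  Fv <- (ssb / dfb) / (ssw / dfw)
  list(SS_between = ssb, SS_within = ssw, SS_total = sst,
       df_between = dfb, df_within = dfw, F = Fv,
       p = stats::pf(Fv, dfb, dfw, lower.tail = FALSE),
       eta2 = ssb / sst, n = n)
}

#' Tukey HSD pairwise comparisons
#'
#' All pairwise group contrasts with studentized-range adjusted p-values
#' (Tukey-Kramer correction for unequal group sizes), via
#' [stats::TukeyHSD()]. With two groups the adjusted p equals the pooled
#' two-sample t-test p.
#'
#' @inheritParams oneWayAnova
#' @param conf.level confidence level of the intervals.
#' @return data.frame: `pair`, `diff`, `lwr`, `upr`, `p_adj`.
#' @export
tukeyPairwise <- function(values, groups, conf.level = 0.95) {
  keep <- !is.na(values) & !is.na(groups)
  df <- data.frame(value = values[keep],
                   group = droplevels(factor(groups[keep])))
  fit <- stats::aov(value ~ group, data = df)
  tk <- stats::TukeyHSD(fit, conf.level = conf.level)$group
  out <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                    lwr = tk[, "lwr"], upr = tk[, "upr"],
                    p_adj = tk[, "p adj"], row.names = NULL,
                    stringsAsFactors = FALSE)
  out
}

#' Linear trend over derived land-use rank
#'
#' Ordinary least squares of a metric on the numeric derived land-use
#' rank (1-5), with the F test of zero slope.
#'
#' @param values numeric vector.
#' @param dlur integer rank 1-5 per sample.
#' @return list: `slope`, `intercept`, `F`, `p`, `r2`, `n`.
#' @export
dlurTrend <- function(values, dlur) {
  keep <- !is.na(values) & !is.na(dlur)
  values <- values[keep]; dlur <- as.numeric(dlur[keep])
  if (length(unique(dlur)) < 3L) {
    stop("need at least 3 distinct rank values")
  }
  fit <- stats::lm(values ~ dlur)
  an <- stats::anova(fit)
  s <- summary(fit)
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       F = an$`F value`[1L], p = an$`Pr(>F)`[1L],
       r2 = s$r.squared, n = length(values))
}

#' Sequential (Type-I) ANOVA over ordered model terms
#'
#' Fits a fixed-effects linear model with the terms entered in the given
#' order and returns the sequential sums of squares, so later terms are
#' charged only with variation unexplained by earlier ones — e.g. whether
#' land-use category explains anything beyond the derived land-use rank.
#' Rank-deficient columns introduced by later terms are dropped by the
#' least-squares fit (their df shrink accordingly).
#'
#' @param values numeric response vector.
#' @param data data.frame holding the predictor columns (e.g. `dlur`,
#'   `land_use`, `taxonomic_group`).
#' @param terms character vector of model terms in entry order;
#'   interactions as `"a:b"`.
#' @return data.frame with one row per term plus `Residuals`: `term`,
#'   `df`, `SS`, `F`, `p`.
#' @export
sequentialAnova <- function(values, data, terms) {
  stopifnot(length(terms) >= 1L)
  df <- data.frame(.y = values, data, check.names = FALSE)
  df <- df[stats::complete.cases(df[, c(".y", all.vars(
    stats::reformulate(terms)))]), , drop = FALSE]
  form <- stats::reformulate(terms, response = ".y")
  fit <- stats::lm(form, data = df)
  if (fit$df.residual < 1L) stop("no residual degrees of freedom")
  an <- stats::anova(fit)
  data.frame(term = rownames(an), df = an$Df, SS = an$`Sum Sq`,
             F = an$`F value`, p = an$`Pr(>F)`, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' PCA of environmental covariates
#'
#' Principal components of the correlation matrix of spatial and
#' soil-chemistry variables (each variable standardized to unit
#' variance), for use as covariates in [sequentialAnova()]. Incomplete
#' samples are dropped casewise; constant variables are dropped with a
#' warning.
#'
#' @param env numeric data.frame / matrix, samples x variables.
#' @return list: `scores`, `loadings`, `varprop` (non-increasing, sums to
#'   1), `dropped`, `samples` (ids of complete cases).
#' @export
pcaCovariates <- function(env) {
  env <- as.data.frame(env)
  num <- vapply(env, is.numeric, logical(1))
  env <- env[, num, drop = FALSE]
  cc <- stats::complete.cases(env)
  if (sum(cc) < 2L) stop("fewer than 2 complete-case samples")
  env <- env[cc, , drop = FALSE]
  sds <- vapply(env, stats::sd, numeric(1))
  dropped <- names(env)[sds == 0 | is.na(sds)]
  if (length(dropped)) {
    warning("dropping constant variable(s): ",
            paste(dropped, collapse = ", "))
    env <- env[, setdiff(names(env), dropped), drop = FALSE]
  }
  fit <- stats::prcomp(env, center = TRUE, scale. = TRUE)
  varprop <- fit$sdev^2 / sum(fit$sdev^2)
  list(scores = fit$x, loadings = fit$rotation, varprop = varprop,
       dropped = dropped, samples = rownames(env))
}

#' Kruskal-Wallis comparison of metric sensitivity
#'
#' Compares the bootstrap distributions of land-use variance proportions
#' across biodiversity metrics with a tie-corrected Kruskal-Wallis test,
#' followed by pairwise Wilcoxon rank-sum post-hoc tests with Holm
#' adjustment.
#'
#' @param boot a [bootstrapVarianceExplained()] result, or a data.frame
#'   with columns `metric` and `eta2`.
#' @return list: `chisq`, `df`, `p`, `posthoc` (matrix of adjusted
#'   pairwise p-values).
#' @export
compareMetricSensitivity <- function(boot) {
  df <- if (is.data.frame(boot)) boot else boot$replicates
  stopifnot(all(c("metric", "eta2") %in% names(df)))
  df$metric <- factor(df$metric)
  if (nlevels(df$metric) < 2L) stop("need at least 2 metrics to compare")
  kw <- stats::kruskal.test(eta2 ~ metric, data = df)
  ph <- stats::pairwise.wilcox.test(df$eta2, df$metric, p.adjust.method =
                                      "holm", exact = FALSE)
  list(chisq = unname(kw$statistic), df = unname(kw$parameter),
       p = kw$p.value, posthoc = ph$p.value)
}
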