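test_that("one-way ANOVA reproduces the hand decomposition", {
  a <- oneWayAnova(c(1, 2, 3, 4, 5, 6), rep(c("g1", "g2"), each = 3))
  expect_equal(a$SS_between, 13.5, tolerance = 1e-12)
  expect_equal(a$SS_within, 4, tolerance = 1e-12)
  expect_equal(a$F, 13.5, tolerance = 1e-12)
  expect_equal(a$df_between, 1); expect_equal(a$df_within, 4)
  expect_equal(a$eta2, 13.5 / 17.5, tolerance = 1e-12)
  # cross-check against stats::aov
  fit <- stats::anova(stats::aov(v ~ g, data.frame(
    v = c(1, 2, 3, 4, 5, 6), g = rep(c("g1", "g2"), each = 3))))
  expect_equal(a$F, fit$`F value`[1], tolerance = 1e-12)
  expect_equal(a$p, fit$`Pr(>F)`[1], tolerance = 1e-12)

  cst <- oneWayAnova(rep(2, 6), rep(c("a", "b"), 3))
  expect_equal(cst$F, 0); expect_equal(cst$p, 1)

  expect_error(oneWayAnova(c(1, 2, NA, NA), rep(c("a", "b"), each = 2)),
               "fewer than 2 groups")
})

test_that("ANOVA holds its nominal type-I error on null data", {
  set.seed(50)
  n <- 1000
  rej <- vapply(seq_len(n), function(i) {
    v <- rnorm(25)
    oneWayAnova(v, rep(letters[1:5], each = 5))$p < 0.05
  }, logical(1))
  ci <- 2.58 * sqrt(0.05 * 0.95 / n)
  expect_lt(abs(mean(rej) - 0.05), ci + 1e-9)
})

test_that("Tukey HSD matches the t-test with two groups and is symmetric", {
  set.seed(51)
  v <- rnorm(12); g <- rep(c("a", "b"), each = 6)
  tk <- tukeyPairwise(v, g)
  tt <- t.test(v ~ g, var.equal = TRUE)$p.value
  expect_equal(tk$p_adj, tt, tolerance = 1e-6)

  # identical groups: adjusted p ~ 1
  v2 <- rep(c(1, 2, 3), 3)
  g2 <- rep(c("a", "b", "c"), each = 3)
  tk2 <- tukeyPairwise(v2, g2)
  expect_true(all(tk2$p_adj > 0.999))

  # {1,2,3}, {4,5,6}, {4,5,6}: the duplicated pair differs by 0
  v3 <- c(1, 2, 3, 4, 5, 6, 4, 5, 6)
  g3 <- rep(c("a", "b", "c"), each = 3)
  tk3 <- tukeyPairwise(v3, g3)
  row <- tk3[tk3$pair == "c-b", ]
  expect_equal(row$diff, 0, tolerance = 1e-12)
  expect_gt(row$p_adj, 0.999)
})

test_that("DLUR trend fits, reverses, and refuses degenerate rank spreads", {
  d <- rep(1:5, each = 3)
  v <- 2 - 0.3 * d
  fit <- suppressWarnings(dlurTrend(v, d))  # exact linear fit
  expect_equal(fit$slope, -0.3, tolerance = 1e-12)
  expect_equal(fit$r2, 1, tolerance = 1e-12)

  set.seed(52)
  v2 <- rnorm(15)
  a <- dlurTrend(v2, d)
  b <- dlurTrend(v2, 6 - d)  # reversed ranks
  expect_equal(b$slope, -a$slope, tolerance = 1e-12)
  expect_equal(b$F, a$F, tolerance = 1e-12)

  expect_error(dlurTrend(rnorm(4), c(1, 1, 2, 2)), "3 distinct")
})

test_that("sequential ANOVA nests and matches the one-way decomposition", {
  set.seed(53)
  d <- data.frame(dlur = rep(1:5, each = 4),
                  land_use = factor(rep(landUseLevels(), each = 4)))
  v <- rnorm(20, mean = d$dlur)

  one <- oneWayAnova(v, d$land_use)
  seqA <- sequentialAnova(v, d, "land_use")
  expect_equal(seqA$SS[1], one$SS_between, tolerance = 1e-9)
  expect_equal(seqA$F[1], one$F, tolerance = 1e-9)

  # data linear in dlur: adding land_use after dlur explains ~nothing
  # (land_use is dlur-collinear here so its increment is pure noise SS)
  seqB <- sequentialAnova(v, d, c("dlur", "land_use"))
  expect_lt(seqB$SS[2] / sum(seqB$SS), 0.25)
  expect_equal(seqB$df[2], 3)  # 4 categories free after the linear rank
  expect_gt(seqB$p[1], 0); expect_lt(seqB$p[1], 1e-4)

  # balanced orthogonal two-factor design: order does not matter
  d2 <- expand.grid(f1 = factor(c("x", "y")), f2 = factor(c("u", "v", "w")))
  d2 <- d2[rep(1:6, 3), ]
  v2 <- rnorm(18)
  s1 <- sequentialAnova(v2, d2, c("f1", "f2"))
  s2 <- sequentialAnova(v2, d2, c("f2", "f1"))
  expect_equal(s1$SS[s1$term == "f1"], s2$SS[s2$term == "f1"],
               tolerance = 1e-9)
  expect_equal(s1$SS[s1$term == "f2"], s2$SS[s2$term == "f2"],
               tolerance = 1e-9)
})

test_that("covariate PCA standardizes, drops constants, and orders variance", {
  set.seed(54)
  z <- rnorm(30)
  env <- data.frame(a = z, b = 2 * z + 1)  # perfectly correlated
  p <- pcaCovariates(env)
  expect_equal(p$varprop[1], 1, tolerance = 1e-9)

  env2 <- data.frame(a = rnorm(30), k = rep(1, 30))
  expect_warning(p2 <- pcaCovariates(env2), "constant")
  expect_equal(length(p2$varprop), 1)
  expect_equal(p2$varprop[1], 1)

  env3 <- as.data.frame(matrix(rnorm(300 * 6), 300, 6))
  p3 <- pcaCovariates(env3)
  expect_true(all(diff(p3$varprop) <= 1e-12))
  expect_equal(sum(p3$varprop), 1, tolerance = 1e-9)
  expect_true(all(abs(p3$varprop - 1 / 6) < 0.1))  # near-identity correlation

  # casewise deletion of incomplete samples
  env4 <- data.frame(a = c(NA, rnorm(9)), b = rnorm(10))
  expect_equal(length(pcaCovariates(env4)$samples), 9)
})

test_that("metric sensitivity comparison matches rank arithmetic", {
  # identical distributions: H ~ 0, p ~ 1
  v <- rep(seq(0.1, 0.9, length.out = 50), 3)
  df <- data.frame(metric = rep(c("A", "B", "C"), each = 50), eta2 = v)
  res <- compareMetricSensitivity(df)
  expect_lt(res$chisq, 1e-9)
  expect_gt(res$p, 0.999)

  # complete separation of two metrics: closed-form H from rank sums
  n <- 100
  df2 <- data.frame(metric = rep(c("lo", "hi"), each = n),
                    eta2 = c(seq(0, 0.1, length.out = n),
                             seq(0.5, 0.9, length.out = n)))
  res2 <- compareMetricSensitivity(df2)
  N <- 2 * n
  Hexp <- 12 / (N * (N + 1)) * (n * (50.5 - (N + 1) / 2)^2 +
                                  n * (150.5 - (N + 1) / 2)^2)
  expect_equal(res2$chisq, Hexp, tolerance = 1e-9)
  expect_lt(res2$p, 1e-10)

  expect_error(compareMetricSensitivity(df[df$metric == "A", ]),
               "at least 2 metrics")
})
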