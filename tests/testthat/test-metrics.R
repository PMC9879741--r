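mkReport <- function(body, lung = body + 10, iso = 0, src = "ground_truth") {
  bb <- BoundingBox3D(body + 50, body - 50, c(-100, 100), c(-100, 100))
  lb <- BoundingBox3D(lung + 30, lung - 30, c(-80, 80), c(-80, 80))
  new("CenterlineReport", bodyCenterline = body, lungCenterline = lung,
      bodyBBox = bb, lungBBox = lb, perSliceCenterlines = NULL,
      truncated = FALSE, lungFallback = FALSE, source = src,
      isocenterY = iso, caseId = "t")
}

test_that("positioning errors follow the definitions and sign convention", {
  # bcdl = bcgth -> bcap = 0
  e0 <- positioningErrors(mkReport(12), mkReport(12, src = "predicted"))
  expect_equal(e0$bcap, 0)
  # centerline 12 mm below the isocenter -> bcmp = -12 (below the gantry centre)
  eNeg <- positioningErrors(mkReport(-12), mkReport(-12, src = "predicted"))
  expect_equal(eNeg$bcmp, -12)
  # bcdl = 10, bcgth = 12, isocenter = 0 -> bcap = -2, bcmp = 12
  e <- positioningErrors(mkReport(12), mkReport(10, src = "predicted"))
  expect_equal(e$bcap, -2)
  expect_equal(e$bcmp, 12)
  expect_equal(e$absBcap, 2)
  # lung metrics follow the same formulas
  expect_equal(e$lcap, -2)
  expect_equal(e$lcmp, 22)
})

test_that("frame mismatch between reports is an error", {
  expect_error(positioningErrors(mkReport(0, iso = 0),
                                 mkReport(0, iso = 5, src = "predicted")),
               "frame")
})

test_that("cohort summaries compute the advertised statistics", {
  df <- data.frame(bcap = rep(3, 10))
  s <- cohortSummary(df, metrics = "bcap")
  expect_equal(s$mean, 3); expect_equal(s$sd, 0)
  expect_equal(s$ciHigh - s$ciLow, 0)

  s2 <- cohortSummary(data.frame(bcap = c(-10, 10)), metrics = "bcap")
  expect_equal(s2$mean, 0)
  expect_equal(s2$fracOver10, 0)    # strictly greater than 10

  set.seed(1)
  s3 <- cohortSummary(data.frame(bcap = rnorm(1000, 0, 7.73)),
                      metrics = "bcap")
  expect_lt(abs(s3$sd - 7.73) / 7.73, 0.10)

  expect_error(cohortSummary(data.frame(bcap = 1), metrics = "bcap"),
               "at least two")
})

test_that("Mann-Whitney exact branch reproduces the textbook example", {
  r <- mannWhitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$p, 0.1)
  expect_identical(r$method, "exact")
})

test_that("Mann-Whitney on identical samples returns p = 1", {
  r <- mannWhitney(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$p, 1)
  expect_warning(r2 <- mannWhitney(rep(2, 4), rep(2, 5)), "identical")
  expect_equal(r2$p, 1)
})

test_that("swapping the samples mirrors U and keeps the p value", {
  set.seed(8)
  a <- rnorm(5); b <- rnorm(4) + 1
  r1 <- mannWhitney(a, b)
  r2 <- mannWhitney(b, a)
  expect_equal(r1$U + r2$U, length(a) * length(b))
  expect_equal(r1$p, r2$p)
})

test_that("exact branch equals brute-force enumeration for all n_a + n_b <= 10", {
  set.seed(13)
  for (na in 1:5) {
    for (nb in na:(10 - na)) {
      for (rep in 1:2) {
        a <- sample(1:6, na, replace = TRUE)   # ties likely
        b <- sample(1:6, nb, replace = TRUE)
        if (length(unique(c(a, b))) == 1L) next
        got <- mannWhitney(a, b, exactThreshold = 10L)
        expect_identical(got$method, "exact")
        expect_equal(got$p, enumMannWhitneyP(a, b),
                     info = sprintf("na=%d nb=%d", na, nb))
      }
    }
  }
})

test_that("the normal-approximation branch tracks wilcox.test with ties", {
  set.seed(4)
  a <- round(rnorm(40), 1); b <- round(rnorm(35, 0.4), 1)
  got <- mannWhitney(a, b, exactThreshold = 5L)
  ref <- suppressWarnings(stats::wilcox.test(a, b, correct = TRUE))
  expect_identical(got$method, "normal")
  expect_equal(got$U, unname(ref$statistic))
  expect_equal(got$p, ref$p.value, tolerance = 1e-8)
})

test_that("Spearman correlation matches the hand-ranked formula", {
  expect_equal(spearmanCorr(1:10, (1:10)^3)$rho, 1)
  expect_equal(spearmanCorr(1:10, -(1:10))$rho, -1)
  x <- c(3, 1, 4, 1.5, 9); y <- c(2.7, 1.8, 2.8, 1.2, 5.7)
  d <- rank(x) - rank(y)
  handRho <- 1 - 6 * sum(d^2) / (5 * (25 - 1))
  r <- spearmanCorr(x, y)
  expect_equal(r$rho, handRho)
  ref <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  expect_equal(r$rho, unname(ref$estimate))
  expect_error(spearmanCorr(1:2, 1:2), "n >= 3")
})

test_that("KS normality behaves on normal and bimodal samples", {
  set.seed(2)
  x <- rnorm(100)
  r <- ksNormality(x, nsim = 499L, seed = 3)
  expect_gte(r$statistic, 0); expect_lte(r$statistic, 1)
  # the statistic itself is the Lilliefors statistic
  ref <- nortest::lillie.test(x)
  expect_equal(r$statistic, unname(ref$statistic), tolerance = 1e-12)

  ok <- 0
  for (s in 1:50) {
    xs <- rnorm(60)                       # draws under the null
    ok <- ok + (ksNormality(xs, nsim = 199L, seed = s)$p > 0.05)
  }
  expect_gte(ok, 45)                      # >= 90% of seeded runs

  bim <- c(rnorm(60, -4, 0.3), rnorm(60, 4, 0.3))
  expect_lt(ksNormality(bim, nsim = 999L, seed = 7)$p, 0.01)
})
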