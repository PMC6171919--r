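test_that("ANOVA decomposition matches hand values and aov()", {
  d1 <- anovaDecompose(rbind(c(1, 1), c(2, 2), c(3, 3)))
  expect_equal(d1@msW, 0)
  expect_equal(d1@msE, 0)
  expect_equal(d1@msR, 2)
  d2 <- anovaDecompose(rbind(c(1, 2), c(1, 2), c(1, 2)))
  expect_equal(d2@msR, 0)
  expect_equal(d2@msC, 1.5)
  expect_equal(d2@msE, 0)
  withr::with_seed(15, {
    for (rep in 1:10) {
      m <- matrix(rnorm(30), 10, 3)
      dec <- anovaDecompose(m)
      # independent brute-force sums of squares
      br <- bruteAnova(m)
      expect_equal(dec@msR, br$msR, tolerance = 1e-10)
      expect_equal(dec@msC, br$msC, tolerance = 1e-10)
      expect_equal(dec@msE, br$msE, tolerance = 1e-10)
      expect_equal(dec@msW, br$msW, tolerance = 1e-10)
      # base-R aov as a second, model-based oracle
      df <- data.frame(y = as.vector(m),
                       row = factor(rep(1:10, 3)),
                       col = factor(rep(1:3, each = 10)))
      ms <- summary(stats::aov(y ~ row + col, df))[[1]][["Mean Sq"]]
      expect_equal(dec@msR, ms[1], tolerance = 1e-9)
      expect_equal(dec@msC, ms[2], tolerance = 1e-9)
      expect_equal(dec@msE, ms[3], tolerance = 1e-9)
      # both sums-of-squares identities
      n <- 10; k <- 3
      expect_equal((n - 1) * dec@msR + n * (k - 1) * dec@msW, br$ssTotal,
                   tolerance = 1e-9)
      expect_equal(n * (k - 1) * dec@msW,
                   (k - 1) * dec@msC + (n - 1) * (k - 1) * dec@msE,
                   tolerance = 1e-9)
    }
  })
  expect_error(anovaDecompose(matrix(1:3, 3, 1)), "k >= 2")
})

test_that("one-way ICC matches hand cases and respects its lower bound", {
  expect_equal(iccOneWay(rbind(c(1, 1), c(2, 2), c(3, 3)))$estimate, 1)
  expect_equal(iccOneWay(rbind(c(1, 2), c(2, 1)))$estimate, -1)
  withr::with_seed(22, {
    for (rep in 1:30) {
      k <- sample(2:5, 1)
      m <- matrix(rnorm(6 * k), 6, k)
      expect_gte(iccOneWay(m)$estimate, -1 / (k - 1) - 1e-12)
    }
  })
})

test_that("two-way mixed ICC(A,1) penalizes offsets and recovers the truth", {
  m <- rbind(c(1, 1), c(2, 2), c(3, 3))
  expect_equal(iccTwoWayMixed(m)$estimate, 1)
  # constant column offset: absolute agreement drops below 1
  mo <- cbind(1:6, 1:6 + 2)
  expect_lt(iccTwoWayMixed(mo)$estimate, 1)
  expect_gt(iccTwoWayMixed(mo)$estimate, 0)
  # Monte-Carlo against the analytic ICC 4/6 (mean over replicates: with
  # k = 3 realized columns a single estimate scatters well beyond this)
  est <- vapply(1:100, function(s)
    iccTwoWayMixed(simulateTwoWay(twoWaySpec(500, 3, varRow = 4, varCol = 1,
                                             varErr = 1, seed = s)))$estimate,
    numeric(1))
  expect_lt(abs(mean(est) - 4 / 6), 0.03)
})

test_that("confidence intervals bracket the estimate and tighten with alpha", {
  m <- simulateTwoWay(twoWaySpec(20, 3, varRow = 2, varCol = 0.3,
                                 varErr = 1, seed = 44L))
  for (fitFun in list(iccOneWay, iccTwoWayMixed)) {
    f05 <- fitFun(m, alpha = 0.05)
    f10 <- fitFun(m, alpha = 0.10)
    expect_lte(f05$ci_low, f05$estimate)
    expect_gte(f05$ci_high, f05$estimate)
    expect_gt(f10$ci_low, f05$ci_low)
    expect_lt(f10$ci_high, f05$ci_high)
  }
  # identical columns: upper bound reaches 1
  ident <- rbind(c(1, 1), c(2, 2), c(3, 3))
  expect_equal(iccOneWay(ident)$ci_high, 1)
  expect_equal(iccTwoWayMixed(ident)$ci_high, 1)
})

test_that("classification implements the printed four-tier bounds", {
  expect_equal(classifyReliability(0.97), "excellent")
  expect_equal(classifyReliability(0.75), "excellent") # closed lower bound
  expect_equal(classifyReliability(0.749999), "good")
  expect_equal(classifyReliability(0.6), "good")
  expect_equal(classifyReliability(0.59), "fair")
  expect_equal(classifyReliability(0.4), "fair")
  expect_equal(classifyReliability(0.399), "poor")
  expect_equal(classifyReliability(-0.2), "poor")
  # basis = CI lower bound downgrades a high estimate with a wide interval
  expect_equal(classifyReliability(0.35), "poor") # estimate 0.80, ci_low 0.35
})

test_that("Lin's CCC matches its closed form and known inequality", {
  expect_equal(ccc(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(ccc(c(1, 2, 3), c(2, 3, 4)), 4 / 7)
  withr::with_seed(18, {
    for (rep in 1:20) {
      x <- rnorm(15); y <- rnorm(15, mean = 0.3)
      expect_lte(abs(ccc(x, y)), abs(cor(x, y)) + 1e-12)
    }
  })
  # k > 2 columns: mean of pairwise CCCs
  m <- matrix(rnorm(30), 10, 3)
  expect_equal(ccc(m),
               mean(c(ccc(m[, 1], m[, 2]), ccc(m[, 1], m[, 3]),
                      ccc(m[, 2], m[, 3]))))
  expect_true(is.na(ccc(rep(1, 5), rep(1, 5))))
})

test_that("ICC-CCC concordance is a rank statistic", {
  icc <- c(0.1, 0.5, 0.3, 0.9, 0.7)
  expect_equal(iccCccConcordance(icc, icc), list(rho = 1, r_squared = 1,
                                                 n = 5))
  mono <- iccCccConcordance(icc, icc^3)
  expect_equal(mono$rho, 1)
  expect_lt(mono$r_squared, 1)
  expect_error(iccCccConcordance(rep(0.5, 5), icc), "ties")
  # matches a brute-force rank correlation
  withr::with_seed(2, { a <- runif(12); b <- a + rnorm(12, sd = 0.1) })
  expect_equal(iccCccConcordance(a, b)$rho, cor(rank(a), rank(b)))
})

test_that("category comparisons use the exact rank-sum null", {
  vals <- c(s1 = 0.9, s2 = 0.91, s3 = 0.92,
            h1 = 0.9, h2 = 0.91, h3 = 0.92,
            t1 = 0.1, t2 = 0.11, t3 = 0.12)
  categ <- c(s1 = "SHP", s2 = "SHP", s3 = "SHP",
             h1 = "HIS", h2 = "HIS", h3 = "HIS",
             t1 = "TXT", t2 = "TXT", t3 = "TXT")
  cmp <- compareCategories(vals, categ)
  shpTxt <- cmp[cmp$category_a == "SHP" & cmp$category_b == "TXT", ]
  expect_equal(shpTxt$p_value, 0.1) # exact two-sided minimum at 3 vs 3
  expect_equal(shpTxt$direction, 1)
  shpHis <- cmp[cmp$category_a == "SHP" & cmp$category_b == "HIS", ]
  expect_equal(shpHis$p_value, 1)
  # invariance under monotone transforms
  cmp2 <- compareCategories(qnorm((vals + 1) / 3), categ)
  expect_equal(cmp2$p_value, cmp$p_value)
})

test_that("estimates are invariant to row permutation (and column for two-way)", {
  withr::with_seed(55, m <- matrix(rnorm(24), 8, 3))
  p <- sample(8)
  expect_equal(iccOneWay(m[p, ])$estimate, iccOneWay(m)$estimate)
  expect_equal(iccTwoWayMixed(m[p, ])$estimate, iccTwoWayMixed(m)$estimate)
  expect_equal(iccTwoWayMixed(m[, c(2, 3, 1)])$estimate,
               iccTwoWayMixed(m)$estimate)
})
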