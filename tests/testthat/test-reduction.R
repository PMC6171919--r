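test_that("patient averages match a brute-force group mean", {
  tab <- mkFeatureTable(data.frame(f1 = c(2, 4, 1, 3, 10, 20)),
                        patients = c("P1", "P1", "P2", "P2", "P3", "P3"))
  avg <- patientAverages(tab)
  expect_equal(avg$f1, c(3, 2, 15))
  # one row per patient: averages equal the rows
  tab1 <- mkFeatureTable(data.frame(f1 = c(5, 7)), patients = c("P1", "P2"))
  expect_equal(patientAverages(tab1)$f1, c(5, 7))
  # against an independent tapply oracle on a larger table
  withr::with_seed(5, {
    tabR <- mkFeatureTable(data.frame(f1 = rnorm(24), f2 = rnorm(24)),
                           patients = rep(sprintf("P%d", 1:4), each = 6))
  })
  avgR <- patientAverages(tabR)
  expect_equal(avgR$f2,
               as.vector(tapply(tabR$f2, tabR$patient_id,
                                mean)[avgR$patient_id]))
})

test_that("NDR follows the z-score convention and its invariances", {
  expect_equal(ndr(c(1, 2, 3)), 2)
  expect_equal(ndr(c(10, 30)), sqrt(2)) # two-patient closed form
  expect_equal(ndr(c(5, 5, 5)), 0)
  withr::with_seed(8, {
    for (i in 1:20) {
      x <- rnorm(7)
      a <- runif(1, 0.1, 10) * sample(c(-1, 1), 1)
      b <- rnorm(1, 0, 100)
      expect_equal(ndr(a * x + b), ndr(x), tolerance = 1e-10)
      expect_equal(ndr(sample(x)), ndr(x), tolerance = 1e-12)
      # upper bound 2 (P - 1) / sqrt(P)
      expect_lte(ndr(x), 2 * (length(x) - 1) / sqrt(length(x)) + 1e-12)
    }
  })
  expect_error(ndr(3), "at least 2")
})

test_that("NDR filtering keeps informative features and drops constants", {
  withr::with_seed(4, {
    tab <- mkFeatureTable(
      data.frame(varying = rnorm(12, sd = 5), constant = rep(1, 12)),
      patients = rep(sprintf("P%d", 1:4), each = 3))
  })
  res0 <- filterByNDR(tab, 0)
  expect_identical(res0$retained, "varying")
  expect_equal(res0$ndr$ndr[res0$ndr$feature == "constant"], 0)
  resHi <- filterByNDR(tab, 2.4)
  expect_false("constant" %in% resHi$retained)
})

test_that("volume has a large dynamic range over a cohort spanning 1-10 cm3", {
  study <- generateStudy(studyDesign(nPatients = 6, seed = 33L))
  tab <- extractAll(study, miniCatalog())
  res <- filterByNDR(tab, 0)
  expect_gt(res$ndr$ndr[res$ndr$feature == "shp_volume"], 2.4)
})

test_that("Spearman matrix matches a rank-then-Pearson oracle", {
  withr::with_seed(12, X <- matrix(rnorm(250), 50, 5,
                                   dimnames = list(NULL, paste0("f", 1:5))))
  tab <- mkFeatureTable(as.data.frame(X),
                        patients = rep(sprintf("P%d", 1:10), 5))
  cm <- spearmanMatrix(tab)
  expect_equal(cm$rho, bruteSpearman(X), tolerance = 1e-12)
  expect_equal(diag(cm$rho), rep(1, 5), ignore_attr = TRUE)
  # monotone invariance: exp() leaves ranks unchanged
  tab$f6 <- exp(tab$f1)
  cm2 <- spearmanMatrix(tab)
  expect_equal(cm2$rho["f1", "f6"], 1)
  # constant column: recorded as 0 and flagged
  tab$f7 <- 2
  cm3 <- spearmanMatrix(tab)
  expect_equal(cm3$rho["f7", "f1"], 0)
  expect_true(cm3$undefined["f7", "f1"])
  expect_false(cm3$significant["f7", "f1"])
})

test_that("correlation pruning removes redundancy deterministically", {
  withr::with_seed(3, {
    f1 <- rnorm(40); f3 <- rnorm(40)
    tab <- mkFeatureTable(data.frame(f1 = f1, f2 = 2 * f1 + 1, f3 = f3),
                          patients = rep(sprintf("P%d", 1:8), 5))
  })
  pr <- pruneCorrelated(spearmanMatrix(tab), 0.95)
  expect_length(pr$retained, 2)
  expect_true("f3" %in% pr$retained)
  expect_equal(nrow(pr$log), 1)
  expect_equal(abs(pr$log$rho), 1)
  # below-threshold matrices are untouched
  tabI <- mkFeatureTable(as.data.frame(matrix(rnorm(200), 50, 4,
                           dimnames = list(NULL, paste0("g", 1:4)))),
                         patients = rep(sprintf("P%d", 1:10), 5))
  prI <- pruneCorrelated(spearmanMatrix(tabI), 0.95)
  expect_identical(prI$retained, paste0("g", 1:4))
  expect_equal(nrow(prI$log), 0)
})

test_that("after pruning no retained pair exceeds the threshold", {
  withr::with_seed(77, {
    for (rep in 1:20) {
      base <- matrix(rnorm(30 * 3), 30, 3)
      # redundant expansions of the base columns plus noise
      X <- cbind(base,
                 base[, sample(3, 4, replace = TRUE)] +
                   matrix(rnorm(30 * 4, sd = 0.01), 30, 4),
                 matrix(rnorm(30 * 2), 30, 2))
      colnames(X) <- sprintf("f%02d", seq_len(ncol(X)))
      tab <- mkFeatureTable(as.data.frame(X),
                            patients = rep(sprintf("P%d", 1:6), 5))
      cm <- spearmanMatrix(tab)
      pr <- pruneCorrelated(cm, 0.95)
      sub <- abs(cm$rho[pr$retained, pr$retained])
      diag(sub) <- 0
      expect_lte(max(sub), 0.95)
    }
  })
})

test_that("the two-step reduction runs NDR before pruning", {
  withr::with_seed(30, {
    f1 <- rnorm(24, sd = 4)
    tab <- mkFeatureTable(
      data.frame(f1 = f1, f2 = f1 * 3 - 2 + rnorm(24, sd = 1e-4),
                 flat = rep(2, 24)),
      patients = rep(sprintf("P%d", 1:6), each = 4))
  })
  red <- reduceFeatures(tab, ndrCutoff = 0, rhoThreshold = 0.95)
  expect_false("flat" %in% red$retained) # dropped by NDR, not by pruning
  expect_length(red$retained, 1)         # f1/f2 collapsed by pruning
  expect_false("flat" %in% rownames(red$correlation$rho))
})
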