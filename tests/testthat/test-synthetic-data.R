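test_that("phantom hits its target volume and is reproducible", {
  spec <- phantomSpec(tumorVolumeCm3 = 4, seed = 5L)
  ph <- generatePhantom(spec)
  vol <- sum(ph$mask) * prod(voxelSpacing(ph$image)) / 1000
  expect_gte(vol, 3.6)
  expect_lte(vol, 4.4)
  ph2 <- generatePhantom(spec)
  expect_identical(ph$mask, ph2$mask)
  expect_identical(intensities(ph$image), intensities(ph2$image))
  # single connected component
  expect_identical(ph$mask, radsegvar:::largestComponent(ph$mask))
})

test_that("lumpiness-free phantoms are near-spherical ellipsoids", {
  for (v in c(2, 8)) for (s in 1:2) {
    ph <- generatePhantom(phantomSpec(tumorVolumeCm3 = v, lumpiness = 0,
                                      noiseSdHu = 0, seed = s))
    sf <- shapeFeatures(ph$mask, voxelSpacing(ph$image))
    expect_gte(sf[["sphericity"]], 0.97)
  }
})

test_that("a tumor larger than the requested grid is rejected with sizes", {
  expect_error(
    generatePhantom(phantomSpec(tumorVolumeCm3 = 10, gridShape = c(8, 8, 8))),
    "requires at least [0-9]+ x [0-9]+ x [0-9]+")
})

test_that("zero perturbation scales reproduce the truth exactly", {
  ph <- generatePhantom(phantomSpec(tumorVolumeCm3 = 3, seed = 2L))
  m <- simulateContour(ph$mask, voxelSpacing(ph$image), observerModel(),
                       seed = 11L)
  expect_identical(m, ph$mask)
  expect_equal(diceCoefficient(m, ph$mask), 1)
})

test_that("a constant radial bias dilates a sphere by that amount", {
  sph <- mkSphereMask(10, c(1, 1, 1), pad = 5)
  m <- simulateContour(sph, c(1, 1, 1), observerModel(observerBiasMm = 2),
                       seed = 3L)
  target <- 4 / 3 * pi * 12^3
  expect_lt(abs(sum(m) - target) / target, 0.05)
})

test_that("contours are deterministic and boundary noise degrades Dice monotonically", {
  sph <- mkSphereMask(10, c(1, 1, 1), pad = 5)
  sdt <- radsegvar:::signedDistance(sph, c(1, 1, 1))
  model <- observerModel(toolSdMm = 0.75)
  m1 <- simulateContour(sph, c(1, 1, 1), model, seed = 7L, sdt = sdt)
  m2 <- simulateContour(sph, c(1, 1, 1), model, seed = 7L, sdt = sdt)
  expect_identical(m1, m2)
  meanDsc <- vapply(c(0.75, 1.5), function(sd0) {
    mean(vapply(1:100, function(s)
      diceCoefficient(simulateContour(sph, c(1, 1, 1),
                                      observerModel(toolSdMm = sd0),
                                      seed = s, sdt = sdt), sph),
      numeric(1)))
  }, numeric(1))
  expect_lt(meanDsc[2], meanDsc[1])
})

test_that("annihilating perturbations raise an error", {
  sph <- mkSphereMask(5, c(1, 1, 1))
  expect_error(
    simulateContour(sph, c(1, 1, 1), observerModel(observerBiasMm = -30),
                    seed = 1L),
    "annihilated")
})

test_that("a single-patient study has the full factorial cell structure", {
  study <- generateStudy(studyDesign(nPatients = 1, seed = 4L))
  recs <- studyContours(study)
  expect_length(recs, 24)
  prov <- do.call(rbind, lapply(recs, provenance))
  expect_setequal(unique(prov$tool_id),
                  c("MIM-like", "Slicer-like", "LSTK-like", "GrowCut-like"))
  expect_setequal(unique(prov$run), 1:2)
  expect_false(anyDuplicated(prov[c("patient_id", "tool_id", "observer_id",
                                    "run")]) > 0)
  # determinism of the full study
  study2 <- generateStudy(studyDesign(nPatients = 1, seed = 4L))
  expect_identical(maskArray(recs[[5]]),
                   maskArray(studyContours(study2)[[5]]))
})

test_that("the low-interaction tool tracks the truth most closely", {
  study <- generateStudy(studyDesign(nPatients = 3, seed = 8L))
  truths <- studyTruths(study)
  d <- vapply(studyContours(study), function(r)
    diceCoefficient(maskArray(r), truths[[r@patientId]]), numeric(1))
  tools <- vapply(studyContours(study), function(r) r@toolId, character(1))
  byTool <- tapply(d, tools, mean)
  expect_equal(names(which.max(byTool)), "LSTK-like")
})

test_that("two-way simulation has the stated component structure", {
  # no column/error variance: every row is constant, perfect agreement
  m <- simulateTwoWay(twoWaySpec(10, 3, varRow = 4, varCol = 0, varErr = 0,
                                 seed = 2L))
  expect_equal(apply(m, 1, sd), rep(0, 10))
  expect_equal(iccTwoWayMixed(m)$estimate, 1)
  # Monte-Carlo mean of the ICC(A,1) estimate near the analytic value
  est <- vapply(1:500, function(s)
    iccTwoWayMixed(simulateTwoWay(twoWaySpec(200, 3, varRow = 9, varCol = 0,
                                             varErr = 1, seed = s)))$estimate,
    numeric(1))
  expect_lt(abs(mean(est) - 0.9), 0.02)
  # no subject variance: estimates scatter around zero
  est0 <- vapply(1:200, function(s)
    iccTwoWayMixed(simulateTwoWay(twoWaySpec(50, 3, varRow = 0, varCol = 0.5,
                                             varErr = 1, seed = s)))$estimate,
    numeric(1))
  expect_lt(abs(mean(est0)), 0.05)
})

test_that("simulated variance components are recovered without bias", {
  # ANOVA estimators of the components on n = 500 matrices, 100 replicates:
  # the mean estimate stays within 3 standard errors of the inputs
  vr <- 2; vc <- 0.5; ve <- 1
  comp <- vapply(1:100, function(s) {
    dec <- anovaDecompose(simulateTwoWay(
      twoWaySpec(500, 3, varRow = vr, varCol = vc, varErr = ve, seed = s)))
    c((dec@msR - dec@msE) / dec@k, (dec@msC - dec@msE) / dec@n, dec@msE)
  }, numeric(3))
  truth <- c(vr, vc, ve)
  for (i in 1:3) {
    se <- sd(comp[i, ]) / sqrt(ncol(comp))
    expect_lt(abs(mean(comp[i, ]) - truth[i]), 3 * se + 1e-8)
  }
})
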