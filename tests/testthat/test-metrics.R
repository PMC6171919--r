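test_that("Dice matches analytic overlaps", {
  dm <- c(20, 20, 20)
  cube <- mkCubeMask(dm, c(3, 3, 3), c(10, 10, 10))
  shifted <- mkCubeMask(dm, c(8, 3, 3), c(10, 10, 10))
  expect_equal(diceCoefficient(cube, cube), 1)
  expect_equal(diceCoefficient(cube, shifted), 0.5)
  expect_equal(diceCoefficient(cube, shifted),
               diceCoefficient(shifted, cube))
  disjoint <- mkCubeMask(dm, c(15, 15, 15), c(3, 3, 3))
  expect_equal(diceCoefficient(cube, disjoint), 0)
  expect_error(diceCoefficient(cube, mkCubeMask(c(10, 10, 10), c(1, 1, 1),
                                                c(2, 2, 2))), "shape")
  expect_error(diceCoefficient(array(FALSE, dm), array(FALSE, dm)), "empty")
})

test_that("Hausdorff distance matches analytic and brute-force values", {
  dm <- c(9, 9, 9)
  a <- array(FALSE, dm); a[3, 3, 3] <- TRUE
  b <- array(FALSE, dm); b[6, 3, 3] <- TRUE
  expect_equal(hausdorffDistance(a, a, c(1, 1, 1)), 0)
  expect_equal(hausdorffDistance(a, b, c(1, 1, 1)), 0.3)
  expect_equal(hausdorffDistance(a, b, c(1, 1, 1)),
               hausdorffDistance(b, a, c(1, 1, 1)))
  # concentric voxelized spheres, radii 8 and 5 mm
  s8 <- mkSphereMask(8, c(1, 1, 1), pad = 3)
  s5 <- mkSphereMask(5, c(1, 1, 1), pad = 6)
  expect_identical(dim(s8), dim(s5))
  hd <- hausdorffDistance(s8, s5, c(1, 1, 1))
  expect_equal(hd * 10, bruteHausdorff(s8, s5, c(1, 1, 1)), tolerance = 1e-12)
  expect_lt(abs(hd - 0.3), sqrt(3) / 10)
  # linear scaling with isotropic spacing
  expect_equal(hausdorffDistance(s8, s5, c(2, 2, 2)), 2 * hd)
})

test_that("Hausdorff satisfies the triangle inequality on random masks", {
  withr::with_seed(21, {
    for (rep in 1:10) {
      ms <- lapply(1:3, function(i) {
        m <- array(FALSE, c(7, 7, 7))
        m[sample(length(m), 15)] <- TRUE
        m
      })
      h12 <- hausdorffDistance(ms[[1]], ms[[2]], c(1, 1, 1))
      h23 <- hausdorffDistance(ms[[2]], ms[[3]], c(1, 1, 1))
      h13 <- hausdorffDistance(ms[[1]], ms[[3]], c(1, 1, 1))
      expect_lte(h13, h12 + h23 + 1e-12)
    }
  })
})

test_that("consensus voting implements the 4-of-6 majority rule", {
  dm <- c(6, 6, 4)
  base <- array(FALSE, dm)
  masks <- lapply(1:6, function(i) base)
  for (i in 1:4) masks[[i]][3, 3, 2] <- TRUE # voxel in exactly 4 of 6
  for (i in 1:3) masks[[i]][4, 4, 2] <- TRUE # voxel in only 3 of 6
  for (i in 1:6) masks[[i]][2, 2, 1] <- TRUE # unanimous voxel
  cons <- consensusMask(masks) # default min_count = ceiling((6+2)/2) = 4
  expect_true(cons[3, 3, 2])
  expect_false(cons[4, 4, 2])
  expect_true(cons[2, 2, 1])
  expect_error(consensusMask(masks, minCount = 7), "exceeds")
  # identical masks: consensus equals them for any valid count
  same <- lapply(1:5, function(i) masks[[1]])
  for (mc in c(1, 3, 5))
    expect_identical(consensusMask(same, mc), masks[[1]])
  # monotone: raising min_count never adds voxels
  for (mc in 1:5)
    expect_true(all(consensusMask(masks, mc + 1) <= consensusMask(masks, mc)))
})

test_that("validation against consensus reduces to the direct metrics", {
  study <- generateStudy(studyDesign(nPatients = 1, seed = 12L))
  recs <- studyContours(study)
  cons <- list(P01 = studyTruths(study)$P01)
  val <- validateAgainstConsensus(recs, cons)
  expect_equal(nrow(val$records), 24)
  r1 <- recs[[1]]
  expect_equal(val$records$dsc[1], diceCoefficient(maskArray(r1), cons$P01))
  expect_equal(val$records$hd_cm[1],
               hausdorffDistance(maskArray(r1), cons$P01, voxelSpacing(r1)))
  # records equal to consensus: DSC 1, HD 0 throughout
  eq <- validateAgainstConsensus(
    lapply(recs[1:3], function(r) {
      contourRecord(cons$P01, r@spacing, r@patientId, r@arm, r@toolId,
                    r@observerId, r@run)
    }), cons)
  expect_true(all(eq$records$dsc == 1))
  expect_true(all(eq$records$hd_cm == 0))
  expect_error(validateAgainstConsensus(recs, list()), "P01")
})
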