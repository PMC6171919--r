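test_that("catalogs have the documented sizes and category structure", {
  full <- featureCatalog("default83")
  expect_equal(nrow(full), 83)
  expect_false(anyDuplicated(full$name) > 0)
  expect_setequal(unique(full$category), c("SHP", "HIS", "TXT"))
  reduced <- featureCatalog("reduced40")
  expect_equal(nrow(reduced), 40)
  expect_true(all(reduced$name %in% full$name))
})

test_that("shape features match analytic sphere geometry", {
  sph <- mkSphereMask(10, c(1, 1, 1))
  sf <- shapeFeatures(sph, c(1, 1, 1))
  expect_lt(abs(sf[["volume"]] - 4.18879) / 4.18879, 0.02)
  expect_gte(sf[["sphericity"]], 0.97)
  expect_lte(sf[["sphericity"]], 1.0)
  expect_equal(sf[["max_diameter_3d"]], 2, tolerance = 0.05)
  expect_equal(sf[["spherical_disproportion"]], 1 / sf[["sphericity"]])
  expect_equal(sf[["elongation"]], 1, tolerance = 0.02)
  # degenerate single voxel: one voxel volume, zero diameter
  one <- array(FALSE, c(5, 5, 5)); one[3, 3, 3] <- TRUE
  s1 <- shapeFeatures(one, c(0.8, 0.8, 2.5))
  expect_equal(s1[["volume"]], prod(c(0.8, 0.8, 2.5)) / 1000)
  expect_equal(s1[["max_diameter_3d"]], 0)
  expect_error(shapeFeatures(array(FALSE, c(4, 4, 4)), c(1, 1, 1)), "empty")
})

test_that("histogram features match hand and moment-oracle values", {
  dm <- c(4, 4, 4)
  img <- array(0, dm)
  mask <- array(FALSE, dm); mask[1:4, 1, 1] <- TRUE
  img[mask] <- c(1, 2, 3, 4)
  h <- histogramFeatures(img, mask)
  expect_equal(h[["mean"]], 2.5)
  expect_equal(h[["variance"]], 1.25) # population variance
  expect_equal(h[["range"]], 3)
  expect_equal(h[["energy"]], 30)
  # constant region: degenerate statistics collapse
  img[mask] <- 7
  hc <- histogramFeatures(img, mask)
  expect_equal(hc[["mean"]], 7)
  expect_equal(hc[["sd"]], 0)
  expect_equal(hc[["entropy"]], 0)
  expect_equal(hc[["uniformity"]], 1)
  expect_equal(hc[["skewness"]], 0)
  # skewness/kurtosis against a direct moment oracle
  withr::with_seed(9, x <- rgamma(200, shape = 2))
  img2 <- array(0, c(10, 10, 2)); mask2 <- array(TRUE, c(10, 10, 2))
  img2[] <- x
  h2 <- histogramFeatures(img2, mask2)
  mu <- mean(x); m2 <- mean((x - mu)^2)
  expect_equal(h2[["skewness"]], mean((x - mu)^3) / m2^1.5,
               tolerance = 1e-10)
  expect_equal(h2[["kurtosis"]], mean((x - mu)^4) / m2^2, tolerance = 1e-10)
})

test_that("the co-occurrence matrix matches brute-force pair enumeration", {
  # printed toy block: one slice, 2x2 in-mask values [[1,2],[1,2]]
  img <- array(0, c(2, 2, 1)); mask <- array(TRUE, c(2, 2, 1))
  img[1, , 1] <- c(1, 2); img[2, , 1] <- c(1, 2)
  g <- glcmMatrix(img, mask, levels = 2, direction = 90, distance = 1)
  expect_equal(g$matrix, matrix(c(0, 0.5, 0.5, 0), 2, 2))
  # constant region: single occupied diagonal cell
  imgc <- array(5, c(3, 3, 2)); maskc <- array(TRUE, c(3, 3, 2))
  gc_ <- glcmMatrix(imgc, maskc, levels = 8, direction = 0, distance = 1)
  expect_equal(gc_$matrix[1, 1], 1)
  expect_equal(sum(gc_$matrix), 1)
  # random input: normalized, symmetric, equals the brute-force oracle
  withr::with_seed(31, {
    img3 <- array(rnorm(250), c(5, 10, 5))
    mask3 <- array(runif(250) < 0.7, c(5, 10, 5))
  })
  for (ang in c(0, 45, 90, 135)) {
    g3 <- glcmMatrix(img3, mask3, levels = 6, direction = ang, distance = 2)
    expect_equal(sum(g3$matrix), 1, tolerance = 1e-9)
    expect_equal(g3$matrix, t(g3$matrix))
    q <- array(radsegvar:::quantizeIntensities(img3, mask3, 6), dim(mask3))
    off <- switch(as.character(ang), "0" = c(1, 0), "45" = c(1, 1),
                  "90" = c(0, 1), "135" = c(-1, 1)) * 2
    oracle <- bruteGlcm(q, 6, off[1], off[2])
    expect_equal(g3$matrix, oracle / sum(oracle))
  }
  expect_error(glcmMatrix(img3, array(FALSE, dim(mask3))), "empty")
  one <- array(FALSE, dim(mask3)); one[3, 3, 3] <- TRUE
  expect_error(glcmMatrix(img3, one), "degenerate")
})

test_that("texture features average the four directions and match a checkerboard", {
  # checkerboard slice: direction 0 at distance 1 gives contrast 1, energy 0.5
  n <- 8
  img <- array(0, c(n, n, 1))
  img[, , 1] <- outer(1:n, 1:n, function(i, j) (i + j) %% 2)
  mask <- array(TRUE, c(n, n, 1))
  g <- glcmMatrix(img, mask, levels = 2, direction = 0, distance = 1)
  st <- radsegvar:::glcmStatistics(g$matrix)
  expect_equal(st[["contrast"]], 1)
  expect_equal(st[["energy"]], 0.5)
  # constant region: energy 1, contrast 0, entropy 0 after averaging
  imgc <- array(3, c(4, 4, 2)); maskc <- array(TRUE, c(4, 4, 2))
  fc <- glcmFeatures(imgc, maskc, levels = 16)
  expect_equal(fc[["energy"]], 1)
  expect_equal(fc[["contrast"]], 0)
  expect_equal(fc[["entropy"]], 0)
  # averaged value is the arithmetic mean of the per-direction values
  withr::with_seed(17, img4 <- array(rnorm(360), c(6, 6, 10)))
  mask4 <- array(TRUE, c(6, 6, 10))
  f4 <- glcmFeatures(img4, mask4, levels = 8, perDirection = TRUE)
  per <- attr(f4, "perDirection")
  expect_equal(unname(colMeans(per)), unname(as.numeric(f4)),
               tolerance = 1e-12)
})

test_that("full extraction yields one finite value per catalog feature", {
  ph <- generatePhantom(phantomSpec(tumorVolumeCm3 = 3, seed = 13L))
  fv <- extractFeatures(ph$image, ph$mask)
  expect_length(fv, 83)
  expect_true(all(is.finite(fv)))
  expect_identical(names(fv), featureCatalog("default83")$name)
  fv40 <- extractFeatures(ph$image, ph$mask, featureCatalog("reduced40"))
  expect_length(fv40, 40)
  # determinism
  expect_identical(fv, extractFeatures(ph$image, ph$mask))
})

test_that("features are invariant to whole-voxel translation and SHP to intensity", {
  ph <- generatePhantom(phantomSpec(tumorVolumeCm3 = 2, seed = 14L))
  img <- intensities(ph$image); mask <- ph$mask
  dm <- dim(mask)
  pad <- 2L
  big <- array(min(img), dm + 2L * pad)
  bigm <- array(FALSE, dm + 2L * pad)
  ins <- function(arr, target, off) {
    target[off + seq_len(dm[1]), off + seq_len(dm[2]),
           off + seq_len(dm[3])] <- arr
    target
  }
  sp <- voxelSpacing(ph$image)
  f0 <- extractFeatures(ins(img, big, 0L), ins(mask, bigm, 0L),
                        featureCatalog("reduced40"), spacing = sp)
  f2 <- extractFeatures(ins(img, big, pad), ins(mask, bigm, pad),
                        featureCatalog("reduced40"), spacing = sp)
  expect_equal(f0, f2, tolerance = 1e-9)
  # shape features ignore the intensities entirely
  f_shift <- extractFeatures(imageVolume(img + 100, sp), mask,
                             miniCatalog())
  f_orig <- extractFeatures(ph$image, mask, miniCatalog())
  expect_equal(f_shift, f_orig)
})
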