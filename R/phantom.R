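# Synthetic CT tumor phantoms and perturbed contour families.

#' Generate a CT-like tumor phantom
#'
#' Builds a single-tumor phantom: a mildly anisotropic ellipsoid whose radius
#' is modulated by a smooth random field (the `lumpiness`), scaled so the
#' voxelized tumor volume matches the target within a fraction of a voxel,
#' embedded in lung-density background with spatially correlated intratumoral
#' texture, a soft tissue interface, optional chest-wall slab, and additive
#' white noise. Fully deterministic given `spec@seed`.
#'
#' @param spec A [PhantomSpec-class].
#' @return A list with elements `image` ([ImageVolume-class]) and `mask`
#'   (3D logical array, a single 6-connected component).
#' @examples
#' ph <- generatePhantom(phantomSpec(tumorVolumeCm3 = 2, seed = 7L))
#' sum(ph$mask) * prod(voxelSpacing(ph$image)) / 1000  # ~2 cm3
#' @export
generatePhantom <- function(spec) {
  validObject(spec)
  sp <- spec@spacing
  withr::with_seed(spec@seed, {
    vTargetMm3 <- spec@tumorVolumeCm3 * 1000
    # mildly anisotropic semi-axes with the requested volume
    rat <- exp(stats::runif(3, -0.15, 0.15))
    r0 <- (3 * vTargetMm3 / (4 * pi * prod(rat)))^(1 / 3)
    ax <- r0 * rat

    margin <- 6 # mm clearance around the tumor
    wallMm <- if (spec@attachWall) 5 else 0
    extent <- 2 * ax * (1 + 2 * spec@lumpiness) + 2 * margin +
      c(wallMm, 0, 0)
    need <- pmax(8L, as.integer(ceiling(extent / sp)))
    if (length(spec@gridShape)) {
      if (any(spec@gridShape < need))
        stop(sprintf(
          "tumor does not fit the grid; requires at least %d x %d x %d voxels",
          need[1], need[2], need[3]), call. = FALSE)
      dm <- spec@gridShape
    } else {
      dm <- need
    }

    # voxel-center coordinates (mm); tumor centered, pushed toward the wall
    # side when a chest wall is requested
    ctr <- (dm - 1) * sp / 2
    if (spec@attachWall) ctr[1] <- (dm[1] - 1) * sp[1] - wallMm -
      ax[1] * (1 + spec@lumpiness)
    x2 <- (((seq_len(dm[1]) - 1) * sp[1] - ctr[1]) / ax[1])^2
    y2 <- (((seq_len(dm[2]) - 1) * sp[2] - ctr[2]) / ax[2])^2
    z2 <- (((seq_len(dm[3]) - 1) * sp[3] - ctr[3]) / ax[3])^2
    u <- sqrt(outer(outer(x2, y2, "+"), z2, "+"))

    # lumpy radial modulation, then bisection on the global scale so the
    # voxel volume hits the target
    if (spec@lumpiness > 0) {
      g <- smoothNoiseField(dm, sp, corrMm = max(ax) * 0.8,
                            seed = childSeed(spec@seed, "lump"))
      rad <- pmax(0.3, 1 + spec@lumpiness * g)
    } else {
      rad <- 1
    }
    nTarget <- vTargetMm3 / prod(sp)
    lo <- 0.3; hi <- 3
    for (it in 1:42) {
      mid <- (lo + hi) / 2
      if (sum(u <= mid * rad) < nTarget) lo <- mid else hi <- mid
    }
    mask <- array(u <= hi * rad, dim = dm)
    mask <- largestComponent(mask)
    vol <- sum(mask) * prod(sp) / 1000
    if (abs(vol - spec@tumorVolumeCm3) / spec@tumorVolumeCm3 > 0.1)
      stop(sprintf(
        "voxelized tumor volume %.3f cm3 deviates more than 10%% from target %.3f cm3 (grid too coarse)",
        vol, spec@tumorVolumeCm3), call. = FALSE)

    # image: lung background + soft tumor edge + correlated texture + noise
    w <- array(cpp_gauss_smooth(as.numeric(mask), as.integer(dm), 1 / sp),
               dim = dm)
    tex <- smoothNoiseField(dm, sp, spec@textureCorrLengthMm,
                            childSeed(spec@seed, "texture")) * spec@textureSdHu
    img <- spec@lungMeanHu + w * (spec@tumorMeanHu - spec@lungMeanHu + tex)
    if (spec@attachWall) {
      wallFrom <- (dm[1] - 1) * sp[1] - wallMm
      wall <- ((seq_len(dm[1]) - 1) * sp[1]) >= wallFrom
      img[wall, , ] <- pmax(img[wall, , ], 40)
    }
    if (spec@noiseSdHu > 0)
      img <- img + array(rnorm(prod(dm), 0, spec@noiseSdHu), dim = dm)

    list(image = imageVolume(img, sp), mask = mask)
  })
}

#' Simulate one observer contour of a ground-truth mask
#'
#' Displaces the ground-truth boundary radially by a smooth Gaussian random
#' field (correlation length ~5 mm, so disagreement is spatially coherent
#' rather than per-voxel) of scale `sqrt(toolSdMm^2 + runSdMm^2)`, plus the
#' constant offset `observerBiasMm`, implemented as re-thresholding the
#' signed distance transform of the truth. The tool's boundary smoothing, if
#' any, is applied afterwards. With every model scale at zero the output
#' equals the truth exactly.
#'
#' @param truth 3D logical ground-truth mask (non-empty).
#' @param spacing numeric(3) voxel spacing, mm.
#' @param model An [ObserverModel-class].
#' @param seed RNG seed; contours are deterministic given it.
#' @param sdt optional precomputed signed distance transform of `truth`
#'   (mm), to amortize across many contours of the same tumor.
#' @param floorErosion cap erosion at half the maximal interior depth so an
#'   extreme negative offset shrinks the contour to a core instead of
#'   annihilating it (the study generator uses this; the default `FALSE`
#'   errors on annihilation).
#' @return A 3D logical mask (largest connected component of the perturbed
#'   region).
#' @export
simulateContour <- function(truth, spacing, model, seed = 1L, sdt = NULL,
                            floorErosion = FALSE) {
  stopIfNot3dMask(truth, "truth")
  if (!any(truth)) stop("truth mask is empty", call. = FALSE)
  validObject(model)
  if (is.null(sdt)) sdt <- signedDistance(truth, spacing)
  scale <- sqrt(model@toolSdMm^2 + model@runSdMm^2)
  offset <- model@observerBiasMm
  if (scale > 0) {
    offset <- offset + scale *
      smoothNoiseField(dim(truth), spacing, corrMm = 5,
                       seed = childSeed(seed, "contour-field"))
  }
  thresholdContour(sdt, offset, spacing, model@smoothingMm, floorErosion)
}

# Shared thresholding step: displace the boundary (sdt <= offset), keep the
# largest component; optionally floor the erosion. Tool smoothing acts on
# the continuous level-set field (sdt - offset) before thresholding, so a
# smoothed boundary stays sub-voxel-consistent instead of snapping whole
# slice terraces on and off.
thresholdContour <- function(sdt, offset, spacing, smoothingMm,
                             floorErosion) {
  if (floorErosion) offset <- pmax(offset, 0.5 * min(sdt))
  lvl <- sdt - offset
  if (smoothingMm > 0)
    lvl <- array(cpp_gauss_smooth(lvl, as.integer(dim(sdt)),
                                  smoothingMm / spacing), dim = dim(sdt))
  m <- array(lvl <= 0, dim = dim(sdt))
  if (!any(m) && floorErosion) # smoothing flattened a small core
    m <- array(sdt - offset <= 0, dim = dim(sdt))
  if (!any(m)) stop("perturbation annihilated the mask", call. = FALSE)
  largestComponent(m)
}

#' Generate a full synthetic segmentation study
#'
#' One phantom per patient (tumor volumes spread evenly over the design's
#' volume range) and one contour per (patient, arm, tool, observer, run)
#' cell. Random components are split hierarchically from the master seed:
#' each (tool, observer) pair draws a systematic radial bias from
#' N(0, observerBiasMm); each (patient, tool, observer) draws a shared
#' tool-level boundary field; each run adds its own jitter field. Runs of
#' the same observer therefore agree more than different observers, who in
#' turn agree more than different tools.
#'
#' @param design A [StudyDesign-class].
#' @return A [SegmentationStudy-class].
#' @examples
#' \donttest{
#' study <- generateStudy(studyDesign(nPatients = 2, seed = 11L))
#' study
#' }
#' @export
generateStudy <- function(design) {
  validObject(design)
  n <- design@nPatients
  vols <- if (n == 1) mean(design@volumeRangeCm3) else
    seq(design@volumeRangeCm3[1], design@volumeRangeCm3[2], length.out = n)
  sp <- design@phantom@spacing

  # systematic per-(tool, observer) biases, constant across patients/runs
  biases <- list()
  for (armName in names(design@arms)) {
    arm <- design@arms[[armName]]
    for (tool in arm$tools) {
      mdl <- design@models[[tool]]
      for (obs in arm$observers) {
        biases[[paste(tool, obs, sep = "|")]] <-
          if (mdl@observerBiasMm > 0)
            withr::with_seed(childSeed(design@seed, "bias", tool, obs),
                             rnorm(1, 0, mdl@observerBiasMm))
          else 0
      }
    }
  }

  images <- list(); truths <- list(); contours <- list()
  for (p in seq_len(n)) {
    pid <- sprintf("P%02d", p)
    spec <- design@phantom
    spec@tumorVolumeCm3 <- vols[p]
    spec@seed <- childSeed(design@seed, "phantom", p)
    if (length(design@variation)) {
      draws <- withr::with_seed(childSeed(design@seed, "patparams", p),
                                stats::runif(length(design@variation)))
      for (vi in seq_along(design@variation)) {
        rng <- design@variation[[vi]]
        slot(spec, names(design@variation)[vi]) <-
          rng[1] + draws[vi] * (rng[2] - rng[1])
      }
    }
    ph <- generatePhantom(spec)
    images[[pid]] <- ph$image
    truths[[pid]] <- ph$mask
    sdt <- signedDistance(ph$mask, sp)
    dm <- dim(ph$mask)

    for (armName in names(design@arms)) {
      arm <- design@arms[[armName]]
      for (tool in arm$tools) {
        mdl <- design@models[[tool]]
        for (obs in arm$observers) {
          b <- biases[[paste(tool, obs, sep = "|")]]
          toolField <- if (mdl@toolSdMm > 0)
            mdl@toolSdMm * smoothNoiseField(
              dm, sp, 5, childSeed(design@seed, "tool", p, tool, obs))
          else 0
          for (r in seq_len(design@runs)) {
            runField <- if (mdl@runSdMm > 0)
              mdl@runSdMm * smoothNoiseField(
                dm, sp, 5, childSeed(design@seed, "run", p, tool, obs, r))
            else 0
            m <- thresholdContour(sdt, b + toolField + runField, sp,
                                  mdl@smoothingMm, floorErosion = TRUE)
            contours[[length(contours) + 1L]] <- contourRecord(
              m, sp, pid, armName, tool, obs, r)
          }
        }
      }
    }
  }
  new("SegmentationStudy", images = images, truths = truths,
      contours = contours, design = design)
}

#' Simulate a plain two-way measurement matrix
#'
#' Draws y_ij = r_i + c_j + e_ij with independent normal components of the
#' specified variances, the validation harness for the ICC estimators: the
#' true single-measure absolute-agreement ICC is
#' varRow / (varRow + varCol + varErr).
#'
#' @param spec A [TwoWaySpec-class].
#' @return An n x k numeric matrix.
#' @examples
#' m <- simulateTwoWay(twoWaySpec(n = 50, k = 3, varRow = 9, varErr = 1))
#' @export
simulateTwoWay <- function(spec) {
  validObject(spec)
  withr::with_seed(spec@seed, {
    r <- rnorm(spec@n, 0, sqrt(spec@varRow))
    cl <- rnorm(spec@k, 0, sqrt(spec@varCol))
    e <- matrix(rnorm(spec@n * spec@k, 0, sqrt(spec@varErr)),
                spec@n, spec@k)
    outer(r, cl, "+") + e
  })
}
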