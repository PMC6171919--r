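#' @import methods
#' @importFrom stats rnorm sd median quantile cor pt pf qf aggregate
#'   wilcox.test var complete.cases
#' @importFrom utils write.csv read.csv
#' @useDynLib radsegvar, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' Volumetric intensity image
#'
#' A 3D scalar grid of CT-like intensities in Hounsfield units together with
#' its physical voxel spacing. Arrays are indexed (x, y, z) with spacing given
#' in the same order, in mm; the transverse plane is a fixed z index.
#'
#' @slot values 3D numeric array of intensities (HU).
#' @slot spacing numeric(3), mm per voxel along (x, y, z); strictly positive.
#' @slot origin numeric(3), physical position (mm) of voxel (1,1,1).
#' @export
setClass("ImageVolume",
  representation(values = "array", spacing = "numeric", origin = "numeric"),
  prototype(origin = c(0, 0, 0))
)

setValidity("ImageVolume", function(object) {
  msg <- character()
  if (length(dim(object@values)) != 3L)
    msg <- c(msg, "values must be a 3D array")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 strictly positive finite values (mm)")
  if (length(object@origin) != 3L)
    msg <- c(msg, "origin must have length 3")
  if (length(msg)) msg else TRUE
})

#' Construct an ImageVolume
#'
#' @param values 3D numeric array (HU).
#' @param spacing numeric(3) voxel spacing in mm, (x, y, z).
#' @param origin numeric(3) physical origin in mm.
#' @return An [ImageVolume-class] object.
#' @export
imageVolume <- function(values, spacing, origin = c(0, 0, 0)) {
  new("ImageVolume", values = values, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' One tumor contour with provenance
#'
#' A binary mask sharing the geometry of its companion image, labeled with
#' the (patient, arm, tool, observer, run) cell of the study design it
#' belongs to.
#'
#' @slot mask 3D logical array; at least one TRUE voxel.
#' @slot spacing numeric(3) voxel spacing in mm.
#' @slot patientId,toolId,observerId character labels.
#' @slot arm `"manual"` or `"semi-automatic"`.
#' @slot run integer contour run (1 or 2 in the default design).
#' @export
setClass("ContourRecord",
  representation(mask = "array", spacing = "numeric", patientId = "character",
                 arm = "character", toolId = "character",
                 observerId = "character", run = "integer")
)

setValidity("ContourRecord", function(object) {
  msg <- character()
  if (length(dim(object@mask)) != 3L || !is.logical(object@mask))
    msg <- c(msg, "mask must be a 3D logical array")
  else if (!any(object@mask))
    msg <- c(msg, "mask must contain at least one TRUE voxel")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 positive values (mm)")
  if (!object@arm %in% c("manual", "semi-automatic"))
    msg <- c(msg, "arm must be 'manual' or 'semi-automatic'")
  if (length(msg)) msg else TRUE
})

#' Construct a ContourRecord
#'
#' @param mask 3D logical array.
#' @param spacing numeric(3) mm.
#' @param patientId,arm,toolId,observerId,run provenance labels.
#' @return A [ContourRecord-class] object.
#' @export
contourRecord <- function(mask, spacing, patientId, arm, toolId, observerId,
                          run) {
  new("ContourRecord", mask = mask, spacing = as.numeric(spacing),
      patientId = as.character(patientId), arm = arm,
      toolId = as.character(toolId), observerId = as.character(observerId),
      run = as.integer(run))
}

#' Specification of a synthetic CT tumor phantom
#'
#' Describes one CT-like tumor phantom: a lumpy ellipsoidal tumor of a target
#' volume embedded in lung-density background, with spatially correlated
#' intratumoral texture and additive acquisition noise. Defaults emulate
#' contrast-enhanced helical chest CT: 2.5 mm slices, sub-millimeter
#' transverse pixels, tumors of a few cm3.
#'
#' @slot gridShape integer(3) voxels per axis, or `integer(0)` to auto-size
#'   the grid around the tumor.
#' @slot spacing numeric(3) mm per axis (x, y, z).
#' @slot tumorVolumeCm3 target tumor volume in cm3 (> 0).
#' @slot lumpiness amplitude of the smooth radial shape irregularity
#'   (unitless, >= 0; 0 gives an exact ellipsoid).
#' @slot tumorMeanHu,lungMeanHu mean intensities (HU) of tumor and lung.
#' @slot textureSdHu SD (HU) of the correlated intratumoral texture.
#' @slot textureCorrLengthMm spatial correlation length (mm) of the texture.
#' @slot noiseSdHu SD (HU) of the additive white acquisition noise (>= 0).
#' @slot attachWall logical; append a chest-wall-like slab touching the tumor.
#' @slot seed integer RNG seed; the phantom is a pure function of the spec.
#' @export
setClass("PhantomSpec",
  representation(gridShape = "integer", spacing = "numeric",
                 tumorVolumeCm3 = "numeric", lumpiness = "numeric",
                 tumorMeanHu = "numeric", lungMeanHu = "numeric",
                 textureSdHu = "numeric", textureCorrLengthMm = "numeric",
                 noiseSdHu = "numeric", attachWall = "logical",
                 seed = "integer"),
  prototype(gridShape = integer(0), spacing = c(0.8, 0.8, 2.5),
            tumorVolumeCm3 = 4, lumpiness = 0.15, tumorMeanHu = 20,
            lungMeanHu = -800, textureSdHu = 40, textureCorrLengthMm = 3,
            noiseSdHu = 20, attachWall = FALSE, seed = 1L)
)

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (object@tumorVolumeCm3 <= 0) msg <- c(msg, "tumorVolumeCm3 must be > 0")
  if (any(object@spacing <= 0)) msg <- c(msg, "spacing components must be > 0")
  if (object@noiseSdHu < 0) msg <- c(msg, "noiseSdHu must be >= 0")
  if (object@lumpiness < 0) msg <- c(msg, "lumpiness must be >= 0")
  if (length(object@gridShape) && length(object@gridShape) != 3L)
    msg <- c(msg, "gridShape must have length 3 (or 0 for auto)")
  if (length(msg)) msg else TRUE
})

#' Construct a PhantomSpec
#'
#' @param tumorVolumeCm3,spacing,gridShape,lumpiness,tumorMeanHu,lungMeanHu,textureSdHu,textureCorrLengthMm,noiseSdHu,attachWall,seed
#'   see [PhantomSpec-class].
#' @return A validated [PhantomSpec-class].
#' @export
phantomSpec <- function(tumorVolumeCm3 = 4, spacing = c(0.8, 0.8, 2.5),
                        gridShape = NULL, lumpiness = 0.15,
                        tumorMeanHu = 20, lungMeanHu = -800,
                        textureSdHu = 40, textureCorrLengthMm = 3,
                        noiseSdHu = 20, attachWall = FALSE, seed = 1L) {
  new("PhantomSpec",
      gridShape = if (is.null(gridShape)) integer(0) else as.integer(gridShape),
      spacing = as.numeric(spacing), tumorVolumeCm3 = tumorVolumeCm3,
      lumpiness = lumpiness, tumorMeanHu = tumorMeanHu,
      lungMeanHu = lungMeanHu, textureSdHu = textureSdHu,
      textureCorrLengthMm = textureCorrLengthMm, noiseSdHu = noiseSdHu,
      attachWall = attachWall, seed = as.integer(seed))
}

#' Contouring-behavior model for one segmentation tool
#'
#' Parameterizes how contours produced with a tool deviate from the true
#' tumor boundary. The boundary is displaced radially by a smooth random
#' field of scale `sqrt(toolSdMm^2 + runSdMm^2)` plus the constant offset
#' `observerBiasMm`, then optionally smoothed. All scales in mm; all zero
#' scales reproduce the ground-truth mask exactly.
#'
#' @slot toolSdMm tool-level boundary perturbation scale (shared by runs).
#' @slot observerBiasMm systematic radial offset; in a study design this is
#'   the SD from which each (tool, observer) pair draws its bias.
#' @slot runSdMm run-to-run boundary jitter scale.
#' @slot smoothingMm width of the tool's boundary-smoothing kernel (0 = none).
#' @export
setClass("ObserverModel",
  representation(toolSdMm = "numeric", observerBiasMm = "numeric",
                 runSdMm = "numeric", smoothingMm = "numeric"),
  prototype(toolSdMm = 0, observerBiasMm = 0, runSdMm = 0, smoothingMm = 0)
)

setValidity("ObserverModel", function(object) {
  v <- c(object@toolSdMm, object@observerBiasMm, object@runSdMm,
         object@smoothingMm)
  if (any(!is.finite(v))) return("all scales must be finite")
  if (any(c(object@toolSdMm, object@runSdMm, object@smoothingMm) < 0))
    return("toolSdMm, runSdMm and smoothingMm must be >= 0")
  TRUE
})

#' Construct an ObserverModel
#'
#' @param toolSdMm,observerBiasMm,runSdMm,smoothingMm see
#'   [ObserverModel-class]; all in mm.
#' @return An [ObserverModel-class].
#' @export
observerModel <- function(toolSdMm = 0, observerBiasMm = 0, runSdMm = 0,
                          smoothingMm = 0) {
  new("ObserverModel", toolSdMm = toolSdMm, observerBiasMm = observerBiasMm,
      runSdMm = runSdMm, smoothingMm = smoothingMm)
}

#' Design of a segmentation-variability study
#'
#' The factorial contouring design: per patient, each arm's tools are used by
#' that arm's observers for a fixed number of repeat runs. The default design
#' mirrors a two-arm setup (manual: 2 tools x 3 physicians; semi-automatic:
#' 2 tools x 3 observers; 2 runs), i.e. 24 contours per patient and 240 for
#' 10 patients.
#'
#' @slot nPatients number of tumors.
#' @slot arms named list (`manual`, `semi-automatic`), each with character
#'   vectors `tools` and `observers`.
#' @slot runs number of repeat contour runs per cell.
#' @slot models named list of [ObserverModel-class], one per tool id.
#' @slot volumeRangeCm3 numeric(2); patient tumor volumes are spread evenly
#'   over this range.
#' @slot phantom [PhantomSpec-class] template for per-patient phantoms.
#' @slot variation named list of `c(lo, hi)` ranges; the named
#'   [PhantomSpec-class] parameters are drawn uniformly per patient so
#'   tumors differ in appearance (mean intensity, texture amplitude and
#'   grain, shape irregularity), not just size.
#' @slot seed master seed; split hierarchically per (patient, tool,
#'   observer, run).
#' @export
setClass("StudyDesign",
  representation(nPatients = "integer", arms = "list", runs = "integer",
                 models = "list", volumeRangeCm3 = "numeric",
                 phantom = "PhantomSpec", variation = "list",
                 seed = "integer")
)

setValidity("StudyDesign", function(object) {
  msg <- character()
  if (object@nPatients < 1L) msg <- c(msg, "nPatients must be >= 1")
  if (!all(c("manual", "semi-automatic") %in% names(object@arms)))
    msg <- c(msg, "arms must be named 'manual' and 'semi-automatic'")
  tools <- unlist(lapply(object@arms, `[[`, "tools"))
  if (anyDuplicated(tools)) msg <- c(msg, "tool ids must be unique")
  if (!all(tools %in% names(object@models)))
    msg <- c(msg, "every tool needs an entry in models")
  if (object@runs < 1L) msg <- c(msg, "runs must be >= 1")
  if (length(object@volumeRangeCm3) != 2L ||
      any(object@volumeRangeCm3 <= 0) ||
      diff(object@volumeRangeCm3) < 0)
    msg <- c(msg, "volumeRangeCm3 must be an increasing positive pair")
  okVary <- c("tumorMeanHu", "lungMeanHu", "textureSdHu",
              "textureCorrLengthMm", "noiseSdHu", "lumpiness")
  if (length(object@variation)) {
    if (!all(names(object@variation) %in% okVary))
      msg <- c(msg, paste("variation names must be among:",
                          paste(okVary, collapse = ", ")))
    if (!all(vapply(object@variation, function(r)
      length(r) == 2 && diff(r) >= 0, logical(1))))
      msg <- c(msg, "each variation entry must be an increasing c(lo, hi)")
  }
  if (length(msg)) msg else TRUE
})

#' Default per-tool contouring presets
#'
#' Variance-component presets encoding the qualitative ordering of contour
#' variability across tools: the low-interaction level-set-like tool perturbs
#' least, the region-growing-like tool more, and the two manual tools most.
#' Magnitudes are plausible stand-ins (the source data quantify no per-tool
#' scales) and are fully user-configurable.
#'
#' @return Named list of [ObserverModel-class] objects for tools
#'   `"LSTK-like"`, `"GrowCut-like"`, `"MIM-like"`, `"Slicer-like"`.
#' @export
toolPresets <- function() {
  list(
    "LSTK-like"    = observerModel(toolSdMm = 0.3, observerBiasMm = 0.4,
                                   runSdMm = 0.3, smoothingMm = 1.0),
    "GrowCut-like" = observerModel(toolSdMm = 0.5, observerBiasMm = 0.8,
                                   runSdMm = 0.8, smoothingMm = 0.5),
    "MIM-like"     = observerModel(toolSdMm = 0.6, observerBiasMm = 1.2,
                                   runSdMm = 1.5, smoothingMm = 0),
    "Slicer-like"  = observerModel(toolSdMm = 0.7, observerBiasMm = 1.2,
                                   runSdMm = 1.7, smoothingMm = 0)
  )
}

#' Construct a StudyDesign
#'
#' @param nPatients number of tumors (default 10).
#' @param arms named list of arms with `tools` and `observers`.
#' @param runs repeat runs per (tool, observer) cell (default 2).
#' @param models named list of [ObserverModel-class] per tool; defaults to
#'   [toolPresets()].
#' @param volumeRangeCm3 tumor volume range, cm3.
#' @param phantom [PhantomSpec-class] template.
#' @param variation named list of per-patient uniform ranges for phantom
#'   parameters (see [StudyDesign-class]); defaults give each patient its
#'   own tumor intensity, texture amplitude/grain and shape irregularity.
#' @param seed master seed.
#' @return A validated [StudyDesign-class].
#' @export
studyDesign <- function(nPatients = 10,
                        arms = list(
                          "manual" = list(
                            tools = c("MIM-like", "Slicer-like"),
                            observers = c("phys1", "phys2", "phys3")),
                          "semi-automatic" = list(
                            tools = c("LSTK-like", "GrowCut-like"),
                            observers = c("obs1", "obs2", "obs3"))),
                        runs = 2, models = toolPresets(),
                        volumeRangeCm3 = c(1.15, 10.53),
                        phantom = phantomSpec(),
                        variation = list(tumorMeanHu = c(-20, 60),
                                         textureSdHu = c(25, 55),
                                         textureCorrLengthMm = c(2, 5),
                                         lumpiness = c(0.08, 0.25)),
                        seed = 1L) {
  new("StudyDesign", nPatients = as.integer(nPatients), arms = arms,
      runs = as.integer(runs), models = models,
      volumeRangeCm3 = as.numeric(volumeRangeCm3), phantom = phantom,
      variation = variation, seed = as.integer(seed))
}

#' Plain two-way measurement-matrix specification
#'
#' A crossed random-effects layout y_ij = r_i + c_j + e_ij with known
#' variance components, used to validate the intraclass-correlation
#' estimators: the true ICC(A,1) is varRow / (varRow + varCol + varErr).
#'
#' @slot n rows (tumors), >= 2.
#' @slot k columns (raters), >= 2.
#' @slot varRow,varCol,varErr variance components, >= 0.
#' @slot seed RNG seed.
#' @export
setClass("TwoWaySpec",
  representation(n = "integer", k = "integer", varRow = "numeric",
                 varCol = "numeric", varErr = "numeric", seed = "integer"),
  prototype(varRow = 1, varCol = 0, varErr = 1, seed = 1L)
)

setValidity("TwoWaySpec", function(object) {
  msg <- character()
  if (object@n < 2L || object@k < 2L) msg <- c(msg, "need n >= 2 and k >= 2")
  if (any(c(object@varRow, object@varCol, object@varErr) < 0))
    msg <- c(msg, "variance components must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a TwoWaySpec
#'
#' @param n,k matrix dimensions.
#' @param varRow,varCol,varErr variance components.
#' @param seed RNG seed.
#' @return A [TwoWaySpec-class].
#' @export
twoWaySpec <- function(n, k, varRow = 1, varCol = 0, varErr = 1, seed = 1L) {
  new("TwoWaySpec", n = as.integer(n), k = as.integer(k), varRow = varRow,
      varCol = varCol, varErr = varErr, seed = as.integer(seed))
}

#' A generated (or loaded) segmentation study
#'
#' Container for one study: per-patient images and ground-truth masks plus
#' the full set of contour records.
#'
#' @slot images named list of [ImageVolume-class], one per patient.
#' @slot truths named list of 3D logical arrays (ground-truth masks).
#' @slot contours list of [ContourRecord-class].
#' @slot design the [StudyDesign-class] that produced the study.
#' @export
setClass("SegmentationStudy",
  representation(images = "list", truths = "list", contours = "list",
                 design = "StudyDesign")
)

#' Two-way ANOVA decomposition of a measurement matrix
#'
#' Mean squares of the crossed tumors-by-raters layout: rows (MS_R), columns
#' (MS_C), residual (MS_E), and the one-way within-rows mean square (MS_W).
#'
#' @slot msR,msC,msE,msW mean squares (>= 0).
#' @slot n,k matrix dimensions (tumors, raters).
#' @export
setClass("AnovaDecomposition",
  representation(msR = "numeric", msC = "numeric", msE = "numeric",
                 msW = "numeric", n = "integer", k = "integer")
)

setMethod("show", "ImageVolume", function(object) {
  d <- dim(object@values)
  cat(sprintf("ImageVolume %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], object@spacing[1], object@spacing[2],
              object@spacing[3]))
  cat(sprintf("  intensity range [%.1f, %.1f] HU\n",
              min(object@values), max(object@values)))
})

setMethod("show", "ContourRecord", function(object) {
  cat(sprintf("ContourRecord %s | %s | %s | %s | run %d: %d voxels (%.2f cm3)\n",
              object@patientId, object@arm, object@toolId, object@observerId,
              object@run, sum(object@mask),
              sum(object@mask) * prod(object@spacing) / 1000))
})

setMethod("show", "SegmentationStudy", function(object) {
  arms <- vapply(object@contours, function(r) r@arm, character(1))
  cat(sprintf("SegmentationStudy: %d patients, %d contours (%d manual, %d semi-automatic)\n",
              length(object@images), length(object@contours),
              sum(arms == "manual"), sum(arms == "semi-automatic")))
})

setMethod("show", "AnovaDecomposition", function(object) {
  cat(sprintf("AnovaDecomposition (n = %d tumors, k = %d raters)\n",
              object@n, object@k))
  cat(sprintf("  MS_R = %.6g, MS_C = %.6g, MS_E = %.6g, MS_W = %.6g\n",
              object@msR, object@msC, object@msE, object@msW))
})

#' Accessors
#'
#' `intensities()` returns the raw 3D array of an [ImageVolume-class];
#' `voxelSpacing()` its (or a [ContourRecord-class]'s) spacing in mm;
#' `maskArray()` a contour's logical array; `provenance()` a contour's label
#' tuple as a one-row data.frame; `studyContours()` / `studyImages()` /
#' `studyTruths()` the components of a [SegmentationStudy-class].
#'
#' @param x the object.
#' @return See description.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))
#' @rdname accessors
#' @export
setMethod("intensities", "ImageVolume", function(x) x@values)

#' @rdname accessors
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))
#' @rdname accessors
#' @export
setMethod("voxelSpacing", "ImageVolume", function(x) x@spacing)
#' @rdname accessors
#' @export
setMethod("voxelSpacing", "ContourRecord", function(x) x@spacing)

#' @rdname accessors
#' @export
setGeneric("maskArray", function(x) standardGeneric("maskArray"))
#' @rdname accessors
#' @export
setMethod("maskArray", "ContourRecord", function(x) x@mask)

#' @rdname accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))
#' @rdname accessors
#' @export
setMethod("provenance", "ContourRecord", function(x) {
  data.frame(patient_id = x@patientId, arm = x@arm, tool_id = x@toolId,
             observer_id = x@observerId, run = x@run,
             stringsAsFactors = FALSE)
})

#' @rdname accessors
#' @export
setGeneric("studyContours", function(x) standardGeneric("studyContours"))
#' @rdname accessors
#' @export
setMethod("studyContours", "SegmentationStudy", function(x) x@contours)

#' @rdname accessors
#' @export
setGeneric("studyImages", function(x) standardGeneric("studyImages"))
#' @rdname accessors
#' @export
setMethod("studyImages", "SegmentationStudy", function(x) x@images)

#' @rdname accessors
#' @export
setGeneric("studyTruths", function(x) standardGeneric("studyTruths"))
#' @rdname accessors
#' @export
setMethod("studyTruths", "SegmentationStudy", function(x) x@truths)
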