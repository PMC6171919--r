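# Segmentation agreement metrics and consensus contours.

asMask <- function(x) {
  if (is(x, "ContourRecord")) x@mask else x
}

#' Dice similarity coefficient
#'
#' Spatial overlap 2|A n B| / (|A| + |B|) between two binary masks of the
#' same geometry; 1 for identical non-empty masks, 0 for disjoint ones.
#' Symmetric and independent of voxel spacing.
#'
#' @param a,b 3D logical masks (or [ContourRecord-class]s) of equal shape;
#'   at least one non-empty.
#' @return Dice coefficient in `[0, 1]`.
#' @examples
#' m <- array(FALSE, c(4, 4, 4)); m[2:3, 2:3, 2:3] <- TRUE
#' diceCoefficient(m, m)  # 1
#' @export
diceCoefficient <- function(a, b) {
  a <- asMask(a); b <- asMask(b)
  if (!identical(dim(a), dim(b)))
    stop("masks must have identical shape", call. = FALSE)
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0) stop("both masks are empty", call. = FALSE)
  2 * sum(a & b) / (na + nb)
}

#' Hausdorff distance between two masks
#'
#' Classic max-max Hausdorff distance between the boundary-voxel center sets
#' of the two masks (boundary = mask voxel with a face-adjacent background
#' neighbor), in physical coordinates, reported in cm. Sensitive to local
#' spikes and holes that barely change volume.
#'
#' @param a,b 3D logical masks (or [ContourRecord-class]s), both non-empty,
#'   same shape.
#' @param spacing numeric(3) voxel spacing in mm (taken from the records if
#'   omitted and available).
#' @return Hausdorff distance in cm.
#' @export
hausdorffDistance <- function(a, b, spacing = NULL) {
  if (is.null(spacing)) {
    if (is(a, "ContourRecord")) spacing <- a@spacing
    else stop("spacing is required for plain-array masks", call. = FALSE)
  }
  a <- asMask(a); b <- asMask(b)
  if (!identical(dim(a), dim(b)))
    stop("masks must have identical shape", call. = FALSE)
  if (!any(a) || !any(b)) stop("masks must be non-empty", call. = FALSE)
  ba <- boundaryCoords(a, spacing)
  bb <- boundaryCoords(b, spacing)
  max(cpp_directed_hd(ba, bb), cpp_directed_hd(bb, ba)) / 10
}

boundaryCoords <- function(mask, spacing) {
  bd <- array(cpp_boundary(as.logical(mask), as.integer(dim(mask))),
              dim = dim(mask))
  voxelCoords(bd, spacing)
}

#' Majority group-consensus contour
#'
#' Voxel-wise majority vote: a voxel belongs to the consensus iff it is
#' inside at least `minCount` of the input masks. The default
#' `ceiling((n + 2) / 2)` reproduces the 4-of-6 majority-of-experts rule for
#' six expert contours.
#'
#' @param masks list of 3D logical masks (or [ContourRecord-class]s) with
#'   common geometry.
#' @param minCount minimum number of masks that must include a voxel.
#' @return A 3D logical consensus mask.
#' @export
consensusMask <- function(masks, minCount = ceiling((length(masks) + 2) / 2)) {
  if (minCount > length(masks))
    stop("minCount exceeds the number of masks", call. = FALSE)
  masks <- lapply(masks, asMask)
  acc <- Reduce(`+`, lapply(masks, function(m) m * 1L))
  array(acc >= minCount, dim = dim(masks[[1]]))
}

#' Validate contours against per-patient consensus masks
#'
#' Computes Dice and Hausdorff distance of every contour record against its
#' patient's consensus mask, plus per-tool summary statistics.
#'
#' @param records list of [ContourRecord-class]s (or a
#'   [SegmentationStudy-class], in which case its contours are used).
#' @param consensus named list of consensus masks keyed by patient id.
#' @return A list with `records` (one row per contour: provenance, `dsc`,
#'   `hd_cm`, `volume_cm3`, `consensus_volume_cm3`) and `byTool` (per-tool
#'   mean/SD of both metrics).
#' @export
validateAgainstConsensus <- function(records, consensus) {
  if (is(records, "SegmentationStudy")) records <- records@contours
  rows <- lapply(records, function(rec) {
    cons <- consensus[[rec@patientId]]
    if (is.null(cons))
      stop("no consensus mask for patient ", rec@patientId, call. = FALSE)
    cbind(provenance(rec),
          dsc = diceCoefficient(rec@mask, cons),
          hd_cm = hausdorffDistance(rec@mask, cons, rec@spacing),
          volume_cm3 = sum(rec@mask) * prod(rec@spacing) / 1000,
          consensus_volume_cm3 = sum(cons) * prod(rec@spacing) / 1000)
  })
  perRecord <- do.call(rbind, rows)
  byTool <- do.call(rbind, lapply(split(perRecord, perRecord$tool_id),
    function(d) data.frame(tool_id = d$tool_id[1], arm = d$arm[1],
                           n = nrow(d),
                           mean_dsc = mean(d$dsc), sd_dsc = sd(d$dsc),
                           mean_hd_cm = mean(d$hd_cm), sd_hd_cm = sd(d$hd_cm),
                           stringsAsFactors = FALSE)))
  rownames(byTool) <- NULL
  list(records = perRecord, byTool = byTool)
}
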