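# Volume/mask IO (NIfTI-1) and feature-table serialization (CSV + JSON
# sidecar).

#' Read and write volumetric images
#'
#' Volumes are stored as NIfTI-1 with voxel spacing in the pixdim header
#' fields; write-then-read round-trips values and spacing. Reading a payload
#' that is not 3D is an error naming the dimensionality.
#'
#' @param vol an [ImageVolume-class].
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `readVolume` returns an [ImageVolume-class]; `writeVolume`
#'   returns `path` invisibly.
#' @export
writeVolume <- function(vol, path) {
  img <- RNifti::asNifti(vol@values)
  RNifti::pixdim(img) <- vol@spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname writeVolume
#' @export
readVolume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop(sprintf("expected a 3D volume, got %dD payload", length(d)),
         call. = FALSE)
  spc <- RNifti::pixdim(img)
  if (length(spc) < 3L || any(!is.finite(spc[1:3])) || any(spc[1:3] <= 0))
    stop("volume has missing or invalid spacing metadata", call. = FALSE)
  imageVolume(array(as.numeric(img), dim = d), spc[1:3])
}

#' Read and write binary masks
#'
#' Masks are stored as unsigned 8-bit 0/1 NIfTI volumes. On read, any
#' nonzero value is coerced to TRUE (with a warning if values other than
#' 0/1 occur); an all-zero mask triggers a warning surfaced to the caller.
#'
#' @param mask 3D logical array.
#' @param spacing numeric(3) voxel spacing in mm.
#' @param path file path.
#' @return `readMask` returns a 3D logical array with the spacing attached
#'   as attribute `"spacing"`; `writeMask` returns `path` invisibly.
#' @export
writeMask <- function(mask, spacing, path) {
  stopIfNot3dMask(mask)
  img <- RNifti::asNifti(array(as.integer(mask), dim = dim(mask)))
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' @rdname writeMask
#' @export
readMask <- function(path) {
  vol <- readVolume(path)
  vals <- vol@values
  if (any(!vals %in% c(0, 1)))
    warning("mask file contains values other than 0/1; coercing nonzero to TRUE")
  m <- array(vals != 0, dim = dim(vals))
  if (!any(m)) warning("mask is empty (no nonzero voxels)")
  attr(m, "spacing") <- vol@spacing
  m
}

#' Serialize feature tables
#'
#' Feature tables are written as CSV with the provenance header
#' `patient_id, arm, tool_id, observer_id, run` followed by the feature
#' columns, plus a JSON sidecar (`<path>.categories.json`) mapping every
#' feature to its SHP/HIS/TXT category. Round trips are lossless to well
#' below statistical precision (15 significant digits).
#'
#' @param table a feature table (see [extractAll()]).
#' @param path CSV path.
#' @return `readFeatureTable` returns the feature table with its category
#'   attribute restored; `writeFeatureTable` returns `path` invisibly.
#' @export
writeFeatureTable <- function(table, path) {
  miss <- setdiff(PROVENANCE_COLS, colnames(table))
  if (length(miss))
    stop("missing provenance column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  feats <- featureColumns(table)
  if (!length(feats)) stop("table has no feature columns", call. = FALSE)
  if (anyDuplicated(colnames(table)))
    stop("duplicate feature names: ",
         paste(unique(colnames(table)[duplicated(colnames(table))]),
               collapse = ", "), call. = FALSE)
  write.csv(table[c(PROVENANCE_COLS, feats)], path, row.names = FALSE)
  categ <- attr(table, "categories")
  if (!is.null(categ))
    jsonlite::write_json(as.list(categ[feats]),
                         paste0(path, ".categories.json"),
                         auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeFeatureTable
#' @export
readFeatureTable <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(PROVENANCE_COLS, colnames(tab))
  if (length(miss))
    stop("missing provenance column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  sidecar <- paste0(path, ".categories.json")
  if (file.exists(sidecar)) {
    categ <- unlist(jsonlite::read_json(sidecar))
    attr(tab, "categories") <- categ
  }
  tab
}

#' Write a study to disk
#'
#' Persists every patient image and contour mask as NIfTI plus a manifest
#' CSV (`patient_id, arm, tool_id, observer_id, run, mask_path, image_path`)
#' from which the study can be reloaded.
#'
#' @param study a [SegmentationStudy-class].
#' @param dir output directory (created if needed).
#' @return Path of the manifest CSV, invisibly.
#' @export
writeStudy <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  imgPaths <- character()
  for (pid in names(study@images)) {
    imgPaths[pid] <- file.path(dir, sprintf("%s_image.nii.gz", pid))
    writeVolume(study@images[[pid]], imgPaths[pid])
    writeMask(study@truths[[pid]], study@images[[pid]]@spacing,
              file.path(dir, sprintf("%s_truth.nii.gz", pid)))
  }
  rows <- lapply(seq_along(study@contours), function(i) {
    rec <- study@contours[[i]]
    mp <- file.path(dir, sprintf("%s_%s_%s_run%d.nii.gz", rec@patientId,
                                 gsub("[^A-Za-z0-9]", "", rec@toolId),
                                 gsub("[^A-Za-z0-9]", "", rec@observerId),
                                 rec@run))
    writeMask(rec@mask, rec@spacing, mp)
    cbind(provenance(rec), mask_path = mp,
          image_path = imgPaths[rec@patientId])
  })
  manifest <- do.call(rbind, rows)
  mpath <- file.path(dir, "manifest.csv")
  write.csv(manifest, mpath, row.names = FALSE)
  invisible(mpath)
}

#' Load a study from a manifest
#'
#' @param manifestPath path to a manifest CSV written by [writeStudy()] (or
#'   assembled by hand with the same columns).
#' @return A list with `images` (named list of [ImageVolume-class]) and
#'   `contours` (list of [ContourRecord-class]); usable wherever a study is
#'   accepted by [extractAll()].
#' @export
loadStudyManifest <- function(manifestPath) {
  man <- read.csv(manifestPath, stringsAsFactors = FALSE)
  need <- c(PROVENANCE_COLS, "mask_path", "image_path")
  miss <- setdiff(need, colnames(man))
  if (length(miss))
    stop("manifest lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  base <- dirname(manifestPath)
  resolve <- function(p) ifelse(file.exists(p), p, file.path(base, basename(p)))
  images <- list()
  contours <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    pid <- man$patient_id[i]
    if (is.null(images[[pid]]))
      images[[pid]] <- readVolume(resolve(man$image_path[i]))
    m <- readMask(resolve(man$mask_path[i]))
    contours[[i]] <- contourRecord(array(as.logical(m), dim = dim(m)),
                                   attr(m, "spacing"), pid, man$arm[i],
                                   man$tool_id[i], man$observer_id[i],
                                   man$run[i])
  }
  list(images = images, contours = contours)
}
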