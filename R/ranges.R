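# Normalized feature-range analysis: per-patient z-scores, then min/max per
# segmentation method.

#' Per-patient z-score normalization of a feature table
#'
#' Standardizes each feature within each patient over all of that patient's
#' contours (both arms pooled, so manual and semi-automatic ranges live on
#' one comparable axis): f_hat = (f - mean_p) / sd_p with sample SD. When a
#' patient's contours all agree on a feature (sd_p = 0) the normalized
#' values are set to 0 and the (patient, feature) pair is flagged.
#'
#' @param table a feature table; every patient needs >= 2 contours.
#' @return The normalized table, with attribute `"zero_sd"` (data.frame of
#'   flagged patient/feature pairs) and the original `"categories"`.
#' @export
normalizePerPatient <- function(table) {
  feats <- featureColumns(table)
  counts <- tabulate(factor(table$patient_id))
  if (any(counts < 2))
    stop("every patient needs at least 2 contours", call. = FALSE)
  out <- table
  flags <- list()
  for (pid in unique(table$patient_id)) {
    rows <- table$patient_id == pid
    for (f in feats) {
      x <- table[[f]][rows]
      s <- sd(x)
      if (s == 0) {
        out[[f]][rows] <- 0
        flags[[length(flags) + 1L]] <- data.frame(
          patient_id = pid, feature = f, stringsAsFactors = FALSE)
      } else {
        out[[f]][rows] <- (x - mean(x)) / s
      }
    }
  }
  attr(out, "zero_sd") <- if (length(flags)) do.call(rbind, flags)
    else data.frame(patient_id = character(), feature = character())
  attr(out, "categories") <- attr(table, "categories")
  out
}

#' Feature range per segmentation method
#'
#' Minimum and maximum normalized feature value per feature, pooled across
#' patients, observers and runs, grouped both by arm (manual vs
#' semi-automatic) and by individual tool. Range width summarizes how much a
#' segmentation method can move a feature; the overlap flags relate each
#' feature's semi-automatic range to its manual range.
#'
#' @param ntable a normalized feature table from [normalizePerPatient()].
#' @return list with `byArm` and `byTool` data.frames (feature, group, min,
#'   max, width) and `overlap` (per feature: manual and semi-automatic
#'   bounds, `overlaps`, `contained` = semi-automatic range inside manual).
#' @export
rangeByMethod <- function(ntable) {
  feats <- featureColumns(ntable)
  rangeOf <- function(groupCol) {
    grps <- sort(unique(ntable[[groupCol]]))
    do.call(rbind, lapply(grps, function(g) {
      rows <- ntable[[groupCol]] == g
      if (!any(rows)) stop("empty group: ", g, call. = FALSE)
      do.call(rbind, lapply(feats, function(f) {
        x <- ntable[[f]][rows]
        data.frame(feature = f, group = g, min = min(x), max = max(x),
                   width = max(x) - min(x), stringsAsFactors = FALSE)
      }))
    }))
  }
  byArm <- rangeOf("arm")
  byTool <- rangeOf("tool_id")
  man <- byArm[byArm$group == "manual", ]
  semi <- byArm[byArm$group == "semi-automatic", ]
  overlap <- if (nrow(man) && nrow(semi)) {
    merge(man[c("feature", "min", "max")],
          semi[c("feature", "min", "max")],
          by = "feature", suffixes = c("_manual", "_semi"))
  } else NULL
  if (!is.null(overlap)) {
    overlap$overlaps <- overlap$min_manual <= overlap$max_semi &
      overlap$min_semi <= overlap$max_manual
    overlap$contained <- overlap$min_semi >= overlap$min_manual &
      overlap$max_semi <= overlap$max_manual
  }
  list(byArm = byArm, byTool = byTool, overlap = overlap)
}
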