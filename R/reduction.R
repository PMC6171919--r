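# Two-step informative-feature reduction: normalized dynamic range across
# per-patient average feature values, then Spearman redundancy pruning.

#' Per-patient average feature values
#'
#' Mean of every feature over all contour rows of each patient (each patient
#' contributes many contours; the patient average is what inter-patient
#' dynamic range is judged on).
#'
#' @param table a feature table (see [extractAll()]).
#' @return data.frame with `patient_id` and one mean column per feature.
#' @export
patientAverages <- function(table) {
  feats <- featureColumns(table)
  if (any(!complete.cases(table[feats])))
    stop("feature table contains missing values", call. = FALSE)
  out <- aggregate(table[feats], by = list(patient_id = table$patient_id),
                   FUN = mean)
  out[order(out$patient_id), , drop = FALSE]
}

#' Normalized dynamic range of one feature
#'
#' z-scores the per-patient averages (sample SD, n-1 denominator) and
#' returns max - min of the z-scores. Affine-invariant; 0 when all patient
#' averages are equal (a feature that cannot differentiate patients, by
#' convention). For two distinct patient values the NDR is sqrt(2) under
#' this convention; for P patients it is bounded by 2 (P - 1) / sqrt(P).
#'
#' @param x numeric vector of per-patient average values (length >= 2).
#' @return Non-negative NDR value.
#' @examples
#' ndr(c(1, 2, 3))  # 2
#' @export
ndr <- function(x) {
  if (length(x) < 2) stop("need at least 2 patients", call. = FALSE)
  s <- sd(x)
  if (s == 0) return(0)
  z <- (x - mean(x)) / s
  max(z) - min(z)
}

#' Filter features by normalized dynamic range
#'
#' Computes the NDR of every feature's per-patient averages and keeps
#' features with NDR strictly above the cutoff. The default cutoff 0 removes
#' only patient-constant features and reports all NDR values (the cutoff is
#' a study-level choice; 2.4 is a typical empirical floor for informative
#' CT features in small cohorts).
#'
#' @param table a feature table.
#' @param cutoff non-negative NDR cutoff (default 0).
#' @return list with `retained` (feature names) and `ndr` (data.frame:
#'   feature, ndr, retained).
#' @export
filterByNDR <- function(table, cutoff = 0) {
  if (cutoff < 0) stop("cutoff must be >= 0", call. = FALSE)
  avg <- patientAverages(table)
  feats <- featureColumns(table)
  vals <- vapply(feats, function(f) ndr(avg[[f]]), numeric(1))
  res <- data.frame(feature = feats, ndr = unname(vals),
                    retained = unname(vals > cutoff),
                    stringsAsFactors = FALSE)
  list(retained = feats[vals > cutoff], ndr = res)
}

#' Spearman correlation matrix of a feature table
#'
#' Pairwise Spearman rank correlations over all contour rows, with two-sided
#' significance flags (t approximation, p < 0.05, uncorrected: the flags
#' annotate, they do not filter). Constant columns yield undefined
#' correlations; these are recorded as 0 and flagged.
#'
#' @param table a feature table (or plain numeric data.frame/matrix of
#'   feature columns), >= 3 rows.
#' @return list of class `"spearmanMatrix"`: `rho` (symmetric, unit
#'   diagonal), `p`, `significant` (logical), `undefined` (logical matrix of
#'   constant-column pairs).
#' @export
spearmanMatrix <- function(table) {
  feats <- featureColumns(as.data.frame(table))
  X <- as.matrix(as.data.frame(table)[feats])
  n <- nrow(X)
  if (n < 3) stop("need at least 3 rows", call. = FALSE)
  rho <- suppressWarnings(cor(X, method = "spearman"))
  undefined <- is.na(rho)
  rho[undefined] <- 0
  diag(rho) <- 1
  r <- pmin(pmax(rho, -1 + 1e-15), 1 - 1e-15)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  diag(p) <- 0
  p[undefined] <- 1
  structure(list(rho = rho, p = p, significant = p < 0.05,
                 undefined = undefined, n = n), class = "spearmanMatrix")
}

#' Prune redundant features at a correlation threshold
#'
#' Greedy redundancy pruning: while any retained pair has |rho| above the
#' threshold, take the pair with the largest |rho| and drop the member whose
#' mean absolute correlation with all other retained features is larger.
#' Ties break toward the larger mean absolute correlation and then the
#' lexicographically later name, making runs deterministic. After pruning,
#' no retained pair exceeds the threshold.
#'
#' @param x a `"spearmanMatrix"` (or a plain correlation matrix with
#'   dimnames).
#' @param threshold absolute-correlation threshold (default 0.95).
#' @return list with `retained` (feature names, original order) and
#'   `log` (data.frame of removals: removed, kept, rho, mean_abs_corr).
#' @export
pruneCorrelated <- function(x, threshold = 0.95) {
  rho <- if (inherits(x, "spearmanMatrix")) x$rho else x
  if (is.null(rownames(rho))) stop("correlation matrix needs dimnames",
                                   call. = FALSE)
  keep <- rownames(rho)
  logRows <- list()
  repeat {
    sub <- abs(rho[keep, keep, drop = FALSE])
    diag(sub) <- 0
    if (length(keep) < 2 || max(sub) <= threshold) break
    hit <- which(sub == max(sub), arr.ind = TRUE)[1, ]
    pair <- keep[hit]
    meanAbs <- vapply(pair, function(f)
      mean(sub[f, setdiff(keep, f)]), numeric(1))
    drop <- if (meanAbs[1] > meanAbs[2]) pair[1]
            else if (meanAbs[2] > meanAbs[1]) pair[2]
            else sort(pair)[2]
    logRows[[length(logRows) + 1L]] <- data.frame(
      removed = drop, kept = setdiff(pair, drop),
      rho = rho[pair[1], pair[2]],
      mean_abs_corr = unname(meanAbs[drop]),
      stringsAsFactors = FALSE)
    keep <- setdiff(keep, drop)
  }
  list(retained = keep,
       log = if (length(logRows)) do.call(rbind, logRows)
             else data.frame(removed = character(), kept = character(),
                             rho = numeric(), mean_abs_corr = numeric()))
}

#' Run the full two-step feature reduction
#'
#' NDR filtering first (least-informative features out), then Spearman
#' redundancy pruning at the absolute-correlation threshold, in that fixed
#' order.
#'
#' @param table a feature table.
#' @param ndrCutoff NDR cutoff (default 0).
#' @param rhoThreshold redundancy threshold (default 0.95).
#' @return list with `retained` feature names, `ndr` results, the
#'   `correlation` matrix of NDR-retained features, and the pruning `log`.
#' @export
reduceFeatures <- function(table, ndrCutoff = 0, rhoThreshold = 0.95) {
  nd <- filterByNDR(table, ndrCutoff)
  kept <- table[c(PROVENANCE_COLS, nd$retained)]
  attr(kept, "categories") <- attr(table, "categories")
  cm <- spearmanMatrix(kept)
  pr <- pruneCorrelated(cm, rhoThreshold)
  list(retained = pr$retained, ndr = nd$ndr, correlation = cm, log = pr$log)
}
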