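# The full reliability analysis across the three relationship families.

# Row indices of the measurement matrix (patients x columns) defined by a
# list of column filters; shared across features of one group.
matrixIndices <- function(table, colFilters) {
  pats <- sort(unique(table$patient_id))
  idx <- vapply(colFilters, function(f) {
    rows <- which(f(table))
    sel <- rows[match(pats, table$patient_id[rows])]
    if (any(is.na(sel)))
      stop("missing design cells for patients: ",
           paste(pats[is.na(sel)], collapse = ", "), call. = FALSE)
    sel
  }, integer(length(pats)))
  rownames(idx) <- pats
  idx
}

# Measurement matrix of one feature for one relationship group.
buildMatrix <- function(table, feature, colFilters) {
  idx <- matrixIndices(table, colFilters)
  matrix(table[[feature]][idx], nrow(idx), ncol(idx),
         dimnames = list(rownames(idx), NULL))
}

# Enumerate the relationship groups of a design-complete feature table:
# intra-observer per (tool, observer), inter-observer per (tool, run),
# inter-software per (arm, observer, run).
relationshipGroups <- function(table) {
  groups <- list()
  # value-capturing filter factory (loop variables are shared otherwise)
  cellFilter <- function(tool = NULL, obs = NULL, run = NULL) {
    force(tool); force(obs); force(run)
    function(t) {
      sel <- rep(TRUE, nrow(t))
      if (!is.null(tool)) sel <- sel & t$tool_id == tool
      if (!is.null(obs)) sel <- sel & t$observer_id == obs
      if (!is.null(run)) sel <- sel & t$run == run
      sel
    }
  }
  armOfTool <- tapply(table$arm, table$tool_id, function(a) a[1])
  tools <- names(armOfTool)
  for (tool in tools) {
    sub <- table[table$tool_id == tool, ]
    for (obs in sort(unique(sub$observer_id))) {
      runs <- sort(unique(sub$run[sub$observer_id == obs]))
      groups[[length(groups) + 1L]] <- list(
        relationship = "intra-observer", model = "oneway",
        label = sprintf("%s | %s", tool, obs),
        arm = armOfTool[[tool]], tool = tool, observer = obs, run = NA,
        filters = lapply(runs, function(r) cellFilter(tool, obs, r)))
    }
    for (r in sort(unique(sub$run))) {
      obss <- sort(unique(sub$observer_id[sub$run == r]))
      groups[[length(groups) + 1L]] <- list(
        relationship = "inter-observer", model = "twoway",
        label = sprintf("%s | run %d", tool, r),
        arm = armOfTool[[tool]], tool = tool, observer = NA, run = r,
        filters = lapply(obss, function(o) cellFilter(tool, o, r)))
    }
  }
  for (arm in sort(unique(table$arm))) {
    armTools <- sort(unique(table$tool_id[table$arm == arm]))
    if (length(armTools) < 2) next
    sub <- table[table$arm == arm, ]
    for (obs in sort(unique(sub$observer_id)))
      for (r in sort(unique(sub$run)))
        groups[[length(groups) + 1L]] <- list(
          relationship = "inter-software", model = "twoway",
          label = sprintf("%s | %s | run %d", arm, obs, r),
          arm = arm, tool = paste(armTools, collapse = " vs "),
          observer = obs, run = r,
          filters = lapply(armTools, function(tl) cellFilter(tl, obs, r)))
  }
  groups
}

#' Run the full reliability analysis of a feature table
#'
#' Builds every measurement matrix family of the study design and analyzes
#' each feature in each group:
#' \itemize{
#'   \item intra-observer: one matrix per (tool, observer); columns are the
#'     repeat runs; one-way random-effects ICC(1).
#'   \item inter-observer: one matrix per (tool, run); columns are the
#'     observers; two-way mixed absolute-agreement ICC(A,1).
#'   \item inter-software: one matrix per (arm, observer, run); columns are
#'     the arm's tools; ICC(A,1).
#' }
#' For every (group, feature) it reports the ICC estimate, the 95% CI, the
#' four-tier classification (on the CI lower bound by default, the
#' conservative convention), and Lin's CCC; per group the mean ICC and mean
#' CI endpoints over features; per relationship the ICC-CCC rank concordance;
#' and per group the category rank-sum comparisons. Negative ICC estimates
#' are reported as computed, never truncated.
#'
#' @param table a feature table complete for the design (every patient
#'   present in every (arm, tool, observer, run) cell).
#' @param basis classification basis: `"ci_lower"` (default) or
#'   `"estimate"`.
#' @param alpha CI miss probability (default 0.05).
#' @return Object of class `"reliabilityReport"`: list with `results`
#'   (per group x feature), `groupSummary`, `classificationGrid` (features x
#'   groups tier matrix), `concordance` (per relationship), and
#'   `categoryComparisons`.
#' @export
runReliabilitySuite <- function(table, basis = c("ci_lower", "estimate"),
                                alpha = 0.05) {
  basis <- match.arg(basis)
  feats <- featureColumns(table)
  categ <- attr(table, "categories")
  if (is.null(categ))
    categ <- stats::setNames(rep(NA_character_, length(feats)), feats)
  groups <- relationshipGroups(table)

  resRows <- vector("list", length(groups))
  for (gi in seq_along(groups)) {
    g <- groups[[gi]]
    idx <- matrixIndices(table, g$filters)
    nf <- length(feats)
    est <- lo <- hi <- cc <- numeric(nf)
    dg <- logical(nf)
    cls <- character(nf)
    for (fi in seq_len(nf)) {
      m <- matrix(table[[feats[fi]]][idx], nrow(idx), ncol(idx))
      fit <- if (g$model == "oneway") iccOneWay(m, alpha)
             else iccTwoWayMixed(m, alpha)
      est[fi] <- fit$estimate; lo[fi] <- fit$ci_low; hi[fi] <- fit$ci_high
      dg[fi] <- fit$degenerate
      cls[fi] <- classifyReliability(
        if (basis == "ci_lower") fit$ci_low else fit$estimate)
      cc[fi] <- ccc(m)
    }
    resRows[[gi]] <- data.frame(
      relationship = g$relationship, group = g$label, arm = g$arm,
      tool = g$tool, observer = g$observer, run = g$run, feature = feats,
      category = unname(categ[feats]), icc = est, ci_low = lo, ci_high = hi,
      degenerate_ci = dg, classification = cls, ccc = cc,
      stringsAsFactors = FALSE)
  }
  results <- do.call(rbind, resRows)

  groupSummary <- do.call(rbind, lapply(
    split(results, list(results$relationship, results$group), drop = TRUE),
    function(d) data.frame(
      relationship = d$relationship[1], group = d$group[1], arm = d$arm[1],
      tool = d$tool[1], observer = d$observer[1], run = d$run[1],
      n_features = nrow(d),
      mean_icc = mean(d$icc, na.rm = TRUE),
      mean_ci_low = mean(d$ci_low, na.rm = TRUE),
      mean_ci_high = mean(d$ci_high, na.rm = TRUE),
      mean_ccc = mean(d$ccc, na.rm = TRUE), stringsAsFactors = FALSE)))
  rownames(groupSummary) <- NULL
  groupSummary <- groupSummary[order(groupSummary$relationship,
                                     groupSummary$group), ]

  grid <- tapply(results$classification,
                 list(results$feature, results$group), `[[`, 1)

  concordance <- lapply(split(results, results$relationship), function(d) {
    ok <- is.finite(d$icc) & is.finite(d$ccc)
    if (sum(ok) >= 3 && length(unique(d$icc[ok])) > 1 &&
        length(unique(d$ccc[ok])) > 1)
      iccCccConcordance(d$icc[ok], d$ccc[ok])
    else list(rho = NA_real_, r_squared = NA_real_, n = sum(ok))
  })

  categoryComparisons <- if (!all(is.na(categ))) {
    do.call(rbind, lapply(split(results, results$group), function(d) {
      cmp <- compareCategories(stats::setNames(d$icc, d$feature), categ)
      cbind(relationship = d$relationship[1], group = d$group[1], cmp,
            stringsAsFactors = FALSE)
    }))
  } else NULL

  structure(list(results = results, groupSummary = groupSummary,
                 classificationGrid = grid, concordance = concordance,
                 categoryComparisons = categoryComparisons,
                 basis = basis, alpha = alpha),
            class = "reliabilityReport")
}

#' @export
print.reliabilityReport <- function(x, ...) {
  cat("Reliability report (classification basis:", x$basis, ")\n")
  for (rel in unique(x$groupSummary$relationship)) {
    d <- x$groupSummary[x$groupSummary$relationship == rel, ]
    cat(sprintf("  %s: %d groups, mean ICC %.3f\n", rel, nrow(d),
                mean(d$mean_icc, na.rm = TRUE)))
  }
  invisible(x)
}
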