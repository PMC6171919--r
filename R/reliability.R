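# ANOVA-based intraclass correlation reliability analysis: one-way random
# and two-way mixed single-measure absolute-agreement models, McGraw-Wong
# confidence intervals, four-tier classification, Lin's concordance, and
# rank-sum comparisons between feature categories.

#' Two-way ANOVA decomposition of a measurement matrix
#'
#' Mean squares of the crossed tumors (rows) by raters (columns) layout:
#' rows MS_R, columns MS_C, residual MS_E, and the one-way within-rows mean
#' square MS_W. These satisfy the one-way identity
#' (n-1) MS_R + n (k-1) MS_W = total SS and the within-rows partition
#' n (k-1) MS_W = (k-1) MS_C + (n-1)(k-1) MS_E.
#'
#' @param m numeric n x k matrix, complete, n >= 2 rows (tumors) and
#'   k >= 2 columns (raters/measurements).
#' @return An [AnovaDecomposition-class].
#' @examples
#' anovaDecompose(rbind(c(1, 1), c(2, 2), c(3, 3)))  # MS_R = 2, MS_W = 0
#' @export
anovaDecompose <- function(m) {
  m <- as.matrix(m)
  n <- nrow(m); k <- ncol(m)
  if (n < 2 || k < 2) stop("need n >= 2 and k >= 2", call. = FALSE)
  if (any(!is.finite(m))) stop("matrix must be complete", call. = FALSE)
  g <- mean(m)
  rm_ <- rowMeans(m)
  cm_ <- colMeans(m)
  msR <- k * sum((rm_ - g)^2) / (n - 1)
  msC <- n * sum((cm_ - g)^2) / (k - 1)
  resid <- m - outer(rm_, rep(1, k)) - outer(rep(1, n), cm_) + g
  msE <- sum(resid^2) / ((n - 1) * (k - 1))
  msW <- sum((m - rm_)^2) / (n * (k - 1))
  new("AnovaDecomposition", msR = msR, msC = msC, msE = msE, msW = msW,
      n = n, k = k)
}

#' One-way random-effects ICC, single measure, absolute agreement
#'
#' ICC(1) = (MS_R - MS_W) / (MS_R + (k - 1) MS_W), the model for
#' intra-observer (run 1 vs run 2) reliability, where repeat measurements
#' have no column structure of their own. Estimates are bounded below by
#' -1/(k - 1) and never truncated.
#'
#' @param m numeric n x k matrix or an [AnovaDecomposition-class].
#' @param alpha confidence level is 1 - alpha (default 0.05).
#' @return list: `estimate`, `ci_low`, `ci_high`, `model = "oneway"`,
#'   `degenerate` flag, and the decomposition.
#' @export
iccOneWay <- function(m, alpha = 0.05) {
  dec <- if (is(m, "AnovaDecomposition")) m else anovaDecompose(m)
  k <- dec@k
  den <- dec@msR + (k - 1) * dec@msW
  est <- if (den > 0) (dec@msR - dec@msW) / den else NA_real_
  ci <- iccConfidenceInterval(dec, "oneway", alpha)
  buildIccResult(est, ci, "oneway", dec)
}

#' Two-way mixed-effects ICC, single measure, absolute agreement
#'
#' ICC(A,1) = (MS_R - MS_E) /
#' (MS_R + (k - 1) MS_E + (k / n)(MS_C - MS_E)), the model for
#' inter-observer (columns = observers) and inter-software (columns = tools)
#' reliability. Absolute agreement penalizes systematic offsets between
#' columns, not just inconsistency.
#'
#' @inheritParams iccOneWay
#' @return list as in [iccOneWay()] with `model = "twoway"`.
#' @export
iccTwoWayMixed <- function(m, alpha = 0.05) {
  dec <- if (is(m, "AnovaDecomposition")) m else anovaDecompose(m)
  n <- dec@n; k <- dec@k
  den <- dec@msR + (k - 1) * dec@msE + (k / n) * (dec@msC - dec@msE)
  est <- if (den != 0) (dec@msR - dec@msE) / den else NA_real_
  ci <- iccConfidenceInterval(dec, "twoway", alpha)
  buildIccResult(est, ci, "twoway", dec)
}

buildIccResult <- function(est, ci, model, dec) {
  if (is.finite(est) && !ci$degenerate) {
    ci$low <- min(ci$low, est)
    ci$high <- max(ci$high, est)
  }
  list(estimate = est, ci_low = ci$low, ci_high = ci$high, model = model,
       degenerate = ci$degenerate, decomposition = dec)
}

#' Confidence interval for a single-measure absolute-agreement ICC
#'
#' F-distribution based intervals in the McGraw-Wong forms: exact for the
#' one-way random model, Satterthwaite-approximate degrees of freedom for
#' the two-way absolute-agreement model. Degenerate mean squares (e.g. a
#' perfect-agreement matrix with zero residuals) give the widest valid
#' interval `[-1, 1]` with `degenerate = TRUE`.
#'
#' @param dec an [AnovaDecomposition-class].
#' @param model `"oneway"` or `"twoway"`.
#' @param alpha two-sided miss probability (default 0.05 for 95% CIs).
#' @return list: `low`, `high`, `degenerate`.
#' @export
iccConfidenceInterval <- function(dec, model = c("oneway", "twoway"),
                                  alpha = 0.05) {
  model <- match.arg(model)
  n <- dec@n; k <- dec@k
  if (model == "oneway") {
    if (dec@msW == 0) {
      if (dec@msR == 0) return(list(low = -1, high = 1, degenerate = TRUE))
      return(list(low = 1, high = 1, degenerate = FALSE)) # perfect agreement
    }
    f0 <- dec@msR / dec@msW
    fl <- f0 / qf(1 - alpha / 2, n - 1, n * (k - 1))
    fu <- f0 * qf(1 - alpha / 2, n * (k - 1), n - 1)
    return(list(low = max(-1, (fl - 1) / (fl + k - 1)),
                high = min(1, (fu - 1) / (fu + k - 1)),
                degenerate = FALSE))
  }
  # two-way mixed, absolute agreement, single measure (Satterthwaite df)
  den <- dec@msR + (k - 1) * dec@msE + (k / n) * (dec@msC - dec@msE)
  est <- if (den != 0) (dec@msR - dec@msE) / den else NA_real_
  if (!is.finite(est))
    return(list(low = -1, high = 1, degenerate = TRUE))
  if (est >= 1) {
    if (dec@msR > 0 && dec@msE == 0 && dec@msC == 0)
      return(list(low = 1, high = 1, degenerate = FALSE)) # perfect agreement
    return(list(low = -1, high = 1, degenerate = TRUE))
  }
  a <- (k * est) / (n * (1 - est))
  b <- 1 + (k * est * (n - 1)) / (n * (1 - est))
  num <- (a * dec@msC + b * dec@msE)^2
  denDf <- (a * dec@msC)^2 / (k - 1) + (b * dec@msE)^2 / ((n - 1) * (k - 1))
  if (!is.finite(num) || !is.finite(denDf) || denDf <= 0)
    return(list(low = -1, high = 1, degenerate = TRUE))
  v <- num / denDf
  fl <- qf(1 - alpha / 2, n - 1, v)
  fu <- qf(1 - alpha / 2, v, n - 1)
  low <- n * (dec@msR - fl * dec@msE) /
    (fl * (k * dec@msC + (k * n - k - n) * dec@msE) + n * dec@msR)
  high <- n * (fu * dec@msR - dec@msE) /
    (k * dec@msC + (k * n - k - n) * dec@msE + n * fu * dec@msR)
  if (!is.finite(low) || !is.finite(high))
    return(list(low = -1, high = 1, degenerate = TRUE))
  list(low = max(-1, low), high = min(1, high), degenerate = FALSE)
}

#' Four-tier reliability classification
#'
#' Maps a reliability value onto the conventional tiers: poor below 0.4,
#' fair in `[0.4, 0.6)`, good in `[0.6, 0.75)`, excellent at or above 0.75
#' (closed lower bound at every tier). The basis value may be the point
#' estimate or, more conservatively, the lower 95% confidence bound.
#'
#' @param value finite reliability value (ICC or CCC scale).
#' @return One of `"poor"`, `"fair"`, `"good"`, `"excellent"`.
#' @examples
#' classifyReliability(0.75)  # "excellent"
#' @export
classifyReliability <- function(value) {
  if (!is.finite(value)) return(NA_character_)
  if (value < 0.4) "poor"
  else if (value < 0.6) "fair"
  else if (value < 0.75) "good"
  else "excellent"
}

#' Lin's concordance correlation coefficient
#'
#' CCC = 2 s_xy / (s_x^2 + s_y^2 + (mean(x) - mean(y))^2) with population
#' (1/n) moments: the product of Pearson precision and an accuracy penalty
#' for scale/location shift. For a matrix with more than two columns the
#' mean of all pairwise CCCs is returned. Undefined (NA) when both inputs
#' are constant.
#'
#' @param x numeric vector, or an n x k matrix (then `y` is ignored).
#' @param y numeric vector of the same length as `x`.
#' @return CCC in `[-1, 1]`, or NA when undefined.
#' @examples
#' ccc(c(1, 2, 3), c(2, 3, 4))  # 4/7
#' @export
ccc <- function(x, y = NULL) {
  if (is.matrix(x)) {
    k <- ncol(x)
    if (k < 2) stop("matrix needs >= 2 columns", call. = FALSE)
    prs <- utils::combn(k, 2)
    return(mean(apply(prs, 2, function(idx) ccc(x[, idx[1]], x[, idx[2]]))))
  }
  if (length(x) != length(y) || length(x) < 2)
    stop("x and y must have equal length >= 2", call. = FALSE)
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sx2 <- mean((x - mx)^2); sy2 <- mean((y - my)^2)
  sxy <- mean((x - mx) * (y - my))
  den <- sx2 + sy2 + (mx - my)^2
  if (den == 0) return(NA_real_) # both constant and equal: undefined
  2 * sxy / den
}

#' Concordance between ICC and CCC reliability rankings
#'
#' Spearman rank correlation and least-squares linear fit R^2 between paired
#' per-feature ICC and CCC values: high values mean the two reliability
#' metrics rank features the same way.
#'
#' @param iccValues,cccValues paired numeric vectors (length >= 3).
#' @return list: `rho` (Spearman), `r_squared`, `n` (complete pairs used).
#' @export
iccCccConcordance <- function(iccValues, cccValues) {
  if (length(iccValues) != length(cccValues) || length(iccValues) < 3)
    stop("need paired vectors of equal length >= 3", call. = FALSE)
  ok <- is.finite(iccValues) & is.finite(cccValues)
  x <- iccValues[ok]; y <- cccValues[ok]
  if (length(x) < 3) stop("fewer than 3 complete pairs", call. = FALSE)
  if (length(unique(x)) == 1 || length(unique(y)) == 1)
    stop("ties-only input: rank correlation undefined", call. = FALSE)
  list(rho = cor(x, y, method = "spearman"), r_squared = cor(x, y)^2,
       n = length(x))
}

#' Rank-sum comparison of reliability between feature categories
#'
#' Two-sided Wilcoxon rank-sum (Mann-Whitney) tests between the per-feature
#' reliability values of each category pair (SHP-HIS, HIS-TXT, SHP-TXT).
#' Exact null when the combined group size is at most 20 and there are no
#' ties; normal approximation with continuity correction otherwise. The
#' direction reports which category's median is higher.
#'
#' @param values named numeric vector of per-feature reliability values.
#' @param categories named character vector feature -> category.
#' @return data.frame: category_a, category_b, n_a, n_b, p_value,
#'   significant (p < 0.05), direction (sign of median(a) - median(b)).
#' @export
compareCategories <- function(values, categories) {
  categories <- categories[names(values)]
  cats <- c("SHP", "HIS", "TXT")
  pairs <- list(c("SHP", "HIS"), c("HIS", "TXT"), c("SHP", "TXT"))
  rows <- lapply(pairs, function(pr) {
    xa <- values[categories == pr[1] & is.finite(values)]
    xb <- values[categories == pr[2] & is.finite(values)]
    if (length(xa) < 2 || length(xb) < 2)
      return(data.frame(category_a = pr[1], category_b = pr[2],
                        n_a = length(xa), n_b = length(xb),
                        p_value = NA_real_, significant = NA,
                        direction = NA_real_,
                        note = "fewer than 2 features in a category",
                        stringsAsFactors = FALSE))
    exact <- (length(xa) + length(xb)) <= 20
    wt <- suppressWarnings(wilcox.test(xa, xb, exact = exact,
                                       correct = TRUE))
    data.frame(category_a = pr[1], category_b = pr[2],
               n_a = length(xa), n_b = length(xb), p_value = wt$p.value,
               significant = wt$p.value < 0.05,
               direction = sign(median(xa) - median(xb)), note = "",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
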