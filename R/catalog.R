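# Feature catalogs: which features are computed, in which category, with
# which co-occurrence distance.

SHP_NAMES <- c("volume", "surface_area", "surface_to_volume", "sphericity",
               "compactness1", "compactness2", "spherical_disproportion",
               "roundness", "max_diameter_3d", "major_axis_length",
               "elongation", "flatness")

HIS_NAMES <- c("mean", "median", "minimum", "maximum", "range", "sd",
               "variance", "skewness", "kurtosis", "p10", "p25", "p75",
               "p90", "iqr", "energy", "rms", "entropy", "uniformity",
               "mad", "medad", "rmad")

TXT_NAMES <- c("energy", "entropy", "contrast", "correlation", "homogeneity",
               "dissimilarity", "autocorrelation", "cluster_shade",
               "cluster_prominence", "cluster_tendency", "max_probability",
               "sum_average", "sum_entropy", "sum_variance",
               "difference_average", "difference_entropy",
               "difference_variance", "imc1", "imc2", "inverse_difference",
               "inverse_difference_norm", "inverse_difference_moment_norm",
               "inverse_variance", "joint_average", "joint_variance")

TXT_REDUCED <- c("energy", "entropy", "contrast", "correlation",
                 "homogeneity", "dissimilarity", "autocorrelation",
                 "cluster_shade", "cluster_prominence", "max_probability",
                 "sum_average", "sum_entropy", "sum_variance",
                 "difference_entropy", "imc1", "imc2")

HIS_REDUCED <- c("mean", "median", "minimum", "maximum", "range", "sd",
                 "variance", "skewness", "kurtosis", "iqr", "entropy",
                 "uniformity")

#' Feature catalog
#'
#' The catalog defines the named features the extractor computes, each tagged
#' with one of three categories: geometric shape (SHP), intensity histogram
#' (HIS), and gray-level co-occurrence texture (TXT, averaged over the four
#' in-plane directions 0/45/90/135 degrees). The `"default83"` profile has
#' 83 features (12 SHP + 21 HIS + 25 TXT at each of co-occurrence distances
#' 1 and 2 voxels); `"reduced40"` is a documented 40-feature non-redundant
#' profile (12 SHP + 12 HIS + 16 TXT at distance 1). The catalogs reproduce
#' the three-category structure of the classic IBEX-era feature sets, not
#' any tool's bit-exact definitions.
#'
#' @param profile `"default83"` or `"reduced40"`.
#' @return A data.frame with columns `name`, `category` (SHP/HIS/TXT),
#'   `base` (extractor-level feature name) and `distance` (GLCM offset in
#'   voxels; NA for SHP/HIS).
#' @examples
#' nrow(featureCatalog("default83"))  # 83
#' @export
featureCatalog <- function(profile = c("default83", "reduced40")) {
  profile <- match.arg(profile)
  if (profile == "default83") {
    shp <- SHP_NAMES; his <- HIS_NAMES
    txt <- TXT_NAMES; dists <- c(1L, 2L)
  } else {
    shp <- SHP_NAMES; his <- HIS_REDUCED
    txt <- TXT_REDUCED; dists <- 1L
  }
  rows <- rbind(
    data.frame(name = paste0("shp_", shp), category = "SHP", base = shp,
               distance = NA_integer_, stringsAsFactors = FALSE),
    data.frame(name = paste0("his_", his), category = "HIS", base = his,
               distance = NA_integer_, stringsAsFactors = FALSE),
    do.call(rbind, lapply(dists, function(d)
      data.frame(name = sprintf("txt_%s_d%d", txt, d), category = "TXT",
                 base = txt, distance = d, stringsAsFactors = FALSE)))
  )
  if (anyDuplicated(rows$name)) stop("catalog has duplicate feature names")
  rownames(rows) <- NULL
  rows
}

#' Category map of a catalog or feature table
#'
#' @param x a catalog data.frame from [featureCatalog()], or a feature table
#'   carrying a `categories` attribute.
#' @return Named character vector feature -> category.
#' @export
featureCategories <- function(x) {
  if (is.data.frame(x) && all(c("name", "category") %in% colnames(x)))
    return(stats::setNames(x$category, x$name))
  categ <- attr(x, "categories")
  if (is.null(categ)) stop("no category information found", call. = FALSE)
  categ
}
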