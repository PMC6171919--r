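# End-to-end orchestration: simulate/load -> consensus + validation ->
# extraction -> reduction -> reliability -> ranges, with persisted artifacts.

#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis. Either a synthetic
#' [StudyDesign-class] or a manifest path supplies the contours.
#'
#' @param design a [StudyDesign-class] (ignored when `manifest` is given).
#' @param manifest optional path to a study manifest CSV ([writeStudy()]).
#' @param catalog feature catalog id: `"default83"` or `"reduced40"`.
#' @param ndrCutoff NDR cutoff (>= 0, default 0).
#' @param rhoThreshold Spearman redundancy threshold in (0, 1], default 0.95.
#' @param consensusMinCount consensus vote threshold; `NULL` = majority rule
#'   `ceiling((n + 2) / 2)`.
#' @param alpha CI miss probability in (0, 1), default 0.05.
#' @param basis classification basis, `"ci_lower"` or `"estimate"`.
#' @param outputDir directory for stage artifacts.
#' @param writeVolumes also persist every image/mask as NIfTI (slower).
#' @param seed master seed; overrides the design's seed.
#' @return Object of class `"pipelineConfig"`.
#' @export
pipelineConfig <- function(design = studyDesign(), manifest = NULL,
                           catalog = "default83", ndrCutoff = 0,
                           rhoThreshold = 0.95, consensusMinCount = NULL,
                           alpha = 0.05, basis = "ci_lower",
                           outputDir = "radsegvar-out", writeVolumes = FALSE,
                           seed = 1L) {
  cfg <- structure(list(design = design, manifest = manifest,
                        catalog = catalog, ndrCutoff = ndrCutoff,
                        rhoThreshold = rhoThreshold,
                        consensusMinCount = consensusMinCount, alpha = alpha,
                        basis = basis, outputDir = outputDir,
                        writeVolumes = writeVolumes, seed = as.integer(seed)),
                   class = "pipelineConfig")
  validatePipelineConfig(cfg)
  cfg
}

validatePipelineConfig <- function(cfg) {
  if (!cfg$catalog %in% c("default83", "reduced40"))
    stop("unknown catalog: ", cfg$catalog, call. = FALSE)
  if (cfg$ndrCutoff < 0) stop("ndrCutoff must be >= 0", call. = FALSE)
  if (cfg$rhoThreshold <= 0 || cfg$rhoThreshold > 1)
    stop("rhoThreshold must be in (0, 1]", call. = FALSE)
  if (cfg$alpha <= 0 || cfg$alpha >= 1)
    stop("alpha must be in (0, 1)", call. = FALSE)
  if (!cfg$basis %in% c("ci_lower", "estimate"))
    stop("basis must be 'ci_lower' or 'estimate'", call. = FALSE)
  if (is.null(cfg$manifest)) validObject(cfg$design)
  invisible(cfg)
}

#' Read / write a pipeline configuration as YAML
#'
#' The YAML block covers the scalar settings plus the synthetic design
#' (patients, arms, runs, per-tool perturbation models, volume range,
#' phantom parameters, seed); configurations round-trip losslessly.
#'
#' @param cfg a `"pipelineConfig"`.
#' @param path YAML file path.
#' @return `readPipelineConfig` returns the `"pipelineConfig"`;
#'   `writePipelineConfig` returns `path` invisibly.
#' @export
writePipelineConfig <- function(cfg, path) {
  d <- cfg$design
  ph <- d@phantom
  lst <- list(
    catalog = cfg$catalog, ndr_cutoff = cfg$ndrCutoff,
    rho_threshold = cfg$rhoThreshold,
    consensus_min_count = cfg$consensusMinCount,
    alpha = cfg$alpha, basis = cfg$basis, output_dir = cfg$outputDir,
    write_volumes = cfg$writeVolumes, seed = cfg$seed,
    manifest = cfg$manifest,
    design = list(
      n_patients = d@nPatients, runs = d@runs,
      volume_range_cm3 = d@volumeRangeCm3,
      arms = lapply(d@arms, function(a)
        list(tools = a$tools, observers = a$observers)),
      variation = d@variation,
      models = lapply(d@models, function(m)
        list(tool_sd_mm = m@toolSdMm, observer_bias_mm = m@observerBiasMm,
             run_sd_mm = m@runSdMm, smoothing_mm = m@smoothingMm)),
      phantom = list(spacing = ph@spacing, lumpiness = ph@lumpiness,
                     tumor_mean_hu = ph@tumorMeanHu,
                     lung_mean_hu = ph@lungMeanHu,
                     texture_sd_hu = ph@textureSdHu,
                     texture_corr_length_mm = ph@textureCorrLengthMm,
                     noise_sd_hu = ph@noiseSdHu)))
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname writePipelineConfig
#' @export
readPipelineConfig <- function(path) {
  lst <- yaml::read_yaml(path)
  dd <- lst$design
  php <- dd$phantom
  ph <- phantomSpec(spacing = unlist(php$spacing),
                    lumpiness = php$lumpiness,
                    tumorMeanHu = php$tumor_mean_hu,
                    lungMeanHu = php$lung_mean_hu,
                    textureSdHu = php$texture_sd_hu,
                    textureCorrLengthMm = php$texture_corr_length_mm,
                    noiseSdHu = php$noise_sd_hu)
  design <- studyDesign(
    nPatients = dd$n_patients, runs = dd$runs,
    volumeRangeCm3 = unlist(dd$volume_range_cm3),
    arms = lapply(dd$arms, function(a)
      list(tools = unlist(a$tools), observers = unlist(a$observers))),
    models = lapply(dd$models, function(m)
      observerModel(m$tool_sd_mm, m$observer_bias_mm, m$run_sd_mm,
                    m$smoothing_mm)),
    variation = lapply(dd$variation, unlist),
    phantom = ph, seed = lst$seed)
  pipelineConfig(design = design, manifest = lst$manifest,
                 catalog = lst$catalog, ndrCutoff = lst$ndr_cutoff,
                 rhoThreshold = lst$rho_threshold,
                 consensusMinCount = lst$consensus_min_count,
                 alpha = lst$alpha, basis = lst$basis,
                 outputDir = lst$output_dir, writeVolumes = lst$write_volumes,
                 seed = lst$seed)
}

designCellCounts <- function(design) {
  perPatient <- sum(vapply(design@arms, function(a)
    length(a$tools) * length(a$observers) * design@runs, numeric(1)))
  intra <- sum(vapply(design@arms, function(a)
    length(a$tools) * length(a$observers), numeric(1)))
  interObs <- sum(vapply(design@arms, function(a)
    length(a$tools) * design@runs, numeric(1)))
  interSoft <- sum(vapply(design@arms, function(a)
    if (length(a$tools) >= 2) length(a$observers) * design@runs else 0,
    numeric(1)))
  list(contours = design@nPatients * perPatient, perPatient = perPatient,
       intraObserver = intra, interObserver = interObs,
       interSoftware = interSoft)
}

#' Dry-run plan of a pipeline configuration
#'
#' Prints the stage list, the expected contour count, and the reliability
#' relationship-group counts without computing anything.
#'
#' @param cfg a `"pipelineConfig"`.
#' @return The count list, invisibly.
#' @export
describePipeline <- function(cfg) {
  validatePipelineConfig(cfg)
  cts <- designCellCounts(cfg$design)
  cat("Pipeline plan:\n")
  cat("  stages: simulate -> consensus/validate -> extract -> reduce",
      "-> reliability -> ranges\n")
  cat(sprintf("  contours: %d (%d patients x %d per patient)\n",
              cts$contours, cfg$design@nPatients, cts$perPatient))
  cat(sprintf("  catalog: %s (%d features)\n", cfg$catalog,
              nrow(featureCatalog(cfg$catalog))))
  cat(sprintf("  relationship groups: %d intra-observer, %d inter-observer, %d inter-software\n",
              cts$intraObserver, cts$interObserver, cts$interSoftware))
  invisible(cts)
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order: generate (or load) the study, build
#' per-patient consensus masks from the manual run-1 contours and validate
#' every contour against them (Dice, Hausdorff), extract the feature
#' catalog, reduce it (NDR filter then redundancy pruning), run the
#' reliability suite on the retained features, and compute normalized
#' feature ranges. Every stage artifact is written under
#' `cfg$outputDir`; the run is fully deterministic given `cfg$seed`.
#'
#' @param cfg a `"pipelineConfig"`.
#' @param quiet suppress per-stage log lines.
#' @return A summary list (invisibly): study counts, validation summary,
#'   reduction outcome, reliability group summary, range results, and paths
#'   of all artifacts.
#' @export
runPipeline <- function(cfg, quiet = FALSE) {
  validatePipelineConfig(cfg)
  outDir <- cfg$outputDir
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  if (is.null(cfg$manifest)) {
    design <- cfg$design
    design@seed <- cfg$seed
    study <- stage("simulate", generateStudy(design))
    records <- study@contours
    images <- study@images
  } else {
    loaded <- stage("load", loadStudyManifest(cfg$manifest))
    records <- loaded$contours
    images <- loaded$images
    study <- NULL
  }
  say("stage simulate/load: %d contours, %d patients", length(records),
      length(images))
  if (cfg$writeVolumes && !is.null(study))
    stage("persist", writeStudy(study, file.path(outDir, "volumes")))

  # consensus from the manual arm's first-run contours (the expert contours)
  manual1 <- Filter(function(r) r@arm == "manual" & r@run == 1L, records)
  byPatient <- split(manual1, vapply(manual1, function(r) r@patientId,
                                     character(1)))
  consensus <- stage("consensus", lapply(byPatient, function(rs) {
    mc <- if (is.null(cfg$consensusMinCount))
      ceiling((length(rs) + 2) / 2) else cfg$consensusMinCount
    consensusMask(lapply(rs, maskArray), mc)
  }))
  metrics <- stage("validate", validateAgainstConsensus(records, consensus))
  write.csv(metrics$records, file.path(outDir, "validation_metrics.csv"),
            row.names = FALSE)
  write.csv(metrics$byTool, file.path(outDir, "validation_by_tool.csv"),
            row.names = FALSE)
  say("stage validate: mean DSC %.3f", mean(metrics$records$dsc))

  catalog <- featureCatalog(cfg$catalog)
  features <- stage("extract",
                    extractAll(records, catalog, images = images))
  writeFeatureTable(features, file.path(outDir, "features.csv"))
  say("stage extract: %d features x %d contours", nrow(catalog),
      nrow(features))

  red <- stage("reduce", reduceFeatures(features, cfg$ndrCutoff,
                                        cfg$rhoThreshold))
  write.csv(red$ndr, file.path(outDir, "ndr.csv"), row.names = FALSE)
  write.csv(as.data.frame(red$correlation$rho),
            file.path(outDir, "correlation_matrix.csv"))
  write.csv(red$log, file.path(outDir, "reduction_log.csv"),
            row.names = FALSE)
  reduced <- features[c(PROVENANCE_COLS, red$retained)]
  attr(reduced, "categories") <-
    attr(features, "categories")[red$retained]
  writeFeatureTable(reduced, file.path(outDir, "features_reduced.csv"))
  say("stage reduce: %d -> %d features", nrow(catalog),
      length(red$retained))

  rel <- stage("reliability",
               runReliabilitySuite(reduced, cfg$basis, cfg$alpha))
  write.csv(rel$results, file.path(outDir, "reliability_results.csv"),
            row.names = FALSE)
  write.csv(rel$groupSummary, file.path(outDir, "reliability_summary.csv"),
            row.names = FALSE)
  write.csv(as.data.frame(rel$classificationGrid),
            file.path(outDir, "classification_grid.csv"))
  if (!is.null(rel$categoryComparisons))
    write.csv(rel$categoryComparisons,
              file.path(outDir, "category_comparisons.csv"),
              row.names = FALSE)
  say("stage reliability: %d group x feature results", nrow(rel$results))

  normed <- stage("ranges", normalizePerPatient(reduced))
  rng <- rangeByMethod(normed)
  write.csv(rng$byArm, file.path(outDir, "ranges_by_arm.csv"),
            row.names = FALSE)
  write.csv(rng$byTool, file.path(outDir, "ranges_by_tool.csv"),
            row.names = FALSE)
  say("stage ranges: done")

  summary <- list(
    n_contours = length(records),
    n_patients = length(images),
    n_features = nrow(catalog),
    n_features_retained = length(red$retained),
    mean_dsc = mean(metrics$records$dsc),
    mean_hd_cm = mean(metrics$records$hd_cm),
    mean_icc_by_relationship = vapply(
      split(rel$groupSummary$mean_icc, rel$groupSummary$relationship),
      mean, numeric(1)),
    concordance_rho = vapply(rel$concordance, function(x)
      if (is.null(x$rho)) NA_real_ else x$rho, numeric(1)),
    seed = cfg$seed)
  jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(summary = summary, validation = metrics, reduction = red,
                 reliability = rel, ranges = rng, features = features,
                 consensus = consensus, study = study))
}
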