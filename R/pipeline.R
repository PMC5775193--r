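# End-to-end cohort driver: four registration/normalization/analysis stages
# per patient, then cohort statistics, with a reproducibility manifest.

#' Assemble a pipeline configuration
#'
#' Exactly one of `phantom` (a [PhantomSpec-class] plus `nPatients`)
#' or `paths` (per-patient NIfTI files plus template and tensor atlas) must
#' be given.
#'
#' @param phantom optional [PhantomSpec-class].
#' @param nPatients phantom cohort size.
#' @param paths optional list with elements `patients` (list of lists with
#'   `diag`, `preop`, `diagMask`, `preopMask` file paths), `template`,
#'   `atlasTensor`.
#' @param outDir output directory.
#' @param seed master seed.
#' @param spacingMM isotropic working resolution, mm.
#' @param tPar,tPerp angle classification thresholds, degrees.
#' @param faMin atlas white-matter FA cutoff.
#' @param magMinMM detectable-vector magnitude threshold, mm.
#' @param intraType,templateType affine transform families for the
#'   intra-patient and template alignments.
#' @param dilateMM tumor-region dilation radius for the non-linear stage.
#' @param segmentThreshold optional intensity threshold; when given, tumor
#'   masks are re-segmented from the images inside the provided masks
#'   (treated as ROIs) instead of being used directly.
#' @param writeVolumes write per-patient NIfTI artifacts (angle maps,
#'   fields) in addition to tables.
#' @return config list (class "gbmGrowthConfig").
#' @export
pipelineConfig <- function(phantom = NULL, nPatients = 10L, paths = NULL,
                           outDir = tempfile("gbmGrowth"), seed = 1L,
                           spacingMM = NULL, tPar = 20, tPerp = 70,
                           faMin = 0.2, magMinMM = 0.5,
                           intraType = "affine", templateType = "affine",
                           dilateMM = 5, segmentThreshold = NULL,
                           writeVolumes = FALSE) {
  if (is.null(phantom) == is.null(paths))
    stop("provide exactly one of `phantom` or `paths`")
  if (!(tPar < tPerp) || tPar <= 0 || tPerp >= 90)
    stop("need 0 < tPar < tPerp < 90")
  structure(list(phantom = phantom, nPatients = as.integer(nPatients),
                 paths = paths, outDir = outDir, seed = as.integer(seed),
                 spacingMM = spacingMM, tPar = tPar, tPerp = tPerp,
                 faMin = faMin, magMinMM = magMinMM,
                 intraType = intraType, templateType = templateType,
                 dilateMM = dilateMM, segmentThreshold = segmentThreshold,
                 writeVolumes = writeVolumes),
            class = "gbmGrowthConfig")
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [pipelineConfig()]; a `phantom` block
#' holds [phantomSpec()] arguments.
#'
#' @param path YAML file.
#' @return config list.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  phantom <- NULL
  if (!is.null(y$phantom)) phantom <- do.call(phantomSpec, y$phantom)
  args <- y[setdiff(names(y), "phantom")]
  do.call(pipelineConfig, c(list(phantom = phantom), args))
}

.log <- function(logLines, stage, msg) {
  line <- sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage, msg)
  message(line)
  c(logLines, line)
}

.patientInputs <- function(config) {
  if (!is.null(config$phantom)) {
    cohort <- makeCohort(config$phantom, config$nPatients,
                         seed = config$seed)
    lapply(seq_along(cohort$patients), function(i) {
      p <- cohort$patients[[i]]
      list(id = p@id, diag = p@imageT1, preop = p@imageT2,
           diagMask = p@maskT1, preopMask = p@maskT2)
    }) -> pats
    list(patients = pats, template = cohort$template, atlas = cohort$atlas)
  } else {
    pats <- lapply(seq_along(config$paths$patients), function(i) {
      pp <- config$paths$patients[[i]]
      list(id = if (is.null(pp$id)) sprintf("P%02d", i) else pp$id,
           diag = readVolume(pp$diag), preop = readVolume(pp$preop),
           diagMask = readVolume(pp$diagMask),
           preopMask = readVolume(pp$preopMask))
    })
    list(patients = pats, template = readVolume(config$paths$template),
         atlas = readTensorVolume(config$paths$atlasTensor))
  }
}

.runPatient <- function(pat, template, fibers, config, spacing) {
  if (!is.null(config$segmentThreshold)) {
    # provided masks act as ROIs; re-segment at the configured threshold
    roi1 <- scalarVolume(array(as.numeric(.dilate6(pat$diagMask@data != 0,
                                                   3L)),
                               volDim(pat$diagMask)), pat$diagMask@affine)
    roi2 <- scalarVolume(array(as.numeric(.dilate6(pat$preopMask@data != 0,
                                                   3L)),
                               volDim(pat$preopMask)), pat$preopMask@affine)
    pat$diagMask <- segmentTumour(pat$diag, roi1, config$segmentThreshold)
    pat$preopMask <- segmentTumour(pat$preop, roi2, config$segmentThreshold)
  }
  # volumes from the native grids (gap-free acquisition: gap = 0)
  vs1 <- voxelSize(pat$diagMask)
  vs2 <- voxelSize(pat$preopMask)
  volDiag <- tumourVolume(pat$diagMask, vs1[1:2], vs1[3])
  volPre <- tumourVolume(pat$preopMask, vs2[1:2], vs2[3])

  # stage 1: isotropic resampling + intra-patient affine. The tumor region
  # (dilated pre-operative mask) is excluded from the metric so that growth
  # does not leak into the global transform.
  diagIso <- resampleIsotropic(pat$diag, spacing)
  preopIso <- resampleIsotropic(pat$preop, spacing)
  preopMaskIso <- resampleIsotropic(pat$preopMask, spacing, "nearest")
  tumorEx <- scalarVolume(
    array(as.numeric(.dilate6(preopMaskIso@data != 0,
                              max(1L, ceiling(8 / min(voxelSize(preopMaskIso)))))),
          volDim(preopMaskIso)), preopMaskIso@affine)
  intra <- registerAffine(diagIso, preopIso, type = config$intraType,
                          excludeMask = tumorEx)
  diagInPre <- applyTransform(diagIso, intra, preopIso)
  diagMaskInPre <- applyTransform(pat$diagMask, intra, preopIso, "nearest")

  # stage 2: tumor-region non-linear registration -> growth field
  field <- registerGrowth(diagInPre, preopIso, diagMaskInPre, preopMaskIso,
                          dilateMM = config$dilateMM)

  # stage 3: template normalization (images, masks, field + reorientation);
  # the tumor is absent from the template, so it is masked from the metric
  toTempl <- registerToTemplate(preopIso, template,
                                type = config$templateType,
                                excludeMask = tumorEx)
  preopMaskT <- applyTransform(preopMaskIso, toTempl, template, "nearest")
  fieldT <- applyTransform(field, toTempl, template)

  # stage 4: down-sample to the atlas grid, angle map, summary
  fieldAtlas <- downsampleField(fieldT, fibers)
  amap <- angleMap(fieldAtlas, fibers, magMinMM = config$magMinMM)
  summ <- classifyAndSummarize(amap, tPar = config$tPar,
                               tPerp = config$tPerp, patientId = pat$id)
  list(summary = summ, angleMap = amap, field = field,
       fieldAtlas = fieldAtlas, maskTemplate = preopMaskT,
       volumes = volumeReport(pat$id, volDiag, volPre),
       intra = intra, toTemplate = toTempl)
}

#' Run the full growth-direction pipeline on a cohort
#'
#' Per patient: (1) intra-patient affine alignment of the diagnostic to the
#' pre-operative image with mask transport, (2) non-linear tumor-region
#' registration yielding the localized growth field, (3) affine
#' normalization to the template applied to images, masks and the field
#' (finite-strain reorientation), (4) down-sampling to the atlas grid,
#' folded-angle map and per-patient classification. Afterwards: the cohort
#' Wilcoxon test of parallel vs perpendicular fractions, the tumor
#' frequency map, and the volume growth summary. Every output is listed in
#' a JSON manifest together with inputs, parameters, package version and
#' seed. Patient-level stage failures are caught, logged and excluded from
#' the cohort statistics.
#'
#' @param config from [pipelineConfig()] or
#'   [readPipelineConfig()].
#' @return invisibly, a list: `summaries`, `pooled`, `wilcoxon`,
#'   `volumeSummary`, `frequencyMap`, `excluded`, `outDir`.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "gbmGrowthConfig"))
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  logLines <- character()
  logLines <- .log(logLines, "setup", "loading inputs")
  inputs <- .patientInputs(config)
  spacing <- config$spacingMM
  if (is.null(spacing)) spacing <- min(voxelSize(inputs$patients[[1]]$preop))
  logLines <- .log(logLines, "setup",
                   sprintf("%d patients, working resolution %g mm",
                           length(inputs$patients), spacing))
  fibers <- principalDirections(inputs$atlas, faMin = config$faMin)
  logLines <- .log(logLines, "atlas",
                   sprintf("%d valid fiber voxels", sum(fibers@valid)))
  results <- list()
  excluded <- character()
  files <- character()
  for (pat in inputs$patients) {
    t0 <- Sys.time()
    res <- tryCatch(.runPatient(pat, inputs$template, fibers, config,
                                spacing),
                    error = function(e) e)
    if (inherits(res, "error")) {
      excluded <- c(excluded, pat$id)
      logLines <- .log(logLines, pat$id,
                       paste("FAILED:", conditionMessage(res)))
      next
    }
    dt <- round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 1)
    logLines <- .log(logLines, pat$id,
                     sprintf("done in %gs; n_valid = %d", dt,
                             res$summary@nValid))
    if (config$writeVolumes) {
      fm <- file.path(config$outDir, sprintf("%s_anglemap.nii.gz", pat$id))
      ff <- file.path(config$outDir, sprintf("%s_field.nii.gz", pat$id))
      writeAngleMap(res$angleMap, fm)
      writeField(res$field, ff)
      files <- c(files, fm, ff)
    }
    results[[pat$id]] <- res
  }
  if (!length(results)) stop("all patients failed; see the log")
  summaries <- lapply(results, `[[`, "summary")
  volumes <- do.call(rbind, lapply(results, `[[`, "volumes"))
  summaryDF <- summariesAsDataFrame(summaries)
  nonEmpty <- Filter(function(s) !s@empty, summaries)
  if (length(nonEmpty) == 0L) {
    logLines <- .log(logLines, "cohort",
                     "no detectable growth in any patient")
    pooled <- NULL
    wres <- NULL
  } else {
    pooled <- poolAlignment(summaries)
    wres <- tryCatch(testParallelVsPerpendicular(summaries),
                     error = function(e) {
                       logLines <<- .log(logLines, "cohort",
                                         paste("Wilcoxon skipped:",
                                               conditionMessage(e)))
                       NULL
                     })
  }
  fmap <- frequencyMap(lapply(results, `[[`, "maskTemplate"))
  volumeSummary <- if (nrow(volumes) >= 2) cohortGrowthSummary(volumes)
                   else c(mean = NA_real_, sd = NA_real_)

  csv <- file.path(config$outDir, "alignment_summaries.csv")
  utils::write.csv(summaryDF, csv, row.names = FALSE)
  volCsv <- file.path(config$outDir, "volumes.csv")
  utils::write.csv(volumes, volCsv, row.names = FALSE)
  fmapPath <- file.path(config$outDir, "frequency_map.nii.gz")
  writeFrequencyMap(fmap, fmapPath)
  statsJson <- file.path(config$outDir, "cohort_stats.json")
  stats <- list(
    n_patients = length(results),
    excluded = as.list(excluded),
    pooled_fractions = if (!is.null(pooled)) as.list(pooled$pooled) else NULL,
    mean_of_patient_fractions =
      if (!is.null(pooled)) as.list(pooled$meanOfPatients) else NULL,
    pooled_n_valid = if (!is.null(pooled)) pooled$nValid else 0,
    no_detectable_growth = is.null(pooled),
    wilcoxon = if (!is.null(wres)) list(W = wres@statistic,
                                        n = wres@nEffective,
                                        p = wres@pValue,
                                        method = wres@method) else NULL,
    volume_ratio = list(mean = unname(volumeSummary["mean"]),
                        sd = unname(volumeSummary["sd"])))
  jsonlite::write_json(stats, statsJson, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  files <- c(files, csv, volCsv, fmapPath, statsJson)
  manifest <- list(
    package = "gbmGrowth",
    version = as.character(utils::packageVersion("gbmGrowth")),
    created = format(Sys.time()),
    seed = config$seed,
    parameters = config[setdiff(names(config), c("phantom", "paths"))],
    phantom = if (!is.null(config$phantom))
      list(gridShape = config$phantom@gridShape,
           voxelSizeT1 = config$phantom@voxelSizeT1,
           voxelSizeT2 = config$phantom@voxelSizeT2,
           fiberGeometry = config$phantom@fiberGeometry,
           gains = c(config$phantom@gainParallel,
                     config$phantom@gainPerpendicular),
           alignmentKappa = config$phantom@alignmentKappa,
           noiseSigma = config$phantom@noiseSigma,
           nPatients = config$nPatients) else NULL,
    inputs = if (!is.null(config$paths)) config$paths else "phantom cohort",
    outputs = as.list(files))
  manifestPath <- file.path(config$outDir, "manifest.json")
  jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  writeLines(logLines, file.path(config$outDir, "pipeline.log"))
  invisible(list(summaries = summaries, pooled = pooled, wilcoxon = wres,
                 volumeSummary = volumeSummary, frequencyMap = fmap,
                 excluded = excluded, outDir = config$outDir,
                 results = results))
}
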