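# End-to-end pipeline orchestration and configuration.
#
# One reproducible command sequence: simulate (or load) injections ->
# align -> blank filter -> duplicate consensus -> jackknife Rep
# optimization -> prevalence filter -> autoscale -> PCA -> PC-count
# selection -> final classifier -> second-subset validation -> annotation
# -> reports. Every stage logs its decisions, seeds and before/after
# counts; a fixed master seed makes the whole run deterministic.

#' Build a pipeline configuration
#'
#' All tunable parameters of the workflow with their defaults. Values are
#' schema-checked before any computation.
#'
#' @param seed master seed for simulation and jackknifing.
#' @param inputDir directory with `injections/*.csv` and `metadata.csv`;
#'   NULL simulates a synthetic dataset instead.
#' @param nShared,nElapidMarkers,nViperidMarkers,effectSize,nContaminants
#'   synthetic panel parameters (see [buildDefaultPanel()]).
#' @param rtJitterSd,mzErrorSd,log10IntensitySd,dropoutProb noise model.
#' @param nBlanks synthetic blank injections.
#' @param mzTol,rtTol alignment tolerances (Da, minutes).
#' @param blankRatio blank-filter fold-change threshold.
#' @param repGrid candidate Rep values (NULL: 2 to the model-subset size).
#' @param nIterations jackknife iterations per Rep value.
#' @param nExtractPerClass venoms held out per family per iteration.
#' @param classifier `"svm"` or `"centroid"`.
#' @param bins confidence-bin table.
#' @param candidatePcs candidate PC counts (NULL: all available).
#' @param annotationMzTol annotation m/z tolerance, Da.
#' @param referenceTable path to the metabolite reference CSV.
#' @return a validated config list (class `metaboclassConfig`).
#' @export
pipelineConfig <- function(seed = 1, inputDir = NULL,
                           nShared = 20, nElapidMarkers = 5,
                           nViperidMarkers = 5, effectSize = 1.0,
                           nContaminants = 2,
                           rtJitterSd = 0.1, mzErrorSd = 0.002,
                           log10IntensitySd = 0.2, dropoutProb = 0.02,
                           nBlanks = 2, mzTol = 0.01, rtTol = 0.5,
                           blankRatio = 3, repGrid = NULL,
                           nIterations = 1000, nExtractPerClass = 4,
                           classifier = "svm",
                           bins = defaultConfidenceBins(),
                           candidatePcs = NULL, annotationMzTol = 0.05,
                           referenceTable = NULL) {
  cfg <- as.list(environment())
  class(cfg) <- "metaboclassConfig"
  validateConfig(cfg)
  cfg
}

#' Validate a pipeline configuration
#'
#' @param cfg a config list.
#' @return invisibly TRUE; errors on the first violated constraint.
#' @export
validateConfig <- function(cfg) {
  chk <- function(ok, msg) if (!ok) .stopf("config error: %s", msg)
  chk(is.numeric(cfg$seed) && length(cfg$seed) == 1, "seed must be one number")
  chk(cfg$mzTol > 0 && cfg$rtTol > 0, "alignment tolerances must be > 0")
  chk(cfg$blankRatio > 0, "blankRatio must be > 0")
  chk(cfg$nIterations >= 1, "nIterations must be >= 1")
  chk(cfg$nExtractPerClass >= 1, "nExtractPerClass must be >= 1")
  chk(cfg$classifier %in% c("svm", "centroid"),
      "classifier must be 'svm' or 'centroid'")
  chk(isTRUE(.checkBins(as.data.frame(cfg$bins))),
      "bins must be five contiguous bins over [50, 100]")
  chk(cfg$annotationMzTol > 0, "annotationMzTol must be > 0")
  chk(cfg$effectSize >= 0, "effectSize must be >= 0")
  for (f in c("rtJitterSd", "mzErrorSd", "log10IntensitySd"))
    chk(cfg[[f]] >= 0, paste(f, "must be >= 0"))
  chk(cfg$dropoutProb >= 0 && cfg$dropoutProb <= 1,
      "dropoutProb must lie in [0, 1]")
  invisible(TRUE)
}

#' Read a pipeline configuration from JSON
#'
#' Unknown keys raise an error; known keys override the defaults of
#' [pipelineConfig()].
#'
#' @param path JSON file path.
#' @return a validated config list.
#' @export
readPipelineConfig <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(pipelineConfig))
  unknown <- setdiff(names(obj), known)
  if (length(unknown))
    .stopf("config error: unknown key '%s'", unknown[1])
  if (!is.null(obj$bins)) obj$bins <- as.data.frame(obj$bins)
  do.call(pipelineConfig, obj)
}

# load injections + metadata from an input directory
.loadInputs <- function(dir) {
  md <- read.csv(file.path(dir, "metadata.csv"), stringsAsFactors = FALSE)
  md$is_blank <- as.logical(md$is_blank)
  inj <- lapply(md$injection_id, function(id)
    readInjectionTable(file.path(dir, "injections", paste0(id, ".csv"))))
  names(inj) <- md$injection_id
  list(injections = inj, metadata = md)
}

#' Run the full classification pipeline
#'
#' @param config a config list from [pipelineConfig()] or
#'   [readPipelineConfig()].
#' @param outdir output directory for the run artifacts.
#' @param verbose echo log lines as messages.
#' @return invisibly, a list with the fitted objects (aligned matrices,
#'   jackknife result, bundle, validation result, reports) and the log.
#' @export
runPipeline <- function(config = pipelineConfig(), outdir = tempfile("run"),
                        verbose = FALSE) {
  validateConfig(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log <- .newLog(verbose)
  log$add("master seed: %d", config$seed)

  # 1. inputs
  if (is.null(config$inputDir)) {
    panel <- buildDefaultPanel(
      nShared = config$nShared, nElapidMarkers = config$nElapidMarkers,
      nViperidMarkers = config$nViperidMarkers,
      seed = .childSeed(config$seed, 1), effectSize = config$effectSize,
      nContaminants = config$nContaminants,
      mzTol = config$mzTol, rtTol = config$rtTol)
    noise <- noiseModel(config$rtJitterSd, config$mzErrorSd,
                        config$log10IntensitySd, config$dropoutProb)
    ds <- simulateDataset(defaultVenomRoster(), panel, noise,
                          nBlanks = config$nBlanks,
                          seed = .childSeed(config$seed, 2))
    log$add("simulated %d injections from a %d-metabolite panel (effect size %.2f log10)",
            length(ds@injections), nrow(panel), config$effectSize)
    injections <- ds; groundTruth <- ds@groundTruth
  } else {
    inp <- .loadInputs(config$inputDir)
    cd <- inp$metadata[, setdiff(names(inp$metadata), "injection_id")]
    rownames(cd) <- inp$metadata$injection_id
    injections <- inp$injections
    attr(injections, "colData") <- cd
    groundTruth <- NULL
    log$add("loaded %d injections from %s", length(injections),
            config$inputDir)
  }

  # leakage guard on declared subsets
  md <- if (is(injections, "SyntheticVenomData")) injections@metadata
        else cbind(injection_id = rownames(attr(injections, "colData")),
                   as.data.frame(attr(injections, "colData")))
  vsub <- unique(md[!md$is_blank, c("venom_id", "subset")])
  if (any(table(vsub$venom_id) > 1))
    .stopf("leakage: a venom is assigned to more than one subset")

  # 2. alignment
  aligned <- if (is(injections, "SyntheticVenomData"))
    alignFeatures(injections, mzTol = config$mzTol, rtTol = config$rtTol)
  else
    alignFeatures(unclass(injections), mzTol = config$mzTol,
                  rtTol = config$rtTol, colData = attr(injections, "colData"))
  log$add("aligned into %d consensus features x %d injections (tolerances %.3g Da, %.2g min)",
          nrow(aligned), ncol(aligned), config$mzTol, config$rtTol)
  writeAlignedMatrix(aligned, file.path(outdir, "aligned_matrix.csv"))

  # 3. pretreatment to venom level
  nBlankCols <- sum(colData(aligned)$is_blank)
  if (nBlankCols > 0) {
    filtered <- blankFilter(aligned, ratio = config$blankRatio)
    cellsZeroed <- sum(assay(aligned, "intensity")[, !colData(aligned)$is_blank] > 0) -
      sum(assay(filtered, "intensity") > 0)
    log$add("blank filter (>= %.1fx over %d blanks): zeroed %d venom cells",
            config$blankRatio, nBlankCols, cellsZeroed)
  } else {
    filtered <- aligned
    log$add("blank filter skipped: no blank injections")
  }
  venoms <- duplicateConsensus(filtered)
  log$add("duplicate consensus: %d venoms, %d features with any signal",
          ncol(venoms), sum(rowSums(assay(venoms, "intensity")) > 0))
  writeAlignedMatrix(venoms, file.path(outdir, "venom_matrix.csv"))

  # 4. Rep optimization by jackknifing
  jk <- optimizeRep(venoms, repGrid = config$repGrid,
                    nIterations = config$nIterations,
                    nExtractPerClass = config$nExtractPerClass,
                    classifier = config$classifier, bins = config$bins,
                    seed = .childSeed(config$seed, 3))
  write.csv(jk@summary, file.path(outdir, "jackknife_summary.csv"),
            row.names = FALSE)
  i <- match(jk@chosenRep, jk@summary$rep)
  log$add("jackknife (%d iterations/Rep, %d venoms out per family, %s rule): chose Rep = %d (fraction fully correct %.3f, %d features)",
          config$nIterations, config$nExtractPerClass, config$classifier,
          jk@chosenRep, jk@summary$fraction_fully_correct[i],
          jk@summary$n_features_retained[i])

  # 5. scale + PCA on the model subset, PC-count selection on validation1
  cd <- colData(venoms)
  modelIds <- colnames(venoms)[cd$subset == "model"]
  val1Ids <- colnames(venoms)[cd$subset == "validation1"]
  xf <- repFilter(venoms, jk@chosenRep, reference = modelIds)
  M <- intensityMatrix(xf)
  as <- .autoscaleMatrix(M[modelIds, , drop = FALSE],
                         seq_along(modelIds), warn = FALSE)
  pcaFull <- fitPca(as$scaled)
  nPcs <- pcaFull@nComponents
  sel <- NULL
  if (length(val1Ids)) {
    scaledVal1 <- applyScaling(M[val1Ids, , drop = FALSE], as$params)
    sel <- selectNPcs(as$scaled, as.character(cd$family[cd$subset == "model"]),
                      scaledVal1, as.character(cd$family[cd$subset == "validation1"]),
                      pcaFull, candidates = config$candidatePcs,
                      classifier = config$classifier, bins = config$bins)
    nPcs <- sel@chosenNPcs
    log$add("PC-count selection on %d first-validation venoms: valid {%s}, chosen %d of %d features",
            length(val1Ids), paste(sel@validPcs, collapse = ","), nPcs,
            ncol(as$scaled))
  } else log$add("no first-validation venoms: keeping all %d components", nPcs)

  # 6. final bundle
  bundle <- fitModelBundle(venoms, rep = jk@chosenRep, nPcs = nPcs,
                           classifier = config$classifier, bins = config$bins)
  saveModelBundle(bundle, file.path(outdir, "model.json"))
  log$add("final model: %d features, %d PCs, %s decision rule",
          length(bundle@featureIds), bundle@pca@nComponents,
          bundle@classifier)

  # 7. second validation
  val2 <- NULL
  if (any(cd$subset == "validation2")) {
    val2 <- validateSecondSubset(bundle, venoms)
    log$add("second validation: %.1f%% of %d venoms correct (%s)",
            val2$accuracy, nrow(val2$report),
            paste(sprintf("%s %.0f%%", val2$perGenus$genus,
                          val2$perGenus$accuracy), collapse = ", "))
  } else log$add("no second-validation venoms")

  # 8. classification report for every venom
  report <- classifyVenoms(bundle, intensityMatrix(venoms))
  report$family <- as.character(cd$family)[match(report$venom_id,
                                                 colnames(venoms))]
  report$subset <- as.character(cd$subset)[match(report$venom_id,
                                                 colnames(venoms))]
  write.csv(report, file.path(outdir, "classification_report.csv"),
            row.names = FALSE)
  hardHits <- mean(report$bin == "hard hit") * 100
  log$add("classification report: %d venoms, %.1f%% hard hits (centroid rule)",
          nrow(report), hardHits)

  # 9. annotation + heatmap of the model-relevant features
  ref <- if (is.null(config$referenceTable)) readReferenceTable()
         else readReferenceTable(config$referenceTable)
  ann <- matchFeatures(bundle@featureIds, bundle@featureMz, bundle@featureRt,
                       ref, mzTol = config$annotationMzTol)
  write.csv(ann, file.path(outdir, "annotation_report.csv"),
            row.names = FALSE)
  log$add("annotation: %d of %d model features matched a reference metabolite (tolerance %.3g Da)",
          length(unique(ann$feature_id)), length(bundle@featureIds),
          config$annotationMzTol)
  prev <- genusPrevalence(venoms)
  scaledAll <- applyScaling(M, as$params)
  hm <- heatmapMatrix(scaledAll, bundle@featureIds, as.data.frame(cd))
  write.csv(hm, file.path(outdir, "heatmap_matrix.csv"))
  writeLines(log$dump(), file.path(outdir, "run_log.txt"))

  invisible(list(aligned = aligned, venoms = venoms, jackknife = jk,
                 pcSelection = sel, bundle = bundle, validation2 = val2,
                 report = report, annotation = ann, prevalence = prev,
                 heatmap = hm, groundTruth = groundTruth,
                 log = log$dump(), outdir = outdir))
}
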