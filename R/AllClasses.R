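# S4 classes for the venom metabolome classification workflow.

#' AlignedFeatureSet: consensus LC-MS features by injections (or venoms)
#'
#' A [SummarizedExperiment::SummarizedExperiment] holding the "coherent
#' matrix" of the workflow: one row per consensus feature, one column per
#' injection (or per venom after duplicate consensus), a single
#' `"intensity"` assay with 0 meaning "feature absent", and `rowData`
#' columns `mz` (consensus m/z, Da) and `rt` (consensus retention time,
#' minutes). Sample annotation (venom id, family, genus, clade, replicate,
#' subset, blank flag) lives in `colData`.
#'
#' @slot .Data inherited SummarizedExperiment structure.
#' @seealso [alignFeatures()], [blankFilter()], [duplicateConsensus()]
#' @export
setClass("AlignedFeatureSet", contains = "SummarizedExperiment")

setValidity("AlignedFeatureSet", function(object) {
  msg <- character()
  if (!"intensity" %in% assayNames(object))
    msg <- c(msg, "assay 'intensity' is required")
  rd <- rowData(object)
  if (!all(c("mz", "rt") %in% colnames(rd)))
    msg <- c(msg, "rowData must contain 'mz' and 'rt'")
  else {
    if (any(!is.finite(rd$mz)) || any(rd$mz <= 0))
      msg <- c(msg, "consensus mz must be finite and > 0")
    if (any(!is.finite(rd$rt)) || any(rd$rt < 0))
      msg <- c(msg, "consensus rt must be finite and >= 0")
  }
  if ("intensity" %in% assayNames(object)) {
    a <- assay(object, "intensity")
    if (any(!is.finite(a)) || any(a < 0))
      msg <- c(msg, "intensities must be finite and >= 0")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an AlignedFeatureSet
#'
#' @param intensity numeric matrix, features x samples; 0 = absent.
#' @param mz,rt numeric vectors of consensus m/z (Da) and retention time
#'   (minutes), one per feature.
#' @param colData a `data.frame` or [S4Vectors::DataFrame] of per-sample
#'   annotation (one row per column of `intensity`).
#' @return an [AlignedFeatureSet-class] object.
#' @export
AlignedFeatureSet <- function(intensity, mz, rt, colData = NULL) {
  intensity <- as.matrix(intensity)
  if (is.null(rownames(intensity)))
    rownames(intensity) <- sprintf("F%04d", seq_len(nrow(intensity)))
  if (is.null(colData))
    colData <- DataFrame(row.names = colnames(intensity))
  se <- SummarizedExperiment(
    assays = list(intensity = intensity),
    rowData = DataFrame(mz = as.numeric(mz), rt = as.numeric(rt),
                        row.names = rownames(intensity)),
    colData = as(colData, "DataFrame"))
  new("AlignedFeatureSet", se)
}

#' Noise model for the synthetic LC-MS generator
#'
#' Measurement-error parameters applied to every simulated feature
#' observation: Gaussian retention-time jitter (minutes), Gaussian m/z error
#' (Da), log10-normal intensity noise, and a global per-observation dropout
#' probability acting on top of the group-level detection probabilities.
#'
#' @slot rtJitterSd numeric, minutes.
#' @slot mzErrorSd numeric, Da.
#' @slot log10IntensitySd numeric, log10 units.
#' @slot dropoutProb numeric in \[0, 1\].
#' @export
setClass("NoiseModel", representation(
  rtJitterSd = "numeric", mzErrorSd = "numeric",
  log10IntensitySd = "numeric", dropoutProb = "numeric"))

setValidity("NoiseModel", function(object) {
  msg <- character()
  sds <- c(object@rtJitterSd, object@mzErrorSd, object@log10IntensitySd)
  if (any(!is.finite(sds)) || any(sds < 0))
    msg <- c(msg, "all noise standard deviations must be finite and >= 0")
  p <- object@dropoutProb
  if (!is.finite(p) || p < 0 || p > 1)
    msg <- c(msg, "dropoutProb must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' @param rtJitterSd,mzErrorSd,log10IntensitySd,dropoutProb see slots.
#' @rdname NoiseModel-class
#' @export
noiseModel <- function(rtJitterSd = 0.1, mzErrorSd = 0.002,
                       log10IntensitySd = 0.2, dropoutProb = 0.02) {
  new("NoiseModel", rtJitterSd = rtJitterSd, mzErrorSd = mzErrorSd,
      log10IntensitySd = log10IntensitySd, dropoutProb = dropoutProb)
}

#' Synthetic venom LC-MS dataset with ground truth
#'
#' Container returned by [simulateDataset()]: the per-injection feature
#' tables (two per venom plus water blanks), the injection metadata, the
#' metabolite panel that generated them, the noise model, and a ground-truth
#' map from every emitted observation to its panel metabolite.
#'
#' @slot injections named list of data.frames with columns mz, rt, intensity.
#' @slot metadata data.frame: injection_id, venom_id, family, genus, clade,
#'   replicate, subset, is_blank.
#' @slot groundTruth named list (per injection) of character vectors giving
#'   the metabolite_id of each observation row.
#' @slot panel the metabolite panel data.frame (see [buildDefaultPanel()]).
#' @slot noise the [NoiseModel-class] used.
#' @export
setClass("SyntheticVenomData", representation(
  injections = "list", metadata = "data.frame", groundTruth = "list",
  panel = "data.frame", noise = "NoiseModel"))

setValidity("SyntheticVenomData", function(object) {
  msg <- character()
  md <- object@metadata
  if (!setequal(names(object@injections), md$injection_id))
    msg <- c(msg, "injection names must match metadata injection_id")
  venoms <- md$venom_id[!md$is_blank]
  if (length(venoms) && any(table(venoms) != 2))
    msg <- c(msg, "every venom must contribute exactly 2 injections")
  if (length(msg)) msg else TRUE
})

#' Per-feature centering and scaling parameters (autoscaling)
#'
#' @slot center named numeric, per-feature mean over the reference rows.
#' @slot scale named numeric, per-feature sample standard deviation
#'   (n-1 denominator) over the reference rows; strictly positive.
#' @export
setClass("ScalingParams",
         representation(center = "numeric", scale = "numeric"))

setValidity("ScalingParams", function(object) {
  msg <- character()
  if (!identical(names(object@center), names(object@scale)))
    msg <- c(msg, "center and scale must cover the same features")
  if (any(!is.finite(object@scale)) || any(object@scale <= 0))
    msg <- c(msg, "scale must be finite and > 0 for every retained feature")
  if (length(msg)) msg else TRUE
})

#' PCA model: loadings, explained variance, retained component count
#'
#' @slot loadings numeric matrix features x components with orthonormal
#'   columns; rownames are feature ids, sign convention: the largest-|loading|
#'   entry of each component is positive.
#' @slot explainedVariance numeric, fraction of total variance per component,
#'   non-increasing.
#' @slot nComponents integer, components retained for projection.
#' @export
setClass("PcaModel", representation(
  loadings = "matrix", explainedVariance = "numeric",
  nComponents = "integer"))

setValidity("PcaModel", function(object) {
  msg <- character()
  L <- object@loadings
  k <- ncol(L)
  if (k < 1L) msg <- c(msg, "at least one component required")
  else {
    g <- crossprod(L)
    if (max(abs(g - diag(k))) > 1e-8)
      msg <- c(msg, "loadings columns must be orthonormal (tol 1e-8)")
  }
  ev <- object@explainedVariance
  if (length(ev) != k)
    msg <- c(msg, "one explained-variance fraction per component")
  else {
    if (any(diff(ev) > 1e-12))
      msg <- c(msg, "explained-variance fractions must be non-increasing")
    if (sum(ev) > 1 + 1e-8 || any(ev < -1e-12))
      msg <- c(msg, "explained-variance fractions must lie in [0,1], sum <= 1")
  }
  if (object@nComponents < 1L || object@nComponents > k)
    msg <- c(msg, "nComponents out of range")
  if (length(msg)) msg else TRUE
})

#' Nearest-centroid classifier with proximity-percentage confidence bins
#'
#' @slot centroids numeric matrix, 2 x components; rownames are the class
#'   labels (the two snake families).
#' @slot bins data.frame with columns label, lower, upper: five bins
#'   partitioning \[50, 100\] (lower inclusive, upper exclusive, last bin
#'   upper inclusive).
#' @export
setClass("CentroidClassifier",
         representation(centroids = "matrix", bins = "data.frame"))

setValidity("CentroidClassifier", function(object) {
  msg <- character()
  if (nrow(object@centroids) != 2L || is.null(rownames(object@centroids)))
    msg <- c(msg, "exactly 2 labelled centroids required")
  bmsg <- .checkBins(object@bins)
  if (!isTRUE(bmsg)) msg <- c(msg, bmsg)
  if (length(msg)) msg else TRUE
})

#' Hard-margin linear SVM over PC scores
#'
#' @slot weights numeric, the hyperplane normal in score space.
#' @slot bias numeric scalar.
#' @slot positiveClass,negativeClass character class labels; predictions on
#'   the positive side of the hyperplane map to `positiveClass`.
#' @export
setClass("SvmModel", representation(
  weights = "numeric", bias = "numeric",
  positiveClass = "character", negativeClass = "character"))

setValidity("SvmModel", function(object) {
  if (sqrt(sum(object@weights^2)) <= 0)
    "weights must have positive norm"
  else TRUE
})

#' Jackknife Rep-optimization result
#'
#' @slot summary data.frame with one row per candidate Rep value: rep,
#'   fraction_fully_correct, n_features_retained, infeasible_count.
#' @slot chosenRep integer, the selected prevalence threshold (argmax of
#'   fraction_fully_correct, ties broken toward larger Rep).
#' @export
setClass("JackknifeResult",
         representation(summary = "data.frame", chosenRep = "integer"))

setValidity("JackknifeResult", function(object) {
  s <- object@summary
  msg <- character()
  need <- c("rep", "fraction_fully_correct", "n_features_retained",
            "infeasible_count")
  if (!all(need %in% names(s)))
    msg <- c(msg, "summary must have rep, fraction_fully_correct, n_features_retained, infeasible_count")
  else {
    f <- s$fraction_fully_correct
    if (any(f < 0 | f > 1, na.rm = TRUE))
      msg <- c(msg, "fractions must lie in [0,1]")
    if (!object@chosenRep %in% s$rep)
      msg <- c(msg, "chosenRep must be one of the evaluated Rep values")
  }
  if (length(msg)) msg else TRUE
})

#' PC-count selection result
#'
#' @slot validPcs integer vector: candidate PC counts for which every
#'   first-validation venom was correctly classified.
#' @slot chosenNPcs integer, the selected component count.
#' @slot accuracies data.frame candidate/accuracy audit trail.
#' @export
setClass("PcSelection", representation(
  validPcs = "integer", chosenNPcs = "integer", accuracies = "data.frame"))

setValidity("PcSelection", function(object) {
  if (length(object@validPcs) && !object@chosenNPcs %in% object@validPcs)
    "chosenNPcs must lie in validPcs when the valid range is nonempty"
  else TRUE
})

#' Trained model bundle: everything needed to classify new venoms
#'
#' @slot featureIds character, retained consensus feature ids.
#' @slot featureMz,featureRt numeric, their consensus coordinates.
#' @slot scaling [ScalingParams-class] frozen on the model subset.
#' @slot pca [PcaModel-class], truncated to the chosen component count.
#' @slot centroid [CentroidClassifier-class].
#' @slot svm [SvmModel-class] (may be absent when the centroid rule is used).
#' @slot rep integer, chosen prevalence threshold.
#' @slot classifier character, "svm" or "centroid" (the decision rule used
#'   for reported classifications).
#' @slot modelVenoms,validation1Venoms character, venom ids consumed during
#'   fitting/selection (leakage guard for later validation).
#' @slot schemaVersion character.
#' @export
setClass("VenomModelBundle", representation(
  featureIds = "character", featureMz = "numeric", featureRt = "numeric",
  scaling = "ScalingParams", pca = "PcaModel",
  centroid = "CentroidClassifier", svm = "ANY",
  rep = "integer", classifier = "character",
  modelVenoms = "character", validation1Venoms = "character",
  schemaVersion = "character"))

setValidity("VenomModelBundle", function(object) {
  msg <- character()
  if (!identical(object@featureIds, rownames(object@pca@loadings)))
    msg <- c(msg, "featureIds must match the PCA loadings rows")
  if (!object@classifier %in% c("svm", "centroid"))
    msg <- c(msg, "classifier must be 'svm' or 'centroid'")
  if (!is.null(object@svm) && !is(object@svm, "SvmModel"))
    msg <- c(msg, "svm slot must be NULL or an SvmModel")
  if (length(msg)) msg else TRUE
})
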