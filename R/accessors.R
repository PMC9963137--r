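# Accessors and show methods.

#' Consensus m/z values of an AlignedFeatureSet
#' @param x an [AlignedFeatureSet-class].
#' @return named numeric vector, Da.
#' @export
setGeneric("consensusMz", function(x) standardGeneric("consensusMz"))

#' @rdname consensusMz
#' @export
setMethod("consensusMz", "AlignedFeatureSet", function(x)
  setNames(rowData(x)$mz, rownames(x)))

#' Consensus retention times of an AlignedFeatureSet
#' @param x an [AlignedFeatureSet-class].
#' @return named numeric vector, minutes.
#' @export
setGeneric("consensusRt", function(x) standardGeneric("consensusRt"))

#' @rdname consensusRt
#' @export
setMethod("consensusRt", "AlignedFeatureSet", function(x)
  setNames(rowData(x)$rt, rownames(x)))

#' Intensity matrix (samples x features)
#'
#' Returns the intensity assay transposed to the row-per-sample orientation
#' used by the statistical layer (pretreatment, PCA, classifiers).
#'
#' @param x an [AlignedFeatureSet-class].
#' @return numeric matrix, samples x features; 0 = absent.
#' @export
setGeneric("intensityMatrix", function(x) standardGeneric("intensityMatrix"))

#' @rdname intensityMatrix
#' @export
setMethod("intensityMatrix", "AlignedFeatureSet", function(x)
  t(assay(x, "intensity")))

setMethod("show", "AlignedFeatureSet", function(object) {
  cd <- colData(object)
  what <- if ("is_blank" %in% colnames(cd) && any(cd$is_blank))
    sprintf("%d injections (%d blanks)", ncol(object), sum(cd$is_blank))
  else if ("replicate" %in% colnames(cd))
    sprintf("%d injections", ncol(object))
  else sprintf("%d venoms", ncol(object))
  cat(sprintf("AlignedFeatureSet: %d consensus features x %s\n",
              nrow(object), what))
  mz <- rowData(object)$mz
  rt <- rowData(object)$rt
  if (nrow(object))
    cat(sprintf("  m/z %.4f-%.4f Da, RT %.2f-%.2f min\n",
                min(mz), max(mz), min(rt), max(rt)))
  callNextMethod()
})

setMethod("show", "NoiseModel", function(object) {
  cat(sprintf(paste0("NoiseModel: rt jitter sd %.3g min, m/z error sd %.3g Da, ",
                     "log10 intensity sd %.3g, dropout %.3g\n"),
              object@rtJitterSd, object@mzErrorSd,
              object@log10IntensitySd, object@dropoutProb))
})

setMethod("show", "SyntheticVenomData", function(object) {
  md <- object@metadata
  cat(sprintf("SyntheticVenomData: %d injections (%d venoms x 2 + %d blanks), %d panel metabolites\n",
              length(object@injections), sum(!md$is_blank) / 2L,
              sum(md$is_blank), nrow(object@panel)))
})

setMethod("show", "PcaModel", function(object) {
  cat(sprintf("PcaModel: %d features, %d components (%d retained)\n",
              nrow(object@loadings), ncol(object@loadings),
              object@nComponents))
  ev <- object@explainedVariance[seq_len(min(5L, ncol(object@loadings)))]
  cat("  explained variance:", paste(sprintf("%.1f%%", 100 * ev),
                                     collapse = " "), "...\n")
})

setMethod("show", "CentroidClassifier", function(object) {
  cat(sprintf("CentroidClassifier: classes %s, %d score dimensions, %d bins\n",
              paste(rownames(object@centroids), collapse = " vs "),
              ncol(object@centroids), nrow(object@bins)))
})

setMethod("show", "SvmModel", function(object) {
  cat(sprintf("SvmModel (hard-margin linear): %d dims, margin %.4g, +1 = %s\n",
              length(object@weights), 2 / sqrt(sum(object@weights^2)),
              object@positiveClass))
})

setMethod("show", "JackknifeResult", function(object) {
  cat(sprintf("JackknifeResult: %d Rep values evaluated, chosen Rep = %d\n",
              nrow(object@summary), object@chosenRep))
  i <- match(object@chosenRep, object@summary$rep)
  cat(sprintf("  fraction fully correct at chosen Rep: %.3f (%d features retained)\n",
              object@summary$fraction_fully_correct[i],
              object@summary$n_features_retained[i]))
})

setMethod("show", "PcSelection", function(object) {
  cat(sprintf("PcSelection: valid PC counts {%s}, chosen %d\n",
              paste(object@validPcs, collapse = ","), object@chosenNPcs))
})

setMethod("show", "VenomModelBundle", function(object) {
  cat(sprintf("VenomModelBundle: %d features (Rep = %d), %d PCs, classifier = %s\n",
              length(object@featureIds), object@rep,
              object@pca@nComponents, object@classifier))
})
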