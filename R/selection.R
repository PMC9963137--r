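# Model selection: jackknife optimization of the prevalence threshold
# (Rep), PC-count selection against the first validation subset, and final
# second-subset validation.
#
# Every jackknife iteration re-runs the full modelling chain (prevalence
# filter, autoscaling, PCA, classifier fit) on the retained venoms only, so
# the held-out venoms leak into neither the feature selection nor the
# scaling. All components are used during Rep optimization; the component
# count is selected afterwards, in a separate step against the first
# validation subset. One master seed spawns an independent deterministic
# stream per (Rep, iteration), so adding candidate Rep values never
# perturbs another candidate's draws.

# one jackknife iteration on a raw venoms x features matrix (model subset)
.jackknifeOnce <- function(M, labels, rep, nExtractPerClass, classifier,
                           bins, seed) {
  set.seed(seed)
  classes <- sort(unique(labels))
  hold <- unlist(lapply(classes, function(cl)
    sample(which(labels == cl), nExtractPerClass)))
  train <- setdiff(seq_len(nrow(M)), hold)
  Mtr <- M[train, , drop = FALSE]
  keep <- colSums(Mtr > 0) >= rep
  if (!any(keep)) return(list(allCorrect = FALSE, infeasible = FALSE))
  res <- tryCatch({
    as <- .autoscaleMatrix(Mtr[, keep, drop = FALSE],
                           seq_along(train), warn = FALSE)
    pca <- fitPca(as$scaled)
    scoresTr <- projectScores(pca, as$scaled)
    scoresHo <- projectScores(pca, applyScaling(M[hold, , drop = FALSE],
                                                as$params))
    if (classifier == "svm") {
      svm <- fitHardMarginSvm(scoresTr, labels[train])
      pred <- svmPredict(svm, scoresHo)$class
    } else {
      cc <- fitCentroidClassifier(scoresTr, labels[train], bins)
      pred <- classifyWithBins(cc, scoresHo)$class
    }
    list(allCorrect = all(pred == labels[hold]), infeasible = FALSE)
  }, error = function(e) {
    infeasible <- grepl("hard margin infeasible", conditionMessage(e))
    list(allCorrect = FALSE, infeasible = infeasible)
  })
  res
}

#' One leave-group-out jackknife iteration
#'
#' Extracts `nExtractPerClass` venoms per family without replacement,
#' re-runs prevalence filtering, autoscaling, PCA (all components) and the
#' classifier fit on the remaining venoms only, projects the held-out
#' venoms and reports whether all of them were correctly classified.
#'
#' @param x venom-level [AlignedFeatureSet-class] restricted to (or
#'   containing) the model subset, or a raw venoms x features matrix.
#' @param labels class labels per venom (taken from `colData(x)$family`
#'   when `x` is an AlignedFeatureSet and `labels` is NULL).
#' @param rep prevalence threshold applied within the iteration.
#' @param nExtractPerClass venoms held out per family (default 4).
#' @param classifier `"svm"` or `"centroid"`.
#' @param bins confidence bins for the centroid rule.
#' @param seed integer seed for the extraction draw.
#' @return list with logical elements `allCorrect` and `infeasible`.
#' @export
jackknifeOnce <- function(x, labels = NULL, rep, nExtractPerClass = 4,
                          classifier = c("svm", "centroid"),
                          bins = defaultConfidenceBins(), seed = 1) {
  classifier <- match.arg(classifier)
  prep <- .modelMatrix(x, labels)
  .jackknifeOnce(prep$M, prep$labels, rep, nExtractPerClass, classifier,
                 bins, seed)
}

# resolve (matrix, labels) for the model subset
.modelMatrix <- function(x, labels = NULL, subset = "model") {
  if (is(x, "AlignedFeatureSet")) {
    cd <- colData(x)
    sel <- if (!is.null(subset) && "subset" %in% colnames(cd))
      which(cd$subset == subset) else seq_len(ncol(x))
    if (is.null(labels)) {
      if (!"family" %in% colnames(cd))
        .stopf("labels not given and colData has no 'family' column")
      labels <- as.character(cd$family[sel])
    }
    M <- intensityMatrix(x)[sel, , drop = FALSE]
  } else {
    M <- as.matrix(x)
    if (is.null(labels)) .stopf("labels are required with a plain matrix")
    labels <- as.character(labels)
  }
  if (length(labels) != nrow(M)) .stopf("one label per venom required")
  list(M = M, labels = labels)
}

#' Optimize the prevalence threshold (Rep) by jackknifing
#'
#' For each candidate Rep value, runs `nIterations` leave-group-out
#' iterations and records the fraction in which all held-out venoms were
#' correctly classified. The chosen Rep is the argmax of that fraction,
#' with ties broken toward the larger Rep (fewer, more prevalent features
#' — less risk of overfitting). Candidates that retain zero features on
#' the full model subset are skipped with a warning.
#'
#' @inheritParams jackknifeOnce
#' @param repGrid candidate Rep values; default `2:n_model_venoms`.
#' @param nIterations jackknife iterations per Rep value (default 1000).
#' @param seed master seed; per-(Rep, iteration) child streams are derived
#'   from it.
#' @return a [JackknifeResult-class].
#' @export
optimizeRep <- function(x, labels = NULL, repGrid = NULL,
                        nIterations = 1000, nExtractPerClass = 4,
                        classifier = c("svm", "centroid"),
                        bins = defaultConfidenceBins(), seed = 1) {
  classifier <- match.arg(classifier)
  prep <- .modelMatrix(x, labels)
  M <- prep$M; labels <- prep$labels
  if (is.null(repGrid)) repGrid <- 2:nrow(M)
  if (!length(repGrid)) .stopf("repGrid must be nonempty")
  nc <- min(table(labels))
  if (nExtractPerClass < 1 || nExtractPerClass >= nc)
    .stopf("nExtractPerClass must be >= 1 and < the smallest class size (%d)", nc)

  prevalence <- colSums(M > 0)
  rows <- lapply(sort(unique(as.integer(repGrid))), function(rep) {
    nFeat <- sum(prevalence >= rep)
    if (nFeat == 0) {
      .warnf("Rep = %d retains 0 features on the model subset; skipped", rep)
      return(data.frame(rep = rep, fraction_fully_correct = NA_real_,
                        n_features_retained = 0L, infeasible_count = NA_integer_))
    }
    correct <- 0L; infeasible <- 0L
    for (it in seq_len(nIterations)) {
      r <- .jackknifeOnce(M, labels, rep, nExtractPerClass, classifier,
                          bins, .childSeed(seed, rep * 1000003 + it))
      if (r$allCorrect) correct <- correct + 1L
      if (r$infeasible) infeasible <- infeasible + 1L
    }
    data.frame(rep = rep, fraction_fully_correct = correct / nIterations,
               n_features_retained = nFeat, infeasible_count = infeasible)
  })
  summary <- do.call(rbind, rows)
  ok <- which(!is.na(summary$fraction_fully_correct))
  if (!length(ok)) .stopf("every candidate Rep retained 0 features")
  best <- max(summary$fraction_fully_correct[ok])
  cand <- summary$rep[ok][summary$fraction_fully_correct[ok] == best]
  new("JackknifeResult", summary = summary,
      chosenRep = as.integer(max(cand)))
}

#' PC-count selection rule
#'
#' The chosen component count is half the number of retained features
#' (rounded up) when that value is among the validated candidates;
#' otherwise the nearest validated candidate (ties toward the smaller).
#' Using as many components as features would amount to no dimensionality
#' reduction and invites overfitting, so the rule stays well inside the
#' validated range.
#'
#' @param nRetainedFeatures number of features in the model.
#' @param validPcs integer vector of validated candidate PC counts.
#' @return integer, the chosen number of components.
#' @export
choosePcCount <- function(nRetainedFeatures, validPcs) {
  validPcs <- sort(as.integer(validPcs))
  if (!length(validPcs)) .stopf("validPcs must be nonempty")
  rule <- as.integer(ceiling(nRetainedFeatures / 2))
  if (rule %in% validPcs) return(rule)
  d <- abs(validPcs - rule)
  validPcs[which.min(d)]  # sorted, so ties resolve toward the smaller value
}

#' Select the retained component count against the first validation subset
#'
#' For each candidate count the PCA model is truncated, the classifier is
#' refit on the truncated training scores and the first-validation venoms
#' are classified; a candidate is valid when every validation venom is
#' correct. The returned count follows [choosePcCount()].
#'
#' @param scaledModel,scaledVal1 autoscaled matrices (samples x features),
#'   the validation rows scaled with the frozen training parameters.
#' @param labelsModel,labelsVal1 true family labels.
#' @param pca the full [PcaModel-class] fit on `scaledModel`.
#' @param candidates candidate PC counts (default: all available).
#' @param classifier `"svm"` or `"centroid"`.
#' @param bins confidence bins for the centroid rule.
#' @return a [PcSelection-class].
#' @export
selectNPcs <- function(scaledModel, labelsModel, scaledVal1, labelsVal1,
                       pca, candidates = NULL,
                       classifier = c("svm", "centroid"),
                       bins = defaultConfidenceBins()) {
  classifier <- match.arg(classifier)
  stopifnot(is(pca, "PcaModel"))
  if (is.null(candidates)) candidates <- seq_len(pca@nComponents)
  candidates <- sort(unique(as.integer(candidates)))
  if (any(candidates < 1 | candidates > pca@nComponents))
    .stopf("candidate PC counts must lie in [1, %d]", pca@nComponents)
  acc <- vapply(candidates, function(k) {
    tryCatch({
      tp <- truncatePca(pca, k)
      sTr <- projectScores(tp, scaledModel)
      sVa <- projectScores(tp, scaledVal1)
      pred <- if (classifier == "svm")
        svmPredict(fitHardMarginSvm(sTr, labelsModel), sVa)$class
      else
        classifyWithBins(fitCentroidClassifier(sTr, labelsModel, bins),
                         sVa)$class
      mean(pred == labelsVal1)
    }, error = function(e) NA_real_)
  }, numeric(1))
  audit <- data.frame(n_pcs = candidates, accuracy = acc)
  valid <- candidates[!is.na(acc) & acc == 1]
  if (!length(valid)) {
    msg <- paste(sprintf("%d PCs: %.0f%%", candidates, 100 * acc),
                 collapse = "; ")
    .stopf("no candidate PC count classifies the first validation subset perfectly (%s)", msg)
  }
  new("PcSelection", validPcs = as.integer(valid),
      chosenNPcs = as.integer(choosePcCount(nrow(pca@loadings), valid)),
      accuracies = audit)
}

#' Fit the final model bundle on the model subset
#'
#' Runs prevalence filtering at the chosen Rep, autoscaling, PCA
#' (truncated to `nPcs` when given) and both classifiers on the model
#' subset of a venom-level matrix.
#'
#' @param x venom-level [AlignedFeatureSet-class] (post blank filter and
#'   duplicate consensus) with `subset` and `family` in its `colData`.
#' @param rep chosen prevalence threshold.
#' @param nPcs retained component count (default: all).
#' @param classifier reported decision rule, `"svm"` or `"centroid"`.
#' @param bins confidence bins.
#' @return a [VenomModelBundle-class].
#' @export
fitModelBundle <- function(x, rep, nPcs = NULL,
                           classifier = c("svm", "centroid"),
                           bins = defaultConfidenceBins()) {
  classifier <- match.arg(classifier)
  stopifnot(is(x, "AlignedFeatureSet"))
  cd <- colData(x)
  if (!all(c("subset", "family") %in% colnames(cd)))
    .stopf("colData must contain 'subset' and 'family'")
  modelIds <- colnames(x)[cd$subset == "model"]
  val1Ids <- colnames(x)[cd$subset == "validation1"]
  xf <- repFilter(x, rep, reference = modelIds)
  M <- intensityMatrix(xf)[modelIds, , drop = FALSE]
  as <- .autoscaleMatrix(M, seq_along(modelIds), warn = FALSE)
  pca <- fitPca(as$scaled)
  if (!is.null(nPcs)) pca <- truncatePca(pca, nPcs)
  scores <- projectScores(pca, as$scaled)
  labels <- as.character(cd$family[cd$subset == "model"])
  centroid <- fitCentroidClassifier(scores, labels, bins)
  svm <- if (classifier == "svm") fitHardMarginSvm(scores, labels) else
    tryCatch(fitHardMarginSvm(scores, labels), error = function(e) NULL)
  feats <- names(as$params@center)
  fi <- match(feats, rownames(xf))
  new("VenomModelBundle",
      featureIds = feats, featureMz = unname(rowData(xf)$mz[fi]),
      featureRt = unname(rowData(xf)$rt[fi]),
      scaling = as$params, pca = pca, centroid = centroid, svm = svm,
      rep = as.integer(rep), classifier = classifier,
      modelVenoms = modelIds, validation1Venoms = val1Ids,
      schemaVersion = .MODEL_SCHEMA_VERSION)
}

#' Classify venoms with a trained model bundle
#'
#' Applies the frozen scaling, projects onto the retained components and
#' reports both decision rules per venom.
#'
#' @param bundle a [VenomModelBundle-class].
#' @param M venoms x features matrix (or venom-level
#'   [AlignedFeatureSet-class]) containing the bundle's features.
#' @return data.frame: venom_id, predicted (bundle's decision rule),
#'   percentage and bin (centroid rule), margin (SVM, NA when absent).
#' @export
classifyVenoms <- function(bundle, M) {
  stopifnot(is(bundle, "VenomModelBundle"))
  if (is(M, "AlignedFeatureSet")) M <- intensityMatrix(M)
  scaled <- applyScaling(M, bundle@scaling)
  scores <- projectScores(bundle@pca, scaled)
  cen <- classifyWithBins(bundle@centroid, scores)
  out <- data.frame(venom_id = rownames(M),
                    centroid_class = cen$class,
                    percentage = cen$percentage, bin = cen$bin,
                    svm_class = NA_character_, margin = NA_real_,
                    stringsAsFactors = FALSE)
  if (!is.null(bundle@svm)) {
    sp <- svmPredict(bundle@svm, scores)
    out$svm_class <- sp$class
    out$margin <- sp$margin
  }
  out$predicted <- if (bundle@classifier == "svm" && !is.null(bundle@svm))
    out$svm_class else out$centroid_class
  out
}

#' Validate the final model on the second validation subset
#'
#' Projects the second-validation venoms (never used in fitting, feature
#' selection or scaling — enforced) through the frozen bundle and reports
#' per-venom predictions, overall accuracy and a per-genus breakdown.
#'
#' @param bundle a [VenomModelBundle-class].
#' @param x venom-level [AlignedFeatureSet-class] containing the
#'   second-validation venoms (`subset == "validation2"` in `colData`, or
#'   give `ids`).
#' @param ids optional explicit venom ids to validate.
#' @return list: `accuracy` (percent correct), `report` (per-venom
#'   data.frame), `perGenus` (accuracy by genus).
#' @export
validateSecondSubset <- function(bundle, x, ids = NULL) {
  stopifnot(is(bundle, "VenomModelBundle"), is(x, "AlignedFeatureSet"))
  cd <- as.data.frame(colData(x))
  if (is.null(ids)) {
    if (!"subset" %in% names(cd))
      .stopf("no 'ids' given and colData has no 'subset' column")
    ids <- colnames(x)[cd$subset == "validation2"]
  }
  if (!length(ids)) .stopf("second validation subset is empty")
  leaked <- intersect(ids, c(bundle@modelVenoms, bundle@validation1Venoms))
  if (length(leaked))
    .stopf("leakage: venom '%s' was used during model fitting or selection",
           leaked[1])
  M <- intensityMatrix(x)[ids, , drop = FALSE]
  rep <- classifyVenoms(bundle, M)
  rep$genus <- cd[ids, "genus"]
  rep$family <- cd[ids, "family"]
  rep$correct <- rep$predicted == rep$family
  perGenus <- aggregate(correct ~ genus, rep, function(z) 100 * mean(z))
  names(perGenus)[2] <- "accuracy"
  list(accuracy = 100 * mean(rep$correct), report = rep,
       perGenus = perGenus)
}
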