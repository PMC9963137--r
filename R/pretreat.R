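# Pretreatment cascade: blank filter, duplicate-presence consensus,
# Rep prevalence filter, autoscaling.
#
# The cleaning rules mirror standard untargeted-metabolomics practice:
# a venom signal survives only when it is at least `ratio` (default 3)
# times the blank signal of the same feature; a feature counts for a venom
# only when present in both duplicate injections; a feature enters the
# model only when present in at least `rep` venoms of the model subset; and
# retained features are mean-centered and autoscaled (z-scored) on the
# model subset before PCA.

#' Blank-signal filter
#'
#' Per feature, the blank level is the maximum intensity observed across
#' blank injections (a conservative aggregation). A venom cell is kept iff
#' its intensity is at least `ratio` times that blank level (boundary
#' inclusive); features absent from all blanks are kept unchanged. Failing
#' cells are zeroed. Blank columns are removed from the output by default.
#'
#' @param x an [AlignedFeatureSet-class] whose `colData` has `is_blank`.
#' @param ratio fold-change threshold (default 3).
#' @param removeBlanks drop the blank columns from the result (default TRUE).
#' @return an [AlignedFeatureSet-class].
#' @export
setGeneric("blankFilter", function(x, ratio = 3, removeBlanks = TRUE)
  standardGeneric("blankFilter"))

#' @rdname blankFilter
#' @export
setMethod("blankFilter", "AlignedFeatureSet", function(x, ratio, removeBlanks) {
  stopifnot(ratio > 0)
  cd <- colData(x)
  if (!"is_blank" %in% colnames(cd))
    .stopf("colData must contain 'is_blank'")
  blanks <- which(cd$is_blank)
  if (!length(blanks))
    .stopf("no blank injections present; disable blank filtering instead of calling blankFilter()")
  a <- assay(x, "intensity")
  blankMax <- apply(a[, blanks, drop = FALSE], 1, max)
  keepCols <- if (removeBlanks) setdiff(seq_len(ncol(a)), blanks)
              else seq_len(ncol(a))
  out <- a[, keepCols, drop = FALSE]
  fail <- out < ratio * blankMax  # blankMax 0 => vacuously kept
  fail[, keepCols %in% blanks] <- FALSE  # never zero the blanks themselves
  out[fail] <- 0
  y <- AlignedFeatureSet(out, mz = rowData(x)$mz, rt = rowData(x)$rt,
                         colData = cd[keepCols, , drop = FALSE])
  y
})

#' Duplicate-presence consensus: injections to venoms
#'
#' Collapses the two duplicate injections of each venom into one venom row:
#' the feature value is the arithmetic mean of the two injection
#' intensities when the feature is present (> 0) in both repetitions, and 0
#' otherwise.
#'
#' @param x an [AlignedFeatureSet-class] over (non-blank) injections whose
#'   `colData` has `venom_id` and `replicate`.
#' @return an [AlignedFeatureSet-class] with one column per venom and
#'   venom-level `colData` (venom_id, family, genus, clade, subset).
#' @export
setGeneric("duplicateConsensus", function(x)
  standardGeneric("duplicateConsensus"))

#' @rdname duplicateConsensus
#' @export
setMethod("duplicateConsensus", "AlignedFeatureSet", function(x) {
  cd <- as.data.frame(colData(x))
  if ("is_blank" %in% names(cd) && any(cd$is_blank)) {
    x <- x[, !cd$is_blank]
    cd <- cd[!cd$is_blank, , drop = FALSE]
  }
  if (!all(c("venom_id", "replicate") %in% names(cd)))
    .stopf("colData must contain 'venom_id' and 'replicate'")
  counts <- table(cd$venom_id)
  bad <- names(counts)[counts != 2]
  if (length(bad))
    .stopf("venom '%s' has %d injections (exactly 2 required)",
           bad[1], counts[bad[1]])
  venoms <- unique(cd$venom_id)
  a <- assay(x, "intensity")
  m <- matrix(0, nrow = nrow(a), ncol = length(venoms),
              dimnames = list(rownames(a), venoms))
  for (j in seq_along(venoms)) {
    cols <- which(cd$venom_id == venoms[j])
    v1 <- a[, cols[1]]; v2 <- a[, cols[2]]
    both <- v1 > 0 & v2 > 0
    m[both, j] <- (v1[both] + v2[both]) / 2
  }
  keepCd <- cd[match(venoms, cd$venom_id),
               intersect(c("venom_id", "family", "genus", "clade", "subset"),
                         names(cd)), drop = FALSE]
  rownames(keepCd) <- venoms
  AlignedFeatureSet(m, mz = rowData(x)$mz, rt = rowData(x)$rt,
                    colData = keepCd)
})

# resolve reference (model-subset) column ids
.referenceIds <- function(x, reference) {
  if (is.null(reference)) {
    cd <- colData(x)
    if (!"subset" %in% colnames(cd))
      .stopf("no 'reference' given and colData has no 'subset' column")
    reference <- colnames(x)[cd$subset == "model"]
  }
  missing <- setdiff(reference, colnames(x))
  if (length(missing))
    .stopf("reference sample '%s' not found in the matrix", missing[1])
  reference
}

#' Prevalence ("Rep") filter
#'
#' Keeps features with a nonzero value in at least `rep` of the reference
#' (model-subset) venoms; validation venoms are subset to the same
#' features but never inspected, so feature selection cannot peek at them.
#'
#' @param x an [AlignedFeatureSet-class] over venoms.
#' @param rep minimum venom count (>= 1).
#' @param reference character vector of reference venom ids; defaults to
#'   the columns whose `subset` is `"model"`.
#' @return an [AlignedFeatureSet-class] restricted to the surviving features.
#' @export
setGeneric("repFilter", function(x, rep, reference = NULL)
  standardGeneric("repFilter"))

#' @rdname repFilter
#' @export
setMethod("repFilter", "AlignedFeatureSet", function(x, rep, reference) {
  stopifnot(rep >= 1)
  reference <- .referenceIds(x, reference)
  if (rep > length(reference))
    .stopf("rep = %d exceeds the number of reference venoms (%d)",
           rep, length(reference))
  a <- assay(x, "intensity")
  prevalence <- rowSums(a[, reference, drop = FALSE] > 0)
  keep <- prevalence >= rep
  if (!any(keep))
    .stopf("no features found in at least %d reference venoms; use a smaller rep", rep)
  x[keep, ]
})

# matrix-level core used by both the exported autoscale and the jackknife
# inner loop; refRows indexes rows of M (samples x features)
.autoscaleMatrix <- function(M, refRows, dropConstant = TRUE, warn = TRUE) {
  if (length(refRows) < 2)
    .stopf("autoscaling requires at least 2 reference samples")
  ref <- M[refRows, , drop = FALSE]
  center <- colMeans(ref)
  scale <- apply(ref, 2, sd)  # n-1 denominator
  constant <- scale <= 0 | !is.finite(scale)
  if (any(constant)) {
    if (!dropConstant)
      .stopf("feature '%s' is constant over the reference samples",
             colnames(M)[which(constant)[1]])
    if (warn)
      .warnf("dropping %d constant feature(s) before autoscaling",
             sum(constant))
    M <- M[, !constant, drop = FALSE]
    center <- center[!constant]; scale <- scale[!constant]
  }
  if (ncol(M) == 0) .stopf("no non-constant features left to autoscale")
  scaled <- sweep(sweep(M, 2, center), 2, scale, "/")
  list(scaled = scaled,
       params = new("ScalingParams", center = center, scale = scale))
}

#' Mean-center and autoscale on a reference subset
#'
#' Per feature, `center` is the mean and `scale` the sample standard
#' deviation (n-1 denominator) computed over the reference (model-subset)
#' rows only; every row is then transformed as `(x - center) / scale`.
#' Features constant over the reference rows are dropped with a warning
#' (or raise an error when `dropConstant = FALSE`).
#'
#' @param x an [AlignedFeatureSet-class] over venoms, or a numeric matrix
#'   (samples x features).
#' @param reference reference sample ids (default: `subset == "model"`
#'   columns) or, for the matrix method, row names / indices.
#' @param dropConstant drop constant features instead of erroring.
#' @return list with `scaled` (samples x features numeric matrix) and
#'   `params` (a [ScalingParams-class]).
#' @export
setGeneric("autoscale", function(x, reference = NULL, dropConstant = TRUE)
  standardGeneric("autoscale"))

#' @rdname autoscale
#' @export
setMethod("autoscale", "AlignedFeatureSet", function(x, reference,
                                                     dropConstant) {
  reference <- .referenceIds(x, reference)
  M <- intensityMatrix(x)
  .autoscaleMatrix(M, match(reference, rownames(M)), dropConstant)
})

#' @rdname autoscale
#' @export
setMethod("autoscale", "matrix", function(x, reference, dropConstant) {
  refRows <- if (is.null(reference)) seq_len(nrow(x))
             else if (is.character(reference)) match(reference, rownames(x))
             else reference
  if (anyNA(refRows)) .stopf("unknown reference sample")
  .autoscaleMatrix(x, refRows, dropConstant)
})

#' Apply frozen scaling parameters to new samples
#'
#' Validation venoms reuse the training center/scale; the output columns
#' follow the parameter order regardless of the input column order.
#'
#' @param M numeric matrix (samples x features) or an
#'   [AlignedFeatureSet-class]; must contain every parameter feature.
#' @param params a [ScalingParams-class].
#' @return numeric matrix, samples x parameter features.
#' @export
applyScaling <- function(M, params) {
  stopifnot(is(params, "ScalingParams"))
  if (is(M, "AlignedFeatureSet")) M <- intensityMatrix(M)
  feats <- names(params@center)
  missing <- setdiff(feats, colnames(M))
  if (length(missing))
    .stopf("feature '%s' required by the scaling parameters is missing",
           missing[1])
  M <- M[, feats, drop = FALSE]
  sweep(sweep(M, 2, params@center), 2, params@scale, "/")
}
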