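# PCA over the autoscaled model subset.
#
# SVD-based fit: the loadings are the right singular vectors of the scaled
# matrix ordered by decreasing singular value (exact and deterministic at
# these matrix sizes, unlike NIPALS). Sign convention: per component the
# largest-|loading| entry is made positive so that serialized models and
# score plots reproduce across platforms.

#' Fit a PCA model on an autoscaled matrix
#'
#' @param M numeric matrix, samples x features, already centered and scaled
#'   (see [autoscale()]); at least 2 rows.
#' @return a [PcaModel-class] with all `min(n, p)` components retained.
#' @export
fitPca <- function(M) {
  M <- as.matrix(M)
  if (nrow(M) < 2) .stopf("PCA requires at least 2 samples")
  if (is.null(colnames(M)))
    colnames(M) <- sprintf("F%04d", seq_len(ncol(M)))
  sv <- svd(M)
  if (max(sv$d) <= 1e-12) .stopf("matrix has rank 0; nothing to decompose")
  L <- sv$v
  # deterministic sign convention: largest-magnitude loading positive
  for (j in seq_len(ncol(L))) {
    i <- which.max(abs(L[, j]))
    if (L[i, j] < 0) L[, j] <- -L[, j]
  }
  dimnames(L) <- list(colnames(M), sprintf("PC%d", seq_len(ncol(L))))
  ev <- sv$d^2 / sum(sv$d^2)
  new("PcaModel", loadings = L, explainedVariance = ev,
      nComponents = ncol(L))
}

#' Project scaled rows onto a PCA model
#'
#' Scores are `rows %*% loadings`, truncated to the retained component
#' count. The input columns must match the model features exactly (same
#' set, same order as produced by [applyScaling()]).
#'
#' @param model a [PcaModel-class].
#' @param M numeric matrix (samples x features), already scaled.
#' @return numeric score matrix, samples x retained components.
#' @export
projectScores <- function(model, M) {
  stopifnot(is(model, "PcaModel"))
  M <- as.matrix(M)
  if (ncol(M) != nrow(model@loadings))
    .stopf("dimension mismatch: %d columns vs %d model features",
           ncol(M), nrow(model@loadings))
  if (!is.null(colnames(M)) &&
      !identical(colnames(M), rownames(model@loadings)))
    .stopf("feature columns do not match the PCA model features (order matters)")
  (M %*% model@loadings)[, seq_len(model@nComponents), drop = FALSE]
}

#' Truncate a PCA model to its first components
#'
#' Keeps the first `nPcs` loadings columns; explained-variance fractions are
#' re-reported for the kept components but not re-normalized.
#'
#' @param model a [PcaModel-class].
#' @param nPcs number of components to keep (1 to available).
#' @return a [PcaModel-class].
#' @export
truncatePca <- function(model, nPcs) {
  stopifnot(is(model, "PcaModel"))
  k <- ncol(model@loadings)
  if (nPcs < 1 || nPcs > k)
    .stopf("nPcs = %d out of range [1, %d]", nPcs, k)
  new("PcaModel",
      loadings = model@loadings[, seq_len(nPcs), drop = FALSE],
      explainedVariance = model@explainedVariance[seq_len(nPcs)],
      nComponents = as.integer(nPcs))
}
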