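# The two decision rules over PC scores.
#
# (1) Nearest-centroid with proximity percentages: the class centers are the
# per-family means of the training scores (classes are known, so no
# iterative re-clustering is needed; an optional Lloyd refinement is
# available for exploration). The reported percentage for a class is the
# complement of its relative distance, 100 * d_other / (d_A + d_B), so that
# the highest percentage always names the nearest center and the winning
# percentage lies in [50, 100], where it is binned into five confidence
# categories ("hard hit" on top).
#
# (2) Hard-margin linear SVM: the maximum-margin separating hyperplane,
# minimizing ||w||^2 subject to y_i (w . s_i + b) >= 1. The quadratic
# program is solved through libsvm (e1071) with an effectively infinite
# slack penalty, after which the solution is rescaled exactly so the
# minimum functional margin equals 1; training constraints are then
# verified and any violation raises a hard-margin infeasibility error
# (never a silent soft margin).

#' Fit the nearest-centroid classifier
#'
#' @param scores numeric matrix, training samples x score dimensions.
#' @param labels factor/character with exactly two classes.
#' @param bins confidence-bin table (see [defaultConfidenceBins()]).
#' @param lloyd if TRUE, refine the class means by Lloyd's k-means updates
#'   (exploratory only; the faithful decision rule uses the group means).
#' @return a [CentroidClassifier-class].
#' @export
fitCentroidClassifier <- function(scores, labels,
                                  bins = defaultConfidenceBins(),
                                  lloyd = FALSE) {
  scores <- as.matrix(scores)
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) != 2)
    .stopf("exactly two classes required (got %d)", length(classes))
  for (cl in classes)
    if (!any(labels == cl)) .stopf("class '%s' has no samples", cl)
  cen <- rbind(colMeans(scores[labels == classes[1], , drop = FALSE]),
               colMeans(scores[labels == classes[2], , drop = FALSE]))
  rownames(cen) <- classes
  if (lloyd) {
    for (it in 1:100) {
      d1 <- sqrt(rowSums(sweep(scores, 2, cen[1, ])^2))
      d2 <- sqrt(rowSums(sweep(scores, 2, cen[2, ])^2))
      memb <- ifelse(d1 <= d2, classes[1], classes[2])
      if (!all(c(classes) %in% memb)) break  # degenerate; keep previous
      newCen <- rbind(colMeans(scores[memb == classes[1], , drop = FALSE]),
                      colMeans(scores[memb == classes[2], , drop = FALSE]))
      rownames(newCen) <- classes
      if (max(abs(newCen - cen)) < 1e-10) { cen <- newCen; break }
      cen <- newCen
    }
  }
  new("CentroidClassifier", centroids = cen, bins = bins)
}

#' Proximity percentages toward each class center
#'
#' With Euclidean distances `d_A`, `d_B` from a score to the two centers,
#' the percentage for class A is `100 * d_B / (d_A + d_B)` (and
#' symmetrically for B): percentages sum to 100 and the nearer center gets
#' the larger value. A score exactly on both centers is defined as 50/50
#' with a warning.
#'
#' @param classifier a [CentroidClassifier-class].
#' @param scores numeric matrix (or vector for one sample) of scores.
#' @return numeric matrix, samples x 2; columns named by class.
#' @export
centroidConfidence <- function(classifier, scores) {
  stopifnot(is(classifier, "CentroidClassifier"))
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1)
  cen <- classifier@centroids
  if (ncol(scores) != ncol(cen))
    .stopf("dimension mismatch: scores have %d dims, centroids %d",
           ncol(scores), ncol(cen))
  dA <- sqrt(rowSums(sweep(scores, 2, cen[1, ])^2))
  dB <- sqrt(rowSums(sweep(scores, 2, cen[2, ])^2))
  tot <- dA + dB
  both0 <- tot == 0
  if (any(both0)) {
    .warnf("%d score(s) coincide with both centroids; reporting 50/50",
           sum(both0))
    tot[both0] <- 1; dA[both0] <- 0.5; dB[both0] <- 0.5
  }
  out <- cbind(100 * dB / tot, 100 * dA / tot)
  colnames(out) <- rownames(cen)
  rownames(out) <- rownames(scores)
  out
}

# locate a winning percentage in the bin table
.binLabel <- function(bins, pct) {
  b <- bins[order(bins$lower), ]
  for (i in seq_len(nrow(b))) {
    last <- i == nrow(b)
    if (pct >= b$lower[i] && (pct < b$upper[i] || (last && pct <= b$upper[i])))
      return(b$label[i])
  }
  NA_character_
}

#' Classify scores with confidence bins
#'
#' @param classifier a [CentroidClassifier-class].
#' @param scores numeric matrix (samples x dims) or vector.
#' @return data.frame: class, percentage, bin (one row per sample).
#' @export
classifyWithBins <- function(classifier, scores) {
  conf <- centroidConfidence(classifier, scores)
  win <- max.col(conf, ties.method = "first")
  pct <- conf[cbind(seq_len(nrow(conf)), win)]
  data.frame(
    class = colnames(conf)[win],
    percentage = pct,
    bin = vapply(pct, function(p) .binLabel(classifier@bins, p), ""),
    row.names = rownames(conf), stringsAsFactors = FALSE)
}

# exact hard-margin polish: given a separating direction, rescale (w, b) so
# the closest point of each class sits at functional margin exactly 1
.polishHyperplane <- function(w, scores, y) {
  proj <- as.numeric(scores %*% w)
  aPos <- min(proj[y > 0]); aNeg <- max(proj[y < 0])
  gap <- aPos - aNeg
  if (gap <= 0) return(NULL)  # direction does not separate
  list(w = w * 2 / gap, b = -(aPos + aNeg) / gap)
}

#' Fit a hard-margin linear SVM
#'
#' @param scores numeric matrix, training samples x score dimensions.
#' @param labels two-class factor/character; `"Elapidae"`, when present, is
#'   mapped to the +1 side by convention (otherwise the alphabetically
#'   first class).
#' @param tol feasibility tolerance on the training constraints
#'   `y_i (w . s_i + b) >= 1 - tol`.
#' @return an [SvmModel-class].
#' @export
fitHardMarginSvm <- function(scores, labels, tol = 1e-6) {
  scores <- as.matrix(scores)
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) != 2)
    .stopf("exactly two classes required (got %d)", length(classes))
  pos <- if ("Elapidae" %in% classes) "Elapidae" else classes[1]
  neg <- setdiff(classes, pos)
  y <- ifelse(labels == pos, 1, -1)
  fit <- e1071::svm(scores, factor(y, levels = c(-1, 1)),
                    kernel = "linear", scale = FALSE, cost = 1e7,
                    tolerance = 1e-8, type = "C-classification")
  w <- as.numeric(t(fit$coefs) %*% fit$SV)
  # libsvm's internal label order can flip the sign; orient w so the +1
  # class projects higher
  if (sum(as.numeric(scores %*% w) * y) < 0) w <- -w
  polished <- .polishHyperplane(w, scores, y)
  if (is.null(polished))
    .stopf("hard margin infeasible: the classes are not linearly separable in score space")
  viol <- y * (as.numeric(scores %*% polished$w) + polished$b)
  if (any(viol < 1 - tol))
    .stopf("hard margin infeasible: the classes are not linearly separable in score space")
  new("SvmModel", weights = polished$w, bias = polished$b,
      positiveClass = pos, negativeClass = neg)
}

#' Predict classes (and signed margins) with a linear SVM
#'
#' The label is the sign of `w . s + b`; a score exactly on the hyperplane
#' is mapped to the positive class with a warning.
#'
#' @param model an [SvmModel-class].
#' @param scores numeric matrix (samples x dims) or vector.
#' @return data.frame: class, margin (signed functional margin `w . s + b`).
#' @export
svmPredict <- function(model, scores) {
  stopifnot(is(model, "SvmModel"))
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1)
  if (ncol(scores) != length(model@weights))
    .stopf("dimension mismatch: scores have %d dims, model %d",
           ncol(scores), length(model@weights))
  f <- as.numeric(scores %*% model@weights) + model@bias
  if (any(f == 0))
    .warnf("%d score(s) lie exactly on the hyperplane; mapped to the positive class",
           sum(f == 0))
  data.frame(class = ifelse(f >= 0, model@positiveClass, model@negativeClass),
             margin = f, row.names = rownames(scores),
             stringsAsFactors = FALSE)
}
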