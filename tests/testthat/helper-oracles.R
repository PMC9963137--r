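# Independent oracles and fixture generators shared across the test files.
# These deliberately avoid the package's own code paths: the SVM oracle
# enumerates support subsets and solves the KKT system directly; the PCA
# oracle goes through the covariance eigendecomposition.

zeroNoise <- function() noiseModel(0, 0, 0, 0)

# exact hard-margin SVM by enumeration of 2- and 3-point support sets:
# solve the equality-constrained KKT system for each subset, keep solutions
# with non-negative dual weights that are feasible on all points, and take
# the maximum-margin (minimum ||w||) one.
svmEnumerationOracle <- function(X, y, tol = 1e-9) {
  n <- nrow(X)
  stopifnot(all(y %in% c(-1, 1)))
  subsets <- list()
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    if (y[i] != y[j]) subsets[[length(subsets) + 1L]] <- c(i, j)
  if (n >= 3)
    for (i in seq_len(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
      s <- c(i, j, k)
      if (length(unique(y[s])) == 2) subsets[[length(subsets) + 1L]] <- s
    }
  best <- NULL
  for (s in subsets) {
    Xs <- X[s, , drop = FALSE]; ys <- y[s]; m <- length(s)
    # unknowns (alpha_1..alpha_m, b):
    #   sum_j alpha_j y_j y_i <x_j, x_i> + y_i b = 1   for i in s
    #   sum_j alpha_j y_j = 0
    K <- Xs %*% t(Xs)
    A <- rbind(cbind(K * outer(ys, ys), ys), c(ys, 0))
    rhs <- c(rep(1, m), 0)
    sol <- tryCatch(solve(A, rhs), error = function(e) NULL)
    if (is.null(sol)) next
    alpha <- unname(sol[seq_len(m)]); b <- unname(sol[m + 1])
    if (any(alpha < -tol)) next
    w <- as.numeric(t(Xs) %*% (alpha * ys))
    if (sum(w^2) < tol) next
    if (any(y * (as.numeric(X %*% w) + b) < 1 - 1e-7)) next
    if (is.null(best) || sum(w^2) < best$ww - tol)
      best <- list(w = w, b = b, ww = sum(w^2))
  }
  best
}

# random linearly separable 2-D instance with a margin wide enough that the
# solver and the oracle cannot disagree through rounding alone
separableInstance2d <- function(seed, n = 10, gap = 1) {
  set.seed(seed)
  theta <- runif(1, 0, 2 * pi)
  u <- c(cos(theta), sin(theta))
  y <- rep(c(-1, 1), length.out = n)
  X <- matrix(rnorm(2 * n), ncol = 2)
  shift <- (gap / 2 + runif(n, 0, 2))
  X <- X - as.numeric(X %*% u) %o% u          # project out u
  X <- X + (shift * y) %o% u                   # place classes along u
  list(X = X, y = y)
}

# principal angles between the subspaces spanned by two orthonormal bases
principalAngles <- function(A, B) {
  s <- svd(crossprod(A, B))$d
  acos(pmin(1, pmax(-1, s)))
}

# covariance-eigendecomposition PCA oracle: orthonormal basis of the
# top-k right singular subspace of a centered matrix
pcaEigenOracle <- function(M, k) {
  C <- crossprod(M)
  e <- eigen(C, symmetric = TRUE)
  e$vectors[, seq_len(k), drop = FALSE]
}

# random noisy alignment instance with within-cluster jitter <= tol/4 and
# between-cluster spacing > 2 * tol in at least one coordinate
alignmentInstance <- function(seed, nFeat = 15, nInj = 8, detect = 0.85,
                              mzTol = 0.01, rtTol = 0.5) {
  set.seed(seed)
  mz <- numeric(); rt <- numeric()
  while (length(mz) < nFeat) {
    m <- runif(1, 100, 1000); r <- runif(1, 1, 30)
    if (!length(mz) || all(abs(mz - m) > 2 * mzTol | abs(rt - r) > 2 * rtTol)) {
      mz <- c(mz, m); rt <- c(rt, r)
    }
  }
  inj <- lapply(seq_len(nInj), function(i) {
    k <- which(runif(nFeat) < detect)
    data.frame(mz = mz[k] + rnorm(length(k), 0, mzTol / 8),
               rt = rt[k] + rnorm(length(k), 0, rtTol / 8),
               intensity = 10^runif(length(k), 4, 6))
  })
  names(inj) <- sprintf("inj%02d", seq_len(nInj))
  list(injections = inj, mz = mz, rt = rt)
}

# partition of observations induced by an aligned matrix, as a canonical
# label per (injection, source row) for partition comparison
alignmentPartition <- function(x) {
  members <- S4Vectors::metadata(x)$memberRows
  out <- list()
  for (f in seq_len(nrow(members))) {
    inj <- which(!is.na(members[f, ]))
    key <- paste(inj, members[f, inj], sep = ":")
    out[[f]] <- sort(key)
  }
  out[order(vapply(out, `[`, "", 1))]
}

# TRUE when any observation sits between tol/2 and tol of >= 2 centroids
# of the reference grouping (the documented near-boundary exclusion)
nearBoundaryInstance <- function(x, injections, mzTol = 0.01, rtTol = 0.5) {
  cm <- SummarizedExperiment::rowData(x)$mz
  cr <- SummarizedExperiment::rowData(x)$rt
  for (tab in injections) {
    for (r in seq_len(nrow(tab))) {
      d <- sqrt(((tab$mz[r] - cm) / mzTol)^2 + ((tab$rt[r] - cr) / rtTol)^2)
      if (sum(d > 0.5 & d <= 1) >= 2) return(TRUE)
    }
  }
  FALSE
}

# small aligned set built directly (features x samples), for pretreatment
# unit tests
makeAlignedSet <- function(m, cd, mz = NULL, rt = NULL) {
  m <- as.matrix(m)
  if (is.null(mz)) mz <- 100 + seq_len(nrow(m))
  if (is.null(rt)) rt <- seq_len(nrow(m))
  AlignedFeatureSet(m, mz = mz, rt = rt, colData = cd)
}

# compact venom-level two-class matrix with planted structure, for
# selection tests: nPer venoms per family, k marker features separated by
# `effect`, plus noisy shared features
plantedVenomMatrix <- function(seed, nPer = 10, k = 4, nShared = 6,
                               effect = 3) {
  set.seed(seed)
  n <- 2 * nPer
  labels <- rep(c("Elapidae", "Viperidae"), each = nPer)
  M <- matrix(10^(4 + matrix(rnorm(n * (k + nShared), 0, 0.2), n)), n)
  for (j in seq_len(k))
    M[labels == "Elapidae", j] <- M[labels == "Elapidae", j] * 10^effect
  # shared features drop out at random so prevalence varies
  for (j in (k + 1):(k + nShared))
    M[runif(n) < 0.5, j] <- 0
  dimnames(M) <- list(sprintf("V%02d", seq_len(n)),
                      sprintf("F%04d", seq_len(k + nShared)))
  list(M = M, labels = labels, markers = colnames(M)[seq_len(k)])
}
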