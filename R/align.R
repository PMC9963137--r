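# Cross-injection feature alignment into the "coherent matrix".
#
# Observations from all injections are grouped into consensus features when
# they fall within an m/z tolerance AND a retention-time tolerance of the
# feature's running centroid. Seeding is greedy in descending intensity
# (the standard deterministic, permutation-invariant choice in peak
# correspondence); candidates are absorbed nearest-first under a scaled
# Euclidean distance with axes normalized by the tolerances, at most one
# observation per injection per feature, with the centroid recomputed after
# every absorption. The study never states its tolerances; the defaults
# (0.01 Da, 0.5 min) are consistent with QTOF mass accuracy and slight
# retention-time drift between repeated injections.

# flatten a named list of injection tables into one observation table
.gatherObservations <- function(injections) {
  if (length(injections) == 0) .stopf("at least one injection required")
  ids <- names(injections)
  if (is.null(ids)) ids <- sprintf("inj%03d", seq_along(injections))
  parts <- lapply(seq_along(injections), function(i) {
    tab <- injections[[i]]
    n <- nrow(tab)
    if (n == 0) return(NULL)
    data.frame(inj = i, row = seq_len(n), mz = tab$mz, rt = tab$rt,
               intensity = tab$intensity)
  })
  obs <- do.call(rbind, parts)
  list(obs = obs, ids = ids)
}

# build the AlignedFeatureSet from a completed assignment
.assembleMatrix <- function(obs, assign, nInj, injIds, colData = NULL) {
  nf <- max(assign)
  mz <- vapply(seq_len(nf), function(f) mean(obs$mz[assign == f]), 0)
  rt <- vapply(seq_len(nf), function(f) mean(obs$rt[assign == f]), 0)
  ord <- order(mz, rt)
  m <- matrix(0, nrow = nf, ncol = nInj,
              dimnames = list(sprintf("F%04d", seq_len(nf)), injIds))
  members <- matrix(NA_integer_, nrow = nf, ncol = nInj)
  for (k in seq_len(nrow(obs))) {
    f <- match(assign[k], ord)
    m[f, obs$inj[k]] <- obs$intensity[k]
    members[f, obs$inj[k]] <- obs$row[k]
  }
  x <- AlignedFeatureSet(m, mz = mz[ord], rt = rt[ord], colData = colData)
  metadata(x)$memberRows <- members  # per (feature, injection) source row
  x
}

#' Align features across injections into a consensus matrix
#'
#' @param injections a named list of per-injection feature tables (columns
#'   mz, rt, intensity) or a [SyntheticVenomData-class] (whose metadata then
#'   populates the result's `colData`).
#' @param mzTol,rtTol alignment tolerances: Da and minutes; both > 0.
#' @param colData optional per-injection annotation (ignored when
#'   `injections` is a `SyntheticVenomData`).
#' @return an [AlignedFeatureSet-class]: consensus features x injections,
#'   absent features as 0, consensus m/z and RT equal to the mean of the
#'   member observations.
#' @export
setGeneric("alignFeatures", function(injections, mzTol = 0.01, rtTol = 0.5,
                                     colData = NULL)
  standardGeneric("alignFeatures"))

#' @rdname alignFeatures
#' @export
setMethod("alignFeatures", "list", function(injections, mzTol, rtTol,
                                            colData) {
  stopifnot(mzTol > 0, rtTol > 0)
  g <- .gatherObservations(injections)
  obs <- g$obs
  if (is.null(obs)) .stopf("no observations found in any injection")
  n <- nrow(obs)
  assign <- integer(n)
  # deterministic seeding order: intensity desc, then injection, then row
  ord <- order(-obs$intensity, obs$inj, obs$row)
  nextFeature <- 0L
  for (s in ord) {
    if (assign[s]) next
    nextFeature <- nextFeature + 1L
    assign[s] <- nextFeature
    cmz <- obs$mz[s]; crt <- obs$rt[s]
    memberInj <- obs$inj[s]
    nMembers <- 1L
    repeat {
      cand <- which(assign == 0L &
                      abs(obs$mz - cmz) <= mzTol &
                      abs(obs$rt - crt) <= rtTol &
                      !(obs$inj %in% memberInj))
      if (!length(cand)) break
      d <- sqrt(((obs$mz[cand] - cmz) / mzTol)^2 +
                  ((obs$rt[cand] - crt) / rtTol)^2)
      pick <- cand[order(d, obs$inj[cand], obs$row[cand])[1]]
      assign[pick] <- nextFeature
      # running centroid update
      cmz <- (cmz * nMembers + obs$mz[pick]) / (nMembers + 1L)
      crt <- (crt * nMembers + obs$rt[pick]) / (nMembers + 1L)
      nMembers <- nMembers + 1L
      memberInj <- c(memberInj, obs$inj[pick])
    }
  }
  .assembleMatrix(obs, assign, length(injections), g$ids, colData)
})

#' @rdname alignFeatures
#' @export
setMethod("alignFeatures", "SyntheticVenomData",
          function(injections, mzTol, rtTol, colData) {
  md <- injections@metadata
  cd <- md[, setdiff(names(md), "injection_id"), drop = FALSE]
  rownames(cd) <- md$injection_id
  alignFeatures(injections@injections[md$injection_id], mzTol = mzTol,
                rtTol = rtTol, colData = cd)
})

#' Reference alignment by global nearest-neighbour agglomeration
#'
#' Test oracle for [alignFeatures()]: instead of growing one feature at a
#' time, every absorption step scans all (unassigned observation, open
#' feature) pairs and commits the globally nearest tolerance-respecting one,
#' recomputing centroids after each step; a new feature is seeded with the
#' most intense unassigned observation only when no pair qualifies. The two
#' algorithms provably coincide when clusters are separated by more than
#' twice the tolerances and within-cluster scatter is small; near-boundary
#' instances may legitimately differ. Guarded to at most 500 observations.
#'
#' @inheritParams alignFeatures
#' @return an [AlignedFeatureSet-class].
#' @export
bruteForceAlign <- function(injections, mzTol = 0.01, rtTol = 0.5,
                            colData = NULL) {
  stopifnot(mzTol > 0, rtTol > 0)
  g <- .gatherObservations(injections)
  obs <- g$obs
  n <- nrow(obs)
  if (n > 500) .stopf("bruteForceAlign is limited to 500 observations (got %d)", n)
  assign <- integer(n)
  cmz <- numeric(); crt <- numeric(); sizes <- integer()
  injSets <- list()
  ord <- order(-obs$intensity, obs$inj, obs$row)
  repeat {
    un <- which(assign == 0L)
    if (!length(un)) break
    # all feasible (observation, feature) pairs, globally nearest first
    best <- NULL; bestKey <- c(Inf, Inf, Inf)
    for (k in un) {
      if (!length(cmz)) break
      ok <- which(abs(cmz - obs$mz[k]) <= mzTol &
                    abs(crt - obs$rt[k]) <= rtTol)
      ok <- ok[!vapply(ok, function(f) obs$inj[k] %in% injSets[[f]], TRUE)]
      if (!length(ok)) next
      d <- sqrt(((obs$mz[k] - cmz[ok]) / mzTol)^2 +
                  ((obs$rt[k] - crt[ok]) / rtTol)^2)
      j <- which.min(d)
      key <- c(d[j], obs$inj[k], obs$row[k])
      if (d[j] < bestKey[1] - 1e-15 ||
          (abs(d[j] - bestKey[1]) <= 1e-15 &&
             (key[2] < bestKey[2] ||
                (key[2] == bestKey[2] && key[3] < bestKey[3])))) {
        best <- c(k, ok[j]); bestKey <- key
      }
    }
    if (is.null(best)) {
      s <- ord[match(TRUE, assign[ord] == 0L)]
      f <- length(cmz) + 1L
      assign[s] <- f
      cmz[f] <- obs$mz[s]; crt[f] <- obs$rt[s]
      sizes[f] <- 1L; injSets[[f]] <- obs$inj[s]
    } else {
      k <- best[1]; f <- best[2]
      assign[k] <- f
      cmz[f] <- (cmz[f] * sizes[f] + obs$mz[k]) / (sizes[f] + 1L)
      crt[f] <- (crt[f] * sizes[f] + obs$rt[k]) / (sizes[f] + 1L)
      sizes[f] <- sizes[f] + 1L
      injSets[[f]] <- c(injSets[[f]], obs$inj[k])
    }
  }
  .assembleMatrix(obs, assign, length(injections), g$ids, colData)
}
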