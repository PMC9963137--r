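# Annotation of model-relevant features against a metabolite reference
# table, genus-prevalence flags, and heatmap matrix export.
#
# Matching is by m/z (default tolerance 0.05 Da — the unit-level feature
# labels of LC-MS family studies imply coarse matching) with optional
# retention-time gating when both sides carry an RT. Identification
# confidence (MSI level) is metadata carried through from the reference
# table, never inferred here: level 1/2 assignment requires standards or
# MS/MS evidence outside this package's scope.

#' Read a metabolite reference table
#'
#' CSV with columns name, ref_mz, ref_rt (may be empty), msi_level
#' (1, 2 or "-" for unassigned) and source.
#'
#' @param path file path; default: the small illustrative table shipped
#'   with the package (metabolites discussed in snake-venom metabolomics:
#'   methionine, citric acid, tryptophan, pENW, deoxyribose
#'   5-monophosphate).
#' @return data.frame.
#' @export
readReferenceTable <- function(path = system.file("extdata",
                                                  "reference_metabolites.csv",
                                                  package = "metaboclass")) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "ref_mz", "ref_rt", "msi_level", "source")
  miss <- setdiff(need, names(df))
  if (length(miss)) .stopf("reference table missing column '%s'", miss[1])
  if (any(df$ref_mz < 100 | df$ref_mz > 1000))
    .stopf("reference m/z values must lie in [100, 1000] Da")
  df$msi_level <- as.character(df$msi_level)
  bad <- !df$msi_level %in% c("1", "2", "-")
  if (any(bad)) .stopf("msi_level must be one of 1, 2, '-'")
  df
}

#' Match features against a metabolite reference table
#'
#' Each feature is matched to all reference records within `mzTol` (and
#' within `rtTol` when both the feature and the record carry a retention
#' time and `rtTol` is given). Matches are ranked by |m/z error|; the best
#' match per feature is flagged, and equidistant records are tie-flagged.
#'
#' @param featureIds character feature identifiers.
#' @param mz,rt numeric consensus coordinates per feature (`rt` may be NULL).
#' @param reference data.frame as from [readReferenceTable()].
#' @param mzTol m/z tolerance, Da (> 0; default 0.05).
#' @param rtTol optional retention-time tolerance, minutes (NULL disables
#'   RT gating).
#' @return data.frame: feature_id, metabolite, ref_mz, mz_error, rt_error,
#'   msi_level, source, rank, best, tie.
#' @export
matchFeatures <- function(featureIds, mz, rt = NULL, reference,
                          mzTol = 0.05, rtTol = NULL) {
  stopifnot(mzTol > 0)
  empty <- data.frame(feature_id = character(), metabolite = character(),
                      ref_mz = numeric(), mz_error = numeric(),
                      rt_error = numeric(), msi_level = character(),
                      source = character(), rank = integer(),
                      best = logical(), tie = logical(),
                      stringsAsFactors = FALSE)
  if (nrow(reference) == 0) {
    .warnf("empty reference table: no annotations possible")
    return(empty)
  }
  rows <- list()
  for (i in seq_along(featureIds)) {
    dmz <- mz[i] - reference$ref_mz
    hit <- abs(dmz) <= mzTol
    if (!is.null(rtTol) && !is.null(rt)) {
      refRt <- suppressWarnings(as.numeric(reference$ref_rt))
      drt <- rt[i] - refRt
      hit <- hit & (is.na(refRt) | abs(drt) <= rtTol)
    }
    if (!any(hit)) next
    sub <- reference[hit, , drop = FALSE]
    err <- dmz[hit]
    o <- order(abs(err))
    refRtN <- suppressWarnings(as.numeric(sub$ref_rt))
    rows[[length(rows) + 1L]] <- data.frame(
      feature_id = featureIds[i], metabolite = sub$name[o],
      ref_mz = sub$ref_mz[o], mz_error = err[o],
      rt_error = if (is.null(rt)) NA_real_ else rt[i] - refRtN[o],
      msi_level = sub$msi_level[o], source = sub$source[o],
      rank = seq_along(o),
      best = abs(err[o]) <= min(abs(err)) + 1e-12,
      tie = sum(abs(abs(err) - min(abs(err))) <= 1e-12) > 1,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-genus feature prevalence
#'
#' Prevalence of a feature in a genus is the fraction of that genus's
#' venoms with a nonzero value; the flag marks prevalence strictly above
#' the threshold ("found in more than 50% of the genus's venoms").
#'
#' @param x venom-level [AlignedFeatureSet-class] with `genus` in
#'   `colData`, or a venoms x features matrix plus a `genus` vector.
#' @param genus character genus per venom (ignored for the
#'   AlignedFeatureSet method).
#' @param threshold strict prevalence threshold (default 0.5).
#' @return data.frame: feature_id, genus, prevalence, flagged.
#' @export
setGeneric("genusPrevalence", function(x, genus = NULL, threshold = 0.5)
  standardGeneric("genusPrevalence"))

#' @rdname genusPrevalence
#' @export
setMethod("genusPrevalence", "AlignedFeatureSet",
          function(x, genus, threshold) {
  cd <- colData(x)
  if (!"genus" %in% colnames(cd)) .stopf("colData has no 'genus' column")
  genusPrevalence(intensityMatrix(x), as.character(cd$genus), threshold)
})

#' @rdname genusPrevalence
#' @export
setMethod("genusPrevalence", "matrix", function(x, genus, threshold) {
  stopifnot(length(genus) == nrow(x))
  keepG <- names(which(table(genus) > 0))
  drop <- setdiff(unique(genus), keepG)
  if (length(drop)) .warnf("genus with 0 venoms excluded: %s",
                           paste(drop, collapse = ", "))
  rows <- list()
  for (g in sort(keepG)) {
    sub <- x[genus == g, , drop = FALSE]
    prev <- colMeans(sub > 0)
    rows[[g]] <- data.frame(feature_id = colnames(x), genus = g,
                            prevalence = unname(prev),
                            flagged = unname(prev > threshold),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
})

#' Heatmap matrix of autoscaled model-relevant features
#'
#' Rows ordered by family, then genus, then clade, then venom id, for
#' direct export to plotting tools.
#'
#' @param scaled autoscaled venoms x features matrix.
#' @param featureIds features to include (must exist).
#' @param metadata data.frame with venom_id, family, genus, clade covering
#'   the rows of `scaled`.
#' @return numeric matrix, reordered venoms x requested features.
#' @export
heatmapMatrix <- function(scaled, featureIds, metadata) {
  miss <- setdiff(featureIds, colnames(scaled))
  if (length(miss)) .stopf("unknown feature id '%s'", miss[1])
  md <- metadata[match(rownames(scaled), metadata$venom_id), ]
  o <- order(md$family, md$genus, md$clade, md$venom_id)
  scaled[o, featureIds, drop = FALSE]
}
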