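# Tabular and model serialization.
#
# CSV throughout for tables (comma separator, "." decimal, UTF-8); JSON for
# model bundles and ground truth. Matrix intensities are written with 6
# significant digits; model JSON keeps full double precision so that
# reloaded models reproduce predictions bit-for-bit.

.MODEL_SCHEMA_VERSION <- "1.0"

#' Read a per-injection LC-MS feature table
#'
#' The file must be a delimited text table whose header declares the
#' columns `mz`, `rt` and `intensity` (any column order; extra columns are
#' ignored). Row order is preserved.
#'
#' @param path file path.
#' @return data.frame with numeric columns mz, rt, intensity.
#' @export
readInjectionTable <- function(path) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  for (col in c("mz", "rt", "intensity"))
    if (!col %in% names(df))
      .stopf("malformed injection table '%s': missing column '%s'", path, col)
  df <- df[, c("mz", "rt", "intensity")]
  for (col in names(df)) {
    df[[col]] <- as.numeric(df[[col]])
    bad <- which(!is.finite(df[[col]]))
    if (length(bad))
      .stopf("injection table '%s': non-numeric %s at row %d", path, col, bad[1])
  }
  bad <- which(df$intensity < 0)
  if (length(bad))
    .stopf("injection table '%s': negative intensity at row %d", path, bad[1])
  bad <- which(df$mz <= 0)
  if (length(bad))
    .stopf("injection table '%s': non-positive mz at row %d", path, bad[1])
  bad <- which(df$rt < 0)
  if (length(bad))
    .stopf("injection table '%s': negative rt at row %d", path, bad[1])
  df
}

#' Write a per-injection feature table
#'
#' @param df data.frame with columns mz, rt, intensity.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeInjectionTable <- function(df, path) {
  out <- data.frame(mz = sprintf("%.6f", df$mz),
                    rt = sprintf("%.4f", df$rt),
                    intensity = sprintf("%.6g", df$intensity))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an aligned intensity matrix as CSV
#'
#' Layout: one row per sample, one column per consensus feature. The first
#' two data lines carry the consensus m/z and retention time of every
#' feature (>= 4 decimals); leading columns carry the sample annotation.
#' Absent features are stored as 0. Writing is deterministic: stable column
#' order and fixed float formatting (6 significant digits for intensities).
#'
#' @param x an [AlignedFeatureSet-class].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeAlignedMatrix <- function(x, path) {
  stopifnot(is(x, "AlignedFeatureSet"))
  cd <- as.data.frame(colData(x))
  metaCols <- names(cd)
  feats <- rownames(x)
  m <- t(assay(x, "intensity"))  # samples x features

  header <- c("sample_id", metaCols, feats)
  mzLine <- c("#consensus_mz", rep("", length(metaCols)),
              sprintf("%.6f", rowData(x)$mz))
  rtLine <- c("#consensus_rt", rep("", length(metaCols)),
              sprintf("%.4f", rowData(x)$rt))
  dataLines <- vapply(seq_len(nrow(m)), function(i) {
    meta <- vapply(metaCols, function(cn) {
      v <- cd[i, cn]
      if (is.na(v)) "" else as.character(v)
    }, character(1))
    paste(c(rownames(m)[i], meta, sprintf("%.6g", m[i, ])), collapse = ",")
  }, character(1))
  writeLines(c(paste(header, collapse = ","),
               paste(mzLine, collapse = ","),
               paste(rtLine, collapse = ","),
               dataLines), path)
  invisible(path)
}

#' Read an aligned intensity matrix written by [writeAlignedMatrix()]
#'
#' @param path file path.
#' @return an [AlignedFeatureSet-class].
#' @export
readAlignedMatrix <- function(path) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  lines <- readLines(path)
  if (length(lines) < 4) .stopf("aligned matrix '%s' is truncated", path)
  cells <- strsplit(lines, ",", fixed = TRUE)
  ncols <- length(cells[[1]])
  if (any(vapply(cells, length, 1L) != ncols))
    .stopf("aligned matrix '%s' has ragged rows", path)
  header <- cells[[1]]
  if (cells[[2]][1] != "#consensus_mz" || cells[[3]][1] != "#consensus_rt")
    .stopf("aligned matrix '%s': consensus m/z / RT header block missing", path)
  blankCells <- which(cells[[2]] == "")
  featStart <- if (length(blankCells)) max(blankCells) + 1L else 2L
  feats <- header[featStart:ncols]
  metaCols <- if (featStart > 2L) header[seq(2L, featStart - 1L)] else character()
  mz <- as.numeric(cells[[2]][featStart:ncols])
  rt <- as.numeric(cells[[3]][featStart:ncols])

  dataCells <- cells[-(1:3)]
  sampleIds <- vapply(dataCells, `[`, character(1), 1L)
  m <- t(vapply(dataCells, function(r)
    as.numeric(r[featStart:ncols]), numeric(length(feats))))
  if (length(feats) == 1L) m <- matrix(m, ncol = 1L)
  dimnames(m) <- list(sampleIds, feats)

  cd <- data.frame(row.names = sampleIds)
  for (j in seq_along(metaCols)) {
    v <- vapply(dataCells, `[`, character(1), j + 1L)
    cn <- metaCols[j]
    cd[[cn]] <- switch(cn,
      replicate = suppressWarnings(as.integer(v)),
      is_blank = as.logical(v),
      v)
  }
  AlignedFeatureSet(t(m), mz = mz, rt = rt, colData = cd)
}

# ---- model bundle serialization ----

#' Save a trained model bundle as JSON
#'
#' Serializes scaling parameters, PCA loadings, both classifiers, the chosen
#' Rep and PC count at full double precision, so that
#' `loadModelBundle(saveModelBundle(x))` reproduces predictions exactly.
#'
#' @param bundle a [VenomModelBundle-class].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
saveModelBundle <- function(bundle, path) {
  stopifnot(is(bundle, "VenomModelBundle"))
  svm <- bundle@svm
  obj <- list(
    schema_version = bundle@schemaVersion,
    feature_ids = bundle@featureIds,
    feature_mz = bundle@featureMz,
    feature_rt = bundle@featureRt,
    scaling = list(center = unname(bundle@scaling@center),
                   scale = unname(bundle@scaling@scale)),
    pca = list(loadings = unname(bundle@pca@loadings),
               explained_variance = bundle@pca@explainedVariance,
               n_components = bundle@pca@nComponents),
    centroid = list(classes = rownames(bundle@centroid@centroids),
                    centroids = unname(bundle@centroid@centroids),
                    bins = bundle@centroid@bins),
    svm = if (is.null(svm)) NULL else
      list(weights = svm@weights, bias = svm@bias,
           positive_class = svm@positiveClass,
           negative_class = svm@negativeClass),
    rep = bundle@rep,
    classifier = bundle@classifier,
    model_venoms = bundle@modelVenoms,
    validation1_venoms = bundle@validation1Venoms)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Load a model bundle saved by [saveModelBundle()]
#'
#' @param path file path.
#' @return a [VenomModelBundle-class].
#' @export
loadModelBundle <- function(path) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e)
                    .stopf("cannot parse model bundle '%s': %s", path,
                           conditionMessage(e)))
  if (is.null(obj$schema_version))
    .stopf("model bundle '%s': missing schema_version", path)
  if (!identical(obj$schema_version, .MODEL_SCHEMA_VERSION))
    .stopf("model bundle '%s': schema version '%s' not supported (expected '%s')",
           path, obj$schema_version, .MODEL_SCHEMA_VERSION)
  for (f in c("feature_ids", "scaling", "pca", "centroid", "rep"))
    if (is.null(obj[[f]]))
      .stopf("model bundle '%s': missing field '%s'", path, f)
  if (is.null(obj$pca$loadings))
    .stopf("model bundle '%s': missing PCA loadings", path)

  ids <- obj$feature_ids
  L <- as.matrix(obj$pca$loadings)
  rownames(L) <- ids
  colnames(L) <- sprintf("PC%d", seq_len(ncol(L)))
  pca <- new("PcaModel", loadings = L,
             explainedVariance = as.numeric(obj$pca$explained_variance),
             nComponents = as.integer(obj$pca$n_components))
  scaling <- new("ScalingParams",
                 center = setNames(as.numeric(obj$scaling$center), ids),
                 scale = setNames(as.numeric(obj$scaling$scale), ids))
  cen <- as.matrix(obj$centroid$centroids)
  rownames(cen) <- obj$centroid$classes
  centroid <- new("CentroidClassifier", centroids = cen,
                  bins = as.data.frame(obj$centroid$bins))
  svm <- NULL
  if (!is.null(obj$svm))
    svm <- new("SvmModel", weights = as.numeric(obj$svm$weights),
               bias = as.numeric(obj$svm$bias),
               positiveClass = obj$svm$positive_class,
               negativeClass = obj$svm$negative_class)
  new("VenomModelBundle",
      featureIds = ids, featureMz = as.numeric(obj$feature_mz),
      featureRt = as.numeric(obj$feature_rt), scaling = scaling, pca = pca,
      centroid = centroid, svm = svm, rep = as.integer(obj$rep),
      classifier = obj$classifier,
      modelVenoms = as.character(obj$model_venoms),
      validation1Venoms = as.character(obj$validation1_venoms),
      schemaVersion = obj$schema_version)
}
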