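# Blank filter, duplicate consensus, Rep prevalence filter, autoscaling.

injCd <- function(venoms, blanks = 0) {
  ids <- c(sprintf("BLK%02d", seq_len(blanks)),
           sprintf("%s_r%d", rep(venoms, each = 2), rep(1:2, length(venoms))))
  data.frame(
    venom_id = c(rep("", blanks), rep(venoms, each = 2)),
    family = "", genus = "", clade = "",
    replicate = c(rep(NA_integer_, blanks), rep(1:2, length(venoms))),
    subset = "", is_blank = c(rep(TRUE, blanks),
                              rep(FALSE, 2 * length(venoms))),
    row.names = ids)
}

test_that("the blank rule keeps cells at exactly the ratio boundary", {
  cd <- injCd("V1", blanks = 1)
  # rows: one feature; columns: blank, V1_r1, V1_r2
  x <- makeAlignedSet(matrix(c(100, 300, 299), nrow = 1), cd)
  y <- blankFilter(x, ratio = 3)
  expect_equal(as.vector(SummarizedExperiment::assay(y)), c(300, 0))
  expect_false(any(SummarizedExperiment::colData(y)$is_blank))
})

test_that("features absent from all blanks pass the blank filter untouched", {
  cd <- injCd("V1", blanks = 2)
  m <- rbind(c(0, 0, 250, 260),    # not in blanks: kept
             c(50, 80, 240, 241),  # max blank 80 -> threshold 240
             c(1000, 0, 500, 2999))
  x <- makeAlignedSet(m, cd)
  y <- blankFilter(x, ratio = 3)
  expect_equal(unname(SummarizedExperiment::assay(y)),
               rbind(c(250, 260), c(240, 241), c(0, 0)))
})

test_that("blank filtering is idempotent and demands blanks", {
  cd <- injCd(c("V1", "V2"), blanks = 1)
  set.seed(1)
  m <- matrix(round(runif(15, 0, 1000)), nrow = 3)
  x <- makeAlignedSet(m, cd)
  once <- blankFilter(x, ratio = 3, removeBlanks = FALSE)
  twice <- blankFilter(once, ratio = 3, removeBlanks = FALSE)
  expect_equal(SummarizedExperiment::assay(twice),
               SummarizedExperiment::assay(once))
  noBlank <- makeAlignedSet(m[, -1], injCd(c("V1", "V2")))
  expect_error(blankFilter(noBlank), "no blank injections")
})

test_that("duplicate consensus means duplicates and zeroes partial presence", {
  cd <- injCd(c("V1", "V2"))
  m <- rbind(c(1000, 2000, 500, 900),  # V1 both -> 1500, V2 both -> 700
             c(1000, 0, 0, 0))         # V1 one rep only -> 0
  x <- makeAlignedSet(m, cd)
  v <- duplicateConsensus(x)
  expect_equal(colnames(v), c("V1", "V2"))
  expect_equal(unname(SummarizedExperiment::assay(v)),
               rbind(c(1500, 700), c(0, 0)))
})

test_that("duplicate consensus names a venom with the wrong injection count", {
  cd <- injCd(c("V1", "V2"))[-1, ]
  x <- makeAlignedSet(matrix(1:3, nrow = 1), cd)
  expect_error(duplicateConsensus(x), "V1")
})

test_that("with duplicate-consistent data the venom matrix halves the rows", {
  panel <- buildDefaultPanel(4, 2, 2, seed = 5, nContaminants = 0)
  panel[, grep("^detect\\.", names(panel))] <- 1  # duplicate-consistent
  ds <- simulateDataset(defaultVenomRoster()[c(1, 10, 25, 48), ], panel,
                        zeroNoise(), nBlanks = 1, seed = 2)
  x <- alignFeatures(ds)
  v <- duplicateConsensus(blankFilter(x))
  expect_equal(ncol(v), 4)
  a <- SummarizedExperiment::assay(x)
  expect_equal(unname(SummarizedExperiment::assay(v)[, "D01"]),
               unname((a[, "D01_r1"] + a[, "D01_r2"]) / 2))
})

venomSet <- function(m, subset) {
  ids <- sprintf("V%02d", seq_len(ncol(m)))
  colnames(m) <- ids
  makeAlignedSet(m, data.frame(venom_id = ids, family = "", genus = "",
                               clade = "", subset = subset, row.names = ids))
}

test_that("the Rep filter applies its boundary on reference venoms only", {
  set.seed(2)
  m <- matrix(10^runif(5 * 25, 3, 5), nrow = 5)
  m[1, 1] <- 0      # feature 1 present in 19 of 20 model venoms
  m[2, 1:20] <- 0   # feature 2 present in 0 model venoms, all validation
  x <- venomSet(m, c(rep("model", 20), rep("validation1", 5)))
  expect_equal(nrow(repFilter(x, 1)), 4)   # any-presence keeps 4 of 5
  y <- repFilter(x, 19)
  expect_true("F0001" %in% rownames(y))
  expect_equal(nrow(repFilter(x, 20)), 3)  # 19 < 20: dropped at the boundary
  expect_error(repFilter(x, 21), "exceeds")
})

test_that("increasing Rep never increases the retained feature count, twice = once", {
  set.seed(3)
  m <- matrix(10^runif(8 * 12, 3, 5), nrow = 8)
  m[matrix(runif(length(m)) < 0.4, nrow(m))] <- 0
  x <- venomSet(m, rep("model", 12))
  counts <- vapply(1:12, function(r)
    tryCatch(nrow(repFilter(x, r)), error = function(e) 0L), 1L)
  expect_true(all(diff(counts) <= 0))
  y <- repFilter(x, 5)
  expect_equal(SummarizedExperiment::assay(repFilter(y, 5)),
               SummarizedExperiment::assay(y))
  expect_error(repFilter(x, 12), "smaller rep")
})

test_that("autoscaling centers and scales on the reference rows", {
  m2 <- rbind(c(1, 10), c(2, 20), c(3, 40))  # venoms x features
  dimnames(m2) <- list(c("a", "b", "c"), c("F0001", "F0002"))
  res <- autoscale(m2)
  expect_equal(unname(res$scaled[, 1]), c(-1, 0, 1))
  expect_equal(unname(colMeans(res$scaled)), c(0, 0), tolerance = 1e-10)
  expect_equal(unname(apply(res$scaled, 2, sd)), c(1, 1))
  expect_error(autoscale(m2, reference = "a"), "at least 2")
})

test_that("constant features are dropped with a warning", {
  m <- cbind(F0001 = c(1, 2, 3), F0002 = c(7, 7, 7))
  rownames(m) <- letters[1:3]
  expect_warning(res <- autoscale(m), "constant")
  expect_equal(names(res$params@center), "F0001")
})

test_that("frozen scaling reproduces training output and fixes column order", {
  set.seed(4)
  m <- matrix(rnorm(6 * 4, 100, 20), nrow = 6,
              dimnames = list(sprintf("V%d", 1:6), sprintf("F%04d", 1:4)))
  res <- autoscale(m, reference = rownames(m)[1:4])
  expect_equal(applyScaling(m[1:4, ], res$params), res$scaled[1:4, ])
  permuted <- m[, c(3, 1, 4, 2)]
  expect_equal(colnames(applyScaling(permuted, res$params)),
               sprintf("F%04d", 1:4))
  expect_equal(applyScaling(permuted, res$params), res$scaled)
  zero <- matrix(0, 1, 4, dimnames = list("z", colnames(m)))
  expect_equal(unname(applyScaling(zero, res$params)[1, ]),
               unname(-res$params@center / res$params@scale))
  expect_error(applyScaling(m[, 1:3], res$params), "F0004")
})

test_that("feature selection and scaling never peek at validation venoms", {
  set.seed(5)
  m <- matrix(10^runif(6 * 15, 3, 5), nrow = 6)
  m[matrix(runif(length(m)) < 0.3, nrow(m))] <- 0
  x <- venomSet(m, c(rep("model", 10), rep("validation1", 5)))
  xNoVal <- x[, 1:10]
  for (r in c(2, 5, 8)) {
    a <- tryCatch(repFilter(x, r), error = function(e) NULL)
    b <- tryCatch(repFilter(xNoVal, r), error = function(e) NULL)
    expect_equal(if (is.null(a)) NULL else rownames(a),
                 if (is.null(b)) NULL else rownames(b))
  }
  sa <- autoscale(x)$params
  sb <- autoscale(xNoVal)$params
  expect_equal(sa@center, sb@center)
  expect_equal(sa@scale, sb@scale)
})
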