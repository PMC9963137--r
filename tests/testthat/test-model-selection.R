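# Jackknife Rep optimization, PC-count selection, second-subset validation.

plantedSet <- function(seed, subset = NULL, nPer = 10, ...) {
  pl <- plantedVenomMatrix(seed, nPer = nPer, ...)
  if (is.null(subset)) subset <- rep("model", nrow(pl$M))
  ids <- rownames(pl$M)
  genus <- ifelse(pl$labels == "Elapidae",
                  rep(c("Naja", "Dendroaspis"), length.out = nrow(pl$M)),
                  rep(c("Crotalus", "Bothrops"), length.out = nrow(pl$M)))
  x <- makeAlignedSet(t(pl$M),
                      data.frame(venom_id = ids, family = pl$labels,
                                 genus = genus, clade = "", subset = subset,
                                 row.names = ids))
  list(x = x, pl = pl)
}

test_that("a jackknife iteration is correct on well-separated data and reproducible", {
  ps <- plantedSet(41)
  r1 <- jackknifeOnce(ps$x, rep = 3, nExtractPerClass = 3,
                      classifier = "centroid", seed = 5)
  expect_true(r1$allCorrect)
  expect_false(r1$infeasible)
  r2 <- jackknifeOnce(ps$x, rep = 3, nExtractPerClass = 3,
                      classifier = "svm", seed = 5)
  expect_true(r2$allCorrect)
  expect_identical(jackknifeOnce(ps$x, rep = 5, seed = 9),
                   jackknifeOnce(ps$x, rep = 5, seed = 9))
})

test_that("Rep optimization recovers the planted markers and breaks ties upward", {
  ps <- plantedSet(42, nPer = 10, k = 4, nShared = 6)
  jk <- optimizeRep(ps$x, nIterations = 20, nExtractPerClass = 2,
                    classifier = "centroid", seed = 7)
  s <- jk@summary
  perfect <- s$rep[!is.na(s$fraction_fully_correct) &
                     s$fraction_fully_correct == 1]
  expect_true(length(perfect) > 1)
  expect_equal(jk@chosenRep, max(perfect))  # tie-break toward larger Rep
  kept <- rownames(repFilter(ps$x, jk@chosenRep))
  expect_true(all(ps$pl$markers %in% kept))
  expect_lte(length(setdiff(kept, ps$pl$markers)), 2)
})

test_that("Rep values retaining zero in-iteration features never win", {
  ps <- plantedSet(43, nPer = 6)
  jk <- optimizeRep(ps$x, repGrid = c(3, 11), nIterations = 10,
                    nExtractPerClass = 2, classifier = "centroid", seed = 1)
  # rep 11 exceeds the 8-venom training subsets: every iteration fails
  s <- jk@summary
  expect_equal(s$fraction_fully_correct[s$rep == 11], 0)
  expect_equal(jk@chosenRep, 3L)
})

test_that("the PC-count rule reproduces its fixed points and fallback", {
  expect_identical(choosePcCount(7, 3:7), 4L)
  expect_identical(choosePcCount(20, 3:20), 10L)
  expect_identical(choosePcCount(10, 5), 5L)   # nearest valid fallback
  expect_identical(choosePcCount(8, c(2, 7)), 2L)  # nearest wins
  expect_identical(choosePcCount(8, c(2, 6)), 2L)  # equidistant: smaller
  expect_error(choosePcCount(5, integer()), "nonempty")
})

test_that("PC-count selection validates candidates on held-out venoms", {
  ps <- plantedSet(44, subset = c(rep("model", 16), rep("validation1", 4)),
                   nPer = 10)
  M <- intensityMatrix(ps$x)
  modelIds <- rownames(M)[1:16]; valIds <- rownames(M)[17:20]
  as <- autoscale(ps$x)
  pca <- fitPca(as$scaled[modelIds, ])
  sel <- selectNPcs(as$scaled[modelIds, ], ps$pl$labels[1:16],
                    applyScaling(M[valIds, ], as$params),
                    ps$pl$labels[17:20], pca, classifier = "centroid")
  expect_true(sel@chosenNPcs %in% sel@validPcs)
  expect_equal(sel@chosenNPcs,
               choosePcCount(nrow(pca@loadings), sel@validPcs))
  # flipped validation labels: no candidate can classify them perfectly
  flipped <- ifelse(ps$pl$labels[17:20] == "Elapidae",
                    "Viperidae", "Elapidae")
  expect_error(selectNPcs(as$scaled[modelIds, ], ps$pl$labels[1:16],
                          applyScaling(M[valIds, ], as$params),
                          flipped, pca, classifier = "centroid"),
               "no candidate PC count")
})

test_that("second-subset validation classifies held-out Viperidae and guards leakage", {
  ps <- plantedSet(45, subset = c(rep("model", 16),
                                  rep("validation2", 4)), nPer = 10)
  bundle <- fitModelBundle(ps$x, rep = 3, classifier = "svm")
  val <- validateSecondSubset(bundle, ps$x)
  expect_equal(val$accuracy, 100)
  expect_equal(nrow(val$report), 4)
  expect_true(all(c("accuracy", "genus") %in% names(val$perGenus)))

  # empty second subset
  psEmpty <- plantedSet(45, nPer = 10)
  expect_error(validateSecondSubset(bundle, psEmpty$x), "empty")

  # a model venom relabelled as validation2 must trip the leakage guard
  cdLeak <- SummarizedExperiment::colData(ps$x)
  cdLeak$subset[1] <- "validation2"
  xLeak <- ps$x; SummarizedExperiment::colData(xLeak) <- cdLeak
  expect_error(validateSecondSubset(bundle, xLeak), "leakage")
})

test_that("SVM infeasibility inside a jackknife iteration is tallied, not fatal", {
  # one-dimensional interleaved classes: never separable
  set.seed(8)
  M <- matrix(10^c(4.0, 4.2, 4.1, 4.3, 4.05, 4.25, 4.15, 4.35), ncol = 1,
              dimnames = list(sprintf("V%d", 1:8), "F0001"))
  M <- cbind(M, F0002 = 10^rnorm(8, 4, 0.01))
  labels <- rep(c("Elapidae", "Viperidae"), 4)
  jk <- optimizeRep(M, labels, repGrid = 2, nIterations = 10,
                    nExtractPerClass = 2, classifier = "svm", seed = 3)
  s <- jk@summary
  expect_true(s$infeasible_count > 0 || s$fraction_fully_correct < 1)
})

test_that("a larger family effect size never hurts jackknife robustness", {
  roster <- defaultVenomRoster()[c(1:3, 6:10, 21:28), ]  # 8 + 8 venoms
  roster$subset <- "model"
  frac <- vapply(c(0.2, 1.5), function(es) {
    panel <- buildDefaultPanel(10, 3, 3, seed = 5, effectSize = es)
    ds <- simulateDataset(roster, panel, noiseModel(), nBlanks = 1,
                          seed = 13)
    venoms <- duplicateConsensus(blankFilter(alignFeatures(ds)))
    jk <- optimizeRep(venoms, repGrid = 8, nIterations = 30,
                      nExtractPerClass = 3, classifier = "centroid",
                      seed = 17)
    jk@summary$fraction_fully_correct
  }, numeric(1))
  expect_gte(frac[2], frac[1])
  expect_gte(frac[2], 0.9)  # strong effect: nearly always fully correct
})
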