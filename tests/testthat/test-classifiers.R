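# Nearest-centroid proximity percentages and the hard-margin linear SVM.

test_that("centroids are the class means and ignore duplication", {
  s <- rbind(c(0, 0), c(2, 2), c(10, 0), c(12, 2))
  cc <- fitCentroidClassifier(s, c("Elapidae", "Elapidae",
                                   "Viperidae", "Viperidae"))
  expect_equal(cc@centroids["Elapidae", ], c(1, 1), ignore_attr = TRUE)
  expect_equal(cc@centroids["Viperidae", ], c(11, 1), ignore_attr = TRUE)

  one <- fitCentroidClassifier(rbind(c(1, 2), c(5, 6)), c("A", "B"))
  expect_equal(one@centroids["A", ], c(1, 2), ignore_attr = TRUE)

  dup <- fitCentroidClassifier(s[c(1, 2, 1, 2, 3, 4), ],
                               c("E", "E", "E", "E", "V", "V"))
  expect_equal(dup@centroids["E", ], c(1, 1), ignore_attr = TRUE)
  expect_error(fitCentroidClassifier(s, rep("A", 4)), "two classes")
})

test_that("class means are recovered on synthetic Gaussian scores", {
  set.seed(21)
  n <- 400
  sE <- matrix(rnorm(2 * n, mean = 0), ncol = 2)
  sV <- matrix(rnorm(2 * n, mean = 3), ncol = 2)
  cc <- fitCentroidClassifier(rbind(sE, sV),
                              rep(c("Elapidae", "Viperidae"), each = n))
  se <- 1 / sqrt(n)  # standard error of each coordinate mean
  expect_lt(max(abs(cc@centroids["Elapidae", ] - 0)), 4 * se)
  expect_lt(max(abs(cc@centroids["Viperidae", ] - 3)), 4 * se)
})

test_that("proximity percentages follow the complement-distance formula", {
  cc <- fitCentroidClassifier(rbind(0, 4), c("A", "B"))  # centers 0 and 4
  expect_equal(unname(centroidConfidence(cc, 2)[1, ]), c(50, 50))
  expect_equal(unname(centroidConfidence(cc, 0)[1, ]), c(100, 0))
  # d_A = 1, d_B = 3 -> class A confidence 75%
  expect_equal(unname(centroidConfidence(cc, 1)[1, ]), c(75, 25))
  expect_warning(conf <- centroidConfidence(
    fitCentroidClassifier(rbind(c(1, 1), c(1, 1)), c("A", "B")),
    c(1, 1)), "50/50")
  expect_equal(unname(conf[1, ]), c(50, 50))
})

test_that("percentages sum to 100 and the winner is the nearer centroid", {
  set.seed(22)
  cc <- fitCentroidClassifier(matrix(rnorm(8), 4), c("A", "A", "B", "B"))
  s <- matrix(rnorm(40), ncol = 2)
  conf <- centroidConfidence(cc, s)
  expect_equal(unname(rowSums(conf)), rep(100, 20), tolerance = 1e-9)
  dA <- sqrt(rowSums(sweep(s, 2, cc@centroids[1, ])^2))
  dB <- sqrt(rowSums(sweep(s, 2, cc@centroids[2, ])^2))
  nearer <- ifelse(dA <= dB, "A", "B")
  expect_equal(classifyWithBins(cc, s)$class, nearer)
})

test_that("confidence bins partition [50,100] with the stated boundaries", {
  cc <- fitCentroidClassifier(rbind(0, 100), c("A", "B"))
  # winning percentages 50, 90, 100 via points at 50, 10, 0
  got <- classifyWithBins(cc, matrix(c(50, 10, 0, 35), ncol = 1))
  expect_equal(got$bin, c("uncertain", "hard hit", "hard hit", "weak"))
  expect_equal(got$percentage, c(50, 90, 100, 65))
  badBins <- data.frame(label = letters[1:5], lower = c(50, 60, 70, 80, 85),
                        upper = c(60, 70, 80, 85, 99))
  expect_error(fitCentroidClassifier(rbind(0, 1), c("A", "B"),
                                     bins = badBins), "50, 100")
})

test_that("the symmetric 1-D instance gives the canonical hyperplane", {
  m <- fitHardMarginSvm(matrix(c(-1, 1), ncol = 1), c("Viperidae", "Elapidae"))
  expect_equal(m@weights, 1, tolerance = 1e-6)
  expect_equal(m@bias, 0, tolerance = 1e-6)
  expect_equal(m@positiveClass, "Elapidae")
})

test_that("training constraints hold and the margin matches the oracle", {
  for (seed in 1:8) {
    inst <- separableInstance2d(seed)
    labels <- ifelse(inst$y > 0, "Elapidae", "Viperidae")
    m <- fitHardMarginSvm(inst$X, labels)
    f <- as.numeric(inst$X %*% m@weights) + m@bias
    expect_true(all(inst$y * f >= 1 - 1e-6))
    oracle <- svmEnumerationOracle(inst$X, inst$y)
    expect_false(is.null(oracle))
    expect_equal(sqrt(sum(m@weights^2)), sqrt(oracle$ww), tolerance = 1e-6)
    expect_equal(m@weights, oracle$w, tolerance = 1e-4)
    expect_equal(m@bias, oracle$b, tolerance = 1e-4)
  }
})

test_that("inseparable data raises a hard-margin infeasibility error", {
  X <- matrix(c(0, 1, 0.1, 0.9), ncol = 1)
  expect_error(fitHardMarginSvm(X, c("A", "A", "B", "B")),
               "hard margin infeasible")
})

test_that("SVM predictions follow the sign rule with the documented tie-break", {
  inst <- separableInstance2d(3)
  labels <- ifelse(inst$y > 0, "Elapidae", "Viperidae")
  m <- fitHardMarginSvm(inst$X, labels)
  pred <- svmPredict(m, inst$X)
  expect_equal(pred$class, labels)
  expect_true(all(sign(pred$margin) == inst$y))
  # exact zero maps to the positive class with a warning
  mExact <- new("SvmModel", weights = c(1, 0), bias = -2,
                positiveClass = "Elapidae", negativeClass = "Viperidae")
  expect_warning(p0 <- svmPredict(mExact, matrix(c(2, 5), nrow = 1)),
                 "hyperplane")
  expect_equal(p0$class, "Elapidae")
  # with b = 0, flipping all scores flips all predictions
  m0 <- fitHardMarginSvm(matrix(c(-2, -1, 1, 2), ncol = 1),
                         c("V", "V", "E", "E"))
  expect_equal(m0@bias, 0, tolerance = 1e-9)
  s <- matrix(c(-3, 0.4, 2), ncol = 1)
  expect_equal(svmPredict(m0, -s)$margin, -svmPredict(m0, s)$margin,
               tolerance = 1e-9)
})

test_that("both classifiers ignore appended all-zero score dimensions", {
  inst <- separableInstance2d(5)
  labels <- ifelse(inst$y > 0, "Elapidae", "Viperidae")
  Xz <- cbind(inst$X, 0, 0)
  m1 <- fitHardMarginSvm(inst$X, labels)
  m2 <- fitHardMarginSvm(Xz, labels)
  expect_equal(svmPredict(m2, Xz)$margin, svmPredict(m1, inst$X)$margin,
               tolerance = 1e-6)
  c1 <- fitCentroidClassifier(inst$X, labels)
  c2 <- fitCentroidClassifier(Xz, labels)
  expect_equal(centroidConfidence(c2, Xz), centroidConfidence(c1, inst$X))
})
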