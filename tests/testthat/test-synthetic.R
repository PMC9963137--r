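# Synthetic dataset generator: panel construction, injection simulation,
# dataset assembly, reproducibility, ground truth.

test_that("panel size and composition follow the requested counts", {
  p <- buildDefaultPanel(0, 1, 1, seed = 1, nContaminants = 0)
  expect_equal(nrow(p), 3)  # 2 markers + internal standard
  expect_equal(sum(p$is_internal_standard), 1)
  expect_setequal(p$role, c("internal_standard", "elapid_marker",
                            "viperid_marker"))

  p2 <- buildDefaultPanel(5, 3, 3, seed = 7, nContaminants = 0)
  expect_equal(nrow(p2), 12)
  # brute-force pairwise separation check at the default tolerances
  for (i in seq_len(nrow(p2) - 1)) for (j in (i + 1):nrow(p2)) {
    sep <- abs(p2$true_mz[i] - p2$true_mz[j]) > 0.01 ||
      abs(p2$true_rt[i] - p2$true_rt[j]) > 0.5
    expect_true(sep, label = sprintf("entries %d/%d separated", i, j))
  }
})

test_that("marker effect size shifts family means and zero effect removes it", {
  p <- buildDefaultPanel(0, 2, 2, seed = 3, effectSize = 1.5,
                         nContaminants = 0)
  em <- p[p$role == "elapid_marker", ]
  expect_equal(em$mean_log10.Naja - em$mean_log10.Crotalus, rep(1.5, 2))
  expect_equal(em$mean_log10.Dendroaspis, em$mean_log10.Naja)

  p0 <- buildDefaultPanel(0, 2, 2, seed = 3, effectSize = 0,
                          nContaminants = 0)
  for (g in c("Naja", "Crotalus", "Bothrops"))
    expect_equal(p0[[paste0("mean_log10.", g)]],
                 p0$mean_log10.Dendroaspis)
})

test_that("noise-free injection with full detection reproduces the panel exactly", {
  p <- buildDefaultPanel(3, 2, 2, seed = 2, nContaminants = 0)
  p[, grep("^detect\\.", names(p))] <- 1  # force full detection
  venom <- list(genus = "Naja")
  tab <- simulateInjection(venom, p, zeroNoise(), seed = 5)
  expect_equal(nrow(tab), nrow(p))
  o <- match(attr(tab, "metabolite_id"), p$metabolite_id)
  expect_equal(tab$mz, p$true_mz[o])
  expect_equal(tab$rt, p$true_rt[o])
  expect_equal(tab$intensity, 10^p$mean_log10.Naja[o])
  # rows come out in elution order
  expect_equal(tab$rt, sort(tab$rt))
})

test_that("dropout removes everything except the spiked internal standard", {
  p <- buildDefaultPanel(3, 2, 2, seed = 2, nContaminants = 0)
  tab <- simulateInjection(list(genus = "Crotalus"), p,
                           noiseModel(dropoutProb = 1), seed = 1)
  expect_equal(attr(tab, "metabolite_id"), "internal_standard_d9caffeine")
})

test_that("injections are reproducible under a fixed seed", {
  p <- buildDefaultPanel(5, 2, 2, seed = 4)
  a <- simulateInjection(list(genus = "Naja"), p, noiseModel(), seed = 11)
  b <- simulateInjection(list(genus = "Naja"), p, noiseModel(), seed = 11)
  expect_identical(a, b)
})

test_that("blanks contain only blank-flagged contaminants", {
  p <- buildDefaultPanel(3, 2, 2, seed = 2, nContaminants = 2)
  tab <- simulateBlank(p, zeroNoise(), seed = 1)
  expect_equal(nrow(tab), 2)
  expect_true(all(grepl("blank_contaminant", attr(tab, "metabolite_id"))))
  expect_equal(tab$intensity, rep(1e4, 2))

  p0 <- buildDefaultPanel(2, 1, 1, seed = 2, nContaminants = 0)
  expect_equal(nrow(simulateBlank(p0, zeroNoise(), seed = 1)), 0)
})

test_that("the default roster mirrors the study inventory", {
  r <- defaultVenomRoster()
  expect_equal(nrow(r), 50)
  expect_equal(as.vector(table(r$genus)[c("Dendroaspis", "Naja",
                                          "Crotalus", "Bothrops")]),
               c(5, 15, 27, 3))
  expect_true(all(venomTaxonomy()[r$genus] == r$family))
  # second validation is Viperidae-only and contains all Bothrops
  v2 <- r[r$subset == "validation2", ]
  expect_true(all(v2$family == "Viperidae"))
  expect_true(all(r$venom_id[r$genus == "Bothrops"] %in% v2$venom_id))
  # Bothrops never enters the model subset
  expect_false(any(r$genus[r$subset == "model"] == "Bothrops"))
  # both families present in model and first validation subsets
  for (s in c("model", "validation1"))
    expect_setequal(unique(r$family[r$subset == s]),
                    c("Elapidae", "Viperidae"))
})

test_that("dataset assembly: duplicates, blanks, ground truth, determinism", {
  panel <- buildDefaultPanel(4, 2, 2, seed = 6)
  ds <- simulateDataset(defaultVenomRoster(), panel, noiseModel(),
                        nBlanks = 2, seed = 9)
  expect_equal(length(ds@injections), 102)  # 2 * 50 + 2
  md <- ds@metadata
  expect_equal(sum(md$is_blank), 2)
  expect_true(all(table(md$venom_id[!md$is_blank]) == 2))
  # ground truth covers every observation of every injection
  for (id in names(ds@injections))
    expect_equal(length(ds@groundTruth[[id]]), nrow(ds@injections[[id]]))
  expect_true(all(unlist(ds@groundTruth) %in% panel$metabolite_id))

  ds2 <- simulateDataset(defaultVenomRoster(), panel, noiseModel(),
                         nBlanks = 2, seed = 9)
  expect_identical(ds@injections, ds2@injections)

  d1 <- tempfile(); d2 <- tempfile()
  writeDataset(ds, d1); writeDataset(ds2, d2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_identical(f1, list.files(d2, recursive = TRUE))
  for (f in f1)
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
})

test_that("zero blanks is allowed but warned about", {
  panel <- buildDefaultPanel(2, 1, 1, seed = 1)
  specs <- defaultVenomRoster()[1:4, ]
  expect_warning(ds <- simulateDataset(specs, panel, noiseModel(),
                                       nBlanks = 0, seed = 1),
                 "blank")
  expect_equal(length(ds@injections), 8)
})
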