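# Synthetic LC-MS venom dataset generator.
#
# Emulates the structure of the venom study: 50 venoms (5 Dendroaspis,
# 15 Naja, 27 Crotalus, 3 Bothrops) injected in duplicate with interleaved
# water blanks; a metabolite panel with family-specific marker abundances,
# a ubiquitous spiked internal standard, retention-time jitter, m/z
# measurement error, log10-normal intensity noise and two-stage detection
# (group-level detection probability x global dropout) so that prevalence
# filtering has realistic structure to act on.

#' Genus-to-family taxonomy map
#'
#' @return named character vector mapping genus to snake family.
#' @export
venomTaxonomy <- function() {
  c(Dendroaspis = "Elapidae", Naja = "Elapidae",
    Crotalus = "Viperidae", Bothrops = "Viperidae")
}

#' Default 50-venom roster with subset assignment
#'
#' Mirrors the study inventory: 5 Dendroaspis, 15 Naja (5 African spitting,
#' 5 African non-spitting, 4 Asian non-spitting, 1 Asian spitting cobras),
#' 27 Crotalus and 3 Bothrops. Venoms are split into a model subset (38), a
#' first validation subset (6, both families) and a second validation subset
#' (6, Viperidae only, including all Bothrops — a genus absent from the
#' model subset).
#'
#' @return data.frame: venom_id, family, genus, clade, subset.
#' @export
defaultVenomRoster <- function() {
  tax <- venomTaxonomy()
  naja_clades <- c(rep("African spitting", 5), rep("African non-spitting", 5),
                   rep("Asian non-spitting", 4), "Asian spitting")
  roster <- rbind(
    data.frame(venom_id = sprintf("D%02d", 1:5), genus = "Dendroaspis",
               clade = "", stringsAsFactors = FALSE),
    data.frame(venom_id = sprintf("N%02d", 1:15), genus = "Naja",
               clade = naja_clades, stringsAsFactors = FALSE),
    data.frame(venom_id = sprintf("C%02d", 1:27), genus = "Crotalus",
               clade = "", stringsAsFactors = FALSE),
    data.frame(venom_id = sprintf("B%02d", 1:3), genus = "Bothrops",
               clade = "", stringsAsFactors = FALSE))
  roster$family <- unname(tax[roster$genus])
  roster$subset <- "model"
  roster$subset[roster$venom_id %in%
                  c("D05", "N05", "N10", "N15", "C23", "C24")] <- "validation1"
  roster$subset[roster$venom_id %in%
                  c("C25", "C26", "C27", "B01", "B02", "B03")] <- "validation2"
  roster[, c("venom_id", "family", "genus", "clade", "subset")]
}

# Fixed marker coordinates (accurate [M+H]+ masses of plausible venom
# metabolites; all elute before 20 min). Used for the first five markers of
# each family; extra markers beyond five are placed randomly.
.elapidMarkerMz <- c(150.0583, 152.0570, 175.1190, 385.2000, 971.2000)
.elapidMarkerRt <- c(2.10, 3.40, 1.60, 12.80, 18.90)
.viperidMarkerMz <- c(193.0343, 205.0972, 215.0315, 430.1721, 859.3000)
.viperidMarkerRt <- c(2.80, 6.20, 4.50, 9.70, 16.40)

#' Build the default synthetic metabolite panel
#'
#' The panel comprises: `nShared` background metabolites detected in ~60% of
#' injections of every genus at a family-independent abundance;
#' `nElapidMarkers` and `nViperidMarkers` marker metabolites detected in
#' every injection but `effectSize` log10 units more abundant in the
#' favoured family; one ubiquitous spiked internal standard (a deuterated
#' caffeine analogue) present in every venom injection; and
#' `nContaminants` background contaminants that also appear in water blanks
#' at a level high enough for the downstream blank filter to remove them.
#' All (m/z, RT) positions are pairwise separated by more than twice the
#' default alignment tolerances (rejection sampling; an error is raised
#' after 1000 failed placement attempts).
#'
#' @param nShared,nElapidMarkers,nViperidMarkers non-negative counts.
#' @param seed integer seed for random placement.
#' @param effectSize log10-unit abundance difference between families for
#'   marker metabolites (default 1.0).
#' @param nContaminants blank contaminants to include (default 2).
#' @param mzTol,rtTol separation tolerances, Da / minutes; placements keep
#'   all pairs more than `2 * tol` apart in at least one coordinate.
#' @return data.frame with one row per panel metabolite: metabolite_id,
#'   role, true_mz, true_rt, in_blank, blank_level, is_internal_standard,
#'   and per-genus columns `mean_log10.<genus>` and `detect.<genus>`.
#' @export
buildDefaultPanel <- function(nShared = 20, nElapidMarkers = 5,
                              nViperidMarkers = 5, seed = 1,
                              effectSize = 1.0, nContaminants = 2,
                              mzTol = 0.01, rtTol = 0.5) {
  stopifnot(nShared >= 0, nElapidMarkers >= 0, nViperidMarkers >= 0,
            nContaminants >= 0)
  set.seed(seed)
  tax <- venomTaxonomy()
  genera <- names(tax)

  rows <- list()
  mzs <- numeric(); rts <- numeric()
  addEntry <- function(id, role, mz, rt, means, detect, inBlank = FALSE,
                       blankLevel = 0, isIS = FALSE) {
    row <- data.frame(metabolite_id = id, role = role, true_mz = mz,
                      true_rt = rt, in_blank = inBlank,
                      blank_level = blankLevel, is_internal_standard = isIS,
                      stringsAsFactors = FALSE)
    for (g in genera) row[[paste0("mean_log10.", g)]] <- unname(means[g])
    for (g in genera) row[[paste0("detect.", g)]] <- unname(detect[g])
    rows[[length(rows) + 1L]] <<- row
    mzs <<- c(mzs, mz); rts <<- c(rts, rt)
  }
  separated <- function(mz, rt) {
    if (!length(mzs)) return(TRUE)
    all(abs(mzs - mz) > 2 * mzTol | abs(rts - rt) > 2 * rtTol)
  }
  place <- function(mzRange, rtRange) {
    for (i in 1:1000) {
      mz <- round(runif(1, mzRange[1], mzRange[2]), 4)
      rt <- round(runif(1, rtRange[1], rtRange[2]), 2)
      if (separated(mz, rt)) return(c(mz, rt))
    }
    .stopf("could not place a panel metabolite without (m/z, RT) collision after 1000 attempts")
  }

  # Internal standard: spiked into every venom injection, never in blanks
  # unless explicitly requested; equal abundance in every group.
  addEntry("internal_standard_d9caffeine", "internal_standard",
           204.1500, 7.50,
           setNames(rep(5.5, 4), genera), setNames(rep(1, 4), genera),
           isIS = TRUE)

  markerMeans <- function(favoured) {
    base <- 4.3
    m <- setNames(rep(base, 4), genera)
    m[tax[genera] == favoured] <- base + effectSize
    m
  }
  fullDetect <- setNames(rep(1, 4), genera)

  addMarkers <- function(n, favoured, fixedMz, fixedRt, prefix) {
    if (n == 0) return()
    for (i in seq_len(n)) {
      if (i <= length(fixedMz) && separated(fixedMz[i], fixedRt[i])) {
        mz <- fixedMz[i]; rt <- fixedRt[i]
      } else {
        pos <- place(c(100, 1000), c(0.5, 19.5))
        mz <- pos[1]; rt <- pos[2]
      }
      addEntry(sprintf("%s_%02d", prefix, i), paste0(prefix, ""), mz, rt,
               markerMeans(favoured), fullDetect)
    }
  }
  addMarkers(nElapidMarkers, "Elapidae", .elapidMarkerMz, .elapidMarkerRt,
             "elapid_marker")
  addMarkers(nViperidMarkers, "Viperidae", .viperidMarkerMz, .viperidMarkerRt,
             "viperid_marker")

  if (nShared > 0) {
    for (i in seq_len(nShared)) {
      pos <- place(c(100, 1000), c(0.5, 34))
      mean_i <- round(runif(1, 4.2, 5.2), 2)
      addEntry(sprintf("shared_%02d", i), "shared", pos[1], pos[2],
               setNames(rep(mean_i, 4), genera),
               setNames(rep(0.6, 4), genera))
    }
  }

  if (nContaminants > 0) {
    for (i in seq_len(nContaminants)) {
      pos <- place(c(100, 1000), c(0.5, 34))
      # present in venoms at < 3x the blank level, so the blank filter
      # removes it downstream
      addEntry(sprintf("blank_contaminant_%02d", i), "contaminant",
               pos[1], pos[2],
               setNames(rep(4.2, 4), genera), setNames(rep(0.9, 4), genera),
               inBlank = TRUE, blankLevel = 1e4)
    }
  }

  do.call(rbind, rows)
}

# rows of a simulated table are sorted by elution order, then m/z
.orderTable <- function(df, ids) {
  o <- order(df$rt, df$mz)
  out <- df[o, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "metabolite_id") <- ids[o]
  out
}

#' Simulate one venom injection
#'
#' Each panel metabolite is detected with probability
#' `detect.<genus> * (1 - dropoutProb)` (the internal standard bypasses
#' dropout: it is spiked, not endogenous). A detected metabolite emits one
#' observation at `true_mz + N(0, mzErrorSd)`, `true_rt + N(0, rtJitterSd)`
#' (truncated at 0) with intensity `10^(mean_log10.<genus> + N(0,
#' log10IntensitySd))`.
#'
#' @param venom one-row data.frame (or list) with at least `genus`.
#' @param panel metabolite panel from [buildDefaultPanel()].
#' @param noise a [NoiseModel-class].
#' @param seed integer seed.
#' @return data.frame with columns mz, rt, intensity, rows in elution order;
#'   attribute `"metabolite_id"` maps each row to its panel metabolite.
#' @export
simulateInjection <- function(venom, panel, noise = noiseModel(), seed = 1) {
  if (nrow(panel) == 0) .stopf("panel must be nonempty")
  genus <- as.character(venom$genus)
  mcol <- paste0("mean_log10.", genus)
  dcol <- paste0("detect.", genus)
  if (!all(c(mcol, dcol) %in% names(panel)))
    .stopf("panel has no abundance columns for genus '%s'", genus)
  set.seed(seed)
  p <- panel[[dcol]] * ifelse(panel$is_internal_standard, 1,
                              1 - noise@dropoutProb)
  detected <- runif(nrow(panel)) < p
  n <- sum(detected)
  if (n == 0) {
    out <- data.frame(mz = numeric(), rt = numeric(), intensity = numeric())
    attr(out, "metabolite_id") <- character()
    return(out)
  }
  sub <- panel[detected, , drop = FALSE]
  df <- data.frame(
    mz = sub$true_mz + rnorm(n, 0, noise@mzErrorSd),
    rt = pmax(0, sub$true_rt + rnorm(n, 0, noise@rtJitterSd)),
    intensity = 10^(sub[[mcol]] + rnorm(n, 0, noise@log10IntensitySd)))
  .orderTable(df, sub$metabolite_id)
}

#' Simulate one water-blank injection
#'
#' Only panel entries flagged `in_blank` emit observations, at their
#' `blank_level` with the same positional and intensity noise as venom
#' injections. The internal standard is excluded unless itself flagged.
#'
#' @inheritParams simulateInjection
#' @return data.frame as in [simulateInjection()].
#' @export
simulateBlank <- function(panel, noise = noiseModel(), seed = 1) {
  set.seed(seed)
  sub <- panel[panel$in_blank, , drop = FALSE]
  n <- nrow(sub)
  if (n == 0) {
    out <- data.frame(mz = numeric(), rt = numeric(), intensity = numeric())
    attr(out, "metabolite_id") <- character()
    return(out)
  }
  df <- data.frame(
    mz = sub$true_mz + rnorm(n, 0, noise@mzErrorSd),
    rt = pmax(0, sub$true_rt + rnorm(n, 0, noise@rtJitterSd)),
    intensity = 10^(log10(sub$blank_level) + rnorm(n, 0, noise@log10IntensitySd)))
  .orderTable(df, sub$metabolite_id)
}

#' Simulate a full venom LC-MS dataset
#'
#' Every venom is injected twice; `nBlanks` water blanks are interleaved
#' with the venom injections (one at the start of each of `nBlanks` evenly
#' sized batches, matching the practice of bracketing analytical batches
#' with blanks).
#'
#' @param specs venom roster data.frame (see [defaultVenomRoster()]).
#' @param panel metabolite panel (see [buildDefaultPanel()]).
#' @param noise a [NoiseModel-class].
#' @param nBlanks number of water blanks (default 2); 0 is allowed but
#'   raises a warning because the blank filter must then be disabled.
#' @param seed master integer seed; each injection draws from its own
#'   deterministic child stream.
#' @return a [SyntheticVenomData-class] object.
#' @export
simulateDataset <- function(specs = defaultVenomRoster(),
                            panel = buildDefaultPanel(),
                            noise = noiseModel(), nBlanks = 2, seed = 1) {
  if (nrow(specs) == 0) .stopf("specs must be nonempty")
  if (nBlanks == 0)
    .warnf("nBlanks = 0: no blank injections; disable the blank filter downstream")

  venomInj <- data.frame(
    venom_id = rep(specs$venom_id, each = 2),
    replicate = rep(1:2, nrow(specs)))
  venomInj$injection_id <- sprintf("%s_r%d", venomInj$venom_id,
                                   venomInj$replicate)
  # interleave blanks: one at the head of each of nBlanks even batches
  orderIds <- character()
  if (nBlanks > 0) {
    splits <- floor(seq(0, nrow(venomInj), length.out = nBlanks + 1L))
    for (b in seq_len(nBlanks)) {
      orderIds <- c(orderIds, sprintf("BLK%02d", b),
                    venomInj$injection_id[seq(splits[b] + 1L, splits[b + 1L])])
    }
  } else orderIds <- venomInj$injection_id

  injections <- list(); groundTruth <- list(); mdRows <- list()
  for (i in seq_along(orderIds)) {
    id <- orderIds[i]
    s <- .childSeed(seed, i)
    if (startsWith(id, "BLK")) {
      tab <- simulateBlank(panel, noise, seed = s)
      mdRows[[i]] <- data.frame(
        injection_id = id, venom_id = "", family = "", genus = "",
        clade = "", replicate = NA_integer_, subset = "", is_blank = TRUE,
        stringsAsFactors = FALSE)
    } else {
      vi <- venomInj[venomInj$injection_id == id, ]
      sp <- specs[specs$venom_id == vi$venom_id, ]
      tab <- simulateInjection(sp, panel, noise, seed = s)
      mdRows[[i]] <- data.frame(
        injection_id = id, venom_id = sp$venom_id, family = sp$family,
        genus = sp$genus, clade = sp$clade, replicate = vi$replicate,
        subset = sp$subset, is_blank = FALSE, stringsAsFactors = FALSE)
    }
    injections[[id]] <- tab
    groundTruth[[id]] <- attr(tab, "metabolite_id")
  }
  new("SyntheticVenomData", injections = injections,
      metadata = do.call(rbind, mdRows), groundTruth = groundTruth,
      panel = panel, noise = noise)
}

#' Write a synthetic dataset to disk
#'
#' Per-injection feature tables as CSV (`injections/<id>.csv`, columns mz,
#' rt, intensity), metadata as `metadata.csv`, ground truth as
#' `ground_truth.json`.
#'
#' @param x a [SyntheticVenomData-class].
#' @param dir output directory (created if missing).
#' @return invisibly, the directory path.
#' @export
writeDataset <- function(x, dir) {
  stopifnot(is(x, "SyntheticVenomData"))
  injDir <- file.path(dir, "injections")
  dir.create(injDir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(x@injections))
    writeInjectionTable(x@injections[[id]], file.path(injDir, paste0(id, ".csv")))
  write.csv(x@metadata, file.path(dir, "metadata.csv"), row.names = FALSE)
  jsonlite::write_json(x@groundTruth, file.path(dir, "ground_truth.json"))
  invisible(dir)
}
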