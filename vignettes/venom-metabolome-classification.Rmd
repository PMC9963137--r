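---
title: "Classifying snake venoms from their small-molecule metabolome"
author: "metaboclass"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying snake venoms from their small-molecule metabolome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metaboclass)
```

## The problem and the model

Snake venoms carry, besides their proteinaceous toxins, a rich complement
of small molecules (roughly 100–1000 Da): amino acids, organic acids,
nucleotide derivatives, short endogenous peptides. Their abundances differ
systematically between the two medically dominant families, Elapidae and
Viperidae, which makes the venom metabolome usable as a family classifier.
`metaboclass` implements that idea as a complete chemometric pipeline over
untargeted LC–MS feature tables — one table per injection, one row per
detected peak with its $m/z$, retention time and intensity.

The workflow is:

1. **Alignment.** Observations from all injections are grouped into
   consensus features whenever they agree within an $m/z$ tolerance
   *and* a retention-time tolerance, producing the *coherent matrix*
   $X \in \mathbb{R}^{\text{samples} \times \text{features}}$ with zeros
   for absent features.
2. **Pretreatment.** A venom cell survives only if it is at least three
   times the blank signal of the same feature; a feature counts for a
   venom only when present in both duplicate injections (the merged value
   is the arithmetic mean); a feature enters the model only when present
   in at least *Rep* venoms of the model subset; retained features are
   mean-centered and autoscaled (z-scored) on the model subset.
3. **PCA.** $X = U S V^{\top}$; the loadings $V$ are the right singular
   vectors, scores are $XV$. Validation samples are scaled with the
   frozen training parameters and multiplied by the same loadings.
4. **Classification.** Two decision rules operate in score space: a
   nearest-centroid rule reporting proximity percentages in five
   confidence bins, and a hard-margin linear SVM,
   $\min \lVert w\rVert^2$ s.t. $y_i(w \cdot s_i + b) \ge 1$.
5. **Model selection.** *Rep* is optimized by leave-group-out
   jackknifing (four venoms per family held out per iteration, the whole
   modelling chain refit each time); the retained PC count is selected
   against a held-out first validation subset; a second, fully held-out
   validation subset measures the final model.

The assumptions are those of any autoscaled-PCA classifier on presence/
intensity data: features are informative through relative intensity
differences, zero means "not detected" rather than "measured as zero",
and the two classes are (after projection) linearly separable — the
hard-margin SVM refuses to fit otherwise, by design.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `mzTol` | 0.01 | Da | QTOF-level mass accuracy; alignment gate |
| `rtTol` | 0.5 | min | tolerates slight retention drift between injections |
| `blankRatio` | 3 | — | venom signal must be ≥ 3× the blank signal |
| `rep` | jackknifed | venoms | prevalence threshold; counted over *venoms* of the model subset, not injections, because the duplicate-presence rule has already collapsed injections |
| `nIterations` | 1000 | — | jackknife iterations per Rep value |
| `nExtractPerClass` | 4 | venoms | held out per family per iteration |
| `bins` | 5 decade bins on [50, 100] | % | confidence categories, "hard hit" on top |
| `annotationMzTol` | 0.05 | Da | coarse m/z-only metabolite matching |

Two points deserve emphasis. First, the proximity percentage: dividing a
score's distance to a center by the sum of both distances and multiplying
by 100 gives the *farthest* center the *largest* number. Because the
decision rule is proximity-based, this package reports the complement —
$100\, d_{\text{other}}/(d_A+d_B)$ — so the highest percentage always
names the nearest center, the winning percentage lives in $[50, 100]$,
and the five bins partition exactly that range. Second, the PC-count
rule: among the candidate counts that classify the first validation
subset perfectly, the package picks half the retained-feature count
(rounded up), or the nearest validated value (ties toward the smaller).
Using as many components as features would be no reduction at all and
invites overfitting; half is the documented, reproducible compromise
(7 features → 4 PCs, 20 features → 10 PCs).

## The synthetic data generator

Venom LC–MS feature data of this design are rarely available in
machine-readable public depositions, so `simulateDataset()` generates
the raw material:
50 venoms (5 *Dendroaspis*, 15 *Naja*, 27 *Crotalus*, 3 *Bothrops*)
injected in duplicate with interleaved water blanks. The metabolite panel
(`buildDefaultPanel()`) plants:

* 10 **marker** metabolites (5 per family), detected in every injection
  but 1.0 log10 unit more abundant in their favoured family — the
  configurable effect size;
* 20 **shared** background metabolites, detected in ~60% of injections at
  family-independent abundance, which gives the prevalence filter real
  structure to act on;
* one ubiquitous spiked **internal standard** (a deuterated caffeine
  analogue) present in every venom injection and never used for
  normalization — it is monitored, not modelled;
* 2 **blank contaminants** present in water at levels the 3× blank rule
  removes.

Intensities are log10-normal (strictly positive, heavy-tailed, like MS
peak intensities); detection is two-stage (group-level detection
probability × a global 2% dropout); $m/z$ error is Gaussian with
σ = 0.002 Da and retention jitter Gaussian with σ = 0.1 min — a quarter
of the alignment tolerances, so alignment is solvable but not trivial.
Markers elute within the first 20 minutes, matching the observation that
the class-relevant chemistry elutes early. The subset split is this
package's own choice: model = 38 (4 *Dendroaspis*, 12 *Naja*,
22 *Crotalus*), first validation = 6 (both families), second
validation = 6 — Viperidae only, including all three *Bothrops*, so the
final validation probes a genus the model never saw.

What the generator does **not** emulate: chromatographic peak shapes,
isotopes and adducts, retention-time drift that is systematic rather than
random, ionization suppression near the dead volume, batch effects, and
real biological covariance between metabolites. Passing tests on this
generator therefore demonstrate that the *pipeline machinery* is correct
and recovers planted structure under realistic noise — not that real
venom data are this easy.

## Numerical choices

* PCA is fit by dense SVD, not NIPALS: exact and deterministic at these
  sizes. Sign convention: per component, the largest-|loading| entry is
  made positive.
* The SVM quadratic program is solved with an effectively infinite slack
  penalty, then the solution is rescaled exactly along its direction so
  the closest point of each class sits at functional margin 1; all
  training constraints are verified to $10^{-6}$ and any violation
  raises a "hard margin infeasible" error rather than silently softening
  the margin. An enumeration oracle over 2- and 3-point support sets
  cross-checks the hyperplane in the test suite.
* Alignment seeds consensus features greedily in descending intensity
  (deterministic and permutation-invariant), absorbs candidates
  nearest-first under tolerance-scaled Euclidean distance, at most one
  observation per injection per feature, recomputing the centroid after
  every absorption. Ties break by lower injection index, then lower row
  index. A global nearest-neighbour agglomeration oracle double-checks
  the grouping; instances with observations between half and one
  tolerance of two centroids are excluded from equivalence testing as
  documented near-boundary cases.
* Degenerate inputs are defined, not crashed on: a score equidistant
  from both centers at distance zero reports 50/50 with a warning; a
  score exactly on the SVM hyperplane maps to the positive class with a
  warning; constant features are dropped with a warning before
  autoscaling; a Rep value retaining zero features is skipped with a
  warning during optimization.
* Seed policy: one master seed spawns an independent multiplicative-hash
  stream per injection and per (Rep, iteration), so enlarging the Rep
  grid or adding injections never perturbs other draws, and every run is
  bit-reproducible.

## Design decisions where the design was open

* **Blank aggregation** is the maximum over blank injections
  (conservative); the duplicate-presence rule is evaluated *after* blank
  filtering, since both conditions apply jointly; the duplicate merge is
  the arithmetic mean (symmetric, scale-conserving).
* **Rep counts venoms**, post-consensus, not injections: thresholds in
  the mid-30s on a 50-venom cohort are inconsistent with any
  injection-pair reading.
* **Jackknife refits everything** (prevalence filter, scaling, PCA,
  classifier) inside each iteration, on the retained venoms only — the
  held-out venoms are projected onto refit loadings; anything less leaks
  the held-out samples into feature selection.
* **All PCs are used during Rep optimization**; the PC count is chosen
  afterwards against the first validation subset, preserving the
  two-stage order of the workflow.
* **Iteration count**: the default is 1000 per Rep value; smaller counts
  are configuration-reachable. The test suite and examples run at 100
  iterations, which this package treats as its standard desk-scale
  setting; the jackknife fraction at 100 iterations carries a binomial
  standard error of at most 0.05.
* **No intensity normalization** by the internal standard: single-analyte
  normalization of a chemically heterogeneous feature set is not
  defensible, so intensities enter the pipeline raw and autoscaling does
  the standardizing per feature.

## Limitations

The centroid rule's percentages are proximity shares, not calibrated
probabilities; the five bins are a reporting convention. Only two-class
problems are supported, with a linear kernel — both deliberate scope
choices. Annotation is m/z-first with optional RT gating and can only
carry the confidence level its reference table provides (MSI level 1/2
require standards or MS/MS evidence produced outside this package); the
shipped reference table is a small illustrative subset. Alignment does no
retention-time warping, so gross chromatographic drift must be handled
upstream.
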