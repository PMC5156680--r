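---
title: "Methods: structure networks, scan aggregation and NMR validation of conformational ensembles"
author: "psnscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structure networks, scan aggregation and NMR validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psnscan)
```

# Scope

`psnscan` analyses conformational ensembles of proteins — NMR ensembles or
frames sampled from molecular-dynamics trajectories — as residue
interaction networks, and surrounds that core with the bookkeeping a
mutational-landscape study needs: aggregation of saturation-mutagenesis
free-energy predictions, cross-validation of ensembles against NMR
observables, and light annotation of interaction networks with variant
and expression data. It does **not** run any of the upstream engines
(force-field simulations, empirical free-energy scans, shift predictors,
docking, RNA-seq normalisation); it consumes their tabular outputs, and it
ships synthetic generators that emulate all of those inputs with planted
ground truth so every stage is testable offline.

# The protein structure network model

Nodes are residues; glycine, having no side chain, is excluded outright.
For every frame the side-chain centre of mass (COM) of each residue is
computed as the mass-weighted mean of its side-chain atoms — everything
except backbone N, CA, C, O, OXT and backbone hydrogens. Two residues are
in contact in a frame when their COM distance is at or below a cutoff
(default 0.5 nm; the boundary is inclusive and configurable). An edge
enters the final network only if its contact *occurs* in at least a
fraction `pCrit` of the frames (default 0.20); the occurrence is stored as
the edge weight.

Choices worth stating explicitly:

* **Units.** Coordinates are converted to nm on load (PDB files are in
  angstrom); all cutoffs are in nm.
* **Hydrogens.** Side-chain COMs use heavy atoms only by default; an
  `includeHydrogens` flag adds them, since conventions differ between
  analysis suites and the choice is rarely reported.
* **Masses.** A single standard element-mass table is used, with
  per-atom-name overrides for force-field-specific mass definitions.
* **Hub rule.** The literature uses both "at least three edges" and
  "more than three edges" for hub residues; the two conventions genuinely
  conflict. `findHubs()` defaults to degree >= 3 and offers
  `strictlyGreater = TRUE`.
* **Path weights.** Shortest communication paths are minimal-*hop* paths
  (direct neighbours are at distance one); all ties are returned in
  lexicographic order, never silently broken. Each path is annotated with
  its edge occurrences on the percent scale plus their sum and average.
  Published path reports of this kind rarely define the weight unit; the
  percent-occurrence scale is this package's documented choice, and the
  identity `avg = sum / hops` is what the tests pin down.
* **Cutoff diagnostics.** `cutoffDiagnostic()` rebuilds the network over a
  cutoff grid and flags values at which the largest connected component
  swallows more than 80% (configurable) of the nodes — the signature of a
  cutoff too generous to be informative, which in practice appears just
  above 0.55 nm for compact domains.
* **Convergence.** `jackknifePsn()` drops 10% contiguous frame blocks at
  regular intervals (block boundaries rounded down), rebuilds the network
  per block, and reports edge-set Jaccard similarity, hub-set overlap and
  the five largest component sizes against the full-ensemble network.

# Saturation-scan aggregation and the empirical correction

A saturation scan evaluates all 19 substitutions at every position, for
every conformer of an ensemble and typically several independent runs.
`aggregateScan()` pools **all** records of a (site, substitution) cell —
runs within conformers are not averaged hierarchically first; for
balanced designs the two orders coincide and the flat pool is the
simpler, documented convention. A complete monomer scan over positions
35–128 therefore has 94 x 19 = 1786 cells, and a two-chain dimer scan
3572; incomplete scans fail loudly with the list of missing cells.

The empirical correction maps predicted stability changes onto the
experimental scale through the inverse of the published calibration
`predicted = -0.078 + 1.14 * experimental`, i.e. `corrected = m * ddg + b`
with `m = 1/1.14 = 0.877` and `b = 0.078/1.14 = 0.068` kcal/mol. (The
source literature prints the forward intercept 0.078 next to the derived
`b = 0.068`; the two are consistent — one is the other divided by 1.14 —
and the derived values are the defaults here.) The mutant unfolding free
energy is computed **exactly as the source writes it**,
`dGu = dGu_WT + m*ddg + b`, even though physical convention would subtract
a destabilising change; a `convention = "subtractive"` flag provides the
alternative and is never substituted silently. The wild-type reference
defaults to 5 kcal/mol, a typical unfolding free energy for small helical
domains.

Classification uses twice the ~0.8 kcal/mol typical prediction error of
empirical energy functions: mean changes strictly above 1.6 kcal/mol are
deleterious (exactly 1.6 is neutral; an `inclusive` flag flips the
boundary). `hotspotPositions()` reports positions where at least half
(configurable) of the 19 substitutions are deleterious.

# NMR cross-validation

**Chemical shifts.** Agreement between per-frame predicted shifts and
experiment is scored per atom-type group as

$$\chi^2 = \frac{1}{s-1} \sum_{j=1}^{s}
  \frac{\left(\tfrac{1}{n}\sum_{i=1}^n \delta_{i,j} -
  \delta_{exp,j}\right)^2}{\delta_{exp,j}}$$

with the frame mean taken first. The experimental shift appearing in both
the difference and the denominator is read per shift *j* — the only
reading under which the sum is well formed. A zero experimental shift is
rejected (undefined denominator); shifts are in ppm and positive for the
nuclei this statistic is used on, which keeps the statistic non-negative.
`runningChi2()` recomputes the statistic over cumulative frame windows;
a flattening curve indicates the predictions are stationary.

**NOEs.** Per-restraint distances are computed per frame and averaged
arithmetically by default — matching the plain "averaged over the frames"
procedure — with $\langle d^{-6}\rangle^{-1/6}$ averaging available for
users expecting the spectroscopic convention (by the power-mean
inequality the r-6 average never exceeds the linear one). The
experimental distance is treated as a target, not an upper bound, and
signed differences are reported so bound-style analysis remains possible
downstream. Categories follow the sequence-context rule: different
chains are intermolecular; more than four residues apart on the same
chain is long-range; the rest is short-range. Restraints are taken at
face value per atom pair — no pseudo-atom corrections or equivalent-proton
summation.

**RMSIP.** The root mean square inner product between the subspaces of
the first 20 (configurable) principal components of the C-alpha
fluctuation covariance matrices quantifies how similar two ensembles'
essential dynamics are. Frames are superposed onto the ensemble mean
structure before the covariance is formed (two fitting passes; the
alignment reference is rarely reported in the literature, and the
ensemble mean is this package's documented choice). RMSIP of an ensemble
with itself is exactly 1.

**Histidine tautomer.** The ring CD2 shift rule is exposed as a
standalone helper: below 122 ppm calls the N&epsilon;2-H tautomer,
at or above 122 ppm N&delta;1-H (strict boundary).

# Annotation utilities

Seven sequence-based variant-effect predictors are binarised by their
published cutoffs (Provean < -2.5, Mutation Assessor > 2, Polyphen2 and
PON-P2 > 0.5, SNAP2 < 0, MutPred > 0.75, Align-GVGD classes C45/C55/C65).
The SNAP2 rule is implemented exactly as published although the tool's
native convention is the opposite; the direction is configurable. Missing
scores shrink the consensus denominator rather than counting as neutral,
and a *complete consensus* means every available method calls the
mutation deleterious.

The docking filter retains complexes with energy strictly below
-2.39 kcal/mol. Expression annotation works on a
`PairedCountMatrix` (a `SummarizedExperiment` with tumor/normal condition
and patient pairing): node values are
`|median(log2(tumor+1)) - median(log2(normal+1))|` per gene, and edge
values are Pearson correlations — by default across patients of the
per-patient paired log2 changes, because the published network legends
describe correlating *changes* in expression; a `tumor_only` mode
correlates tumor samples directly, since which cohort the published edge
shading used is not fully specified. Zero-variance series give `NA` with
a warning, never a silent 0.

# The synthetic generators: what they emulate and what they do not

Every generator is a pure function of its arguments and a seed, and with
zero noise every downstream statistic hits its planted truth exactly.

* `makeDimerEnsemble()` builds two chains of minimal residues (backbone
  plus one CB pseudo-atom) on a 3 nm grid, 8 nm between chains, and
  realises each planted contact in exactly `round(p * nFrames)` frames
  chosen by a seeded permutation — deterministic persistence even for
  tiny ensembles, unlike i.i.d. frame draws. It exercises COM, contact,
  persistence and network logic; it does **not** attempt realistic
  geometry, rotamers or covalent connectivity, so passing tests say
  nothing about force-field realism — only about the network arithmetic.
* `makeDdgScan()` plants hotspot positions whose true means exceed the
  1.6 kcal/mol threshold by a margin for 90% (configurable) of
  substitutions, everything else staying below threshold minus margin,
  with Gaussian record noise (default sd 0.2 kcal/mol, the order of
  run-to-run scatter of empirical energy functions).
* `makeShiftData()` returns experiment = truth and predictions = truth
  plus frame noise, giving the chi-square statistic the closed-form
  expectation $(s/(s-1))\,\mathrm{mean}(\sigma^2/(n\,\delta))$ used in
  the test suite.
* `makeNoeSet()` samples unique atom pairs per category (exact requested
  counts, e.g. the 1018/2422/623 split used in the acceptance checks) and
  sets experimental distances to linear ensemble averages plus jitter.
* `makePairedCounts()` draws negative-binomial counts for paired
  tumor/normal samples. Per-patient log2 changes are
  `lfc + changeSd * (loading * z + sqrt(1-loading^2) * e)` with a shared
  patient factor `z`, so the planted change-correlation between two genes
  is the product of their loadings. Defaults — baseline 5000 counts,
  dispersion 0.002, changeSd 0.4 — describe deeply sequenced, moderately
  expressed genes whose biological variability lives in the change term;
  count noise then attenuates recovered correlations by only a few
  percent. Real cohorts have larger dispersion, batch structure and
  library-size variation, none of which is emulated: recovery results
  here certify the estimators, not robustness to real RNA-seq artefacts.

# Numerical and degenerate-input conventions

* Frame subsampling uses endpoint-anchored equal spacing,
  `round((i-1)(n-1)/(k-1)) + 1`, with `k = 1` returning the first frame.
* Distance and classification boundaries: contact `d <= cutoff`
  (inclusive), persistence `occurrence >= pCrit` (inclusive), deleterious
  `ddg > 1.6` (strict), docking `energy < -2.39` (strict), tautomer
  `shift < 122` (strict). Each is documented at its function and, where
  scientifically contested, configurable.
* Disconnected node pairs in path searches return a `connected = FALSE`
  result, not an error; empty contact sets, edgeless networks and empty
  edge lists are all legal values.
* Multi-model structure files must have identical atom composition across
  models; the first offending model is named. Unknown residue names are
  rejected at load.

# Problem sizes used in the shipped checks

The test and acceptance suites are sized to run comfortably on one CPU:
random-graph oracle comparisons use 1000 graphs of up to 12 nodes;
persistence recovery uses 500 frames; chi-square calibration uses 500
replicates of a 10-shift, 5-frame system; the paired-cohort recovery uses
3 genes x 100 patients; and the full-scale NOE bookkeeping builds a
4063-restraint set on a 3-frame, 80-residue toy dimer. These sizes were
chosen as the smallest at which the statistical claims (recovery within
±0.05 persistence, ±0.1 correlation, zero hotspot false positives) have
comfortable margins.

# Known limitations

* The network model is untyped: no salt-bridge/H-bond/interaction-energy
  edge classes, and no centrality measures beyond degree — hubs,
  components and minimal paths are the analysis vocabulary.
* Chi-square with negative experimental shifts is arithmetically allowed
  (only zero is rejected) but sign-mixed denominators would break the
  non-negativity of the statistic; the intended domain is positive-ppm
  backbone/side-chain shifts.
* `readFoldxDif()` trusts the caller's mutation ordering, because the
  difference files themselves do not record mutation identity.
* RMSIP requires at least as many frames as requested modes; with few
  frames the trailing eigenvectors are poorly determined and RMSIP values
  between *different* ensembles become noisy (self-overlap is always 1).
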