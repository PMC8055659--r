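---
title: "Methods: phenotyping, reproducibility and spatial statistics for mIF cell tables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phenotyping, reproducibility and spatial statistics for mIF cell tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mifspatial)
```

# The data model

Multiplex immunofluorescence (mIF) image analysis exports one row per
segmented cell: its position within a scanned region of interest (ROI) and
a 0/1 positivity call per marker. `mifspatial` standardises this as a
`cell_table`: columns `sample_id, roi_id, timepoint, cell_id, x_um, y_um`
followed by marker columns, with the ROI field dimensions attached as
attributes. Coordinates use the image convention — origin at the ROI's
top-left corner, y increasing downward, continuous microns — and the
default field is 931 × 698 µm (0.650 mm², the high-magnification scan field
of current multispectral scanners). Every segmented cell is nucleated, so a
frame's total row count is its DAPI+ count and serves as the percentage
denominator; no separate DAPI column is stored.

Because each marker is often scored in a separate analysis run over the
same segmentation, co-expression requires merging per-marker tables
cell-by-cell. `merge_marker_tables()` joins cells whose coordinates agree
exactly after rounding to 0.1 µm. The choice of an exact-match join (rather
than a nearest-neighbour tolerance match) reflects that the runs share one
segmentation: matching cells carry identical centroids up to export
rounding, and any two distinct cells closer than 0.1 µm would be a
segmentation artefact — the merge therefore fails loudly on such
collisions instead of guessing. Cells missing from any input are dropped,
but every drop is tallied per input in a merge report; nothing is discarded
silently.

# Phenotyping

A phenotype is a co-expression rule: a set of required-positive markers and
an optional set of required-negative markers (e.g. regulatory T cells,
`CD3+FOXP3+CD8-`). Membership is deliberately **non-exclusive**: the
published panel tables list overlapping rows (all T cells, cytotoxic
T cells, cytotoxic T cells expressing PD-1, ...), and only don't-care
semantics for unlisted markers reproduces that nesting. An exclusive
"best label" assignment was considered and rejected: it cannot express
`count(CD3+CD8+) ≤ count(CD3+)` style hierarchies. Negative requirements
are encoded only where a rule prints a minus.

Densities are counts over the ROI area in mm²; percentages are counts over
the frame's DAPI+ total (the area cancels, so percent is invariant to ROI
size — a property the tests check exactly). The five shipped panels encode
all 44 published phenotype rows; one table row prints `CD11b+CD66+`, which
we encode as `CD11b+CD66b+` since CD66 is not among the panel's markers.

# Two-timepoint reproducibility

Staining the same ROI locations on consecutive sections one week apart
yields paired measurements per (sample, ROI, phenotype). Three statistics
quantify agreement:

- **Two-point CV.** With only two replicates the CV uses the sample
  standard deviation (denominator n−1), giving
  `CV(a, b) = |a − b| / (√2 · mean(a, b))`. The upstream convention
  (ddof) is not fixed by common practice; we state ours explicitly. A pair
  of zeros has CV 0 by convention: an absent phenotype reproduced as
  absent is perfect agreement, not an indeterminate 0/0. The benchmark
  flag is a median CV above 0.5.
- **Within-sample Spearman ρ** between the week-1 and week-2 percent
  vectors over each sample's ROIs (average ranks for ties — percent ties
  at zero are common; two-sided p from the t approximation, since ties
  preclude the exact null distribution). Fewer than three pairs or a
  zero-variance vector is undefined (`NA` with a warning), not silently 0.
- **Across-sample Spearman ρ** per phenotype. Whether such correlations
  should pool per-ROI points or use sample-level summaries is genuinely
  open; we default to sample-level means (10 points, one per tumour),
  because pooling ROIs conflates within-sample heterogeneity with
  between-sample agreement. The pooled alternative is exposed via
  `across_mode = "pooled"`.

P-values are Bonferroni-adjusted with the family being the phenotypes of
one panel (the natural unit of simultaneous testing here); the family size
is recorded in the result object.

Phenotypes with zero counts in at least half of the (ROI, timepoint)
observations are excluded from the battery and listed: a rank correlation
over vectors that are mostly zeros measures tie-breaking noise, not assay
reproducibility. On the default synthetic cohort this rule removes the
same kind of rare checkpoint/MDSC phenotypes that are scarce in real
tissue.

# Spatial proximity

`nn_distances()` computes Euclidean nearest-neighbour distances from each
reference cell to the nearest target cell **within the same ROI** (scanned
fields are separate captures; no cross-ROI stitching). When reference and
target phenotypes overlap — e.g. CK+ versus CK+PD-L1+ — the same segmented
cell may appear on both sides, and its self-distance of zero is excluded:
the nearest *other* cell counts. The implementation is a block-wise
vectorised exhaustive search; the tests pin it exactly (tolerance zero) to
a plain O(n²) double loop on random instances, so any future acceleration
must preserve bit-level equality.

Per-pair summaries pool the per-cell distances across all ROIs and samples
and take the median (`pooling = "pooled"`). Pooling first matches the idea
of one cohort-level median per pair; the per-sample-median alternative
(`"per_sample"`) is available where samples should weigh equally regardless
of cell counts. The global close/far radius is the median of the per-pair
medians across panels, and the close call is boundary-inclusive
(`median ≤ radius`).

These are descriptive medians: no edge correction is applied, so distances
near the ROI boundary are right-censored and large medians are biased
slightly downward. For ranking phenotypes by proximity this affects all
pairs alike; it is documented rather than corrected.

# Mixed/unmixed pattern classification

The spatial architecture of a tumour is summarised by the cross-type
nearest-neighbour G function from malignant cells (CK+) to T cells (CD3+):
the empirical CDF `G_emp(r)` of the CK→CD3 NN distances, compared with the
theoretical curve under complete spatial randomness (CSR) of the target at
the observed intensity, `G_theo(r) = 1 − exp(−λπr²)` with
`λ = n_CD3 / area` pooled over the sample's ROIs.

The deviation score is defined as the signed trapezoid area between the
curves over the working radius range:

`score = ∫₀^200 (G_theo(r) − G_emp(r)) dr`  (µm).

The 200 µm upper limit matches the working radius used for proximity maps
at this field size; by `∫(1−G) = E[min(d, r_max)]`, the score is the
difference in (censored) mean NN distance between the observed pattern and
its CSR counterpart, which makes µm its natural unit. The sign convention
puts T-cell exclusion (empirical curve below Poisson) at positive scores.
Scores within ±10 µm are labelled **mixed**, above +10 **unmixed** (band
boundary inclusive to mixed, since unmixed is defined as *more than* +10);
scores below −10 — target cells markedly closer than random, outside the
published two-label scheme — receive the flagged extension label
`aggregated`. The numeric score behind the published ±10 band is not
defined anywhere we could follow; this integral is our declared
reconstruction, chosen so that (i) it is zero in expectation under CSR
(verified by simulation: the mean score over 100 CSR replicates is within
±1 µm of 0), and (ii) its magnitude is interpretable in microns.

An optional border correction (discarding reference cells within `r_max`
of the boundary) is provided for the empirical CDF; it is off by default
because at `r_max = 200` µm it discards most of a 931 × 698 µm field, and
the classification contrasts curves at short range where censoring is
mild.

# The synthetic tissue generator

The generator exists so that every downstream stage has a testable input
with known ground truth. It emulates, per ROI:

- **Malignant nests**: a Matérn cluster process — Poisson(8) nest centres
  per ROI, uniform on the field inset by the nest radius (120 µm, so nests
  lie wholly inside and offspring counts are not boundary-censored), each
  with Poisson(250) malignant cells uniform in its disc. Expected CK+
  density at defaults: 8 × 250 × 0.97 / 0.65 mm² ≈ 2,990 cells/mm², the
  order of magnitude of published malignant-cell medians. The
  uniform-in-disc choice is the simplest process producing the cohesive
  nest morphology that defines the unmixed pattern.
- **Immune cells**: Poisson(400) T cells and Poisson(75) macrophages; each
  is placed inside a random nest with probability `mixing` (uniform in the
  disc) and otherwise uniformly in the stromal complement (rejection
  sampling). `mixing` is the single dial between the unmixed (0) and fully
  infiltrated (1) architectures; the default 0.5 is an intermediate,
  realistic degree of infiltration.
- **Other nucleated cells**: Poisson(600) uniform background (stroma),
  completing the DAPI+ denominator at ≈ 4,700 cells/mm².
- **Markers**: conditionally independent Bernoulli draws given the cell's
  class, with per-panel probabilities calibrated so the *rank order* of
  phenotype abundances matches the published cohort (memory T cells the
  most abundant subset, CD3+TIM3+ rare, etc.). Exact published medians are
  10-patient cohort values and are not reproduction targets. One published
  inconsistency is deliberately not copied: a subset row denser than its
  superset is impossible under nested co-expression rules.
- **Between-sample heterogeneity**: per-sample, per-class log-normal
  abundance multipliers with log-sd 0.5 (mean 1), shared between
  timepoints — this is what gives samples stable ranks for the
  across-sample correlation.
- **Week-2 replicate**: each week-1 cell retained with probability
  q = 0.9, retained cells keep their marker calls and get 2 µm isotropic
  Gaussian positional jitter (clamped to the field); Poisson(0.1 · n) new
  cells per class appear from the same spatial model. No noise model for
  consecutive-section replicates is established anywhere we could adopt
  one from; thinning + jitter + additions is our assumption, and all four
  parameters are config-exposed.

Seeding: one master seed; each (panel, sample, ROI, timepoint) unit draws
its own sub-stream seed through a Lehmer-style modular hash of the indices
(`derive_seed()`), so any single ROI can be regenerated in isolation — a
property the tests exercise.

What the generator does **not** emulate: staining intensity and its
thresholds (positivity is already binary), segmentation errors (split or
merged cells), spatially varying marker expression within a class,
anisotropic tissue structures (vessels, stromal bands), or correlated
marker noise between consecutive sections. Passing tests therefore show
that the statistics behave correctly on point patterns with this
structure — not that any particular tissue will meet the reproducibility
benchmarks.

# Numerical choices and degenerate inputs

- Coordinates are stored at 1e-6 µm resolution, so the CSV writer
  (6 decimals) round-trips exactly; the merge join rounds to 0.1 µm.
- `empirical_G` is the right-continuous ECDF via `stats::ecdf`; the score
  uses the trapezoid rule on the 1 µm grid (for the smooth Poisson curve
  the grid error is far below the ±10 µm band).
- Zero-count conventions: CV(0, 0) = 0; a frame with zero total cells gets
  `NA` percents and a warning; a proximity pair with no co-occurring cells
  is a logged `NA` entry; a sample without key-marker cells gets no
  pattern call rather than a fabricated score.
- Degenerate Spearman inputs (length < 3, zero variance) return `NA` with
  a warning and are dropped from medians.
- A ROI that happens to draw zero nests places all immune cells in stroma
  (there is nothing to infiltrate); at the default Poisson(8) nest rate
  this affects ~0.03% of ROIs.

# Problem sizes

The shipped tests and the cohort summary script use the full default
design — 10 samples × 5 ROIs × 2 timepoints × 5 panels, ≈ 3,100 cells per
ROI — for the reproducibility battery (about ten seconds of compute), CSR
checks at 2,000 target points with 100 replicates for the G-function
calibration, and n ≤ 200 instances for the exact brute-force equality of
the nearest-neighbour search. These sizes give stable cohort-level medians
while keeping the whole suite interactive.

# Known limitations

- NN medians and G curves carry finite-window censoring (documented above).
- The ±10 µm band is a reconstruction; scores near the boundary should be
  read as borderline regardless of label.
- The reproducibility benchmarks (CV 0.5, ρ 0.5/0.7) are conventions
  adopted from practice for this assay class, not derived thresholds.
- The generator's marker draws are independent given class; real
  co-expression has within-class correlation structure the tests do not
  probe.
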