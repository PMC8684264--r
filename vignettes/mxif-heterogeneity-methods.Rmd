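---
title: "Methods: single-cell heterogeneity analysis of MxIF breast-cancer TMAs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-cell heterogeneity analysis of MxIF breast-cancer TMAs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The analysis problem

Multiplexed immunofluorescence (MxIF) images a single FFPE tissue section
through repeated cycles of antibody staining, imaging and fluorophore
bleaching, yielding per-cell signal for many protein markers on the same
cells. After upstream registration and segmentation (out of scope here),
the data reduce to a table with one row per segmented cell: centroid
coordinates, morphology (perimeter, cell area, nuclear area, in pixels;
pixel size 0.293 µm by default) and raw marker signal extracted from each
marker's subcellular compartment — ER, PR, Ki67, P21 and P16 nuclear, HER2
and pan-cytokeratin (PCK) membranous, P53 nuclear+cytosol, CD8 and CD20
whole-cell.

`mxifhet` takes such a table for a breast-cancer tissue microarray (TMA) —
here 1.1 mm cores, two cores per specimen ("paired cores") — together with
each core's clinical IHC scores, and quantifies *intra-tumoral
heterogeneity*: how variable the single-cell marker co-expression
signatures and their spatial arrangement are within cores that carry the
same clinical subtype label.

## Normalization and IHC-calibrated thresholds

Each marker is min–max normalized to the 0–15 scale,
$x' = 15\,(x - \min x)/(\max x - \min x)$, independently per marker.
The min/max are fitted over **all QC-passing segmented cells of the whole
dataset**, before cancer gating. The immune thresholds apply to all cells
(cancer and stroma), so normalization cannot be fitted on the cancer
population only; fitting globally keeps one scale for both analyses.
Per-core normalization is available (`per_core = TRUE`) but off by
default, and no percentile clipping is applied. The fitted ranges are
recorded in the returned `norm_spec` attribute; re-normalizing an already
normalized table is refused unless forced, since a second fit would not be
idempotent.

Positivity cut-points on the normalized scale were calibrated upstream
against clinical IHC scoring of the same cores and enter this package as
constants (`marker_thresholds()`): ER 0.4 (separating negative/weak from
moderate/strong, "ER-high"), PR 1.6, HER2 5.0, Ki67 0.2, P53 0, P16 2,
P21 1, CD8 and CD20 0.2. All comparisons are **strict** (`>`): the only
comparator stated for the calibration is "greater than zero" for P53, and
one convention is applied everywhere else; a cell sitting exactly at a
cut-point is negative. The PCK cancer gate is the one deliberate
exception, inclusive at raw signal ≥ 1500, as specified for the gating
step.

## EPH groups and the sixteen-class scheme

Thresholded ER ("ER-high"), PR and HER2 define eight co-expression groups
(EPH groups):

| group | ER | PR | HER2 |
|---|---|---|---|
| 1 | w/neg | − | − |
| 2 | w/neg | − | + |
| 3 | w/neg | + | − |
| 4 | w/neg | + | + |
| 5 | m/s | − | − |
| 6 | m/s | − | + |
| 7 | m/s | + | − |
| 8 | m/s | + | + |

Crossing with Ki67 yields sixteen classes in a fixed group-major order,
`class = 2(group − 1) + 1 + [Ki67+]` — the Ki67− class of a group
immediately precedes its Ki67+ class. The ordering is a package
convention (the shaded-bar sub-labelling of the original figure is not
fully recoverable); it is documented because the paired-core test consumes
these indices as scores.

Core-level subtypes follow the St. Gallen surrogate rules applied to the
clinical IHC scores (`assign_surrogate_subtype()`): HER2+ means IHC 3+ or
FISH-amplified 2+ (an unresolved 2+ is an error, never a guess); ER/PR
receptor positivity is ≥ 1% positive cells; among ER+/HER2− cores, Luminal
A-like requires Ki67 below 20% *and* PR at or above 20%, else Luminal
B-like. The consensus leaves the exact Ki67/PR cuts to the laboratory, so
both are configurable (`subtype_rules()`); changing them relabels
borderline luminal cores and therefore shifts which pairs enter each
subtype tally. ER−/PR+ score combinations fall outside the rule table and
raise an error rather than being silently binned.

## Cancer-population gating

Gates run in a fixed order so reject reasons are unambiguous: upstream QC
flag → size gate → region/PCK gate. The size gate keeps cells with
perimeter > 90 px, cell area > 400 px², nuclear area > 10 px² (strict, as
calibrated for distinguishing the larger cancer epithelium). Luminal and
HER2+ cores then keep PCK ≥ 1500 cells outside any benign-duct
(`exclude_benign`) annotation; TNBC cores — whose cells express PCK too
weakly to threshold — instead keep cells inside manually annotated
`include_tumor` regions. Annotations are GeoJSON polygons in pixel
coordinates (y down); each feature carries a `label` and a `core_id`
property. Cells are assigned to regions by centroid only, and points on a
polygon boundary count as inside (deterministic and conservative for
inclusion regions). A TNBC core without tumor annotations is a
configuration error naming the core.

## Spatial neighborhoods and diversity

Neighbors of a cell are all other cells within a Euclidean radius of its
centroid — 30 µm (100 px) and 100 µm (341 px) by default. The comparison
is inclusive (≤ r): the printed radius/pixel equivalences are themselves
rounded, so boundary semantics cannot matter at data scale, and
inclusivity is the common convention. The central cell is never its own
neighbor. The implementation bins cells into a grid of bucket width r and
sweeps 3×3 buckets; it is exact, and the test suite holds it equal to the
quadratic all-pairs scan on randomized cores. No edge correction is
applied at core boundaries.

Neighborhood heterogeneity is the Shannon equitability
$E_H = H / \ln S$ with $H = -\sum_i p_i \ln p_i$ over the neighbor-class
proportions. $S$ defaults to the number of classes present in the core
(`present_in_core`), which makes $E_H$ comparable across central classes
within a core; classes present in the neighborhood itself, or the fixed
8/16-class panel, are selectable alternatives. Conventions for degenerate
input: a neighborhood with no cells has an *undefined* (NA) index and is
excluded from aggregation (with `n` reported); $E_H := 0$ when $S = 1$ (a
one-species scope has no diversity to normalize); all-zero count vectors
are an error. Whether the original figures used the 8-group or 16-class
scheme is not stated; the 8-group scheme is the default
(`class_scheme = "EPH8"`).

Immune analysis runs on **all** QC-passing segmented cells with no size or
PCK gating: CD8/CD20 positivity at 0.2 gives per-core densities as percent
of all cells, and the 100 µm neighborhoods of each immune cell are
summarized under a three-class scheme (cancer / CD8 / CD20, every
non-immune cell counted as cancer).

## Paired-core heterogeneity statistics

Each core is represented as the vector of its cancer cells' class indices
1–16, and the two cores of a case are compared with (i) a two-sample
Wilcoxon rank-sum test and (ii) a permutation test on the absolute
difference of mean class index, declaring heterogeneity when **both**
p-values fall below α = 0.01. Treating a nominal class index as an ordinal
score is a deliberate reproduction of the original design and is sensitive
mainly to composition shifts that move rank mass; a Pearson chi-squared
alternative on the 2×16 contingency table is provided
(`compare_paired_cores_chisq()`) for nominal-scale sensitivity, but is not
the default. No multiple-testing correction is applied across cases (fixed
per-test α).

Numerical choices: the Wilcoxon test uses the normal approximation with
tie correction (class vectors are massively tied), switching to exact
enumeration only below a combined n of 50 without ties; the permutation
test uses 10,000 label shuffles by default with the add-one estimator
$p = (1 + \#\{T^\ast \ge T\})/(1 + n_{perm})$, is seeded and bit-for-bit
reproducible, and permutes the *sorted* pooled vector so the p-value
depends only on the pooled multiset and the group sizes (exact label-swap
exchangeability for equal sizes). A pooled-constant pair returns p = 1
for both tests. Across-subtype comparisons of per-core class fractions,
and across-central-class comparisons of per-cell equitability, use
one-way ANOVA with Tukey's HSD.

## The synthetic TMA generator

No raw single-cell data ship with the package; `generate_core()` /
`tma_scenario()` create datasets with the statistical and spatial
structure the analysis assumes, with a ground-truth manifest kept
*outside* the cell table so tests cannot leak labels through the pipeline.

* **Composition.** A core draws its cancer / CD8 / CD20 / stroma split
  multinomially from configured fractions (default 3% CD8, 2% CD20, 20%
  stroma), and cancer classes multinomially from a 16-class vector.
  Default compositions per subtype mirror the qualitative study findings
  (Luminal A dominated by PR+ groups 7/3 plus 5; Luminal B by PR− groups
  1/5; HER2+ by groups 1/2; TNBC by group 1; Ki67+ rates rising from 8%
  to 50% across that order).
* **Geometry.** Cells live on a 1.1 mm disc (pixel size 0.293 µm),
  uniformly or from a Thomas cluster process (Poisson parents uniform on
  the disc, Gaussian offspring, rejection-clipped); with
  `cluster_by_class` the clusters are class-pure, emulating cells that
  form spatial clusters within their own group. Immune cells are
  scattered or aggregated.
* **Intensities.** Signals are drawn on the normalized-target scale —
  planted negatives from a scaled Beta below the marker's cut-point,
  positives from cut-point + Gamma, both with a 5% guard margin — then
  mapped linearly to raw units (250 raw units per normalized unit by
  default; only the ordering relative to the cut-points matters to the
  pipeline, the distribution shapes being known only graphically).
  Each core also contains two tiny QC-passing *artifact* cells, one blank
  and one saturated on every marker, emulating the debris and hot pixels
  ubiquitous in fluorescence imaging. They pin each marker's dataset
  min/max, so global min–max normalization reproduces the intended
  normalized values exactly and the planted positivity is recovered with
  zero leak (the default; a nonzero `leak_rate` plants controlled
  classification error). P53 intensity has a high mode for IHC-OE cores
  and a low 0–1 mode for the occasional positive cells of IHC-normal
  cores; per-core P53/P16 positivity rates depend on the generated IHC
  status.
* **Nuisance structure.** Luminal/HER2+ cores carry a benign-duct
  exclusion region populated with PCK-high benign epithelium (2% extra
  cells); TNBC cores carry a tumor-inclusion region containing all their
  cancer cells; 2% extra QC-failing cells are appended. Morphology is
  drawn so cancer-sized populations clear the size gate strictly and
  stroma/immune/artifact cells fail it.
* **Study design.** `tma_scenario("default")` builds the paired-core
  design at the study's paired-case mix (10 LumA, 15 LumB, 2 LumB-HER2+,
  4 HER2+, 10 TNBC cases, two cores each): a fixed per-subtype share of
  cases (6/10, 9/15, 1/2, 4/4, 2/10) receives a planted 30% composition
  shift between its cores, one LumA case is discordant (second core built
  from a LumB spec), HER2+ cores are immune-rich (8%/6%), and luminal
  cores use class-pure clustering. `"null_pairs"` removes all planted
  shifts; `"clustered"` makes every core a Thomas process.

What the generator does *not* emulate: staining-round bleaching artifacts
and batch effects, segmentation errors (each row is an honest cell),
continuous biological intensity gradients (class-conditional draws are
i.i.d.), irregular tissue shapes, and correlated marker noise. Passing the
validation suite therefore demonstrates the *pipeline's* correctness under
controlled conditions, not robustness to every failure mode of real
imaging data.

## Validation problem sizes

The package validates itself at desk scale, chosen to exercise each
property well inside routine test budgets: neighbor-search equivalence on
100 randomized cores of up to 1,000 cells at both radii; equitability
bounds and scale invariance on 10,000 random count vectors; paired-test
calibration on 1,000 simulated null pairs (500 cells/core, 2,000
permutations, observed significant fraction required ≤ 0.02 at α = 0.01)
and power ≥ 0.9 against the planted 30% shift at 1,000 cells/core;
composition recovery through the full pipeline at 2,000 cells within ±3
binomial SE; and clustered-versus-uniform discrimination of within-class
neighbor enrichment at 30 µm. `scripts/acceptance.R` re-runs the full
default scenario (82 cores, 600 cells each) from a caller-supplied seed
and writes the headline quantities as JSON.

## Known limitations

* The ordinal treatment of the 16 nominal classes makes the default
  paired test blind to shifts that happen to preserve the mean and rank
  mass of class indices; use the chi-squared alternative when that
  matters.
* Global min–max normalization is sensitive to single extreme cells; an
  optional robust variant (percentile clipping) is deliberately not the
  default because the reference procedure used the raw extremes.
* QC criteria for lost/damaged cells are taken as an upstream input flag
  and not re-derived.
* No survival/outcome modelling and no second-order spatial statistics
  (Ripley's K, cross-K, graph neighborhoods) — the neighborhood radius
  census and equitability are the implemented scope.
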