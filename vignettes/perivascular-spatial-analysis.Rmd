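---
title: "Quantifying perivascular T cell niches: methods and design notes"
author: "perivasc authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying perivascular T cell niches}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perivasc)
```

## The biological setting

In IDH-mutant astrocytoma, T cells do not diffuse through the tumor
parenchyma: they accumulate in the perivascular space, the compartment
between the endothelial and the parenchymal basement membrane (the
latter demarcated by laminin-alpha-2, LAMA2). Aggregates of three or
more T cells confined inside such a membrane region are called
*T cell cuffs*. The tumor stroma surrounding these cuffs is enriched in
gemistocytic tumor cells (GTCs, identifiable by CD44/CRYAB staining) and
in a population of tumor-associated macrophages/microglia (TAMs) that
co-localises with the GTC network.

`perivasc` implements the spatial quantification used to establish that
picture from phenotyped multiplex immunofluorescence data: permutation
nearest-neighbour z-scores, cuff geometry from polygon containment,
corrected marker-density fields with pooled equal-count binning, a
bin-matched gene-set enrichment score for expression data, and a rigid
registration of consecutive section outlines. A synthetic tissue and
expression generator with recorded ground truth makes every stage
testable without patient data.

## The permutation nearest-neighbour z-score

For a phenotype pair (from, to), the observed statistic is the mean
distance from each from-type cell to its nearest to-type cell, averaged
over all from-type cells of the map (one ROI or one whole slide). The
null distribution is obtained by randomly reassigning the phenotype
labels of *all* cells in the map, preserving the marginal label counts,
and recomputing the statistic; the z-score is the observed value minus
the null mean, divided by the null SD. Negative z means the pair sits
closer than label-exchangeability predicts (clustering), positive z
means dispersion. Defaults follow the two published procedures: 1000
reassignments per ROI, 100 per whole slide.

Conventions that the procedure itself leaves open, fixed here:

* The null permutes labels over the whole field jointly, across all
  phenotypes, not only the two types being compared.
* The observed labelling is not added to the null sample: the statistic
  of interest is the z-score, not a permutation p-value.
* When from and to are the same type, a cell is never its own
  neighbour; two distinct cells at identical coordinates still count at
  distance zero.
* A degenerate null (SD zero, e.g. a single-phenotype field) flags the
  result as undefined rather than returning z = 0.
* `mode = "exhaustive"` enumerates every distinct placement of the
  from/to labels (cells with other labels are exchangeable for this
  statistic) and is seed-independent; it uses the population SD over
  the enumeration, while sampled mode uses the sample SD of the drawn
  reassignments.

Calibration was verified on completely random labelings of spatially
random fields (criterion: near-zero mean z and near-nominal tail mass),
and the sign convention on planted Thomas-cluster and hard-core
patterns; the test suite performs these checks.

## Cuff geometry

Membrane polygons (e.g. QuPath GeoJSON exports of LAMA2-positive
objects) are converted to working hulls by *morphological closing*: the
polygons are rasterised, dilated and eroded by a disc of the
user-chosen smoothing radius (in micrometres), and each connected
component's outer contour is traced and simplified. Closing with an
erosion one pixel smaller than the dilation guarantees that the input
region is contained in the output hull at raster precision. This
replaces ad-hoc concave-hull reconstructions with an operation whose
single parameter has physical units and whose output can be validated
against a raster oracle.

Cells are assigned to hulls by even-odd containment of their centroid,
with three deterministic conventions: boundary points count as
contained; a cell inside the hole of an annulus is outside; nested
hulls resolve to the smallest containing area. A hull containing more
than two T cells (i.e. at least three) is a cuff; its equivalent radius
is `sqrt(area / pi)` — the paper never defines its "cuff radius"
computation, so the equivalent-area radius is this package's explicit
choice — and size classes use configurable radius cutoffs (defaults 50
and 100 um, also a package choice since no thresholds are published).
Area-adjusted counts divide centroid counts by region area in mm^2.

ROIs (670 x 502 um frames, the published acquisition geometry) are
classified *cuff* when at least one detected cuff is present,
*stromal_T* when T cells exist without a cuff, and *absent* otherwise.

## Registration of consecutive sections

Two tissue outlines are aligned by brute-force grid search over
rotations about the moving outline's centroid and XY translations,
maximising raster intersection-over-union (defaults: +/-15 degrees in
0.5-degree steps, +/-500 um in 25 um steps, raster at half the
translation step). The grid contains the identity, so the aligned IoU
never falls below the unaligned one; ties resolve to the
identity-nearest candidate because angles are scanned outward from zero
and improvements must be strict. The consensus outline is the largest
connected component of the aligned intersection — only tissue present
in both sections is compared downstream.

## Corrected marker density and binning

Cell density fields use an isotropic Gaussian kernel without edge
correction,

$$ \hat\lambda(g) = \sum_i \frac{1}{2\pi\sigma^2}
   \exp\!\left(-\frac{\lVert g - p_i\rVert^2}{2\sigma^2}\right), $$

on a regular grid with spacing sigma/10 and a bounding box padded by
4 sigma, which keeps the integral within 1% of the point count. The
*corrected* marker density is the ratio of the marker-positive cell
field over the all-cell field — a local positive fraction in [0, 1].
The published pipeline passes `sigma = 500` to a pixel-based routine
without stating units; here sigma is defined in micrometres with
default 500 and is fully configurable (the ratio field is
scale-equivariant, so this choice rescales geography, not values).

The ratio is masked where it is not statistically meaningful: nodes
with total density below `minTotal` (default 1e-12 per um^2) or farther
than 2 sigma from every cell. Masked locations propagate as flagged,
not silently dropped, when fields are sampled at cell positions
(bilinear interpolation).

Following the published order of operations, density fields are
computed per sample, sampled at that sample's cells, and only then are
the per-cell values from all samples pooled and cut into equal-count
bins (default 20). Binning sorts by value with ties broken by stable
input order; when the count is not divisible by the bin number, the
lowest bins take the extra cell — an arbitrary but deterministic rule.
Bin composition tables report, per bin, the fraction of cells from each
sample group and, per bin and group, the phenotype composition.

## Bin-matched enrichment score

For a gene set G on an expression matrix, all genes are ranked by mean
expression and cut into 30 equal-count bins; for each gene of G, 100
random genes from its bin join the reference set R (so R is 100x larger
than G), and the per-unit score is the mean expression of G minus the
mean of R. Draws are without replacement within one target's
background when the bin is large enough, with replacement otherwise
(flagged), and a gene may serve several targets. The target gene itself
is eligible for its own background, matching the published phrasing;
an `exhaustive` option replaces sampling with the whole bin. Scores are
computed on the values as provided — normalise first (e.g.
`logTransformCounts`); the module performs no normalisation itself.
An optional gene-universe filter (e.g. a most-variable-genes
restriction) is applied before bin construction; whether the original
analysis intersected before or after binning is not recoverable, so the
choice is exposed rather than guessed.

One property of this score deserves emphasis because it constrains how
recovery experiments must be designed. If a program of shift $s$ is
planted in a fraction $f$ of units, the planted genes' *overall* means
rise by $fs$, so their expression-matched background rises by $fs$ too:
the expected score is $(1-f)s$ in affected units and $-fs$ elsewhere.
The score separates carriers from non-carriers perfectly in
expectation, but its magnitude is diluted by the carrier fraction —
at $f = 0.5$ the two groups sit at $\pm s/2$. The validation suite
checks this derived behaviour directly at $f = 0.5$ and runs the
threshold-based recovery check at $f = 0.1$, the minority cell-state
regime the score is used for in single-nucleus data.

GTC histology scores follow the published bins (0%, 0-20%, 20-40%,
>40%) with right-closed boundaries — a fraction of exactly 0.20 is "+"
— and the binary GTC-high class requires strictly more than the ~20%
threshold. The published interval labels overlap at their endpoints, so
a deterministic convention was required; both are configurable.

## The synthetic tissue generator

`simulateTissue` produces the structures the analyses assume, with
recorded per-cell ground truth:

| parameter | meaning | default |
|---|---|---|
| `width`, `height` | domain (um) | 2000 x 2000 |
| `nVessels`, `vesselRadius` | disk vessels | 8, 30 um |
| `annulusOuter` | perivascular annulus outer radius | 90 um |
| `cuffTPerVessel` | cuff T cells, uniform in each annulus | 12 |
| `tParentIntensity`, `tOffspringMean`, `tOffspringSigma` | Thomas stromal T | 1.5/mm^2, 6, 40 um |
| `gtcIntensity`, `gtcDecay` | GTC intensity at vessel wall, decay length | 250/mm^2, 300 um |
| `tamIntensity`, `tamCoupling` | TAM baseline, GTC-gradient coupling | 120/mm^2, 1.5 |
| `intensities` | homogeneous background phenotypes | tumor 350, other 80, B 10 /mm^2 |

Background phenotypes are homogeneous Poisson; stromal T cells a Thomas
cluster process; the GTC field an inhomogeneous Poisson process whose
intensity decays exponentially with distance to the nearest cuff-vessel
wall (simulated by thinning); TAM intensity is the baseline multiplied
by `1 + coupling * g(x)` with `g` the normalised GTC gradient (when the
GTC field is flat, the gradient is zero and TAMs are homogeneous). The
published work does not report cuff cell densities or annulus
thicknesses, so these defaults are plausible free parameters of a
desk-scale model — sized so a simulated section carries a few thousand
cells — not estimates of real tissue. Offspring displaced outside the
domain are discarded (finite sections; no toroidal wrap), which thins
edge clusters slightly. Each generator stage draws from its own
seed-derived stream, so changing one stage's parameters does not
perturb another's draws.

The ROI generator wraps the same machinery in a 670 x 502 um frame and
enforces the declared tissue phenotype: *absent* ROIs carry no T-cell
process, *stromal_T* ROIs discard T cells that fall inside an annulus
(placing one deterministic far-from-vessel T cell if none survive), and
*cuff* ROIs place at least three T cells per annulus. Whole-slide
presets mirror the published GTC-high/GTC-low contrast: the high preset
carries the gradient, coupling and cuff T cells; the low preset a flat,
sparse GTC field, no coupling, and stromal T cells only.

`simulateExpression` draws negative-binomial counts (`size` =
dispersion; variance mu + mu^2/size, Poisson in the infinite limit)
with a lognormal spread of per-gene baseline means, and multiplies a
planted gene set by `2^log2Effect` in a chosen fraction of units.

What the generator does *not* emulate — staining artefacts,
autofluorescence, segmentation error, phenotype misassignment, 3-D
structure, irregular vessel shapes, anisotropic tissue — bounds what
passing tests show: they validate the statistics and geometry on data
satisfying the model assumptions, not robustness to imaging noise,
which enters upstream of this package's inputs.

## Numerical choices and problem sizes

* Exhaustive enumeration is capped at 2e5 label placements; larger
  requests are directed to sampled mode.
* Distances use dense pairwise matrices (fields up to a few thousand
  cells), with row minima via `max.col`.
* Raster resolutions: smoothing/5 for hull closing, half the
  translation step for registration, 0.5 um for the validation oracle.
* The validation suite sizes its simulations for a desk run: 50
  exhaustive-oracle maps of up to 10 cells, 200 calibration replicates
  of 500 cells at 500 permutations, 100 sign-recovery simulations per
  pattern, 50-seed density-recovery and 20-seed enrichment-recovery
  loops, and one default ROI cohort (30 ROIs at 1000 permutations)
  plus one 14-sample whole-slide cohort; the full suite completes in a
  few minutes on one core.

## Known limitations

* The mean-NN permutation z-score is the only spatial statistic
  implemented; no edge-corrected K/L functions and no mark-correlation
  functions.
* KDE bandwidth is global; no adaptive or edge-corrected estimators.
* Registration is rigid (rotation + translation) on a grid; no elastic
  deformation, and accuracy is bounded by the grid steps.
* Whether the original cuff counting included T cells between
  endothelium and a fragmented membrane is unstated; this
  implementation counts exactly the cells whose centroids fall in the
  membrane hull.
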