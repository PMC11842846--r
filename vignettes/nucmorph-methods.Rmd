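---
title: "Models and methods behind nucmorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind nucmorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucmorph)
```

# The scientific problem

Cells in a crowding epithelial monolayer are genetically identical yet far
from morphologically identical: cell areas, nucleus areas and aspect
ratios all spread widely around their means, and the spread persists as
the monolayer densifies toward a jammed, solid-like state. Two statistical
regularities organize this heterogeneity. First, mean-normalized cell and
nucleus areas collapse onto a common log-normal curve,

$$\mathrm{PDF}(x) \propto \frac{1}{x}
  \exp\!\left(-\frac{(\ln x + 0.05)^2}{0.19}\right),
  \qquad x = \frac{A}{\langle A\rangle},$$

i.e. $\ln x \sim N(\mu = -0.05,\ \sigma^2 = 0.095)$. Second, aspect
ratios rescaled as $x = (AR - 1)/(\langle AR\rangle - 1)$ collapse onto a
unit-mean gamma curve
$\mathrm{PDF}(x;k) = k^k x^{k-1} e^{-kx} / \Gamma(k)$ with shape
$k \approx 2.43$. Area and aspect ratio are essentially uncorrelated
(mean $|r| \approx 0.05$), so the two collapses describe independent
axes of shape variability.

The heterogeneity is generated at division — daughters of one mother do
not receive equal areas — and it matters downstream: nucleus area tracks
cell area (a stable NC ratio), and nucleus size in turn couples to
chromatin state. Nuclear levels of the repressive mark H3K27me3
(normalized to DAPI) fall with nucleus area while the active mark H3K9ac
rises with it, and the radial arrangement of the active mark (the ratio of
mean intensity in the outer 20% shell of the nucleus to the inner 80%
core) also increases with nucleus size.

`nucmorph` implements the full quantitative chain — synthetic data
generation, morphometric feature extraction, distribution collapse and
fitting, correlation inference, radial chromatin statistics, and
multivariable prediction — as a tested, seed-deterministic pipeline. The
original imaging data are not publicly deposited, so the package ships a
generator that emulates the reported statistical structure and lets every
downstream stage be verified against oracles and known constructions.

# The synthetic-data models

## Division lineage

`simulate_lineage()` implements the two-step origin of size
heterogeneity:

* **Uneven division.** A mother of area $A$ splits into $fA$ and
  $(1-f)A$, $f \sim N(0.5, \sigma_f)$ truncated to $(0.05, 0.95)$. The
  two daughters' areas sum to the mother's exactly, at every division.
  The distributional form of $f$ is not constrained by observation beyond
  its asymmetry, so a symmetric one-parameter truncated normal is used.
* **Size-proportional growth.** Between divisions, $dA/dt = g\,A$ sampled
  hourly for `growth_hours` (default 6 h, the window over which daughter
  sizes stabilize); a linear law ($dA/dt = g\,A_{birth}$) is available for
  sensitivity analyses.

Nucleus area follows $\rho\,e^{\varepsilon} A(t)$ with the noise factor
$\varepsilon \sim N(0, \sigma_{nc})$ redrawn once per cell at birth, so
the NC ratio is a per-cell constant during growth, as observed for
tracked daughters.

Because divisions multiply areas by i.i.d. factors, $\ln A$ performs a
random walk across generations: its variance grows linearly at rate
$\mathrm{var}(\ln f)$ per generation and the terminal population is
log-normal. Defaults are chosen to make the default simulation land on
the steady-state statistics: with $\sigma_f = 0.05$,
$\mathrm{var}(\ln f) \approx (2\sigma_f)^2 = 0.01$, and ten generations
accumulate $\sigma^2 \approx 0.1 \approx 0.095$. The founder area
(300 µm²) and growth rate (0.035 h⁻¹, roughly a doubling per 20-h cycle)
set scales only; they drop out of every normalized statistic. The 6-h
amplification asymmetry between cell and nucleus growth (slopes ~1.12 vs
~0.88 in tracked daughters) is a reported observation the generator does
not target: no parameter controls it, and the model keeps the NC factor
fixed during growth.

## Labeled monolayer rendering

`generate_monolayer()` renders co-registered label masks and intensity
channels. Per-cell **target areas** are drawn from the log-normal model
and **aspect ratios** from the gamma model (defaults µ = −0.05,
σ² = 0.095, k = 2.43, ⟨AR⟩ = 1.4 — epithelial cell and nucleus aspect
ratios typically average 1.3–1.5). Cells must partition the field, so
targets are realized by a tessellation:

* Seeds sit on a jittered square lattice (jitter 0.2 of the spacing), one
  seed per lattice cell, so each pixel only inspects its 5×5 block of
  neighboring seeds.
* Each seed carries a unit-determinant elliptical metric whose axis ratio
  is its drawn AR and whose orientation is uniform; the assignment
  minimizes the metric distance minus an additive capacity weight.
* Capacity weights are iterated (10 rounds on a 3×-coarse grid,
  step 0.15) so realized pixel areas track the drawn targets.
* The metric is pre-scaled by $(s^2/A_i)^{\gamma}$ with lattice spacing
  $s$ and $\gamma = 0.85$. The exponent interpolates between unscaled
  power weighting ($\gamma = 0$), whose equilibrium makes large cells
  systematically rounder (spurious area–AR correlation ≈ −0.08), and
  fully size-normalized metrics ($\gamma = 1$, correlation ≈ +0.01);
  $\gamma = 0.85$ is the null point at which the tessellation's geometric
  area–elongation coupling vanishes, so the rendered field inherits the
  sampling model's independence of area and AR (rendered mean
  $|r| \approx 0.02$ at n ≈ 900).

**Nuclei** are filled ellipses at the cell centroid, oriented along the
cell's long axis, with area $\rho\,e^{\varepsilon}A_{cell}$
($\rho = 0.35$, a typical projected NC area ratio in confluent epithelia;
$\sigma_{nc} = 0.2$, which places the nucleus–cell area correlation near
the reported steady-state values ~0.7–0.8) and AR drawn from the gamma
model. Nuclei are clipped to their cell; clips are counted and surfaced
as a warning.

**Channels.** DAPI is a constant per-nucleus level plus pixel noise. Each
mark channel has a per-nucleus DAPI-normalized level
$1 + \beta\,(A_n - \bar A_n)/\bar A_n + \eta$, with slope
$\beta = -0.3$ for the repressive (H3K27me3-like) channel and $+0.3$ for
the active (H3K9ac-like) channel, matching the opposite signs of the
observed size couplings; level noise $\eta$ has sd 0.1. Within each
nucleus, the mark is rendered as a two-zone radial profile — the outer
20% shell and inner 80% core get different plateaus — whose
periphery/center mean-intensity ratio is
$1 + c\,(A_n - \bar A_n)/\bar A_n$; the coupling $c$ defaults to $+0.3$
for the active mark and 0 for the repressive one (nucleus size chiefly
reorganizes euchromatin). The area-weighted mean of the two plateaus
equals the per-nucleus level, so radial structure never distorts total
intensity. Pixel noise is additive Gaussian, sd 2% of the mean DAPI
level, clipped at zero.

What the generator does **not** emulate: curved or lobed nuclei, nucleoli
and chromocenters, optical blur and shading, segmentation errors,
mitotic figures, and any mechanical relaxation of cell shapes. Passing
tests therefore certify the statistical machinery — not robustness to
real microscopy artifacts; with real data, segmentation quality is the
dominant unmodeled error source.

# Morphometry

Features follow the literal working definitions: shape index
$P/\sqrt{A}$, solidity $A/A_{convex}$, circularity $A/P^2$, roundness
$A/\mathrm{major}^2$, aspect ratio major/minor from the second-moment
ellipse. `conventional = TRUE` switches circularity and roundness to the
textbook $4\pi A/P^2$ and $4A/(\pi\,\mathrm{major}^2)$ scalings. Axis
lengths add a $1/12$ pixel-footprint term to the central moments so
single-pixel objects stay finite. Convex hulls are taken over pixel-square
corners, which guarantees solidity ≤ 1.

The default perimeter is a weighted boundary-pixel count: straight-edge
pixels (one exposed 4-neighbor) weigh 1.02 and corner pixels (two
adjacent exposed neighbors) 1.22, weights calibrated on digital disks of
radius 20–60 and axis-aligned squares (disk circumference error ≈ 1%,
square error ≈ 0.7%). The raw crack length — exact for axis-aligned
shapes, where a side-$s$ square gives exactly $4s$ — remains available as
`perimeter_method = "crack"`. Intensity statistics (mean, sd, CV,
mark/DAPI ratio) are computed over the nucleus mask; the normalized mark
level is the ratio of means rather than the mean of per-pixel ratios,
which is far less noise-sensitive when DAPI approaches zero at the
nuclear rim.

Exclusion rules: any record whose cell or nucleus touches the image
border is dropped (its morphology is not measurable), and actively
dividing cells are dropped via an explicit id list or an optional DAPI
outlier rule (mean above median + 3 MAD — condensed mitotic chromatin is
atypically bright). Nuclei are matched to cells by shared label id; when
the masks share no ids, by nucleus-centroid-in-cell, with ambiguous
matches (two nuclei claiming one cell) excluded and reported.

# Distribution fits

Both fits are maximum likelihood; a histogram least-squares criterion was
considered and rejected because it depends on binning. For the
log-normal, $\hat\mu$ and $\hat\sigma^2$ are the sample mean and
population (1/n) variance of $\ln x$ — the exact MLE, so the estimate
matches direct-formula oracles to machine precision. For the unit-mean
gamma, the input is first rescaled to unit mean (the rescaled-AR variable
is unit-mean by construction; rescaling makes the one-parameter family
well-posed for any input). The score equation
$\ln k - \psi(k) = -\overline{\ln x}$ is solved by Newton iteration with
a bisection safeguard on $(10^{-3}, 10^{3})$, started from the standard
closed-form approximation; the solver agrees with a 0.001-step
grid search of the log-likelihood to better than 0.002. Goodness of fit
uses the Kolmogorov–Smirnov statistic against the fitted CDF (asymptotic
p-values, exact below n = 30). Collapse across conditions is summarized
by the matrix of two-sample KS tests and its maximum statistic.

The quoted prefactor of the log-normal form (0.25/x) is not the
normalizing constant of its own exponential; the form is treated as
specified up to normalization and only µ and σ² are matched.

# Correlation inference

Pearson correlations are computed from the covariance/sd-product formula
and Spearman correlations as Pearson on average ranks. Confidence
intervals use the Fisher z-transform, $z = \mathrm{atanh}(r)$ with
standard error $1/\sqrt{n-3}$ and $z_{0.975} = 1.959964$ — no method is
attached to the published intervals, but this choice reproduces the
subconfluent-timepoint interval (upper bound exact to 3 decimals, lower
bound within one unit in the third decimal of rounding the printed r);
the printed intervals for the three later timepoints are not internally
consistent with their printed r and N under any standard method, so they
are not used for validation. Permutation p-values shuffle one variable
against the other, $p = (1 + \#\{|r_b| \ge |r|\})/(1 + B)$ with
B = 10000 by default; the add-one correction avoids p = 0. The two
vectors are put in a canonical order before permuting so the p-value is
exactly invariant to swapping x and y.

The family-level FDR follows the Monte-Carlo reading: every report's
stored data are permuted, null |r| values are pooled across the family,
and each test's FDR is the expected null exceedance count (scaled to one
family) divided by its observed exceedance count, capped at 1 and made
monotone in |r|. The family is whatever set of reports is passed in one
call.

The spatial area–area autocorrelation bins unordered cell pairs by
centroid distance and averages products of mean-centered values,
normalized by the variance; the zero-distance bin holds the self-pairs
(value 1) and bins with fewer than 10 pairs are flagged rather than
dropped.

# Radial chromatin statistics

The nuclear periphery is defined by area, not by a fixed erosion depth:
pixels are ranked by the interior Euclidean distance transform and the
lowest 20% (configurable) form the periphery. This hits any requested
fraction exactly even on small masks, where whole-pixel erosion steps
overshoot; ties at the threshold resolve by scan order, making the
realized fraction the closest achievable and the split deterministic.
Holes are filled before the distance transform (and flagged) so interior
voids do not masquerade as boundary; intensity statistics still use only
original mask pixels. The periphery/center statistic is the ratio of mean
intensities (each region's total normalized to its area), which is
invariant to global intensity scaling; the per-nucleus CV uses raw
intensities by default. `split_robustness()` re-runs the size correlation
over a grid of fractions to confirm conclusions do not hinge on the
80/20 choice.

# Multivariable prediction

All models are evaluated by seeded k-fold cross-validation (5 folds;
the upstream regression tooling documents no fold scheme, so one is fixed
here) with predictions taken only from held-out folds and accuracy
summarized as the Pearson correlation between out-of-fold predictions and
measurements. Predictors are z-scored inside each training fold. The
linear model is ordinary least squares with a pseudoinverse fallback for
rank deficiency; the nonlinear model is a squared-exponential-kernel
Gaussian process (via `kernlab::gausspr`) whose length scale and noise
are picked by an inner 3-fold grid around the median-heuristic distance
(×{0.25, 1, 4}) and noise {1e-3, 1e-2, 1e-1} — only the kernel family is
externally specified. For DAPI-normalized histone targets, DAPI mean, sd
and CV are removed from the predictor list automatically: their
association with a mark/DAPI ratio is arithmetic, not biological.
NC-ratio features join the predictor set only when requested, mirroring
the grouping of predictor panels. Dropout importance refits the model
with each predictor removed on the same folds and ranks by the drop in
prediction r, ties broken by name order. CCA standardizes both blocks and
regularizes near-singular within-block covariances with a logged 1e-6
ridge; PCA standardizes and reports loadings, scores and variance
fractions. Per-fold GP posterior variances are not aggregated across
folds; no cross-fold confidence band is reported.

# Problem sizes and numerical choices

The test suite and acceptance script run at sizes a laptop handles in
minutes, chosen as the package's own verification scale: 20 000 draws
for distribution recovery (shape-recovery tolerance ±0.05 ≈ 2 standard
errors at that n), 225–1000-cell monolayers for rendering checks, 20
monolayers at the default 1000 cells for the area–AR independence check,
500 repeats for null-calibration of permutation p, and 200 repeats of a
20-test family for the FDR check. Oracle comparisons use masks up to
64×64 pixels where brute-force per-pixel computation is exact and fast.
Degenerate inputs are rejected explicitly (zero-variance correlations,
all-equal samples, all-circular aspect ratios, constant prediction
targets), and every stochastic component takes an explicit seed, with the
caller's RNG state restored afterwards.

# Known limitations

* The tessellation approximates target areas to ~5% relative error;
  rendered area distributions are slightly narrower than their targets.
* The renderer's AR fidelity is partial (drawn vs measured cell AR
  correlate ~0.5): neighbors deform each cell's imposed ellipse. The
  gamma *family* of the measured AR distribution is preserved, which is
  what the fitting stages consume.
* The empirical FDR is one defensible reading of a one-sentence
  published description of the procedure; alternatives (per-test rather
  than pooled nulls) would differ in small families.
* Areas are 2D projections; no 3D volume features are computed.
* The pipeline consumes label masks; segmentation itself is upstream and
  out of scope.
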