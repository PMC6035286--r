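---
title: "Quantifying epithelial convergent extension: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying epithelial convergent extension: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wingmorph)
```

## The scientific problem

During early pupal development the *Drosophila* wing imaginal disc elongates
along its proximal--distal (PD) axis while narrowing along the
anterior--posterior (AP) axis -- convergent extension -- and does so
autonomously, without external pulling. Two cellular mechanisms can produce
tissue shear: cells changing shape, and cells exchanging neighbors
(intercalation). Telling them apart requires (i) a measure of mean cell
elongation, (ii) a measure of tissue elongation, and (iii) a kinematic
decomposition connecting the two. `wingmorph` implements that chain, the
image-processing steps that feed it, and a minimal continuum model that
explains the observed dynamics with three effective parameters.

Throughout, x is the PD axis and y the AP axis; times are hours after
puparium formation (h APF); rates are per hour.

## Cell elongation from triangulation

Cell shape is quantified on the network of cell centers: each interior
tricellular vertex (a point where three cells meet) defines a triangle
connecting the three cell centroids. Comparing a triangle with a reference
equilateral triangle (unit area, one side along +x) gives a linear map $M$,
and the nematic elongation tensor is

$$Q = \tfrac12\,\log\!\big(M M^\top / \det M\big),$$

a symmetric traceless $2\times2$ tensor with components $(Q_{xx}, Q_{xy})$.
We use the finite (matrix-logarithm) definition rather than its
small-deformation linearization because it makes the tests sharp: an affine
pure shear $(x,y)\mapsto(x e^s, y e^{-s})$ applied to an isotropic tissue
changes $\langle Q_{xx}\rangle$ by exactly $s$, and rotating the tissue by
$\theta$ rotates $(Q_{xx},Q_{xy})$ by exactly $2\theta$. The polar form
$MM^\top$ (not $M^\top M$) is what lives in tissue space and transforms
covariantly under tissue rotations; the choice of reference triangle cancels
in it. The $2\times2$ logarithm is evaluated in closed hyperbolic form
($A = \cosh m\,I + \sinh m\,N$ with $\operatorname{tr}N = 0$, so
$\tfrac12\log A = \tfrac{m}{2}N$), and the tests cross-check it against an
independent eigendecomposition.

Averaging choices the tissue literature leaves open, resolved here:

* `mean_elongation()` averages components (uniform weights by default;
  area weighting available). `mean_anisotropy()` averages magnitudes
  $|Q|$. The two differ on disordered tissue and both are reported, since
  the distinction between $|\langle Q\rangle|$ and $\langle|Q|\rangle$ is
  often blurred in method descriptions.
* Vertices where four or more cells meet are fanned into triangles in
  counter-clockwise cell order -- deterministic and orientation-stable;
  such vertices are transient T1 intermediates.
* Triangles are built only at interior vertices, so the clipped hull
  contributes no artificial boundary anisotropy.

One caveat worth stating precisely: exact additivity of $Q_{xx}$ under pure
shear holds when every triangle starts isotropic (the honeycomb limit). On a
disordered tissue, matrix logarithms of non-commuting maps do not add, and
the mean response to a shear $s$ deviates from $(s, 0)$ at order
$s\,|Q|^2$ per triangle (about $10^{-3}$ for the default disorder). The
tissue-series generator therefore targets *measured* elongation rather than
assuming additivity.

## Tissue elongation and the shear decomposition

Tissue shape is summarized by maximal PD length $l$ and AP width $h$, with
natural (Hencky) strains $L = \log(l/l_0)$, $H = \log(h/h_0)$ relative to
the first frame. The anisotropic tissue shear rate is
$\tilde v_{xx} = \tfrac12\,\partial_t(L-H)$, and the rearrangement shear is
the residual

$$R_{xx} = \tfrac12\,\frac{d(L-H)}{dt} - \frac{d\langle Q_{xx}\rangle}{dt}.$$

Both derivatives use the same finite-difference operator (central at
interior points, second-order one-sided at the ends), so the discrete
decomposition identity $\tilde v_{xx} = d\langle Q_{xx}\rangle/dt + R_{xx}$
holds exactly at every time point by construction -- what is informative is
the *value* of $R_{xx}$, not the identity.

Discrete events are detected from tracked topology between consecutive
frames: a T1 is a lost adjacency pair whose quartet's complementary pair is
gained; a T2 is a disappearing cell id whose area had been shrinking
(the shrink guard protects against tracking loss misread as extrusion; with
fewer than two prior observations the disappearance alone counts); a rosette
is a vertex with five or more incident cells -- a 4-fold vertex is a
transient T1 intermediate, so the threshold is five, configurable. Pairs
involving disappeared cells are excluded from T1 analysis so a T2 cannot
masquerade as an exchange.

## The continuum model

The wing is modeled as a rectangle under spatially uniform shear. Three
ingredients: the shear decomposition above; a constitutive assumption that
rearrangements follow myosin anisotropy, $R_{xx} = \lambda\,q_{xx}(t)$; and
a traceless stress balance which, for a tissue free to expand (zero
anisotropic stress), reduces to

$$\frac{d\langle Q_{xx}\rangle}{dt}
  = -\frac{\langle Q_{xx}\rangle}{\tau_s}
    - \frac{\zeta/2K}{\tau_s}\, q_{xx}(t),$$

with $\tau_s = \mu/K$ the cell-shape relaxation timescale (hours) and
$\zeta/2K$ the dimensionless active-stress ratio -- negative when
junctional myosin contracts AP-oriented junctions and drives PD extension.
Tissue elongation follows as

$$(L-H)(t) = -2\int_{t_0}^{t}
  \Big[\frac{\langle Q_{xx}\rangle}{\tau_s}
  + \Big(\frac{\zeta/2K}{\tau_s} - \lambda\Big) q_{xx}\Big]\,dt',
  \qquad (L-H)(t_0) = 0.$$

The myosin anisotropy schedule is piecewise linear: $q_{xx} = 1$ on
$(t_0, t_1)$, a linear ramp to 0 on $(t_1, t_2)$, and 0 afterwards, with
defaults $t_0 = 4$, $t_1 = 5$, $t_2 = 6$ h APF matching measured myosin
dynamics. The plateau magnitude 1 is a normalization absorbed into $\zeta$
and $\lambda$. Open-interval boundary values resolve by right-continuity --
a measure-zero choice that affects no integral.

Numerical design:

* `solve_Qxx_closed()` evaluates the exact solution with per-segment
  antiderivatives against the damped kernel $e^{-(t-t')/\tau_s}\le 1$, so it
  is stable down to $\tau_s = 0.01$ h (used in the quasi-static limit
  check). `solve_Qxx_ode()` is the independent cross-check: adaptive
  integration restarted at the schedule breakpoints, agreeing to below
  $10^{-6}$ everywhere.
* `predict_LmH()` integrates the closed-form integrand with 16-point
  Gauss--Legendre panels split at the breakpoints. The exact identity
  $(L-H) = 2(\langle Q_{xx}\rangle - Q_{xx,0}) + 2\lambda\int q_{xx}$
  (algebraic consequence of the three model equations) is used as its test
  oracle, not as its implementation.

### Fitting

Following the physiological range, $\tau_s$ is scanned on a grid
(default 10 values, 0.1--1 h). Given $\tau_s$, the model is *linear* in
$(\zeta/2K, \lambda)$, so the inner fit is an exact linear least-squares
solve -- no iterative optimizer, no starting values, no convergence
failures; the SSE Hessian is positive definite whenever both curves are
supplied (verified as a test). $Q_{xx}(t_0)$ is pinned to the measured value
at $t_0$ rather than fitted. Residuals from the $Q_{xx}$ and $L-H$ curves
are pooled with equal weight by default; per-point standard deviations can
be used as weights, and a sequential mode (fit $\zeta/2K$ on $Q_{xx}$, then
$\lambda$ on $L-H$) is available because both are defensible when curve
noise levels differ.

On noiseless synthetic curves the fit recovers the generating parameters to
$10^{-4}$ at the true $\tau_s$ and the SSE profile is minimized there; with
Gaussian noise of sd 0.01 on 13 timepoints, the median over 50 replicates
recovers $\lambda$ and $\zeta/2K$ within a few percent. Parameters fitted at
the wrong $\tau_s$ trade off smoothly ($\lambda$ stays near 0.1/h while
$\zeta/2K$ drifts over roughly $-0.06$ to $-0.16$ across the grid), which is
why the grid is reported in full rather than a single point estimate.

## Synthetic data: what it emulates, and what it does not

All inputs are generated in code; the package needs no microscopy data.

* **Meshes** (`make_cell_mesh()`): Voronoi tessellation of a perturbed
  hexagonal lattice (unit spacing; perturbation uniform in a disk of radius
  `disorder`/2). A buffer ring of sites guarantees every kept cell is a
  complete Voronoi cell, so at `disorder = 0` all cells are congruent
  regular hexagons and the tissue is exactly isotropic -- the reference
  state for the exactness tests. Default `disorder = 0.3` gives a
  mix of 5-, 6-, 7-sided cells resembling segmented wing epithelium.
* **Tissue series** (`simulate_tissue_series()`): deformation is
  kinematically imposed, not mechanically relaxed (no vertex-model energy
  minimization -- a non-goal). Per frame interval the generator applies the
  affine shear that makes $L-H$ track the model, then plants T1 exchanges
  (edge collapsed to its midpoint, reopened at the same length between the
  other two quartet cells) until measured $\langle Q_{xx}\rangle$ returns
  to the model path. Because targets are absolute, T1 quantization errors
  do not accumulate; at 400 cells one T1 moves $\langle Q_{xx}\rangle$ by
  roughly $4\times10^{-3}$, which sets the closed-loop tolerance. The
  spatial pattern of intercalation is thus imposed and recorded rather than
  derived from junction mechanics -- the measurement chain, not the
  generator, is the object under test.
* **Planted T2** events shrink the victim over two frames and then remove
  it, leaving a micro-hole; neighbor polygons are untouched. This keeps
  detection clean (no spurious adjacency gains or high-order vertices) at
  the cost of not emulating the final junction resealing of real
  extrusions.
* **Membrane images** (`render_membrane_image()`): Gaussian-profile
  skeleton (FWHM = membrane width) on dark interiors, optical blur, then
  Poisson shot noise plus Gaussian read noise split evenly so that
  `snr` = membrane mean / total noise sd -- the standard fluorescence noise
  model. Rendering at 45 px per cell diameter-ish (cells span roughly 40
  pixels, typical of confocal data of this tissue) keeps the IoU evaluation
  meaningful. What is *not* emulated: uneven illumination, out-of-focus
  light, membrane intensity variation along junctions, and segmentation
  over time (tracking is taken from ground truth, a non-goal).
* **Elongation curves, junction intensities, surface profiles**: direct
  model/noise generators with ground truth attached; the junction-intensity
  generator uses the same 30-degree orientation classes as the measurement
  so the planted polarity ratio is exactly the expected value of the
  measured one.

Passing the closed-loop tests therefore shows that the measurement chain
inverts the generator under realistic geometry, noise and event rates -- it
does not certify performance on real movies with illumination artifacts or
imperfect tracking.

## Segmentation

The chain mirrors a standard membrane-segmentation recipe: Shen--Castan
infinite symmetric exponential filter (ISEF) smoothing, implemented as the
separable recursive first-order exponential filter with constant-preserving
boundary handling; principal-curvature ridge enhancement (most negative
Hessian eigenvalue at Gaussian scale, clipped at zero); watershed on the
ridge map with two correction rules replacing interactive proofreading:
h-minima suppression (`h`) and merging of basins below a minimum area into
the neighbor behind their lowest ridge barrier. Watershed lines are the
pixels whose 4-neighborhood contains a different basin.

Defaults (`alpha = 0.8`, `ridge_scale = 1.2` px, `min_area = 150` px,
`h = 0.03`) were calibrated on the synthetic fixtures -- the operators are
standard but carry no canonical parameter values -- and give 100% of cells
matched at IoU $\ge$ 0.9 on noiseless renders and at snr 5 on the default
fixture. Accuracy is checked to be non-increasing in noise.
`mesh_from_labels()` closes the loop back to morphometry: label centroids,
adjacency across $\le 2$ px membrane lines (with a two-vote rule so
tricellular corners do not create spurious contacts), and clustered
tricellular vertex positions.

## Problem sizes and determinism

The test and acceptance workloads use 100--400-cell tissues, 13-frame
series, 50-replicate fit studies, and three rendered noise levels --
sizes chosen so each closed loop has clear statistical margin while a full
run stays in the minutes range on one core. Every stochastic step takes an
explicit integer seed and touches no global random state beyond `set.seed`
at entry; rasters are byte-identical and meshes value-identical on reruns
with the same seed.

## Known limitations

* Deformation is kinematic; no force balance on junctions, hence no
  prediction of *where* intercalations happen.
* 3-D cell shape is reduced to a scalar epithelial height accepted as
  input; columnar-to-cuboidal flattening is not meshed.
* The T2 micro-hole convention slightly perturbs local triangulation
  around extrusion sites (a handful of triangles out of hundreds).
* The continuum fit identifies only the ratios $(\tau_s, \zeta/2K,
  \lambda)$; $K$, $\mu$, $\zeta$ are not separately identifiable from
  elongation curves, and $\tau_s$ itself is only weakly constrained by
  noisy data (the grid scan makes that visible).
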