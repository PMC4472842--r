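---
title: "A hybrid discrete-continuum model of biofilm morphology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A hybrid discrete-continuum model of biofilm morphology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biofilmca)
```

## The model

biofilmca simulates early biofilm growth in two dimensions as a
stochastic cellular automaton coupled to continuum resource fields. The
domain is a `w x d` grid of 1 um x 1 um cells in the vertical plane
perpendicular to the coverslip (`z = 0` is the coverslip row); each cell
is biomass-filled or media-filled. Borders are reflective: for widths
above ~100 cells the difference between reflective and periodic side
borders is negligible, and reflective borders make the discrete operators
simpler.

Each time step has two phases.

**Phase 1 — fields.** Nutrient transport is split into a well-mixed bulk
and a diffusive boundary layer of thickness `b`, constructed as the
circular dilation of the biomass by radius `b` (Euclidean distance
between cell centers). On biomass and boundary-layer cells the
equilibrium uptake-diffusion balance

$$\nabla^2 n = r\, c_{xz}\, n$$

is solved with `n = 1` on bulk cells and zero-flux conditions at the
coverslip, sides, and top. Here `n` is the nutrient concentration
relative to the bulk, `c` the 0/1 occupancy, and `r = u0/D` the
uptake-diffusion ratio (diffusion constant and uptake rate enter only
through their ratio; `r` plays the role of a Thiele modulus). The
discretization is the standard 5-point stencil at unit spacing with
mirrored ghost cells at the borders and identity rows for Dirichlet
cells, assembled sparse and solved directly (Matrix/CHOLMOD — the same
class of direct sparse solver as the UMFPACK solver classically used for
such systems). Equilibration is justified by the separation of time
scales between diffusion and division under constant-flow conditions.

For light-dependent (photoheterotrophic) growth, a uniform source at the
coverslip attenuates through biomass columns (Beer-Lambert):

$$I_{xz} = \exp\!\Big(-\tfrac1p \sum_{i=0}^{z} c_{xi}\Big),$$

with `p` the characteristic penetration depth and the source intensity
absorbed into the light Monod parameter. The sum is inclusive of row `z`
itself — a biomass cell shades itself — which is the literal reading of
the attenuation sum; the alternative exclusive convention differs only
by a factor `exp(-1/p)` uniform over biomass cells and does not change
any qualitative behavior.

**Phase 2 — division and placement.** Each biomass cell divides with
Monod probability `K(n, n_half)`, times `K(I, i_half)` when
light-dependent, where `K(y, y_half) = y/(y + y_half)`; division happens
when `P > V` with `V ~ U[0,1]` (strict). Daughters are placed inside the
`N x N` block centered on the parent (`N = 11`). Candidates must be
media-filled and 4-adjacent to biomass (daughters stay connected to the
biofilm); each gets probability proportional to

$$R^\alpha S^\beta, \qquad
R = \frac{1}{(x-x_0)^2 + (z-z_0)^2}, \qquad
S = e^{-\Delta L},$$

where `dL` is the perimeter change the daughter would cause. `R` is the
literal reciprocal of the squared Euclidean distance — the 1/2 power
that would turn it into a plain reciprocal distance is folded into the
weighting `alpha`, and the surface tension and `kT` of the
Maxwell-Boltzmann surface-energy factor are folded into `beta`. If the
normalization `A = 1/sum(R^alpha S^beta)` exceeds `a_max = 1e12` (a cell
dividing deep inside the biofilm, whose nearest vacancy is half a block
away), no daughter is placed.

Dividing cells are processed in uniformly random order and each daughter
is sampled against the *current* state, so daughters placed earlier in a
step are visible to later parents. The alternative — freezing the state
for the whole step — would allow a later daughter to be placed onto a
cell just filled by an earlier one; sequential updating avoids that
collision and preserves connectivity by construction.

Runs stop at a prescribed biomass count (the placement loop truncates
exactly at the target, so cohorts are grown to identical total mass), at
a negligible maximum division probability (`1e-6`; "negligible" is not
quantified by the model description, and any threshold a few orders
below one division per grid per step behaves identically), or at a step
cap.

## Perimeter and border conventions

The perimeter `L` counts lattice edges between a biomass and a media
cell; 4-connectivity is used everywhere (adjacency, connectivity,
perimeter) for consistency with the edge-based definition. Edges on the
grid border are not interfaces: under reflection a daughter at the
coverslip mirrors onto itself, so placing it creates no new interface
there. This gives the local rule `dL = deg - 2k` (in-grid degree minus
twice the biomass neighbors), which equals the global perimeter
difference exactly. One consequence worth noting: an isolated parent on
the coverslip does *not* have a uniform 3-candidate distribution when
`beta > 0`, because its lateral candidates touch the border (`dL = 1`)
while the candidate above it does not (`dL = 2`); uniformity there is a
`beta = 0` property.

## Parameters

| Symbol | Meaning | Units | Default / explored range |
|---|---|---|---|
| `w`, `d` | grid width, depth | cells (um) | 128, 40 |
| `s` | inoculation separation | cells | 1-64 (default 32) |
| `b` | boundary-layer thickness | cells | 1-16 (default 7) |
| `r` | uptake-diffusion ratio | 1/cell^2 | 0-5 |
| `p` | light penetration depth | cells | 0-30 (2 is the measured late-stage value) |
| `i_half`, `n_half` | Monod parameters | relative | 0-1 (n_half default 0.25) |
| `N` | placement block length | cells | 11 |
| `alpha`, `beta` | distance / surface-energy weights | -, 1/cell | 0-3 (defaults 2, 1) |
| `a_max` | normalization cutoff | - | 1e12 |

The default inoculation separation is `s = 32` (four colonies across the
default grid). The separation is genuinely open — no value is prescribed
for the morphology surveys — and it matters: published model outputs
show three to four distinct column/mushroom structures across a 128 um
grid, i.e. ~32 um spacing, and the coverage-curve signatures that
distinguish the two growth modes (monotone decrease vs a localized peak
above the base) only develop when colonies are sparse enough not to
merge into a uniform base layer before columns form. Dense inoculation
(`s <= 8`) fills the first several rows solid in every regime and
flattens those signatures.

The dimensionless *nutrient scarcity* `n_s = 1/(b^2 r)` is approximately
the equilibrium concentration an isolated cell experiences relative to
the bulk; its inverse `b^2 r` is the axis along which morphology
transitions from dense laminar slabs (nutrient-rich) to porous columns
and mushrooms (nutrient-scarce).

## Sweeps and study conditions

`sweep_biofilm()` samples `b` uniformly on [1, 16] and the inverse
scarcity `b^2 r` log-uniformly on [1/30, 300] by default, deriving
`r = (b^2 r)/b^2`, with `alpha = 2`, `beta = 1`, `n_half = 0.25` fixed
and every sample grown to 2000 cells — the morphology-survey
conditions. Two deliberate choices:

* *Log-uniform scarcity.* The morphology transition spans decades of
  `b^2 r` and is examined on a logarithmic axis; sampling `r` uniformly
  on a linear range would put almost no mass in the nutrient-rich
  regime.
* *Upper bound 300.* The survey constraint in the source conditions
  bounds scarcity below (`b^2 r >= 1/30`) and allows `r` up to 30, i.e.
  `b^2 r` up to ~7.7e3. Growth to 2000 cells at such scarcities needs
  hundreds of automaton steps per run; at `b^2 r = 300` the package's
  supported sweep scale (10^2-10^3 samples rather than the survey's
  3e5-4.7e5) already reaches strongly columnar morphologies
  (convex-hull densities ~0.6 vs ~0.92 for nutrient-rich runs), so the
  default range trades the extreme tail for sample count.

Per-run metrics are the biomass count, COMSTAT-style mean thickness
(count / w, in um), mean cell depth, the coverage-vs-depth profile, and
the convex-hull density — biomass count divided by the area of the
convex hull over the *corners* of occupied cells. Corners rather than
centers make solid convex shapes score exactly 1 and keep the
single-cell case finite; with centers, a solid rectangle would score
above 1 and a single cell would divide by zero.

## Image quantification

The image path mirrors COMSTAT-style biovolume analysis with one
extension: a depth-adaptive intensity threshold. Anchor thresholds are
chosen at specified depths, linearly interpolated between anchors, and
held constant beyond the first and last; a voxel is foreground iff its
intensity strictly exceeds its slice threshold. Stack biomass is
foreground biovolume per substratum area (mean thickness, um);
coverage-vs-depth is the per-slice foreground fraction. Vertical
sections of a chosen physical size (96 um x 20 um by default) are
extracted at seeded random lateral positions and orientations — the
sampling scheme for slice datasets is not prescribed anywhere, so a
seeded uniform scheme was chosen for reproducibility.

Because no experimental stacks are deposited, `synth_stack()` renders
parametric phantoms: a base layer plus columns that taper (columnar,
coverage decreasing monotonically with depth — the heterotrophic
signature), widen into caps (mushroom, a localized coverage peak above
the base — the photoheterotrophic signature), or fill a slab (laminar).
Rendered intensity decays exponentially with depth and carries additive
Gaussian detector noise. The phantom emulates the *geometry and
attenuation* of confocal reflectance stacks; it does not model the point
spread function, pinhole cross-talk, speckle, or biological texture
inside colonies, so tests passing on phantoms demonstrate the
correctness of the quantification pipeline, not segmentation performance
on real stacks. The attenuation model makes the adaptive threshold's
purpose testable: with signal and stray background both decaying, deep
foreground falls below shallow background intensity, and no single
constant threshold can segment every slice.

## Morphology classification

Feature vectors follow the two classifier variants: *age variant* — age
plus 21 samples of the coverage curve every 1 um from 0 to 20 um;
*biomass variant* — biomass plus coverage every 1 um from 2 to 20 um
inclusive (20 features), the first 2 um being dropped because model and
experiment differ most near the coverslip. The source description gives
both "19" and "20" features for the biomass variant; sampling 2-20 um
inclusive yields 19 coverage points and 20 features total, consistent
with the 21-point arithmetic of the age variant, and `drop_20um = TRUE`
provides the 19-feature alternative. Coverage blocks are normalized to
sum to one, making classification invariant to uniform scaling of a
curve; all-zero blocks are undefined and those slices are excluded.

Forests use 1000 trees, Gini splitting, and at most 5 features per split
(classification), or 500 trees with the squared-error criterion
(regression), via the randomForest package, with out-of-bag error /
R^2 as the accuracy estimate and a majority-class naive baseline as
reference. `synth_training_set()` renders the two experimental
signatures as labeled stacks — heterotrophic: a thick dense base layer
with columns tapering above it, so coverage is monotone non-increasing
with depth; photoheterotrophic: a thin base with rounded-cap columns
putting a localized coverage peak at depth — and runs the full
render-threshold-quantify-featurize path on each. Training on
image-side data and applying the classifier to simulator output mirrors
the original procedure (experimentally trained classifier applied to
the model parameter space). The phantom classes are deliberately dense
(base slabs up to 14 um, packed columns), matching the coverage scale
of the confocal curves they emulate; with sparse phantoms the
simulator's dense curves would fall outside the training manifold and
the transferred probabilities would be extrapolation artifacts. Published accuracies for the experimentally trained
classifier (3%/9%/10% OOB, 87% per-stack) depend on the unavailable
324-stack dataset and are out of scope; on synthetic phantoms the
corresponding property is separation far above the naive baseline.

## Numerical choices and degenerate inputs

* Dirichlet cells are eliminated from the linear system (their known
  value moves to the right-hand side), which keeps the matrix symmetric
  positive definite; solutions are clipped to [0,1] against roundoff
  (the discrete maximum principle bounds the exact solution).
* At unit spacing the film-profile value at the coverslip agrees with
  the two-region 1D closed form to within ~1%; under refinement
  (spacing 1/m, `r/m^2`, `b*m`) the error decreases monotonically from
  m = 2 on. The m = 1 error benefits partly from cancellation of the
  two half-cell interface offsets.
* Empty biofilms: fields are identically 1, a step is a no-op, metrics
  that need biomass (mean depth, hull density) raise errors rather than
  returning sentinels.
* `r = 0` or an empty unknown set short-circuits the solver.
* Ties in placement sampling cannot occur (continuous weights); ties in
  `P > V` resolve to "not dividing" by strictness.
* One R RNG stream per run, seeded once: division variates (column-major
  cell order), then placement order, then placement draws, each step.
  Sweeps draw per-run seeds from a master-seeded stream, so tables are
  reproducible end to end.

## Test scales

The test suite and the acceptance script run the study conditions at
desk scale, chosen as the package's supported defaults: 200-sample
sweeps to 2000 cells for the scarcity-porosity trend, 20 paired runs for
the light-compression comparison, 120 phantom stacks (60 per class) for
classifier training, and 10^5-draw frequency checks for the placement
sampler. Property tests on randomized lattices use grids up to 15 x 15
where exhaustive enumeration is the oracle.

## Known limitations

* Two-dimensional only; no cell death, shear, erosion, or motility (all
  excluded from the model's scope — early-growth biofilms).
* The boundary layer is a geometric dilation, not a flow solution;
  convection inside the layer is neglected.
* Monod parameters are relative quantities; no physical concentration
  or irradiance calibration is attempted.
* The classifier transfer from phantom-trained features to simulator
  output is a stand-in for the experimental transfer; it shares the
  coverage-curve feature space but not the noise structure of real
  confocal data.
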