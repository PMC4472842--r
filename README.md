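# biofilmca

A two-dimensional hybrid discrete–continuum model of early bacterial
biofilm growth, with the image-quantification and machine-learning
tooling needed to compare its output to confocal data. It is aimed at
researchers studying how abiotic factors — nutrient transport, flow,
light — shape biofilm architecture, in particular the contrast between
(organo)heterotrophic growth (tapering pillars, coverage decreasing
monotonically with height) and photoheterotrophic growth ("T"- or
mushroom-shaped structures with a coverage peak above the base layer).

## The model

Biomass occupies cells of a `w × d` lattice (1 µm² cells, `z = 0` at the
coverslip, reflective borders). Each time step:

1. **Fields.** The boundary layer is the circular dilation of the biomass
   by radius `b`. On biomass and boundary-layer cells the equilibrium
   nutrient field solves `∇²n = r·c·n` (5-point stencil, sparse direct
   solve) with `n = 1` in the bulk and zero-flux borders, where
   `r = u₀/D` is the uptake–diffusion ratio. In light-dependent mode,
   `I(x,z) = exp(−(1/p)·Σ_{i≤z} c(x,i))` attenuates a coverslip-side
   source with penetration depth `p`.
2. **Division.** Each biomass cell divides with Monod probability
   `K(n, n½)` (times `K(I, I½)` when light-dependent), where
   `K(y, y½) = y/(y + y½)`; division occurs when `P > V`, `V ~ U[0,1]`.
3. **Placement.** Daughters land in the 11×11 block around the parent on
   media cells adjacent to biomass, with probability ∝ `Rᵅ·Sᵝ`:
   `R = 1/((x−x₀)² + (z−z₀)²)` (distance factor) and `S = exp(−ΔL)`
   (surface-energy factor, `ΔL` the perimeter change). Divisions whose
   normalization factor exceeds `A_max = 10¹²` (deep interior cells)
   place no daughter.

Morphology is summarized by coverage-vs-depth profiles, mean cell depth,
COMSTAT-style biomass (mean thickness, µm), and convex-hull density (an
inverse porosity proxy). The dimensionless nutrient scarcity
`n_s = 1/(b²r)` organizes the morphology diagram: its inverse `b²r` is
small for dense laminar growth and large for porous columns/mushrooms.

The package also quantifies 3-D grayscale stacks (multi-page TIFF) with
depth-adaptive intensity thresholds, renders synthetic confocal
reflectance stacks from parametric phantoms, and trains random-forest
classifiers/regressors on coverage-curve features (1000 trees, Gini,
max 5 features per split; 500-tree squared-error regression).

## Worked example

Grow two biofilms that differ only in nutrient demand (the classic
dense-vs-columnar contrast at boundary-layer thickness `b = 7`):

```r
library(biofilmca)

rich   <- run_biofilm(simulation_params(b = 7, r = 0.04, seed = 42,
                                        target_biomass = 2000))
scarce <- run_biofilm(simulation_params(b = 7, r = 0.56, seed = 42,
                                        target_biomass = 2000))

sapply(list(rich = rich, scarce = scarce), function(tr) c(
  steps        = tr$state$step,
  inv_ns       = inverse_nutrient_scarcity(tr$params$b, tr$params$r),
  thickness_um = mean_thickness(tr$state),
  hull_density = convex_hull_density(tr$state)))
```

```
                   rich     scarce
steps        15.0000000 34.0000000
inv_ns        1.9600000 27.4400000
thickness_um 15.6250000 15.6250000
hull_density  0.8758485  0.7497657
```

Both runs stop at exactly 2000 cells (mean thickness 15.6 µm). The
nutrient-rich run (`b²r = 1.96`) packs them into a dense slab
(convex-hull density 0.88); the nutrient-scarce run (`b²r = 27.4`)
spends more steps building porous columnar/mushroom structures
(0.75) — increasing scarcity raises porosity. `coverage_by_depth()`,
`mean_cell_depth()`, and `sweep_biofilm()` extend this to depth profiles
and parameter surveys, and `synth_training_set()` + `train_forest()` +
`classify_model_output()` score simulated morphologies as
heterotrophic- vs photoheterotrophic-like.

A command-line interface wrapping these functions is installed as
`exec/biofilmca` (`run`, `sweep`, `quantify`, `classify`).

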