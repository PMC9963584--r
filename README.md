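# voroshell

Three-dimensional characterization of a solute's solvation shell by Voronoi
polyhedra in periodic molecular configurations.

## The problem

The usual one-dimensional description of a solvation shell — the solute–solvent
radial distribution function g(r), its first-peak position R_max, first-minimum
position R_min, and the running coordination number — averages out all angular
structure. For a solute in a cubic periodic box, the Voronoi polyhedron (VP) of
the solute site gives an unambiguous 3D alternative: the minimal convex
polyhedron bounded by the perpendicular bisector planes between the solute and
its neighbors. Its geometry encodes the shell:

- **N_F** — number of faces = number of geometric first neighbors (the
  VP estimate of the solvation number); with vertex and edge counts it obeys
  the Euler relation N_F + N_V − N_E = 2;
- **V, S_tot** — cell volume and total surface area (the space owned by the
  solute);
- **R = max_i d_i** — cage radius: radius of the smallest sphere about the
  solute containing every face-contributing neighbor;
- **R_w = 3V/S_tot** — face-weighted radius, the S_i/S_tot-weighted mean of
  the half neighbor distances d_i/2 (closer molecules make bigger faces and
  count more);
- **α = S_tot³/(36πV²) = V / ((4/3)πR_w³)** — asphericity; α = 1 for a
  sphere, larger for anisotropic shells.

`voroshell` constructs the solute VP under periodic boundary conditions by
half-space clipping (with image-shell expansion for low densities), computes
all descriptors per frame, provides the matching 1D RDF baseline
(n(r) = 4πρ ∫ g r² dr), and summarizes descriptor distributions with the
quartile/box/violin statistics used to compare thermodynamic states. Synthetic
generators — perfect lattices with analytically known cells, Poisson gas, and
a Metropolis soft-sphere liquid at water-equivalent densities — make the whole
pipeline testable without molecular-dynamics trajectories. Thirteen bundled
thermodynamic state presets span ambient water to low-density supercritical
fluid.

Intended users: simulators and structural-chemistry researchers analyzing
stored MD/MC configurations (extended-XYZ) of dilute solutes.

## Worked example

```r
library(voroshell)

# 25 independent dense-liquid frames (401 sites, 0.720 kg/L water-equivalent)
frames <- make_trajectory(
  fixture_spec("liquid", n = 401, density = 0.720, seed = 42, sweeps = 300),
  n_frames = 25)

met <- analyze_trajectory(frames)
head(met[, c("frame", "nf", "volume", "surface", "cage_radius", "rw", "alpha")], 3)
#>   frame nf volume surface cage_radius    rw alpha
#> 1     1 14  46.65   72.15       5.390 1.940 1.526
#> 2     2 16  48.30   71.57       5.425 2.024 1.390
#> 3     3 15  43.21   69.06       5.724 1.877 1.560

summarize_distribution(met$rw[met$converged])
#> <distribution_summary> n=25  mean=1.864819  median=1.877166  [Q1,Q3]=[1.772314,1.939767]  range=[1.567736,2.09758]
#>   skewness=-0.3665965  excess kurtosis=-0.08947793

rdf <- find_peak_features(compute_rdf(frames, bin_width = 0.1, r_cut = 9),
                          smoothing_window = 5)
sprintf("R0 = %.2f  Rmax = %.2f  Rmin = %.2f  n(Rmax) = %.2f  n(Rmin) = %.2f",
        rdf$R0, rdf$Rmax, rdf$Rmin, rdf$n_at_Rmax, rdf$n_at_Rmin)
#> "R0 = 2.55  Rmax = 3.45  Rmin = 4.45  n(Rmax) = 2.78  n(Rmin) = 8.58"
```

Reading: each frame's solute cell has ~15 faces (geometric neighbors), a cage
radius ~5.4 Å but a face-weighted radius ~1.9 Å (R_w weights the *half*
neighbor distances, so 2R_w ≈ 3.7 Å tracks the first-peak region, exposed as
the `rw_doubled` column), and α ≈ 1.5, a moderately aspherical shell. The RDF
view of the same frames puts the first peak at 3.45 Å and counts 8.6 neighbors
up to its first minimum — fewer than N_F, because for a one-component
repulsive fluid many geometric neighbors sit beyond the sharp first minimum.

The full bundle (per-frame CSV, RDF TSV + feature JSON, distribution
summaries, state-comparison table, resolved config and manifest) is produced
by `run_analyze()` / `run_states_sweep()`, or from a shell via the CLI:

```sh
Rscript inst/cli/voroshell.R synth --kind liquid --n 401 --density 0.72 \
    --frames 50 --seed 1 --out frames.xyz
Rscript inst/cli/voroshell.R analyze --input frames.xyz --out-dir results
```

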