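---
title: "Voronoi-polyhedron characterization of solvation shells: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voronoi-polyhedron characterization of solvation shells: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voroshell)
```

## The model

A solute site in a periodic cubic box of edge $L$ owns the region of space
closer to it than to any solvent site: its Voronoi polyhedron (VP), the
minimal convex polyhedron whose faces lie on the perpendicular bisector
planes between the solute and its neighbors. The face-contributing neighbors
*are* the solvation shell in a purely geometric sense — no distance cutoff
has to be chosen, and angular structure is retained.

For the VP with face areas $S_i$, plane distances $h_i = d_i/2$ (half the
neighbor distance), the package computes

$$V = \tfrac13 \sum_i S_i h_i, \qquad S_{tot} = \sum_i S_i,$$

the cage radius $R = \max_i d_i$, the face-weighted radius

$$R_w = \sum_i \frac{S_i}{S_{tot}}\,\frac{d_i}{2} = \frac{3V}{S_{tot}},$$

and the asphericity

$$\alpha = \frac{S_{tot}^3}{36\pi V^2} = \frac{V}{\tfrac43\pi R_w^3},$$

which is $1$ for a sphere and $\ge 1$ for every convex body (isoperimetric
inequality). Counts of faces, vertices and edges satisfy the Euler relation
$N_F + N_V - N_E = 2$; $N_F$ is the VP estimate of the solvation number.

Because $R_w$ averages *half* neighbor distances, it lives on half the scale
of the first peak of the radial distribution function; the table column
`rw_doubled` ($= 6V/S_{tot}$) is the face-weighted mean of the full neighbor
distances and is the natural quantity to place against the first-peak
position $R_{max}$.

The 1D baseline is the solute–solvent partial RDF $g(r)$ computed from
minimum-image distances, with onset $R_0$, first maximum $R_{max}$, first
minimum $R_{min}$, and the running coordination number

$$n(r) = 4\pi\rho \int_{R_0}^{r} g(r')\,r'^2\,dr',$$

with $\rho$ the number density of solvent sites (solute excluded). A
dimensionally inconsistent variant without the $r^2$ Jacobian is retained
behind `strict_printed_form = TRUE` for auditability against sources that
print the integral in that form; the default is always the $r^2$ form, since
only it counts neighbors.

## Cell construction

The engine clips an axis-aligned bounding cube with bisector planes taken in
order of increasing minimum-image distance. A plane at distance $h$ can only
cut the current cell if $h$ is below the distance of the farthest current
vertex, so the sorted candidate stream terminates provably early; for a
dense liquid a cell typically needs a few dozen plane applications.

Periodicity is handled in two stages. Minimum-image neighbors suffice
whenever the finished cell's farthest vertex lies within $L/4$ (then no
periodic image can contribute a face). Otherwise the candidate set expands
shell-by-shell with image copies of all sites *including the center itself*,
up to `max_image_shells` (default 2); the cell of an $n$-site frame is then
exact down to very low densities, and a cell that still cannot be certified
is flagged `converged = FALSE`, reported, and excluded from statistics. This
matters for the lowest-density supercritical states (0.310 kg/L), where
solvation cells grow large relative to the box.

### Numerical tolerances

Degenerate geometry is the central numerical difficulty: in a perfect fcc
lattice four bisector planes meet in each vertex, and in large batches of
random frames a plane occasionally grazes a flat corner at depths near
machine precision, carving a face of tiny area but much larger lateral
extent. The package separates *metric* from *topological* computations:

- clipping and all metric quantities ($V$, $S_i$, vertex coordinates) use a
  near-machine tolerance (`tol_plane`, default $10^{-12} L$), keeping faces
  exactly planar, $V$ verified against an independent divergence-theorem
  triangulation to $10^{-8}$ relative, and $\alpha$'s two algebraic forms
  consistent to $10^{-10}$;
- the counts $N_F, N_V, N_E$ are taken on a vertex-merged copy of the
  complex (`tol_vertex`, default $10^{-6} L$), and the merge tolerance
  escalates (at most three times, $\times 5$ each) until the complex is
  topologically *closed* — every edge shared by exactly two faces. Closure,
  not any fixed tolerance, is the invariant that guarantees the Euler
  relation; a fixed tolerance always leaves a marginal band of features.

Exactly tangent planes (lattices) are classified as non-cutting, which is
why the fcc cell comes out with $N_F = 12$ rather than 18. Face vertices are
ordered by angle about the outward normal, making output deterministic.

Validation anchors, all exercised in the test suite:

- simple cubic, fcc and bcc lattices reproduce the cube, rhombic
  dodecahedron and truncated octahedron (counts exactly; $V$, $S_{tot}$,
  $R_w$, $\alpha$ to $10^{-9}$ relative);
- on small random frames, faces, vertices, counts and volume match an
  independent brute-force oracle that intersects all triples of candidate
  planes over all sites and their 26 periodic images;
- full tessellations fill the box: $\sum V = L^3$ to $10^{-8}$ relative;
- over $4\times 10^4$ Poisson cells the mean face count agrees with the
  stochastic-geometry constant $48\pi^2/35 + 2 \approx 15.535$ within
  Monte-Carlo error.

## Synthetic fixtures and what they do (not) show

No reference trajectories are shipped; three generators stand in:

- **Lattices** (`make_lattice`): exact analytic oracles for the geometry.
- **Poisson gas** (`make_poisson`): the structureless null. Its RDF is flat
  ($g \equiv 1$ within counting statistics — the test accepts the handful of
  isolated $3\sigma$ bins that Poisson noise must produce and rejects any
  $5\sigma$ bin or a biased mean), and its cells follow Poisson–Voronoi
  statistics.
- **Soft-sphere liquid** (`make_liquid`): Metropolis Monte Carlo of a purely
  repulsive $\varepsilon(\sigma/r)^{12}$ fluid at the number density implied
  by a water-equivalent mass density (molar mass 18.0153 g/mol, so the
  bundled presets translate to the same number densities as the
  corresponding aqueous systems). Defaults: $\sigma = 2.5$ Å (a
  water-oxygen-like exclusion diameter), $\varepsilon = 10\,k_BT$ — chosen
  so the core genuinely excludes ($g < 0.05$ inside $\sigma$; at
  $\varepsilon = 4$ the measured contact leakage reached $g \approx 0.16$),
  400 sweeps from a grid start, displacement $0.3\sigma$. Frames are
  generated independently (frame $k$ uses seed `master + k - 1`), so they
  are uncorrelated by construction; everything is bit-reproducible from the
  master seed.

The liquid fixture emulates *excluded-volume packing at controlled density*,
not water: it has no hydrogen bonds, no orientational structure, and no
distinct solute species. Consequently the package's tests validate the
machinery (geometry, normalization, statistics, trends), not absolute
water values. Two consequences are worth stating plainly:

- the qualitative density trend is reproduced — decreasing density at fixed
  $n$ increases mean $V$, $S_{tot}$ and $\alpha$ of the solute cell;
- the relation between $n(R_{min})$ and $N_F$ is *not* transferable. For a
  dilute, weakly structuring solute in water the first RDF minimum is
  shallow and far out, so integrating to it overestimates the solvation
  number relative to $N_F$. A one-component repulsive fluid instead has a
  sharp, close first minimum: we measure $n(R_{min}) \approx 10$ against
  mean $N_F \approx 14.6$ at 0.997 kg/L-equivalent — many geometric
  neighbors sit beyond $R_{min}$. The corresponding acceptance check is
  therefore expected to fail on this fixture, and is left failing rather
  than weakened; it documents a genuine limitation of the fixture, not of
  the estimators.

## Statistics layer

`summarize_distribution()` reports the box-and-whisker/violin quantities:
true minimum and maximum as whiskers (not $1.5\,\mathrm{IQR}$ fences),
type-7 quartiles, mean, bias-corrected Fisher skewness
$G_1 = \sqrt{n(n-1)}/(n-2)\, g_1$ and excess kurtosis
$G_2 = \frac{n-1}{(n-2)(n-3)}[(n+1)g_2 + 6]$ (so "platykurtic" means
$G_2 < 0$), a Freedman–Diaconis density histogram (unit-width integer bins
for $N_F$), and a Gaussian KDE (normal-reference bandwidth) evaluated at
$Q_0, Q_1, Q_2, Q_3, Q_4$ and the mean — the violin annotation points. The
KDE is annotation-only; no statistic is derived from it. Zero-variance input
yields undefined (not zero) shape statistics.

`normality_check()` computes the empirical-CDF sup-distance against a
moment-fitted normal and compares it with the asymptotic
$1.358/\sqrt{n}$ critical value. With estimated parameters this is
conservative (accepts slightly too readily); it is the descriptive
"does the $N_F$ distribution look normal" check, not a calibrated test.

`compare_states()` assembles the per-state table — quartile summaries of
$R$, $R_w$, $N_F$, $V$, $S_{tot}$, $\alpha$ next to $R_{max}$, $R_{min}$,
$n(R_{max})$, $n(R_{min})$ — and classifies $R_{max}$ against the $R_w$
interquartile range (`below_Q1` / `within_IQR` / `above_Q3`).

## Defaults and problem sizes

RDF bin width defaults to 0.02 Å for production-length trajectories; the
examples and tests use 0.1 Å with a 5-bin moving average because their frame
counts (tens, not tens of thousands) need coarser bins for stable extrema.
Extremum detection requires a strict local extremum against every bin within
two bins on either side; undefined features are reported `NA`, never
guessed. The test and acceptance runs use 100 frames of 401 sites for the
Poisson batteries and 40-frame liquid suites at three densities — sizes
chosen to keep Monte-Carlo error comfortably inside the asserted bounds
while the whole suite runs in minutes on one core.

## Known limitations

- Cubic boxes only; triclinic cells and Laguerre (radical) tessellations are
  out of scope.
- Cells are built from oxygen-like point sites; hydrogens are dropped, so
  orientational information never enters the geometry.
- At extremely low density the image-shell budget can be exhausted; such
  frames are flagged and excluded rather than extrapolated.
- `read_xyz()` supports (extended-)XYZ only.
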