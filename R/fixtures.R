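#' Perfect-lattice configuration
#'
#' Generates a periodic simple-cubic, face-centered-cubic or body-centered
#' cubic lattice.  These have analytically known Voronoi cells (cube, rhombic
#' dodecahedron, truncated octahedron) and serve as exact geometry oracles.
#' The site closest to the box center is tagged as the solute (`"Or"`); all
#' others are `"Ow"`.
#'
#' @param kind `"sc"`, `"fcc"` or `"bcc"`.
#' @param n_cells_per_edge conventional cells per box edge (>= 2).
#' @param spacing conventional-cell edge `a` in Angstrom (> 0).
#' @return a [configuration()] with `L = n_cells_per_edge * spacing`.
#' @examples
#' make_lattice("fcc", 3, 4.0)  # 108 sites
#' @export
make_lattice <- function(kind = c("sc", "fcc", "bcc"), n_cells_per_edge,
                         spacing) {
  kind <- match.arg(kind)
  if (n_cells_per_edge < 2) stop("need at least 2 cells per edge")
  if (spacing <= 0) stop("`spacing` must be positive")
  basis <- switch(kind,
    sc  = matrix(c(0, 0, 0), 1, 3, byrow = TRUE),
    fcc = matrix(c(0, 0, 0, 0.5, 0.5, 0, 0.5, 0, 0.5, 0, 0.5, 0.5), 4, 3,
                 byrow = TRUE),
    bcc = matrix(c(0, 0, 0, 0.5, 0.5, 0.5), 2, 3, byrow = TRUE))
  g <- expand.grid(x = seq_len(n_cells_per_edge) - 1,
                   y = seq_len(n_cells_per_edge) - 1,
                   z = seq_len(n_cells_per_edge) - 1)
  cells <- as.matrix(g)
  pos <- do.call(rbind, lapply(seq_len(nrow(basis)), function(b)
    sweep(cells, 2, basis[b, ], `+`)))
  pos <- pos * spacing
  L <- n_cells_per_edge * spacing
  center <- rep(L / 2, 3)
  d2 <- rowSums(sweep(pos, 2, center)^2)
  solute <- which.min(d2)  # ties: lowest index, deterministic
  species <- rep("Ow", nrow(pos))
  species[solute] <- "Or"
  configuration(pos, L, species = species, solute_index = solute)
}

#' Ideal-gas (Poisson) configuration
#'
#' `n` uniform i.i.d. positions in a cubic box; site 1 is the solute.  The
#' structureless null model: its RDF is flat and its Voronoi cells follow
#' Poisson--Voronoi statistics (mean face count \eqn{48\pi^2/35 + 2}).
#'
#' @param n number of sites (>= 5).
#' @param box_length box edge in Angstrom.
#' @param seed integer RNG seed; the frame is bit-reproducible from it.
#' @return a [configuration()].
#' @export
make_poisson <- function(n, box_length, seed) {
  if (n < 5L) stop("need at least 5 sites")
  pos <- .with_seed(seed, matrix(runif(3 * n, 0, box_length), ncol = 3))
  species <- c("Or", rep("Ow", n - 1L))
  configuration(pos, box_length, species = species, solute_index = 1L)
}

#' Dense disordered liquid-like configuration
#'
#' Equilibrates a purely repulsive soft-sphere fluid
#' (\eqn{u(r) = \epsilon (\sigma/r)^{12}}, \eqn{k_BT = 1}) by Metropolis
#' Monte Carlo at the number density implied by a water-equivalent mass
#' density, starting from a cubic grid.  This is a generic excluded-core
#' fluid emulating oxygen-site packing, not a water model: descriptor values
#' computed from it are compared to real-water results qualitatively only.
#'
#' @param n number of sites.
#' @param density water-equivalent mass density in kg/L (0 < d <= 1.2);
#'   converted with the molar mass of water, see [number_density()].
#' @param seed integer RNG seed.
#' @param sweeps Monte-Carlo sweeps (>= 100; one sweep = one trial move per
#'   site).
#' @param core_diameter soft-core diameter \eqn{\sigma} in Angstrom
#'   (default 2.5, a water-oxygen-like first-neighbor exclusion).
#' @param epsilon repulsion strength in units of \eqn{k_BT} (default 10;
#'   strong enough that \eqn{g(r) < 0.05} everywhere inside the core at
#'   liquid densities, so `core_diameter` really is an exclusion diameter).
#' @return a [configuration()] with site 1 as solute.
#' @export
make_liquid <- function(n, density, seed, sweeps = 400L, core_diameter = 2.5,
                        epsilon = 10) {
  if (density <= 0 || density > 1.2)
    stop("`density` must be in (0, 1.2] kg/L")
  if (sweeps < 100L) stop("need at least 100 sweeps to equilibrate")
  L <- box_length_for(n, density)
  if (L < 2 * core_diameter)
    stop("box too small for the requested density and core diameter")
  # overlap-free start: first n nodes of a cubic grid
  k <- ceiling(n^(1 / 3))
  g <- seq(0, L, length.out = k + 1L)[seq_len(k)]
  grid <- as.matrix(expand.grid(x = g, y = g, z = g))[seq_len(n), , drop = FALSE]
  pos <- .with_seed(seed,
    mc_soft_sphere_cpp(grid, L, core_diameter, epsilon, as.integer(sweeps),
                       max_disp = 0.3 * core_diameter))
  species <- c("Or", rep("Ow", n - 1L))
  configuration(pos, L, species = species, solute_index = 1L)
}

#' Fixture specification
#'
#' Bundles the parameters of one synthetic-configuration family for
#' [make_trajectory()] and the command-line interface.
#'
#' @param kind `"sc"`, `"fcc"`, `"bcc"`, `"poisson"` or `"liquid"`.
#' @param n sites per frame (poisson/liquid) .
#' @param n_cells_per_edge conventional cells per edge (lattices).
#' @param spacing lattice constant in Angstrom (lattices).
#' @param box_length box edge in Angstrom (poisson).
#' @param density water-equivalent kg/L (liquid).
#' @param seed master seed.
#' @param sweeps MC sweeps per liquid frame.
#' @param core_diameter soft-core diameter (liquid), Angstrom.
#' @return list of class `fixture_spec`.
#' @export
fixture_spec <- function(kind, n = 401L, n_cells_per_edge = 4L, spacing = 3.1,
                         box_length = 22.9, density = 0.997, seed = 1L,
                         sweeps = 400L, core_diameter = 2.5) {
  kind <- match.arg(kind, c("sc", "fcc", "bcc", "poisson", "liquid"))
  structure(list(kind = kind, n = as.integer(n),
                 n_cells_per_edge = as.integer(n_cells_per_edge),
                 spacing = spacing, box_length = box_length,
                 density = density, seed = as.integer(seed),
                 sweeps = as.integer(sweeps), core_diameter = core_diameter),
            class = "fixture_spec")
}

#' Per-frame seed derived from a master seed
#'
#' Frame `k` of a trajectory uses `master_seed + k - 1` (kept inside the
#' 32-bit integer range), so any single frame can be regenerated in
#' isolation without producing the whole trajectory.
#'
#' @param master_seed master seed of the trajectory.
#' @param k 1-based frame number.
#' @return integer seed for frame `k`.
#' @export
frame_seed <- function(master_seed, k) {
  as.integer((as.numeric(master_seed) + k - 1) %% 2147483647)
}

.make_frame <- function(spec, seed) {
  switch(spec$kind,
    sc = , fcc = , bcc =
      make_lattice(spec$kind, spec$n_cells_per_edge, spec$spacing),
    poisson = make_poisson(spec$n, spec$box_length, seed),
    liquid = make_liquid(spec$n, spec$density, seed, spec$sweeps,
                         spec$core_diameter))
}

#' Generate a multi-frame synthetic trajectory
#'
#' Produces `n_frames` statistically independent frames from a
#' [fixture_spec()], each generated from its own seed derived from the master
#' seed (`master + frame - 1`), and either returns them or writes them as one
#' extended-XYZ file.  Output is byte-reproducible for a fixed master seed.
#'
#' @param spec a [fixture_spec()].
#' @param n_frames number of frames (>= 1).
#' @param path optional output path; when given, frames are written with
#'   [write_xyz()] and the path is returned.
#' @return list of configurations, or `path` when writing.
#' @export
make_trajectory <- function(spec, n_frames, path = NULL) {
  stopifnot(inherits(spec, "fixture_spec"), n_frames >= 1)
  frames <- lapply(seq_len(n_frames), function(k)
    .make_frame(spec, frame_seed(spec$seed, k)))
  if (is.null(path)) return(frames)
  write_xyz(frames, path)
  path
}

# run `expr` under a fixed RNG seed without disturbing the caller's stream
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
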