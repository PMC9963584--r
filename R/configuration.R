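#' @title Periodic configuration objects
#' @name configuration
#' @description
#' A `configuration` holds one frame of a periodic cubic system: wrapped site
#' positions (\enc{Å}{Angstrom}), per-site species labels and the index of the
#' site designated as the solute center.  All analysis functions in the
#' package consume this class.
NULL

# Avogadro constant (mol^-1) and molar mass of water (g/mol) used to convert
# mass density in kg/L to oxygen-site number density in Angstrom^-3.
.AVOGADRO <- 6.02214076e23
.M_WATER <- 18.0153

#' Construct a periodic configuration
#'
#' @param positions numeric n x 3 matrix of site coordinates in Angstrom.
#'   Coordinates are wrapped into `[0, box_length)`.
#' @param box_length cubic box edge length in Angstrom (> 0).
#' @param species character vector of per-site labels (e.g. `"Ow"`, `"Or"`,
#'   `"Hw"`).  Defaults to `"Ow"` for every site.
#' @param solute_index 1-based index of the solute site, or `NULL` to resolve
#'   it from `solute_species`.
#' @param solute_species species label identifying the solute when
#'   `solute_index` is `NULL` (default `"Or"`).
#' @param state optional [thermo_state()] describing the thermodynamic state.
#' @return an object of class `configuration`.
#' @examples
#' pos <- matrix(runif(30, 0, 10), ncol = 3)
#' cfg <- configuration(pos, 10, species = c("Or", rep("Ow", 9)))
#' cfg$solute_index
#' @export
configuration <- function(positions, box_length, species = NULL,
                          solute_index = NULL, solute_species = "Or",
                          state = NULL) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3L) stop("`positions` must be an n x 3 matrix")
  storage.mode(positions) <- "double"
  if (!is.numeric(box_length) || length(box_length) != 1L || box_length <= 0)
    stop("`box_length` must be a single positive number")
  n <- nrow(positions)
  if (n < 5L) stop("a configuration needs at least 5 sites")
  if (is.null(species)) species <- rep("Ow", n)
  species <- as.character(species)
  if (length(species) != n) stop("`species` must have one label per site")
  if (is.null(solute_index)) {
    hit <- which(species == solute_species)
    if (length(hit) == 0L)
      stop("no site matches solute species label '", solute_species, "'")
    if (length(hit) > 1L)
      stop("multiple sites match solute species label '", solute_species,
           "'; give `solute_index` explicitly")
    solute_index <- hit
  }
  solute_index <- as.integer(solute_index)
  if (length(solute_index) != 1L || is.na(solute_index) ||
      solute_index < 1L || solute_index > n)
    stop("`solute_index` out of range")
  structure(
    list(positions = wrap_positions(positions, box_length),
         box_length = as.numeric(box_length),
         species = species,
         solute_index = solute_index,
         state = state),
    class = "configuration")
}

#' @export
print.configuration <- function(x, ...) {
  cat("<configuration> ", nrow(x$positions), " sites, L = ",
      format(x$box_length), " A, solute = site ", x$solute_index,
      " ('", x$species[x$solute_index], "')\n", sep = "")
  if (!is.null(x$state))
    cat("  state: T = ", x$state$temperature_K, " K, rho = ",
        x$state$density_kgL, " kg/L\n", sep = "")
  invisible(x)
}

#' Wrap coordinates into the primary box
#'
#' Folds every coordinate into `[0, L)`.  Idempotent.
#'
#' @param x numeric vector or matrix of coordinates (Angstrom).
#' @param box_length box edge (Angstrom).
#' @return wrapped coordinates, same shape as `x`.
#' @export
wrap_positions <- function(x, box_length) {
  x - box_length * floor(x / box_length)
}

#' Minimum-image displacement between two points
#'
#' Returns the displacement `b - a` with each Cartesian component folded into
#' `(-L/2, L/2]`; its norm is the minimum-image distance.  A component at
#' exactly half the box maps to `+L/2` (deterministic tie convention).
#'
#' @param a,b numeric 3-vectors, or n x 3 matrices (rowwise displacements).
#' @param box_length box edge (Angstrom).
#' @return displacement with the same shape as the broadcast of `a` and `b`.
#' @examples
#' minimum_image(c(9.5, 0, 0), c(0.5, 0, 0), 10)  # c(1, 0, 0)
#' @export
minimum_image <- function(a, b, box_length) {
  d <- b - a
  d - box_length * ceiling(d / box_length - 0.5)
}

#' Restrict a configuration to its oxygen sites
#'
#' Drops hydrogen (and any other non-oxygen) sites, keeping solvent oxygens
#' `"Ow"` and the solute oxygen, and remaps the solute index.  Idempotent on
#' oxygen-only configurations.  The Voronoi construction and the O--O RDF both
#' operate on the oxygen skeleton, the oxygens sitting near the molecular
#' centers of mass.
#'
#' @param config a [configuration()].
#' @param oxygen_species labels regarded as oxygen sites.
#' @return an oxygen-only `configuration`.
#' @export
select_oxygens <- function(config, oxygen_species = c("Or", "Ow", "O")) {
  stopifnot(inherits(config, "configuration"))
  oxy <- config$species %in% oxygen_species
  if (!any(oxy)) stop("configuration contains no oxygen sites")
  keep <- oxy | seq_along(config$species) == config$solute_index
  idx <- which(keep)
  new_solute <- match(config$solute_index, idx)
  configuration(config$positions[idx, , drop = FALSE], config$box_length,
                species = config$species[idx], solute_index = new_solute,
                state = config$state)
}

#' Thermodynamic state descriptor
#'
#' @param temperature_K temperature in kelvin (> 0).
#' @param density_kgL mass density in kg/L (> 0).
#' @param n_probes number of configurations analyzed at this state.
#' @return an object of class `thermo_state`.
#' @export
thermo_state <- function(temperature_K, density_kgL, n_probes = NA_integer_) {
  if (temperature_K <= 0) stop("temperature must be positive")
  if (density_kgL <= 0) stop("density must be positive")
  structure(list(temperature_K = as.numeric(temperature_K),
                 density_kgL = as.numeric(density_kgL),
                 n_probes = as.integer(n_probes)),
            class = "thermo_state")
}

#' Bundled thermodynamic state presets
#'
#' The thirteen water states studied in the source workflow, spanning ambient
#' liquid water through pressurized high-temperature liquid to supercritical
#' fluid, read from the YAML shipped with the package.
#'
#' @return a data.frame with columns `temperature_K`, `density_kgL`, `n_probes`.
#' @export
thermo_states <- function() {
  path <- system.file("extdata", "thermo_states.yaml", package = "voroshell",
                      mustWork = TRUE)
  raw <- yaml::read_yaml(path)$states
  out <- do.call(rbind, lapply(raw, function(s)
    data.frame(temperature_K = s$temperature_K, density_kgL = s$density_kgL,
               n_probes = s$n_probes)))
  out
}

#' Convert mass density to oxygen number density
#'
#' Converts a water-equivalent mass density in kg/L to the number density of
#' molecules (oxygen sites) in Angstrom^-3, using the molar mass of water
#' (18.0153 g/mol).
#'
#' @param density_kgL mass density in kg/L.
#' @return number density in Angstrom^-3.
#' @examples
#' number_density(0.997)  # ~0.0333 A^-3, ambient water
#' @export
number_density <- function(density_kgL) {
  density_kgL * 1000 / .M_WATER * .AVOGADRO / 1e27
}

#' Box edge for a given site count and mass density
#'
#' @param n number of molecules (oxygen sites).
#' @param density_kgL water-equivalent mass density in kg/L.
#' @return cubic box edge in Angstrom.
#' @export
box_length_for <- function(n, density_kgL) {
  (n / number_density(density_kgL))^(1 / 3)
}
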