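#' Parameters for the Voronoi cell construction
#'
#' Numerical tolerances and the periodic-image search depth used by
#' [voronoi_cell()].  Tolerances are relative to the box edge `L`: vertices
#' closer than `tol_vertex * L` are merged and faces with area below
#' `tol_area * L^2` are discarded before the face/vertex/edge counts are
#' taken, so that cospherical degeneracies (e.g. perfect lattices, where more
#' than three bisector planes meet in a point) collapse to the correct
#' combinatorics.  Merging affects only the topological counts; volumes and
#' areas are always evaluated on the raw, exactly planar clipped polygons.
#'
#' @param tol_plane relative on-plane classification tolerance for clipping.
#'   Kept near machine precision so that even planes cutting only a few
#'   1e-11 L deep are applied: a shallow cut at a flat corner can carve a
#'   face of far larger lateral extent, which must exist in the raw complex
#'   for the counts to balance.  Exact tangencies (perfect lattices) sit at
#'   1e-16 and are still classified as non-cutting.
#' @param tol_vertex relative vertex-merge tolerance for counting.  The
#'   default 1e-6 is deliberately much larger than the clipping tolerance:
#'   a bisector plane passing within `tol_plane` of an existing vertex
#'   scatters combinatorially distinct vertex copies over a
#'   `~sqrt(tol_plane)`-sized neighborhood, and all of them must collapse to
#'   one vertex for the Euler relation to hold.
#' @param tol_area relative minimum face area.
#' @param max_image_shells how many shells of periodic images may be added
#'   when the cell is not provably complete from minimum-image neighbors
#'   alone (shell `s` uses all image shifts in `{-s..s}^3`).  Low-density
#'   states need 1--2 shells; dense liquids almost never leave shell 0.
#' @return a list of class `vp_params`.
#' @export
vp_params <- function(tol_plane = 1e-12, tol_vertex = 1e-6, tol_area = 1e-12,
                      max_image_shells = 2L) {
  stopifnot(tol_plane > 0, tol_vertex > 0, tol_area > 0, max_image_shells >= 0)
  structure(list(tol_plane = tol_plane, tol_vertex = tol_vertex,
                 tol_area = tol_area,
                 max_image_shells = as.integer(max_image_shells)),
            class = "vp_params")
}

# Candidate bisector displacements for `center` at image-shell depth s.
# Shell 0: minimum-image displacements of all other sites.  Shell s >= 1:
# every site (including the center's own periodic images) shifted by all
# image vectors in {-s..s}^3.
.vp_candidates <- function(positions, center, L, shell) {
  u <- sweep(positions, 2, positions[center, ])
  u <- u - L * ceiling(u / L - 0.5)
  if (shell == 0L) return(u[-center, , drop = FALSE])
  g <- seq.int(-shell, shell) * L
  shifts <- as.matrix(expand.grid(x = g, y = g, z = g))
  m <- nrow(u)
  rel <- shifts[rep(seq_len(nrow(shifts)), each = m), , drop = FALSE] +
    u[rep(seq_len(m), times = nrow(shifts)), , drop = FALSE]
  src <- rep(seq_len(m), times = nrow(shifts))
  keep <- !(src == center & rowSums(rel^2) < 1e-12)
  structure(rel[keep, , drop = FALSE], source = src[keep])
}

.vp_build <- function(positions, center, L, params, return_faces) {
  shell <- 0L
  repeat {
    rel <- .vp_candidates(positions, center, L, shell)
    halfwidth <- (shell + 0.5) * L
    res <- clip_cell_cpp(rel, halfwidth,
                         params$tol_plane * L, params$tol_vertex * L,
                         params$tol_area * L^2, return_faces)
    # provably complete: the cell neither touches the bounding cube nor
    # extends to where an unexplored image plane could still cut it
    complete <- !res$touches_bound &&
      res$max_vertex_dist <= (shell + 0.5) * L / 2
    if (complete || shell >= params$max_image_shells) {
      res$converged <- complete
      res$shell <- shell
      src <- attr(rel, "source")
      fn <- res$face_neighbor
      fs <- rep(NA_integer_, length(fn))
      nz <- fn > 0L
      if (is.null(src)) {
        # shell 0: candidate row k is site k, skipping the center row
        k <- fn[nz]
        fs[nz] <- k + (k >= center)
      } else {
        fs[nz] <- src[fn[nz]]
      }
      res$face_source <- fs
      if (!complete)
        warning("Voronoi cell of site ", center,
                " not complete after ", shell, " image shell(s)",
                call. = FALSE)
      return(res)
    }
    shell <- shell + 1L
  }
}

#' Construct the Voronoi polyhedron of one site
#'
#' Builds the Voronoi cell of a site of a periodic configuration by clipping
#' a bounding cube with the perpendicular bisector planes of candidate
#' neighbors, taken in order of increasing minimum-image distance.  Clipping
#' stops as soon as the next candidate's half distance exceeds the distance of
#' the farthest cell vertex from the center, at which point no further plane
#' can cut.  If the cell cannot be proven complete from minimum-image
#' neighbors (low densities), the candidate set is expanded shell-by-shell
#' with periodic images, including images of the center site itself.
#'
#' @param config an oxygen-only [configuration()] (see [select_oxygens()]).
#' @param site 1-based index of the cell center; defaults to the solute.
#' @param params a [vp_params()] object.
#' @return an object of class `voronoi_cell`: list with `faces` (one matrix of
#'   ordered vertex coordinates per face, center at the origin),
#'   `neighbor_site` (contributing site index per face), `face_h` (plane
#'   distances \eqn{h_i}), `face_d` (neighbor distances \eqn{d_i = 2h_i}),
#'   `face_area`, counts `nf`/`nv`/`ne`, `volume`, `surface`, and `converged`.
#' @examples
#' cfg <- make_lattice("sc", 4, spacing = 3.1)
#' cell <- voronoi_cell(cfg)
#' cell$nf  # 6: a cube
#' @export
voronoi_cell <- function(config, site = config$solute_index,
                         params = vp_params()) {
  stopifnot(inherits(config, "configuration"))
  n <- nrow(config$positions)
  if (n < 5L) stop("need at least 4 neighbor sites to bound a cell")
  res <- .vp_build(config$positions, site, config$box_length, params,
                   return_faces = TRUE)
  structure(
    list(center = config$positions[site, ],
         site = site,
         faces = res$faces,
         neighbor_site = res$face_source,
         face_h = res$face_h,
         face_d = res$face_d,
         face_area = res$face_area,
         nf = res$nf, nv = res$nv, ne = res$ne,
         volume = res$volume, volume_alt = res$volume_alt,
         surface = res$surface,
         max_vertex_dist = res$max_vertex_dist,
         image_shell = res$shell,
         converged = res$converged,
         box_length = config$box_length),
    class = "voronoi_cell")
}

#' @export
print.voronoi_cell <- function(x, ...) {
  cat("<voronoi_cell> site ", x$site, ": N_F=", x$nf, " N_V=", x$nv,
      " N_E=", x$ne, ", V=", format(x$volume), " A^3",
      if (!x$converged) "  [NOT converged]", "\n", sep = "")
  invisible(x)
}

#' Asphericity of a closed body
#'
#' \eqn{\alpha = S^3 / (36 \pi V^2)}; equals 1 for a sphere and grows with
#' shape anisotropy (isoperimetric inequality guarantees \eqn{\alpha \ge 1}
#' for convex bodies).
#'
#' @param surface total surface area.
#' @param volume enclosed volume.
#' @return dimensionless asphericity.
#' @examples
#' asphericity(4 * pi * 2^2, 4 / 3 * pi * 2^3)  # 1, sphere
#' @export
asphericity <- function(surface, volume) {
  surface^3 / (36 * pi * volume^2)
}

#' Metric and topological descriptors of a Voronoi cell
#'
#' Computes the full descriptor set of a converged cell: counts
#' \eqn{N_F, N_V, N_E} (which satisfy the Euler relation
#' \eqn{N_F + N_V - N_E = 2}), volume \eqn{V = \frac13\sum_i S_i h_i}, total
#' surface \eqn{S_{tot}}, cage radius \eqn{R = \max_i d_i} (radius of the
#' smallest sphere about the center containing all face-contributing
#' neighbors), face-weighted radius \eqn{R_w = 3V/S_{tot}} (the face-area
#' weighted mean of the half neighbor distances) and asphericity
#' \eqn{\alpha = S_{tot}^3/(36\pi V^2)}.  `rw_doubled` exposes
#' \eqn{2 R_w = 6V/S_{tot}}, the face-area weighted mean of the full neighbor
#' distances, on the scale of the first RDF peak position.
#'
#' @param cell a converged [voronoi_cell()].
#' @return a one-row data.frame of class `cell_metrics` with columns
#'   `nf`, `nv`, `ne`, `volume`, `surface`, `cage_radius`, `rw`, `rw_doubled`,
#'   `alpha`.
#' @export
cell_metrics <- function(cell) {
  stopifnot(inherits(cell, "voronoi_cell"))
  if (!isTRUE(cell$converged))
    stop("cell did not converge; metrics are undefined")
  if (cell$surface <= 0 || cell$volume <= 0)
    stop("degenerate cell with zero area or volume")
  if (abs(cell$volume - cell$volume_alt) >
      1e-8 * max(cell$volume, .Machine$double.xmin))
    stop("internal consistency failure: pyramid and divergence-theorem ",
         "volumes disagree")
  rw <- 3 * cell$volume / cell$surface
  out <- data.frame(
    nf = cell$nf, nv = cell$nv, ne = cell$ne,
    volume = cell$volume, surface = cell$surface,
    cage_radius = max(cell$face_d, na.rm = TRUE),
    rw = rw, rw_doubled = 2 * rw,
    alpha = asphericity(cell$surface, cell$volume))
  class(out) <- c("cell_metrics", "data.frame")
  out
}

#' Voronoi tessellation of every site of a frame
#'
#' Constructs the cell of every site.  For a complete tessellation the cell
#' volumes partition the box: `sum(volume) == box_length^3` (space-filling
#' check used by the test suite).
#'
#' @param config an oxygen-only [configuration()].
#' @param params a [vp_params()].
#' @return data.frame with one row per site: `site`, `nf`, `nv`, `ne`,
#'   `volume`, `surface`, `cage_radius`, `rw`, `rw_doubled`, `alpha`,
#'   `converged`.
#' @export
tessellate_all <- function(config, params = vp_params()) {
  stopifnot(inherits(config, "configuration"))
  n <- nrow(config$positions)
  L <- config$box_length
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    res <- tryCatch(
      .vp_build(config$positions, i, L, params, return_faces = FALSE),
      error = function(e) stop("site ", i, ": ", conditionMessage(e),
                               call. = FALSE))
    rw <- 3 * res$volume / res$surface
    rows[[i]] <- data.frame(
      site = i, nf = res$nf, nv = res$nv, ne = res$ne,
      volume = res$volume, surface = res$surface,
      cage_radius = if (all(is.na(res$face_d))) NA_real_
                    else max(res$face_d, na.rm = TRUE),
      rw = rw, rw_doubled = 2 * rw,
      alpha = asphericity(res$surface, res$volume),
      converged = res$converged)
  }
  do.call(rbind, rows)
}

#' Per-frame solvation-shell descriptors of a trajectory
#'
#' Applies [select_oxygens()], [voronoi_cell()] and [cell_metrics()] to the
#' solute site of every frame.  Frames whose cell does not converge within
#' the image-shell budget are kept in the table with `converged = FALSE` and
#' `NA` metrics; they are excluded from downstream statistics but counted in
#' the `skipped` attribute.
#'
#' @param frames list of [configuration()] objects.
#' @param params a [vp_params()].
#' @return data.frame with one row per frame (`frame`, descriptor columns,
#'   `converged`); attribute `skipped` holds the non-converged frame count.
#' @export
analyze_trajectory <- function(frames, params = vp_params()) {
  if (inherits(frames, "configuration")) frames <- list(frames)
  if (!length(frames)) stop("no frames supplied")
  rows <- vector("list", length(frames))
  skipped <- 0L
  for (k in seq_along(frames)) {
    oxy <- select_oxygens(frames[[k]])
    cell <- withCallingHandlers(
      voronoi_cell(oxy, params = params),
      warning = function(w) invokeRestart("muffleWarning"))
    if (cell$converged) {
      m <- cell_metrics(cell)
      rows[[k]] <- cbind(frame = k, as.data.frame(m), converged = TRUE)
    } else {
      skipped <- skipped + 1L
      rows[[k]] <- data.frame(frame = k, nf = NA_integer_, nv = NA_integer_,
                              ne = NA_integer_, volume = NA_real_,
                              surface = NA_real_, cage_radius = NA_real_,
                              rw = NA_real_, rw_doubled = NA_real_,
                              alpha = NA_real_, converged = FALSE)
    }
  }
  if (skipped == length(frames))
    stop("no frame produced a converged solute cell")
  out <- do.call(rbind, rows)
  attr(out, "skipped") <- skipped
  out
}

#' Write per-frame cell metrics as CSV
#'
#' Header: `frame,N_F,N_V,N_E,V_A3,S_tot_A2,R_A,Rw_A,Rw2_A,alpha,converged`.
#'
#' @param metrics output of [analyze_trajectory()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metrics_csv <- function(metrics, path) {
  out <- data.frame(frame = metrics$frame, N_F = metrics$nf, N_V = metrics$nv,
                    N_E = metrics$ne, V_A3 = metrics$volume,
                    S_tot_A2 = metrics$surface, R_A = metrics$cage_radius,
                    Rw_A = metrics$rw, Rw2_A = metrics$rw_doubled,
                    alpha = metrics$alpha, converged = metrics$converged)
  write.table(out, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
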