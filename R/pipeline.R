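#' Resolved run configuration
#'
#' Collects every knob of an analysis run in one serializable list: the input
#' (a trajectory file or a [fixture_spec()]), solute selection, Voronoi
#' tolerances, RDF binning, statistics options, output directory and master
#' seed.  The resolved configuration is written alongside the outputs so that
#' a run can be reproduced from its own artifacts.
#'
#' @param input path to an (extended-)XYZ trajectory, or `NULL` when
#'   `fixture` is given.
#' @param fixture a [fixture_spec()], or `NULL` when `input` is given.
#' @param n_frames frames to generate when using a fixture.
#' @param box_length box edge for plain-XYZ input (Angstrom).
#' @param solute_index,solute_species solute selection (explicit index wins).
#' @param vp a [vp_params()].
#' @param bin_width,r_cut,onset_threshold,smoothing_window RDF options, see
#'   [compute_rdf()] and [find_peak_features()].
#' @param out_dir output directory.
#' @param seed master seed.
#' @return list of class `run_config`.
#' @export
run_config <- function(input = NULL, fixture = NULL, n_frames = 50L,
                       box_length = NULL, solute_index = NULL,
                       solute_species = "Or", vp = vp_params(),
                       bin_width = 0.05, r_cut = NULL,
                       onset_threshold = 0.01, smoothing_window = 5L,
                       out_dir = ".", seed = 1L) {
  if (is.null(input) == is.null(fixture))
    stop("give exactly one of `input` or `fixture`")
  structure(list(input = input, fixture = fixture,
                 n_frames = as.integer(n_frames), box_length = box_length,
                 solute_index = solute_index, solute_species = solute_species,
                 vp = vp, bin_width = bin_width, r_cut = r_cut,
                 onset_threshold = onset_threshold,
                 smoothing_window = as.integer(smoothing_window),
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

.load_frames <- function(config) {
  if (!is.null(config$input)) {
    if (!file.exists(config$input))
      stop("input file not found: ", config$input)
    read_xyz(config$input, box_length = config$box_length,
             solute_index = config$solute_index,
             solute_species = config$solute_species)
  } else {
    spec <- config$fixture
    spec$seed <- config$seed
    make_trajectory(spec, config$n_frames)
  }
}

#' Run the full solvation-shell analysis
#'
#' Orchestrates the complete workflow on one set of frames: solute Voronoi
#' cells and their descriptors, the solute--solvent RDF with first-peak
#' features and coordination numbers, a distribution summary per descriptor,
#' and the descriptor-versus-RDF comparison row.  All outputs are written
#' under `config$out_dir`:
#' \itemize{
#'   \item `cell_metrics.csv` -- per-frame descriptors,
#'   \item `rdf.tsv` and `rdf_features.json` -- the 1D baseline,
#'   \item `summary_<descriptor>.json` -- distribution summaries,
#'   \item `comparison.tsv` -- the cross-view row,
#'   \item `run_config.json` and `manifest.json` -- reproducibility records.
#' }
#'
#' @param config a [run_config()].
#' @return invisibly, a list with `metrics`, `rdf`, `summaries`, `comparison`.
#' @export
run_analyze <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  frames <- .load_frames(config)
  metrics <- analyze_trajectory(frames, config$vp)
  rdf <- compute_rdf(frames, bin_width = config$bin_width,
                     r_cut = config$r_cut)
  rdf <- suppressWarnings(
    find_peak_features(rdf, config$onset_threshold, config$smoothing_window))
  ok <- metrics[metrics$converged %in% TRUE, , drop = FALSE]
  descriptors <- c("nf", "volume", "surface", "cage_radius", "rw", "alpha")
  # distribution summaries need >= 4 converged frames
  summaries <- if (nrow(ok) >= 4L) {
    s <- lapply(descriptors, function(col)
      summarize_distribution(ok[[col]], integer_bins = col == "nf"))
    names(s) <- descriptors
    s
  } else list()
  comparison <- compare_states(list(run = list(metrics = metrics, rdf = rdf)))

  write_metrics_csv(metrics, file.path(config$out_dir, "cell_metrics.csv"))
  write_rdf_tsv(rdf, file.path(config$out_dir, "rdf.tsv"))
  jsonlite::write_json(
    list(R0 = rdf$R0, Rmax = rdf$Rmax, Rmin = rdf$Rmin,
         n_at_Rmax = rdf$n_at_Rmax, n_at_Rmin = rdf$n_at_Rmin,
         rho = rdf$rho, n_frames = rdf$n_frames),
    file.path(config$out_dir, "rdf_features.json"),
    auto_unbox = TRUE, digits = NA, na = "null")
  for (col in names(summaries))
    write_summary_json(summaries[[col]],
                       file.path(config$out_dir,
                                 paste0("summary_", col, ".json")))
  write.table(comparison, file.path(config$out_dir, "comparison.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  cfg <- config
  cfg$vp <- unclass(cfg$vp)
  if (!is.null(cfg$fixture)) cfg$fixture <- unclass(cfg$fixture)
  jsonlite::write_json(unclass(cfg),
                       file.path(config$out_dir, "run_config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  jsonlite::write_json(
    list(package = "voroshell",
         version = as.character(utils::packageVersion("voroshell")),
         seed = config$seed, n_frames = length(frames),
         n_nonconverged = attr(metrics, "skipped")),
    file.path(config$out_dir, "manifest.json"), auto_unbox = TRUE)
  invisible(list(metrics = metrics, rdf = rdf, summaries = summaries,
                 comparison = comparison))
}

#' Analyze a sweep of thermodynamic states
#'
#' Runs [run_analyze()] for each of several state presets (rows of
#' [thermo_states()]-like data), generating a liquid fixture at each state's
#' density, and collects the per-state comparison rows into one table in
#' input order.  A state that fails is recorded in the manifest and skipped;
#' the remaining states still run.
#'
#' @param states data.frame with columns `temperature_K`, `density_kgL`
#'   (e.g. a subset of [thermo_states()]); at least 2 rows.
#' @param n number of sites per frame.
#' @param n_frames frames per state.
#' @param out_dir output root; each state gets a subdirectory.
#' @param seed master seed (each state uses `seed + row - 1`).
#' @param ... passed to [run_config()].
#' @return data.frame: one comparison row per successful state.
#' @export
run_states_sweep <- function(states, n = 401L, n_frames = 25L,
                             out_dir = ".", seed = 1L, ...) {
  if (nrow(states) < 2L) stop("a sweep needs at least 2 states")
  rows <- list()
  failures <- list()
  for (i in seq_len(nrow(states))) {
    label <- sprintf("T%03dK_rho%0.3f", round(states$temperature_K[i]),
                     states$density_kgL[i])
    res <- tryCatch({
      cfg <- run_config(
        fixture = fixture_spec("liquid", n = n,
                               density = states$density_kgL[i]),
        n_frames = n_frames, out_dir = file.path(out_dir, label),
        seed = seed + i - 1L, ...)
      out <- run_analyze(cfg)
      row <- out$comparison
      row$state <- label
      row$temperature_K <- states$temperature_K[i]
      row$density_kgL <- states$density_kgL[i]
      row
    }, error = function(e) {
      failures[[label]] <<- conditionMessage(e)
      NULL
    })
    if (!is.null(res)) rows[[label]] <- res
  }
  if (!length(rows)) stop("every state failed")
  jsonlite::write_json(list(failed_states = failures),
                       file.path(out_dir, "sweep_manifest.json"),
                       auto_unbox = TRUE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
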