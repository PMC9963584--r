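#' Read trajectory frames from an (extended-)XYZ file
#'
#' Supports plain XYZ (atom count / comment / `species x y z` records, the box
#' edge supplied through `box_length`) and extended-XYZ with a cubic
#' `Lattice="L 0 0 0 L 0 0 0 L"` comment line.  Multiple frames concatenated
#' in one file become one [configuration()] each.  Non-cubic lattices are
#' rejected rather than silently orthogonalized.
#'
#' @param path path to the file.
#' @param box_length cubic box edge in Angstrom; required for plain XYZ,
#'   overrides the header when given for extended-XYZ.
#' @param solute_index explicit 1-based solute index (applies to all frames),
#'   or `NULL` to resolve from `solute_species`.
#' @param solute_species species label marking the solute (default `"Or"`).
#' @return list of `configuration` objects, one per frame.
#' @seealso [write_xyz()]
#' @export
read_xyz <- function(path, box_length = NULL, solute_index = NULL,
                     solute_species = "Or") {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 1L)
      stop("parse error at line ", i, ": expected atom count, got '",
           lines[i], "'")
    if (i + 1L + n > length(lines))
      stop("parse error at line ", i, ": frame declares ", n,
           " atoms but the file ends after ",
           length(lines) - i - 1L, " atom records")
    comment <- lines[i + 1L]
    L <- box_length
    lat <- regmatches(comment,
                      regexpr('Lattice="[^"]*"', comment, perl = TRUE))
    if (length(lat) == 1L && is.null(box_length)) {
      vals <- as.numeric(strsplit(trimws(sub('Lattice="([^"]*)"', "\\1", lat)),
                                  "\\s+")[[1]])
      if (length(vals) != 9L)
        stop("parse error at line ", i + 1L, ": Lattice header needs 9 numbers")
      M <- matrix(vals, 3, 3, byrow = TRUE)
      off <- M[row(M) != col(M)]
      if (any(abs(off) > 1e-10) || abs(M[1, 1] - M[2, 2]) > 1e-10 ||
          abs(M[1, 1] - M[3, 3]) > 1e-10)
        stop("non-cubic lattice at line ", i + 1L,
             ": only cubic boxes are supported")
      L <- M[1, 1]
    }
    if (is.null(L))
      stop("no box length: frame at line ", i,
           " has no cubic Lattice header and `box_length` was not given")
    rec <- strsplit(trimws(lines[(i + 2L):(i + 1L + n)]), "\\s+")
    bad <- which(vapply(rec, length, 1L) < 4L)
    if (length(bad))
      stop("parse error at line ", i + 1L + bad[1],
           ": expected 'species x y z'")
    sp <- vapply(rec, `[[`, "", 1L)
    pos <- matrix(as.numeric(unlist(lapply(rec, `[`, 2:4))),
                  ncol = 3, byrow = TRUE)
    if (anyNA(pos))
      stop("parse error in frame at line ", i, ": non-numeric coordinate")
    frames[[length(frames) + 1L]] <-
      configuration(pos, L, species = sp, solute_index = solute_index,
                    solute_species = solute_species)
    i <- i + 2L + n
  }
  if (!length(frames)) stop("no frames found in ", path)
  frames
}

#' Write configurations as extended-XYZ
#'
#' Writes one extended-XYZ frame per configuration, with a cubic `Lattice`
#' header and `Properties=species:S:1:pos:R:3`.  Coordinates are printed with
#' nine decimal places so that a read/write round trip reproduces positions to
#' 1e-9 Angstrom.
#'
#' @param frames a `configuration` or list of them.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(frames, path) {
  if (inherits(frames, "configuration")) frames <- list(frames)
  out <- character(0)
  for (f in frames) {
    L <- f$box_length
    hdr <- sprintf(
      'Lattice="%.9f 0.0 0.0 0.0 %.9f 0.0 0.0 0.0 %.9f" Properties=species:S:1:pos:R:3',
      L, L, L)
    body <- sprintf("%s %.9f %.9f %.9f", f$species,
                    f$positions[, 1], f$positions[, 2], f$positions[, 3])
    out <- c(out, as.character(nrow(f$positions)), hdr, body)
  }
  writeLines(out, path)
  invisible(path)
}
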