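#' Write a trajectory as an XYZ file
#'
#' Standard XYZ layout: atom count, one comment line encoding the simulation
#' parameters, then one \code{"C x y z"} line per visited position in visit
#' order. Coordinates are in units of the step distance, 6 decimal places.
#' Output is byte-for-byte deterministic for identical inputs.
#'
#' @param trajectory a \code{sirw_trajectory}, or an n x 3 position matrix.
#' @param path output file.
#' @param comment overrides the parameter comment line.
#' @export
write_xyz <- function(trajectory, path, comment = NULL) {
  pos <- as_points(trajectory)
  if (is.null(comment)) {
    comment <- if (inherits(trajectory, "sirw_trajectory")) {
      p <- trajectory$params
      sprintf("sirw T=%g epsilon=%g r0=%g d0=%g seed=%d rule=%s",
              p$temperature, p$epsilon, p$r0, p$d0, p$seed, p$rule)
    } else "sirw positions"
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(as.character(nrow(pos)), comment,
               sprintf("C %.6f %.6f %.6f", pos[, 1], pos[, 2], pos[, 3])),
             con)
  invisible(path)
}

#' Write a trajectory as a PDB alpha-carbon trace
#'
#' One CA atom per visited position (residue numbers from 1, chain A, no
#' CONECT records; molecular viewers infer the trace). The default scale of
#' 3.8 Angstrom per step length is the standard alpha-carbon virtual-bond
#' distance, so walks display at protein-like dimensions; the scale is
#' recorded in a REMARK.
#'
#' @param trajectory a \code{sirw_trajectory} or n x 3 matrix (step-length
#'   units).
#' @param path output file.
#' @param scale Angstrom per unit step distance.
#' @export
write_pdb <- function(trajectory, path, scale = 3.8) {
  pos <- as_points(trajectory) * scale
  lines <- c(
    sprintf("REMARK   1 SELF-INTERACTING WALK CA TRACE, SCALE %.3f ANGSTROM PER STEP",
            scale),
    if (inherits(trajectory, "sirw_trajectory"))
      sprintf("REMARK   1 T=%g EPSILON=%g R0=%g SEED=%d",
              trajectory$params$temperature, trajectory$params$epsilon,
              trajectory$params$r0, trajectory$params$seed),
    sprintf("ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
            seq_len(nrow(pos)), seq_len(nrow(pos)),
            pos[, 1], pos[, 2], pos[, 3]),
    "END")
  writeLines(lines, path)
  invisible(path)
}

#' Read an ordered 3D point list from XYZ or PDB
#'
#' For PDB input, CA atoms of the first chain encountered are taken in
#' record order; coordinates are returned exactly as stored (no unit
#' conversion — the helix metrics are scale-invariant and the radius of
#' gyration scales linearly, so rescale afterwards if step-length units are
#' needed).
#'
#' @param path input file.
#' @param format \code{"auto"} (by extension), \code{"xyz"} or \code{"pdb"}.
#' @return n x 3 numeric matrix.
#' @export
read_positions <- function(path, format = c("auto", "xyz", "pdb")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("pdb", "ent")) "pdb" else "xyz"
  }
  if (!file.exists(path)) stop(sprintf("cannot read '%s': no such file", path))
  lines <- readLines(path)
  if (length(lines) == 0L) stop(sprintf("parse error in '%s': empty file", path))
  if (format == "xyz") read_xyz_lines(lines, path) else read_pdb_lines(lines, path)
}

read_xyz_lines <- function(lines, path) {
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || n < 1)
    stop(sprintf("parse error in '%s' at line 1: expected an atom count", path))
  if (length(lines) < n + 2L)
    stop(sprintf("parse error in '%s': %d atom lines expected, %d found",
                 path, n, length(lines) - 2L))
  pos <- matrix(NA_real_, n, 3L)
  for (i in seq_len(n)) {
    tok <- strsplit(trimws(lines[i + 2L]), "[[:space:]]+")[[1]]
    if (length(tok) < 4L)
      stop(sprintf("parse error in '%s' at line %d: expected 'elem x y z'",
                   path, i + 2L))
    xyz <- suppressWarnings(as.numeric(tok[2:4]))
    if (anyNA(xyz))
      stop(sprintf("parse error in '%s' at line %d: non-numeric coordinates",
                   path, i + 2L))
    pos[i, ] <- xyz
  }
  pos
}

read_pdb_lines <- function(lines, path) {
  atoms <- lines[startsWith(lines, "ATOM  ") | startsWith(lines, "HETATM")]
  name <- trimws(substr(atoms, 13, 16))
  ca <- atoms[name == "CA"]
  if (length(ca) == 0L)
    stop(sprintf("empty input: no CA atoms in '%s'", path))
  chain <- substr(ca, 22, 22)
  ca <- ca[chain == chain[1]]
  pos <- cbind(as.numeric(substr(ca, 31, 38)),
               as.numeric(substr(ca, 39, 46)),
               as.numeric(substr(ca, 47, 54)))
  if (anyNA(pos))
    stop(sprintf("parse error in '%s': malformed ATOM coordinates", path))
  pos
}

#' Read / write a run configuration
#'
#' A run configuration is a flat list of [walk_params()] fields plus optional
#' \code{n_runs}, grids and output settings, stored as YAML or JSON; it
#' round-trips through serialization without loss.
#'
#' @param path file ending in \code{.yaml}/\code{.yml} or \code{.json}.
#' @return \code{read_run_config}: named list. \code{write_run_config}: the
#'   path, invisibly.
#' @export
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.list(cfg)) stop(sprintf("parse error in '%s': expected a mapping", path))
  cfg
}

#' @rdname read_run_config
#' @param config named list of settings.
#' @export
write_run_config <- function(config, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) yaml::write_yaml(config, path)
  else writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                                   pretty = TRUE), path)
  invisible(path)
}
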