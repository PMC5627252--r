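#' @importFrom stats rnorm runif sd setNames aggregate
#' @importFrom utils read.table write.table head tail
NULL

# Residue-name tables used to partition a structure into protein / glycan /
# other.  The carbohydrate table covers PDB three-letter codes and the
# CHARMM-style names written by glycan-aware builders.
.PROTEIN_RESNAMES <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "HSD",
  "HSE", "HSP", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR",
  "TRP", "TYR", "VAL"
)

.DEFAULT_CARB_RESNAMES <- c(
  "NAG", "BMA", "MAN", "BGC", "GLC", "GAL", "FUC", "FUL", "SIA", "NDG",
  "AGLC", "BGLC", "AMAN", "BMAN", "AGAL", "BGAL", "BGLN", "BGLCNA", "AFUC"
)

#' Construct a molecular system from an atom table
#'
#' A `fc_system` is the topology container every descriptor operates on: an
#' ordered atom table partitioned into chains and residues, with each residue
#' tagged as `protein`, `glycan` or `other`.
#'
#' @param atoms data frame with columns `serial`, `name`, `element`,
#'   `chain_id`, `residue_number`, `insert` (insertion code, `""` if none),
#'   `residue_name`, `x`, `y`, `z`. An `is_heavy` column is derived from
#'   `element`.
#' @param carb_resnames residue names recognised as carbohydrate.
#' @return an object of class `fc_system`.
#' @export
molecular_system <- function(atoms, carb_resnames = .DEFAULT_CARB_RESNAMES) {
  required <- c("serial", "name", "element", "chain_id", "residue_number",
                "insert", "residue_name", "x", "y", "z")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols) > 0)
    stop("atom table lacks columns: ", paste(missing_cols, collapse = ", "))
  if (nrow(atoms) == 0)
    stop("empty structure: no atoms")
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("non-finite atom coordinates")

  atoms$element <- toupper(trimws(atoms$element))
  atoms$is_heavy <- atoms$element != "H" & atoms$element != "D"
  atoms$residue_key <- paste0(atoms$chain_id, "/", atoms$residue_number,
                              atoms$insert)

  res_first <- !duplicated(atoms$residue_key)
  residues <- data.frame(
    residue_key    = atoms$residue_key[res_first],
    chain_id       = atoms$chain_id[res_first],
    residue_number = atoms$residue_number[res_first],
    insert         = atoms$insert[res_first],
    residue_name   = toupper(trimws(atoms$residue_name[res_first])),
    stringsAsFactors = FALSE
  )
  residues$component <- ifelse(
    residues$residue_name %in% toupper(carb_resnames), "glycan",
    ifelse(residues$residue_name %in% .PROTEIN_RESNAMES, "protein", "other")
  )

  structure(
    list(atoms = atoms, residues = residues,
         chains = sort(unique(atoms$chain_id))),
    class = "fc_system"
  )
}

#' @export
print.fc_system <- function(x, ...) {
  comp <- table(x$residues$component)
  cat("fc_system:", nrow(x$atoms), "atoms,", nrow(x$residues), "residues,",
      length(x$chains), "chain(s) [", paste(x$chains, collapse = ", "), "]\n")
  cat("  residues by component:",
      paste(names(comp), as.integer(comp), sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Number of atoms in a system
#' @param system an `fc_system`.
#' @return integer atom count.
#' @export
n_atoms <- function(system) {
  stopifnot(inherits(system, "fc_system"))
  nrow(system$atoms)
}

#' Coordinates of a system as an n x 3 matrix
#' @param system an `fc_system`.
#' @return numeric matrix with columns x, y, z (Angstrom).
#' @export
system_coords <- function(system) {
  stopifnot(inherits(system, "fc_system"))
  m <- as.matrix(system$atoms[, c("x", "y", "z")])
  dimnames(m) <- NULL
  m
}

# Component tag for every atom (looked up through its residue).
atom_components <- function(system) {
  comp <- setNames(system$residues$component, system$residues$residue_key)
  unname(comp[system$atoms$residue_key])
}

#' Construct a trajectory
#'
#' A `fc_trajectory` couples one topology with an ordered stack of coordinate
#' frames and per-frame times.
#'
#' @param topology an `fc_system`.
#' @param coords numeric array of dimension `c(n_atoms, 3, n_frames)`,
#'   Angstrom.
#' @param times numeric vector of per-frame times in ns; defaults to
#'   `frame_dt_ns * (0:(n_frames-1))`.
#' @param frame_dt_ns frame interval used when `times` is absent. The default
#'   0.24 ns matches a 240 ps trajectory save interval.
#' @return an object of class `fc_trajectory`.
#' @export
trajectory <- function(topology, coords, times = NULL, frame_dt_ns = 0.24) {
  stopifnot(inherits(topology, "fc_system"))
  if (length(dim(coords)) != 3 || dim(coords)[2] != 3)
    stop("coords must be an n_atoms x 3 x n_frames array")
  if (dim(coords)[1] != n_atoms(topology))
    stop("coords atom count (", dim(coords)[1],
         ") does not match topology (", n_atoms(topology), ")")
  n_frames <- dim(coords)[3]
  if (is.null(times)) times <- frame_dt_ns * (seq_len(n_frames) - 1)
  if (length(times) != n_frames)
    stop("times length does not match frame count")
  if (n_frames > 1 && any(diff(times) <= 0))
    stop("frame times must be strictly increasing")
  structure(list(topology = topology, coords = coords, times = times),
            class = "fc_trajectory")
}

#' @export
print.fc_trajectory <- function(x, ...) {
  cat("fc_trajectory:", n_frames(x), "frames x", dim(x$coords)[1], "atoms, ",
      sprintf("t = %.3f..%.3f ns\n", x$times[1], x$times[n_frames(x)]))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj an `fc_trajectory`.
#' @return integer frame count.
#' @export
n_frames <- function(traj) {
  stopifnot(inherits(traj, "fc_trajectory"))
  dim(traj$coords)[3]
}

#' Coordinates of one frame
#' @param traj an `fc_trajectory`.
#' @param i frame index (1-based).
#' @return n_atoms x 3 coordinate matrix, Angstrom.
#' @export
frame_coords <- function(traj, i) {
  stopifnot(inherits(traj, "fc_trajectory"))
  if (i < 1 || i > n_frames(traj)) stop("frame index out of range: ", i)
  m <- traj$coords[, , i, drop = TRUE]
  dim(m) <- c(dim(traj$coords)[1], 3)
  m
}

#' Construct a per-frame descriptor series
#'
#' @param frame integer frame indices.
#' @param time_ns per-frame times, ns.
#' @param value per-frame scalar values (or labels).
#' @param units unit string, e.g. `"A"` or `"deg"`.
#' @param label human-readable description of the descriptor.
#' @return a data frame of class `fc_series` with columns
#'   `frame`, `time_ns`, `value` and attributes `units`, `label`.
#' @export
descriptor_series <- function(frame, time_ns, value, units = "A",
                              label = "descriptor") {
  stopifnot(length(frame) == length(time_ns), length(frame) == length(value))
  out <- data.frame(frame = frame, time_ns = time_ns, value = value)
  attr(out, "units") <- units
  attr(out, "label") <- label
  class(out) <- c("fc_series", "data.frame")
  out
}

#' @export
print.fc_series <- function(x, ...) {
  cat(sprintf("fc_series '%s' (%s): %d frames\n",
              attr(x, "label"), attr(x, "units"), nrow(x)))
  if (is.numeric(x$value))
    cat(sprintf("  range %.4g .. %.4g, mean %.4g\n",
                min(x$value), max(x$value), mean(x$value)))
  invisible(x)
}
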