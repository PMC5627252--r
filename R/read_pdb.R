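#' Read a PDB structure into a molecular system
#'
#' Parses ATOM/HETATM records (first MODEL only) and partitions residues into
#' protein and glycan components. Alternate locations are resolved by keeping
#' the highest-occupancy record (ties: first in file); insertion codes are
#' folded into the residue key; hydrogens are retained but flagged so that
#' heavy-atom-only selections (the default for every descriptor) exclude them.
#'
#' @param path path to a PDB file.
#' @param carb_resnames residue names treated as carbohydrate; the default
#'   covers PDB codes (NAG/BMA/MAN/...) and CHARMM-style names.
#' @return an `fc_system`.
#' @export
read_pdb <- function(path, carb_resnames = .DEFAULT_CARB_RESNAMES) {
  if (!file.exists(path)) stop("no such file: ", path)
  pdb <- tryCatch(
    bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE),
    error = function(e) stop("PDB parse error in '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0) stop("empty structure: ", path)

  # altloc: keep highest occupancy per (residue, atom name), tie -> first.
  alt <- at$alt
  alt[is.na(alt)] <- ""
  if (any(alt != "")) {
    occ <- at$o
    occ[is.na(occ)] <- 1
    key <- paste(at$chain, at$resno, at$insert, at$resid, at$elety, sep = "|")
    ord <- order(key, -occ, seq_len(nrow(at)))
    keep <- ord[!duplicated(key[ord])]
    at <- at[sort(keep), , drop = FALSE]
  }

  elem <- at$elesy
  elem[is.na(elem) | trimws(elem) == ""] <-
    .element_from_name(at$elety[is.na(elem) | trimws(elem) == ""])
  ins <- at$insert
  ins[is.na(ins)] <- ""
  chain <- at$chain
  chain[is.na(chain)] <- " "

  atoms <- data.frame(
    serial = at$eleno,
    name = trimws(at$elety),
    element = elem,
    chain_id = chain,
    residue_number = at$resno,
    insert = ins,
    residue_name = trimws(at$resid),
    x = at$x, y = at$y, z = at$z,
    stringsAsFactors = FALSE
  )
  molecular_system(atoms, carb_resnames = carb_resnames)
}

# Infer the element symbol from a PDB atom name when columns 77-78 are blank.
.element_from_name <- function(name) {
  name <- trimws(name)
  vapply(name, function(nm) {
    if (nm == "") return("X")
    # strip leading digits (e.g. "1HB1")
    nm2 <- sub("^[0-9]+", "", nm)
    first <- toupper(substr(nm2, 1, 1))
    if (first == "H") "H" else first
  }, character(1), USE.NAMES = FALSE)
}

#' Read a trajectory from a multi-model PDB or DCD file
#'
#' @param path trajectory file; format is inferred from the extension
#'   (`.dcd` for CHARMM/NAMD DCD, anything else is read as multi-model PDB)
#'   unless `format` is given.
#' @param topology the `fc_system` the frames belong to.
#' @param frame_dt_ns frame time interval (ns) used to construct frame times;
#'   neither container stores times, so the default mirrors a 240 ps save
#'   interval.
#' @param format `"dcd"`, `"pdb"` or `NULL` (infer).
#' @return an `fc_trajectory`.
#' @export
read_trajectory <- function(path, topology, frame_dt_ns = 0.24,
                            format = NULL) {
  stopifnot(inherits(topology, "fc_system"))
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0) stop("empty trajectory file: ", path)
  if (is.null(format))
    format <- if (grepl("\\.dcd$", path, ignore.case = TRUE)) "dcd" else "pdb"

  nat <- n_atoms(topology)
  if (format == "dcd") {
    xyz <- bio3d::read.dcd(path, verbose = FALSE)
  } else {
    pdb <- tryCatch(
      bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
      error = function(e) stop("trajectory PDB parse error in '", path,
                               "': ", conditionMessage(e), call. = FALSE)
    )
    xyz <- pdb$xyz
  }
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  nf <- nrow(xyz)
  if (nf == 0) stop("no frames in trajectory: ", path)
  if (ncol(xyz) != 3 * nat)
    stop("frame 1 atom count (", ncol(xyz) / 3,
         ") does not match topology (", nat, ")")

  coords <- array(0, dim = c(nat, 3, nf))
  for (t in seq_len(nf))
    coords[, , t] <- matrix(xyz[t, ], ncol = 3, byrow = TRUE)
  trajectory(topology, coords, frame_dt_ns = frame_dt_ns)
}

#' Write a trajectory as a multi-model PDB file
#'
#' Plain-text companion to [write_dcd()]; coordinates are written with
#' the standard fixed-format 3-decimal precision.
#'
#' @param traj an `fc_trajectory`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_multimodel_pdb <- function(traj, path) {
  stopifnot(inherits(traj, "fc_trajectory"))
  at <- traj$topology$atoms
  rec <- ifelse(atom_components(traj$topology) == "protein", "ATOM  ",
                "HETATM")
  con <- file(path, "w")
  on.exit(close(con))
  nf <- n_frames(traj)
  for (t in seq_len(nf)) {
    writeLines(sprintf("MODEL     %4d", t), con)
    xyz <- frame_coords(traj, t)
    name4 <- ifelse(nchar(at$name) < 4, sprintf(" %-3s", at$name),
                    sprintf("%-4s", at$name))
    lines <- sprintf(
      "%s%5d %s %-4s%1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      rec, at$serial %% 100000L, name4, substr(at$residue_name, 1, 4),
      at$chain_id, at$residue_number %% 10000L,
      ifelse(at$insert == "", " ", at$insert),
      xyz[, 1], xyz[, 2], xyz[, 3], 1, 0, at$element
    )
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Write a trajectory as a CHARMM-dialect DCD file
#'
#' Minimal single-precision DCD writer (no unit cell, no fixed atoms),
#' readable by standard DCD readers.
#'
#' @param traj an `fc_trajectory`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dcd <- function(traj, path) {
  stopifnot(inherits(traj, "fc_trajectory"))
  nf <- n_frames(traj)
  nat <- dim(traj$coords)[1]
  con <- file(path, "wb")
  on.exit(close(con))
  wrec <- function(writer) {
    # Fortran unformatted record: payload length, payload, payload length
    raw_payload <- writer
    writeBin(as.integer(length(raw_payload)), con, size = 4,
             endian = "little")
    writeBin(raw_payload, con)
    writeBin(as.integer(length(raw_payload)), con, size = 4,
             endian = "little")
  }
  icntrl <- integer(20)
  icntrl[1] <- nf        # number of frames
  icntrl[2] <- 1L        # first step
  icntrl[3] <- 1L        # step interval
  icntrl[4] <- nf
  icntrl[20] <- 24L      # CHARMM version flag
  hdr <- c(charToRaw("CORD"), writeBin(icntrl, raw(), size = 4,
                                       endian = "little"))
  wrec(hdr)
  title <- sprintf("%-80s", "fcdyn synthetic trajectory")
  wrec(c(writeBin(1L, raw(), size = 4, endian = "little"),
         charToRaw(title)))
  wrec(writeBin(as.integer(nat), raw(), size = 4, endian = "little"))
  for (t in seq_len(nf)) {
    xyz <- frame_coords(traj, t)
    for (k in 1:3)
      wrec(writeBin(as.numeric(xyz[, k]), raw(), size = 4,
                    endian = "little"))
  }
  invisible(path)
}
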