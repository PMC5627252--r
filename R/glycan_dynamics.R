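# Per-frame minimum distance between a fixed atom set and a fixed atom set,
# vectorised over frames in the inner loop.
.min_dist_series <- function(traj, idx_a, idx_b) {
  nf <- n_frames(traj)
  out <- numeric(nf)
  for (t in seq_len(nf)) {
    fr <- traj$coords[, , t]
    out[t] <- min_heavy_distance(fr[idx_a, , drop = FALSE],
                                 fr[idx_b, , drop = FALSE])
  }
  out
}

#' Glycan-termini minimum-distance time series
#'
#' Per frame, the minimum distance between any heavy atom of any terminal
#' glycan residue of one chain's glycan and any protein heavy atom. Large
#' sharp peaks in this series flag frames where the glycan is detached from
#' the Fc surface and its termini are solvent-exposed.
#'
#' @param traj an `fc_trajectory`.
#' @param glycan_tree a structure-bound `fc_glycan_tree`.
#' @param protein_selection heavy-atom protein selection; defaults to all
#'   protein heavy atoms of the topology.
#' @return an `fc_series` in Angstrom.
#' @export
terminal_min_distance_series <- function(traj, glycan_tree,
                                         protein_selection = NULL) {
  stopifnot(inherits(traj, "fc_trajectory"),
            inherits(glycan_tree, "fc_glycan_tree"))
  if (length(glycan_tree$terminals) == 0)
    stop("chain ", glycan_tree$chain_id,
         " carries no glycan terminals (aglycosylated); skip this chain")
  sys <- traj$topology
  if (is.null(protein_selection))
    protein_selection <- select_atoms(sys, component = "protein",
                                      heavy_only = TRUE)
  term_atoms <- unlist(lapply(glycan_tree$terminals, function(i)
    glycan_residue_atoms(sys, glycan_tree, i, heavy_only = TRUE)))
  if (length(term_atoms) == 0) stop("no heavy atoms in terminal residues")
  vals <- .min_dist_series(traj, term_atoms, as.integer(protein_selection))
  descriptor_series(seq_len(n_frames(traj)), traj$times, vals, units = "A",
                    label = sprintf("terminal min distance (chain %s)",
                                    glycan_tree$chain_id))
}

#' Glycan residue-by-frame contact matrix
#'
#' Boolean matrix over (glycan residue x frame): `TRUE` when the minimum
#' heavy-atom distance between that glycan residue and the protein is within
#' the cutoff (default 4.5 Angstrom).
#'
#' @param traj an `fc_trajectory`.
#' @param glycan_tree a structure-bound `fc_glycan_tree`.
#' @param protein_selection heavy-atom protein selection (default: all
#'   protein heavy atoms).
#' @param cutoff contact cutoff, Angstrom.
#' @return logical matrix of class `fc_contact_matrix`, rownames = glycan
#'   indices, with attributes `cutoff` and `chain_id`.
#' @export
residue_contact_matrix <- function(traj, glycan_tree,
                                   protein_selection = NULL, cutoff = 4.5) {
  stopifnot(inherits(traj, "fc_trajectory"),
            inherits(glycan_tree, "fc_glycan_tree"))
  if (cutoff <= 0) stop("cutoff must be positive")
  if (length(glycan_tree$indices) == 0)
    stop("chain ", glycan_tree$chain_id, " carries no glycan")
  sys <- traj$topology
  if (is.null(protein_selection))
    protein_selection <- select_atoms(sys, component = "protein",
                                      heavy_only = TRUE)
  prot <- as.integer(protein_selection)
  nf <- n_frames(traj)
  m <- matrix(FALSE, nrow = length(glycan_tree$indices), ncol = nf,
              dimnames = list(glycan_tree$indices, NULL))
  for (r in seq_along(glycan_tree$indices)) {
    atoms_r <- glycan_residue_atoms(sys, glycan_tree,
                                    glycan_tree$indices[r],
                                    heavy_only = TRUE)
    m[r, ] <- .min_dist_series(traj, atoms_r, prot) <= cutoff
  }
  structure(m, class = c("fc_contact_matrix", "matrix"),
            cutoff = cutoff, chain_id = glycan_tree$chain_id)
}

#' Detect glycan detachment events in a minimum-distance series
#'
#' Maximal runs of consecutive frames whose terminal minimum distance
#' exceeds the threshold (default 9 Angstrom, the criterion for frames where
#' most glycan residues are detached from the Fc surface).
#'
#' @param series an `fc_series` (or numeric vector) of minimum distances.
#' @param threshold detachment threshold, Angstrom.
#' @param min_duration minimum event length in frames.
#' @return data frame with columns `start_frame`, `end_frame`,
#'   `peak_distance`, sorted by `start_frame` (zero rows if no events).
#' @export
detect_detachment_events <- function(series, threshold = 9.0,
                                     min_duration = 1L) {
  if (threshold <= 0) stop("threshold must be positive")
  vals <- if (is.data.frame(series)) series$value else as.numeric(series)
  above <- vals > threshold
  events <- data.frame(start_frame = integer(0), end_frame = integer(0),
                       peak_distance = numeric(0))
  if (!any(above)) return(events)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_duration
  if (!any(keep)) return(events)
  starts <- starts[keep]; ends <- ends[keep]
  peaks <- mapply(function(s, e) max(vals[s:e]), starts, ends)
  data.frame(start_frame = starts, end_frame = ends, peak_distance = peaks)
}

#' Per-residue bound fraction from a contact matrix
#'
#' @param contact_matrix an `fc_contact_matrix`.
#' @return named numeric vector: fraction of frames in contact per glycan
#'   residue, in \[0, 1\].
#' @export
bound_fraction <- function(contact_matrix) {
  if (length(contact_matrix) == 0) stop("empty contact matrix")
  rowMeans(unclass(contact_matrix))
}
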