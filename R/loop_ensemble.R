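#' Configuration for C'E loop analysis
#'
#' Residue ranges and thresholds for the loop descriptors and the
#' three-state classifier. All residue numbers are EU numbering as used in
#' the structure file.
#'
#' @param loop_resno C'E loop residues (Gln295-Thr299).
#' @param fit_resno Calpha superposition anchors flanking the loop.
#' @param c_prime_resno short C' beta-strand residues (classifier evidence).
#' @param e_strand_resno E-strand residues paired antiparallel with the C'
#'   strand (`c_prime_resno[i]` pairs with `rev(e_strand_resno)[i]`).
#' @param r_native loop RMSD below which an ordered-strand frame is labelled
#'   `native`, Angstrom.
#' @param s_min strand-order score below which a frame is `unstructured`.
#' @param pair_tol a strand pair counts as intact when its Calpha-Calpha
#'   distance deviates from the reference pairing distance by at most this
#'   many Angstrom.
#' @param cg2_resno Cgamma2 domain residue range (defines the inter-chain
#'   cavity axis used for the inward/outward direction).
#' @return list of class `fc_loop_config`.
#' @export
loop_config <- function(loop_resno = 295:299,
                        fit_resno = c(259:265, 301:306),
                        c_prime_resno = 290:294,
                        e_strand_resno = 304:308,
                        r_native = 3.0, s_min = 0.5, pair_tol = 6.5,
                        cg2_resno = 238:340) {
  if (length(c_prime_resno) != length(e_strand_resno))
    stop("C' and E strand ranges must pair one-to-one")
  structure(list(loop_resno = loop_resno, fit_resno = fit_resno,
                 c_prime_resno = c_prime_resno,
                 e_strand_resno = e_strand_resno,
                 r_native = r_native, s_min = s_min, pair_tol = pair_tol,
                 cg2_resno = cg2_resno),
            class = "fc_loop_config")
}

# Reference coordinates: accept an fc_system or a bare n x 3 matrix.
.ref_coords <- function(reference, traj) {
  if (inherits(reference, "fc_system")) {
    if (n_atoms(reference) != dim(traj$coords)[1])
      stop("reference atom count does not match trajectory")
    system_coords(reference)
  } else {
    reference <- as.matrix(reference)
    if (nrow(reference) != dim(traj$coords)[1])
      stop("reference atom count does not match trajectory")
    reference
  }
}

# Per-frame RMSD of `measure_sel` heavy atoms after a Calpha-anchor fit.
.rmsd_series_after_fit <- function(traj, ref_xyz, fit_sel, measure_sel,
                                   label) {
  nf <- n_frames(traj)
  vals <- numeric(nf)
  for (t in seq_len(nf))
    vals[t] <- rmsd_after_fit(frame_coords(traj, t), ref_xyz, fit_sel,
                              measure_sel)
  descriptor_series(seq_len(nf), traj$times, vals, units = "A",
                    label = label)
}

#' C'E loop RMSD time series
#'
#' Per frame: superpose the chain onto the reference using the Calpha atoms
#' of the anchor residues (259-265 and 301-306 by default), then measure the
#' RMSD of all heavy atoms of the C'E loop (295-299) under that transform.
#'
#' @param traj an `fc_trajectory`.
#' @param reference reference coordinates (`fc_system` or n x 3 matrix with
#'   the trajectory's atom order); typically the initial structure.
#' @param chain chain id.
#' @param config an [loop_config()].
#' @return an `fc_series` in Angstrom.
#' @export
ce_loop_rmsd_series <- function(traj, reference, chain,
                                config = loop_config()) {
  sys <- traj$topology
  fit_sel <- select_atoms(sys, chain = chain, resno = config$fit_resno,
                          name = "CA")
  missing <- setdiff(config$fit_resno,
                     sys$atoms$residue_number[as.integer(fit_sel)])
  if (length(missing) > 0)
    stop("chain ", chain, ": unresolved fit residues ",
         paste(missing, collapse = ","))
  loop_sel <- select_atoms(sys, chain = chain, resno = config$loop_resno,
                           heavy_only = TRUE)
  missing <- setdiff(config$loop_resno,
                     sys$atoms$residue_number[as.integer(loop_sel)])
  if (length(missing) > 0)
    stop("chain ", chain, ": unresolved loop residues ",
         paste(missing, collapse = ","))
  .rmsd_series_after_fit(traj, .ref_coords(reference, traj),
                         as.integer(fit_sel), as.integer(loop_sel),
                         sprintf("C'E loop RMSD (chain %s)", chain))
}

#' GlcNAc1 RMSD time series
#'
#' Same protocol as [ce_loop_rmsd_series()] but the measured atoms are the
#' heavy atoms of the first (asparagine-linked) GlcNAc of the chain's
#' glycan.
#'
#' @param traj an `fc_trajectory`.
#' @param reference reference coordinates (`fc_system` or n x 3 matrix).
#' @param glycan_tree structure-bound `fc_glycan_tree` of the chain.
#' @param config an [loop_config()] (for the fit anchors).
#' @return an `fc_series` in Angstrom.
#' @export
glcnac1_rmsd_series <- function(traj, reference, glycan_tree,
                                config = loop_config()) {
  stopifnot(inherits(glycan_tree, "fc_glycan_tree"))
  if (length(glycan_tree$indices) == 0 || !1 %in% glycan_tree$indices)
    stop("chain ", glycan_tree$chain_id,
         " is aglycosylated: no GlcNAc1 to measure")
  sys <- traj$topology
  chain <- glycan_tree$chain_id
  fit_sel <- select_atoms(sys, chain = chain, resno = config$fit_resno,
                          name = "CA")
  g1 <- glycan_residue_atoms(sys, glycan_tree, 1, heavy_only = TRUE)
  if (length(g1) == 0) stop("GlcNAc1 has no heavy atoms")
  .rmsd_series_after_fit(traj, .ref_coords(reference, traj),
                         as.integer(fit_sel), g1,
                         sprintf("GlcNAc1 RMSD (chain %s)", chain))
}

#' Windowed mean and SD of a descriptor series
#'
#' Arithmetic mean and population standard deviation over the frames whose
#' times fall inside the window. The default window is the last 75% of the
#' simulated time span (the analysis convention "last 1.5 us of a 2 us
#' run", generalised so it also applies to short trajectories).
#'
#' @param series an `fc_series`.
#' @param window `c(start_ns, end_ns)`, or `NULL` for the default.
#' @param last_fraction fraction of the time span used when `window` is
#'   `NULL`.
#' @return list: `mean`, `sd` (population), `window` (ns), `n_frames`,
#'   `formatted` ("mean +/- sd").
#' @export
window_summary <- function(series, window = NULL, last_fraction = 0.75) {
  stopifnot(is.data.frame(series))
  t <- series$time_ns
  if (is.null(window)) {
    t0 <- max(t) - last_fraction * (max(t) - min(t))
    window <- c(t0, max(t))
  }
  sel <- t >= window[1] & t <= window[2]
  if (!any(sel)) stop("window [", window[1], ", ", window[2],
                      "] ns does not overlap the series")
  v <- series$value[sel]
  if (length(v) < 2) stop("window contains fewer than 2 frames")
  m <- mean(v)
  s <- sqrt(mean((v - m)^2))
  list(mean = m, sd = s, window = window, n_frames = length(v),
       formatted = sprintf("%.2f \u00b1 %.2f %s", m, s,
                           attr(series, "units") %||% ""))
}

#' Strand-pairing order score
#'
#' Distance-based beta-pairing score: the fraction of expected cross-strand
#' Calpha pairs whose distance deviates from its reference pairing distance
#' by at most `pair_tol`. Chosen over DSSP-style hydrogen-bond assignment so
#' the score does not depend on hydrogen placement.
#'
#' @param frame n x 3 frame coordinates.
#' @param reference n x 3 reference coordinates.
#' @param ca_cprime,ca_e Calpha atom indices of the paired strands
#'   (`ca_cprime[i]` pairs with `rev(ca_e)[i]`).
#' @param pair_tol allowed deviation, Angstrom.
#' @return score in \[0, 1\].
#' @export
strand_order <- function(frame, reference, ca_cprime, ca_e,
                         pair_tol = 6.5) {
  if (length(ca_cprime) != length(ca_e) || length(ca_cprime) == 0)
    stop("strand index vectors must be non-empty and of equal length")
  j <- rev(ca_e)
  d_frame <- sqrt(rowSums((frame[ca_cprime, , drop = FALSE] -
                             frame[j, , drop = FALSE])^2))
  d_ref <- sqrt(rowSums((reference[ca_cprime, , drop = FALSE] -
                           reference[j, , drop = FALSE])^2))
  mean(abs(d_frame - d_ref) <= pair_tol)
}

#' Classify C'E loop conformational states along a trajectory
#'
#' Deterministic three-way decision rule applied per frame and chain,
#' operationalising the qualitative unstructured / outward-facing /
#' inward-facing snapshot classification:
#' \enumerate{
#'   \item strand order below `s_min` -> `unstructured`;
#'   \item else loop RMSD below `r_native` -> `native`;
#'   \item else the sign of the projection of the loop-centroid displacement
#'     (after the Calpha-anchor fit) onto the inter-chain cavity axis
#'     decides: toward the opposing chain's Cgamma2 centroid -> `inward_facing`,
#'     away -> `outward_facing`.
#' }
#'
#' @param traj an `fc_trajectory`.
#' @param reference reference coordinates (`fc_system` or n x 3 matrix).
#' @param chain chain to classify.
#' @param opposing_chain chain defining the cavity direction.
#' @param config an [loop_config()].
#' @return data frame: `frame`, `time_ns`, `loop_rmsd`, `strand_order`,
#'   `projection`, `state`.
#' @export
classify_loop_states <- function(traj, reference, chain, opposing_chain,
                                 config = loop_config()) {
  sys <- traj$topology
  ref <- .ref_coords(reference, traj)
  fit_sel <- as.integer(select_atoms(sys, chain = chain,
                                     resno = config$fit_resno, name = "CA"))
  loop_sel <- as.integer(select_atoms(sys, chain = chain,
                                      resno = config$loop_resno,
                                      heavy_only = TRUE))
  ca_cp <- as.integer(select_atoms(sys, chain = chain,
                                   resno = config$c_prime_resno,
                                   name = "CA"))
  ca_e <- as.integer(select_atoms(sys, chain = chain,
                                  resno = config$e_strand_resno,
                                  name = "CA"))
  own_cg2 <- as.integer(select_atoms(sys, chain = chain,
                                     resno = config$cg2_resno, name = "CA"))
  opp_cg2 <- as.integer(select_atoms(sys, chain = opposing_chain,
                                     resno = config$cg2_resno, name = "CA"))
  # cavity axis in the reference frame: own Cgamma2 centroid -> opposing
  axis <- geometric_center(ref[opp_cg2, , drop = FALSE]) -
    geometric_center(ref[own_cg2, , drop = FALSE])
  axis <- axis / sqrt(sum(axis^2))
  ref_loop_ctr <- geometric_center(ref[loop_sel, , drop = FALSE])

  nf <- n_frames(traj)
  loop_rmsd <- numeric(nf); so <- numeric(nf); proj <- numeric(nf)
  for (t in seq_len(nf)) {
    fr <- frame_coords(traj, t)
    fit <- kabsch_fit(fr[fit_sel, , drop = FALSE],
                      ref[fit_sel, , drop = FALSE])
    loop_fit <- apply_fit(fr[loop_sel, , drop = FALSE], fit)
    loop_rmsd[t] <- sqrt(mean(rowSums(
      (loop_fit - ref[loop_sel, , drop = FALSE])^2)))
    so[t] <- strand_order(fr, ref, ca_cp, ca_e, config$pair_tol)
    proj[t] <- sum((geometric_center(loop_fit) - ref_loop_ctr) * axis)
  }
  state <- ifelse(so < config$s_min, "unstructured",
                  ifelse(loop_rmsd < config$r_native, "native",
                         ifelse(proj > 0, "inward_facing",
                                "outward_facing")))
  data.frame(frame = seq_len(nf), time_ns = traj$times,
             loop_rmsd = loop_rmsd, strand_order = so, projection = proj,
             state = state)
}
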