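#' Assign receptor-interface residues from a complex structure
#'
#' Fc residues with any heavy atom within `cutoff` of any receptor heavy
#' atom, per Fc chain -- the residue sets whose geometric-center separation
#' defines the binding-interface openness descriptor D_AB.
#'
#' @param complex_system `fc_system` holding both Fc and receptor chains.
#' @param fc_chains chain ids of the Fc dimer.
#' @param receptor_chains chain ids of the receptor.
#' @param cutoff contact cutoff, Angstrom.
#' @return named list (per Fc chain) of residue numbers, with attribute
#'   `cutoff`.
#' @export
assign_interface_residues <- function(complex_system, fc_chains,
                                      receptor_chains, cutoff = 4.5) {
  stopifnot(inherits(complex_system, "fc_system"))
  rec_sel <- select_atoms(complex_system, chain = receptor_chains,
                          heavy_only = TRUE)
  xyz <- system_coords(complex_system)
  rec_xyz <- xyz[as.integer(rec_sel), , drop = FALSE]
  at <- complex_system$atoms
  out <- list()
  for (ch in fc_chains) {
    sel <- as.integer(select_atoms(complex_system, chain = ch,
                                   heavy_only = TRUE))
    resnos <- sort(unique(at$residue_number[sel]))
    hit <- vapply(resnos, function(rn) {
      idx <- sel[at$residue_number[sel] == rn]
      min_heavy_distance(xyz[idx, , drop = FALSE], rec_xyz) <= cutoff
    }, logical(1))
    out[[ch]] <- resnos[hit]
  }
  if (all(lengths(out) == 0))
    stop("no Fc-receptor contacts within ", cutoff,
         " A; check chain labels")
  attr(out, "cutoff") <- cutoff
  out
}

#' Receptor-interface distance series (D_AB)
#'
#' Per frame, the distance between the geometric center of chain A's
#' interface residues (heavy atoms) and that of chain B's.
#'
#' @param traj an `fc_trajectory`.
#' @param interface_set named list `chain -> residue numbers` (two chains),
#'   e.g. from [assign_interface_residues()] or a config.
#' @return an `fc_series` in Angstrom.
#' @export
interface_distance_series <- function(traj, interface_set) {
  stopifnot(inherits(traj, "fc_trajectory"))
  chains <- names(interface_set)
  if (length(chains) != 2) stop("interface_set must name exactly 2 chains")
  sys <- traj$topology
  sel <- lapply(chains, function(ch)
    as.integer(select_atoms(sys, chain = ch,
                            resno = interface_set[[ch]],
                            heavy_only = TRUE)))
  nf <- n_frames(traj)
  vals <- numeric(nf)
  for (t in seq_len(nf)) {
    fr <- frame_coords(traj, t)
    ca <- geometric_center(fr[sel[[1]], , drop = FALSE])
    cb <- geometric_center(fr[sel[[2]], , drop = FALSE])
    vals[t] <- sqrt(sum((ca - cb)^2))
  }
  descriptor_series(seq_len(nf), traj$times, vals, units = "A",
                    label = sprintf("D_AB (%s-%s)", chains[1], chains[2]))
}

#' Default anchor selections for a domain pair
#'
#' Four anchor points per measured pair, each the geometric center of a
#' Calpha selection: for each domain, the Calpha centers of its N-terminal
#' and C-terminal halves. Any user-supplied list of four selections can be
#' passed to [domain_angle_series()] instead.
#'
#' @param system an `fc_system`.
#' @param pair `"cg2_cg3_A"`, `"cg2_cg3_B"` or `"cg3_cg3"`.
#' @param chains chain ids, `c(A, B)` order.
#' @param cg2_resno,cg3_resno domain residue ranges (EU numbering
#'   convention for the IgG1 CH2/CH3 domains).
#' @return list of four `fc_selection`s (P1..P4) defining theta as
#'   `angle(P1,P2,P3)` and phi as `dihedral(P1,P2,P3,P4)`.
#' @export
domain_anchors <- function(system, pair = "cg2_cg3_A",
                           chains = c("A", "B"),
                           cg2_resno = 238:340, cg3_resno = 341:443) {
  halves <- function(ch, resno) {
    present <- sort(intersect(
      unique(system$atoms$residue_number[system$atoms$chain_id == ch]),
      resno))
    if (length(present) < 2)
      stop("chain ", ch, ": domain residues not resolved")
    cut <- floor(length(present) / 2)
    list(n = select_atoms(system, chain = ch, resno = present[1:cut],
                          name = "CA"),
         c = select_atoms(system, chain = ch,
                          resno = present[(cut + 1):length(present)],
                          name = "CA"))
  }
  if (pair == "cg2_cg3_A" || pair == "cg2_cg3_B") {
    ch <- if (pair == "cg2_cg3_A") chains[1] else chains[2]
    h2 <- halves(ch, cg2_resno); h3 <- halves(ch, cg3_resno)
    list(h2$n, h2$c, h3$n, h3$c)
  } else if (pair == "cg3_cg3") {
    ha <- halves(chains[1], cg3_resno); hb <- halves(chains[2], cg3_resno)
    list(ha$n, ha$c, hb$n, hb$c)
  } else stop("unknown pair '", pair, "'")
}

#' Inter-domain orientation angle series (theta, phi)
#'
#' Per frame, computes the four anchor centers and returns
#' theta = angle(P1, P2, P3) and phi = dihedral(P1, P2, P3, P4), degrees.
#'
#' @param traj an `fc_trajectory`.
#' @param anchors list of four atom-index selections (see
#'   [domain_anchors()]).
#' @return list of two `fc_series`: `theta` and `phi`.
#' @export
domain_angle_series <- function(traj, anchors) {
  stopifnot(inherits(traj, "fc_trajectory"), length(anchors) == 4)
  anchors <- lapply(anchors, as.integer)
  if (any(lengths(anchors) == 0)) stop("empty anchor selection")
  nf <- n_frames(traj)
  th <- numeric(nf); ph <- numeric(nf)
  for (t in seq_len(nf)) {
    fr <- frame_coords(traj, t)
    p <- lapply(anchors, function(s)
      geometric_center(fr[s, , drop = FALSE]))
    th[t] <- angle_deg(p[[1]], p[[2]], p[[3]])
    ph[t] <- dihedral_deg(p[[1]], p[[2]], p[[3]], p[[4]])
  }
  list(theta = descriptor_series(seq_len(nf), traj$times, th,
                                 units = "deg", label = "theta"),
       phi = descriptor_series(seq_len(nf), traj$times, ph,
                               units = "deg", label = "phi"))
}

#' Radius-of-gyration series
#'
#' @param traj an `fc_trajectory`.
#' @param selection atom selection (default: all protein heavy atoms).
#' @param mass_weighted use atomic masses as weights (default); `FALSE`
#'   gives the uniform-weight convention (absolute Rg shifts by roughly
#'   0.1-0.3 Angstrom between conventions for proteins).
#' @return an `fc_series` in Angstrom.
#' @export
rg_series <- function(traj, selection = NULL, mass_weighted = TRUE) {
  stopifnot(inherits(traj, "fc_trajectory"))
  sys <- traj$topology
  if (is.null(selection))
    selection <- select_atoms(sys, component = "protein", heavy_only = TRUE)
  sel <- as.integer(selection)
  w <- if (mass_weighted) element_masses(sys$atoms$element[sel]) else NULL
  nf <- n_frames(traj)
  vals <- numeric(nf)
  for (t in seq_len(nf))
    vals[t] <- radius_of_gyration(traj$coords[sel, , t], w)
  descriptor_series(seq_len(nf), traj$times, vals, units = "A",
                    label = "radius of gyration")
}

#' Normalised histogram of a descriptor series
#'
#' Fixed-width bins anchored at `origin` (so distributions from different
#' runs share bin edges); probabilities sum to 1.
#'
#' @param series an `fc_series` or numeric vector.
#' @param bin_width bin width in the series' units.
#' @param origin anchor for the bin grid.
#' @return data frame `bin_left`, `bin_right`, `probability`.
#' @export
descriptor_distribution <- function(series, bin_width, origin = 0) {
  if (bin_width <= 0) stop("bin_width must be positive")
  vals <- if (is.data.frame(series)) series$value else as.numeric(series)
  if (length(vals) == 0) stop("empty series")
  k <- floor((vals - origin) / bin_width)
  tab <- table(k)
  kk <- as.integer(names(tab))
  data.frame(bin_left = origin + kk * bin_width,
             bin_right = origin + (kk + 1) * bin_width,
             probability = as.numeric(tab) / length(vals))
}

#' First-half / second-half convergence check
#'
#' Compares the average of a descriptor over the first and second halves of
#' the series (split at the midpoint frame); the run is flagged converged
#' when the absolute difference is within the tolerance.
#'
#' @param series an `fc_series` or numeric vector.
#' @param tolerance allowed |mean difference| (default 0.5, appropriate for
#'   RMSD series in Angstrom).
#' @return list: `first_half_mean`, `second_half_mean`, `delta` (absolute),
#'   `pass`.
#' @export
convergence_check <- function(series, tolerance = 0.5) {
  vals <- if (is.data.frame(series)) series$value else as.numeric(series)
  n <- length(vals)
  if (n < 4) stop("series too short for a half-split convergence check")
  mid <- floor(n / 2)
  m1 <- mean(vals[1:mid]); m2 <- mean(vals[(mid + 1):n])
  list(first_half_mean = m1, second_half_mean = m2,
       delta = abs(m2 - m1), pass = abs(m2 - m1) <= tolerance)
}
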