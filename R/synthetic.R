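# Synthetic Fc-like fixture generator.
#
# Emulates the statistical structure of the system under study without any
# physics: a two-chain homodimer of single-bead "Calpha" residues (Cgamma2
# 238-340, Cgamma3 341-443 per chain), a 5-residue surface loop (295-299)
# flanked by a short antiparallel strand pair (290-294 / 304-308) and the
# Calpha fit anchors (259-265, 301-306), and a branched glycan of up to 10
# single-bead residues rooted at residue 297. Loop states, glycan two-state
# kinetics and Cgamma2-Cgamma3 orientation angles are planted per frame and
# recorded as ground truth.

.DOMAIN_RADIUS <- 12
.CG2_CENTER_X <- 30
.CG2_CENTER_Z <- 20
.CG3_CENTER_X <- 14
.CG3_CENTER_Z <- -15
.STRAND_RISE <- 3.4
.STRAND_SEP <- 2.4        # half-separation of the paired strands
.GLYCAN_STANDOFF <- 3.0   # glycan bead height above its host surface bead
.ROOT_BOND <- 1.45        # GlcNAc1 to Asn297 link length

#' Specification of a synthetic Fc trajectory
#'
#' Fully parameterises the planted ground truth: chain plan, loop-state
#' schedule, glycan two-state (bound/unbound) kinetics, orientation-angle
#' model and coordinate noise. Defaults describe a Man8-like homodimer
#' sampled at 240 ps/frame with rare stochastic glycan detachments, a loop
#' that visits all four states, and orientation fluctuations matching the
#' breadth reported for intra-chain Cgamma2-Cgamma3 motion.
#'
#' @param seed integer RNG seed; every realisation is deterministic in it.
#' @param n_frames number of frames.
#' @param frame_dt_ns frame interval, ns.
#' @param chains named list `chain_id -> list(glycoform = ...)`.
#' @param loop_schedule list of `list(state=, fraction=)` segments covering
#'   the trajectory in order; fractions must sum to 1.
#' @param loop_displacement planted inward/outward loop displacement,
#'   Angstrom.
#' @param p_detach per-frame bound -> unbound switch probability.
#' @param p_attach per-frame unbound -> bound switch probability.
#' @param unbound_offset radial offset of detached glycan residues,
#'   Angstrom.
#' @param theta_mean,theta_sd Gaussian model for the Cgamma2-Cgamma3 angle
#'   theta, degrees.
#' @param phi_mean,phi_sd wrapped-Gaussian model for the dihedral phi,
#'   degrees.
#' @param noise_sd isotropic per-coordinate noise SD, Angstrom.
#' @return list of class `fc_synthetic_spec`.
#' @export
synthetic_spec <- function(seed = 1L, n_frames = 5000L, frame_dt_ns = 0.24,
                           chains = list(A = list(glycoform = "Man8"),
                                         B = list(glycoform = "Man8")),
                           loop_schedule = list(
                             list(state = "native", fraction = 0.4),
                             list(state = "outward_facing", fraction = 0.2),
                             list(state = "inward_facing", fraction = 0.2),
                             list(state = "unstructured", fraction = 0.2)),
                           loop_displacement = 6.0,
                           p_detach = 0.02, p_attach = 0.9,
                           unbound_offset = 15.0,
                           theta_mean = 85, theta_sd = 6,
                           phi_mean = -17, phi_sd = 12,
                           noise_sd = 0.2) {
  if (length(chains) != 2 || is.null(names(chains)))
    stop("chain plan must name exactly two chains")
  for (ch in names(chains)) glycoform_definition(chains[[ch]]$glycoform)
  fr <- vapply(loop_schedule, function(s) s$fraction, numeric(1))
  if (any(fr < 0) || abs(sum(fr) - 1) > 1e-9)
    stop("loop schedule fractions must be non-negative and sum to 1")
  states <- vapply(loop_schedule, function(s) s$state, character(1))
  ok <- c("native", "outward_facing", "inward_facing", "unstructured")
  if (!all(states %in% ok))
    stop("unknown loop state(s): ",
         paste(setdiff(states, ok), collapse = ", "))
  if (p_detach < 0 || p_detach > 1 || p_attach < 0 || p_attach > 1)
    stop("switch probabilities must be in [0, 1]")
  if (theta_sd < 0 || phi_sd < 0 || noise_sd < 0)
    stop("standard deviations must be non-negative")
  if (n_frames < 1) stop("n_frames must be positive")
  structure(
    list(seed = as.integer(seed), n_frames = as.integer(n_frames),
         frame_dt_ns = frame_dt_ns, chains = chains,
         loop_schedule = loop_schedule,
         loop_displacement = loop_displacement,
         p_detach = p_detach, p_attach = p_attach,
         unbound_offset = unbound_offset,
         theta_mean = theta_mean, theta_sd = theta_sd,
         phi_mean = phi_mean, phi_sd = phi_sd, noise_sd = noise_sd),
    class = "fc_synthetic_spec"
  )
}

# Deterministic quasi-uniform points on a sphere (Fibonacci spiral).
.fib_sphere <- function(n, radius) {
  i <- seq_len(n)
  z <- 1 - 2 * (i - 0.5) / n
  r <- sqrt(pmax(0, 1 - z^2))
  ga <- pi * (3 - sqrt(5))
  radius * cbind(r * cos(ga * i), r * sin(ga * i), z)
}

# Reference template for one chain: bead positions plus the metadata the
# frame builder needs (special index sets, local directions).
.chain_template <- function(chain_id, sgn, glycoform) {
  c2 <- c(sgn * .CG2_CENTER_X, 0, .CG2_CENTER_Z)
  c3 <- c(sgn * .CG3_CENTER_X, 0, .CG3_CENTER_Z)
  cg2_res <- 238:340
  cg3_res <- 341:443
  R <- .DOMAIN_RADIUS

  cavity <- c(-sgn, 0, 0)
  nhat <- (cavity + c(0, 0, 1)) / sqrt(2)
  u <- c(0, 1, 0)
  v <- .cross3(nhat, u)

  pos <- matrix(NA_real_, nrow = length(cg2_res), ncol = 3)
  rownames(pos) <- cg2_res
  fib <- .fib_sphere(length(cg2_res), R)
  pos[] <- sweep(fib, 2, c2, `+`)

  # antiparallel strand pair: C' 290-294 against E 304-308
  for (i in 0:4) {
    along <- (i - 2) * .STRAND_RISE
    pos[as.character(290 + i), ] <- c2 + R * nhat + along * u -
      .STRAND_SEP * v
    pos[as.character(308 - i), ] <- c2 + R * nhat + along * u +
      .STRAND_SEP * v
  }
  # C'E loop 295-299: arc from the C' end across to the E side, bulging out
  start <- pos["294", ]; end <- c2 + R * nhat + 2 * .STRAND_RISE * u +
    .STRAND_SEP * v
  for (k in 1:5) {
    tt <- k / 6
    pos[as.character(294 + k), ] <- (1 - tt) * start + tt * end +
      sin(pi * tt) * (3 * u + 3 * nhat)
  }
  # connector 300-303 between the loop and the E strand
  for (j in 300:303) {
    s <- (j - 299) / 5
    pos[as.character(j), ] <- (1 - s) * pos["299", ] + s * pos["304", ]
  }

  cg3 <- sweep(.fib_sphere(length(cg3_res), R), 2, c3, `+`)
  rownames(cg3) <- cg3_res

  root_dir <- pos["297", ] - c2
  root_dir <- root_dir / sqrt(sum(root_dir^2))

  # glycan host beads: generic surface beads nearest the loop direction
  generic <- setdiff(cg2_res, 290:308)
  dirs <- sweep(pos[as.character(generic), , drop = FALSE], 2, c2)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  align <- dirs %*% nhat
  hosts <- generic[order(-align)]

  def <- glycoform_definition(glycoform)
  n_gly <- length(def$indices)
  gly_pos <- NULL
  if (n_gly > 0) {
    gly_pos <- matrix(NA_real_, nrow = n_gly, ncol = 3)
    rownames(gly_pos) <- def$indices
    gly_pos[1, ] <- pos["297", ] + .ROOT_BOND * root_dir
    if (n_gly > 1) {
      hs <- hosts[seq_len(n_gly - 1)]
      hd <- sweep(pos[as.character(hs), , drop = FALSE], 2, c2)
      hd <- hd / sqrt(rowSums(hd^2))
      gly_pos[2:n_gly, ] <- sweep(
        (.DOMAIN_RADIUS + .GLYCAN_STANDOFF) * hd, 2, c2, `+`)
    }
  }

  list(chain_id = chain_id, c2 = c2, c3 = c3, cavity = cavity,
       nhat = nhat, u = u, v = v, root_dir = root_dir,
       cg2_res = cg2_res, cg3_res = cg3_res, cg2_pos = pos, cg3_pos = cg3,
       glycoform = glycoform, glycan_def = def, glycan_pos = gly_pos)
}

#' Generate the synthetic molecular system
#'
#' Builds the bead topology and reference coordinates described by the spec;
#' deterministic (uses no random numbers). Bead residues carry Fc residue
#' numbering so all production descriptor code paths run unchanged; glycan
#' beads are numbered 1..10 with residue names NAG/MAN.
#'
#' @param spec an [synthetic_spec()].
#' @return list: `system` (`fc_system`), `trees` (list of `fc_glycan_tree`),
#'   `templates` (internal per-chain reference geometry).
#' @export
generate_system <- function(spec) {
  stopifnot(inherits(spec, "fc_synthetic_spec"))
  chain_ids <- names(spec$chains)
  templates <- list()
  rows <- list()
  serial <- 0L
  for (k in seq_along(chain_ids)) {
    ch <- chain_ids[k]
    tpl <- .chain_template(ch, sgn = if (k == 1) 1 else -1,
                           spec$chains[[ch]]$glycoform)
    templates[[ch]] <- tpl
    prot <- rbind(tpl$cg2_pos, tpl$cg3_pos)
    resno <- c(tpl$cg2_res, tpl$cg3_res)
    n <- nrow(prot)
    rows[[length(rows) + 1]] <- data.frame(
      serial = serial + seq_len(n), name = "CA", element = "C",
      chain_id = ch, residue_number = resno, insert = "",
      residue_name = "ALA", x = prot[, 1], y = prot[, 2], z = prot[, 3],
      stringsAsFactors = FALSE)
    serial <- serial + n
    if (!is.null(tpl$glycan_pos)) {
      def <- tpl$glycan_def
      ng <- nrow(tpl$glycan_pos)
      rows[[length(rows) + 1]] <- data.frame(
        serial = serial + seq_len(ng), name = "C1", element = "C",
        chain_id = ch, residue_number = def$indices, insert = "",
        residue_name = ifelse(def$names == "GlcNAc", "NAG", "MAN"),
        x = tpl$glycan_pos[, 1], y = tpl$glycan_pos[, 2],
        z = tpl$glycan_pos[, 3], stringsAsFactors = FALSE)
      serial <- serial + ng
    }
  }
  system <- molecular_system(do.call(rbind, rows))
  glycoforms <- vapply(spec$chains, function(p) p$glycoform, character(1))
  form <- if (length(unique(glycoforms)) == 1) unique(glycoforms)
          else "Man8/N297Q"
  trees <- if (all(glycoforms == "N297Q")) list()
           else build_glycan_topology(system, form)
  list(system = system, trees = trees, templates = templates)
}

# Rotation taking direction a to direction b (Rodrigues, minimal rotation).
.rotation_between <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  v <- .cross3(a, b)
  s2 <- sum(v^2)
  c1 <- sum(a * b)
  if (s2 < 1e-24) {
    if (c1 > 0) return(diag(3))
    # antiparallel: rotate pi about any axis orthogonal to a
    ax <- .cross3(a, if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0))
    ax <- ax / sqrt(sum(ax^2))
    K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3)
    return(diag(3) + 2 * K %*% K)
  }
  K <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3)
  diag(3) + K + K %*% K * ((1 - c1) / s2)
}

# Place point D given A, B, C so that |D-C| = b, angle(D,C,B) = theta and
# dihedral(D,C,B,A) = phi (degrees), matching dihedral_deg's convention.
.nerf_place <- function(A, B, C, b, theta_deg, phi_deg) {
  th <- theta_deg * pi / 180; ph <- phi_deg * pi / 180
  b1 <- C - B; b1 <- b1 / sqrt(sum(b1^2))
  ab <- B - A
  n <- .cross3(ab, b1)
  n <- n / sqrt(sum(n^2))
  m <- .cross3(n, b1)
  C + b * (-cos(th) * b1 + sin(th) * cos(ph) * m - sin(th) * sin(ph) * n)
}

.wrap_angle <- function(x) {
  y <- (x + 180) %% 360 - 180
  y[y == -180] <- 180
  y
}

#' Generate a synthetic trajectory with planted ground truth
#'
#' Realises the spec frame by frame: the Cgamma2 domain of each chain is
#' rigidly re-oriented so the four anchor centers reproduce theta/phi values
#' drawn from the declared Gaussian (phi wrapped), the C'E loop is displaced
#' along the inter-chain cavity axis (or its strand pairing broken) per the
#' state schedule, detachable glycan residues (all but GlcNAc1) are pushed
#' radially off the surface during unbound intervals of a two-state Markov
#' chain, and isotropic Gaussian noise is added to every coordinate.
#'
#' @param spec an [synthetic_spec()].
#' @return list: `trajectory` (`fc_trajectory`), `system`, `trees`,
#'   `truth` (data frame: frame, chain, loop_state, glycan_bound, theta,
#'   phi).
#' @export
generate_trajectory <- function(spec) {
  stopifnot(inherits(spec, "fc_synthetic_spec"))
  gen <- generate_system(spec)
  sys <- gen$system
  nf <- spec$n_frames
  nat <- n_atoms(sys)
  ref <- system_coords(sys)
  chain_ids <- names(spec$chains)

  set.seed(spec$seed)

  # per-frame loop state labels from the schedule
  fr <- vapply(spec$loop_schedule, function(s) s$fraction, numeric(1))
  states <- vapply(spec$loop_schedule, function(s) s$state, character(1))
  counts <- diff(round(c(0, cumsum(fr)) * nf))
  frame_state <- rep(states, counts)
  if (length(frame_state) < nf)
    frame_state <- c(frame_state, rep(states[length(states)],
                                      nf - length(frame_state)))
  frame_state <- frame_state[seq_len(nf)]

  # per-chain precomputation
  per_chain <- list()
  for (k in seq_along(chain_ids)) {
    ch <- chain_ids[k]
    tpl <- gen$templates[[ch]]
    at <- sys$atoms
    prot_idx <- which(at$chain_id == ch & at$residue_name == "ALA")
    cg2_idx <- prot_idx[at$residue_number[prot_idx] %in% tpl$cg2_res]
    loop_idx <- prot_idx[at$residue_number[prot_idx] %in% 295:299]
    strand_idx <- prot_idx[at$residue_number[prot_idx] %in% 290:294]
    gly_idx <- which(at$chain_id == ch & at$residue_name %in%
                       c("NAG", "MAN"))
    root_idx <- gly_idx[at$residue_number[gly_idx] == 1]
    detach_idx <- setdiff(gly_idx, root_idx)
    i297 <- prot_idx[at$residue_number[prot_idx] == 297]

    anchors <- domain_anchors(
      sys, pair = if (k == 1) "cg2_cg3_A" else "cg2_cg3_B",
      chains = chain_ids)
    p_ref <- lapply(anchors, function(s)
      geometric_center(ref[as.integer(s), , drop = FALSE]))
    opp_tpl_c2 <- c(-tpl$c2[1], tpl$c2[2], tpl$c2[3])
    axis <- opp_tpl_c2 - tpl$c2
    axis <- axis / sqrt(sum(axis^2))

    theta <- rnorm(nf, spec$theta_mean, spec$theta_sd)
    phi <- .wrap_angle(rnorm(nf, spec$phi_mean, spec$phi_sd))
    # two-state Markov chain, started bound
    bound <- logical(nf)
    if (length(gly_idx) > 0) {
      u <- runif(nf)
      state <- TRUE
      for (t in seq_len(nf)) {
        state <- if (state) u[t] >= spec$p_detach else u[t] < spec$p_attach
        bound[t] <- state
      }
    } else bound <- rep(NA, nf)

    per_chain[[ch]] <- list(
      tpl = tpl, cg2_idx = cg2_idx, loop_idx = loop_idx,
      strand_idx = strand_idx, gly_idx = gly_idx, root_idx = root_idx,
      detach_idx = detach_idx, i297 = i297, p_ref = p_ref, axis = axis,
      b12 = sqrt(sum((p_ref[[1]] - p_ref[[2]])^2)),
      u1ref = p_ref[[1]] - p_ref[[2]],
      theta = theta, phi = phi, bound = bound)
  }

  coords <- array(0, dim = c(nat, 3, nf))
  for (t in seq_len(nf)) {
    fr_xyz <- ref
    st <- frame_state[t]
    for (ch in chain_ids) {
      pc <- per_chain[[ch]]
      tpl <- pc$tpl
      P1t <- .nerf_place(pc$p_ref[[4]], pc$p_ref[[3]], pc$p_ref[[2]],
                         pc$b12, pc$theta[t], pc$phi[t])
      R <- .rotation_between(pc$u1ref, P1t - pc$p_ref[[2]])
      pivot <- pc$p_ref[[2]]
      move <- c(pc$cg2_idx, pc$gly_idx)
      fr_xyz[move, ] <- sweep(
        sweep(ref[move, , drop = FALSE], 2, pivot) %*% t(R), 2, pivot, `+`)

      if (st == "inward_facing" || st == "outward_facing") {
        d <- spec$loop_displacement * if (st == "inward_facing") 1 else -1
        disp <- as.numeric(R %*% (d * pc$axis))
        fr_xyz[pc$loop_idx, ] <- sweep(fr_xyz[pc$loop_idx, , drop = FALSE],
                                       2, disp, `+`)
        if (length(pc$root_idx) > 0)
          fr_xyz[pc$root_idx, ] <- fr_xyz[pc$root_idx, , drop = FALSE] +
            rep(disp, each = length(pc$root_idx))
      } else if (st == "unstructured") {
        brk <- as.numeric(R %*% (-9 * tpl$v))
        fr_xyz[pc$strand_idx, ] <- sweep(
          fr_xyz[pc$strand_idx, , drop = FALSE], 2, brk, `+`)
        nl <- length(pc$loop_idx)
        # scatter the loop tangentially to the domain surface, so detached
        # glycan residues (far out along the radial direction) stay clear
        # of even the most displaced loop bead
        radial <- sweep(ref[pc$loop_idx, , drop = FALSE], 2, tpl$c2)
        radial <- radial / sqrt(rowSums(radial^2))
        dirs <- matrix(rnorm(3 * nl), ncol = 3)
        dirs <- dirs - radial * rowSums(dirs * radial)
        dirs <- dirs / sqrt(rowSums(dirs^2))
        mag <- runif(nl, 6, 9)
        fr_xyz[pc$loop_idx, ] <- fr_xyz[pc$loop_idx, , drop = FALSE] +
          (dirs * mag) %*% t(R)
        if (length(pc$root_idx) > 0) {
          # keep the root bonded to the (scattered) attachment residue
          d297 <- fr_xyz[pc$i297, ] -
            (pivot + as.numeric(R %*% (ref[pc$i297, ] - pivot)))
          fr_xyz[pc$root_idx, ] <- fr_xyz[pc$root_idx, , drop = FALSE] +
            rep(d297, each = length(pc$root_idx))
        }
      }

      if (length(pc$gly_idx) > 0 && !isTRUE(pc$bound[t]) &&
          length(pc$detach_idx) > 0) {
        # push detachable residues radially off the (rotated) domain surface
        rel <- sweep(ref[pc$detach_idx, , drop = FALSE], 2, tpl$c2)
        rel <- rel / sqrt(rowSums(rel^2))
        fr_xyz[pc$detach_idx, ] <- fr_xyz[pc$detach_idx, , drop = FALSE] +
          (spec$unbound_offset * rel) %*% t(R)
      }
    }
    coords[, , t] <- fr_xyz
  }
  if (spec$noise_sd > 0)
    coords <- coords + rnorm(length(coords), 0, spec$noise_sd)

  truth <- do.call(rbind, lapply(chain_ids, function(ch) {
    data.frame(frame = seq_len(nf), chain = ch,
               loop_state = frame_state,
               glycan_bound = per_chain[[ch]]$bound,
               theta = per_chain[[ch]]$theta, phi = per_chain[[ch]]$phi,
               stringsAsFactors = FALSE)
  }))

  list(trajectory = trajectory(sys, coords,
                               frame_dt_ns = spec$frame_dt_ns),
       system = sys, trees = gen$trees, truth = truth)
}

#' Write a synthetic fixture to disk
#'
#' Writes `system.pdb`, the trajectory (`traj.dcd` or `traj.models.pdb`),
#' `truth.tsv` and `spec.json` into a directory; re-running with the same
#' spec reproduces identical ground truth.
#'
#' @param spec an [synthetic_spec()].
#' @param out_dir output directory (created if needed).
#' @param traj_format `"dcd"` or `"pdb"`.
#' @return named list of the written paths, invisibly.
#' @export
write_fixture <- function(spec, out_dir, traj_format = c("dcd", "pdb")) {
  traj_format <- match.arg(traj_format)
  gen <- generate_trajectory(spec)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    system = file.path(out_dir, "system.pdb"),
    trajectory = file.path(out_dir,
                           if (traj_format == "dcd") "traj.dcd"
                           else "traj.models.pdb"),
    truth = file.path(out_dir, "truth.tsv"),
    spec = file.path(out_dir, "spec.json")
  )
  ref_traj <- trajectory(gen$system,
                         array(system_coords(gen$system),
                               dim = c(n_atoms(gen$system), 3, 1)))
  write_multimodel_pdb(ref_traj, paths$system)
  if (traj_format == "dcd") write_dcd(gen$trajectory, paths$trajectory)
  else write_multimodel_pdb(gen$trajectory, paths$trajectory)
  write.table(gen$truth, paths$truth, sep = "\t", row.names = FALSE,
              quote = FALSE)
  writeLines(jsonlite::toJSON(unclass(spec), auto_unbox = TRUE,
                              digits = NA), paths$spec)
  invisible(paths)
}
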