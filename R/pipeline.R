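#' Pipeline run configuration
#'
#' Aggregates every parameter the descriptor stages use, so a run is fully
#' reproducible from its config (the run report echoes the effective values;
#' there are no silent defaults).
#'
#' @param topology path to the topology PDB.
#' @param trajectory path to the trajectory (multi-model PDB or DCD).
#' @param glycoform declared glycoform (`"Man8"`, `"Man5"`, `"GlcNAc"`,
#'   `"N297Q"`, `"Man8/N297Q"`).
#' @param chains the two Fc chain ids, A then B.
#' @param out_dir output directory for TSVs and the JSON report.
#' @param contact_cutoff glycan-protein contact cutoff, Angstrom.
#' @param detach_threshold detachment threshold on the terminal
#'   minimum-distance series, Angstrom.
#' @param interface_resno named list `chain -> residue numbers` for the
#'   D_AB interface sets (default: the C'E loop region of each chain as a
#'   receptor-interface proxy when no complex structure is supplied).
#' @param window_fraction analysis window as the trailing fraction of the
#'   time span (0.75 generalises "last 1.5 us of a 2 us run").
#' @param frame_dt_ns frame interval when the trajectory stores no times.
#' @param loop [loop_config()] thresholds and residue ranges.
#' @param cg2_resno,cg3_resno domain ranges for the orientation anchors.
#' @param convergence_tol tolerance for the half-split convergence check.
#' @param min_event_frames minimum detachment-event duration, frames.
#' @param seed RNG seed echoed into the report (the descriptors themselves
#'   are deterministic).
#' @return list of class `fc_run_config`.
#' @export
run_config <- function(topology, trajectory, glycoform = "Man8",
                       chains = c("A", "B"), out_dir = "fcdyn_out",
                       contact_cutoff = 4.5, detach_threshold = 9.0,
                       interface_resno = NULL, window_fraction = 0.75,
                       frame_dt_ns = 0.24, loop = loop_config(),
                       cg2_resno = 238:340, cg3_resno = 341:443,
                       convergence_tol = 0.5, min_event_frames = 1L,
                       seed = 1L) {
  if (length(chains) != 2) stop("exactly two Fc chains are required")
  if (is.null(interface_resno))
    interface_resno <- setNames(list(loop$loop_resno, loop$loop_resno),
                                chains)
  structure(list(topology = topology, trajectory = trajectory,
                 glycoform = glycoform, chains = chains, out_dir = out_dir,
                 contact_cutoff = contact_cutoff,
                 detach_threshold = detach_threshold,
                 interface_resno = interface_resno,
                 window_fraction = window_fraction,
                 frame_dt_ns = frame_dt_ns, loop = loop,
                 cg2_resno = cg2_resno, cg3_resno = cg3_resno,
                 convergence_tol = convergence_tol,
                 min_event_frames = as.integer(min_event_frames),
                 seed = as.integer(seed)),
            class = "fc_run_config")
}

#' Read a run configuration from a flat key-value file
#'
#' Minimal TOML-like format: one `key = value` per line, `#` comments,
#' integer ranges as `a:b`, lists comma-separated. Recognised keys are the
#' arguments of [run_config()] (ranges: `loop_resno`, `fit_resno`,
#' `c_prime_resno`, `e_strand_resno`, `cg2_resno`, `cg3_resno`;
#' per-chain interface sets as `interface_resno_A` etc.).
#'
#' @param path config file path.
#' @return an `fc_run_config`.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE))
      stop("malformed config line (expected key = value): '", ln, "'")
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    kv[[key]] <- val
  }
  parse_ints <- function(s) {
    parts <- trimws(strsplit(s, ",")[[1]])
    unlist(lapply(parts, function(p) {
      if (grepl(":", p)) {
        ab <- as.integer(strsplit(p, ":")[[1]])
        ab[1]:ab[2]
      } else as.integer(p)
    }))
  }
  num <- function(key, default) if (is.null(kv[[key]])) default
         else as.numeric(kv[[key]])
  rng <- function(key, default) if (is.null(kv[[key]])) default
         else parse_ints(kv[[key]])
  chr <- function(key, default) kv[[key]] %||% default

  chains <- trimws(strsplit(chr("chains", "A,B"), ",")[[1]])
  lc <- loop_config(
    loop_resno = rng("loop_resno", 295:299),
    fit_resno = rng("fit_resno", c(259:265, 301:306)),
    c_prime_resno = rng("c_prime_resno", 290:294),
    e_strand_resno = rng("e_strand_resno", 304:308),
    r_native = num("r_native", 3.0), s_min = num("s_min", 0.5),
    pair_tol = num("pair_tol", 6.5),
    cg2_resno = rng("cg2_resno", 238:340))
  iface <- NULL
  iface_keys <- paste0("interface_resno_", chains)
  if (all(iface_keys %in% names(kv)))
    iface <- setNames(lapply(iface_keys, function(k) parse_ints(kv[[k]])),
                      chains)
  run_config(
    topology = chr("topology", stop("config must set 'topology'")),
    trajectory = chr("trajectory", stop("config must set 'trajectory'")),
    glycoform = chr("glycoform", "Man8"), chains = chains,
    out_dir = chr("out_dir", "fcdyn_out"),
    contact_cutoff = num("contact_cutoff", 4.5),
    detach_threshold = num("detach_threshold", 9.0),
    interface_resno = iface,
    window_fraction = num("window_fraction", 0.75),
    frame_dt_ns = num("frame_dt_ns", 0.24), loop = lc,
    cg2_resno = rng("cg2_resno", 238:340),
    cg3_resno = rng("cg3_resno", 341:443),
    convergence_tol = num("convergence_tol", 0.5),
    min_event_frames = num("min_event_frames", 1),
    seed = num("seed", 1))
}

# Load inputs and fail-fast validate every selection before any stage runs.
.load_run_inputs <- function(config) {
  stopifnot(inherits(config, "fc_run_config"))
  sys <- read_pdb(config$topology)
  unknown <- setdiff(config$chains, sys$chains)
  if (length(unknown) > 0)
    stop("chain map references unknown chain(s): ",
         paste(unknown, collapse = ", "))
  traj <- read_trajectory(config$trajectory, sys,
                          frame_dt_ns = config$frame_dt_ns)
  trees <- if (config$glycoform == "N297Q") list()
           else build_glycan_topology(sys, config$glycoform)
  # fail-fast selection validation
  for (ch in config$chains) {
    select_atoms(sys, chain = ch, resno = config$loop$fit_resno,
                 name = "CA")
    select_atoms(sys, chain = ch, resno = config$loop$loop_resno)
    select_atoms(sys, chain = ch, resno = config$interface_resno[[ch]])
  }
  ref <- system_coords(sys)
  list(system = sys, traj = traj, trees = trees, ref = ref)
}

.write_series_tsv <- function(series, path) {
  write.table(series, path, sep = "\t", row.names = FALSE, quote = FALSE)
  path
}

.stage_glycan <- function(config, inp) {
  out <- list(chains = list(), files = character(0))
  for (ch in config$chains) {
    tree <- inp$trees[[ch]]
    if (is.null(tree) || length(tree$indices) == 0) {
      out$chains[[ch]] <- list(skipped = "aglycosylated chain")
      message("fcdyn: chain ", ch,
              " is aglycosylated; glycan stage skipped")
      next
    }
    series <- terminal_min_distance_series(inp$traj, tree)
    cm <- residue_contact_matrix(inp$traj, tree,
                                 cutoff = config$contact_cutoff)
    events <- detect_detachment_events(series, config$detach_threshold,
                                       config$min_event_frames)
    bf <- bound_fraction(cm)
    f1 <- .write_series_tsv(series, file.path(
      config$out_dir, sprintf("glycan_min_distance_%s.tsv", ch)))
    cm_long <- data.frame(
      glycan_index = rep(as.integer(rownames(cm)), times = ncol(cm)),
      frame = rep(seq_len(ncol(cm)), each = nrow(cm)),
      contact = as.vector(unclass(cm)))
    f2 <- file.path(config$out_dir, sprintf("glycan_contacts_%s.tsv", ch))
    write.table(cm_long, f2, sep = "\t", row.names = FALSE, quote = FALSE)
    out$files <- c(out$files, f1, f2)
    out$chains[[ch]] <- list(
      n_events = nrow(events), events = events,
      bound_fraction = as.list(bf),
      min_distance_summary = window_summary(
        series, last_fraction = config$window_fraction))
  }
  out
}

.stage_loop <- function(config, inp) {
  out <- list(chains = list(), files = character(0))
  for (i in seq_along(config$chains)) {
    ch <- config$chains[i]
    opp <- config$chains[if (i == 1) 2 else 1]
    rmsd <- ce_loop_rmsd_series(inp$traj, inp$ref, ch, config$loop)
    states <- classify_loop_states(inp$traj, inp$ref, ch, opp, config$loop)
    tree <- inp$trees[[ch]]
    g1 <- if (!is.null(tree) && 1 %in% tree$indices)
      glcnac1_rmsd_series(inp$traj, inp$ref, tree, config$loop) else NULL
    tab <- data.frame(frame = states$frame, time_ns = states$time_ns,
                      loop_rmsd = states$loop_rmsd,
                      glcnac1_rmsd = if (is.null(g1)) NA else g1$value,
                      strand_order = states$strand_order,
                      projection = states$projection, state = states$state)
    f <- file.path(config$out_dir, sprintf("loop_states_%s.tsv", ch))
    write.table(tab, f, sep = "\t", row.names = FALSE, quote = FALSE)
    out$files <- c(out$files, f)
    conv <- convergence_check(rmsd, config$convergence_tol)
    out$chains[[ch]] <- list(
      loop_rmsd_summary = window_summary(
        rmsd, last_fraction = config$window_fraction),
      glcnac1_rmsd_summary = if (is.null(g1)) NULL else window_summary(
        g1, last_fraction = config$window_fraction),
      state_fractions = as.list(table(states$state) / nrow(states)),
      convergence = conv)
  }
  out
}

.stage_domains <- function(config, inp) {
  traj <- inp$traj; sys <- inp$system
  dab <- interface_distance_series(traj, config$interface_resno)
  pairs <- c("cg2_cg3_A", "cg2_cg3_B", "cg3_cg3")
  angles <- lapply(pairs, function(p)
    domain_angle_series(traj, domain_anchors(
      sys, p, chains = config$chains, cg2_resno = config$cg2_resno,
      cg3_resno = config$cg3_resno)))
  names(angles) <- pairs
  rg <- rg_series(traj)

  files <- character(0)
  f <- file.path(config$out_dir, "interface_distance.tsv")
  files <- c(files, .write_series_tsv(dab, f))
  for (p in pairs) {
    tab <- data.frame(frame = angles[[p]]$theta$frame,
                      time_ns = angles[[p]]$theta$time_ns,
                      theta = angles[[p]]$theta$value,
                      phi = angles[[p]]$phi$value)
    fp <- file.path(config$out_dir, sprintf("angles_%s.tsv", p))
    write.table(tab, fp, sep = "\t", row.names = FALSE, quote = FALSE)
    files <- c(files, fp)
  }
  files <- c(files, .write_series_tsv(
    rg, file.path(config$out_dir, "radius_of_gyration.tsv")))
  dist_dab <- descriptor_distribution(dab, bin_width = 1)
  fd <- file.path(config$out_dir, "interface_distance_hist.tsv")
  write.table(dist_dab, fd, sep = "\t", row.names = FALSE, quote = FALSE)
  files <- c(files, fd)

  list(
    files = files,
    d_ab_summary = window_summary(dab,
                                  last_fraction = config$window_fraction),
    rg_summary = window_summary(rg,
                                last_fraction = config$window_fraction),
    rg_convergence = convergence_check(rg, config$convergence_tol),
    angle_summaries = lapply(angles, function(a) list(
      theta = window_summary(a$theta,
                             last_fraction = config$window_fraction),
      phi = window_summary(a$phi,
                           last_fraction = config$window_fraction),
      theta_range = range(a$theta$value),
      phi_range = range(a$phi$value))))
}

.STAGES <- c("glycan", "loop", "domains")

#' Run one pipeline stage
#'
#' @param config an `fc_run_config`.
#' @param stage one of `"glycan"`, `"loop"`, `"domains"`.
#' @param inputs pre-loaded inputs (internal reuse); loaded from the config
#'   paths when `NULL`.
#' @return the stage's report fragment (also written under `out_dir`).
#' @export
run_stage <- function(config, stage, inputs = NULL) {
  if (!stage %in% .STAGES)
    stop("unknown stage '", stage, "'; valid stages: ",
         paste(.STAGES, collapse = ", "))
  inp <- inputs %||% .load_run_inputs(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- tryCatch(
    switch(stage,
           glycan = .stage_glycan(config, inp),
           loop = .stage_loop(config, inp),
           domains = .stage_domains(config, inp)),
    error = function(e) stop("stage '", stage, "' failed: ",
                             conditionMessage(e), call. = FALSE))
  res
}

#' Run the full descriptor pipeline
#'
#' Executes the glycan-dynamics, loop-ensemble and domain-orientation stages
#' on one (topology, trajectory, config) triple, writes per-stage TSVs and a
#' JSON run report aggregating window summaries (formatted "mean ± sd"),
#' detachment events, loop-state fractions, distributions and convergence
#' verdicts. Aglycosylated chains skip the glycan stage with a logged
#' notice.
#'
#' @param config an `fc_run_config`.
#' @return the report as a list (also written to `out_dir/report.json`),
#'   invisibly.
#' @export
run_all <- function(config) {
  inp <- .load_run_inputs(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(
    parameters = list(
      topology = config$topology, trajectory = config$trajectory,
      glycoform = config$glycoform, chains = as.list(config$chains),
      contact_cutoff = config$contact_cutoff,
      detach_threshold = config$detach_threshold,
      interface_resno = config$interface_resno,
      window_fraction = config$window_fraction,
      frame_dt_ns = config$frame_dt_ns,
      r_native = config$loop$r_native, s_min = config$loop$s_min,
      pair_tol = config$loop$pair_tol,
      convergence_tol = config$convergence_tol,
      min_event_frames = config$min_event_frames, seed = config$seed),
    n_frames = n_frames(inp$traj),
    glycan = run_stage(config, "glycan", inp),
    loop = run_stage(config, "loop", inp),
    domains = run_stage(config, "domains", inp))
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(report)
}
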