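# Toy Fc/receptor complex: two "Fc" chains of 3 residues and a receptor
# chain; exactly one Fc residue lies within 4 A of the receptor.
toy_complex <- function() {
  mk <- function(serial, ch, resno, x, y = 0, z = 0)
    data.frame(serial = serial, name = "CA", element = "C", chain_id = ch,
               residue_number = resno, insert = "", residue_name = "ALA",
               x = x, y = y, z = z, stringsAsFactors = FALSE)
  atoms <- rbind(
    mk(1, "A", 1, 0), mk(2, "A", 2, 3), mk(3, "A", 3, 20),
    mk(4, "B", 1, 40), mk(5, "B", 2, 37), mk(6, "B", 3, 25),
    mk(7, "R", 1, 22.5), mk(8, "R", 2, 22.5, 3))
  molecular_system(atoms)
}

test_that("interface residues are the contacts within the cutoff", {
  sys <- toy_complex()
  iface <- assign_interface_residues(sys, c("A", "B"), "R", cutoff = 4.0)
  expect_equal(iface$A, 3)   # |20 - 22.5| = 2.5 A
  expect_equal(iface$B, 3)   # |25 - 22.5| = 2.5 A
  wide <- assign_interface_residues(sys, c("A", "B"), "R", cutoff = 6.0)
  expect_true(all(iface$A %in% wide$A))
  expect_true(all(iface$B %in% wide$B))
  expect_error(assign_interface_residues(sys, c("A", "B"), "R",
                                         cutoff = 0.5), "contacts")
})

test_that("interface assignment matches a brute-force residue scan", {
  run <- small_man8_run()
  sys <- run$system
  # treat chain B as a stand-in "receptor" for the scan
  iface <- assign_interface_residues(sys, "A", "B", cutoff = 25)
  xyz <- system_coords(sys)
  at <- sys$atoms
  bsel <- which(at$chain_id == "B" & at$is_heavy)
  asel <- which(at$chain_id == "A" & at$is_heavy)
  expected <- integer(0)
  for (rn in sort(unique(at$residue_number[asel]))) {
    idx <- asel[at$residue_number[asel] == rn]
    if (brute_min_distance(xyz[idx, , drop = FALSE],
                           xyz[bsel, , drop = FALSE]) <= 25)
      expected <- c(expected, rn)
  }
  expect_equal(iface$A, expected)
})

test_that("D_AB is the distance between the two interface centers", {
  sys <- toy_complex()
  traj <- trajectory(sys, array(system_coords(sys), dim = c(8, 3, 1)))
  s <- interface_distance_series(traj, list(A = c(1, 2), B = c(1, 2)))
  expect_equal(s$value, 38.5 - 1.5)  # centers at x = 1.5 and 38.5
  # invariance under a rigid motion of the whole frame
  set.seed(12)
  rt <- random_rigid()
  moved <- apply_rigid(system_coords(sys), rt)
  traj2 <- trajectory(sys, array(moved, dim = c(8, 3, 1)))
  s2 <- interface_distance_series(traj2, list(A = c(1, 2), B = c(1, 2)))
  expect_equal(s2$value, s$value, tolerance = 1e-8)
})

test_that("anchor geometry reproduces planted right angles and trans planes", {
  mk <- function(serial, ch, resno, x, y, z)
    data.frame(serial = serial, name = "CA", element = "C", chain_id = ch,
               residue_number = resno, insert = "", residue_name = "ALA",
               x = x, y = y, z = z, stringsAsFactors = FALSE)
  # one atom per anchor selection: P1..P4 directly
  atoms <- rbind(mk(1, "A", 1, 0, 1, 0), mk(2, "A", 2, 0, 0, 0),
                 mk(3, "A", 3, 1, 0, 0), mk(4, "A", 4, 1, -1, 0))
  sys <- molecular_system(atoms)
  traj <- trajectory(sys, array(system_coords(sys), dim = c(4, 3, 1)))
  anchors <- lapply(1:4, function(i)
    select_atoms(sys, resno = i))
  ang <- domain_angle_series(traj, anchors)
  expect_equal(ang$theta$value, 90)
  expect_equal(ang$phi$value, 180)
})

test_that("noise-free frames reproduce planted theta/phi exactly", {
  spec <- synthetic_spec(seed = 35, n_frames = 400, noise_sd = 0,
                         loop_schedule = list(list(state = "native",
                                                   fraction = 1)))
  gen <- generate_trajectory(spec)
  for (pair in c("cg2_cg3_A", "cg2_cg3_B")) {
    ch <- if (pair == "cg2_cg3_A") "A" else "B"
    ang <- domain_angle_series(gen$trajectory,
                               domain_anchors(gen$system, pair))
    tr <- subset(gen$truth, chain == ch)
    expect_lt(max(abs(ang$theta$value - tr$theta)), 1e-8)
    expect_lt(max(abs(ang$phi$value - tr$phi)), 1e-8)
    expect_true(all(ang$theta$value >= 0 & ang$theta$value <= 180))
    expect_true(all(ang$phi$value > -180 & ang$phi$value <= 180))
  }
})

test_that("rg_series matches the primitive applied per frame", {
  run <- small_man8_run()
  s <- rg_series(run$trajectory)
  sel <- as.integer(select_atoms(run$system, component = "protein"))
  w <- fcdyn:::element_masses(run$system$atoms$element[sel])
  direct <- radius_of_gyration(frame_coords(run$trajectory, 7)[sel, ], w)
  expect_equal(s$value[7], direct, tolerance = 1e-12)
  s_unw <- rg_series(run$trajectory, mass_weighted = FALSE)
  expect_equal(
    s_unw$value[7],
    radius_of_gyration(frame_coords(run$trajectory, 7)[sel, ]),
    tolerance = 1e-12)
})

test_that("distributions are normalised, anchored histograms", {
  const <- descriptor_series(1:5, 1:5, rep(2.3, 5))
  h <- descriptor_distribution(const, bin_width = 1)
  expect_equal(nrow(h), 1)
  expect_equal(h$probability, 1)
  expect_equal(h$bin_left, 2)
  set.seed(13)
  s <- descriptor_series(1:2000, 1:2000, runif(2000, 0, 10))
  h2 <- descriptor_distribution(s, bin_width = 0.5)
  expect_equal(sum(h2$probability), 1, tolerance = 1e-12)
  # uniform series: per-bin deviation bounded by a 3-sigma binomial bound
  p0 <- 0.05
  expect_true(all(abs(h2$probability - p0) <
                    3 * sqrt(p0 * (1 - p0) / 2000)))
  expect_error(descriptor_distribution(s, bin_width = 0), "positive")
})

test_that("halving the bin width refines the histogram consistently", {
  set.seed(14)
  s <- descriptor_series(1:500, 1:500, rnorm(500, 50, 5))
  coarse <- descriptor_distribution(s, bin_width = 2)
  fine <- descriptor_distribution(s, bin_width = 1)
  expect_equal(sum(fine$probability), 1, tolerance = 1e-12)
  for (i in seq_len(nrow(coarse))) {
    merged <- sum(fine$probability[fine$bin_left >= coarse$bin_left[i] &
                                     fine$bin_right <= coarse$bin_right[i]])
    expect_equal(merged, coarse$probability[i], tolerance = 1e-12)
  }
})

test_that("convergence verdicts separate stationary noise from drift", {
  set.seed(15)
  for (k in 1:10) {
    noise <- rnorm(2000, mean = 2, sd = 0.1)
    expect_true(convergence_check(noise, tolerance = 0.5)$pass)
  }
  n <- 1000
  ramp <- 5 * (seq_len(n) - 0.5) / n    # linear 0 -> 5 A drift
  cc <- convergence_check(ramp, tolerance = 0.5)
  expect_equal(cc$delta, 2.5, tolerance = 1e-12)
  expect_false(cc$pass)
  expect_equal(convergence_check(rep(1.7, 10))$delta, 0)
  expect_true(convergence_check(rep(1.7, 10))$pass)
  expect_error(convergence_check(c(1, 2)), "too short")
})
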