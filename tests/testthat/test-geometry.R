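test_that("kabsch_fit recovers exact rigid transforms", {
  set.seed(1)
  X <- matrix(rnorm(30), ncol = 3)
  f <- kabsch_fit(X, X)
  expect_equal(f$rotation, diag(3), tolerance = 1e-10)
  expect_equal(f$translation, rep(0, 3), tolerance = 1e-10)
  expect_equal(f$fit_rmsd, 0, tolerance = 1e-10)

  Rz <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, byrow = TRUE)
  Y <- sweep(X %*% t(Rz), 2, c(1, 2, 3), `+`)
  f2 <- kabsch_fit(Y, X)
  expect_lt(f2$fit_rmsd, 1e-8)
  expect_equal(apply_fit(Y, f2), X, tolerance = 1e-8)
})

test_that("kabsch_fit matches the quaternion-method oracle", {
  set.seed(7)
  for (k in 1:40) {
    X <- matrix(rnorm(150, sd = 5), ncol = 3)
    Y <- matrix(rnorm(150, sd = 5), ncol = 3)
    expect_lt(abs(kabsch_fit(X, Y)$fit_rmsd - quaternion_fit_rmsd(X, Y)),
              1e-6)
  }
})

test_that("kabsch rotations are proper and orthonormal", {
  set.seed(2)
  for (k in 1:25) {
    X <- matrix(rnorm(60, sd = 4), ncol = 3)
    Y <- matrix(rnorm(60, sd = 4), ncol = 3)
    R <- kabsch_fit(X, Y)$rotation
    expect_lt(max(abs(crossprod(R) - diag(3))), 1e-10)
    expect_equal(det(R), 1, tolerance = 1e-10)
  }
})

test_that("degenerate and mismatched fits are rejected", {
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_fit(line, line), "collinear")
  expect_error(kabsch_fit(matrix(rnorm(9), 3), matrix(rnorm(12), 4)))
  expect_error(kabsch_fit(matrix(rnorm(6), 2), matrix(rnorm(6), 2)),
               "at least 3")
})

test_that("rmsd_after_fit is zero for rigid copies, exact for planted shifts", {
  set.seed(3)
  ref <- matrix(rnorm(90, sd = 6), ncol = 3)
  fit_sel <- 1:15; meas_sel <- 16:30
  expect_equal(rmsd_after_fit(ref, ref, fit_sel, meas_sel), 0,
               tolerance = 1e-12)
  rt <- random_rigid()
  moved <- apply_rigid(ref, rt)
  expect_lt(rmsd_after_fit(moved, ref, fit_sel, meas_sel), 1e-8)
  # rigid motion plus a pure translation of the measured atoms:
  # the RMSD equals the planted displacement norm exactly
  d <- c(1.2, -0.7, 2.0)
  moved2 <- moved
  moved2[meas_sel, ] <- sweep(moved2[meas_sel, ], 2,
                              as.numeric(rt$R %*% d), `+`)
  expect_equal(rmsd_after_fit(moved2, ref, fit_sel, meas_sel),
               sqrt(sum(d^2)), tolerance = 1e-8)
  expect_error(rmsd_after_fit(ref, ref, integer(0), meas_sel), "empty")
})

test_that("fitted RMSD never exceeds unfitted RMSD", {
  set.seed(4)
  for (k in 1:20) {
    X <- matrix(rnorm(75, sd = 3), ncol = 3)
    Y <- matrix(rnorm(75, sd = 3), ncol = 3)
    raw <- sqrt(mean(rowSums((X - Y)^2)))
    expect_lte(rmsd_after_fit(X, Y, 1:25, 1:25), raw + 1e-12)
  }
})

test_that("min_heavy_distance is exact", {
  expect_equal(min_heavy_distance(rbind(c(0, 0, 0)), rbind(c(3, 4, 0))), 5)
  A <- rbind(c(1, 1, 1), c(5, 5, 5))
  expect_equal(min_heavy_distance(A, rbind(c(9, 9, 9), c(1, 1, 1))), 0)
  expect_error(min_heavy_distance(A[0, , drop = FALSE], A), "empty")
  set.seed(5)
  for (k in 1:50) {
    a <- matrix(rnorm(90, sd = 8), ncol = 3)
    b <- matrix(rnorm(120, sd = 8), ncol = 3)
    expect_equal(min_heavy_distance(a, b), brute_min_distance(a, b),
                 tolerance = 1e-12)
  }
})

test_that("geometric_center is the mean and is translation-equivariant", {
  expect_equal(geometric_center(rbind(c(0, 0, 0), c(2, 0, 0))), c(1, 0, 0))
  set.seed(6)
  X <- matrix(rnorm(60), ncol = 3)
  t0 <- c(3, -2, 7)
  expect_equal(geometric_center(sweep(X, 2, t0, `+`)),
               geometric_center(X) + t0, tolerance = 1e-12)
  expect_equal(geometric_center(X), colMeans(X), tolerance = 1e-12)
  expect_error(geometric_center(X[0, , drop = FALSE]), "empty")
})

test_that("angles and dihedrals follow the standard conventions", {
  expect_equal(angle_deg(c(-1, 0, 0), c(0, 0, 0), c(1, 0, 0)), 180)
  expect_equal(angle_deg(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0)), 90)
  # cis / trans planar
  expect_equal(dihedral_deg(c(1, 1, 0), c(1, 0, 0), c(-1, 0, 0),
                            c(-1, 1, 0)), 0)
  expect_equal(dihedral_deg(c(1, 1, 0), c(1, 0, 0), c(-1, 0, 0),
                            c(-1, -1, 0)), 180)
  # right-handed sign convention
  expect_equal(dihedral_deg(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0),
                            c(0, 1, 1)), 90)
  expect_equal(dihedral_deg(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0),
                            c(0, 1, -1)), -90)
  expect_error(angle_deg(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0)),
               "degenerate")
  expect_error(dihedral_deg(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0),
                            c(3, 1, 0)), "degenerate")
})

test_that("radius_of_gyration matches the direct formula", {
  expect_equal(radius_of_gyration(rbind(c(0, 0, 0), c(2, 0, 0))), 1)
  expect_equal(radius_of_gyration(matrix(5, 4, 3)), 0)
  set.seed(8)
  X <- matrix(rnorm(300, sd = 4), ncol = 3)
  w <- runif(100, 1, 16)
  ctr <- colSums(X * (w / sum(w)))
  direct <- sqrt(sum(w * rowSums(sweep(X, 2, ctr)^2)) / sum(w))
  expect_equal(radius_of_gyration(X, w), direct, tolerance = 1e-10)
  expect_error(radius_of_gyration(X, -w), "positive")
})

test_that("geometric primitives are invariant under global rigid motion", {
  set.seed(9)
  for (k in 1:10) {
    rt <- random_rigid()
    A <- matrix(rnorm(45, sd = 5), ncol = 3)
    B <- matrix(rnorm(60, sd = 5), ncol = 3)
    A2 <- apply_rigid(A, rt); B2 <- apply_rigid(B, rt)
    expect_equal(min_heavy_distance(A2, B2), min_heavy_distance(A, B),
                 tolerance = 1e-8)
    expect_equal(radius_of_gyration(A2), radius_of_gyration(A),
                 tolerance = 1e-8)
    p <- lapply(1:4, function(i) rnorm(3, sd = 3))
    p2 <- lapply(p, function(x) as.numeric(rt$R %*% x + rt$t))
    expect_equal(angle_deg(p2[[1]], p2[[2]], p2[[3]]),
                 angle_deg(p[[1]], p[[2]], p[[3]]), tolerance = 1e-8)
    expect_equal(dihedral_deg(p2[[1]], p2[[2]], p2[[3]], p2[[4]]),
                 dihedral_deg(p[[1]], p[[2]], p[[3]], p[[4]]),
                 tolerance = 1e-8)
  }
})
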