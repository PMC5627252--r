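test_that("a minimal handcrafted PDB parses into one chain and residue", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       2.009   1.420   0.000  1.00  0.00           C",
    "END"), f)
  sys <- read_pdb(f)
  expect_equal(n_atoms(sys), 3)
  expect_equal(sys$chains, "A")
  expect_equal(nrow(sys$residues), 1)
  expect_equal(sys$residues$component, "protein")
  expect_equal(system_coords(sys)[2, 1], 1.458)
})

test_that("carbohydrate residues are tagged as glycan component", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A 297       0.000   0.000   0.000  1.00  0.00           C",
    "HETATM    2  C1  NAG A 501       3.000   0.000   0.000  1.00  0.00           C",
    "END"), f)
  sys <- read_pdb(f)
  expect_equal(sys$residues$component, c("protein", "glycan"))
})

test_that("altloc records keep the highest occupancy (tie: first)", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA AALA A   1       1.000   0.000   0.000  0.40  0.00           C",
    "ATOM      2  CA BALA A   1       2.000   0.000   0.000  0.60  0.00           C",
    "ATOM      3  CB AALA A   1       3.000   0.000   0.000  0.50  0.00           C",
    "ATOM      4  CB BALA A   1       4.000   0.000   0.000  0.50  0.00           C",
    "END"), f)
  sys <- read_pdb(f)
  expect_equal(n_atoms(sys), 2)
  expect_equal(sort(system_coords(sys)[, 1]), c(2, 3))
})

test_that("empty or missing structures are rejected", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines("END", f)
  expect_error(read_pdb(f))
  expect_error(read_pdb(file.path(tempdir(), "nope.pdb")), "no such file")
})

test_that("multi-model PDB trajectories read in file order", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "MODEL        1",
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA  ALA A   2       3.800   0.000   0.000  1.00  0.00           C",
    "ATOM      3  CA  ALA A   3       7.600   0.000   0.000  1.00  0.00           C",
    "ENDMDL",
    "MODEL        2",
    "ATOM      1  CA  ALA A   1       0.000   0.000   1.000  1.00  0.00           C",
    "ATOM      2  CA  ALA A   2       3.800   0.000   1.000  1.00  0.00           C",
    "ATOM      3  CA  ALA A   3       7.600   0.000   1.000  1.00  0.00           C",
    "ENDMDL", "END"), f)
  sys <- read_pdb(f)
  traj <- read_trajectory(f, sys)
  expect_equal(n_frames(traj), 2)
  expect_equal(frame_coords(traj, 2)[, 3], rep(1, 3))
  expect_equal(traj$times, c(0, 0.24))
})

test_that("empty trajectory files and atom-count mismatches error", {
  f <- withr::local_tempfile(fileext = ".pdb")
  file.create(f)
  sys <- small_man8_run()$system
  expect_error(read_trajectory(f, sys), "empty")
})

test_that("DCD written by the generator round-trips through the reader", {
  run <- small_man8_run()
  sub <- trajectory(run$system, run$trajectory$coords[, , 1:5])
  f <- withr::local_tempfile(fileext = ".dcd")
  write_dcd(sub, f)
  back <- read_trajectory(f, run$system)
  expect_equal(n_frames(back), 5)
  # single-precision storage
  expect_lt(max(abs(back$coords - sub$coords)), 1e-4)
})

test_that("multi-model PDB written by the generator round-trips", {
  run <- small_man8_run()
  sub <- trajectory(run$system, run$trajectory$coords[, , 1:3])
  f <- withr::local_tempfile(fileext = ".pdb")
  write_multimodel_pdb(sub, f)
  sys2 <- read_pdb(f)
  expect_equal(n_atoms(sys2), n_atoms(run$system))
  expect_equal(sys2$atoms$chain_id, run$system$atoms$chain_id)
  expect_equal(sys2$residues$component, run$system$residues$component)
  back <- read_trajectory(f, sys2)
  expect_equal(n_frames(back), 3)
  # fixed-format 3-decimal precision
  expect_lt(max(abs(back$coords - sub$coords)), 5.1e-4)
})

test_that("select_atoms filters by chain, range, name, heaviness", {
  sys <- make_toy_system()
  sel <- select_atoms(sys, chain = "A", resno = 295:299,
                      heavy_only = TRUE)
  expect_equal(length(sel), 4)  # HA excluded, NAG (resno 1) excluded
  expect_false(any(sys$atoms$name[as.integer(sel)] == "HA"))
  with_h <- select_atoms(sys, chain = "A", resno = 295:299,
                         heavy_only = FALSE)
  expect_equal(length(with_h), 5)
  expect_error(select_atoms(sys, chain = "Z"), "unknown chain")
  expect_warning(
    empty <- select_atoms(sys, resno = 999, allow_empty = TRUE), "empty")
  expect_length(empty, 0)
  expect_error(select_atoms(sys, resno = 999), "empty selection")
})

test_that("CA fit-anchor selection resolves 13 atoms per chain", {
  sys <- small_man8_run()$system
  for (ch in c("A", "B")) {
    sel <- select_atoms(sys, chain = ch, resno = c(259:265, 301:306),
                        name = "CA")
    expect_equal(length(sel), 13)
  }
})

test_that("selection is deterministic and frame-independent", {
  sys <- small_man8_run()$system
  s1 <- select_atoms(sys, chain = "A", component = "glycan")
  s2 <- select_atoms(sys, chain = "A", component = "glycan")
  expect_identical(as.integer(s1), as.integer(s2))
  expect_equal(as.integer(s1), sort(as.integer(s1)))
})

test_that("glycoform trees carry the documented terminal sets and sizes", {
  expect_equal(glycoform_definition("Man8")$terminals, c(6, 7, 10))
  expect_equal(glycoform_definition("Man5")$terminals, c(5, 7, 8))
  expect_equal(glycoform_definition("GlcNAc")$terminals, 1)
  expect_length(glycoform_definition("Man8")$indices, 10)
  expect_length(glycoform_definition("Man5")$indices, 7)
  expect_length(glycoform_definition("N297Q")$indices, 0)
  # Man5 is Man8 truncated: shared residues keep identical parents
  m8 <- glycoform_definition("Man8"); m5 <- glycoform_definition("Man5")
  shared <- intersect(m5$indices, m8$indices)
  expect_setequal(shared, m5$indices)
  expect_equal(m5$parents[match(shared, m5$indices)],
               m8$parents[match(shared, m8$indices)])
})

test_that("glycan trees bind to structures and are rooted at GlcNAc1", {
  run <- small_man8_run()
  trees <- build_glycan_topology(run$system, "Man8")
  expect_named(trees, c("A", "B"))
  for (tr in trees) {
    expect_equal(tr$indices[1], 1)
    expect_true(is.na(tr$parents[1]))
    expect_equal(tr$terminals, c(6, 7, 10))
    expect_length(tr$residue_keys, 10)
  }
  expect_error(build_glycan_topology(run$system, "Man5"),
               "glycoform Man5 defines")
  expect_equal(build_glycan_topology(
    generate_system(synthetic_spec(
      chains = list(A = list(glycoform = "N297Q"),
                    B = list(glycoform = "N297Q"))))$system,
    "N297Q"), list())
})

test_that("asymmetric glycoform yields a single Man8 tree", {
  spec <- synthetic_spec(n_frames = 2,
                         chains = list(A = list(glycoform = "Man8"),
                                       B = list(glycoform = "N297Q")))
  gen <- generate_system(spec)
  expect_named(gen$trees, "A")
  expect_equal(gen$trees$A$terminals, c(6, 7, 10))
})

test_that("malformed glycan trees are rejected", {
  expect_error(glycan_tree("A", c(2, 3), c(NA, 2), c("Man", "Man"), 2),
               "rooted")
  expect_error(glycan_tree("A", 1:3, c(NA, 1, 1), rep("Man", 3), 5),
               "terminal set")
  expect_error(glycan_tree("A", c(1, 1), c(NA, 1), rep("Man", 2), 1),
               "duplicate")
})
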