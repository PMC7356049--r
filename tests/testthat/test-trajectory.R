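test_that("minimum-image distance wraps around the cell and matches brute force", {
  expect_equal(minimum_image_distance(c(0, 0, 0), c(9, 0, 0), c(10, 10, 10)), 1.0)
  expect_equal(minimum_image_distance(c(3, 4, 5), c(3, 4, 5), c(10, 10, 10)), 0.0)

  set.seed(11)
  box <- c(12, 9, 15)
  for (i in 1:50) {
    a <- runif(3, -5, 20)
    b <- runif(3, -5, 20)
    mi <- minimum_image_distance(a, b, box)
    expect_equal(mi, brute_min_image(a, b, box), tolerance = 1e-12)
    # symmetry and the no-wrap upper bound
    expect_equal(mi, minimum_image_distance(b, a, box))
    expect_lte(mi, sqrt(sum((a - b)^2)) + 1e-12)
  }
  expect_error(minimum_image_distance(c(0, 0, 0), c(1, 1, 1), c(10, -1, 10)),
               "positive")
})

test_that("equilibration cut drops early frames and preserves retained classifications", {
  coords <- array(rnorm(5 * 3 * 100, 50, 4), c(5, 3, 100))
  traj <- gas_trajectory(coords, box = 100, dt = 4)
  cut <- trim_equilibration(traj, 80)
  expect_equal(cut$n_frames, 80)
  expect_equal(trim_equilibration(traj, 0)$n_frames, 100)
  expect_error(trim_equilibration(traj, 1e6), "empty")

  # classifying then cutting equals cutting then classifying
  sys <- build_point_system(matrix(runif(30, 40, 60), 10),
                            c(50, 50, 50),
                            list(c(51, 50, 50), c(90, 90, 90)),
                            n_frames = 1)
  coords2 <- array(rnorm(13 * 3 * 20, 50, 10), c(13, 3, 20))
  traj2 <- gas_trajectory(coords2, box = 100, dt = 4)
  sm_full <- classify_trajectory(traj2, sys$selection)
  sm_cut <- classify_trajectory(trim_equilibration(traj2, 40), sys$selection)
  expect_identical(sm_cut$states, sm_full$states[11:20, , drop = FALSE])
})

test_that("XYZ trajectory and state-matrix formats round-trip losslessly", {
  spec <- toy_system_spec(box_edge = 80, n_ligands = 5, n_frames = 30,
                          shell_atom_count = 60, seed = 4)
  sys <- generate_toy_system(spec)
  path <- withr::local_tempfile(fileext = ".xyz")
  write_xyz_trajectory(sys$trajectory, path)
  back <- read_trajectory(path, NULL, dt = spec$dt, box = NULL)
  expect_equal(back$box, sys$trajectory$box)
  expect_equal(back$coords, sys$trajectory$coords, tolerance = 1e-7)

  sm1 <- classify_trajectory(sys$trajectory, sys$structure$selection)
  sm2 <- classify_trajectory(back, sys$structure$selection)
  expect_identical(sm1$states, sm2$states)

  smf <- withr::local_tempfile(fileext = ".txt")
  write_state_matrix(sm1, smf)
  sm3 <- read_state_matrix(smf)
  expect_identical(sm3$states, sm1$states)
  expect_equal(sm3$dt, sm1$dt)
  expect_identical(sm3$ligand_ids, sm1$ligand_ids)
})

test_that("PDB structures are read with correct Fe/ligand/protein selections", {
  atoms <- build_atom_table(n_residues = 4, atoms_per_residue = 3)  # 12 heavy
  # turn residue 4 into water (excluded), add Fe and two 3-site ligands
  atoms$resid[atoms$resno == 4] <- "HOH"
  extra <- data.frame(
    eleno = 13:19,
    elety = c("FE", "N1", "D1", "O1", "N2", "D2", "O2"),
    resid = c("HEM", rep("NO", 3), rep("NO", 3)),
    resno = c(50, 61, 61, 61, 62, 62, 62),
    chain = "A", element = c("FE", "N", "N", "O", "N", "N", "O"),
    x = 10 + 1:7, y = 20, z = 30, stringsAsFactors = FALSE)
  st <- structure(list(atoms = rbind(atoms, extra), box = c(90, 90, 90),
                       source = "fixture"), class = "gas_structure")
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure_pdb(st, path)

  rd <- read_structure(path)
  expect_length(rd$selection$ligands, 2)
  expect_true(all(lengths(rd$selection$ligands) == 3))
  expect_equal(rd$selection$fe, 13L)
  expect_length(rd$selection$protein_heavy, 9)  # 12 minus the 3 water atoms
  expect_equal(rd$box, c(90, 90, 90))

  expect_error(read_structure(path, fe_name = "ZZ"), "selection error")
})

test_that("synthetic system written to PDB re-reads with an identical selection", {
  spec <- toy_system_spec(box_edge = 70, n_ligands = 4, n_frames = 2,
                          shell_atom_count = 50, seed = 9)
  sys <- generate_toy_system(spec)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure_pdb(sys$structure, path)
  rd <- read_structure(path)
  expect_equal(rd$selection$protein_heavy, sys$structure$selection$protein_heavy)
  expect_equal(rd$selection$fe, sys$structure$selection$fe)
  expect_equal(unname(lapply(rd$selection$ligands, identity)),
               unname(lapply(sys$structure$selection$ligands, identity)))
})

test_that("GRO files parse with nm-to-Angstrom conversion", {
  lines <- c(
    "toy system",
    "    4",
    "    1ALA     CA    1   1.000   2.000   3.000",
    "    1ALA     CB    2   1.100   2.000   3.000",
    "    2HEM     FE    3   2.000   2.000   2.000",
    "    3NO       N    4   3.000   3.000   3.000",
    "   8.00000   8.00000   8.00000")
  path <- withr::local_tempfile(fileext = ".gro")
  writeLines(lines, path)
  st <- read_structure(path)
  expect_equal(st$atoms$x, c(10, 11, 20, 30))
  expect_equal(st$box, c(80, 80, 80))
  expect_equal(st$selection$fe, 3L)
  expect_length(st$selection$ligands, 1)
})

test_that("selection invariants are enforced", {
  expect_error(site_selection(1:3, 2, list(5L)), "disjoint")
  expect_error(site_selection(1:3, 4, list(integer())), "at least one site")
  expect_error(site_selection(1:3, 4, list(5L, 5L)), "overlap")
  expect_error(site_selection(1:3, 4, list()), "at least one ligand")
})
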