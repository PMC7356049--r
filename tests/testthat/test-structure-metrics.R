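test_that("superposition removes pure rigid transforms and is idempotent", {
  set.seed(8)
  base <- matrix(rnorm(150, 50, 5), 50, 3)
  R <- random_rotation(); tr <- c(3, -7, 2)
  moved <- sweep(base %*% R, 2, tr, "+")
  coords <- array(c(base, moved), c(50, 3, 2))
  traj <- gas_trajectory(coords, box = 200, dt = 4)
  fitted <- superpose_frames(traj, seq_len(50), reference = "first")
  expect_lt(sqrt(mean((fitted$coords[, , 2] - base)^2)), 1e-6)

  refit <- superpose_frames(fitted, seq_len(50), reference = "first")
  expect_lt(max(abs(refit$coords - fitted$coords)), 1e-6)

  expect_error(superpose_frames(traj, 1:2), "degenerate")
  collinear <- gas_trajectory(array(rep(cbind(1:5, 0, 0), 2), c(5, 3, 2)),
                              box = 10, dt = 4)
  expect_error(superpose_frames(collinear, 1:5), "collinear")
})

test_that("superposition RMSD matches the bio3d fitting oracle", {
  skip_if_not_installed("bio3d")
  set.seed(12)
  base <- matrix(rnorm(150, 0, 6), 50, 3)
  for (i in 1:5) {
    noisy <- base + matrix(rnorm(150, 0, 0.4), 50, 3)
    moved <- sweep(noisy %*% random_rotation(), 2, runif(3, -10, 10), "+")
    ours <- kabsch_transform(moved, base)$rmsd
    fit <- bio3d::fit.xyz(as.numeric(t(base)), as.numeric(t(moved)),
                          fixed.inds = 1:150, mobile.inds = 1:150)
    theirs <- sqrt(mean(colSums(matrix(fit - as.numeric(t(base)), 3)^2)))
    expect_equal(ours, theirs, tolerance = 1e-6)
  }
})

test_that("RMSF is zero for static structures and follows the sigma*sqrt(3) law", {
  base <- as.matrix(build_atom_table(6, 4)[, c("x", "y", "z")])
  static <- generate_jittered_structure(base, 0, n_frames = 5, seed = 1)
  prof0 <- compute_rmsf(static, seq_len(24), rep(1:6, each = 4))
  expect_equal(prof0$rmsf_nm, rep(0, 6))
  expect_false(any(prof0$flagged))

  jit <- generate_jittered_structure(base, 0.1, n_frames = 500, seed = 2)
  prof <- compute_rmsf(jit, seq_len(24), rep(1:6, each = 4))
  truth <- 0.1 * sqrt(3)
  se <- truth * sqrt(1 / (6 * 4 * 500))
  expect_true(all(abs(prof$rmsf_nm - truth) < 3 * se))

  expect_error(compute_rmsf(generate_jittered_structure(base, 0.1, 1),
                            seq_len(24), rep(1:6, each = 4)), "2 frames")
})

test_that("doubling jitter doubles RMSF and flagging picks exactly the mobile residues", {
  base <- as.matrix(build_atom_table(8, 5)[, c("x", "y", "z")])
  sigma <- rep(0.05 / sqrt(3), 40)          # target rmsf 0.05 nm
  sigma[11:15] <- 0.2 / sqrt(3)             # residue 3 -> rmsf 0.2 nm
  jit <- generate_jittered_structure(base, sigma, n_frames = 600, seed = 3)
  prof <- compute_rmsf(jit, seq_len(40), rep(1:8, each = 5))
  expect_identical(prof$residue[prof$flagged], "3")

  # linearity: sigma and 2*sigma give an RMSF ratio of 2 within noise
  s2 <- rep(c(0.04, 0.08), each = 20)
  jit2 <- generate_jittered_structure(base, s2, n_frames = 800, seed = 4)
  prof2 <- compute_rmsf(jit2, seq_len(40), rep(1:2, each = 20))
  expect_equal(prof2$rmsf_nm[2] / prof2$rmsf_nm[1], 2, tolerance = 0.05)
})

test_that("RMSF is invariant under a global rigid transform after fitting", {
  base <- as.matrix(build_atom_table(6, 4)[, c("x", "y", "z")])
  jit <- generate_jittered_structure(base, 0.08, n_frames = 80, seed = 5)
  prof_a <- compute_rmsf(superpose_frames(jit, seq_len(24)),
                         seq_len(24), rep(1:6, each = 4))
  R <- random_rotation(); tr <- c(12, -4, 9)
  moved <- jit
  for (f in seq_len(moved$n_frames)) {
    moved$coords[, , f] <- sweep(moved$coords[, , f] %*% R, 2, tr, "+")
  }
  prof_b <- compute_rmsf(superpose_frames(moved, seq_len(24)),
                         seq_len(24), rep(1:6, each = 4))
  expect_equal(prof_a$rmsf_nm, prof_b$rmsf_nm, tolerance = 1e-8)
})

test_that("global descriptors count in-matrix ligands and their contacts", {
  # 1 ligand in geminate contact with exactly 5 heavy atoms, 1 ligand far out
  prot <- rbind(matrix(c(51, 50, 50, 49, 50, 50, 50, 51, 50, 50, 49, 50,
                         50, 50, 52), 5, 3, byrow = TRUE),
                matrix(70, 5, 3))
  sys <- build_point_system(prot, c(50, 50, 51),
                            list(c(50, 50, 50), c(20, 20, 20)),
                            box = 200, n_frames = 8)
  sm <- classify_trajectory(sys$trajectory, sys$selection)
  desc <- global_descriptors(sys$trajectory, sys$selection, sm)
  expect_equal(desc$avg_gas_in_protein, 1)
  expect_equal(desc$avg_contacts_total, 5)
  expect_equal(desc$contacts_per_molecule, 5)

  # all-solvent case warns and returns zeros
  sys2 <- build_point_system(matrix(50, 4, 3), c(50, 50, 50),
                             list(c(150, 150, 150)), box = 400, n_frames = 3)
  sm2 <- classify_trajectory(sys2$trajectory, sys2$selection)
  expect_warning(d2 <- global_descriptors(sys2$trajectory, sys2$selection, sm2),
                 "no ligand")
  expect_equal(d2$avg_contacts_total, 0)
  expect_equal(d2$contacts_per_molecule, 0)
})

test_that("descriptors match a brute-force per-frame recount", {
  set.seed(31)
  box <- c(25, 25, 25)
  np <- 8; nl <- 4; nf <- 12
  coords <- array(runif((np + 1 + nl) * 3 * nf, 0, 25),
                  c(np + 1 + nl, 3, nf))
  sel <- site_selection(seq_len(np), np + 1L, as.list(np + 1L + seq_len(nl)))
  traj <- gas_trajectory(coords, box = box, dt = 4)
  sm <- classify_trajectory(traj, sel)
  desc <- global_descriptors(traj, sel, sm, contact_cutoff = 4)

  tot_in <- 0; tot_contacts <- 0
  for (f in seq_len(nf)) for (l in seq_len(nl)) {
    if (sm$states[f, l] == "S") next
    tot_in <- tot_in + 1
    p <- coords[np + 1L + l, , f]
    tot_contacts <- tot_contacts + sum(vapply(seq_len(np), function(i)
      brute_min_image(p, coords[i, , f], box), 0) < 4)
  }
  expect_equal(desc$avg_gas_in_protein, tot_in / nf)
  expect_equal(desc$avg_contacts_total, tot_contacts / nf)
  expect_lte(desc$avg_gas_in_protein, nl)
})
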