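test_that("contact ranking counts (frame, ligand) pairs and orders correctly", {
  # ligand parked 3 A from atom 1 for 100 frames
  prot <- rbind(c(50, 50, 50), c(60, 60, 60), c(40, 40, 40))
  sys <- build_point_system(prot, c(30, 30, 30), list(c(53, 50, 50)),
                            box = 200, n_frames = 100)
  ranked <- rank_contact_atoms(sys$trajectory, sys$selection)
  expect_equal(ranked$atom[1], 1L)
  expect_equal(ranked$count[1], 100L)
  expect_equal(ranked$count[-1], c(0L, 0L))

  # nothing in reach -> all zero
  sys2 <- build_point_system(prot, c(30, 30, 30), list(c(120, 120, 120)),
                             box = 300, n_frames = 10)
  expect_true(all(rank_contact_atoms(sys2$trajectory, sys2$selection)$count == 0))
})

test_that("contact counts match brute force and grow monotonically with the cutoff", {
  set.seed(41)
  box <- c(20, 20, 20)
  np <- 7; nl <- 3; nf <- 10
  coords <- array(runif((np + 1 + nl) * 3 * nf, 0, 20), c(np + 1 + nl, 3, nf))
  sel <- site_selection(seq_len(np), np + 1L, as.list(np + 1L + seq_len(nl)))
  traj <- gas_trajectory(coords, box = box, dt = 4)
  ranked <- rank_contact_atoms(traj, sel, contact_cutoff = 4)

  want <- stats::setNames(integer(np), seq_len(np))
  for (f in seq_len(nf)) for (l in seq_len(nl)) for (i in seq_len(np)) {
    d <- brute_min_image(coords[np + 1L + l, , f], coords[i, , f], box)
    if (d < 4) want[i] <- want[i] + 1L
  }
  expect_equal(ranked$count, unname(sort(want, decreasing = TRUE)))
  expect_equal(unname(want[as.character(ranked$atom)]), ranked$count)

  wider <- rank_contact_atoms(traj, sel, contact_cutoff = 6)
  merged <- merge(ranked, wider, by = "atom")
  expect_true(all(merged$count.y >= merged$count.x))
})

test_that("top-fraction selection keeps the upper half and honors boundary ties", {
  ranked <- data.frame(atom = 1:10, count = c(10, 9, 8, 7, 6, 5, 4, 3, 2, 1))
  expect_equal(nrow(select_top_atoms(ranked, 0.5)), 5)
  expect_equal(nrow(select_top_atoms(ranked, 1.0)), 10)

  # tie at the boundary: both tied atoms kept
  tied <- data.frame(atom = 1:4, count = c(9, 5, 5, 1))
  kept <- select_top_atoms(tied, 0.5)
  expect_equal(kept$atom, c(1, 2, 3))
  # enumeration oracle: every kept atom outranks-or-ties every dropped atom
  for (frac in c(0.25, 0.5, 0.75)) {
    k <- select_top_atoms(tied, frac)
    dropped <- setdiff(tied$atom, k$atom)
    expect_true(all(outer(tied$count[k$atom], tied$count[dropped], ">=")))
    expect_gte(nrow(k), ceiling(frac * 4))
  }

  zero <- data.frame(atom = 1:3, count = c(0, 0, 0))
  expect_warning(empty <- select_top_atoms(zero, 0.5), "no atom")
  expect_equal(nrow(empty), 0)
})

test_that("single-linkage pocket clustering matches a graph-components oracle", {
  # two tight groups 20 A apart -> two pockets
  g1 <- matrix(rnorm(15, 0, 0.8), 5, 3)
  g2 <- sweep(matrix(rnorm(15, 0, 0.8), 5, 3), 2, c(20, 0, 0), "+")
  avg <- rbind(g1, g2)
  top <- data.frame(atom = 1:10, count = 10:1)
  pockets <- cluster_pockets(top, avg, linkage_cutoff = 5)
  expect_length(pockets, 2)
  expect_setequal(unlist(lapply(pockets, `[[`, "member_atoms")), 1:10)

  # everything within 2 A -> one pocket
  close_avg <- matrix(rnorm(12, 0, 0.5), 4, 3)
  one <- cluster_pockets(data.frame(atom = 1:4, count = 4:1), close_avg,
                         linkage_cutoff = 5)
  expect_length(one, 1)

  skip_if_not_installed("igraph")
  set.seed(17)
  for (i in 1:10) {
    n <- sample(5:14, 1)
    pts <- matrix(runif(n * 3, 0, 15), n, 3)
    pk <- cluster_pockets(data.frame(atom = seq_len(n), count = n:1), pts,
                          linkage_cutoff = 4, min_atoms = 1L)
    ours <- lapply(pk, `[[`, "member_atoms")
    adj <- as.matrix(stats::dist(pts)) <= 4
    gr <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    comp <- igraph::components(gr)$membership
    theirs <- unname(split(seq_len(n), comp))
    norm <- function(part) sort(vapply(part, function(p)
      paste(sort(p), collapse = ","), ""))
    expect_identical(norm(ours), norm(theirs))
  }
})

test_that("small clusters are discarded and pockets stay disjoint within the top set", {
  avg <- rbind(matrix(rnorm(12, 0, 0.5), 4, 3),          # pocket of 4
               sweep(matrix(rnorm(6, 0, 0.5), 2, 3), 2, c(30, 0, 0), "+"))
  pockets <- cluster_pockets(data.frame(atom = 1:6, count = 6:1), avg,
                             linkage_cutoff = 5)
  expect_length(pockets, 1)
  expect_setequal(pockets[[1]]$member_atoms, 1:4)
})

test_that("pocket occupancy and residence statistics are exact run-length accounting", {
  # ligand inside for 3 runs of 10 frames within 100 frames
  nf <- 100
  inside <- rep(FALSE, nf)
  inside[c(11:20, 41:50, 71:80)] <- TRUE
  lig_xyz <- matrix(80, nf, 3)
  lig_xyz[inside, ] <- matrix(rep(c(50, 50, 50), sum(inside)), ncol = 3,
                              byrow = TRUE)
  coords <- array(NA_real_, c(5, 3, nf))
  for (f in seq_len(nf)) {
    coords[1:3, , f] <- matrix(c(48, 50, 50, 52, 50, 50, 50, 48, 50), 3, 3,
                               byrow = TRUE)
    coords[4, , f] <- c(50, 52, 50)
    coords[5, , f] <- lig_xyz[f, ]
  }
  traj <- gas_trajectory(coords, box = 200, dt = 4)
  sel <- site_selection(1:3, 4L, list(5L))
  pocket <- list(centroid = c(50, 50, 50))
  st <- pocket_statistics(pocket, traj, sel)
  expect_equal(st$occupancy_pct, 30)
  expect_equal(st$mean_residence_ps, 40)
  expect_equal(st$n_in_out_events, 3)
  expect_equal(st$avg_simultaneous, 1)
  expect_equal(st$max_simultaneous, 1)
  # exact accounting invariants
  expect_equal(st$occupancy_pct * nf / 100, st$total_in_frames)
  expect_equal(st$mean_residence_ps * st$n_in_out_events,
               st$total_in_frames * 4)

  far <- pocket_statistics(list(centroid = c(5, 5, 5)), traj, sel)
  expect_equal(far$occupancy_pct, 0)
  expect_equal(far$n_in_out_events, 0)
})

test_that("occupancy statistics agree with a run-length-encoding oracle", {
  set.seed(23)
  for (rep_i in 1:5) {
    nf <- 60
    inmat <- matrix(runif(3 * nf) < 0.3, 3, nf)
    # place 3 ligands at/away from a centroid according to inmat
    coords <- array(NA_real_, c(5, 3, nf))
    coords[1, , ] <- c(48, 50, 50); coords[2, , ] <- c(52, 50, 50)
    for (l in 1:3) for (f in seq_len(nf)) {
      coords[2 + l, , f] <- if (inmat[l, f]) c(50, 50, 50) + runif(3, -1, 1)
      else c(90, 90, 90) + runif(3, -1, 1)
    }
    traj <- gas_trajectory(coords[c(1, 2, 3, 4, 5), , , drop = FALSE],
                           box = 200, dt = 4)
    sel <- site_selection(1L, 2L, list(3L, 4L, 5L))
    st <- pocket_statistics(list(centroid = c(50, 50, 50)), traj, sel)

    runs <- 0; frames_in <- 0
    for (l in 1:3) {
      r <- rle(inmat[l, ])
      runs <- runs + sum(r$values)
      frames_in <- frames_in + sum(r$lengths[r$values])
    }
    counts <- colSums(inmat)
    expect_equal(st$n_in_out_events, runs)
    expect_equal(st$occupancy_pct, 100 * mean(counts > 0))
    expect_equal(st$mean_residence_ps,
                 if (runs > 0) frames_in * 4 / runs else 0)
    expect_equal(st$max_simultaneous, max(counts))
    if (any(counts > 0)) {
      expect_equal(st$avg_simultaneous, mean(counts[counts > 0]))
      expect_gte(st$max_simultaneous, st$avg_simultaneous)
      expect_gte(st$avg_simultaneous, 1)
    }
  }
})

test_that("named-site statistics anchor on Fe and agree with a pinned centroid", {
  # ligand fixed 4.0 A from Fe: occupied under a 5 A cutoff, mean distance 4.0
  prot <- matrix(c(46, 50, 50, 54, 50, 50, 50, 46, 50), 3, 3, byrow = TRUE)
  sys <- build_point_system(prot, c(50, 50, 50), list(c(54, 50, 50)),
                            box = 200, n_frames = 20)
  st <- named_site_statistics("distal", sys$trajectory, sys$selection,
                              occupancy_cutoff = 5)
  expect_equal(st$occupancy_pct, 100)
  expect_equal(st$mean_anchor_distance, 4.0)
  expect_equal(st$n_in_out_events, 1)

  # equals pocket_statistics with the centroid pinned to the (static) anchor
  pin <- pocket_statistics(list(centroid = c(50, 50, 50)), sys$trajectory,
                           sys$selection, occupancy_cutoff = 5)
  for (fld in c("occupancy_pct", "avg_simultaneous", "max_simultaneous",
                "mean_residence_ps", "n_in_out_events")) {
    expect_equal(st[[fld]], pin[[fld]], label = fld)
  }

  expect_error(named_site_statistics("proximal", sys$trajectory,
                                     sys$selection), "anchor")
  prox <- named_site_statistics("proximal", sys$trajectory, sys$selection,
                                proximal_atoms = 1:2, occupancy_cutoff = 5)
  expect_equal(prox$occupancy_pct, 100)  # ligand is 4 A from the 1-2 midpoint
})
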