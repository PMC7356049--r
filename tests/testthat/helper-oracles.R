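# Independent oracles and small fixture builders shared across tests.
# Oracles deliberately use different algorithms than the package code paths
# they check.

# brute-force minimum-image distance: minimum over all 27 neighbor images
brute_min_image <- function(a, b, box, shells = 3) {
  best <- Inf
  r <- -shells:shells
  for (i in r) for (j in r) for (k in r) {
    d <- sqrt(sum((a - b + box * c(i, j, k))^2))
    best <- min(best, d)
  }
  best
}

# event-count oracle by string reduction: delete P, collapse repeats, count
# S->G and G->S adjacencies (exhaustive over the collapsed passage path)
oracle_events <- function(states) {
  r <- states[states != "P"]
  if (length(r) == 0L) return(c(n_in = 0L, n_out = 0L))
  r <- rle(r)$values
  if (length(r) < 2L) return(c(n_in = 0L, n_out = 0L))
  trans <- paste0(r[-length(r)], r[-1])
  c(n_in = sum(trans == "SG"), n_out = sum(trans == "GS"))
}

count_events_one <- function(states, dt = 4) {
  count_global_events(state_matrix(matrix(states, ncol = 1), dt = dt))
}

# all state strings over {S,P,G} of a given length, as a character matrix
all_state_strings <- function(len) {
  as.matrix(expand.grid(rep(list(c("S", "P", "G")), len),
                        stringsAsFactors = FALSE))
}

# random proper rotation matrix
random_rotation <- function() {
  qr_d <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr_d)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# tiny hand-built system: protein cloud + Fe + ligand point sites at given
# positions; returns structure-ish list and a single-frame trajectory
build_point_system <- function(protein_xyz, fe_xyz, ligand_xyz_list,
                               box = c(100, 100, 100), n_frames = 1, dt = 4) {
  np <- nrow(protein_xyz)
  nl <- length(ligand_xyz_list)
  coords1 <- rbind(protein_xyz, fe_xyz,
                   do.call(rbind, ligand_xyz_list))
  coords <- array(rep(coords1, n_frames),
                  dim = c(nrow(coords1), 3, n_frames))
  sel <- site_selection(protein_heavy = seq_len(np), fe = np + 1L,
                        ligands = as.list(np + 1L + seq_len(nl)))
  list(trajectory = gas_trajectory(coords, box = box, dt = dt),
       selection = sel)
}

# atom table for a small multi-residue structure (for RMSF / IO fixtures)
build_atom_table <- function(n_residues = 4, atoms_per_residue = 3,
                             spread = 8) {
  n <- n_residues * atoms_per_residue
  set.seed(99)
  data.frame(
    eleno = seq_len(n),
    elety = rep(c("CA", "CB", "CG"), length.out = n),
    resid = "ALA",
    resno = rep(seq_len(n_residues), each = atoms_per_residue),
    chain = "A",
    element = "C",
    x = rnorm(n, 50, spread), y = rnorm(n, 50, spread),
    z = rnorm(n, 50, spread),
    stringsAsFactors = FALSE)
}
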