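#' Per-residue RMSF profile
#'
#' Root mean square fluctuation of each atom about its time-average
#' position, `sqrt(mean_t |r_t - <r>|^2)`, aggregated per residue and
#' reported in nm. Residues whose RMSF exceeds the flagging threshold
#' (default 0.15 nm, the mobile-region criterion) are marked.
#'
#' The trajectory should normally be superposed first (see
#' [superpose_frames()]); for synthetic jitter about a fixed frame the raw
#' trajectory can be profiled directly.
#'
#' @param traj a [gas_trajectory()] (coordinates in Angstrom).
#' @param atoms integer indices of the atoms to profile (e.g. protein heavy
#'   atoms, or Calpha atoms for a backbone-only profile).
#' @param residue_ids vector parallel to `atoms` giving each atom's residue
#'   label; per-residue values are the mean over that residue's atoms.
#' @param threshold_nm flagging threshold (nm).
#' @return object of class `rmsf_profile`: data frame with columns
#'   `residue`, `rmsf_nm`, `flagged`, plus attributes `atom_rmsf_nm` and
#'   `threshold_nm`.
#' @export
compute_rmsf <- function(traj, atoms, residue_ids, threshold_nm = 0.15) {
  stopifnot(inherits(traj, "gas_trajectory"))
  if (traj$n_frames < 2L) {
    stop("RMSF needs at least 2 frames", call. = FALSE)
  }
  atoms <- as.integer(atoms)
  if (length(residue_ids) != length(atoms)) {
    stop("residue_ids must parallel atoms", call. = FALSE)
  }
  xyz <- traj$coords[atoms, , , drop = FALSE]
  mean_xyz <- rowMeans(xyz, dims = 2)
  dev2 <- sweep(xyz, c(1, 2), mean_xyz)^2
  # mean over frames of the squared 3D displacement, per atom
  msf <- rowSums(rowMeans(dev2, dims = 2))
  atom_rmsf_nm <- sqrt(msf) / 10
  res_f <- factor(residue_ids, levels = unique(residue_ids))
  per_res <- tapply(atom_rmsf_nm, res_f, mean)
  out <- data.frame(residue = names(per_res), rmsf_nm = as.numeric(per_res),
                    flagged = as.numeric(per_res) > threshold_nm,
                    stringsAsFactors = FALSE)
  attr(out, "atom_rmsf_nm") <- stats::setNames(atom_rmsf_nm, atoms)
  attr(out, "threshold_nm") <- threshold_nm
  class(out) <- c("rmsf_profile", "data.frame")
  out
}

#' @export
print.rmsf_profile <- function(x, ...) {
  cat(sprintf("rmsf_profile: %d residues, %d flagged above %g nm\n",
              nrow(x), sum(x$flagged), attr(x, "threshold_nm")))
  NextMethod()
}
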