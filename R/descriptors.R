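#' Global gas-protein interaction descriptors
#'
#' Three trajectory-wide averages characterizing how much gas the protein
#' matrix holds: the mean number of ligands inside the matrix per frame
#' (state `P` or `G`), the mean number of protein heavy-atom contacts
#' summed over those ligands per frame, and their ratio (contacts per
#' in-matrix gas molecule). A contact is a protein heavy atom within
#' `contact_cutoff` of the ligand reference site (the central/dummy site by
#' default, the convention of the contact analysis).
#'
#' @param traj a [gas_trajectory()].
#' @param selection a [site_selection()].
#' @param sm the [state_matrix()] for this trajectory.
#' @param contact_cutoff contact distance (Angstrom), default 4.0.
#' @param reference ligand reference mode (default `"central"`).
#' @param wrap use minimum-image distances.
#' @return list of class `contact_descriptors`: `avg_gas_in_protein`,
#'   `avg_contacts_total`, `contacts_per_molecule`, `contact_cutoff`,
#'   `n_frames`.
#' @export
global_descriptors <- function(traj, selection, sm, contact_cutoff = 4.0,
                               reference = "central", wrap = TRUE) {
  stopifnot(inherits(sm, "state_matrix"))
  if (nrow(sm$states) != traj$n_frames ||
      ncol(sm$states) != length(selection$ligands)) {
    stop("state matrix does not match trajectory/selection", call. = FALSE)
  }
  scan <- ligand_protein_scan(traj, selection, what = "contact_counts",
                              contact_cutoff = contact_cutoff,
                              reference = reference, wrap = wrap)
  inside <- t(sm$states != "S")            # ligand x frame
  n_in <- colSums(inside)
  contacts <- colSums(scan$contact_counts * inside)
  avg_gas <- mean(n_in)
  avg_contacts <- mean(contacts)
  if (avg_gas == 0) {
    warning("no ligand ever inside the protein matrix; descriptors are 0",
            call. = FALSE)
    ratio <- 0
  } else {
    ratio <- avg_contacts / avg_gas
  }
  structure(list(avg_gas_in_protein = avg_gas,
                 avg_contacts_total = avg_contacts,
                 contacts_per_molecule = ratio,
                 contact_cutoff = contact_cutoff,
                 n_frames = traj$n_frames),
            class = "contact_descriptors")
}

#' @export
print.contact_descriptors <- function(x, ...) {
  cat(sprintf(paste0("contact_descriptors: %.3g gas molecules in protein/frame, ",
                     "%.3g contacts/frame, %.3g contacts per molecule ",
                     "(cutoff %g A)\n"),
              x$avg_gas_in_protein, x$avg_contacts_total,
              x$contacts_per_molecule, x$contact_cutoff))
  invisible(x)
}
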