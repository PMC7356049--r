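#' Classifier cutoffs for the three-state model
#'
#' A ligand is a geminate pair when its reference point lies within
#' `geminate_cutoff` of the heme Fe; otherwise it is in the protein state
#' when within `protein_cutoff` of any protein heavy atom; otherwise it is
#' in the solvent. Both comparisons are strict `<`.
#'
#' @param geminate_cutoff Fe distance bound (Angstrom), default 3.5.
#' @param protein_cutoff protein heavy-atom distance bound (Angstrom),
#'   default 6.0.
#' @return object of class `classifier_config`.
#' @export
classifier_config <- function(geminate_cutoff = 3.5, protein_cutoff = 6.0) {
  if (!(geminate_cutoff > 0 && geminate_cutoff < protein_cutoff)) {
    stop("need 0 < geminate_cutoff < protein_cutoff", call. = FALSE)
  }
  structure(list(geminate_cutoff = geminate_cutoff,
                 protein_cutoff = protein_cutoff),
            class = "classifier_config")
}

#' Classify a single (ligand, frame) observation
#'
#' Vectorized over its distance arguments.
#'
#' @param fe_distance distance from the ligand reference point to the heme
#'   Fe (Angstrom).
#' @param min_protein_distance minimum distance to any protein heavy atom
#'   (Angstrom).
#' @param config a [classifier_config()].
#' @return character vector of `"G"`, `"P"` or `"S"`.
#' @export
classify_state <- function(fe_distance, min_protein_distance,
                           config = classifier_config()) {
  stopifnot(all(fe_distance >= 0), all(min_protein_distance >= 0))
  ifelse(fe_distance < config$geminate_cutoff, "G",
         ifelse(min_protein_distance < config$protein_cutoff, "P", "S"))
}

#' Classify every ligand in every frame
#'
#' Applies the three-state rule to a whole trajectory. Distances use the
#' minimum-image convention by default and the ligand reference point is
#' the center of the ligand's sites (`"com"`), the convention used for the
#' kinetic model.
#'
#' @param traj a [gas_trajectory()].
#' @param selection a [site_selection()].
#' @param config a [classifier_config()].
#' @param reference ligand reference mode (`NULL` uses the selection's).
#' @param wrap use minimum-image distances.
#' @return a [state_matrix()] (`n_frames x n_ligands`).
#' @export
classify_trajectory <- function(traj, selection, config = classifier_config(),
                                reference = NULL, wrap = TRUE) {
  scan <- ligand_protein_scan(traj, selection, what = c("min_dist", "fe_dist"),
                              reference = reference, wrap = wrap)
  states <- matrix(classify_state(scan$fe_dist, scan$min_dist, config),
                   nrow = nrow(scan$fe_dist))
  # scan matrices are ligand x frame; the state matrix is frame x ligand
  state_matrix(t(states), dt = traj$dt,
               ligand_ids = names(selection$ligands))
}
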