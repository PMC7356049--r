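#' Atom-site selection for gas-migration analysis
#'
#' Bundles the three index sets every downstream computation needs: the
#' protein heavy atoms, the heme Fe atom, and one index group per gas
#' ligand. Indices refer to rows of the trajectory coordinate block.
#'
#' The per-ligand reference point used in distance computations is either
#' the unweighted center of its sites (`"com"`, the default, used for state
#' classification) or the middle site of the group (`"central"`; for 3-site
#' diatomic gas models this is the massless central dummy site, the
#' convention used for contact and pocket analysis).
#'
#' @param protein_heavy integer indices of protein heavy atoms.
#' @param fe single integer index of the heme Fe atom.
#' @param ligands list of integer vectors, one per ligand, each the ligand's
#'   interaction sites (length >= 1).
#' @param reference default ligand reference point mode, `"com"` or
#'   `"central"`.
#' @return an object of class `site_selection`.
#' @export
site_selection <- function(protein_heavy, fe, ligands,
                           reference = c("com", "central")) {
  reference <- match.arg(reference)
  protein_heavy <- as.integer(protein_heavy)
  fe <- as.integer(fe)
  if (length(fe) != 1L || is.na(fe)) {
    stop("selection error: exactly one Fe atom index is required", call. = FALSE)
  }
  if (!is.list(ligands) || length(ligands) == 0L) {
    stop("selection error: at least one ligand site group is required",
         call. = FALSE)
  }
  ligands <- lapply(ligands, as.integer)
  if (any(vapply(ligands, length, 1L) < 1L)) {
    stop("selection error: every ligand needs at least one site", call. = FALSE)
  }
  lig_all <- unlist(ligands)
  if (anyDuplicated(lig_all)) {
    stop("selection error: ligand site groups overlap", call. = FALSE)
  }
  if (fe %in% protein_heavy || fe %in% lig_all ||
      length(intersect(protein_heavy, lig_all)) > 0L) {
    stop("selection error: protein, Fe and ligand index sets must be disjoint",
         call. = FALSE)
  }
  if (is.null(names(ligands))) {
    names(ligands) <- paste0("lig", seq_along(ligands))
  }
  structure(
    list(protein_heavy = protein_heavy, fe = fe, ligands = ligands,
         reference = reference),
    class = "site_selection"
  )
}

#' @export
print.site_selection <- function(x, ...) {
  cat("site_selection:", length(x$protein_heavy), "protein heavy atoms, Fe atom",
      x$fe, ",", length(x$ligands), "ligands (reference:", x$reference, ")\n")
  invisible(x)
}

#' Number of ligands in a selection
#' @param selection a [site_selection()].
#' @return integer ligand count.
#' @export
n_ligands <- function(selection) length(selection$ligands)

# index of the reference site used in "central" mode: the middle site
.central_site <- function(sites) sites[ceiling(length(sites) / 2)]
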