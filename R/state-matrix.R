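#' Per-ligand, per-frame state matrix
#'
#' Holds the three-state classification of every ligand in every retained
#' frame: `"G"` (geminate pair with the heme Fe), `"P"` (inside the protein
#' matrix), `"S"` (solvent phase).
#'
#' @param states character matrix, `n_frames x n_ligands`, entries in
#'   `c("G","P","S")`.
#' @param dt time between frames (ps).
#' @param ligand_ids optional ligand labels (column names).
#' @return object of class `state_matrix`.
#' @export
state_matrix <- function(states, dt, ligand_ids = NULL) {
  states <- as.matrix(states)
  if (!all(states %in% c("G", "P", "S"))) {
    stop("state matrix contains labels outside {G, P, S}", call. = FALSE)
  }
  if (!is.numeric(dt) || dt <= 0) stop("dt must be positive", call. = FALSE)
  if (is.null(ligand_ids)) {
    ligand_ids <- colnames(states)
    if (is.null(ligand_ids)) ligand_ids <- paste0("lig", seq_len(ncol(states)))
  }
  colnames(states) <- ligand_ids
  structure(list(states = states, dt = dt, ligand_ids = ligand_ids),
            class = "state_matrix")
}

#' @export
print.state_matrix <- function(x, ...) {
  tab <- table(factor(x$states, levels = c("G", "P", "S")))
  cat(sprintf("state_matrix: %d frames x %d ligands (dt = %g ps); G:%d P:%d S:%d\n",
              nrow(x$states), ncol(x$states), x$dt, tab["G"], tab["P"], tab["S"]))
  invisible(x)
}

#' Write a state matrix in the internal text format
#'
#' Line 1 is a JSON header (`dt`, `ligand_ids`, `n_frames`); each following
#' line is one frame as a string of single-character codes, one per ligand.
#' The format is diffable and round-trips losslessly.
#'
#' @param sm a [state_matrix()].
#' @param path output file.
#' @export
write_state_matrix <- function(sm, path) {
  stopifnot(inherits(sm, "state_matrix"))
  header <- jsonlite::toJSON(
    list(dt = sm$dt, ligand_ids = sm$ligand_ids, n_frames = nrow(sm$states)),
    auto_unbox = TRUE, digits = NA)
  rows <- apply(sm$states, 1, paste, collapse = "")
  writeLines(c(as.character(header), rows), path)
  invisible(path)
}

#' Read a state matrix written by [write_state_matrix()]
#'
#' @param path input file.
#' @return a [state_matrix()].
#' @export
read_state_matrix <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L) stop("truncated state-matrix file", call. = FALSE)
  header <- jsonlite::fromJSON(lines[1])
  rows <- lines[-1]
  if (length(rows) != header$n_frames) {
    stop("state-matrix frame count disagrees with header", call. = FALSE)
  }
  states <- do.call(rbind, strsplit(rows, ""))
  state_matrix(states, dt = header$dt, ligand_ids = header$ligand_ids)
}
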