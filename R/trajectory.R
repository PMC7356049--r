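#' Construct an in-memory trajectory
#'
#' The central container of the package: coordinates of all atoms over
#' frames of a periodic, orthorhombic simulation cell. Coordinates are in
#' Angstrom, times in picoseconds throughout; volumes appear in dm^3 only
#' inside the kinetics functions.
#'
#' The original simulations use a dodecahedral cell; the analysis here
#' adopts an orthorhombic periodic cell because the kinetic model consumes
#' only the cell volume, which is shape-independent.
#'
#' @param coords numeric array `n_atoms x 3 x n_frames` (Angstrom).
#' @param box numeric length-3 orthorhombic edge lengths (Angstrom).
#' @param dt time between stored frames (ps).
#' @param start_time time of the first stored frame (ps); frame times are
#'   `start_time + (0:(n_frames-1)) * dt`.
#' @return object of class `gas_trajectory` with elements `coords`, `box`,
#'   `dt`, `times`, `n_atoms`, `n_frames`.
#' @export
gas_trajectory <- function(coords, box, dt, start_time = 0) {
  if (length(dim(coords)) == 2L) {
    coords <- array(coords, dim = c(dim(coords), 1L))
  }
  stopifnot(length(dim(coords)) == 3L, dim(coords)[2] == 3L)
  box <- as.numeric(box)
  if (length(box) == 1L) box <- rep(box, 3L)
  stopifnot(length(box) == 3L)
  if (any(box <= 0)) stop("box edges must be positive", call. = FALSE)
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0) {
    stop("dt must be a positive scalar (ps)", call. = FALSE)
  }
  nf <- dim(coords)[3]
  structure(
    list(coords = coords, box = box, dt = dt,
         times = start_time + (seq_len(nf) - 1) * dt,
         n_atoms = dim(coords)[1], n_frames = nf),
    class = "gas_trajectory"
  )
}

#' @export
print.gas_trajectory <- function(x, ...) {
  cat(sprintf("gas_trajectory: %d atoms, %d frames, dt = %g ps, box = %s A\n",
              x$n_atoms, x$n_frames, x$dt,
              paste(signif(x$box, 6), collapse = " x ")))
  invisible(x)
}

#' Discard the equilibration portion of a trajectory
#'
#' Frames with time earlier than `cut_ps` are dropped; retained frames keep
#' their original times, so per-frame classifications of retained frames are
#' unchanged by the cut.
#'
#' @param traj a [gas_trajectory()].
#' @param cut_ps equilibration time to discard (ps).
#' @return the trimmed trajectory.
#' @export
trim_equilibration <- function(traj, cut_ps) {
  stopifnot(inherits(traj, "gas_trajectory"), cut_ps >= 0)
  keep <- traj$times >= cut_ps
  if (!any(keep)) stop("empty trajectory after equilibration cut", call. = FALSE)
  out <- traj
  out$coords <- traj$coords[, , keep, drop = FALSE]
  out$times <- traj$times[keep]
  out$n_frames <- sum(keep)
  out
}

#' Minimum-image distance in an orthorhombic periodic cell
#'
#' Shortest distance between two points over all periodic images of the
#' cell. `a` and `b` may be single points (length-3) or `n x 3` matrices of
#' paired points.
#'
#' @param a,b points (Angstrom).
#' @param box length-3 orthorhombic edge lengths (Angstrom).
#' @param wrap if `FALSE`, plain Euclidean distance is returned (provided
#'   because the source protocol does not state whether periodic wrapping
#'   was applied; minimum-image is the default assumption).
#' @return numeric distance(s), Angstrom.
#' @export
minimum_image_distance <- function(a, b, box, wrap = TRUE) {
  if (is.null(dim(a))) a <- matrix(a, ncol = 3)
  if (is.null(dim(b))) b <- matrix(b, ncol = 3)
  box <- as.numeric(box)
  if (length(box) == 1L) box <- rep(box, 3L)
  if (any(box <= 0)) stop("box edges must be positive", call. = FALSE)
  d <- a - b
  if (wrap) {
    d <- sweep(d, 2, box, function(x, L) x - L * round(x / L))
  }
  sqrt(rowSums(d * d))
}

# displacement matrix with minimum-image wrapping applied per dimension
.mi_delta <- function(d, edge) d - edge * round(d / edge)

#' Per-ligand reference points across frames
#'
#' @param traj a [gas_trajectory()].
#' @param selection a [site_selection()].
#' @param reference `"com"` (unweighted center of the ligand's sites) or
#'   `"central"` (middle/dummy site); defaults to the selection's own mode.
#' @return array `n_ligands x 3 x n_frames` of reference coordinates.
#' @export
ligand_positions <- function(traj, selection, reference = NULL) {
  stopifnot(inherits(traj, "gas_trajectory"), inherits(selection, "site_selection"))
  if (is.null(reference)) reference <- selection$reference
  reference <- match.arg(reference, c("com", "central"))
  nl <- length(selection$ligands)
  out <- array(NA_real_, dim = c(nl, 3L, traj$n_frames))
  for (l in seq_len(nl)) {
    sites <- selection$ligands[[l]]
    if (reference == "central" || length(sites) == 1L) {
      out[l, , ] <- traj$coords[.central_site(sites), , , drop = TRUE]
    } else {
      out[l, , ] <- colMeans(traj$coords[sites, , , drop = FALSE], dims = 1)
    }
  }
  out
}

# TRUE when a coordinate subset is identical in every frame (static scaffold
# fast path used by the distance scans)
.is_static <- function(coords, idx) {
  ref <- coords[idx, , 1L]
  for (f in seq_len(dim(coords)[3])) {
    if (any(coords[idx, , f] != ref)) return(FALSE)
  }
  TRUE
}

# fast row-wise minimum of a numeric matrix
.row_min <- function(m) {
  m[cbind(seq_len(nrow(m)), max.col(-m, ties.method = "first"))]
}

#' Ligand-to-protein distance scan
#'
#' One pass over the trajectory computing, per ligand and frame, whatever
#' subset of the following is requested: the minimum distance to any protein
#' heavy atom, the distance to the Fe atom, the number of protein heavy
#' atoms within `contact_cutoff`, and the per-protein-atom total contact
#' count over all (frame, ligand) pairs. All distances are minimum-image
#' unless `wrap = FALSE`.
#'
#' A fast vectorized path is used when the protein scaffold is static
#' across frames (as in the toy shell system); otherwise frames are
#' processed one at a time.
#'
#' @param traj a [gas_trajectory()].
#' @param selection a [site_selection()].
#' @param what character vector among `"min_dist"`, `"fe_dist"`,
#'   `"contact_counts"`, `"atom_counts"`.
#' @param contact_cutoff contact distance (Angstrom) for the count outputs.
#' @param reference ligand reference mode passed to [ligand_positions()].
#' @param wrap use minimum-image distances.
#' @param chunk number of frames per block in the static fast path.
#' @return list with the requested elements: `min_dist` and `fe_dist` are
#'   `n_ligands x n_frames` matrices, `contact_counts` an integer matrix of
#'   the same shape, `atom_counts` an integer vector over protein heavy
#'   atoms (named by atom index).
#' @export
ligand_protein_scan <- function(traj, selection,
                                what = c("min_dist", "fe_dist"),
                                contact_cutoff = 4.0,
                                reference = NULL, wrap = TRUE,
                                chunk = 100L) {
  stopifnot(inherits(traj, "gas_trajectory"), inherits(selection, "site_selection"))
  what <- match.arg(what, c("min_dist", "fe_dist", "contact_counts",
                            "atom_counts"), several.ok = TRUE)
  lig <- ligand_positions(traj, selection, reference)
  nl <- dim(lig)[1]; nf <- traj$n_frames
  prot <- selection$protein_heavy
  np <- length(prot)
  box <- traj$box
  out <- list()

  if ("fe_dist" %in% what) {
    fe_xyz <- t(traj$coords[selection$fe, , , drop = TRUE])  # nf x 3
    if (nf == 1L) fe_xyz <- matrix(fe_xyz, ncol = 3)
    fd <- matrix(NA_real_, nl, nf)
    for (l in seq_len(nl)) {
      fd[l, ] <- minimum_image_distance(t(lig[l, , , drop = TRUE]), fe_xyz,
                                        box, wrap = wrap)
    }
    out$fe_dist <- fd
  }

  need_prot <- any(c("min_dist", "contact_counts", "atom_counts") %in% what)
  if (!need_prot) return(out)
  if (np == 0L) stop("selection has no protein heavy atoms", call. = FALSE)

  want_min <- "min_dist" %in% what
  want_cc <- "contact_counts" %in% what
  want_ac <- "atom_counts" %in% what
  if (want_min) out$min_dist <- matrix(NA_real_, nl, nf)
  if (want_cc) out$contact_counts <- matrix(0L, nl, nf)
  if (want_ac) acc_atoms <- numeric(np)

  c2 <- contact_cutoff^2

  # squared distances of a block of ligand points (m x 3) to protein coords
  # (np x 3), minimum image
  block_d2 <- function(L, P) {
    d2 <- matrix(0, nrow(L), np)
    for (k in 1:3) {
      dk <- outer(L[, k], P[, k], "-")
      if (wrap) dk <- .mi_delta(dk, box[k])
      d2 <- d2 + dk * dk
    }
    d2
  }

  static <- .is_static(traj$coords, prot)
  if (static) {
    P <- traj$coords[prot, , 1L, drop = TRUE]
    if (np == 1L) P <- matrix(P, ncol = 3)
    starts <- seq(1L, nf, by = chunk)
    for (s in starts) {
      fr <- s:min(s + chunk - 1L, nf)
      m <- length(fr)
      # rows ordered ligand-major within frame: (l1f1..lnlf1, l1f2, ...)
      L <- matrix(aperm(lig[, , fr, drop = FALSE], c(1, 3, 2)), ncol = 3)
      d2 <- block_d2(L, P)
      if (want_min) {
        out$min_dist[, fr] <- matrix(sqrt(.row_min(d2)), nl, m)
      }
      hit <- d2 < c2
      if (want_cc) out$contact_counts[, fr] <- matrix(rowSums(hit), nl, m)
      if (want_ac) acc_atoms <- acc_atoms + colSums(hit)
    }
  } else {
    for (f in seq_len(nf)) {
      P <- traj$coords[prot, , f, drop = TRUE]
      if (np == 1L) P <- matrix(P, ncol = 3)
      L <- matrix(lig[, , f], ncol = 3)
      d2 <- block_d2(L, P)
      if (want_min) out$min_dist[, f] <- sqrt(.row_min(d2))
      hit <- d2 < c2
      if (want_cc) out$contact_counts[, f] <- rowSums(hit)
      if (want_ac) acc_atoms <- acc_atoms + colSums(hit)
    }
  }
  if (want_ac) {
    out$atom_counts <- stats::setNames(as.integer(acc_atoms), prot)
  }
  out
}
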