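#' Rigid-body least-squares superposition of trajectory frames
#'
#' Fits every frame onto a reference by the optimal rotation + translation
#' (Kabsch algorithm via SVD) computed on a fitting selection, then applies
#' the transform to all atoms. By default a two-pass scheme is used: frames
#' are first fitted to the first frame, the time-average structure of that
#' fit becomes the reference, and frames are refitted to it — the standard
#' convention for fluctuation analysis.
#'
#' Periodic images are not unwrapped; the fitting selection is assumed to
#' be a whole molecule within one image.
#'
#' @param traj a [gas_trajectory()].
#' @param fit_atoms integer indices used to compute the fit (>= 3
#'   non-collinear atoms).
#' @param reference `"mean"` (two-pass, default) or `"first"` (single pass
#'   onto frame 1).
#' @return the fitted trajectory; the reference coordinates of the fitting
#'   selection are attached as attribute `"reference"`.
#' @export
superpose_frames <- function(traj, fit_atoms,
                             reference = c("mean", "first")) {
  stopifnot(inherits(traj, "gas_trajectory"))
  reference <- match.arg(reference)
  fit_atoms <- as.integer(fit_atoms)
  if (length(fit_atoms) < 3L) {
    stop("degenerate fitting selection: need at least 3 atoms", call. = FALSE)
  }
  ref0 <- traj$coords[fit_atoms, , 1L]
  if (qr(sweep(ref0, 2, colMeans(ref0)))$rank < 2L) {
    stop("degenerate fitting selection: atoms are collinear", call. = FALSE)
  }
  pass <- function(tr, ref) {
    out <- tr$coords
    for (f in seq_len(tr$n_frames)) {
      tf <- kabsch_transform(tr$coords[fit_atoms, , f], ref)
      out[, , f] <- sweep(tr$coords[, , f] %*% tf$rotation, 2, tf$translation, "+")
    }
    tr$coords <- out
    tr
  }
  fitted <- pass(traj, ref0)
  if (reference == "mean") {
    ref <- rowMeans(fitted$coords[fit_atoms, , , drop = FALSE], dims = 2)
    fitted <- pass(fitted, ref)
    attr(fitted, "reference") <- rowMeans(fitted$coords[fit_atoms, , ,
                                                        drop = FALSE], dims = 2)
  } else {
    attr(fitted, "reference") <- ref0
  }
  fitted
}

#' Optimal rigid transform between two point sets
#'
#' Returns the proper rotation `R` and translation `t` minimizing
#' `|| P R + t - Q ||^2` (Kabsch, with reflection correction).
#'
#' @param P,Q `n x 3` matrices of paired points.
#' @return list with `rotation` (3x3), `translation` (length 3), and the
#'   post-fit `rmsd`.
#' @export
kabsch_transform <- function(P, Q) {
  stopifnot(nrow(P) == nrow(Q), ncol(P) == 3L, ncol(Q) == 3L)
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  s <- svd(crossprod(Pc, Qc))
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  tvec <- cq - as.numeric(cp %*% R)
  fitted <- sweep(P %*% R, 2, tvec, "+")
  list(rotation = R, translation = tvec,
       rmsd = sqrt(mean(rowSums((fitted - Q)^2))))
}
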