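#' Specification of a three-state Markov state-sequence generator
#'
#' Ligands are independent continuous-time Markov chains over the states
#' `S` (solvent), `P` (protein), `G` (geminate). Direct S<->G jumps are
#' forbidden: a ligand must traverse the protein matrix, mirroring the
#' physical passage the event counter assumes.
#'
#' @param rates named numeric vector/list of transition rates in ps^-1 with
#'   elements `SP`, `PS`, `PG`, `GP` (others default to 0; `SG`/`GS` must
#'   be 0).
#' @param n_ligands number of independent chains.
#' @param n_frames frames to discretize onto.
#' @param dt frame spacing (ps).
#' @param seed RNG seed (R's default Mersenne-Twister generator).
#' @return object of class `markov_spec`.
#' @export
markov_spec <- function(rates, n_ligands = 40, n_frames = 10000, dt = 4,
                        seed = 1) {
  r <- c(SP = 0, PS = 0, PG = 0, GP = 0, SG = 0, GS = 0)
  r[names(rates)] <- unlist(rates)
  if (any(r < 0)) stop("rates must be >= 0", call. = FALSE)
  if (r["SG"] != 0 || r["GS"] != 0) {
    stop("direct S<->G transitions are forbidden", call. = FALSE)
  }
  if (all(r == 0)) stop("all rates are zero", call. = FALSE)
  stopifnot(n_ligands >= 1, n_frames >= 2, dt > 0)
  structure(list(rates = r, n_ligands = n_ligands, n_frames = n_frames,
                 dt = dt, seed = seed),
            class = "markov_spec")
}

#' Generate Markov state sequences with known rates
#'
#' Samples each ligand's chain with exact exponential event times and then
#' discretizes onto the frame grid (the state in effect at each frame
#' time), which avoids time-step bias in the underlying dwell statistics.
#' Chains start from the stationary distribution when it exists (all four
#' S-P-G rates positive), otherwise in `S`.
#'
#' Alongside the matrix, the analytic quantities the estimators should
#' recover are returned: the effective geminate escape rate
#' `GP * PS / (PS + PG)` (the rate at which an anchored geminate ligand
#' completes a passage back to solvent, per unit geminate time: excursions
#' to `P` that return to `G` do not terminate a passage) and the expected
#' global event rate per ligand.
#'
#' @param spec a [markov_spec()].
#' @return list with `states` (a [state_matrix()]), `rates`, `stationary`,
#'   and `analytic` (`escape_rate_ps`, `event_rate_per_ligand_ps`,
#'   `expected_events`).
#' @export
generate_markov_states <- function(spec) {
  stopifnot(inherits(spec, "markov_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  r <- spec$rates
  labels <- c("S", "P", "G")
  Q <- matrix(0, 3, 3, dimnames = list(labels, labels))
  Q["S", "P"] <- r["SP"]; Q["P", "S"] <- r["PS"]
  Q["P", "G"] <- r["PG"]; Q["G", "P"] <- r["GP"]
  out_rate <- rowSums(Q)

  stationary <- if (all(r[c("SP", "PS", "PG", "GP")] > 0)) {
    w <- c(S = 1,
           P = r[["SP"]] / r[["PS"]],
           G = r[["SP"]] * r[["PG"]] / (r[["PS"]] * r[["GP"]]))
    w / sum(w)
  } else NULL

  frame_times <- (seq_len(spec$n_frames) - 1) * spec$dt
  t_end <- frame_times[spec$n_frames]
  states <- matrix(NA_character_, spec$n_frames, spec$n_ligands)
  for (l in seq_len(spec$n_ligands)) {
    s <- if (is.null(stationary)) 1L else
      sample.int(3L, 1L, prob = stationary)
    seq_states <- s
    jump_times <- 0
    t <- 0
    while (t <= t_end) {
      rate <- out_rate[s]
      if (rate == 0) break  # absorbing state
      t <- t + stats::rexp(1L, rate)
      if (t > t_end) break
      s <- sample.int(3L, 1L, prob = Q[s, ])
      seq_states <- c(seq_states, s)
      jump_times <- c(jump_times, t)
    }
    states[, l] <- labels[seq_states[findInterval(frame_times, jump_times)]]
  }

  p_escape <- if (r[["PS"]] + r[["PG"]] > 0) {
    r[["PS"]] / (r[["PS"]] + r[["PG"]])
  } else 0
  escape_rate <- r[["GP"]] * p_escape
  event_rate <- if (!is.null(stationary)) {
    stationary[["G"]] * escape_rate
  } else NA_real_

  list(states = state_matrix(states, dt = spec$dt),
       rates = r, stationary = stationary,
       analytic = list(
         escape_rate_ps = escape_rate,
         event_rate_per_ligand_ps = event_rate,
         expected_events = if (is.na(event_rate)) NA_real_ else
           event_rate * t_end * spec$n_ligands))
}

#' Specification of the Brownian toy shell system
#'
#' A desk-scale stand-in for a gas-diffusion simulation box: a static
#' spherical shell of pseudo-atoms (the "protein") with an Fe site at its
#' center sits in a periodic cubic cell; point ligands perform a Gaussian
#' random walk with hard-core exclusion from the shell atoms. Circular
#' channels (gaps in the shell) are the only way into the central cavity,
#' so blocking them (aperture 0) makes complete solvent-to-geminate
#' passages impossible.
#'
#' Defaults reproduce the physical study conditions: 40 ligands in a cubic
#' cell of edge 73 A (volume 3.89e-22 dm^3, inside the simulated cell-volume
#' range, gas concentration ~0.17 M), frames every 4 ps. The shell radius
#' (9.5 A) keeps every interior point either in the geminate zone or within
#' the protein-state cutoff of the classifier, so the cavity never reads as
#' solvent; the atom count (400) keeps every point of the closed surface
#' within 1.28 A of an atom, which the 1.5 A hard core makes impassable;
#' and the step width (2 A/frame per
#' coordinate) corresponds to a diffusion coefficient of ~5e-9 m^2/s, the
#' scale of a light gas in water at body temperature.
#'
#' @param box_edge cubic cell edge (Angstrom).
#' @param shell_radius shell radius (Angstrom), must be < `box_edge/2`.
#' @param shell_atom_count number of shell pseudo-atoms before channel
#'   carving.
#' @param channel_count number of circular channels through the shell.
#' @param channel_aperture_deg half-angle of each channel (degrees); 0
#'   closes all channels.
#' @param n_ligands number of gas ligands.
#' @param step_sigma per-coordinate Gaussian step width per frame
#'   (Angstrom).
#' @param n_frames,dt trajectory length and frame spacing (ps).
#' @param hardcore hard-core exclusion radius of shell atoms (Angstrom).
#' @param shell_jitter optional per-coordinate Gaussian jitter of shell
#'   atoms per frame (Angstrom); 0 keeps the scaffold static.
#' @param seed RNG seed.
#' @return object of class `toy_system_spec`.
#' @export
toy_system_spec <- function(box_edge = 73.0, shell_radius = 9.5,
                            shell_atom_count = 400, channel_count = 3,
                            channel_aperture_deg = 45, n_ligands = 40,
                            step_sigma = 2.0, n_frames = 25000, dt = 4,
                            hardcore = 1.5, shell_jitter = 0, seed = 1) {
  stopifnot(box_edge > 0, shell_radius > 0, shell_atom_count >= 4,
            channel_count >= 0, channel_aperture_deg >= 0,
            n_ligands >= 1, step_sigma >= 0, n_frames >= 1, dt > 0,
            hardcore > 0, shell_jitter >= 0)
  if (shell_radius >= box_edge / 2) {
    stop("shell_radius must be smaller than half the box edge", call. = FALSE)
  }
  structure(list(box_edge = box_edge, shell_radius = shell_radius,
                 shell_atom_count = shell_atom_count,
                 channel_count = channel_count,
                 channel_aperture_deg = channel_aperture_deg,
                 n_ligands = n_ligands, step_sigma = step_sigma,
                 n_frames = n_frames, dt = dt, hardcore = hardcore,
                 shell_jitter = shell_jitter, seed = seed),
            class = "toy_system_spec")
}

# near-uniform points on the unit sphere (Fibonacci lattice)
.fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (3 - sqrt(5)) * (seq_len(n) - 1)
  z <- 1 - 2 * i / n
  rho <- sqrt(pmax(0, 1 - z^2))
  cbind(rho * cos(phi), rho * sin(phi), z)
}

#' Generate the Brownian toy shell trajectory
#'
#' See [toy_system_spec()] for the model. Ligand moves that would bring a
#' ligand within the hard-core radius of a shell atom anywhere along the
#' step segment (checked at <= 1 A resolution whenever the segment crosses
#' the shell band) are rejected, so the shell is impenetrable except
#' through its channels; positions wrap periodically at the box.
#'
#' @param spec a [toy_system_spec()].
#' @return list with `structure` (a `gas_structure`: atom table, selection,
#'   box), `trajectory` (a [gas_trajectory()]), and `spec`.
#' @export
generate_toy_system <- function(spec) {
  stopifnot(inherits(spec, "toy_system_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  L <- spec$box_edge
  center <- rep(L / 2, 3)
  R <- spec$shell_radius
  hc <- spec$hardcore

  shell <- sweep(.fibonacci_sphere(spec$shell_atom_count) * R, 2, center, "+")
  if (spec$channel_count > 0 && spec$channel_aperture_deg > 0) {
    axes <- .fibonacci_sphere(spec$channel_count)
    u <- sweep(shell, 2, center)
    u <- u / sqrt(rowSums(u^2))
    cosmax <- cos(spec$channel_aperture_deg * pi / 180)
    in_channel <- apply(u %*% t(axes) > cosmax, 1, any)
    shell <- shell[!in_channel, , drop = FALSE]
  }
  ns <- nrow(shell)
  if (ns < 4L) stop("channel carving removed almost the whole shell", call. = FALSE)

  # initial ligand placement in the bulk phase
  nl <- spec$n_ligands
  pos <- matrix(NA_real_, nl, 3)
  for (l in seq_len(nl)) {
    ok <- FALSE
    for (try in seq_len(1000L)) {
      p <- stats::runif(3, 0, L)
      if (sqrt(sum((.mi_delta(p - center, L))^2)) > R + hc) {
        pos[l, ] <- p; ok <- TRUE; break
      }
    }
    if (!ok) stop("ligand insertion failed: box too crowded", call. = FALSE)
  }

  nf <- spec$n_frames
  na <- ns + 1L + nl
  coords <- array(NA_real_, c(na, 3, nf))
  shell_idx <- seq_len(ns)
  fe_idx <- ns + 1L
  lig_idx <- ns + 1L + seq_len(nl)

  seg_blocked <- function(p0, p1) {
    # sample the step segment at <= 0.5 A spacing and test the hard core
    len <- sqrt(sum((p1 - p0)^2))
    ts <- seq(0, 1, length.out = max(2L, ceiling(2 * len) + 1L))
    for (tt in ts) {
      q <- p0 + tt * (p1 - p0)
      dq <- sweep(shell, 2, q)
      if (min(rowSums(.mi_delta(dq, L)^2)) < hc^2) return(TRUE)
    }
    FALSE
  }

  for (f in seq_len(nf)) {
    if (f > 1L && spec$step_sigma > 0) {
      step <- matrix(stats::rnorm(nl * 3, 0, spec$step_sigma), nl, 3)
      prop <- pos + step
      d0 <- sqrt(rowSums(.mi_delta(sweep(pos, 2, center), L)^2))
      d1 <- sqrt(rowSums(.mi_delta(sweep(prop, 2, center), L)^2))
      steplen <- sqrt(rowSums(step^2))
      # ligands whose step segment cannot reach the shell band are free
      maybe <- pmax(d0, d1) >= R - hc & pmin(d0, d1) - steplen <= R + hc
      free <- which(!maybe)
      if (length(free)) pos[free, ] <- prop[free, , drop = FALSE] %% L
      for (l in which(maybe)) {
        # closest approach of the segment to the shell center
        p0 <- pos[l, ]; p1 <- prop[l, ]
        seg <- p1 - p0
        w <- .mi_delta(center - p0, L)
        tt <- if (sum(seg^2) > 0) min(1, max(0, sum(w * seg) / sum(seg^2))) else 0
        rmin <- sqrt(sum((.mi_delta(p0 + tt * seg - center, L))^2))
        rmax <- max(d0[l], d1[l])
        crosses_band <- rmax >= R - hc && rmin <= R + hc
        if (!crosses_band || !seg_blocked(p0, p1)) {
          pos[l, ] <- p1 %% L
        }
      }
    }
    coords[shell_idx, , f] <- if (spec$shell_jitter > 0) {
      shell + matrix(stats::rnorm(ns * 3, 0, spec$shell_jitter), ns, 3)
    } else shell
    coords[fe_idx, , f] <- center
    coords[lig_idx, , f] <- pos
  }

  atoms <- data.frame(
    eleno = seq_len(na),
    elety = c(sprintf("C%d", shell_idx), "FE", rep("X", nl)),
    resid = c(rep("SHL", ns), "HEM", rep("LIG", nl)),
    resno = c(rep(1L, ns), 2L, 2L + seq_len(nl)),
    chain = "A",
    element = c(rep("C", ns), "FE", rep("X", nl)),
    x = coords[, 1, 1], y = coords[, 2, 1], z = coords[, 3, 1],
    stringsAsFactors = FALSE)
  sel <- site_selection(protein_heavy = shell_idx, fe = fe_idx,
                        ligands = as.list(lig_idx), reference = "com")
  structure_obj <- structure(
    list(atoms = atoms, selection = sel, box = rep(L, 3),
         source = "synthetic:toy-shell"),
    class = "gas_structure")
  list(structure = structure_obj,
       trajectory = gas_trajectory(coords, box = rep(L, 3), dt = spec$dt),
       spec = spec)
}

#' Jittered copies of a base structure
#'
#' Adds independent isotropic Gaussian displacements to every atom in
#' every frame, the validation harness for the RMSF estimator: per-atom
#' RMSF converges to `sigma * sqrt(3)`.
#'
#' @param base_coords `n_atoms x 3` base coordinates (Angstrom).
#' @param sigma_nm per-coordinate jitter, nm; scalar or per-atom vector.
#' @param n_frames number of frames.
#' @param dt frame spacing (ps).
#' @param box cell edges (Angstrom); defaults to a loose bounding box.
#' @param seed RNG seed.
#' @return a [gas_trajectory()].
#' @export
generate_jittered_structure <- function(base_coords, sigma_nm, n_frames,
                                        dt = 4, box = NULL, seed = 1) {
  base_coords <- as.matrix(base_coords)
  stopifnot(ncol(base_coords) == 3L, n_frames >= 1, all(sigma_nm >= 0))
  n <- nrow(base_coords)
  sigma_A <- rep(sigma_nm * 10, length.out = n)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(box)) {
    box <- apply(base_coords, 2, function(v) diff(range(v))) + 100
  }
  coords <- array(NA_real_, c(n, 3, n_frames))
  for (f in seq_len(n_frames)) {
    coords[, , f] <- base_coords + matrix(stats::rnorm(n * 3), n, 3) * sigma_A
  }
  gas_trajectory(coords, box = box, dt = dt)
}
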