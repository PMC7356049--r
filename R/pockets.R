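#' Pocket-identification parameters
#'
#' @param contact_cutoff ligand-site to protein-atom contact distance used
#'   for ranking (Angstrom, default 4.0).
#' @param top_fraction fraction of contacted atoms retained (default 0.5,
#'   the upper half).
#' @param occupancy_cutoff centroid-to-ligand distance defining pocket
#'   occupancy (Angstrom, default 3.5).
#' @param cluster_linkage_cutoff single-linkage distance joining top atoms
#'   into one pocket (Angstrom, default 5.0).
#' @return object of class `pocket_config`.
#' @export
pocket_config <- function(contact_cutoff = 4.0, top_fraction = 0.5,
                          occupancy_cutoff = 3.5,
                          cluster_linkage_cutoff = 5.0) {
  stopifnot(contact_cutoff > 0, occupancy_cutoff > 0,
            cluster_linkage_cutoff > 0,
            top_fraction > 0, top_fraction <= 1)
  structure(list(contact_cutoff = contact_cutoff, top_fraction = top_fraction,
                 occupancy_cutoff = occupancy_cutoff,
                 cluster_linkage_cutoff = cluster_linkage_cutoff),
            class = "pocket_config")
}

#' Rank protein heavy atoms by gas-contact count
#'
#' Counts, for every protein heavy atom, the number of (frame, ligand)
#' pairs in which the ligand reference site lies within `contact_cutoff`,
#' and returns the atoms in descending count order (ties broken by atom
#' index).
#'
#' @param traj a [gas_trajectory()].
#' @param selection a [site_selection()].
#' @param contact_cutoff contact distance (Angstrom).
#' @param reference ligand reference mode; the dummy/central site by
#'   default.
#' @param wrap use minimum-image distances.
#' @return data frame `atom`, `count`, ordered by decreasing count.
#' @export
rank_contact_atoms <- function(traj, selection, contact_cutoff = 4.0,
                               reference = "central", wrap = TRUE) {
  scan <- ligand_protein_scan(traj, selection, what = "atom_counts",
                              contact_cutoff = contact_cutoff,
                              reference = reference, wrap = wrap)
  counts <- scan$atom_counts
  ord <- order(-counts, as.integer(names(counts)))
  data.frame(atom = as.integer(names(counts))[ord],
             count = as.integer(counts[ord]))
}

#' Keep the top fraction of contacted atoms
#'
#' Among atoms with at least one contact, retains the top
#' `ceiling(fraction * n)` by count. Atoms tied with the boundary count are
#' all kept, so the result can exceed the nominal size at ties.
#'
#' @param ranked output of [rank_contact_atoms()].
#' @param top_fraction fraction to keep (default 0.5).
#' @return subset of `ranked` (possibly empty, with a warning, when no atom
#'   made any contact).
#' @export
select_top_atoms <- function(ranked, top_fraction = 0.5) {
  stopifnot(top_fraction > 0, top_fraction <= 1)
  contacted <- ranked[ranked$count > 0, , drop = FALSE]
  if (nrow(contacted) == 0L) {
    warning("no atom made any gas contact; empty top set", call. = FALSE)
    return(contacted)
  }
  k <- ceiling(top_fraction * nrow(contacted))
  threshold <- contacted$count[k]
  contacted[contacted$count >= threshold, , drop = FALSE]
}

#' Cluster top-contact atoms into pockets
#'
#' Single-linkage clustering of the trajectory-averaged positions of the
#' selected atoms; clusters joined below `linkage_cutoff` form one pocket,
#' and clusters with fewer than `min_atoms` members are discarded. (The
#' reference protocol grouped close-lying contact residues by visual
#' inspection; deterministic single-linkage clustering reproduces that
#' step algorithmically.)
#'
#' @param top_atoms data frame with column `atom` ([select_top_atoms()]).
#' @param avg_coords `n_atoms_total x 3` matrix of trajectory-averaged
#'   coordinates, indexed by atom number (see [average_coordinates()]).
#' @param linkage_cutoff single-linkage joining distance (Angstrom).
#' @param min_atoms minimum pocket size (default 3).
#' @param residue_ids optional per-atom residue labels (full atom table
#'   indexing) recorded in each pocket.
#' @return list of `pocket` objects: `member_atoms`, `member_residues`,
#'   `centroid` (time-averaged, Angstrom).
#' @export
cluster_pockets <- function(top_atoms, avg_coords, linkage_cutoff = 5.0,
                            min_atoms = 3L, residue_ids = NULL) {
  atoms <- top_atoms$atom
  if (length(atoms) == 0L) return(list())
  xyz <- avg_coords[atoms, , drop = FALSE]
  membership <- if (length(atoms) == 1L) {
    1L
  } else {
    hc <- stats::hclust(stats::dist(xyz), method = "single")
    stats::cutree(hc, h = linkage_cutoff)
  }
  pockets <- list()
  for (cl in sort(unique(membership))) {
    members <- atoms[membership == cl]
    if (length(members) < min_atoms) next
    pockets[[length(pockets) + 1L]] <- structure(
      list(member_atoms = members,
           member_residues = if (is.null(residue_ids)) NULL else
             unique(residue_ids[members]),
           centroid = colMeans(avg_coords[members, , drop = FALSE])),
      class = "pocket")
  }
  # larger pockets first, deterministic order
  pockets[order(-vapply(pockets, function(p) length(p$member_atoms), 1L),
                vapply(pockets, function(p) min(p$member_atoms), 1L))]
}

#' @export
print.pocket <- function(x, ...) {
  cat(sprintf("pocket: %d atoms, centroid (%.2f, %.2f, %.2f) A\n",
              length(x$member_atoms), x$centroid[1], x$centroid[2],
              x$centroid[3]))
  invisible(x)
}

#' Trajectory-averaged atom coordinates
#'
#' @param traj a [gas_trajectory()].
#' @return `n_atoms x 3` matrix of per-atom time averages.
#' @export
average_coordinates <- function(traj) {
  stopifnot(inherits(traj, "gas_trajectory"))
  rowMeans(traj$coords, dims = 2)
}

# occupancy/residence statistics from a ligand x frame logical matrix
.occupancy_stats <- function(inmat, dt) {
  nf <- ncol(inmat)
  counts <- colSums(inmat)
  occupied <- counts > 0
  n_runs <- 0L; in_frames <- 0L
  for (l in seq_len(nrow(inmat))) {
    r <- rle(inmat[l, ])
    n_runs <- n_runs + sum(r$values)
    in_frames <- in_frames + sum(r$lengths[r$values])
  }
  list(
    occupancy_pct = 100 * sum(occupied) / nf,
    avg_simultaneous = if (any(occupied)) mean(counts[occupied]) else 0,
    max_simultaneous = max(counts),
    mean_residence_ps = if (n_runs > 0) in_frames * dt / n_runs else 0,
    n_in_out_events = n_runs,
    total_in_frames = in_frames
  )
}

#' Occupancy and residence statistics of a pocket
#'
#' A ligand occupies the pocket in a frame when its reference site lies
#' within `occupancy_cutoff` of the pocket's (time-averaged) centroid.
#' Contiguous occupied stretches are residence runs (entry frame counted,
#' exit frame not); each run is one in-and-out transfer event.
#'
#' @param pocket a `pocket` (or any list with a `centroid`).
#' @param traj a [gas_trajectory()].
#' @param selection a [site_selection()].
#' @param occupancy_cutoff centroid distance bound (Angstrom, default 3.5).
#' @param reference ligand reference mode (default `"central"`).
#' @param wrap use minimum-image distances.
#' @return object of class `pocket_stats`: `occupancy_pct`,
#'   `avg_simultaneous` (over occupied frames), `max_simultaneous`,
#'   `mean_residence_ps`, `n_in_out_events`, `total_in_frames`.
#' @export
pocket_statistics <- function(pocket, traj, selection,
                              occupancy_cutoff = 3.5, reference = "central",
                              wrap = TRUE) {
  stopifnot(!is.null(pocket$centroid))
  lig <- ligand_positions(traj, selection, reference)
  nl <- dim(lig)[1]; nf <- dim(lig)[3]
  inmat <- matrix(FALSE, nl, nf)
  for (l in seq_len(nl)) {
    d <- minimum_image_distance(t(matrix(lig[l, , ], nrow = 3)),
                                matrix(pocket$centroid, nf, 3, byrow = TRUE),
                                traj$box, wrap = wrap)
    inmat[l, ] <- d < occupancy_cutoff
  }
  st <- .occupancy_stats(inmat, traj$dt)
  structure(c(st, list(occupancy_cutoff = occupancy_cutoff)),
            class = "pocket_stats")
}

#' @export
print.pocket_stats <- function(x, ...) {
  cat(sprintf(paste0("pocket_stats: occupancy %.1f%%, avg/max simultaneous ",
                     "%.2f/%d, mean residence %.1f ps, %d events\n"),
              x$occupancy_pct, x$avg_simultaneous, x$max_simultaneous,
              x$mean_residence_ps, x$n_in_out_events))
  if (!is.null(x$mean_anchor_distance)) {
    cat(sprintf("  mean anchor-ligand distance over occupied pairs: %.2f A\n",
                x$mean_anchor_distance))
  }
  invisible(x)
}

#' Statistics of the named distal or proximal site
#'
#' Same occupancy/residence statistics as [pocket_statistics()], but
#' computed around a per-frame anchor instead of a discovered centroid: the
#' heme Fe for the distal pocket, or the centroid of user-specified anchor
#' atoms for the proximal pocket. Additionally reports the mean
#' anchor-to-ligand distance over occupied (ligand, frame) pairs, the
#' distal-pocket descriptor of the output tables.
#'
#' @param site `"distal"` or `"proximal"`.
#' @param traj a [gas_trajectory()].
#' @param selection a [site_selection()].
#' @param proximal_atoms integer atom indices anchoring the proximal site
#'   (required for `site = "proximal"`).
#' @param occupancy_cutoff centroid distance bound (Angstrom).
#' @param reference ligand reference mode.
#' @param wrap use minimum-image distances.
#' @return a `pocket_stats` object with an extra `mean_anchor_distance`
#'   (Angstrom, NA when never occupied).
#' @export
named_site_statistics <- function(site = c("distal", "proximal"), traj,
                                  selection, proximal_atoms = NULL,
                                  occupancy_cutoff = 3.5,
                                  reference = "central", wrap = TRUE) {
  site <- match.arg(site)
  nf <- traj$n_frames
  anchor <- if (site == "distal") {
    t(matrix(traj$coords[selection$fe, , ], nrow = 3))
  } else {
    if (is.null(proximal_atoms) || length(proximal_atoms) == 0L) {
      stop("proximal site requires anchor atoms", call. = FALSE)
    }
    t(colMeans(traj$coords[proximal_atoms, , , drop = FALSE], dims = 1))
  }
  lig <- ligand_positions(traj, selection, reference)
  nl <- dim(lig)[1]
  inmat <- matrix(FALSE, nl, nf)
  dsum <- 0; dn <- 0L
  for (l in seq_len(nl)) {
    d <- minimum_image_distance(t(matrix(lig[l, , ], nrow = 3)), anchor,
                                traj$box, wrap = wrap)
    sel <- d < occupancy_cutoff
    inmat[l, ] <- sel
    dsum <- dsum + sum(d[sel]); dn <- dn + sum(sel)
  }
  st <- .occupancy_stats(inmat, traj$dt)
  structure(c(st, list(occupancy_cutoff = occupancy_cutoff,
                       mean_anchor_distance = if (dn > 0) dsum / dn else NA_real_,
                       site = site)),
            class = "pocket_stats")
}

#' Identify pockets and score them in one call
#'
#' Convenience wrapper chaining [rank_contact_atoms()],
#' [select_top_atoms()], [cluster_pockets()] and [pocket_statistics()].
#'
#' @param traj a [gas_trajectory()].
#' @param selection a [site_selection()].
#' @param config a [pocket_config()].
#' @param reference ligand reference mode.
#' @param wrap use minimum-image distances.
#' @param residue_ids optional per-atom residue labels.
#' @return list with `ranked`, `top`, `pockets`, and `stats` (one
#'   `pocket_stats` per pocket).
#' @export
find_pockets <- function(traj, selection, config = pocket_config(),
                         reference = "central", wrap = TRUE,
                         residue_ids = NULL) {
  ranked <- rank_contact_atoms(traj, selection, config$contact_cutoff,
                               reference = reference, wrap = wrap)
  top <- select_top_atoms(ranked, config$top_fraction)
  pockets <- cluster_pockets(top, average_coordinates(traj),
                             linkage_cutoff = config$cluster_linkage_cutoff,
                             residue_ids = residue_ids)
  stats <- lapply(pockets, pocket_statistics, traj = traj,
                  selection = selection,
                  occupancy_cutoff = config$occupancy_cutoff,
                  reference = reference, wrap = wrap)
  list(ranked = ranked, top = top, pockets = pockets, stats = stats)
}
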