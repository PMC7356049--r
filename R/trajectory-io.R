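#' Read a structure file and build the analysis selection
#'
#' Reads a PDB (via bio3d) or GRO file, classifies atoms into protein heavy
#' atoms, the heme Fe, and gas-ligand site groups, and returns the atom
#' table together with a validated [site_selection()].
#'
#' Ligands are recognized by residue name; each ligand residue becomes one
#' site group. Water and monatomic ions are excluded from the protein set.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"pdb"` or `"gro"`.
#' @param fe_name atom name identifying the heme iron.
#' @param ligand_resnames residue names treated as gas ligands.
#' @param reference default ligand reference mode for the selection.
#' @param solvent_resnames residue names excluded from the protein set.
#' @return object of class `gas_structure`: list with `atoms` (data frame:
#'   `eleno`, `elety`, `resid`, `resno`, `chain`, `element`, `x`, `y`, `z`),
#'   `selection`, and `box` (length-3 Angstrom edges, or `NULL` if the file
#'   carries none).
#' @export
read_structure <- function(path, format = c("auto", "pdb", "gro"),
                           fe_name = "FE",
                           ligand_resnames = c("NO", "CO", "OXY", "O2", "XO", "LIG"),
                           reference = c("com", "central"),
                           solvent_resnames = c("HOH", "WAT", "SOL", "TIP3",
                                                "NA", "CL", "SOD", "CLA", "K")) {
  format <- match.arg(format)
  reference <- match.arg(reference)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, pdb = "pdb", ent = "pdb", gro = "gro",
                     stop("format error: cannot infer format from extension '",
                          ext, "'", call. = FALSE))
  }
  atoms <- switch(format, pdb = .read_pdb_atoms(path), gro = .read_gro_atoms(path))
  box <- switch(format, pdb = .read_pdb_box(path), gro = attr(atoms, "box"))
  attr(atoms, "box") <- NULL
  sel <- build_selection(atoms, fe_name = fe_name,
                         ligand_resnames = ligand_resnames,
                         reference = reference,
                         solvent_resnames = solvent_resnames)
  structure(list(atoms = atoms, selection = sel, box = box, source = path),
            class = "gas_structure")
}

#' @export
print.gas_structure <- function(x, ...) {
  cat("gas_structure:", nrow(x$atoms), "atoms from", x$source, "\n")
  print(x$selection)
  invisible(x)
}

#' Build a site selection from an atom table
#'
#' @param atoms data frame with columns `elety`, `resid`, `resno`, `chain`,
#'   `element` (as produced by [read_structure()] or the toy generator).
#' @inheritParams read_structure
#' @return a [site_selection()].
#' @export
build_selection <- function(atoms, fe_name = "FE",
                            ligand_resnames = c("NO", "CO", "OXY", "O2", "XO", "LIG"),
                            reference = "com",
                            solvent_resnames = c("HOH", "WAT", "SOL", "TIP3",
                                                 "NA", "CL", "SOD", "CLA", "K")) {
  fe_idx <- which(toupper(atoms$elety) == toupper(fe_name))
  if (length(fe_idx) == 0L) {
    stop("selection error: no atom named '", fe_name, "' found", call. = FALSE)
  }
  if (length(fe_idx) > 1L) {
    stop("selection error: multiple atoms named '", fe_name, "'", call. = FALSE)
  }
  is_lig <- toupper(atoms$resid) %in% toupper(ligand_resnames)
  if (!any(is_lig)) {
    stop("selection error: no ligand residues (",
         paste(ligand_resnames, collapse = ", "), ") found", call. = FALSE)
  }
  lig_key <- paste(atoms$chain, atoms$resno, atoms$resid)[is_lig]
  lig_groups <- split(which(is_lig), factor(lig_key, levels = unique(lig_key)))
  is_solvent <- toupper(atoms$resid) %in% toupper(solvent_resnames)
  is_heavy <- toupper(atoms$element) != "H"
  prot <- which(!is_lig & !is_solvent & is_heavy &
                seq_len(nrow(atoms)) != fe_idx)
  site_selection(protein_heavy = prot, fe = fe_idx,
                 ligands = unname(lig_groups), reference = reference)
}

.element_from_name <- function(name) {
  el <- sub("^[0-9']*", "", toupper(name))
  two <- substr(el, 1, 2)
  ifelse(two %in% c("FE", "CL", "NA", "MG", "ZN", "BR", "CA"), two,
         substr(el, 1, 1))
}

.read_pdb_atoms <- function(path) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  a <- pdb$atom
  el <- a$elesy
  el[is.na(el) | el == ""] <- .element_from_name(a$elety[is.na(el) | el == ""])
  data.frame(eleno = a$eleno, elety = a$elety, resid = a$resid,
             resno = a$resno,
             chain = ifelse(is.na(a$chain), "A", a$chain),
             element = toupper(el),
             x = a$x, y = a$y, z = a$z, stringsAsFactors = FALSE)
}

.read_pdb_box <- function(path) {
  lines <- readLines(path, n = 500L)
  cr <- grep("^CRYST1", lines, value = TRUE)
  if (length(cr) == 0L) return(NULL)
  as.numeric(c(substr(cr[1], 7, 15), substr(cr[1], 16, 24),
               substr(cr[1], 25, 33)))
}

# GRO fixed-column format; coordinates and box are in nm -> converted to A
.read_gro_atoms <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L) stop("format error: truncated GRO file", call. = FALSE)
  n <- as.integer(trimws(lines[2]))
  if (is.na(n) || length(lines) < n + 3L) {
    stop("format error: bad GRO atom count", call. = FALSE)
  }
  body <- lines[3:(n + 2L)]
  resno <- as.integer(substr(body, 1, 5))
  resid <- trimws(substr(body, 6, 10))
  elety <- trimws(substr(body, 11, 15))
  eleno <- as.integer(substr(body, 16, 20))
  x <- as.numeric(substr(body, 21, 28)) * 10
  y <- as.numeric(substr(body, 29, 36)) * 10
  z <- as.numeric(substr(body, 37, 44)) * 10
  box <- as.numeric(strsplit(trimws(lines[n + 3L]), "\\s+")[[1]])[1:3] * 10
  out <- data.frame(eleno = eleno, elety = elety, resid = resid, resno = resno,
                    chain = "A", element = .element_from_name(elety),
                    x = x, y = y, z = z, stringsAsFactors = FALSE)
  attr(out, "box") <- box
  out
}

#' Read a coordinate trajectory
#'
#' Supports multi-model PDB (via bio3d) and multi-frame XYZ (the package's
#' plain-text interchange format, see [write_xyz_trajectory()]). Frame times
#' are assigned as `frame_index * dt` starting at 0, and frames before
#' `equilibration_cut` are discarded.
#'
#' @param path trajectory file.
#' @param topology a `gas_structure` (atom counts are validated against it).
#' @param dt time between stored frames (ps).
#' @param equilibration_cut initial time span to drop (ps).
#' @param format `"auto"`, `"pdb"` or `"xyz"`.
#' @param box orthorhombic cell edges (Angstrom); defaults to the box stored
#'   in the file or topology.
#' @return a [gas_trajectory()].
#' @export
read_trajectory <- function(path, topology, dt = 4, equilibration_cut = 0,
                            format = c("auto", "pdb", "xyz"), box = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, pdb = "pdb", xyz = "xyz",
                     stop("format error: cannot infer trajectory format",
                          call. = FALSE))
  }
  if (format == "pdb") {
    pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
    xyz <- pdb$xyz
    nf <- nrow(xyz)
    na <- ncol(xyz) / 3
    coords <- array(NA_real_, c(na, 3, nf))
    for (f in seq_len(nf)) {
      coords[, , f] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
    }
    if (is.null(box)) box <- .read_pdb_box(path)
  } else {
    parsed <- .read_xyz_frames(path)
    coords <- parsed$coords
    if (is.null(box)) box <- parsed$box
  }
  if (!is.null(topology) && dim(coords)[1] != nrow(topology$atoms)) {
    stop("atom-count mismatch: trajectory has ", dim(coords)[1],
         " atoms, topology has ", nrow(topology$atoms), call. = FALSE)
  }
  if (is.null(box) && !is.null(topology)) box <- topology$box
  if (is.null(box)) stop("no periodic box available for trajectory", call. = FALSE)
  traj <- gas_trajectory(coords, box = box, dt = dt)
  if (equilibration_cut > 0) traj <- trim_equilibration(traj, equilibration_cut)
  traj
}

.read_xyz_frames <- function(path) {
  lines <- readLines(path)
  i <- 1L; frames <- list(); box <- NULL
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- as.integer(trimws(lines[i]))
    if (is.na(n)) stop("format error: bad XYZ frame header", call. = FALSE)
    comment <- lines[i + 1L]
    bm <- regmatches(comment,
                     regexec("box=\\s*([0-9.eE+-]+)\\s+([0-9.eE+-]+)\\s+([0-9.eE+-]+)",
                             comment))[[1]]
    if (length(bm) == 4L) box <- as.numeric(bm[2:4])
    block <- lines[(i + 2L):(i + 1L + n)]
    toks <- strsplit(trimws(block), "\\s+")
    xyz <- t(vapply(toks, function(t) as.numeric(t[2:4]), numeric(3)))
    frames[[length(frames) + 1L]] <- xyz
    i <- i + 2L + n
  }
  if (length(frames) == 0L) stop("empty trajectory", call. = FALSE)
  coords <- array(NA_real_, c(nrow(frames[[1]]), 3, length(frames)))
  for (f in seq_along(frames)) coords[, , f] <- frames[[f]]
  list(coords = coords, box = box)
}

#' Write a trajectory as multi-frame XYZ
#'
#' Plain-text interchange format: per frame an atom count line, a comment
#' line `t= <ps> box= <a> <b> <c>` (Angstrom), then `name x y z` records.
#'
#' @param traj a [gas_trajectory()].
#' @param path output file.
#' @param names per-atom labels (defaults to `X`).
#' @export
write_xyz_trajectory <- function(traj, path, names = NULL) {
  stopifnot(inherits(traj, "gas_trajectory"))
  if (is.null(names)) names <- rep("X", traj$n_atoms)
  con <- file(path, "w"); on.exit(close(con))
  for (f in seq_len(traj$n_frames)) {
    writeLines(as.character(traj$n_atoms), con)
    writeLines(sprintf("t= %.6g box= %.8g %.8g %.8g", traj$times[f],
                       traj$box[1], traj$box[2], traj$box[3]), con)
    m <- traj$coords[, , f]
    writeLines(sprintf("%s %.8f %.8f %.8f", names, m[, 1], m[, 2], m[, 3]), con)
  }
  invisible(path)
}

#' Write a structure (single frame) as PDB
#'
#' Thin wrapper over [bio3d::write.pdb()] so synthetic systems can round-trip
#' through the standard format.
#'
#' @param structure a `gas_structure`.
#' @param path output file.
#' @param coords optional `n_atoms x 3` coordinates overriding the atom table.
#' @export
write_structure_pdb <- function(structure, path, coords = NULL) {
  a <- structure$atoms
  if (is.null(coords)) coords <- as.matrix(a[, c("x", "y", "z")])
  xyz <- as.numeric(t(coords))
  bio3d::write.pdb(file = path, xyz = xyz, type = "ATOM",
                   resno = a$resno, resid = a$resid, eleno = a$eleno,
                   elety = a$elety, chain = a$chain, elesy = a$element)
  if (!is.null(structure$box)) {
    lines <- readLines(path)
    cryst <- sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                     structure$box[1], structure$box[2], structure$box[3],
                     90, 90, 90)
    writeLines(c(cryst, lines), path)
  }
  invisible(path)
}
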