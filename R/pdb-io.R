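# Structures, trajectories and their PDB interchange format.
#
# Multi-model PDB (one structure per MODEL record) is the canonical,
# dependency-free trajectory format of this package.  Reading and writing
# follow the PDB v3.3 fixed-column layout for ATOM/HETATM records.

# ---- constructors -----------------------------------------------------

#' Construct a structure from an atom table
#'
#' An `md_structure` is an ordered table of atoms plus a list of ligand
#' groups (HETATM residues).  Atom order is stable under write/read
#' round-trips.
#'
#' @param atoms data.frame with columns `serial`, `name`, `resname`,
#'   `chain`, `resno`, `x`, `y`, `z`, `b`, `element`, `hetatm` (logical).
#' @return An object of class `md_structure`.
#' @export
md_structure <- function(atoms) {
  if (!is.data.frame(atoms) || nrow(atoms) == 0L)
    stop("empty structure: at least one atom is required")
  needed <- c("serial", "name", "resname", "chain", "resno",
              "x", "y", "z", "b", "element", "hetatm")
  missing <- setdiff(needed, names(atoms))
  if (length(missing))
    stop("atom table lacks columns: ", paste(missing, collapse = ", "))
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("all atom coordinates must be finite")
  if (any(atoms$b < 0, na.rm = TRUE))
    stop("B-factors must be non-negative")
  key <- paste(atoms$chain, atoms$resno, atoms$name)
  if (anyDuplicated(key))
    stop("duplicate (chain, residue, atom name) in structure: ",
         key[duplicated(key)][1L])
  rownames(atoms) <- NULL
  ligands <- list()
  if (any(atoms$hetatm)) {
    het <- which(atoms$hetatm)
    grp <- paste(atoms$resname[het], atoms$chain[het], atoms$resno[het])
    for (g in unique(grp)) {
      idx <- het[grp == g]
      ligands[[length(ligands) + 1L]] <-
        list(resname = atoms$resname[idx[1L]],
             chain = atoms$chain[idx[1L]],
             resno = atoms$resno[idx[1L]],
             indices = idx)
    }
  }
  structure(list(atoms = atoms, ligands = ligands), class = "md_structure")
}

#' @export
print.md_structure <- function(x, ...) {
  nres <- nrow(unique(x$atoms[!x$atoms$hetatm, c("chain", "resno")]))
  cat(sprintf("md_structure: %d atoms, %d protein residues, %d ligand group(s)\n",
              nrow(x$atoms), nres, length(x$ligands)))
  invisible(x)
}

#' Construct a trajectory
#'
#' Coordinates are stored as an F x 3N matrix with the bio3d-style
#' interleaved layout (x1, y1, z1, x2, ...), one row per frame, in the
#' atom order of `topology`.
#'
#' @param xyz numeric matrix, F x 3N, Angstrom.
#' @param topology an [md_structure()] with N atoms.
#' @param frame_interval time between frames, ps.
#' @return An object of class `md_trajectory`.
#' @export
md_trajectory <- function(xyz, topology, frame_interval = 1) {
  if (!inherits(topology, "md_structure")) stop("topology must be an md_structure")
  xyz <- as.matrix(xyz)
  n <- nrow(topology$atoms)
  if (nrow(xyz) < 2L) stop("a trajectory requires at least 2 frames")
  if (ncol(xyz) != 3L * n)
    stop(sprintf("xyz has %d columns but topology has %d atoms (need %d)",
                 ncol(xyz), n, 3L * n))
  if (!all(is.finite(xyz))) stop("all trajectory coordinates must be finite")
  stopifnot_scalar_number(frame_interval, "frame_interval", lower = 0)
  structure(list(xyz = xyz, topology = topology,
                 frame_interval = frame_interval),
            class = "md_trajectory")
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat(sprintf("md_trajectory: %d frames x %d atoms (interval %g ps)\n",
              nrow(x$xyz), ncol(x$xyz) / 3L, x$frame_interval))
  invisible(x)
}

#' Number of frames / atoms in a trajectory
#' @param traj an `md_trajectory`.
#' @return integer.
#' @export
n_frames <- function(traj) nrow(traj$xyz)

#' @rdname n_frames
#' @export
n_atoms <- function(traj) ncol(traj$xyz) %/% 3L

#' Extract one frame as an N x 3 coordinate matrix
#' @param traj an `md_trajectory`.
#' @param i frame index (1-based).
#' @return N x 3 numeric matrix.
#' @export
traj_frame <- function(traj, i) {
  if (i < 1L || i > n_frames(traj)) stop("frame index out of range")
  matrix(traj$xyz[i, ], ncol = 3L, byrow = TRUE)
}

# Column indices in the flat xyz layout for atom indices `idx`.
xyz_cols <- function(idx) as.vector(rbind(3L * idx - 2L, 3L * idx - 1L, 3L * idx))

# Structure coordinates as N x 3.
structure_coords <- function(s) as.matrix(s$atoms[, c("x", "y", "z")])

# ---- selections -------------------------------------------------------

#' Select atoms from a structure
#'
#' @param structure an [md_structure()].
#' @param name atom name(s) to keep, or NULL for all.
#' @param include_het keep HETATM atoms?
#' @param label selection label for reports.
#' @return An `md_selection`: list with strictly increasing `indices`
#'   and a `label`.
#' @export
select_atoms <- function(structure, name = "CA", include_het = FALSE,
                         label = NULL) {
  a <- structure$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(name)) keep <- keep & a$name %in% name
  if (!include_het) keep <- keep & !a$hetatm
  idx <- which(keep)
  if (!length(idx)) stop("selection matches no atoms")
  structure(list(indices = idx,
                 label = label %||% paste(name %||% "all", collapse = "+")),
            class = "md_selection")
}

as_selection <- function(x, traj) {
  if (inherits(x, "md_selection")) return(x)
  if (is.null(x)) {
    # default: all Calpha atoms, falling back to every atom for
    # non-protein toy systems
    a <- traj$topology$atoms
    idx <- which(a$name == "CA" & !a$hetatm)
    if (!length(idx)) idx <- seq_len(nrow(a))
    return(structure(list(indices = idx, label = "calpha"),
                     class = "md_selection"))
  }
  idx <- as.integer(x)
  if (any(diff(idx) <= 0L)) stop("selection indices must be strictly increasing")
  if (any(idx < 1L) || any(idx > n_atoms(traj)))
    stop("selection indices out of range")
  structure(list(indices = idx, label = "custom"), class = "md_selection")
}

# ---- PDB parsing ------------------------------------------------------

parse_pdb_atoms <- function(lines, lineno) {
  rec <- substr(lines, 1, 6)
  keep <- rec %in% c("ATOM  ", "HETATM") |
    substr(rec, 1, 4) %in% c("ATOM", "HETA")
  lines <- lines[keep]
  lineno <- lineno[keep]
  if (!length(lines)) return(NULL)
  short <- nchar(lines) < 54L
  if (any(short))
    stop(sprintf("malformed (truncated) ATOM/HETATM record at line %d",
                 lineno[which(short)[1L]]))
  num <- function(s, what) {
    v <- suppressWarnings(as.numeric(s))
    bad <- which(!is.finite(v))
    if (length(bad))
      stop(sprintf("cannot parse %s in ATOM/HETATM record at line %d",
                   what, lineno[bad[1L]]))
    v
  }
  altloc <- substr(lines, 17, 17)
  keep2 <- altloc %in% c(" ", "", "A")   # single-conformer topology
  lines <- lines[keep2]; lineno <- lineno[keep2]
  if (!length(lines)) stop("no atoms left after alternate-location filtering")
  b_raw <- trimws(substr(lines, 61, 66))
  data.frame(
    serial  = as.integer(num(substr(lines, 7, 11), "serial")),
    name    = trimws(substr(lines, 13, 16)),
    resname = trimws(substr(lines, 18, 20)),
    chain   = substr(lines, 22, 22),
    resno   = as.integer(num(substr(lines, 23, 26), "residue number")),
    x       = num(substr(lines, 31, 38), "x coordinate"),
    y       = num(substr(lines, 39, 46), "y coordinate"),
    z       = num(substr(lines, 47, 54), "z coordinate"),
    b       = ifelse(b_raw == "", 0, suppressWarnings(as.numeric(b_raw))),
    element = trimws(substr(paste0(lines, strrep(" ", 24)), 77, 78)),
    hetatm  = substr(lines, 1, 6) == "HETATM",
    stringsAsFactors = FALSE
  )
}

#' Read a structure from a PDB file
#'
#' Parses ATOM/HETATM records of the first model (or of the whole file if
#' no MODEL records are present).  Alternate locations other than blank
#' or 'A' are dropped, yielding a deterministic single-conformer
#' topology.  HETATM residues are retained and exposed as ligand groups.
#'
#' @param path file path.
#' @param dialect format tag; only `"pdb"` is supported.
#' @return An [md_structure()].
#' @export
read_structure <- function(path, dialect = "pdb") {
  dialect <- match.arg(dialect, "pdb")
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lineno <- seq_along(lines)
  endm <- which(substr(lines, 1, 6) == "ENDMDL")
  if (length(endm)) { lines <- lines[seq_len(endm[1L])]; lineno <- lineno[seq_len(endm[1L])] }
  atoms <- parse_pdb_atoms(lines, lineno)
  if (is.null(atoms)) stop("empty structure: no ATOM/HETATM records in ", path)
  md_structure(atoms)
}

#' Read a multi-model PDB trajectory
#'
#' Each MODEL/ENDMDL block becomes one frame; the first model defines
#' the topology.  All models must list the same atoms in the same order.
#'
#' @param path file path.
#' @param frame_interval time between frames, ps (metadata only).
#' @return An [md_trajectory()].
#' @export
read_trajectory <- function(path, frame_interval = 1) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  starts <- which(substr(lines, 1, 5) == "MODEL")
  ends <- which(substr(lines, 1, 6) == "ENDMDL")
  if (length(starts) < 2L || length(ends) < 2L)
    stop("a trajectory requires at least 2 MODEL blocks; found ",
         length(starts))
  if (length(starts) != length(ends))
    stop("unbalanced MODEL/ENDMDL records")
  frames <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    block <- seq.int(starts[k] + 1L, ends[k] - 1L)
    frames[[k]] <- parse_pdb_atoms(lines[block], block)
    if (is.null(frames[[k]]))
      stop("MODEL block ", k, " contains no atoms")
  }
  topo <- frames[[1L]]
  sig0 <- paste(topo$name, topo$resname, topo$chain, topo$resno)
  xyz <- matrix(NA_real_, length(frames), 3L * nrow(topo))
  for (k in seq_along(frames)) {
    fk <- frames[[k]]
    if (nrow(fk) != nrow(topo) ||
        !identical(paste(fk$name, fk$resname, fk$chain, fk$resno), sig0))
      stop("inconsistent topology: MODEL ", k,
           " does not list the same atoms as MODEL 1")
    xyz[k, ] <- as.vector(t(as.matrix(fk[, c("x", "y", "z")])))
  }
  md_trajectory(xyz, md_structure(topo), frame_interval = frame_interval)
}

format_pdb_line <- function(a, x, y, z) {
  rec <- ifelse(a$hetatm, "HETATM", "ATOM  ")
  # names of <4 characters start in column 14 per the v3.3 layout
  nm <- ifelse(nchar(a$name) < 4L, paste0(" ", a$name), a$name)
  sprintf("%-6s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          rec, a$serial %% 100000L, nm, " ", a$resname, a$chain,
          a$resno %% 10000L, " ", x, y, z, 1.00, a$b, a$element)
}

#' Write a structure to a PDB file
#' @param structure an [md_structure()].
#' @param path output file path.
#' @export
write_structure <- function(structure, path) {
  a <- structure$atoms
  out <- c(format_pdb_line(a, a$x, a$y, a$z), "END")
  writeLines(out, path)
  invisible(path)
}

#' Write a trajectory as a multi-model PDB file
#'
#' Frames become MODEL 1..F blocks (1-indexed, matching PDB MODEL
#' numbering).  [read_trajectory()] inverts this up to the format's
#' 0.001 Angstrom coordinate precision.
#'
#' @param traj an [md_trajectory()].
#' @param path output file path.
#' @export
write_trajectory <- function(traj, path) {
  if (!inherits(traj, "md_trajectory")) stop("traj must be an md_trajectory")
  a <- traj$topology$atoms
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(n_frames(traj))) {
    co <- traj_frame(traj, f)
    writeLines(sprintf("MODEL     %4d", f), con)
    writeLines(format_pdb_line(a, co[, 1], co[, 2], co[, 3]), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

# ---- node maps --------------------------------------------------------

#' Map residues and ligand atoms to network nodes
#'
#' Each amino-acid residue contributes exactly one node anchored at its
#' Calpha atom.  Ligand residues named in `ligand_rules` contribute one
#' node per listed anchor atom; the default rule maps SAH
#' (S-adenosyl-L-homocysteine) to three nodes at atoms CA, C4' and N9.
#' HETATM residues with no rule (e.g. ions, waters) are excluded.
#'
#' @param structure an [md_structure()].
#' @param ligand_rules named list: `list(SAH = c("CA", "C4'", "N9"))`.
#' @return A `node_map`: data.frame with columns `label`, `atom`
#'   (anchor atom index), `chain`, `resno`, `resname`, `is_ligand`,
#'   ordered by (chain, residue number) with ligand nodes appended.
#' @export
build_node_map <- function(structure,
                           ligand_rules = list(SAH = c("CA", "C4'", "N9"))) {
  a <- structure$atoms
  prot <- a[!a$hetatm, , drop = FALSE]
  rows <- list()
  if (nrow(prot)) {
    res <- unique(prot[, c("chain", "resno")])
    res <- res[order(res$chain, res$resno), , drop = FALSE]
    for (r in seq_len(nrow(res))) {
      in_res <- which(!a$hetatm & a$chain == res$chain[r] & a$resno == res$resno[r])
      ca <- in_res[a$name[in_res] == "CA"]
      if (!length(ca))
        stop(sprintf("missing anchor: residue %s%d (chain %s) has no CA atom",
                     a$resname[in_res[1L]], res$resno[r], res$chain[r]))
      rows[[length(rows) + 1L]] <- data.frame(
        label = paste0(a$resname[ca[1L]], res$resno[r]),
        atom = ca[1L], chain = res$chain[r], resno = res$resno[r],
        resname = a$resname[ca[1L]], is_ligand = FALSE,
        stringsAsFactors = FALSE)
    }
  }
  for (lig in structure$ligands) {
    rule <- ligand_rules[[lig$resname]]
    if (is.null(rule)) next
    for (an in rule) {
      hit <- lig$indices[a$name[lig$indices] == an]
      if (!length(hit))
        stop(sprintf("missing anchor: ligand %s%d has no atom named %s",
                     lig$resname, lig$resno, an))
      rows[[length(rows) + 1L]] <- data.frame(
        label = paste0(lig$resname, lig$resno, ":", an),
        atom = hit[1L], chain = lig$chain, resno = lig$resno,
        resname = lig$resname, is_ligand = TRUE,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) stop("node map is empty: no residues or mapped ligands")
  nm <- do.call(rbind, rows)
  if (anyDuplicated(nm$label)) {
    dup <- nm$label %in% nm$label[duplicated(nm$label)]
    nm$label[dup] <- paste0(nm$chain[dup], ":", nm$label[dup])
  }
  if (anyDuplicated(nm$label)) stop("node labels are not unique")
  rownames(nm) <- NULL
  class(nm) <- c("node_map", "data.frame")
  nm
}

as_node_map <- function(node_map, traj) {
  if (is.null(node_map)) node_map <- build_node_map(traj$topology)
  if (!inherits(node_map, "node_map")) stop("node_map must come from build_node_map()")
  if (any(node_map$atom < 1L) || any(node_map$atom > n_atoms(traj)))
    stop("node map anchors fall outside the trajectory topology")
  node_map
}

node_lookup <- function(node_map, label) {
  i <- match(label, node_map$label)
  if (is.na(i)) stop("unknown node label: ", label)
  i
}

# xyz matrix (F x 3K) restricted to node anchors
node_xyz <- function(traj, node_map) traj$xyz[, xyz_cols(node_map$atom), drop = FALSE]
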