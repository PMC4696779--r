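# Superposition and fluctuation statistics: Kabsch fitting, RMSD/RMSF,
# B-factor conversion, inter-residue distance series and deviation maps.

#' Kabsch superposition of two coordinate sets
#'
#' Finds the proper rotation R and translation t minimizing the RMSD of
#' `mobile %*% R + t` to `reference` (SVD solution, reflection
#' corrected).
#'
#' @param mobile,reference N x 3 coordinate matrices, N >= 3.
#' @return list with `rotation` (3 x 3, det +1), `translation`
#'   (length 3) and `rmsd` (Angstrom).
#' @export
kabsch_superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (nrow(mobile) != nrow(reference) || ncol(mobile) != 3L ||
      ncol(reference) != 3L)
    stop("mobile and reference must be N x 3 with equal N")
  if (nrow(mobile) < 3L)
    stop("underdetermined superposition: need at least 3 atoms")
  cm <- colMeans(mobile); cr <- colMeans(reference)
  A <- sweep(mobile, 2, cm); B <- sweep(reference, 2, cr)
  if (qr(A)$rank < 2L || qr(B)$rank < 2L)
    stop("underdetermined superposition: coordinates are collinear")
  s <- svd(t(A) %*% B)
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  aligned <- A %*% R
  rmsd <- sqrt(mean(rowSums((aligned - B)^2)))
  list(rotation = R, translation = as.vector(cr - cm %*% R), rmsd = rmsd)
}

#' Superpose every frame of a trajectory onto a reference frame
#'
#' Least-squares fit on the selection; the fitted rigid transform is
#' applied to all atoms of the frame.  Removes overall translation and
#' rotation ahead of fluctuation, correlation and PCA analyses.
#'
#' @param traj an [md_trajectory()].
#' @param selection an `md_selection`, atom indices, or NULL for all
#'   Calpha atoms.
#' @param reference_frame frame fitted onto (default the first).
#' @return The aligned [md_trajectory()].
#' @export
align_trajectory <- function(traj, selection = NULL, reference_frame = 1L) {
  sel <- as_selection(selection, traj)
  ref <- traj_frame(traj, reference_frame)[sel$indices, , drop = FALSE]
  xyz <- traj$xyz
  for (f in seq_len(n_frames(traj))) {
    fr <- traj_frame(traj, f)
    fit <- kabsch_superpose(fr[sel$indices, , drop = FALSE], ref)
    moved <- fr %*% fit$rotation
    moved <- sweep(moved, 2, fit$translation, "+")
    xyz[f, ] <- as.vector(t(moved))
  }
  out <- md_trajectory(xyz, traj$topology, traj$frame_interval)
  attr(out, "aligned") <- TRUE
  attr(out, "truth") <- attr(traj, "truth")
  out
}

is_aligned <- function(traj) isTRUE(attr(traj, "aligned"))

#' Per-frame RMSD relative to a reference
#'
#' @param traj an [md_trajectory()].
#' @param reference an [md_structure()], an N x 3 matrix, or a frame
#'   index into `traj`.
#' @param selection atoms entering the RMSD (default all Calpha).
#' @param align superpose each frame onto the reference first?
#' @return numeric vector, one RMSD (Angstrom) per frame.
#' @export
rmsd_series <- function(traj, reference = 1L, selection = NULL, align = TRUE) {
  sel <- as_selection(selection, traj)
  ref <- if (inherits(reference, "md_structure")) {
    structure_coords(reference)
  } else if (is.matrix(reference)) reference
  else traj_frame(traj, reference)
  if (nrow(ref) == n_atoms(traj)) ref <- ref[sel$indices, , drop = FALSE]
  if (nrow(ref) != length(sel$indices))
    stop("reference does not match the selection size")
  vapply(seq_len(n_frames(traj)), function(f) {
    fr <- traj_frame(traj, f)[sel$indices, , drop = FALSE]
    if (align) kabsch_superpose(fr, ref)$rmsd
    else sqrt(mean(rowSums((fr - ref)^2)))
  }, numeric(1))
}

#' Root-mean-square fluctuation profile
#'
#' RMSF_i = sqrt(mean over frames |r_i - <r_i>|^2) on the aligned
#' trajectory.  If the trajectory is not flagged as aligned, a warning
#' is issued and alignment to the first frame is applied.
#'
#' @param traj an [md_trajectory()].
#' @param selection atoms to profile (default all Calpha).
#' @param aligned set TRUE to assert the input is already superposed.
#' @return data.frame of class `fluct_profile` with columns `atom` and
#'   `rmsf` (Angstrom).
#' @export
rmsf_profile <- function(traj, selection = NULL, aligned = is_aligned(traj)) {
  sel <- as_selection(selection, traj)
  if (!aligned) {
    warning("trajectory not flagged as aligned; superposing onto frame 1")
    traj <- align_trajectory(traj, selection = sel)
  }
  X <- traj$xyz[, xyz_cols(sel$indices), drop = FALSE]
  D <- sweep(X, 2, colMeans(X))
  msf <- rowSums(matrix(colMeans(D^2), ncol = 3L, byrow = TRUE))
  out <- data.frame(atom = sel$indices, rmsf = sqrt(msf))
  class(out) <- c("fluct_profile", "data.frame")
  out
}

#' Convert between crystallographic B-factors and RMSF
#'
#' Isotropic harmonic relation B = (8 pi^2 / 3) RMSF^2.
#'
#' @param b B-factor(s), Angstrom^2 (non-negative).
#' @return RMSF in Angstrom.
#' @export
bfactor_to_rmsf <- function(b) {
  if (any(b < 0)) stop("B-factors must be non-negative")
  sqrt(3 * b / (8 * pi^2))
}

#' @rdname bfactor_to_rmsf
#' @param rmsf fluctuation(s), Angstrom (non-negative).
#' @return B-factor in Angstrom^2.
#' @export
rmsf_to_bfactor <- function(rmsf) {
  if (any(rmsf < 0)) stop("RMSF must be non-negative")
  (8 * pi^2 / 3) * rmsf^2
}

#' Inter-node distance time series
#'
#' Euclidean distance between the anchor atoms of two nodes, per frame.
#'
#' @param traj an [md_trajectory()].
#' @param node_map a node map from [build_node_map()] (NULL builds the
#'   default Calpha map).
#' @param node_a,node_b node labels.
#' @return list of class `distance_series` with `pair` and `values`
#'   (Angstrom per frame).
#' @export
distance_series <- function(traj, node_map = NULL, node_a, node_b) {
  nm <- as_node_map(node_map, traj)
  ia <- nm$atom[node_lookup(nm, node_a)]
  ib <- nm$atom[node_lookup(nm, node_b)]
  da <- traj$xyz[, xyz_cols(ia), drop = FALSE] -
    traj$xyz[, xyz_cols(ib), drop = FALSE]
  structure(list(pair = c(node_a, node_b), values = sqrt(rowSums(da^2))),
            class = "distance_series")
}

#' Inter-node distance deviation map
#'
#' Entry (i, j) is the standard deviation over frames of the anchor
#' distance d_ij.  Distances are rigid-motion invariants, so no
#' alignment is required.
#'
#' @param traj an [md_trajectory()].
#' @param node_map node map (NULL for the default Calpha map).
#' @return N x N symmetric matrix (class `distance_deviation_map`) with
#'   zero diagonal, labeled by node.
#' @export
distance_deviation_map <- function(traj, node_map = NULL) {
  nm <- as_node_map(node_map, traj)
  k <- nrow(nm)
  f <- n_frames(traj)
  X <- node_xyz(traj, nm)
  # accumulate deviations from the first frame's distances to avoid
  # catastrophic cancellation for large, nearly constant distances
  d0 <- as.matrix(stats::dist(matrix(X[1L, ], ncol = 3L, byrow = TRUE)))
  s1 <- matrix(0, k, k); s2 <- matrix(0, k, k)
  for (fr in seq_len(f)) {
    d <- as.matrix(stats::dist(matrix(X[fr, ], ncol = 3L, byrow = TRUE))) - d0
    s1 <- s1 + d; s2 <- s2 + d^2
  }
  v <- (s2 - s1^2 / f) / (f - 1)
  v[v < 0] <- 0
  sig <- sqrt(v)
  diag(sig) <- 0
  dimnames(sig) <- list(nm$label, nm$label)
  class(sig) <- c("distance_deviation_map", class(sig))
  sig
}

#' Block-to-background ratio of a distance deviation map
#'
#' Mean deviation over the cross pairs of two disjoint node sets,
#' divided by the mean deviation over all off-diagonal pairs.  Values
#' well above 1 indicate a block (e.g. an inter-lobe cleft) fluctuating
#' more than the rest of the structure.
#'
#' @param map a [distance_deviation_map()].
#' @param set_a,set_b disjoint, non-empty vectors of node labels.
#' @return a single ratio.
#' @export
block_deviation_ratio <- function(map, set_a, set_b) {
  if (!length(set_a) || !length(set_b)) stop("block sets must be non-empty")
  if (length(intersect(set_a, set_b))) stop("block sets must be disjoint")
  labs <- rownames(map)
  ia <- match(set_a, labs); ib <- match(set_b, labs)
  if (anyNA(ia) || anyNA(ib)) stop("unknown node label in block sets")
  cross <- mean(map[ia, ib])
  off <- mean(map[upper.tri(map)])
  if (off == 0) stop("map has zero average deviation")
  cross / off
}
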