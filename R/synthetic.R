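# Synthetic trajectory and graph generators with planted, analytically
# known structure.  These are the test-bed for every downstream stage:
# statistics are planted, physics is not claimed.

# Build a Calpha-only topology for N synthetic nodes.
synthetic_topology <- function(coords, resname = "ALA", chain = "A") {
  n <- nrow(coords)
  md_structure(data.frame(
    serial = seq_len(n), name = "CA", resname = resname, chain = chain,
    resno = seq_len(n), x = coords[, 1], y = coords[, 2], z = coords[, 3],
    b = 0, element = "C", hetatm = FALSE, stringsAsFactors = FALSE))
}

# Compact cubic-lattice cluster of n points (spacing in Angstrom),
# centered at the origin; deterministic ordering.
grid_cluster <- function(n, spacing = 3.8) {
  k <- 3L
  g <- as.matrix(expand.grid(-k:k, -k:k, -k:k)) * spacing
  ord <- order(rowSums(g^2), g[, 1], g[, 2], g[, 3])
  g <- g[ord[seq_len(n)], , drop = FALSE]
  sweep(g, 2, colMeans(g))
}

# ---- Gaussian ensembles ----------------------------------------------

#' Specify a Gaussian displacement ensemble
#'
#' Frames are drawn as mean + dr with dr ~ N(0, Sigma) for a planted
#' 3N x 3N displacement covariance Sigma (interleaved x,y,z per node),
#' so every downstream covariance-based statistic has an analytic
#' expectation.
#'
#' @param mean_structure N x 3 mean coordinates, Angstrom.
#' @param covariance 3N x 3N symmetric positive-semidefinite matrix,
#'   Angstrom^2.
#' @param n_frames number of frames to draw.
#' @param seed RNG seed; identical spec + seed gives identical output.
#' @return A `gaussian_ensemble_spec` list.
#' @export
gaussian_ensemble_spec <- function(mean_structure, covariance, n_frames,
                                   seed = 1L) {
  mean_structure <- as.matrix(mean_structure)
  covariance <- as.matrix(covariance)
  n <- nrow(mean_structure)
  if (ncol(mean_structure) != 3L) stop("mean_structure must be N x 3")
  if (!all(dim(covariance) == 3L * n))
    stop("covariance must be 3N x 3N for N = ", n)
  if (max(abs(covariance - t(covariance))) >
      1e-8 * max(1, max(abs(covariance))))
    stop("covariance must be symmetric")
  stopifnot_scalar_number(n_frames, "n_frames", lower = 2)
  structure(list(mean_structure = mean_structure, covariance = covariance,
                 n_frames = as.integer(n_frames), seed = as.integer(seed)),
            class = "gaussian_ensemble_spec")
}

#' Draw a trajectory from a Gaussian ensemble specification
#'
#' Sampling uses the eigen-decomposition of the planted covariance with
#' negative eigenvalues (down to -1e-10) clipped at zero, so
#' rank-deficient planted modes are allowed.
#'
#' @param spec a [gaussian_ensemble_spec()].
#' @return An [md_trajectory()].
#' @export
generate_gaussian_ensemble <- function(spec) {
  if (!inherits(spec, "gaussian_ensemble_spec"))
    stop("spec must come from gaussian_ensemble_spec()")
  ev <- eigen(spec$covariance, symmetric = TRUE)
  tol <- 1e-10 * max(1, max(abs(ev$values)))
  if (min(ev$values) < -tol)
    stop("covariance is not positive semidefinite (min eigenvalue ",
         format(min(ev$values)), ")")
  lam <- pmax(ev$values, 0)
  d <- length(lam)
  mu <- as.vector(t(spec$mean_structure))
  X <- with_seed(spec$seed, matrix(stats::rnorm(spec$n_frames * d), spec$n_frames, d))
  disp <- X %*% (sqrt(lam) * t(ev$vectors))
  xyz <- sweep(disp, 2, mu, "+")
  md_trajectory(xyz, synthetic_topology(spec$mean_structure))
}

#' Planted block displacement covariance
#'
#' Node-level correlation matrix K with unit diagonal, `intra` within
#' blocks and `inter` between blocks, expanded isotropically to a
#' 3N x 3N displacement covariance `var * K (x) I3`.  Because the
#' expansion is isotropic, the analytic DCCM of the ensemble equals K
#' exactly, which makes K the oracle for correlation recovery.
#'
#' @param block_sizes integer vector of nodes per block.
#' @param intra within-block correlation.
#' @param inter between-block correlation.
#' @param var per-coordinate displacement variance, Angstrom^2.
#' @return list with `covariance` (3N x 3N), `node_correlation` (N x N)
#'   and `block` (block index per node).
#' @export
planted_block_covariance <- function(block_sizes, intra = 0.7, inter = -0.6,
                                     var = 0.25) {
  n <- sum(block_sizes)
  block <- rep(seq_along(block_sizes), block_sizes)
  K <- matrix(inter, n, n)
  same <- outer(block, block, "==")
  K[same] <- intra
  diag(K) <- 1
  list(covariance = var * kronecker(K, diag(3)),
       node_correlation = K, block = block)
}

# ---- two-lobe mechanism ----------------------------------------------

#' Specify a two-lobe clamshell/twist mechanism
#'
#' Two rigid lobes face each other across a cleft and are joined by a
#' narrow bridge of collinear nodes (emulating a lobe-bridging beta
#' hairpin).  Per frame the lobes counter-rotate about the hinge axis by
#' a clamshell angle ~ N(0, clamshell_amplitude^2) and about the
#' inter-lobe axis by a twist angle ~ N(0, twist_amplitude^2); bridge
#' nodes interpolate the rotations, and isotropic Gaussian noise is
#' added to every node.  Intra-lobe geometry is rigid, so intra-lobe
#' correlations are high and the two lobes are anti-correlated across
#' the cleft; the bridge is the unique contact path between the lobes.
#'
#' @param lobe_a_nodes,lobe_b_nodes nodes per lobe.
#' @param bridge_nodes number of bridge nodes (>= 1).
#' @param hinge_axis unit 3-vector, the clamshell hinge direction.
#' @param clamshell_amplitude,twist_amplitude angular standard
#'   deviations, degrees.
#' @param noise_sigma per-coordinate noise, Angstrom.
#' @param gap inner-face separation bridged by the bridge nodes, Angstrom.
#' @param n_frames frames to generate.
#' @param seed RNG seed.
#' @return A `two_lobe_spec` list.
#' @export
two_lobe_spec <- function(lobe_a_nodes = 20L, lobe_b_nodes = 12L,
                          bridge_nodes = 4L, hinge_axis = c(0, 0, 1),
                          clamshell_amplitude = 5, twist_amplitude = 3,
                          noise_sigma = 0.3, gap = 15, n_frames = 2000L,
                          seed = 1L) {
  if (lobe_a_nodes < 1L || lobe_b_nodes < 1L) stop("lobes must be non-empty")
  if (bridge_nodes < 1L) stop("at least one bridge node is required")
  if (clamshell_amplitude < 0 || twist_amplitude < 0 || noise_sigma < 0)
    stop("amplitudes and noise must be non-negative")
  if (length(hinge_axis) != 3L || sum(hinge_axis^2) == 0)
    stop("hinge_axis must be a nonzero 3-vector")
  stopifnot_scalar_number(n_frames, "n_frames", lower = 2)
  structure(list(lobe_a_nodes = as.integer(lobe_a_nodes),
                 lobe_b_nodes = as.integer(lobe_b_nodes),
                 bridge_nodes = as.integer(bridge_nodes),
                 hinge_axis = hinge_axis / sqrt(sum(hinge_axis^2)),
                 clamshell_amplitude = clamshell_amplitude,
                 twist_amplitude = twist_amplitude,
                 noise_sigma = noise_sigma, gap = gap,
                 n_frames = as.integer(n_frames), seed = as.integer(seed)),
            class = "two_lobe_spec")
}

# Reference (mean) geometry of the two-lobe scaffold.  The hinge sits at
# the origin; lobe centroids lie at polar angle +/- delta0 from the
# first in-plane axis so that counter-rotation about the hinge opens and
# closes the cleft like a clamshell.
two_lobe_geometry <- function(spec) {
  h <- spec$hinge_axis
  # orthonormal in-plane axes e1, e2 perpendicular to the hinge
  ref <- if (abs(h[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * h) * h; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(h[2] * e1[3] - h[3] * e1[2],
          h[3] * e1[1] - h[1] * e1[3],
          h[1] * e1[2] - h[2] * e1[1])
  delta0 <- 25 * pi / 180
  cl_a <- grid_cluster(spec$lobe_a_nodes)
  cl_b <- grid_cluster(spec$lobe_b_nodes)
  # centroid separation chosen so the facing surfaces are `gap` apart;
  # lobe A faces B along -e2, B faces A along +e2
  ext_a <- max(cl_a %*% (-e2))
  ext_b <- max(cl_b %*% (+e2))
  D <- spec$gap + ext_a + ext_b
  L <- D / (2 * sin(delta0))
  cA <- L * (cos(delta0) * e1 + sin(delta0) * e2)
  cB <- L * (cos(delta0) * e1 - sin(delta0) * e2)
  A <- sweep(cl_a, 2, cA, "+")
  B <- sweep(cl_b, 2, cB, "+")
  # facing anchor nodes: extreme node of each lobe toward the other
  ia <- which.max(A %*% (cB - cA))
  ib <- which.max(B %*% (cA - cB))
  m <- spec$bridge_nodes
  tfrac <- seq_len(m) / (m + 1)
  Br <- outer(1 - tfrac, A[ia, ]) + outer(tfrac, B[ib, ])
  list(A = A, B = B, bridge = Br, cA = cA, cB = cB,
       u = (cB - cA) / sqrt(sum((cB - cA)^2)),
       mid = (cA + cB) / 2, e1 = e1, e2 = e2)
}

#' Generate a two-lobe mechanism trajectory
#'
#' @param spec a [two_lobe_spec()].
#' @return An [md_trajectory()]; attribute `"truth"` carries the planted
#'   node groups (lobe A, bridge, lobe B labels) and mechanism
#'   parameters for test harnesses.
#' @export
generate_two_lobe_trajectory <- function(spec) {
  if (!inherits(spec, "two_lobe_spec")) stop("spec must come from two_lobe_spec()")
  geo <- two_lobe_geometry(spec)
  P0 <- rbind(geo$A, geo$bridge, geo$B)
  n <- nrow(P0)
  na <- spec$lobe_a_nodes; m <- spec$bridge_nodes; nb <- spec$lobe_b_nodes
  group <- rep(c("lobeA", "bridge", "lobeB"), c(na, m, nb))
  # per-node interpolation fraction of the mechanism: +1 on lobe A,
  # -1 on lobe B, linear across the bridge
  frac <- c(rep(1, na), 1 - 2 * seq_len(m) / (m + 1), rep(-1, nb))
  clam <- spec$clamshell_amplitude * pi / 180
  twi <- spec$twist_amplitude * pi / 180
  xyz <- with_seed(spec$seed, {
    th <- stats::rnorm(spec$n_frames, 0, clam)
    ph <- stats::rnorm(spec$n_frames, 0, twi)
    noise <- array(stats::rnorm(spec$n_frames * n * 3, 0, spec$noise_sigma),
                   dim = c(spec$n_frames, n * 3))
    out <- matrix(NA_real_, spec$n_frames, 3 * n)
    ufrac <- unique(frac)
    for (f in seq_len(spec$n_frames)) {
      P <- P0
      for (fr in ufrac) {
        idx <- which(frac == fr)
        Rc <- rotation_about_axis(spec$hinge_axis, fr * th[f] / 2)
        Rt <- rotation_about_axis(geo$u, fr * ph[f] / 2)
        # twist about the inter-lobe axis through the centroid midpoint,
        # then clamshell about the hinge through the origin
        Q <- sweep(P0[idx, , drop = FALSE], 2, geo$mid)
        Q <- Q %*% t(Rt)
        Q <- sweep(Q, 2, geo$mid, "+")
        P[idx, ] <- Q %*% t(Rc)
      }
      out[f, ] <- as.vector(t(P))
    }
    out + noise
  })
  traj <- md_trajectory(xyz, synthetic_topology(P0))
  labels <- paste0("ALA", seq_len(n))
  attr(traj, "truth") <- list(
    groups = split(labels, factor(group, levels = c("lobeA", "bridge", "lobeB"))),
    lobe_a = labels[group == "lobeA"],
    bridge = labels[group == "bridge"],
    lobe_b = labels[group == "lobeB"],
    clamshell_amplitude = spec$clamshell_amplitude,
    twist_amplitude = spec$twist_amplitude,
    noise_sigma = spec$noise_sigma, seed = spec$seed)
  traj
}

# ---- planted-community graphs ----------------------------------------

#' Generate a graph with planted community structure
#'
#' Communities are cliques of high-|correlation| edges; the listed
#' bridge edges carry lower correlation.  Edge distances follow the
#' network convention w = -ln|C|.  Planted labels are returned for
#' recovery scoring.
#'
#' @param n_communities number of communities (>= 2).
#' @param nodes_per_community nodes in each community (scalar or vector).
#' @param bridge_edges list of integer pairs (global node indices), or
#'   NULL to chain consecutive communities with one edge each.
#' @param seed RNG seed for the drawn correlation values.
#' @param corr_intra,corr_inter correlation ranges (length-2) for
#'   within-community and bridge edges.
#' @return list with `network` (a `dynamical_network`), `labels`
#'   (planted community index per node) and `bridge_edges`.
#' @export
generate_planted_graph <- function(n_communities, nodes_per_community,
                                   bridge_edges = NULL, seed = 1L,
                                   corr_intra = c(0.80, 0.90),
                                   corr_inter = c(0.25, 0.35)) {
  if (n_communities < 2L) stop("need at least 2 communities")
  sizes <- rep_len(nodes_per_community, n_communities)
  n <- sum(sizes)
  memb <- rep(seq_len(n_communities), sizes)
  first <- cumsum(c(1L, sizes))[seq_len(n_communities)]
  last <- cumsum(sizes)
  if (is.null(bridge_edges))
    bridge_edges <- lapply(seq_len(n_communities - 1L),
                           function(c) c(last[c], first[c + 1L]))
  be <- t(vapply(bridge_edges, function(e) sort(as.integer(e)), integer(2)))
  if (anyDuplicated(paste(be[, 1], be[, 2])))
    stop("duplicate bridge edge")
  if (any(be < 1L) || any(be > n)) stop("bridge edge index out of range")
  ii <- jj <- integer(0)
  for (c in seq_len(n_communities)) {
    v <- first[c]:last[c]
    if (length(v) > 1L) {
      cmb <- utils::combn(v, 2L)
      ii <- c(ii, cmb[1L, ]); jj <- c(jj, cmb[2L, ])
    }
  }
  intra_n <- length(ii)
  ii <- c(ii, be[, 1]); jj <- c(jj, be[, 2])
  key <- paste(ii, jj)
  if (anyDuplicated(key)) stop("bridge edge duplicates an intra-community edge")
  cij <- with_seed(seed, c(stats::runif(intra_n, corr_intra[1], corr_intra[2]),
                           stats::runif(nrow(be), corr_inter[1], corr_inter[2])))
  labels <- sprintf("n%02d", seq_len(n))
  edges <- data.frame(i = ii, j = jj, cij = cij, w = -log(abs(cij)),
                      stringsAsFactors = FALSE)
  list(network = new_dynamical_network(labels, edges),
       labels = memb,
       bridge_edges = lapply(seq_len(nrow(be)), function(r) be[r, ]))
}
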