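# Dynamic cross-correlation maps, Cartesian covariance PCA, mode
# interpolation, and clustering of conformers in PC space.

#' Dynamic cross-correlation map (DCCM)
#'
#' C_ij = <dr_i . dr_j> / sqrt(<|dr_i|^2> <|dr_j|^2>) with dr the
#' displacement from the time-mean position of each node anchor.
#' +1 is fully correlated, -1 fully anti-correlated motion.
#'
#' @param traj an [md_trajectory()]; aligned input expected (set
#'   `align = TRUE` to superpose here).
#' @param node_map node map (NULL for the default Calpha map).
#' @param align superpose onto frame 1 before computing?
#' @return N x N matrix of class `dccm`, node-labeled, unit diagonal.
#' @export
dccm <- function(traj, node_map = NULL, align = !is_aligned(traj)) {
  nm <- as_node_map(node_map, traj)
  if (align) traj <- align_trajectory(traj)
  X <- node_xyz(traj, nm)
  D <- sweep(X, 2, colMeans(X))
  f <- nrow(D)
  k <- nrow(nm)
  ix <- 3L * seq_len(k) - 2L
  num <- (crossprod(D[, ix]) + crossprod(D[, ix + 1L]) +
            crossprod(D[, ix + 2L])) / f
  v <- diag(num)
  zero <- v <= .Machine$double.eps * max(v, 1)
  if (any(zero)) {
    warning("node(s) with zero variance: ",
            paste(nm$label[zero], collapse = ", "),
            "; their correlations are set to 0")
    v[zero] <- 1
  }
  C <- num / sqrt(outer(v, v))
  if (any(zero)) { C[zero, ] <- 0; C[, zero] <- 0 }
  diag(C) <- 1
  C[C > 1] <- 1; C[C < -1] <- -1
  dimnames(C) <- list(nm$label, nm$label)
  class(C) <- c("dccm", class(C))
  C
}

#' Principal component analysis of the Cartesian covariance
#'
#' Builds the 3N x 3N covariance matrix of the node-anchor Cartesian
#' coordinates over frames and diagonalizes it.  Eigenvalues are in
#' descending order; the variance fraction of component k is
#' lambda_k / sum(lambda).  Eigenvector signs are fixed so the largest
#' absolute loading is positive, making results deterministic.
#'
#' @param traj an [md_trajectory()].
#' @param node_map node map (NULL for the default Calpha map).
#' @param align superpose onto frame 1 before analysis?
#' @return list of class `md_pca`: `mean` (N x 3), `values` (3N,
#'   Angstrom^2), `fractions`, `vectors` (3N x 3N orthonormal columns),
#'   `projections` (F x 3N), `labels`, `topology`, `total_variance`.
#' @export
pca_fit <- function(traj, node_map = NULL, align = !is_aligned(traj)) {
  nm <- as_node_map(node_map, traj)
  if (align) traj <- align_trajectory(traj)
  if (n_frames(traj) < 2L) stop("PCA requires at least 2 frames")
  X <- node_xyz(traj, nm)
  mu <- colMeans(X)
  D <- sweep(X, 2, mu)
  S <- crossprod(D) / (nrow(D) - 1)
  e <- eigen(S, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  vecs <- e$vectors
  for (k in seq_len(ncol(vecs))) {
    i <- which.max(abs(vecs[, k]))
    if (vecs[i, k] < 0) vecs[, k] <- -vecs[, k]
  }
  topo_nodes <- md_structure(traj$topology$atoms[nm$atom, , drop = FALSE])
  structure(list(mean = matrix(mu, ncol = 3L, byrow = TRUE),
                 values = vals, fractions = vals / sum(vals),
                 vectors = vecs, projections = D %*% vecs,
                 labels = nm$label, topology = topo_nodes,
                 total_variance = sum(diag(S))),
            class = "md_pca")
}

#' @export
print.md_pca <- function(x, ...) {
  cat(sprintf("md_pca: %d modes; PC1-3 variance fractions %s (cumulative %.1f%%)\n",
              length(x$values),
              paste(sprintf("%.1f%%", 100 * x$fractions[1:3]), collapse = ", "),
              100 * sum(x$fractions[1:3])))
  invisible(x)
}

#' Project frames onto principal components
#'
#' Projects each frame's mean-centered coordinate vector onto the
#' selected eigenvectors.  Per-component projection variance equals the
#' corresponding eigenvalue.
#'
#' @param traj an [md_trajectory()] over the same nodes (or an F x 3N
#'   coordinate matrix).
#' @param pca an [pca_fit()] result.
#' @param components component indices (default 1:3).
#' @param node_map node map used to extract the node coordinates when
#'   `traj` is a trajectory.
#' @return F x K projection matrix.
#' @export
pca_project <- function(traj, pca, components = 1:3, node_map = NULL) {
  if (any(components < 1L) || any(components > length(pca$values)))
    stop("component index out of range")
  X <- if (inherits(traj, "md_trajectory"))
    node_xyz(traj, as_node_map(node_map, traj)) else as.matrix(traj)
  if (ncol(X) != nrow(pca$vectors))
    stop("coordinate dimension does not match the PCA")
  D <- sweep(X, 2, as.vector(t(pca$mean)))
  D %*% pca$vectors[, components, drop = FALSE]
}

#' Interpolate structures along a principal component
#'
#' Returns structures mean + t * v_k for t spanning the observed
#' projection range on component k, visualizing the concerted motion
#' that the mode describes.
#'
#' @param pca an [pca_fit()] result.
#' @param component component index.
#' @param n_steps number of interpolated structures.
#' @return An [md_trajectory()] over the node topology (a single
#'   midpoint structure is duplicated when `n_steps = 1` so the
#'   trajectory contract of >= 2 frames holds; frame 1 carries it).
#' @export
interpolate_along_pc <- function(pca, component, n_steps = 10L) {
  if (component < 1L || component > length(pca$values))
    stop("component index out of range")
  p <- pca$projections[, component]
  t_grid <- if (n_steps == 1L) mean(range(p))
  else seq(min(p), max(p), length.out = n_steps)
  mu <- as.vector(t(pca$mean))
  xyz <- outer(t_grid, pca$vectors[, component]) +
    matrix(mu, length(t_grid), length(mu), byrow = TRUE)
  if (nrow(xyz) == 1L) xyz <- xyz[c(1L, 1L), , drop = FALSE]
  md_trajectory(xyz, pca$topology)
}

# ---- clustering -------------------------------------------------------

lloyd_kmeans <- function(X, centers, iter_max = 100L) {
  k <- nrow(centers)
  for (it in seq_len(iter_max)) {
    d2 <- vapply(seq_len(k), function(c)
      rowSums(sweep(X, 2, centers[c, ], "-")^2), numeric(nrow(X)))
    lab <- max.col(-d2, ties.method = "first")
    # re-seed empty clusters with the point farthest from its center
    for (c in setdiff(seq_len(k), unique(lab))) {
      far <- which.max(d2[cbind(seq_len(nrow(X)), lab)])
      centers[c, ] <- X[far, ]
      lab[far] <- c
    }
    new_centers <- centers
    for (c in unique(lab))
      new_centers[c, ] <- colMeans(X[lab == c, , drop = FALSE])
    if (max(abs(new_centers - centers)) < 1e-12) { centers <- new_centers; break }
    centers <- new_centers
  }
  d2 <- vapply(seq_len(k), function(c)
    rowSums(sweep(X, 2, centers[c, ], "-")^2), numeric(nrow(X)))
  lab <- max.col(-d2, ties.method = "first")
  wss <- sum(d2[cbind(seq_len(nrow(X)), lab)])
  list(labels = lab, centers = centers, wss = wss)
}

canonical_labels <- function(lab) {
  match(lab, unique(lab))
}

new_cluster_assignment <- function(labels, k, wss, tss, method,
                                   centers = NULL, heights = NULL) {
  structure(list(labels = canonical_labels(labels), k = k,
                 bss_tss = if (tss > 0) 1 - wss / tss else 0,
                 wss = wss, tss = tss, method = method,
                 centers = centers, heights = heights),
            class = "cluster_assignment")
}

#' k-means clustering of frames in PC space
#'
#' Best-of-restarts Lloyd iteration; each restart initializes centers by
#' sampling k distinct observations.  Deterministic given the seed.
#' The cluster quality is reported as BSS/TSS = 1 - WSS/TSS
#' (between-group over total sum of squares).
#'
#' @param points F x D matrix (e.g. projections onto PC1-PC2).
#' @param k number of clusters (k <= F).
#' @param restarts random restarts (default 25).
#' @param seed RNG seed.
#' @return A `cluster_assignment`: per-frame `labels` (canonicalized by
#'   first occurrence), `k`, `bss_tss`, `wss`, `method`.
#' @export
kmeans_cluster <- function(points, k, restarts = 25L, seed = 1L) {
  X <- as.matrix(points)
  f <- nrow(X)
  if (k > f) stop("k must not exceed the number of observations")
  if (k < 1L) stop("k must be at least 1")
  tss <- sum(sweep(X, 2, colMeans(X))^2)
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(restarts)) {
      init <- X[sample.int(f, k), , drop = FALSE]
      sol <- lloyd_kmeans(X, init)
      if (is.null(best) || sol$wss < best$wss - 1e-12) best <- sol
    }
  })
  # reorder centers to match the canonical (first-occurrence) labels
  map <- unique(best$labels)
  map <- c(map, setdiff(seq_len(k), map))
  new_cluster_assignment(best$labels, k, best$wss, tss, "kmeans",
                         centers = best$centers[map, , drop = FALSE])
}

#' Complete-linkage hierarchical clustering of frames
#'
#' Euclidean complete-link dendrogram cut into k clusters;
#' deterministic.
#'
#' @inheritParams kmeans_cluster
#' @return A `cluster_assignment` with the dendrogram merge `heights`
#'   retained.
#' @export
hierarchical_cluster <- function(points, k) {
  X <- as.matrix(points)
  if (nrow(X) < k) stop("k must not exceed the number of observations")
  hc <- stats::hclust(stats::dist(X), method = "complete")
  lab <- stats::cutree(hc, k = k)
  wss <- 0
  for (c in unique(lab)) {
    Xc <- X[lab == c, , drop = FALSE]
    wss <- wss + sum(sweep(Xc, 2, colMeans(Xc))^2)
  }
  tss <- sum(sweep(X, 2, colMeans(X))^2)
  new_cluster_assignment(lab, k, wss, tss, "hierarchical-complete",
                         heights = hc$height)
}

#' BSS/TSS elbow scan over cluster counts
#'
#' Runs best-of-restarts k-means for k = 1..k_max.  Monotonicity of
#' BSS/TSS in k is enforced by also seeding each k with the previous
#' best solution plus one split-off center (nested solutions), so the
#' curve is non-decreasing.
#'
#' The visual "elbow criterion" is formalized as the point of largest
#' *relative* drop in marginal gain: with g_k = BSS/TSS(k) -
#' BSS/TSS(k-1), the suggested k maximizes g_k / g_(k+1) over k whose
#' gain is non-negligible (>= 1% of the total gain).  This is the
#' curvature of the log-gain curve; the absolute second difference is
#' dominated by the first large split and misses the flattening point
#' that the eye picks out.  The suggestion is advisory and flagged
#' low-confidence when the elbow is not sharp (maximum gain ratio
#' below `min_ratio`) or the curve keeps climbing past it (more than
#' `residual_frac` of the achievable gain remains).
#'
#' @param points F x D matrix.
#' @param k_max largest k scanned (>= 2).
#' @param restarts restarts per k.
#' @param seed RNG seed.
#' @param min_ratio gain-drop sharpness required for a confident elbow.
#' @param residual_frac residual-gain fraction above which the
#'   suggestion is flagged low-confidence.
#' @return list with `k`, `bss_tss`, `suggested_k`, `low_confidence`,
#'   and `rule = "relative-gain-drop"`.
#' @export
elbow_scan <- function(points, k_max, restarts = 10L, seed = 1L,
                       min_ratio = 3, residual_frac = 0.1) {
  if (k_max < 2L) stop("k_max must be at least 2")
  X <- as.matrix(points)
  tss <- sum(sweep(X, 2, colMeans(X))^2)
  wss <- numeric(k_max)
  wss[1L] <- tss
  prev <- list(centers = matrix(colMeans(X), 1L), wss = tss,
               labels = rep(1L, nrow(X)))
  for (k in 2:k_max) {
    sol <- NULL
    if (k <= nrow(X)) {
      km <- kmeans_cluster(X, k, restarts = restarts, seed = seed + k)
      sol <- list(centers = km$centers, wss = km$wss, labels = km$labels)
      # nested candidate: previous centers plus the worst-fit point
      d2p <- vapply(seq_len(nrow(prev$centers)), function(c)
        rowSums(sweep(X, 2, prev$centers[c, ], "-")^2), numeric(nrow(X)))
      far <- which.max(d2p[cbind(seq_len(nrow(X)), prev$labels)])
      nested <- lloyd_kmeans(X, rbind(prev$centers, X[far, ]))
      if (nested$wss < sol$wss) sol <- nested
    } else sol <- prev
    wss[k] <- min(sol$wss, wss[k - 1L])
    prev <- sol
  }
  b <- if (tss > 0) 1 - wss / tss else rep(0, k_max)
  total <- b[k_max] - b[1L]
  eps <- 1e-12 + 1e-9 * max(total, 0)
  suggested <- 2L; best_ratio <- 0
  if (k_max >= 3L && total > 0) {
    for (k in 2:(k_max - 1L)) {
      gk <- b[k] - b[k - 1L]
      gk1 <- b[k + 1L] - b[k]
      if (gk < 0.01 * total) next
      ratio <- gk / max(gk1, eps)
      if (ratio > best_ratio) { best_ratio <- ratio; suggested <- k }
    }
  }
  low_conf <- total <= 0 || best_ratio < min_ratio ||
    (b[k_max] - b[suggested]) > residual_frac * total
  list(k = seq_len(k_max), bss_tss = b, suggested_k = suggested,
       low_confidence = low_conf, rule = "relative-gain-drop")
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement of two labelings; 1 means identical
#' partitions, ~0 the agreement expected at random.
#'
#' @param a,b label vectors of equal length.
#' @return numeric in [-1, 1].
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors must have equal length")
  tab <- table(a, b)
  n <- length(a)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  exp_idx <- sum_a * sum_b / comb2(n)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == exp_idx) return(1)
  (sum_ij - exp_idx) / (max_idx - exp_idx)
}
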