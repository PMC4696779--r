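# Independent brute-force oracles and fixture builders.  Everything here
# deliberately avoids the code paths (and the igraph routines) used by
# the package: Floyd-Warshall for distances, exhaustive DFS for paths,
# restricted-growth-string enumeration for set partitions.

# ---- graph fixtures ---------------------------------------------------

# Edge table (i, j, w) -> dynamical_network, with |C| = exp(-w).
edges_to_network <- function(n, edges) {
  labels <- sprintf("v%02d", seq_len(n))
  corrnet:::new_dynamical_network(labels, data.frame(
    i = edges[, 1], j = edges[, 2], cij = exp(-edges[, 3]), w = edges[, 3]))
}

# Connected Erdos-Renyi graph with uniform random weights; retries until
# connected (checked by a hand-rolled flood fill).
random_connected_graph <- function(n, p, seed) {
  set.seed(seed)
  repeat {
    pair <- t(combn(n, 2))
    keep <- runif(nrow(pair)) < p
    e <- pair[keep, , drop = FALSE]
    if (nrow(e) >= n - 1 && oracle_connected(n, e)) break
  }
  w <- runif(nrow(e), 0.5, 2)
  list(n = n, edges = cbind(e, w),
       network = edges_to_network(n, cbind(e, w)))
}

oracle_connected <- function(n, e) {
  seen <- c(TRUE, rep(FALSE, n - 1))
  repeat {
    grew <- FALSE
    for (r in seq_len(nrow(e))) {
      a <- e[r, 1]; b <- e[r, 2]
      if (seen[a] != seen[b]) { seen[a] <- seen[b] <- TRUE; grew <- TRUE }
    }
    if (!grew) break
  }
  all(seen)
}

# All-pairs shortest distances by Floyd-Warshall.
oracle_distances <- function(n, edges) {
  d <- matrix(Inf, n, n); diag(d) <- 0
  for (r in seq_len(nrow(edges))) {
    i <- edges[r, 1]; j <- edges[r, 2]; w <- edges[r, 3]
    d[i, j] <- min(d[i, j], w); d[j, i] <- d[i, j]
  }
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

# All simple paths from s to t with total weight <= bound (exhaustive
# DFS; the only pruning is the bound itself, so this stays independent
# of the implementation's distance-based pruning).
oracle_simple_paths <- function(n, edges, s, t, bound) {
  adj <- vector("list", n)
  for (v in seq_len(n)) adj[[v]] <- matrix(numeric(0), 0, 2)
  for (r in seq_len(nrow(edges))) {
    i <- edges[r, 1]; j <- edges[r, 2]; w <- edges[r, 3]
    adj[[i]] <- rbind(adj[[i]], c(j, w))
    adj[[j]] <- rbind(adj[[j]], c(i, w))
  }
  paths <- list(); lens <- numeric(0)
  visited <- logical(n)
  walk <- function(v, acc, len) {
    if (len > bound + 1e-9) return(invisible(NULL))
    if (v == t) {
      paths[[length(paths) + 1L]] <<- c(acc, v)
      lens[length(lens) + 1L] <<- len
      return(invisible(NULL))
    }
    visited[v] <<- TRUE
    nb <- adj[[v]]
    if (nrow(nb)) for (r in seq_len(nrow(nb)))
      if (!visited[nb[r, 1]]) walk(nb[r, 1], c(acc, v), len + nb[r, 2])
    visited[v] <<- FALSE
  }
  walk(s, integer(0), 0)
  list(paths = paths, lengths = lens)
}

# Weighted node betweenness by pair-by-pair enumeration of all shortest
# paths (fractional sharing among equal-length paths).
oracle_betweenness <- function(n, edges) {
  d <- oracle_distances(n, edges)
  bt <- numeric(n)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    if (!is.finite(d[s, t])) next
    res <- oracle_simple_paths(n, edges, s, t, d[s, t])
    sp <- res$paths[abs(res$lengths - d[s, t]) < 1e-9]
    if (!length(sp)) next
    for (p in sp) {
      inner <- setdiff(p, c(s, t))
      bt[inner] <- bt[inner] + 1 / length(sp)
    }
  }
  bt
}

# ---- exhaustive modularity --------------------------------------------

# Unweighted Newman modularity of membership `m` on edge list `e`.
oracle_modularity <- function(e, deg, m) {
  nn <- nrow(e)
  intra <- sum(m[e[, 1]] == m[e[, 2]]) / nn
  intra - sum(tapply(deg, m, sum)^2) / (4 * nn^2)
}

# Maximum modularity over ALL set partitions of n nodes (restricted
# growth strings); n <= 10 stays tractable.
oracle_max_modularity <- function(n, e) {
  deg <- tabulate(c(e[, 1], e[, 2]), n)
  best_q <- -Inf; best_m <- NULL
  a <- integer(n)          # growth string, a[1] = 0
  b <- integer(n)          # running maxima
  recurse <- function(i) {
    if (i > n) {
      q <- oracle_modularity(e, deg, a + 1L)
      if (q > best_q + 1e-12) { best_q <<- q; best_m <<- a + 1L }
      return(invisible(NULL))
    }
    for (v in 0:(b[i - 1L] + 1L)) {
      a[i] <<- v
      b[i] <<- max(b[i - 1L], v)
      recurse(i + 1L)
    }
  }
  a[1] <- 0L; b[1] <- 0L
  if (n == 1L) return(list(q = 0, membership = 1L))
  recurse(2L)
  list(q = best_q, membership = best_m)
}

# Partition equality up to relabeling.
same_partition <- function(a, b) {
  length(a) == length(b) &&
    identical(match(a, unique(a)), match(b, unique(b)))
}

# ---- trajectory fixtures ---------------------------------------------

# Minimal multi-model PDB text for frames given as list of N x 3 mats.
pdb_text <- function(frames, resnames = NULL, het = NULL, names = NULL) {
  n <- nrow(frames[[1]])
  resnames <- resnames %||% rep("ALA", n)
  het <- het %||% rep(FALSE, n)
  names <- names %||% rep("CA", n)
  out <- character(0)
  for (f in seq_along(frames)) {
    out <- c(out, sprintf("MODEL     %4d", f))
    co <- frames[[f]]
    for (i in seq_len(n)) {
      nm <- if (nchar(names[i]) < 4) paste0(" ", names[i]) else names[i]
      out <- c(out, sprintf(
        "%-6s%5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        if (het[i]) "HETATM" else "ATOM", i, nm, resnames[i], "A", i,
        co[i, 1], co[i, 2], co[i, 3], 1.00, 10.00, "C"))
    }
    out <- c(out, "ENDMDL")
  }
  c(out, "END")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_pdb_fixture <- function(frames, ...) {
  path <- tempfile(fileext = ".pdb")
  writeLines(pdb_text(frames, ...), path)
  path
}

# Static trajectory object (all frames equal) over simple coordinates.
static_traj <- function(coords, f = 5L) {
  xyz <- matrix(rep(as.vector(t(coords)), f), f, byrow = TRUE)
  corrnet::md_trajectory(xyz, corrnet:::synthetic_topology(coords))
}

# Well-separated Gaussian blobs in D dimensions; returns points+labels.
make_blobs <- function(centers, n_per = 50L, sd = 0.4, seed = 1L) {
  set.seed(seed)
  pts <- do.call(rbind, lapply(seq_len(nrow(centers)), function(c)
    sweep(matrix(rnorm(n_per * ncol(centers), 0, sd), n_per), 2,
          centers[c, ], "+")))
  list(points = pts, labels = rep(seq_len(nrow(centers)), each = n_per))
}

# Two 3-cliques joined by one bridge edge (nodes 1:3, 4:6; bridge 3-4).
two_clique_bridge <- function() {
  e <- rbind(c(1, 2), c(1, 3), c(2, 3), c(4, 5), c(4, 6), c(5, 6), c(3, 4))
  edges_to_network(6, cbind(e, 1))
}
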