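# Correlation-weighted dynamical networks: contact-persistence edges,
# Girvan-Newman communities, betweenness, critical nodes, and
# optimal/suboptimal communication paths.
#
# Edge distances use the information-transfer convention w = -ln|C|:
# strongly correlated contacts are "short", weak ones "long", so
# shortest paths trace the most probable communication routes.

#' Contact persistence over a trajectory
#'
#' p_ij is the fraction of frames in which two nodes are in contact,
#' i.e. their minimum inter-atom distance is below the cutoff.  Mode
#' `"heavy"` measures the minimum distance over all non-hydrogen atoms
#' of the two residues; mode `"anchor"` uses the node anchor atoms only
#' (the natural choice for Calpha-only models).
#'
#' @param traj an [md_trajectory()].
#' @param node_map node map (NULL for the default Calpha map).
#' @param cutoff contact distance cutoff, Angstrom (default 4.5).
#' @param mode `"anchor"` or `"heavy"`.
#' @return N x N symmetric matrix of fractions in [0, 1] (class
#'   `contact_stats`); the diagonal is set to 1 but carries no meaning.
#' @export
contact_persistence <- function(traj, node_map = NULL, cutoff = 4.5,
                                mode = c("anchor", "heavy")) {
  mode <- match.arg(mode)
  if (cutoff <= 0) stop("cutoff must be positive")
  nm <- as_node_map(node_map, traj)
  k <- nrow(nm)
  f <- n_frames(traj)
  count <- matrix(0, k, k)
  if (mode == "anchor") {
    X <- node_xyz(traj, nm)
    for (fr in seq_len(f)) {
      d <- as.matrix(stats::dist(matrix(X[fr, ], ncol = 3L, byrow = TRUE)))
      count <- count + (d < cutoff)
    }
  } else {
    a <- traj$topology$atoms
    sets <- lapply(seq_len(k), function(i) {
      idx <- which(a$chain == nm$chain[i] & a$resno == nm$resno[i] &
                     a$element != "H")
      if (!length(idx)) nm$atom[i] else idx
    })
    for (fr in seq_len(f)) {
      co <- traj_frame(traj, fr)
      for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
        dmin <- min(as.matrix(stats::dist(rbind(co[sets[[i]], , drop = FALSE],
                                                co[sets[[j]], , drop = FALSE])))[
                      seq_along(sets[[i]]),
                      length(sets[[i]]) + seq_along(sets[[j]])])
        if (dmin < cutoff) count[i, j] <- count[j, i] <- count[i, j] + 1
      }
    }
    diag(count) <- f
  }
  p <- count / f
  diag(p) <- 1
  dimnames(p) <- list(nm$label, nm$label)
  attr(p, "cutoff") <- cutoff
  attr(p, "mode") <- mode
  class(p) <- c("contact_stats", class(p))
  p
}

# Construct a dynamical_network from labels and an edge table with
# columns i, j (node indices), cij, w.
new_dynamical_network <- function(labels, edges) {
  if (nrow(edges)) {
    swap <- edges$i > edges$j
    tmp <- edges$i[swap]; edges$i[swap] <- edges$j[swap]; edges$j[swap] <- tmp
    edges <- edges[order(edges$i, edges$j), , drop = FALSE]
    rownames(edges) <- NULL
  }
  edges$label_i <- labels[edges$i]
  edges$label_j <- labels[edges$j]
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges$label_i, to = edges$label_j),
    directed = FALSE,
    vertices = data.frame(name = labels))
  igraph::E(g)$w <- edges$w
  igraph::E(g)$cij <- edges$cij
  structure(list(graph = g, nodes = labels, edges = edges),
            class = "dynamical_network")
}

#' @export
print.dynamical_network <- function(x, ...) {
  cat(sprintf("dynamical_network: %d nodes, %d edges (w = -ln|C|)\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Build a correlation-weighted dynamical network
#'
#' Draws an edge (i, j) when the contact persistence p_ij meets the
#' threshold and the nodes are more than `exclude_neighbors` apart in
#' the node ordering (bonded neighbors are trivially in contact and
#' would short-circuit communication paths).  Edge distances are
#' w_ij = -ln|C_ij|; edges with C_ij = 0 are dropped with a warning.
#'
#' @param contacts a [contact_persistence()] matrix.
#' @param corr a [dccm()] matrix over the same nodes.
#' @param persistence_min minimum contact fraction (default 0.75,
#'   i.e. "in contact for at least 75% of the trajectory").
#' @param exclude_neighbors sequence-neighbor exclusion (default 1:
#'   drop |i - j| <= 1).
#' @return A `dynamical_network` (igraph-backed, with an edge table).
#' @export
build_network <- function(contacts, corr, persistence_min = 0.75,
                          exclude_neighbors = 1L) {
  if (!all(dim(contacts) == dim(corr)))
    stop("contact and correlation matrices must have matching dimensions")
  if (!is.null(rownames(contacts)) && !is.null(rownames(corr)) &&
      !identical(rownames(contacts), rownames(corr)))
    stop("contact and correlation matrices must share node ordering")
  if (persistence_min < 0 || persistence_min > 1)
    stop("persistence_min must be in [0, 1]")
  n <- nrow(contacts)
  labels <- rownames(contacts) %||% sprintf("n%02d", seq_len(n))
  pair <- which(upper.tri(contacts), arr.ind = TRUE)
  keep <- contacts[pair] >= persistence_min &
    (pair[, 2] - pair[, 1]) > exclude_neighbors
  pair <- pair[keep, , drop = FALSE]
  cij <- corr[pair]
  zero <- cij == 0
  if (any(zero)) {
    warning(sum(zero), " edge(s) dropped: zero correlation gives infinite distance")
    pair <- pair[!zero, , drop = FALSE]
    cij <- cij[!zero]
  }
  new_dynamical_network(labels, data.frame(
    i = pair[, 1], j = pair[, 2], cij = cij, w = -log(abs(cij)),
    stringsAsFactors = FALSE))
}

# Edge chosen deterministically among ties: maximum value, then lowest
# (i, j) endpoint pair.
pick_max_edge <- function(ends_i, ends_j, values) {
  mx <- max(values)
  cand <- which(values >= mx - 1e-12)
  if (length(cand) > 1L) {
    a <- pmin(ends_i[cand], ends_j[cand])
    b <- pmax(ends_i[cand], ends_j[cand])
    cand <- cand[order(a, b)][1L]
  }
  cand[1L]
}

# Unweighted Newman modularity of a membership vector with respect to
# the ORIGINAL network's edges and degrees.
partition_modularity <- function(edges_i, edges_j, degree, membership) {
  m <- length(edges_i)
  if (m == 0L) return(0)
  intra <- sum(membership[edges_i] == membership[edges_j]) / m
  dsum <- tapply(degree, membership, sum)
  intra - sum((dsum / (2 * m))^2)
}

#' Girvan-Newman community detection
#'
#' Iteratively removes the edge of highest (distance-weighted) edge
#' betweenness; among all partitions into connected components arising
#' along the removal sequence, the one maximizing the unweighted Newman
#' modularity Q of the original network is returned.  Ties are broken
#' deterministically (lowest endpoint pair; earliest partition at equal
#' Q).  Disconnected inputs are handled naturally: components are
#' subdivided independently.
#'
#' @param network a `dynamical_network`.
#' @param weighted_betweenness use w = -ln|C| edge distances when
#'   computing edge betweenness (default TRUE).
#' @return A `community_partition`: named `membership` (community index
#'   per node, canonical order), `modularity`, `n_communities`.
#' @export
girvan_newman <- function(network, weighted_betweenness = TRUE) {
  g0 <- network$graph
  if (igraph::vcount(g0) == 0L) stop("empty network")
  n <- length(network$nodes)
  lab2idx <- stats::setNames(seq_len(n), network$nodes)
  e0 <- network$edges
  deg <- igraph::degree(g0)[network$nodes]
  score <- function(memb) partition_modularity(e0$i, e0$j, deg, memb)
  g <- g0
  best_memb <- igraph::components(g)$membership[network$nodes]
  best_q <- score(best_memb)
  while (igraph::ecount(g) > 0L) {
    wts <- if (weighted_betweenness) igraph::E(g)$w else NULL
    eb <- igraph::edge_betweenness(g, weights = wts, directed = FALSE)
    ends <- igraph::ends(g, igraph::E(g), names = TRUE)
    pick <- pick_max_edge(lab2idx[ends[, 1]], lab2idx[ends[, 2]], eb)
    g <- igraph::delete_edges(g, pick)
    memb <- igraph::components(g)$membership[network$nodes]
    q <- score(memb)
    if (q > best_q + 1e-12) { best_q <- q; best_memb <- memb }
  }
  memb <- canonical_labels(as.integer(best_memb))
  names(memb) <- network$nodes
  structure(list(membership = memb, modularity = best_q,
                 n_communities = max(memb)),
            class = "community_partition")
}

#' @export
print.community_partition <- function(x, ...) {
  cat(sprintf("community_partition: %d communities, Q = %.4f\n",
              x$n_communities, x$modularity))
  invisible(x)
}

#' Node and edge betweenness of a dynamical network
#'
#' Shortest-path betweenness under the w = -ln|C| edge distances;
#' multiplicities of equal-length shortest paths are shared
#' fractionally (Brandes' convention).
#'
#' @param network a `dynamical_network`.
#' @return list of class `centrality_profile`: `node` (data.frame
#'   label, betweenness) and `edge` (edge table plus betweenness).
#' @export
network_betweenness <- function(network) {
  g <- network$graph
  if (igraph::vcount(g) == 0L) stop("empty network")
  wts <- if (igraph::ecount(g)) igraph::E(g)$w else NULL
  nb <- igraph::betweenness(g, weights = wts, directed = FALSE)
  eb <- igraph::edge_betweenness(g, weights = wts, directed = FALSE)
  edges <- network$edges
  edges$betweenness <- if (nrow(edges)) {
    ends <- igraph::ends(g, igraph::E(g), names = TRUE)
    key_g <- paste(pmin(ends[, 1], ends[, 2]), pmax(ends[, 1], ends[, 2]))
    key_e <- paste(pmin(edges$label_i, edges$label_j),
                   pmax(edges$label_i, edges$label_j))
    eb[match(key_e, key_g)]
  } else numeric(0)
  structure(list(node = data.frame(label = network$nodes,
                                   betweenness = as.vector(nb[network$nodes])),
                 edge = edges),
            class = "centrality_profile")
}

#' Critical nodes between communities
#'
#' For every pair of communities joined by at least one edge, the
#' connecting edge of maximum edge betweenness is selected and both its
#' endpoints are reported.  These are the nodes mediating
#' inter-community communication.
#'
#' @param network a `dynamical_network`.
#' @param partition a [girvan_newman()] partition.
#' @param centrality a [network_betweenness()] profile (computed if
#'   NULL).
#' @return character vector of node labels (sorted, unique); empty when
#'   there is a single community.
#' @export
critical_nodes <- function(network, partition, centrality = NULL) {
  if (is.null(centrality)) centrality <- network_betweenness(network)
  ed <- centrality$edge
  if (!nrow(ed)) return(character(0))
  ci <- partition$membership[ed$label_i]
  cj <- partition$membership[ed$label_j]
  inter <- which(ci != cj)
  if (!length(inter)) return(character(0))
  pair_key <- paste(pmin(ci[inter], cj[inter]), pmax(ci[inter], cj[inter]))
  out <- character(0)
  for (pk in unique(pair_key)) {
    rows <- inter[pair_key == pk]
    pick <- rows[pick_max_edge(ed$i[rows], ed$j[rows], ed$betweenness[rows])]
    out <- c(out, ed$label_i[pick], ed$label_j[pick])
  }
  sort(unique(out))
}

# Bounded depth-first enumeration of simple paths from `src` to `dst`
# with total length <= bound; `dist_to_dst` provides an admissible
# lower bound for pruning.  Adjacency passed as list of (neighbor,
# weight) matrices.
bounded_path_dfs <- function(adj, src, dst, bound, dist_to_dst, hard_cap) {
  paths <- list(); lens <- numeric(0)
  n <- length(adj)
  visited <- logical(n)
  path <- integer(n + 1L)
  eps <- 1e-9 * max(1, bound)
  recurse <- function(v, depth, len) {
    if (length(paths) >= hard_cap) return(invisible(TRUE))
    path[depth] <<- v
    if (v == dst) {
      paths[[length(paths) + 1L]] <<- path[seq_len(depth)]
      lens[length(lens) + 1L] <<- len
      return(invisible(NULL))
    }
    visited[v] <<- TRUE
    nb <- adj[[v]]
    if (nrow(nb)) for (r in seq_len(nrow(nb))) {
      u <- nb[r, 1L]
      if (!visited[u]) {
        nl <- len + nb[r, 2L]
        if (nl + dist_to_dst[u] <= bound + eps)
          recurse(u, depth + 1L, nl)
      }
    }
    visited[v] <<- FALSE
    invisible(NULL)
  }
  recurse(src, 1L, 0)
  list(paths = paths, lengths = lens)
}

network_adjacency <- function(network) {
  n <- length(network$nodes)
  adj <- vector("list", n)
  for (v in seq_len(n)) adj[[v]] <- matrix(numeric(0), 0L, 2L)
  e <- network$edges
  if (nrow(e)) for (r in seq_len(nrow(e))) {
    adj[[e$i[r]]] <- rbind(adj[[e$i[r]]], c(e$j[r], e$w[r]))
    adj[[e$j[r]]] <- rbind(adj[[e$j[r]]], c(e$i[r], e$w[r]))
  }
  # deterministic neighbor order
  lapply(adj, function(m) m[order(m[, 1L]), , drop = FALSE])
}

#' Optimal (shortest) path between two nodes
#'
#' Minimum total edge distance (w = -ln|C|) path; when several optimal
#' paths exist the lexicographically smallest node sequence is
#' returned, making the result deterministic.
#'
#' @param network a `dynamical_network`.
#' @param source,target node labels.
#' @return list with `path` (node label sequence) and `length`.
#' @export
optimal_path <- function(network, source, target) {
  si <- match(source, network$nodes); ti <- match(target, network$nodes)
  if (is.na(si)) stop("unknown node label: ", source)
  if (is.na(ti)) stop("unknown node label: ", target)
  if (si == ti) return(list(path = source, length = 0))
  ps <- suboptimal_paths(network, source, target, delta = 0, max_paths = 16L)
  list(path = ps$paths[[1L]], length = ps$lengths[[1L]])
}

#' Optimal and suboptimal paths between two nodes
#'
#' Enumerates every simple path whose total edge distance is within
#' `delta` of the optimal length L_opt, sorted by ascending length
#' (ties: lexicographic node sequence).  The optimal path comes first.
#' "Slightly longer" is not a sharp notion; the default tolerance is
#' 20% of L_opt and is a reported parameter.
#'
#' @param network a `dynamical_network`.
#' @param source,target node labels.
#' @param delta path-length tolerance in edge-distance units (default
#'   0.2 * L_opt).
#' @param max_paths truncate the returned set at this many paths.
#' @return A `path_set`: `paths` (list of label sequences), `lengths`,
#'   `optimal`, `delta`, `truncated`.
#' @export
suboptimal_paths <- function(network, source, target, delta = NULL,
                             max_paths = 500L) {
  si <- match(source, network$nodes); ti <- match(target, network$nodes)
  if (is.na(si)) stop("unknown node label: ", source)
  if (is.na(ti)) stop("unknown node label: ", target)
  g <- network$graph
  dmat <- igraph::distances(g, v = igraph::V(g), to = network$nodes[ti],
                            weights = if (igraph::ecount(g)) igraph::E(g)$w else NULL)
  dist_to_dst <- as.vector(dmat)[match(network$nodes, rownames(dmat))]
  l_opt <- dist_to_dst[si]
  if (!is.finite(l_opt)) stop("no path: ", source, " and ", target,
                              " are not connected")
  if (is.null(delta)) delta <- 0.2 * l_opt
  if (delta < 0) stop("delta must be non-negative")
  adj <- network_adjacency(network)
  hard_cap <- max(50L * max_paths, 5000L)
  res <- bounded_path_dfs(adj, si, ti, l_opt + delta, dist_to_dst, hard_cap)
  seqs <- lapply(res$paths, function(p) network$nodes[p])
  keys <- vapply(seqs, paste, character(1), collapse = "\r")
  ord <- order(res$lengths, keys)
  truncated <- length(ord) > max_paths || length(res$paths) >= hard_cap
  ord <- ord[seq_len(min(length(ord), max_paths))]
  structure(list(source = source, target = target,
                 paths = seqs[ord], lengths = res$lengths[ord],
                 optimal = seqs[[ord[1L]]], optimal_length = res$lengths[ord[1L]],
                 delta = delta, truncated = truncated),
            class = "path_set")
}

#' @export
print.path_set <- function(x, ...) {
  cat(sprintf("path_set: %s -> %s, %d path(s), L_opt = %.4f, delta = %.4f%s\n",
              x$source, x$target, length(x$paths), x$optimal_length, x$delta,
              if (x$truncated) " (truncated)" else ""))
  invisible(x)
}

#' Per-edge usage counts of a path set
#'
#' Number of paths in the set crossing each edge (the quantity edge
#' thickness is weighted by in network-path figures).
#'
#' @param pathset a [suboptimal_paths()] result.
#' @return data.frame with `label_i`, `label_j`, `count`, sorted by
#'   decreasing count.
#' @export
edge_path_usage <- function(pathset) {
  if (!length(pathset$paths)) stop("empty path set")
  keys <- unlist(lapply(pathset$paths, function(p) {
    a <- p[-length(p)]; b <- p[-1L]
    paste(pmin(a, b), pmax(a, b), sep = "\r")
  }))
  tab <- sort(table(keys), decreasing = TRUE)
  parts <- strsplit(names(tab), "\r", fixed = TRUE)
  data.frame(label_i = vapply(parts, `[`, character(1), 1L),
             label_j = vapply(parts, `[`, character(1), 2L),
             count = as.integer(tab), stringsAsFactors = FALSE)
}

#' Write a dynamical network to GraphML / edge-list files
#'
#' @param network a `dynamical_network`.
#' @param graphml,edges output paths (NULL to skip either).
#' @return invisibly, the paths written.
#' @export
write_network <- function(network, graphml = NULL, edges = NULL) {
  out <- character(0)
  if (!is.null(graphml)) {
    igraph::write_graph(network$graph, graphml, format = "graphml")
    out <- c(out, graphml)
  }
  if (!is.null(edges)) {
    utils::write.table(
      network$edges[, c("label_i", "label_j", "cij", "w")],
      edges, sep = "\t", quote = FALSE, row.names = FALSE)
    out <- c(out, edges)
  }
  invisible(out)
}
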