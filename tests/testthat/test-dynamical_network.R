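# Contact persistence, network construction, communities, betweenness,
# optimal/suboptimal paths -- checked against brute-force oracles.

test_that("contact_persistence honors the cutoff threshold semantics", {
  # three nodes; pair (1,2) in contact 14/20 frames, pair (1,3) 15/20
  f <- 20L
  base <- rbind(c(0, 0, 0), c(4, 0, 0), c(0, 4, 0))
  xyz <- matrix(rep(as.vector(t(base)), f), f, byrow = TRUE)
  xyz[15:20, 4] <- 6    # node 2 beyond cutoff in 6 frames -> p = 0.70
  xyz[16:20, 8] <- 6    # node 3 beyond cutoff in 5 frames -> p = 0.75
  tr <- md_trajectory(xyz, corrnet:::synthetic_topology(base))
  p <- contact_persistence(tr, cutoff = 4.5)
  expect_equal(p[1, 2], 0.70)
  expect_equal(p[1, 3], 0.75)

  C <- matrix(0.5, 3, 3); diag(C) <- 1
  dimnames(C) <- dimnames(p)
  net <- build_network(p, C, persistence_min = 0.75, exclude_neighbors = 0)
  keys <- paste(net$edges$label_i, net$edges$label_j)
  expect_false("ALA1 ALA2" %in% keys)   # 70% -> excluded
  expect_true("ALA1 ALA3" %in% keys)    # 75% -> included

  # fixed separations: 4.0 A -> p = 1, 5.0 A -> p = 0 at a 4.5 cutoff
  st <- static_traj(rbind(c(0, 0, 0), c(4, 0, 0), c(9, 0, 0)))
  ps <- contact_persistence(st, cutoff = 4.5)
  expect_equal(ps[1, 2], 1)
  expect_equal(ps[2, 3], 0)
  expect_error(contact_persistence(st, cutoff = -1), "positive")
})

test_that("heavy-atom contact mode uses minimum inter-residue distance", {
  # two residues of two atoms each; anchors far apart, side atoms close
  atoms <- data.frame(
    serial = 1:4, name = c("CA", "CB", "CA", "CB"),
    resname = "ALA", chain = "A", resno = c(1, 1, 2, 2),
    x = c(0, 0, 10, 4), y = 0, z = 0, b = 0, element = "C", hetatm = FALSE)
  s <- md_structure(atoms)
  xyz <- matrix(rep(as.vector(t(cbind(atoms$x, atoms$y, atoms$z))), 3), 3,
                byrow = TRUE)
  tr <- md_trajectory(xyz, s)
  nm <- build_node_map(s)
  expect_equal(contact_persistence(tr, nm, mode = "anchor")[1, 2], 0)
  expect_equal(contact_persistence(tr, nm, mode = "heavy")[1, 2], 1)
})

test_that("build_network: closed-form weights, counting, monotonicity", {
  p <- matrix(1, 4, 4)
  C <- diag(4)
  C[1, 2] <- C[2, 1] <- 1          # w = 0
  C[1, 3] <- C[3, 1] <- exp(-1)    # w = 1
  C[1, 4] <- C[4, 1] <- -0.5       # w = -ln(0.5), sign dropped
  C[2, 4] <- C[4, 2] <- 0          # dropped with warning
  C[2, 3] <- C[3, 2] <- 0.8
  C[3, 4] <- C[4, 3] <- 0.8
  expect_warning(net <- build_network(p, C, persistence_min = 0.75,
                                      exclude_neighbors = 0),
                 "zero correlation")
  e <- net$edges
  key <- function(i, j) which(e$i == i & e$j == j)
  expect_equal(e$w[key(1, 2)], 0)
  expect_equal(e$w[key(1, 3)], 1)
  expect_equal(e$w[key(1, 4)], -log(0.5))
  expect_equal(nrow(e), 5L)                      # 6 pairs - 1 dropped

  # persistence matrix with exactly 3 entries over threshold
  p2 <- matrix(0, 4, 4); diag(p2) <- 1
  p2[1, 3] <- p2[3, 1] <- 0.8
  p2[1, 4] <- p2[4, 1] <- 0.9
  p2[2, 4] <- p2[4, 2] <- 0.75
  C2 <- matrix(0.5, 4, 4); diag(C2) <- 1
  net2 <- build_network(p2, C2, persistence_min = 0.75, exclude_neighbors = 1)
  expect_equal(nrow(net2$edges), 3L)

  # raising persistence_min never adds edges
  set.seed(6)
  pr <- matrix(runif(100), 10); pr <- (pr + t(pr)) / 2; diag(pr) <- 1
  Cr <- matrix(0.6, 10, 10); diag(Cr) <- 1
  sizes <- vapply(c(0.25, 0.5, 0.75, 0.9), function(th)
    nrow(build_network(pr, Cr, persistence_min = th)$edges), numeric(1))
  expect_true(all(diff(sizes) <= 0))
  expect_error(build_network(pr[1:9, 1:9], Cr), "matching dimensions")
})

test_that("girvan_newman equals exhaustive max-modularity on fixtures", {
  # two 3-cliques + bridge: Q = 5/14, two communities of 3
  tc <- two_clique_bridge()
  part <- girvan_newman(tc)
  expect_equal(part$modularity, 5 / 14, tolerance = 1e-12)
  expect_equal(part$n_communities, 2L)
  expect_true(same_partition(part$membership, rep(1:2, each = 3)))

  # single clique stays one community
  cl <- edges_to_network(4, cbind(t(combn(4, 2)), 1))
  expect_equal(girvan_newman(cl)$n_communities, 1L)
  expect_error(girvan_newman(corrnet:::new_dynamical_network(
    character(0), data.frame(i = integer(0), j = integer(0),
                             cij = numeric(0), w = numeric(0)))),
               "empty network")

  # fixture suite <= 10 nodes vs exhaustive set-partition enumeration
  fixtures <- list(
    two_clique_bridge(),
    edges_to_network(8, cbind(rbind(t(combn(1:4, 2)), t(combn(5:8, 2)),
                                    c(4, 5)), 1)),
    generate_planted_graph(3, 3, seed = 2)$network,
    generate_planted_graph(2, 5, seed = 3)$network,
    generate_planted_graph(3, c(3, 3, 4), seed = 4)$network)
  for (net in fixtures) {
    e <- as.matrix(net$edges[, c("i", "j")])
    oracle <- oracle_max_modularity(length(net$nodes), e)
    got <- girvan_newman(net)
    expect_equal(got$modularity, oracle$q, tolerance = 1e-9)
    expect_true(same_partition(got$membership, oracle$membership))
  }
})

test_that("betweenness matches hand counts and the enumeration oracle", {
  # path a-b-c: center 1, endpoints 0
  path3 <- edges_to_network(3, cbind(rbind(c(1, 2), c(2, 3)), 1))
  bt <- network_betweenness(path3)
  expect_equal(bt$node$betweenness, c(0, 1, 0))
  # 5-node star: center lies on all 6 leaf pairs
  star <- edges_to_network(5, cbind(rbind(c(1, 2), c(1, 3), c(1, 4), c(1, 5)), 1))
  bs <- network_betweenness(star)
  expect_equal(bs$node$betweenness, c(6, 0, 0, 0, 0))

  for (seed in 1:6) {
    g <- random_connected_graph(sample(5:9, 1), 0.4, seed = seed)
    got <- network_betweenness(g$network)$node$betweenness
    expect_equal(got, oracle_betweenness(g$n, g$edges), tolerance = 1e-8)
  }
})

test_that("optimal and suboptimal paths match exhaustive enumeration", {
  tri <- edges_to_network(3, rbind(c(1, 2, 1), c(2, 3, 1), c(1, 3, 3)))
  op <- optimal_path(tri, "v01", "v03")
  expect_equal(op$path, c("v01", "v02", "v03"))
  expect_equal(op$length, 2)
  expect_equal(optimal_path(tri, "v02", "v02"), list(path = "v02", length = 0))

  ps <- suboptimal_paths(tri, "v01", "v03", delta = 1.5)
  expect_equal(length(ps$paths), 2L)
  expect_equal(ps$lengths, c(2, 3))
  expect_equal(ps$paths[[2]], c("v01", "v03"))
  # delta = 0 -> optimal path(s) only
  expect_equal(length(suboptimal_paths(tri, "v01", "v03", delta = 0)$paths), 1L)

  # disconnected pair -> no-path error
  disc <- edges_to_network(4, rbind(c(1, 2, 1), c(3, 4, 1)))
  expect_error(suboptimal_paths(disc, "v01", "v03"), "no path")

  # edge usage on the triangle case
  use <- edge_path_usage(ps)
  expect_equal(sort(use$count), c(1L, 1L, 1L))
  expect_equal(nrow(use), 3L)

  for (seed in 1:8) {
    g <- random_connected_graph(sample(6:10, 1), 0.35, seed = 100 + seed)
    labs <- g$network$nodes
    st <- sort(sample(g$n, 2))
    d <- oracle_distances(g$n, g$edges)
    l_opt <- d[st[1], st[2]]
    for (delta in c(0, 0.5 * l_opt)) {
      oracle <- oracle_simple_paths(g$n, g$edges, st[1], st[2], l_opt + delta)
      got <- suboptimal_paths(g$network, labs[st[1]], labs[st[2]],
                              delta = delta, max_paths = 10000L)
      expect_equal(length(got$paths), length(oracle$paths))
      expect_equal(got$lengths, sort(oracle$lengths), tolerance = 1e-9)
      okey <- sort(vapply(oracle$paths, function(p)
        paste(labs[p], collapse = "-"), character(1)))
      gkey <- sort(vapply(got$paths, paste, character(1), collapse = "-"))
      expect_identical(gkey, okey)
    }
  }
})

test_that("suboptimal path sets are nested in delta", {
  g <- random_connected_graph(9, 0.35, seed = 42)
  labs <- g$network$nodes
  p1 <- suboptimal_paths(g$network, labs[1], labs[9], delta = 0.3)
  p2 <- suboptimal_paths(g$network, labs[1], labs[9], delta = 0.9)
  k1 <- vapply(p1$paths, paste, character(1), collapse = "-")
  k2 <- vapply(p2$paths, paste, character(1), collapse = "-")
  expect_true(all(k1 %in% k2))
})

test_that("critical nodes sit on maximum-betweenness community bridges", {
  tc <- two_clique_bridge()
  part <- girvan_newman(tc)
  expect_equal(critical_nodes(tc, part), c("v03", "v04"))

  clique <- edges_to_network(5, cbind(t(combn(5, 2)), 1))
  expect_equal(critical_nodes(clique, girvan_newman(clique)), character(0))

  # planted 3-community chain: each inter-community bridge contributes
  # exactly its two endpoints
  g <- generate_planted_graph(3, 4, seed = 9)
  part3 <- girvan_newman(g$network)
  crit <- critical_nodes(g$network, part3)
  bridge_ends <- sort(unique(g$network$nodes[unlist(g$bridge_edges)]))
  expect_equal(crit, bridge_ends)
})

test_that("edge_path_usage counts every edge of every path once", {
  g <- random_connected_graph(8, 0.4, seed = 77)
  labs <- g$network$nodes
  ps <- suboptimal_paths(g$network, labs[1], labs[8], delta = 0.8)
  use <- edge_path_usage(ps)
  expect_equal(sum(use$count), sum(lengths(ps$paths) - 1L))
  single <- suboptimal_paths(g$network, labs[1], labs[8], delta = 0)
  u1 <- edge_path_usage(single)
  expect_true(all(u1$count == 1L))
  expect_equal(nrow(u1), length(single$paths[[1]]) - 1L)
})
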