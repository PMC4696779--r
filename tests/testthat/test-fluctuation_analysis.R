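# Superposition, RMSD/RMSF, B-factor conversion, distance statistics.

test_that("kabsch_superpose recovers exact rigid transforms", {
  set.seed(1)
  P <- matrix(rnorm(30), 10)
  fit0 <- kabsch_superpose(P, P)
  expect_equal(fit0$rmsd, 0, tolerance = 1e-10)
  expect_equal(fit0$rotation, diag(3), tolerance = 1e-10)

  R <- corrnet:::rotation_about_axis(c(1, 2, 3), 0.7)
  Q <- sweep(P %*% t(R), 2, c(5, -2, 9), "+")
  fit <- kabsch_superpose(Q, P)
  expect_lt(fit$rmsd, 1e-8)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-10)

  expect_error(kabsch_superpose(P[1:2, ], P[1:2, ]), "underdetermined")
  line <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(kabsch_superpose(line, line), "underdetermined")
})

test_that("kabsch RMSD matches a derivative-free minimizer over rotations", {
  # unit square vs stretched square (no exact superposition exists)
  sq <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  stretched <- sq %*% diag(c(2, 1, 1))
  fit <- kabsch_superpose(sq, stretched)
  # independent oracle: optimize RMSD over Euler angles + translation
  obj <- function(par) {
    Rz <- corrnet:::rotation_about_axis(c(0, 0, 1), par[1])
    Ry <- corrnet:::rotation_about_axis(c(0, 1, 0), par[2])
    Rx <- corrnet:::rotation_about_axis(c(1, 0, 0), par[3])
    moved <- sweep(sq %*% t(Rx %*% Ry %*% Rz), 2, par[4:6], "+")
    sqrt(mean(rowSums((moved - stretched)^2)))
  }
  best <- Inf
  for (s in 1:8) {
    set.seed(s)
    o <- optim(runif(6, -1, 1), obj, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-14))
    best <- min(best, o$value)
  }
  expect_equal(fit$rmsd, best, tolerance = 1e-6)
})

test_that("align_trajectory removes rigid motion and never raises variance", {
  base <- corrnet:::grid_cluster(10)
  f <- 20L
  set.seed(7)
  frames <- lapply(seq_len(f), function(i) {
    R <- corrnet:::rotation_about_axis(rnorm(3), runif(1, 0, pi))
    sweep(base %*% t(R), 2, rnorm(3, 0, 5), "+")
  })
  xyz <- do.call(rbind, lapply(frames, function(m) as.vector(t(m))))
  traj <- md_trajectory(xyz, corrnet:::synthetic_topology(base))
  al <- align_trajectory(traj)
  expect_equal(max(rmsd_series(al, reference = 1, align = FALSE)), 0,
               tolerance = 1e-8)

  # already-aligned static trajectory unchanged
  st <- static_traj(base, f = 4L)
  expect_equal(align_trajectory(st)$xyz, st$xyz, tolerance = 1e-9,
               ignore_attr = TRUE)

  # variance is non-increasing under alignment on a noisy fixture
  tl <- generate_two_lobe_trajectory(two_lobe_spec(n_frames = 100, seed = 3))
  v0 <- sum(apply(tl$xyz, 2, var))
  v1 <- sum(apply(align_trajectory(tl)$xyz, 2, var))
  expect_lte(v1, v0 + 1e-9)
})

test_that("rmsd_series matches the isotropic-noise closed form", {
  mu <- corrnet:::grid_cluster(60)
  sigma <- 0.4
  tr <- generate_gaussian_ensemble(gaussian_ensemble_spec(
    mu, diag(180) * sigma^2, n_frames = 500, seed = 13))
  r <- rmsd_series(tr, reference = mu, align = FALSE)
  expect_equal(mean(r), sigma * sqrt(3), tolerance = 0.02)
  expect_equal(rmsd_series(tr, reference = 1, align = FALSE)[1], 0)
  # invariance under a global rigid transform when alignment is on
  R <- corrnet:::rotation_about_axis(c(1, 1, 0), 1.1)
  moved_xyz <- t(apply(tr$xyz, 1, function(v) {
    as.vector(t(sweep(matrix(v, ncol = 3, byrow = TRUE) %*% t(R), 2, c(3, 4, 5), "+")))
  }))
  moved <- md_trajectory(moved_xyz, tr$topology)
  expect_equal(rmsd_series(moved, reference = mu, align = TRUE),
               rmsd_series(tr, reference = mu, align = TRUE), tolerance = 1e-8)
})

test_that("rmsf_profile: closed forms and variance conservation", {
  base <- corrnet:::grid_cluster(5)
  st <- static_traj(base)
  expect_equal(rmsf_profile(st, aligned = TRUE)$rmsf, rep(0, 5))

  # one node oscillating +-a along one axis -> RMSF = a
  a <- 0.8
  xyz <- matrix(rep(as.vector(t(base)), 10), 10, byrow = TRUE)
  xyz[, 4] <- xyz[, 4] + rep(c(-a, a), 5)
  tr <- md_trajectory(xyz, corrnet:::synthetic_topology(base))
  prof <- rmsf_profile(tr, aligned = TRUE)
  expect_equal(prof$rmsf[2], a, tolerance = 1e-12)
  expect_equal(prof$rmsf[-2], rep(0, 4))

  # unaligned input without the flag warns and aligns
  expect_warning(rmsf_profile(tr), "not flagged as aligned")

  # Gaussian ensemble with per-coordinate variance v -> RMSF ~ sqrt(3v);
  # conservation: sum RMSF^2 = total per-node variance (1/F convention)
  v <- 0.09
  mu <- corrnet:::grid_cluster(30)
  g <- generate_gaussian_ensemble(gaussian_ensemble_spec(
    mu, diag(90) * v, n_frames = 2000, seed = 17))
  pg <- rmsf_profile(g, aligned = TRUE)
  expect_equal(mean(pg$rmsf), sqrt(3 * v), tolerance = 0.02)
  D <- sweep(g$xyz, 2, colMeans(g$xyz))
  expect_equal(sum(pg$rmsf^2), sum(colMeans(D^2)), tolerance = 1e-10)
})

test_that("B-factor conversion closed forms and round trip", {
  expect_equal(bfactor_to_rmsf(0), 0)
  expect_equal(bfactor_to_rmsf(8 * pi^2 / 3), 1.0)
  r <- c(0.3, 1.2, 2.5)
  expect_equal(bfactor_to_rmsf(rmsf_to_bfactor(r)), r, tolerance = 1e-12)
  expect_error(bfactor_to_rmsf(-1), "non-negative")
})

test_that("distance series and deviation maps match brute force", {
  base <- corrnet:::grid_cluster(6)
  base[1, ] <- c(0, 0, 0); base[2, ] <- c(10, 0, 0)
  st <- static_traj(base)
  ds <- distance_series(st, node_a = "ALA1", node_b = "ALA2")
  expect_equal(ds$values, rep(10, 5))
  expect_error(distance_series(st, node_a = "ALA1", node_b = "NOPE"),
               "unknown node label")

  # single pair oscillating with known sigma
  f <- 400L
  xyz <- matrix(rep(as.vector(t(base)), f), f, byrow = TRUE)
  set.seed(5)
  osc <- rnorm(f, 0, 0.5)
  xyz[, 4] <- xyz[, 4] + osc   # node 2 moves along x only
  tr <- md_trajectory(xyz, corrnet:::synthetic_topology(base))
  dm <- distance_deviation_map(tr)
  expect_equal(dm["ALA1", "ALA2"], sd(10 + osc), tolerance = 1e-9)
  expect_equal(diag(dm), rep(0, 6), ignore_attr = TRUE)
  expect_equal(dm, t(dm), ignore_attr = TRUE)

  # brute-force agreement on a random trajectory
  set.seed(11)
  rxyz <- matrix(rnorm(20 * 12, sd = 2), 20)
  rtr <- md_trajectory(sweep(rxyz, 2, rep(as.vector(t(corrnet:::grid_cluster(4))), each = 1), "+"),
                       corrnet:::synthetic_topology(corrnet:::grid_cluster(4)))
  dm2 <- distance_deviation_map(rtr)
  for (i in 1:3) for (j in (i + 1):4) {
    dij <- vapply(1:20, function(f) {
      co <- traj_frame(rtr, f); sqrt(sum((co[i, ] - co[j, ])^2))
    }, numeric(1))
    expect_equal(dm2[i, j], sd(dij), tolerance = 1e-9)
  }

  # deviation maps are invariant under global rigid motion (no alignment)
  R <- corrnet:::rotation_about_axis(c(0, 1, 1), 0.9)
  moved_xyz <- t(apply(rtr$xyz, 1, function(v)
    as.vector(t(sweep(matrix(v, ncol = 3, byrow = TRUE) %*% t(R), 2, c(1, 2, 3), "+")))))
  expect_equal(distance_deviation_map(md_trajectory(moved_xyz, rtr$topology)),
               dm2, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("block_deviation_ratio arithmetic and brute-force agreement", {
  m <- matrix(1, 6, 6); diag(m) <- 0
  dimnames(m) <- list(paste0("ALA", 1:6), paste0("ALA", 1:6))
  class(m) <- c("distance_deviation_map", class(m))
  expect_equal(block_deviation_ratio(m, paste0("ALA", 1:3), paste0("ALA", 4:6)), 1)
  m2 <- m
  m2[1:3, 4:6] <- 2; m2[4:6, 1:3] <- 2
  bg <- mean(m2[upper.tri(m2)])
  expect_equal(block_deviation_ratio(m2, paste0("ALA", 1:3), paste0("ALA", 4:6)),
               2 / bg)
  expect_error(block_deviation_ratio(m, character(0), "ALA1"), "non-empty")
  expect_error(block_deviation_ratio(m, "ALA1", "ALA1"), "disjoint")

  set.seed(3)
  r <- matrix(runif(64), 8); r <- (r + t(r)) / 2; diag(r) <- 0
  dimnames(r) <- list(paste0("ALA", 1:8), paste0("ALA", 1:8))
  class(r) <- c("distance_deviation_map", class(r))
  sa <- paste0("ALA", c(1, 3, 5)); sb <- paste0("ALA", c(2, 6))
  # two-loop brute force
  num <- 0; cnt <- 0
  for (i in c(1, 3, 5)) for (j in c(2, 6)) { num <- num + r[i, j]; cnt <- cnt + 1 }
  den <- 0; dc <- 0
  for (i in 1:7) for (j in (i + 1):8) { den <- den + r[i, j]; dc <- dc + 1 }
  expect_equal(block_deviation_ratio(r, sa, sb), (num / cnt) / (den / dc),
               tolerance = 1e-12)
})
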