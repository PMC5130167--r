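test_that("triangle sampling is contained, centered and area-uniform", {
  set.seed(21)
  A <- c(0, 0, 0); B <- c(2, 0, 0); C <- c(0.5, 1.5, 0)
  X <- sample_uniform_triangle(1e5, A, B, C)
  # barycentric containment
  M <- rbind(B - A, C - A)
  uv <- t(qr.solve(t(M[, 1:2]), t(X[, 1:2] - matrix(A[1:2], nrow(X), 2,
                                                    byrow = TRUE))))
  expect_true(all(uv >= -1e-12 & rowSums(uv) <= 1 + 1e-12))
  # mean at the centroid within 3 standard errors
  ctr <- (A + B + C) / 3
  se <- apply(X, 2, stats::sd) / sqrt(nrow(X))
  expect_true(all(abs(colMeans(X) - ctr) < 3 * pmax(se, 1e-12)))
  # occupancy of the 4 congruent midpoint subtriangles is uniform
  mid <- function(p, q) (p + q) / 2
  corner <- function(P1, P2, P3) {
    M2 <- rbind(P2 - P1, P3 - P1)
    w <- t(qr.solve(t(M2[, 1:2]), t(X[, 1:2] - matrix(P1[1:2], nrow(X), 2,
                                                      byrow = TRUE))))
    mean(w[, 1] >= 0 & w[, 2] >= 0 & rowSums(w) <= 1)
  }
  occ <- c(corner(A, mid(A, B), mid(A, C)),
           corner(B, mid(A, B), mid(B, C)),
           corner(C, mid(A, C), mid(B, C)))
  chisq <- sum((occ - 0.25)^2 / (0.25 / nrow(X) * 0.75)) # ~ chi2, loose
  expect_true(all(abs(occ - 0.25) < 0.01))
  expect_error(sample_uniform_triangle(5, A, B, 2 * B - A), "degenerate")
})

test_that("ball sampling is contained with the right radial profile", {
  set.seed(22)
  ctr <- c(1, -2, 3)
  X <- sample_uniform_ball(1e5, ctr, 2)
  d <- sqrt(rowSums((X - matrix(ctr, nrow(X), 3, byrow = TRUE))^2))
  expect_lte(max(d), 2)
  se <- apply(X, 2, stats::sd) / sqrt(nrow(X))
  expect_true(all(abs(colMeans(X) - ctr) < 3 * se))
  # volume ratio: fraction within half the radius is 1/8
  expect_lt(abs(mean(d <= 1) - 1 / 8), 0.004)  # ~4 Monte-Carlo SEs
  expect_error(sample_uniform_ball(5, ctr, 0), "positive")
})

test_that("all schemes preserve topology, tips and source exactly", {
  net <- generate_tree(synthetic_spec(depth = 5L, seed = 23L,
                                      tortuosity_factor = 1.1))
  v <- net$vessels
  tip_rows <- v$n_children == 0L
  for (scheme in c("local", "intermediate1", "intermediate2", "global")) {
    sim <- simulate_network(net, scheme, seed = 5L, realization = 2L)
    sv <- sim$vessels
    expect_identical(sv$vessel_id, v$vessel_id)
    expect_identical(sv$parent_id, v$parent_id)
    expect_identical(sv$n_children, v$n_children)
    expect_identical(sv[tip_rows, c("x_dist", "y_dist", "z_dist")],
                     v[tip_rows, c("x_dist", "y_dist", "z_dist")])
    root <- which(is.na(v$parent_id))
    expect_identical(sv[root, c("x_prox", "y_prox", "z_prox")],
                     v[root, c("x_prox", "y_prox", "z_prox")])
    expect_silent(validate_network(sim))
    # determinism under the seed contract
    sim_b <- simulate_network(net, scheme, seed = 5L, realization = 2L)
    expect_identical(sim$vessels, sim_b$vessels)
    sim_c <- simulate_network(net, scheme, seed = 5L, realization = 3L)
    expect_false(identical(sim$vessels, sim_c$vessels))
  }
})

test_that("local scheme keeps every junction in its original triangle", {
  net <- generate_tree(synthetic_spec(depth = 5L, seed = 24L))
  jf0 <- junction_frame(net)
  sim <- simulate_local(net, seed = 6L)
  jf1 <- junction_frame(sim)
  for (i in seq_len(nrow(jf0))) {
    V <- rbind(c(jf0$v0x[i], jf0$v0y[i], jf0$v0z[i]),
               c(jf0$v1x[i], jf0$v1y[i], jf0$v1z[i]),
               c(jf0$v2x[i], jf0$v2y[i], jf0$v2z[i]))
    J <- c(jf1$jx[i], jf1$jy[i], jf1$jz[i])
    # barycentric coordinates of J w.r.t. the original triangle
    A <- cbind(V[2, ] - V[1, ], V[3, ] - V[1, ])   # 3 x 2
    w <- drop(solve(crossprod(A), crossprod(A, J - V[1, ])))
    resid <- sqrt(sum((V[1, ] + A %*% w - J)^2))
    expect_lt(resid, 1e-9)                          # in the triangle's plane
    expect_true(all(w >= -1e-12) && sum(w) <= 1 + 1e-12)
  }
})

test_that("intermediate1 junctions are coplanar with their sampling triangle", {
  net <- generate_tree(synthetic_spec(depth = 5L, seed = 25L))
  struct <- vascbranch:::.sim_structure(net)
  set.seed(1)
  J <- vascbranch:::.simulate_coords(struct, "intermediate1")
  V0u <- attr(J, "V0_used")
  for (i in seq_len(nrow(J))) {
    n <- pracma_cross(struct$V1o[i, ] - V0u[i, ],
                      struct$V2o[i, ] - V0u[i, ])
    n <- n / sqrt(sum(n^2))
    expect_lt(abs(sum((J[i, ] - V0u[i, ]) * n)), 1e-9)
  }
  # in the final network planarity is small but generally nonzero
  sim <- simulate_intermediate1(net, seed = 2L)
  g <- junction_geometry(sim)
  expect_lt(stats::median(g$planarity), 0.2)
})

test_that("intermediate2 ignores V0 and frees junctions from the plane", {
  net <- generate_tree(synthetic_spec(depth = 5L, seed = 26L))
  sim <- simulate_intermediate2(net, seed = 3L)
  g <- junction_geometry(sim)
  expect_gt(mean(g$planarity > 1e-6), 0.5)  # 3-D freedom
})

test_that("global scheme stays inside the enclosing sphere of the data", {
  net <- generate_tree(synthetic_spec(depth = 5L, seed = 27L))
  struct <- vascbranch:::.sim_structure(net)
  # the sphere contains every original node
  v <- net$vessels
  nodes <- rbind(as.matrix(v[, c("x_dist", "y_dist", "z_dist")]),
                 matrix(unlist(v[is.na(v$parent_id),
                                 c("x_prox", "y_prox", "z_prox")]), 1))
  d <- sqrt(rowSums((nodes - matrix(struct$sphere$center, nrow(nodes), 3,
                                    byrow = TRUE))^2))
  expect_lte(max(d), struct$sphere$radius + 1e-9)
  sim <- simulate_global(net, seed = 4L)
  jf <- junction_frame(sim)
  dj <- sqrt((jf$jx - struct$sphere$center[1])^2 +
             (jf$jy - struct$sphere$center[2])^2 +
             (jf$jz - struct$sphere$center[3])^2)
  expect_lte(max(dj), struct$sphere$radius + 1e-9)
})

test_that("ensembles pool measurements and order lambda_l by constraint scale", {
  net <- generate_tree(synthetic_spec(depth = 3L, seed = 28L))
  ens <- run_ensemble(net, "local", n_realizations = 100L, seed = 9L)
  expect_identical(nrow(ens$measurements), 700L)  # 7 junctions x 100
  expect_identical(nrow(ens$per_realization), 100L)
  expect_true(all(ens$measurements$lambda_l > 0 &
                    ens$measurements$lambda_l <= 1))
  # local-scheme lambda_l is broad with a mean in the uniform-like range
  expect_gt(mean(ens$measurements$lambda_l), 0.45)
  expect_lt(mean(ens$measurements$lambda_l), 0.75)
  # reproducibility of the whole ensemble under the master seed
  ens_b <- run_ensemble(net, "local", n_realizations = 100L, seed = 9L)
  expect_identical(ens$measurements, ens_b$measurements)
})
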