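test_that("vessel impedance follows the Poiseuille r^-4 law", {
  expect_equal(vessel_impedance(1, 1, impedance_model("physical", mu = pi / 8)),
               1)
  expect_equal(vessel_impedance(2, 1) / vessel_impedance(1, 1), 1 / 16)
  mu <- 3.5e-3
  expect_equal(vessel_impedance(1e-3, 1e-2, impedance_model("physical", mu)),
               8 * mu * 1e-2 / (pi * 1e-12))
  expect_error(vessel_impedance(0, 1), "positive")
  expect_error(impedance_model("physical"), "mu")
})

test_that("equivalent impedance combines series and parallel correctly", {
  expect_equal(junction_equivalent_impedance(1, 2, 2), 2)
  # one daughter blocked: series of parent and the remaining daughter
  expect_equal(junction_equivalent_impedance(1, 1e12, 3), 4, tolerance = 1e-9)
  expect_equal(junction_equivalent_impedance(0, 0, 0), 0)
  # brute-force two-branch hydraulic solve: equal pressure drop across the
  # daughters, flows add; Z_eq = dp_total / Q_total
  set.seed(12)
  for (i in 1:30) {
    Z <- stats::runif(3, 0.1, 5)
    Q <- 1
    dp_d <- Q / (1 / Z[2] + 1 / Z[3])   # daughters share the drop
    dp <- Q * Z[1] + dp_d
    expect_equal(junction_equivalent_impedance(Z[1], Z[2], Z[3]), dp / Q)
  }
  # monotonicity: raising any one impedance never lowers Z_eq
  for (i in 1:30) {
    Z <- stats::runif(3, 0.1, 5)
    base <- junction_equivalent_impedance(Z[1], Z[2], Z[3])
    expect_gte(junction_equivalent_impedance(Z[1] + 1, Z[2], Z[3]), base)
    expect_gte(junction_equivalent_impedance(Z[1], Z[2] + 1, Z[3]), base)
    expect_gte(junction_equivalent_impedance(Z[1], Z[2], Z[3] + 1), base)
  }
})

test_that("PC-0 equilateral hand values: vertex V0 wins at h*a/2", {
  V0 <- c(0, 0); V1 <- c(1, 0); V2 <- c(0.5, sqrt(3) / 2)
  res <- pc0_minimize(V0, V1, V2, 1, 1, 1)
  expect_identical(res$collapse_vertex, "V0")
  expect_equal(res$Z_eq, 0.5, tolerance = 1e-9)
  expect_equal(unname(res$vertex_costs), c(0.5, 1, 1), tolerance = 1e-12)
  expect_true(res$interior_exceeds)
  # a very wide daughter 1 makes its path cheap; the costly path collapses
  res2 <- pc0_minimize(V0, V1, V2, 1, 10, 1)
  expect_false(is.na(res2$collapse_vertex))
  expect_identical(res2$collapse_vertex,
                   paste0("V", which.min(res2$vertex_costs) - 1L))
})

test_that("subtree impedance recursion matches closed forms", {
  # single junction: parent plus two parallel leaf subtrees
  net <- toy_network()
  v <- net$vessels
  Z <- vessel_impedance(v$radius, v$length)
  c_cap <- 2
  manual <- Z[1] + 1 / (1 / (Z[2] + c_cap) + 1 / (Z[3] + c_cap))
  expect_equal(downstream_equivalent_impedance(net, "p", c_cap = c_cap),
               manual)
  expect_equal(downstream_equivalent_impedance(net, "a", c_cap = c_cap),
               Z[2] + c_cap)
  expect_error(downstream_equivalent_impedance(net, "p", c_cap = 0), "c_cap")
  # symmetric binary tree: closed-form geometric recursion
  spec <- synthetic_spec(depth = 3L, seed = 1L, split_sd = 0,
                         length_ratio_range = c(0.7, 0.7))
  net3 <- generate_tree(spec)
  # independent symbolic recursion level by level (perfectly symmetric tree:
  # all vessels at one depth share radius and length)
  v3 <- net3$vessels
  depth <- integer(nrow(v3))
  for (i in seq_len(nrow(v3))) {
    d <- 0L; j <- i
    while (!is.na(v3$parent_id[j])) { j <- match(v3$parent_id[j], v3$vessel_id); d <- d + 1L }
    depth[i] <- d
  }
  Zv <- vessel_impedance(v3$radius, v3$length)
  zl <- Zv[match(3L, depth)] + 1          # c_cap = 1
  for (d in 2:0) {
    idx <- which(depth == d)[1L]
    zl <- Zv[idx] + zl / 2
    if (d == 0L) break
  }
  expect_equal(downstream_equivalent_impedance(net3, net3$root_id, c_cap = 1),
               zl, tolerance = 1e-9)
})

test_that("PC-1 rescaled costs diminish the daughters", {
  expect_equal(pc1_effective_costs(1, 1, 1), c(1 / 4, 1 / 4))
  expect_equal(pc1_effective_costs(1, 1, 0), c(1, 0))
  expect_equal(pc1_effective_costs(1, 1, 2), c(1 / 9, 4 / 9))
  expect_error(pc1_effective_costs(1, 1, -1), "non-negative")
  for (k in c(0.1, 0.5, 2, 10)) {
    e <- pc1_effective_costs(1.3, 0.7, k)
    expect_lt(e[1], 1.3)
    expect_lt(e[2], 0.7)
  }
})

test_that("PC-1 analytic labels match the exact numeric minimizer", {
  V0 <- c(0, 0); V1 <- c(1, 0); V2 <- c(0.5, sqrt(3) / 2)
  # equal radii, large symmetric downstream: parent cost dominates the
  # quartered daughter costs, so both routes collapse to the parent endpoint
  expect_identical(pc1_classify(V0, V1, V2, 1, 1, 1, 10, 10),
                   "collapse_to_parent_endpoint")
  expect_identical(pc1_numeric_solution(V0, V1, V2, 1, 1, 1, 10, 10)$label,
                   "collapse_to_parent_endpoint")
  # cheap parent (wide r0) with asymmetric downstream: genuine branching
  expect_identical(pc1_classify(V0, V1, V2, 1.2, 1, 1, 10, 20),
                   "no_collapse")
  expect_identical(pc1_numeric_solution(V0, V1, V2, 1.2, 1, 1, 10, 20)$label,
                   "no_collapse")
  # c1 = c2 = 0 routes to PC-0: always a collapse
  lab0 <- pc1_classify(V0, V1, V2, 1.2, 1, 1, 0, 0)
  num0 <- pc1_numeric_solution(V0, V1, V2, 1.2, 1, 1, 0, 0)
  expect_identical(lab0, num0$label)
  expect_true(lab0 %in% c("collapse_to_parent_endpoint",
                          "collapse_to_daughter_endpoint"))
  # k -> 0 limit: daughter-2 cost vanishes, two-vessel geometry decides
  expect_true(pc1_classify(V0, V1, V2, 1, 1, 1, 0, 5) %in%
                c("collapse_to_parent_endpoint",
                  "collapse_to_daughter_endpoint"))
})

test_that("PC-1 boundary set is symmetric under k <-> 1/k for symmetric junctions", {
  V0 <- c(0, 0); V1 <- c(1, 0); V2 <- c(0.5, sqrt(3) / 2)
  bl <- pc1_boundary_lines(V0, V1, V2, 1.2, 1, 1)
  expect_gt(nrow(bl), 0L)
  ks <- sort(bl$k_star)
  expect_equal(sort(log(ks)), sort(-log(ks)), tolerance = 1e-6)
  # each boundary passes through the origin of the (c1,c2)-plane by
  # construction: the label along a ray c1 = k c2 is constant
  k <- ks[1] * 1.05
  labs <- vapply(c(5, 10, 20), function(c2) {
    pc1_classify(V0, V1, V2, 1.2, 1, 1, k * c2, c2)
  }, character(1))
  expect_length(unique(labs), 1L)
})

test_that("each boundary k* marks an analytic label flip along its ray", {
  V0 <- c(0, 0); V1 <- c(0.8, 0); V2 <- c(0.4, sqrt(1 - 0.16))
  bl <- pc1_boundary_lines(V0, V1, V2, 1.1, 0.85, 1)
  expect_gt(nrow(bl), 0L)
  lab_at <- function(k) pc1_classify(V0, V1, V2, 1.1, 0.85, 1,
                                     k * 1000, 1000)
  flips <- vapply(bl$k_star, function(ks) {
    lab_at(ks * (1 - 1e-4)) != lab_at(ks * (1 + 1e-4))
  }, logical(1))
  # every analytic label change along the ray coincides with a listed k*
  kgrid <- exp(seq(log(0.01), log(100), length.out = 400))
  labs <- vapply(kgrid, lab_at, character(1))
  changes <- which(labs[-1] != labs[-length(labs)])
  for (ch in changes) {
    expect_true(any(bl$k_star >= kgrid[ch] - 1e-9 &
                    bl$k_star <= kgrid[ch + 1] + 1e-9))
  }
  expect_true(any(flips))
})

test_that("PC-1 converges to the rescaled Fermat solution as c grows", {
  V0 <- c(0, 0); V1 <- c(1, 0); V2 <- c(0.5, sqrt(3) / 2)
  r <- c(1.2, 1, 1)
  h <- 1 / r^4
  k <- 1.9  # inside the no-collapse wedge for this geometry
  heff <- c(h[1], pc1_effective_costs(h[2], h[3], k))
  target <- numeric_fermat_oracle(V0, V1, V2, heff, grid_n = 120L)$J
  dists <- vapply(c(20, 100, 500), function(c2) {
    J <- pc1_numeric_solution(V0, V1, V2, r[1], r[2], r[3],
                              k * c2, c2)$J
    sqrt(sum((J - target)^2))
  }, numeric(1))
  expect_lt(dists[3], 0.01)
  expect_true(all(diff(dists) < 1e-6))  # non-increasing toward the limit
})

test_that("degenerate single-cell scan reduces to the point classification", {
  V0 <- c(0, 0); V1 <- c(1, 0); V2 <- c(0.5, sqrt(3) / 2)
  ps <- pc1_plane_scan(V0, V1, V2, 1.2, 1, 1, c_range = c(15, 15),
                       resolution = 2L, grid_n = 60L)
  expect_true(all(ps$grid$analytic_label ==
                    pc1_classify(V0, V1, V2, 1.2, 1, 1, 15, 15)))
  expect_true(all(ps$grid$agree == (ps$grid$analytic_label ==
                                      ps$grid$numeric_label)))
})
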