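test_that("cost weights follow the mode and scale homogeneously", {
  expect_equal(as.numeric(cost_weights(1, 1, 1, "surface_area")), c(1, 1, 1))
  expect_equal(as.numeric(cost_weights(2, 1, 1, "volume")), c(4, 1, 1))
  expect_error(cost_weights(0, 1, 1), "positive")
  set.seed(2)
  tri <- random_triangle2d()
  for (i in 1:20) {
    r <- stats::runif(3, 0.5, 2)
    cc <- stats::runif(1, 0.5, 3)
    for (mode in c("surface_area", "volume")) {
      h1 <- cost_weights(r[1], r[2], r[3], mode)
      h2 <- cost_weights(cc * r[1], cc * r[2], cc * r[3], mode)
      expect_equal(as.numeric(h2) / as.numeric(h1),
                   rep(if (mode == "surface_area") cc else cc^2, 3))
      expect_identical(classify_junction(h1, tri[1, ], tri[2, ], tri[3, ]),
                       classify_junction(h2, tri[1, ], tri[2, ], tri[3, ]))
    }
  }
})

test_that("closed-form angles: worked cosine, symmetry, and angle sum", {
  # parent cost dominating: cosine beyond 1, angle undefined
  cf <- closed_form_angles(c(2.1, 1, 1))
  expect_equal(cf$cosines[["cos_theta0"]], 1.205)
  expect_false(cf$defined)
  expect_null(cf$angles)
  # classic unweighted Fermat point
  cf1 <- closed_form_angles(c(1, 1, 1))
  expect_equal(unname(cf1$angles), rep(2 * pi / 3, 3))
  # direct evaluation
  cf2 <- closed_form_angles(c(1.5, 1, 1))
  expect_equal(cf2$cosines[["cos_theta0"]], 0.125)
  expect_equal(cf2$angles[["theta0"]], acos(0.125), tolerance = 1e-9)
  expect_equal(sum(cf2$angles), 2 * pi, tolerance = 1e-9)
  # whenever defined, the three angles close up around the junction
  set.seed(5)
  n_defined <- 0L
  for (i in 1:200) {
    h <- stats::runif(3, 0.3, 2)
    cf <- closed_form_angles(h)
    if (cf$defined) {
      n_defined <- n_defined + 1L
      expect_equal(sum(cf$angles), 2 * pi, tolerance = 1e-9)
    }
  }
  expect_gt(n_defined, 50L)
})

test_that("degeneracy classification follows cost dominance and the triangle condition", {
  tri <- rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2))
  expect_identical(classify_junction(c(2.1, 1, 1), tri[1, ], tri[2, ],
                                     tri[3, ]), "vertex_V0")
  expect_identical(classify_junction(c(1, 1, 1), tri[1, ], tri[2, ],
                                     tri[3, ]), "interior")
  # obtuse (> 120 degrees) corner at V0 forces collapse despite equal costs
  expect_identical(classify_junction(c(1, 1, 1), c(0, 0), c(-1, 0.1),
                                     c(1, 0.1)), "vertex_V0")
  o <- numeric_fermat_oracle(c(0, 0), c(-1, 0.1), c(1, 0.1), c(1, 1, 1))
  expect_identical(o$at_vertex, 1L)
  expect_error(classify_junction(c(1, 1, 1), c(0, 0), c(1, 0), c(2, 0)),
               "degenerate")
})

test_that("classification is invariant under rigid motions of the triangle", {
  set.seed(6)
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  for (i in 1:30) {
    V <- random_triangle2d()
    h <- stats::runif(3, 0.3, 2)
    base <- classify_junction(h, V[1, ], V[2, ], V[3, ])
    Vr <- V %*% R + matrix(c(3, -1), 3, 2, byrow = TRUE)
    expect_identical(classify_junction(h, Vr[1, ], Vr[2, ], Vr[3, ]), base)
    expect_identical(classify_junction(h, 2.5 * V[1, ], 2.5 * V[2, ],
                                       2.5 * V[3, ]), base)
    expect_identical(classify_junction(3 * h, V[1, ], V[2, ], V[3, ]), base)
  }
})

test_that("interior solver matches the closed form and the grid oracle", {
  # equilateral, equal weights: centroid, full symmetry
  j <- list(V0 = c(0, 0, 0), V1 = c(1, 0, 0), V2 = c(0.5, sqrt(3) / 2, 0),
            r = c(1, 1, 1))
  sol <- solve_optimal_junction(j, "surface_area")
  expect_identical(sol$classification, "interior")
  expect_equal(sol$J_opt, c(0.5, sqrt(3) / 6, 0), tolerance = 1e-8)
  expect_equal(unname(sol$asymmetry), c(1, 1), tolerance = 1e-8)
  # cost dominance example: collapse on V0 with l0 = 0
  jd <- j; jd$r <- c(2.1, 1, 1)
  sold <- solve_optimal_junction(jd, "surface_area")
  expect_identical(sold$classification, "vertex_V0")
  expect_equal(sold$lengths[["l0"]], 0)
  expect_null(sold$angles)
  # random interior instances vs closed form and refined oracle
  set.seed(7)
  n_int <- 0L
  while (n_int < 60L) {
    V <- random_triangle2d()
    r <- stats::runif(3, 0.6, 1.4)
    mode <- sample(c("surface_area", "volume"), 1)
    jj <- list(V0 = c(V[1, ], 0), V1 = c(V[2, ], 0), V2 = c(V[3, ], 0), r = r)
    sol <- solve_optimal_junction(jj, mode)
    if (sol$classification != "interior") next
    n_int <- n_int + 1L
    cf <- closed_form_angles(cost_weights(r[1], r[2], r[3], mode))
    expect_equal(unname(sol$angles), unname(cf$angles), tolerance = 1e-6)
    o <- numeric_fermat_oracle(jj$V0, jj$V1, jj$V2,
                               cost_weights(r[1], r[2], r[3], mode))
    expect_equal(sol$cost_value, o$cost, tolerance = 1e-10)
  }
})

test_that("solver and oracle classifications agree on random instances", {
  set.seed(8)
  n <- 300L
  mismatch <- 0L
  for (i in seq_len(n)) {
    V <- random_triangle2d()
    r <- stats::runif(3, 0.4, 1.8)
    mode <- sample(c("surface_area", "volume"), 1)
    jj <- list(V0 = c(V[1, ], 0), V1 = c(V[2, ], 0), V2 = c(V[3, ], 0), r = r)
    sol <- solve_optimal_junction(jj, mode)
    o <- numeric_fermat_oracle(jj$V0, jj$V1, jj$V2,
                               cost_weights(r[1], r[2], r[3], mode),
                               grid_n = 60L)
    agree <- (sol$classification == "interior" && o$at_vertex == 0L) ||
      (sol$classification == paste0("vertex_V", o$at_vertex - 1L))
    if (!agree) mismatch <- mismatch + 1L
  }
  expect_lte(mismatch / n, 0.01)
})

test_that("non-planar junctions are optimized in their endpoint plane", {
  set.seed(9)
  j <- random_junction()
  sol <- solve_optimal_junction(j, "volume")
  # optimal junction lies in the plane of V0, V1, V2
  n <- pracma_cross(j$V1 - j$V0, j$V2 - j$V0)
  n <- n / sqrt(sum(n^2))
  expect_lt(abs(sum((sol$J_opt - j$V0) * n)), 1e-8)
})

test_that("Murray exponent solves the radius relation by bisection", {
  expect_equal(murray_exponent(2^(1 / 3), 1, 1)$d, 3, tolerance = 1e-8)
  expect_true(murray_exponent(2^(1 / 3), 1, 1)$murray_ok)
  expect_equal(murray_exponent(sqrt(2), 1, 1)$d, 2, tolerance = 1e-8)
  expect_true(murray_exponent(sqrt(2), 1, 1)$murray_ok)
  m <- murray_exponent(2, 1, 1)
  expect_equal(m$d, 1, tolerance = 1e-8)
  expect_false(m$murray_ok)
  expect_true(is.na(murray_exponent(1, 1, 1)$d))  # daughter as wide as parent
})

test_that("Murray-law radii never trigger cost dominance in either mode", {
  set.seed(10)
  rr <- murray_radii(2000L)
  for (mode in c("surface_area", "volume")) {
    h <- if (mode == "surface_area") rr[, 1:3] else rr[, 1:3]^2
    dom <- h[, 1] >= h[, 2] + h[, 3] | h[, 2] >= h[, 1] + h[, 3] |
      h[, 3] >= h[, 1] + h[, 2]
    expect_false(any(dom))
  }
})
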