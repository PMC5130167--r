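# Fixtures built in code: toy tables, random junctions, independent oracles.

# minimal 3-row table: one root splitting into two daughters
toy_table <- function() {
  data.frame(
    vessel_id = c("p", "a", "b"),
    parent_id = c(NA, "p", "p"),
    x_prox = c(0, 0, 0), y_prox = c(0, 0, 0), z_prox = c(0, 1, 1),
    x_dist = c(0, -1, 1), y_dist = c(0, 0.5, 0.5), z_dist = c(1, 2, 2),
    radius = c(1, 0.8, 0.8),
    length = c(1, sqrt(1 + 0.25 + 1), sqrt(1 + 0.25 + 1)),
    n_children = c(2L, 0L, 0L),
    stringsAsFactors = FALSE)
}

toy_network <- function() vascular_network(toy_table())

# random well-separated junction record (possibly non-planar)
random_junction <- function() {
  repeat {
    J <- stats::rnorm(3)
    V0 <- J + stats::rnorm(3); V1 <- J + stats::rnorm(3)
    V2 <- J + stats::rnorm(3)
    ok <- min(sqrt(sum((V0 - J)^2)), sqrt(sum((V1 - J)^2)),
              sqrt(sum((V2 - J)^2))) > 0.2
    area <- sqrt(sum(pracma_cross(V1 - V0, V2 - V0)^2))
    if (ok && area > 0.1) break
  }
  list(J = J, V0 = V0, V1 = V1, V2 = V2,
       r = stats::runif(3, 0.5, 1.5), l = stats::runif(3, 1, 2))
}

pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

# independent angle oracle: plain arccos of normalized dot products
oracle_angle <- function(u, v) {
  acos(sum(u * v) / sqrt(sum(u * u) * sum(v * v)))
}

# independent brute-force minimum enclosing sphere for <= 10 points:
# smallest candidate sphere (from all pairs, triples, quadruples) that
# contains every point
brute_mes <- function(pts) {
  n <- nrow(pts)
  cand <- list()
  sphere_through <- function(S) {
    k <- nrow(S)
    if (k == 2L) {
      ctr <- colMeans(S)
      return(list(center = ctr, radius = sqrt(sum((S[1, ] - ctr)^2))))
    }
    A <- sweep(S[-1L, , drop = FALSE], 2L, S[1L, ])
    b <- 0.5 * rowSums(A * A)
    G <- A %*% t(A)
    if (abs(det(G)) < 1e-12) return(NULL)
    w <- solve(G, b)
    ctr <- S[1L, ] + drop(t(A) %*% w)
    list(center = ctr, radius = sqrt(sum((S[1L, ] - ctr)^2)))
  }
  idx2 <- utils::combn(n, 2)
  for (i in seq_len(ncol(idx2)))
    cand[[length(cand) + 1L]] <- sphere_through(pts[idx2[, i], , drop = FALSE])
  if (n >= 3L) {
    idx3 <- utils::combn(n, 3)
    for (i in seq_len(ncol(idx3)))
      cand[[length(cand) + 1L]] <- sphere_through(pts[idx3[, i], , drop = FALSE])
  }
  if (n >= 4L) {
    idx4 <- utils::combn(n, 4)
    for (i in seq_len(ncol(idx4)))
      cand[[length(cand) + 1L]] <- sphere_through(pts[idx4[, i], , drop = FALSE])
  }
  best <- Inf
  for (s in cand) {
    if (is.null(s)) next
    d <- sqrt(rowSums((pts - matrix(s$center, n, 3, byrow = TRUE))^2))
    if (max(d) <= s$radius + 1e-9 && s$radius < best) best <- s$radius
  }
  best
}

# random radii satisfying r0^d = r1^d + r2^d for d in [2, 3]
murray_radii <- function(n) {
  d <- stats::runif(n, 2, 3)
  u <- stats::runif(n, 0.02, 0.98)
  r0 <- stats::runif(n, 0.5, 2)
  cbind(r0 = r0, r1 = r0 * u^(1 / d), r2 = r0 * (1 - u)^(1 / d), d = d)
}

# random triangle in the plane with a guaranteed non-degenerate shape
random_triangle2d <- function() {
  repeat {
    V <- matrix(stats::rnorm(6), 3, 2)
    ab <- V[2, ] - V[1, ]; ac <- V[3, ] - V[1, ]
    area <- abs(ab[1] * ac[2] - ab[2] * ac[1]) / 2
    if (area > 0.1) return(V)
  }
}
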