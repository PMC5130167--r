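# Material-cost (MC) optimal branching: closed-form angles, degeneracy
# classification, weighted-Fermat solver, Murray exponent.

#' Cost-per-length weights for material-cost optimization
#'
#' The material cost of a vessel is h*l with h proportional to the radius
#' (surface-area mode, vessel-wall material) or the squared radius (volume
#' mode, blood volume); constant geometric factors such as 2*pi cancel in
#' the optimization and are dropped.
#'
#' @param r0,r1,r2 positive radii of parent and daughters.
#' @param mode `"surface_area"` or `"volume"`.
#' @return numeric vector `c(h0, h1, h2)` with attribute `mode`.
#' @export
cost_weights <- function(r0, r1, r2, mode = c("surface_area", "volume")) {
  mode <- match.arg(mode)
  r <- c(r0, r1, r2)
  if (any(!(r > 0))) stop("radii must be positive")
  h <- if (mode == "surface_area") r else r^2
  structure(stats::setNames(h, c("h0", "h1", "h2")), mode = mode)
}

#' Closed-form optimal branching angles
#'
#' Stationary (interior) solution of the weighted Fermat problem
#' min sum(h_i * l_i): cos(theta0) = (h0^2-h1^2-h2^2)/(2 h1 h2) and
#' cyclic permutations. The solution exists only when all three cosines lie
#' in [-1, 1]; outside that range the true optimum is degenerate (at a
#' vertex) and the angles are flagged undefined rather than blindly applied.
#'
#' @param h cost weights `c(h0, h1, h2)` (see [cost_weights()]).
#' @return list with `cosines` (always returned), `angles` (radians, or NULL
#'   when undefined) and logical `defined`.
#' @export
closed_form_angles <- function(h) {
  h <- as.numeric(h)
  if (any(!(h > 0))) stop("cost weights must be positive")
  cosines <- c(cos_theta0 = (h[1L]^2 - h[2L]^2 - h[3L]^2) / (2 * h[2L] * h[3L]),
               cos_theta1 = (h[2L]^2 - h[1L]^2 - h[3L]^2) / (2 * h[1L] * h[3L]),
               cos_theta2 = (h[3L]^2 - h[1L]^2 - h[2L]^2) / (2 * h[1L] * h[2L]))
  defined <- all(cosines >= -1 & cosines <= 1)
  angles <- if (defined) {
    stats::setNames(acos(cosines), c("theta0", "theta1", "theta2"))
  } else NULL
  list(cosines = cosines, angles = angles, defined = defined)
}

#' Classify the optimal junction of a triangle
#'
#' Decides whether the cost-minimizing junction lies strictly inside the
#' triangle V0 V1 V2 (`"interior"`) or collapses onto a vertex
#' (`"vertex_V0"`, `"vertex_V1"`, `"vertex_V2"`), eliminating that vessel.
#' Collapse onto V_i happens when either (a) cost dominance: h_i >= h_j +
#' h_k, so eradicating the single most expensive vessel is always worth it,
#' or (b) the triangle condition: the stationary angle theta_i is smaller
#' than the triangle's interior angle at V_i (cos theta_i > cos angle
#' V_j V_i V_k), so the stationary point falls outside the triangle. Cost
#' dominance is checked first; the outcomes are mutually exclusive.
#'
#' @param h cost weights `c(h0, h1, h2)`; non-negative (a zero weight is
#'   allowed and resolves through cost dominance).
#' @param V0,V1,V2 triangle vertices: 2-vectors or 3-vectors.
#' @return character label.
#' @export
classify_junction <- function(h, V0, V1, V2) {
  h <- as.numeric(h)
  if (any(h < 0)) stop("cost weights must be non-negative")
  a <- sqrt(sum((V1 - V2)^2))  # side opposite V0
  b <- sqrt(sum((V0 - V2)^2))
  co <- sqrt(sum((V0 - V1)^2))
  if (min(a, b, co) == 0 ||
      abs(b + co - a) < 1e-12 * a || abs(a + co - b) < 1e-12 * b ||
      abs(a + b - co) < 1e-12 * co)
    stop("degenerate (collinear) triangle")
  # cost dominance
  if (h[1L] >= h[2L] + h[3L]) return("vertex_V0")
  if (h[2L] >= h[1L] + h[3L]) return("vertex_V1")
  if (h[3L] >= h[1L] + h[2L]) return("vertex_V2")
  # all weights strictly positive here (a zero weight implies dominance)
  cf <- closed_form_angles(h)
  cosines <- cf$cosines
  # interior angles of the triangle at V0, V1, V2 (law of cosines)
  cosA <- c((b^2 + co^2 - a^2) / (2 * b * co),
            (a^2 + co^2 - b^2) / (2 * a * co),
            (a^2 + b^2 - co^2) / (2 * a * b))
  for (i in 1:3) {
    if (cosines[i] > cosA[i]) return(paste0("vertex_V", i - 1L))
  }
  "interior"
}

#' Material-cost optimal junction placement
#'
#' Solves the weighted Fermat problem for one bifurcation: the unshared
#' endpoints V0, V1, V2 and the radii are fixed, the junction J moves.
#' Non-planar triangles are handled by optimizing in the plane of the three
#' endpoints (the 2-D planar scheme), which is exact because the optimum of
#' a sum of distances to three points always lies in their plane. Interior
#' solutions are found by damped Weiszfeld iteration on the convex cost
#' H = sum h_i |J - V_i|; degenerate solutions sit at the classified vertex.
#'
#' @param junction a junction record (fields `V0`, `V1`, `V2`, `r`), e.g.
#'   from [extract_junctions()]; `J` is ignored (it is the unknown).
#' @param mode `"surface_area"` or `"volume"`.
#' @param tol convergence tolerance on the iterate step.
#' @param max_iter iteration cap.
#' @return list (class `branching_solution`): `classification`, `J_opt`
#'   (3-vector), `angles` (theta0..2 at the optimum, NULL for vertex
#'   collapse), `lengths` (l0, l1, l2), `asymmetry` (lambda_l, lambda_theta;
#'   NULL for vertex collapse), `cost_value`, `mode`.
#' @export
solve_optimal_junction <- function(junction, mode = c("surface_area", "volume"),
                                   tol = 1e-12, max_iter = 10000L) {
  mode <- match.arg(mode)
  h <- cost_weights(junction$r[1L], junction$r[2L], junction$r[3L], mode)
  V <- list(junction$V0, junction$V1, junction$V2)
  pr <- project_to_plane(rbind(V[[1L]], V[[2L]], V[[3L]]),
                         V[[1L]], V[[2L]], V[[3L]])
  P <- pr$xy  # 3 x 2, exact in-plane coordinates
  cls <- classify_junction(h, P[1L, ], P[2L, ], P[3L, ])
  hnum <- as.numeric(h)
  if (cls != "interior") {
    i <- as.integer(substring(cls, 9L)) + 1L
    Jop <- V[[i]]
    lens <- vapply(V, function(vv) sqrt(sum((Jop - vv)^2)), numeric(1L))
    return(structure(list(classification = cls, J_opt = Jop, angles = NULL,
                          lengths = stats::setNames(lens, c("l0", "l1", "l2")),
                          asymmetry = NULL,
                          cost_value = sum(hnum * lens), mode = mode),
                     class = "branching_solution"))
  }
  x <- colMeans(P)  # start at centroid
  for (it in seq_len(max_iter)) {
    d <- sqrt(rowSums((P - matrix(x, 3L, 2L, byrow = TRUE))^2))
    if (any(d < 1e-12)) {
      # iterate hit a vertex: nudge toward the centroid (interior class
      # guarantees the optimum is not at a vertex)
      x <- x + 1e-9 * (colMeans(P) - x)
      next
    }
    w <- hnum / d
    xn <- colSums(P * w) / sum(w)
    if (sqrt(sum((xn - x)^2)) < tol) { x <- xn; break }
    x <- xn
  }
  Jop <- drop(pr$back(x))
  lens <- vapply(V, function(vv) sqrt(sum((Jop - vv)^2)), numeric(1L))
  ang <- branching_angles(list(J = Jop, V0 = V[[1L]], V1 = V[[2L]], V2 = V[[3L]]))
  structure(list(classification = "interior", J_opt = Jop, angles = ang,
                 lengths = stats::setNames(lens, c("l0", "l1", "l2")),
                 asymmetry = c(lambda_l = min(lens[2L], lens[3L]) /
                                 max(lens[2L], lens[3L]),
                               lambda_theta = min(ang[2L], ang[3L]) /
                                 max(ang[2L], ang[3L])),
                 cost_value = sum(hnum * lens), mode = mode),
            class = "branching_solution")
}

#' Brute-force weighted-Fermat oracle
#'
#' Independent check for [solve_optimal_junction()]: minimizes
#' H = sum h_i |J - V_i| over a barycentric grid of the closed triangle
#' (vertices included) followed by local grid-shrink refinement.
#' Deterministic; used in tests and for classification cross-validation.
#'
#' @param V0,V1,V2 triangle vertices (2- or 3-vectors).
#' @param h cost weights `c(h0, h1, h2)`.
#' @param grid_n grid subdivisions per edge (>= 50).
#' @param refine_steps shrink-refinement iterations.
#' @return list with `J` (optimal point, same dimension as input), `cost`,
#'   and `at_vertex` (0 = interior, i = collapsed onto V_{i-1}).
#' @export
numeric_fermat_oracle <- function(V0, V1, V2, h, grid_n = 100L,
                                  refine_steps = 30L) {
  stopifnot(grid_n >= 50L)
  h <- as.numeric(h)
  V <- rbind(V0, V1, V2)
  costf <- function(B) {  # B: m x 3 barycentric
    X <- B %*% V
    d0 <- sqrt(rowSums((X - matrix(V[1L, ], nrow(X), ncol(V), byrow = TRUE))^2))
    d1 <- sqrt(rowSums((X - matrix(V[2L, ], nrow(X), ncol(V), byrow = TRUE))^2))
    d2 <- sqrt(rowSums((X - matrix(V[3L, ], nrow(X), ncol(V), byrow = TRUE))^2))
    h[1L] * d0 + h[2L] * d1 + h[3L] * d2
  }
  ij <- expand.grid(i = 0:grid_n, j = 0:grid_n)
  ij <- ij[ij$i + ij$j <= grid_n, ]
  B <- cbind(ij$i, ij$j, grid_n - ij$i - ij$j) / grid_n
  cost <- costf(B)
  best <- which.min(cost)
  bb <- B[best, ]
  bestcost <- cost[best]
  # local refinement: pattern search over a barycentric neighborhood that
  # shrinks only when no candidate improves (so it can travel several cells)
  w <- 1 / grid_n
  loc <- expand.grid(a = seq(-1, 1, length.out = 9L),
                     b = seq(-1, 1, length.out = 9L))
  shrinks <- 0L
  for (s in seq_len(40L * refine_steps)) {
    cand <- cbind(bb[1L] + loc$a * w, bb[2L] + loc$b * w)
    cand <- cbind(cand, 1 - cand[, 1L] - cand[, 2L])
    ok <- cand[, 1L] >= 0 & cand[, 2L] >= 0 & cand[, 3L] >= 0
    cand <- cand[ok, , drop = FALSE]
    cc <- costf(cand)
    if (min(cc) < bestcost) {
      bestcost <- min(cc)
      bb <- cand[which.min(cc), ]
    } else {
      w <- w / 2
      shrinks <- shrinks + 1L
      if (shrinks >= refine_steps) break
    }
  }
  # Nelder-Mead polish in barycentric coordinates: pattern search alone can
  # stall in the narrow valleys that form when the optimum hugs a vertex.
  # Infeasible points are clamped into the simplex with a violation penalty.
  scale <- abs(bestcost) + 1
  clamp <- function(b) {
    v <- pmax(c(b[1L], b[2L], 1 - b[1L] - b[2L]), 0)
    v / sum(v)
  }
  f <- function(b) {
    v <- c(b[1L], b[2L], 1 - b[1L] - b[2L])
    viol <- -sum(pmin(v, 0))
    costf(matrix(clamp(b), 1L, 3L)) + viol * scale
  }
  start <- 0.95 * bb + 0.05 / 3
  op <- tryCatch(stats::optim(start[1:2], f, method = "Nelder-Mead",
                              control = list(reltol = 1e-15, maxit = 1000L)),
                 error = function(e) NULL)
  if (!is.null(op) && op$value < bestcost) {
    bestcost <- op$value
    bb <- clamp(op$par)
  }
  J <- drop(bb %*% V)
  at_vertex <- 0L
  diam <- max(sqrt(sum((V[1L, ] - V[2L, ])^2)), sqrt(sum((V[1L, ] - V[3L, ])^2)),
              sqrt(sum((V[2L, ] - V[3L, ])^2)))
  for (i in 1:3) {
    if (sqrt(sum((J - V[i, ])^2)) < 1e-6 * diam) at_vertex <- i
  }
  list(J = J, cost = bestcost, at_vertex = at_vertex)
}

#' Murray-law exponent of one bifurcation
#'
#' Solves r0^d = r1^d + r2^d for the unique positive d, by bisection to
#' 1e-10. A solution exists iff both daughters are strictly narrower than
#' the parent. The classical expectation is d in [2, 3]; radii obeying it
#' are guaranteed never to trigger material-cost dominance.
#'
#' @param r0,r1,r2 positive radii.
#' @return list with `d` (or NA when unsolvable) and logical `murray_ok`
#'   (`d` within [2, 3]).
#' @export
murray_exponent <- function(r0, r1, r2) {
  if (any(!(c(r0, r1, r2) > 0))) stop("radii must be positive")
  if (max(r1, r2) >= r0) return(list(d = NA_real_, murray_ok = FALSE))
  a <- r1 / r0; b <- r2 / r0
  f <- function(d) a^d + b^d - 1  # strictly decreasing, f(0) = 1
  lo <- 1e-12
  hi <- 1
  while (f(hi) > 0) hi <- hi * 2
  while (hi - lo > 1e-10) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  d <- (lo + hi) / 2
  list(d = d, murray_ok = (d >= 2 - 1e-8 && d <= 3 + 1e-8))
}

#' Material-cost optimization table for a network
#'
#' Runs [solve_optimal_junction()] at every bifurcation and assembles the
#' per-junction results, including the Murray exponent of the observed
#' radii. Degenerate (vertex-collapse) junctions carry NA angles and
#' asymmetries; their fraction is the degeneracy rate.
#'
#' @param network a `vascular_network`.
#' @param mode `"surface_area"` or `"volume"`.
#' @return data.frame: junction_id, mode, classification, theta0_opt..
#'   theta2_opt, lambda_l_opt, lambda_theta_opt, murray_d, murray_ok.
#' @export
mc_optimize_network <- function(network, mode = c("surface_area", "volume")) {
  mode <- match.arg(mode)
  js <- extract_junctions(network)
  rows <- lapply(js, function(j) {
    sol <- solve_optimal_junction(j, mode)
    mur <- murray_exponent(j$r[1L], j$r[2L], j$r[3L])
    data.frame(junction_id = j$parent_id, mode = mode,
               classification = sol$classification,
               theta0_opt = if (is.null(sol$angles)) NA_real_ else sol$angles[[1L]],
               theta1_opt = if (is.null(sol$angles)) NA_real_ else sol$angles[[2L]],
               theta2_opt = if (is.null(sol$angles)) NA_real_ else sol$angles[[3L]],
               lambda_l_opt = if (is.null(sol$asymmetry)) NA_real_ else
                 sol$asymmetry[["lambda_l"]],
               lambda_theta_opt = if (is.null(sol$asymmetry)) NA_real_ else
                 sol$asymmetry[["lambda_theta"]],
               murray_d = mur$d, murray_ok = mur$murray_ok,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
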