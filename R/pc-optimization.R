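# Power-cost (PC) optimization: Poiseuille impedances, equivalent impedance
# of a bifurcation, PC-0 vertex collapse, PC-1 with downstream impedances,
# analytic region boundaries and the analytic-vs-numeric plane scan.

#' Poiseuille impedance model
#'
#' In physical units the impedance of a cylindrical vessel under smooth
#' Poiseuille flow is Z = 8*mu*l/(pi*r^4), with mu the blood viscosity. For
#' optimization the constant 8*mu/pi rescales every term identically and
#' never moves an argmin, so the default `"reduced"` mode uses Z = l/r^4.
#'
#' @param mode `"reduced"` or `"physical"`.
#' @param mu viscosity (Pa s), required for `"physical"`.
#' @return list of class `impedance_model`.
#' @export
impedance_model <- function(mode = c("reduced", "physical"), mu = NULL) {
  mode <- match.arg(mode)
  if (mode == "physical") {
    if (is.null(mu) || !(mu > 0)) stop("physical mode requires viscosity mu > 0")
  }
  structure(list(mode = mode, mu = mu), class = "impedance_model")
}

#' Impedance of a single vessel
#'
#' @param r,l positive radius and length.
#' @param model an [impedance_model()].
#' @return Z = l/r^4 (reduced) or 8*mu*l/(pi*r^4) (physical).
#' @export
vessel_impedance <- function(r, l, model = impedance_model()) {
  if (any(!(r > 0)) || any(!(l > 0))) stop("radius and length must be positive")
  k <- if (model$mode == "physical") 8 * model$mu / pi else 1
  k * l / r^4
}

# cost-per-length for PC objectives
.pc_h <- function(r, model = impedance_model()) {
  k <- if (model$mode == "physical") 8 * model$mu / pi else 1
  k / r^4
}

#' Equivalent impedance of one bifurcation
#'
#' Siblings are in parallel (equal pressure drop across the daughters),
#' the parent is in series: Z_eq = Z0 + (1/Z1 + 1/Z2)^-1. A zero daughter
#' impedance short-circuits the parallel pair (parallel term 0).
#'
#' @param Z0,Z1,Z2 non-negative impedances (vectorized).
#' @return Z_eq. The fully degenerate case Z0 = Z1 = Z2 = 0 returns 0.
#' @export
junction_equivalent_impedance <- function(Z0, Z1, Z2) {
  if (any(Z0 < 0 | Z1 < 0 | Z2 < 0)) stop("impedances must be non-negative")
  s <- Z1 + Z2
  par <- ifelse(s == 0, 0, Z1 * Z2 / s)
  Z0 + par
}

# Nelder-Mead polish in barycentric coordinates (handles the narrow
# anisotropic valleys that defeat axis-aligned pattern search near vertices)
.nm_polish <- function(V, costf, bb, bestcost, maxit = 1000L) {
  scale <- abs(bestcost) + 1
  clamp <- function(b) {
    v <- pmax(c(b[1L], b[2L], 1 - b[1L] - b[2L]), 0)
    v / sum(v)
  }
  f <- function(b) {
    v <- c(b[1L], b[2L], 1 - b[1L] - b[2L])
    viol <- -sum(pmin(v, 0))
    vc <- clamp(b)
    costf(matrix(vc, 1L, 3L) %*% V) + viol * scale
  }
  start <- 0.95 * bb + 0.05 / 3  # nudge off the boundary so NM can move
  op <- tryCatch(stats::optim(start[1:2], f, method = "Nelder-Mead",
                              control = list(reltol = 1e-15, maxit = maxit)),
                 error = function(e) NULL)
  if (!is.null(op) && op$value < bestcost) {
    bb <- clamp(op$par)
    bestcost <- op$value
  }
  list(bb = bb, bestcost = bestcost)
}

# Minimize a cost function over the closed triangle V (3 x dim rows) by a
# dense barycentric grid (vertices included) plus shrink refinement.
# costf(X) takes an m x dim matrix of points, returns m costs.
.tri_minimize <- function(V, costf, grid_n = 100L, refine_steps = 30L) {
  ij <- expand.grid(i = 0:grid_n, j = 0:grid_n)
  ij <- ij[ij$i + ij$j <= grid_n, ]
  B <- cbind(ij$i, ij$j, grid_n - ij$i - ij$j) / grid_n
  X <- B %*% V
  cost <- costf(X)
  best <- which.min(cost)
  bb <- B[best, ]
  bestcost <- cost[best]
  w <- 1 / grid_n
  loc <- expand.grid(a = seq(-1, 1, length.out = 9L),
                     b = seq(-1, 1, length.out = 9L))
  shrinks <- 0L
  for (s in seq_len(40L * refine_steps)) {
    cand <- cbind(bb[1L] + loc$a * w, bb[2L] + loc$b * w)
    cand <- cbind(cand, 1 - cand[, 1L] - cand[, 2L])
    ok <- cand[, 1L] >= 0 & cand[, 2L] >= 0 & cand[, 3L] >= 0
    cand <- cand[ok, , drop = FALSE]
    cc <- costf(cand %*% V)
    if (min(cc) < bestcost) {
      bestcost <- min(cc)
      bb <- cand[which.min(cc), ]
    } else {
      w <- w / 2
      shrinks <- shrinks + 1L
      if (shrinks >= refine_steps) break
    }
  }
  pol <- .nm_polish(V, costf, bb, bestcost)
  bb <- pol$bb; bestcost <- pol$bestcost
  J <- drop(bb %*% V)
  diam <- max(sqrt(sum((V[1L, ] - V[2L, ])^2)),
              sqrt(sum((V[1L, ] - V[3L, ])^2)),
              sqrt(sum((V[2L, ] - V[3L, ])^2)))
  at_vertex <- 0L
  for (i in 1:3) {
    if (sqrt(sum((J - V[i, ])^2)) < 1e-6 * diam) { at_vertex <- i; break }
  }
  # grid interior values, for collapse verification
  interior <- B[, 1L] > 0 & B[, 2L] > 0 & B[, 3L] > 0
  list(J = J, cost = bestcost, at_vertex = at_vertex,
       min_interior_grid = if (any(interior)) min(cost[interior]) else NA_real_,
       vertex_costs = costf(V))
}

#' PC-0: minimize equivalent impedance of a single junction
#'
#' Minimizes Z_eq(J) = h0 l0 + (1/(h1 l1) + 1/(h2 l2))^-1 with l_i =
#' |J - V_i| over the closed triangle. For a single bifurcation the optimum
#' always collapses onto a vertex (the costliest path is eliminated
#' entirely), whatever the radii; this function verifies the collapse
#' numerically and reports the attaining vertex.
#'
#' @param V0,V1,V2 triangle vertices (2- or 3-vectors).
#' @param r0,r1,r2 positive radii.
#' @param model an [impedance_model()].
#' @param grid_n grid subdivisions per edge (>= 100).
#' @return list: `J` (argmin), `Z_eq` (minimum), `collapse_vertex`
#'   ("V0"/"V1"/"V2", or NA if the argmin was not within tolerance of a
#'   vertex), `vertex_costs`, and `interior_exceeds` (TRUE when every
#'   strictly interior grid sample exceeds the best vertex value).
#' @export
pc0_minimize <- function(V0, V1, V2, r0, r1, r2, model = impedance_model(),
                         grid_n = 100L) {
  stopifnot(grid_n >= 100L)
  V <- rbind(V0, V1, V2)
  h <- .pc_h(c(r0, r1, r2), model)
  costf <- function(X) {
    d0 <- sqrt(rowSums((X - matrix(V[1L, ], nrow(X), ncol(V), byrow = TRUE))^2))
    d1 <- sqrt(rowSums((X - matrix(V[2L, ], nrow(X), ncol(V), byrow = TRUE))^2))
    d2 <- sqrt(rowSums((X - matrix(V[3L, ], nrow(X), ncol(V), byrow = TRUE))^2))
    junction_equivalent_impedance(h[1L] * d0, h[2L] * d1, h[3L] * d2)
  }
  res <- .tri_minimize(V, costf, grid_n = grid_n)
  best_vertex <- min(res$vertex_costs)
  list(J = res$J, Z_eq = res$cost,
       collapse_vertex = if (res$at_vertex > 0L)
         paste0("V", res$at_vertex - 1L) else NA_character_,
       vertex_costs = stats::setNames(res$vertex_costs, c("V0", "V1", "V2")),
       interior_exceeds = is.na(res$min_interior_grid) ||
         res$min_interior_grid > best_vertex)
}

#' Equivalent impedance of a subtree
#'
#' Post-order recursion over the network: a terminal vessel contributes its
#' own impedance plus the terminal (capillary-ward) impedance `c_cap`; an
#' internal vessel contributes its own impedance plus the parallel
#' combination of its children's subtree impedances. This is the quantity
#' the downstream constants c1, c2 of the PC-1 scheme stand for.
#'
#' @param network a `vascular_network`.
#' @param vessel_id vessel whose subtree impedance is wanted.
#' @param model an [impedance_model()].
#' @param c_cap positive terminal impedance attached below every tip.
#' @return scalar Z_subtree.
#' @export
downstream_equivalent_impedance <- function(network, vessel_id,
                                            model = impedance_model(),
                                            c_cap = 1) {
  if (!(c_cap > 0)) stop("c_cap must be positive")
  v <- network$vessels
  i0 <- match(as.character(vessel_id), v$vessel_id)
  if (is.na(i0)) stop("unknown vessel id: ", vessel_id)
  kids <- split(seq_len(nrow(v)), factor(v$parent_id, levels = v$vessel_id))
  Zv <- vessel_impedance(v$radius, v$length, model)
  rec <- function(i) {
    ch <- kids[[v$vessel_id[i]]]
    if (length(ch) == 0L) return(Zv[i] + c_cap)
    zs <- vapply(ch, rec, numeric(1L))
    Zv[i] + 1 / sum(1 / zs)
  }
  rec(i0)
}

#' PC-1 rescaled daughter costs
#'
#' With downstream impedances c1, c2 in series below the daughters and
#' c_i >> Z_i, the first-order power-cost objective is
#' h0 l0 + h1 l1/(k+1)^2 + h2 l2 k^2/(k+1)^2 with k = c1/c2. The daughter
#' costs are strictly diminished for k in (0, Inf), which is what makes
#' non-degenerate (branching) optima possible at all.
#'
#' @param h1,h2 daughter costs per length.
#' @param k non-negative ratio c1/c2.
#' @return numeric `c(h1_eff, h2_eff)`.
#' @export
pc1_effective_costs <- function(h1, h2, k) {
  if (any(k < 0)) stop("k must be non-negative")
  c(h1 / (k + 1)^2, h2 * k^2 / (k + 1)^2)
}

# effective weight triple directly from (c1, c2); c1 = c2 = 0 not allowed here
.pc1_h_eff <- function(h, c1, c2) {
  s <- c1 + c2
  c(h[1L], h[2L] * (c2 / s)^2, h[3L] * (c1 / s)^2)
}

# map a vertex classification to the PC-1 region label
.pc1_label <- function(cls) {
  switch(cls,
         interior = "no_collapse",
         vertex_V0 = "collapse_to_parent_endpoint",
         vertex_V1 = "collapse_to_daughter_endpoint",
         vertex_V2 = "collapse_to_daughter_endpoint",
         stop("unknown classification: ", cls))
}

#' Analytic PC-1 region label
#'
#' Classifies one point of the (c1, c2) downstream-impedance plane by
#' building the rescaled cost triple and applying the material-cost
#' degeneracy classification; `c1 = c2 = 0` routes to the PC-0 vertex
#' comparison (always a collapse).
#'
#' @param V0,V1,V2 triangle vertices.
#' @param r0,r1,r2 positive radii.
#' @param c1,c2 non-negative downstream impedances.
#' @param model an [impedance_model()].
#' @return `"no_collapse"`, `"collapse_to_parent_endpoint"` or
#'   `"collapse_to_daughter_endpoint"`.
#' @export
pc1_classify <- function(V0, V1, V2, r0, r1, r2, c1, c2,
                         model = impedance_model()) {
  if (c1 < 0 || c2 < 0) stop("c1, c2 must be non-negative")
  h <- .pc_h(c(r0, r1, r2), model)
  if (c1 == 0 && c2 == 0) {
    # PC-0: collapse to the vertex with the smallest equivalent impedance
    vc <- c(junction_equivalent_impedance(0, h[2L] * sqrt(sum((V0 - V1)^2)),
                                          h[3L] * sqrt(sum((V0 - V2)^2))),
            h[1L] * sqrt(sum((V0 - V1)^2)),
            h[1L] * sqrt(sum((V0 - V2)^2)))
    return(.pc1_label(paste0("vertex_V", which.min(vc) - 1L)))
  }
  heff <- .pc1_h_eff(h, c1, c2)
  .pc1_label(classify_junction(heff, V0, V1, V2))
}

#' Analytic boundary lines of the PC-1 plane
#'
#' The two degeneracy conditions (cost dominance and the triangle
#' condition), applied to the rescaled weights, give six inequalities in
#' k = c1/c2 alone, so the region boundaries are lines c1 = k* c2 through
#' the origin. This function locates every critical k* > 0 where one of the
#' six margins changes sign, by sign-scan over a log-spaced k grid followed
#' by bisection, and labels each root by the condition it marks.
#'
#' @param V0,V1,V2 triangle vertices.
#' @param r0,r1,r2 positive radii.
#' @param model an [impedance_model()].
#' @param k_range positive range scanned (default 1e-4 .. 1e4).
#' @param n_scan scan resolution.
#' @return data.frame with columns `k_star` and `condition`
#'   (e.g. "cost_dominance_V0", "triangle_V2"); zero rows when no margin
#'   crosses zero in range.
#' @export
pc1_boundary_lines <- function(V0, V1, V2, r0, r1, r2,
                               model = impedance_model(),
                               k_range = c(1e-4, 1e4), n_scan = 4000L) {
  h <- .pc_h(c(r0, r1, r2), model)
  a <- sqrt(sum((V1 - V2)^2)); b <- sqrt(sum((V0 - V2)^2))
  co <- sqrt(sum((V0 - V1)^2))
  cosA <- c((b^2 + co^2 - a^2) / (2 * b * co),
            (a^2 + co^2 - b^2) / (2 * a * co),
            (a^2 + b^2 - co^2) / (2 * a * b))
  heff <- function(k) c(h[1L], h[2L] / (k + 1)^2, h[3L] * k^2 / (k + 1)^2)
  margins <- list(
    cost_dominance_V0 = function(k) { e <- heff(k); e[1L] - e[2L] - e[3L] },
    cost_dominance_V1 = function(k) { e <- heff(k); e[2L] - e[1L] - e[3L] },
    cost_dominance_V2 = function(k) { e <- heff(k); e[3L] - e[1L] - e[2L] },
    triangle_V0 = function(k) {
      e <- heff(k)
      (e[1L]^2 - e[2L]^2 - e[3L]^2) / (2 * e[2L] * e[3L]) - cosA[1L]
    },
    triangle_V1 = function(k) {
      e <- heff(k)
      (e[2L]^2 - e[1L]^2 - e[3L]^2) / (2 * e[1L] * e[3L]) - cosA[2L]
    },
    triangle_V2 = function(k) {
      e <- heff(k)
      (e[3L]^2 - e[1L]^2 - e[2L]^2) / (2 * e[1L] * e[2L]) - cosA[3L]
    })
  ks <- exp(seq(log(k_range[1L]), log(k_range[2L]), length.out = n_scan))
  out <- list()
  for (nm in names(margins)) {
    f <- margins[[nm]]
    vals <- vapply(ks, function(k) tryCatch(f(k), error = function(e) NA_real_),
                   numeric(1L))
    ok <- is.finite(vals)
    idx <- which(ok[-length(ok)] & ok[-1L] &
                   sign(vals[-length(vals)]) * sign(vals[-1L]) < 0)
    for (i in idx) {
      root <- stats::uniroot(f, c(ks[i], ks[i + 1L]), tol = 1e-12)$root
      out[[length(out) + 1L]] <- data.frame(k_star = root, condition = nm,
                                            stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(k_star = numeric(0), condition = character(0)))
  res <- do.call(rbind, out)
  res <- res[order(res$k_star), ]
  rownames(res) <- NULL
  res
}

#' Numeric PC-1 solution at one (c1, c2) point
#'
#' Minimizes the exact equivalent impedance
#' Z_eq(J) = Z0 + (1/(Z1 + c1) + 1/(Z2 + c2))^-1, with Z_i = h_i |J - V_i|,
#' over the closed triangle by dense grid plus shrink refinement, and labels
#' the argmin as a vertex collapse (within 1e-6 of the triangle diameter)
#' or an interior (no-collapse) solution.
#'
#' @inheritParams pc1_classify
#' @param grid_n grid subdivisions per edge.
#' @return list with `label` and `J`.
#' @export
pc1_numeric_solution <- function(V0, V1, V2, r0, r1, r2, c1, c2,
                                 model = impedance_model(), grid_n = 100L) {
  V <- rbind(V0, V1, V2)
  h <- .pc_h(c(r0, r1, r2), model)
  costf <- function(X) {
    d0 <- sqrt(rowSums((X - matrix(V[1L, ], nrow(X), ncol(V), byrow = TRUE))^2))
    d1 <- sqrt(rowSums((X - matrix(V[2L, ], nrow(X), ncol(V), byrow = TRUE))^2))
    d2 <- sqrt(rowSums((X - matrix(V[3L, ], nrow(X), ncol(V), byrow = TRUE))^2))
    Z1 <- h[2L] * d1 + c1
    Z2 <- h[3L] * d2 + c2
    s <- Z1 + Z2
    h[1L] * d0 + ifelse(s == 0, 0, Z1 * Z2 / s)
  }
  res <- .tri_minimize(V, costf, grid_n = grid_n)
  label <- if (res$at_vertex == 1L) "collapse_to_parent_endpoint"
  else if (res$at_vertex > 1L) "collapse_to_daughter_endpoint"
  else "no_collapse"
  list(label = label, J = res$J)
}

#' Analytic-vs-numeric scan of the PC-1 plane
#'
#' Labels every cell of a (c1, c2) grid by both the analytic first-order
#' classification and the exact numeric minimization, and records where the
#' two agree. The analytic approximation assumes c_i >> Z_i, so mismatches
#' concentrate at small c1, c2.
#'
#' @inheritParams pc1_classify
#' @param c_range range of both c axes (default `c(0, 20)`).
#' @param resolution cells per axis (>= 50 for production scans).
#' @param grid_n triangle grid for the numeric minimizer.
#' @return list of class `pc1_plane_scan`: `grid` (data.frame with c1, c2,
#'   analytic_label, numeric_label, agree), `agreement` (overall fraction),
#'   `boundaries` (from [pc1_boundary_lines()]).
#' @export
pc1_plane_scan <- function(V0, V1, V2, r0, r1, r2, model = impedance_model(),
                           c_range = c(0, 20), resolution = 50L, grid_n = 60L) {
  V <- rbind(V0, V1, V2)
  h <- .pc_h(c(r0, r1, r2), model)
  cs <- seq(c_range[1L], c_range[2L], length.out = resolution)
  cells <- expand.grid(c1 = cs, c2 = cs)
  # precompute barycentric grid distances once
  ij <- expand.grid(i = 0:grid_n, j = 0:grid_n)
  ij <- ij[ij$i + ij$j <= grid_n, ]
  B <- cbind(ij$i, ij$j, grid_n - ij$i - ij$j) / grid_n
  X <- B %*% V
  d0 <- sqrt(rowSums((X - matrix(V[1L, ], nrow(X), ncol(V), byrow = TRUE))^2))
  d1 <- sqrt(rowSums((X - matrix(V[2L, ], nrow(X), ncol(V), byrow = TRUE))^2))
  d2 <- sqrt(rowSums((X - matrix(V[3L, ], nrow(X), ncol(V), byrow = TRUE))^2))
  Z0g <- h[1L] * d0; Z1g <- h[2L] * d1; Z2g <- h[3L] * d2
  diam <- max(sqrt(sum((V[1L, ] - V[2L, ])^2)),
              sqrt(sum((V[1L, ] - V[3L, ])^2)),
              sqrt(sum((V[2L, ] - V[3L, ])^2)))
  loc <- expand.grid(a = seq(-1, 1, length.out = 7L),
                     b = seq(-1, 1, length.out = 7L))
  numeric_label <- character(nrow(cells))
  analytic_label <- character(nrow(cells))
  for (i in seq_len(nrow(cells))) {
    c1 <- cells$c1[i]; c2 <- cells$c2[i]
    analytic_label[i] <- pc1_classify(V0, V1, V2, r0, r1, r2, c1, c2, model)
    A1 <- Z1g + c1; A2 <- Z2g + c2
    s <- A1 + A2
    cost <- Z0g + ifelse(s == 0, 0, A1 * A2 / s)
    best <- which.min(cost)
    bb <- B[best, ]
    bestcost <- cost[best]
    w <- 1 / grid_n
    shrinks <- 0L
    for (st in 1:400) {
      cand <- cbind(bb[1L] + loc$a * w, bb[2L] + loc$b * w)
      cand <- cbind(cand, 1 - cand[, 1L] - cand[, 2L])
      ok <- cand[, 1L] >= 0 & cand[, 2L] >= 0 & cand[, 3L] >= 0
      cand <- cand[ok, , drop = FALSE]
      Xc <- cand %*% V
      e0 <- sqrt(rowSums((Xc - matrix(V[1L, ], nrow(Xc), ncol(V), byrow = TRUE))^2))
      e1 <- sqrt(rowSums((Xc - matrix(V[2L, ], nrow(Xc), ncol(V), byrow = TRUE))^2))
      e2 <- sqrt(rowSums((Xc - matrix(V[3L, ], nrow(Xc), ncol(V), byrow = TRUE))^2))
      A1c <- h[2L] * e1 + c1; A2c <- h[3L] * e2 + c2
      sc <- A1c + A2c
      cc <- h[1L] * e0 + ifelse(sc == 0, 0, A1c * A2c / sc)
      if (min(cc) < bestcost) {
        bestcost <- min(cc)
        bb <- cand[which.min(cc), ]
      } else {
        w <- w / 2
        shrinks <- shrinks + 1L
        if (shrinks >= 20L) break
      }
    }
    clamp3 <- function(b) {
      v <- pmax(c(b[1L], b[2L], 1 - b[1L] - b[2L]), 0)
      v / sum(v)
    }
    fcell <- function(b) {
      v <- c(b[1L], b[2L], 1 - b[1L] - b[2L])
      viol <- -sum(pmin(v, 0))
      Xc <- drop(matrix(clamp3(b), 1L, 3L) %*% V)
      e0 <- sqrt(sum((Xc - V[1L, ])^2)); e1 <- sqrt(sum((Xc - V[2L, ])^2))
      e2 <- sqrt(sum((Xc - V[3L, ])^2))
      A1c <- h[2L] * e1 + c1; A2c <- h[3L] * e2 + c2
      base <- if (A1c + A2c == 0) h[1L] * e0 else
        h[1L] * e0 + A1c * A2c / (A1c + A2c)
      base + viol * (abs(bestcost) + 1)
    }
    op <- tryCatch(stats::optim((0.95 * bb + 0.05 / 3)[1:2], fcell,
                                method = "Nelder-Mead",
                                control = list(reltol = 1e-14, maxit = 300L)),
                   error = function(e) NULL)
    if (!is.null(op) && op$value < bestcost) bb <- clamp3(op$par)
    J <- drop(bb %*% V)
    at_vertex <- 0L
    for (k in 1:3) {
      if (sqrt(sum((J - V[k, ])^2)) < 1e-6 * diam) { at_vertex <- k; break }
    }
    numeric_label[i] <- if (at_vertex == 1L) "collapse_to_parent_endpoint"
    else if (at_vertex > 1L) "collapse_to_daughter_endpoint"
    else "no_collapse"
  }
  grid <- data.frame(c1 = cells$c1, c2 = cells$c2,
                     analytic_label = analytic_label,
                     numeric_label = numeric_label,
                     agree = analytic_label == numeric_label,
                     stringsAsFactors = FALSE)
  structure(list(grid = grid, agreement = mean(grid$agree),
                 boundaries = pc1_boundary_lines(V0, V1, V2, r0, r1, r2, model)),
            class = "pc1_plane_scan")
}

#' @export
print.pc1_plane_scan <- function(x, ...) {
  cat("PC-1 plane scan: ", nrow(x$grid), " cells, analytic/numeric agreement ",
      sprintf("%.1f%%", 100 * x$agreement), "\n", sep = "")
  invisible(x)
}
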