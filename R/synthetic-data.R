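# Synthetic vascular trees emulating segmented-angiography output: rooted
# binary trees embedded in 3-D with Murray-law radii, broad sibling length
# ratios, and optional tortuosity and noise.

#' Specification for a synthetic vascular tree
#'
#' The generator emulates the statistical structure of segmented vascular
#' data: radii follow a generalized Murray law r0^d = r1^d + r2^d with a
#' near-symmetric split (radius asymmetry concentrated near 1), sibling
#' chord lengths are drawn from a wide ratio distribution (length asymmetry
#' broadly spread), and parent-daughter branching angles are drawn around a
#' typical empirical value. Centerline length = tortuosity_factor * chord.
#'
#' @param depth branching generations for a full binary tree (>= 1); ignored
#'   when `n_junctions` is given.
#' @param n_junctions optional exact number of bifurcations; the tree is
#'   grown breadth-first (complete-tree shape).
#' @param murray_d radius exponent (default 3).
#' @param radius_noise_sd multiplicative log-normal radius noise sd.
#' @param split_sd sd of the Murray flow-split fraction around 1/2; small
#'   values give radius ratios near 1.
#' @param root_radius,root_length radius and chord of the root vessel
#'   (length units; defaults roughly lung-scaled: mm).
#' @param length_ratio_range daughter/parent chord ratio, drawn uniformly.
#' @param angle_mean,angle_sd parent-daughter branching angle draw (radians),
#'   clamped to (pi/2, pi).
#' @param tortuosity_factor centerline/chord factor (>= 1).
#' @param seed integer seed.
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(depth = 5L, n_junctions = NULL, murray_d = 3,
                           radius_noise_sd = 0, split_sd = 0.08,
                           root_radius = 1, root_length = 10,
                           length_ratio_range = c(0.3, 0.95),
                           angle_mean = 2.2, angle_sd = 0.3,
                           tortuosity_factor = 1, seed = 1L) {
  stopifnot(depth >= 1L, murray_d > 0, tortuosity_factor >= 1,
            radius_noise_sd >= 0, root_radius > 0, root_length > 0)
  structure(list(depth = as.integer(depth), n_junctions = n_junctions,
                 murray_d = murray_d, radius_noise_sd = radius_noise_sd,
                 split_sd = split_sd, root_radius = root_radius,
                 root_length = root_length,
                 length_ratio_range = length_ratio_range,
                 angle_mean = angle_mean, angle_sd = angle_sd,
                 tortuosity_factor = tortuosity_factor, seed = seed),
            class = "synthetic_spec")
}

#' Mouse-lung-sized synthetic preset
#'
#' A synthetic tree with 633 bifurcations (the size of a segmented mouse
#' lung arterial network), default Murray exponent 3 and a lung-scale root.
#'
#' @param seed integer seed.
#' @param ... overrides passed to [synthetic_spec()].
#' @return a `synthetic_spec`.
#' @export
mouse_like_spec <- function(seed = 1L, ...) {
  args <- list(n_junctions = 633L, root_radius = 0.5, root_length = 6,
               seed = seed)
  override <- list(...)
  args[names(override)] <- override
  do.call(synthetic_spec, args)
}

# one random unit vector orthogonal to u
.random_perp <- function(u) {
  repeat {
    g <- stats::rnorm(3L)
    w <- g - sum(g * u) * u
    nw <- sqrt(sum(w * w))
    if (nw > 1e-8) return(w / nw)
  }
}

# draw daughter geometry relative to a junction at J with incoming unit
# direction u: radii (Murray split + noise), chords, unit directions
.draw_daughters <- function(J, u, r, chord, spec) {
  x <- min(0.95, max(0.05, 0.5 + stats::rnorm(1L, 0, spec$split_sd)))
  r1 <- r * x^(1 / spec$murray_d)
  r2 <- r * (1 - x)^(1 / spec$murray_d)
  if (spec$radius_noise_sd > 0) {
    r1 <- r1 * exp(stats::rnorm(1L, 0, spec$radius_noise_sd))
    r2 <- r2 * exp(stats::rnorm(1L, 0, spec$radius_noise_sd))
  }
  th <- pmin(pi - 0.12, pmax(pi / 2 + 0.05,
                             stats::rnorm(2L, spec$angle_mean, spec$angle_sd)))
  w <- .random_perp(u)
  rot <- function(dev, s) {  # rotate u by dev toward s*w in the (u, w) plane
    cos(dev) * u + sin(dev) * s * w
  }
  # theta2 is the angle between parent side (J -> V0) and daughter-1 side
  u1 <- rot(pi - th[2L], +1)
  u2 <- rot(pi - th[1L], -1)
  c1 <- chord * stats::runif(1L, spec$length_ratio_range[1L],
                             spec$length_ratio_range[2L])
  c2 <- chord * stats::runif(1L, spec$length_ratio_range[1L],
                             spec$length_ratio_range[2L])
  list(r = c(r1, r2), u = rbind(u1, u2), chord = c(c1, c2))
}

#' Generate a synthetic vascular tree
#'
#' Builds a rooted binary tree embedded in 3-D by recursive placement:
#' daughters branch off at sampled angles, with Murray-split radii and wide
#' sibling chord ratios, growing breadth-first either to a full tree of
#' `depth` generations or to exactly `n_junctions` bifurcations. The result
#' passes full network validation and is deterministic given the seed.
#'
#' @param spec a [synthetic_spec()].
#' @return a `vascular_network`.
#' @export
generate_tree <- function(spec = synthetic_spec()) {
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(spec$seed)
  target <- if (!is.null(spec$n_junctions)) as.integer(spec$n_junctions)
  else 2L^spec$depth - 1L
  rows <- list()
  nid <- 0L
  new_vessel <- function(parent, P, D, r, chord) {
    nid <<- nid + 1L
    rows[[nid]] <<- list(vessel_id = sprintf("v%04d", nid), parent_id = parent,
                         P = P, D = D, r = r, chord = chord)
    nid
  }
  u0 <- c(0, 0, 1)
  root <- new_vessel(NA_character_, c(0, 0, 0),
                     c(0, 0, spec$root_length), spec$root_radius,
                     spec$root_length)
  queue <- list(list(idx = root, u = u0, gen = 1L))
  n_split <- 0L
  while (n_split < target && length(queue) > 0L) {
    cur <- queue[[1L]]; queue <- queue[-1L]
    if (is.null(spec$n_junctions) && cur$gen > spec$depth) break
    v <- rows[[cur$idx]]
    dd <- .draw_daughters(v$D, cur$u, v$r, v$chord, spec)
    if (any(dd$r <= 0)) stop("spec produced a non-positive radius")
    for (k in 1:2) {
      ui <- dd$u[k, ]
      idx <- new_vessel(v$vessel_id, v$D, v$D + ui * dd$chord[k],
                        dd$r[k], dd$chord[k])
      queue[[length(queue) + 1L]] <- list(idx = idx, u = ui, gen = cur$gen + 1L)
    }
    n_split <- n_split + 1L
  }
  .rows_to_network(rows, spec)
}

.rows_to_network <- function(rows, spec) {
  tab <- do.call(rbind, lapply(rows, function(x) {
    data.frame(vessel_id = x$vessel_id, parent_id = x$parent_id,
               x_prox = x$P[1L], y_prox = x$P[2L], z_prox = x$P[3L],
               x_dist = x$D[1L], y_dist = x$D[2L], z_dist = x$D[3L],
               radius = x$r, length = spec$tortuosity_factor * x$chord,
               n_children = 0L, stringsAsFactors = FALSE)
  }))
  cnt <- table(factor(tab$parent_id, levels = tab$vessel_id))
  tab$n_children <- as.integer(cnt)
  vascular_network(tab)
}

#' Generate a material-cost-optimal synthetic tree
#'
#' Builds a tree in which every bifurcation junction sits exactly at the
#' material-cost optimum of its own endpoint triangle. The construction
#' inverts the closed-form solution: at each junction the daughter radii
#' are drawn (Murray split, optional noise), the optimal branching angles
#' are computed from the cost weights, and the daughter endpoints are then
#' placed along directions making exactly those angles with the parent
#' chord, in a randomly oriented plane through the junction. The junction
#' is therefore the stationary point of the convex weighted-Fermat cost of
#' its final triangle, so re-analyzing the network recovers the closed-form
#' angles to numerical precision and classifies every junction interior.
#' Radius draws whose optimal angles are undefined (possible with large
#' radius noise) are redrawn up to `max_retries` times. Lengths are chords
#' (tortuosity is not applied).
#'
#' @param spec a [synthetic_spec()].
#' @param mode `"surface_area"` or `"volume"`.
#' @param max_retries redraw budget per junction.
#' @return a `vascular_network`.
#' @export
generate_mc_optimal_tree <- function(spec = synthetic_spec(),
                                     mode = c("surface_area", "volume"),
                                     max_retries = 200L) {
  mode <- match.arg(mode)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(spec$seed)
  target <- if (!is.null(spec$n_junctions)) as.integer(spec$n_junctions)
  else 2L^spec$depth - 1L
  rows <- list()
  nid <- 0L
  new_vessel <- function(parent, P, D, r, chord) {
    nid <<- nid + 1L
    rows[[nid]] <<- list(vessel_id = sprintf("v%04d", nid), parent_id = parent,
                         P = P, D = D, r = r, chord = chord)
    nid
  }
  root <- new_vessel(NA_character_, c(0, 0, 0), c(0, 0, spec$root_length),
                     spec$root_radius, spec$root_length)
  queue <- list(list(idx = root, gen = 1L))
  n_split <- 0L
  while (n_split < target && length(queue) > 0L) {
    cur <- queue[[1L]]; queue <- queue[-1L]
    if (is.null(spec$n_junctions) && cur$gen > spec$depth) break
    v <- rows[[cur$idx]]
    J <- v$D
    u0 <- (v$P - J) / sqrt(sum((v$P - J)^2))  # unit chord toward V0
    th <- NULL; rr <- NULL
    for (try in seq_len(max_retries)) {
      x <- min(0.95, max(0.05, 0.5 + stats::rnorm(1L, 0, spec$split_sd)))
      r1 <- v$r * x^(1 / spec$murray_d)
      r2 <- v$r * (1 - x)^(1 / spec$murray_d)
      if (spec$radius_noise_sd > 0) {
        r1 <- r1 * exp(stats::rnorm(1L, 0, spec$radius_noise_sd))
        r2 <- r2 * exp(stats::rnorm(1L, 0, spec$radius_noise_sd))
      }
      cf <- closed_form_angles(cost_weights(v$r, r1, r2, mode))
      if (cf$defined) { th <- cf$angles; rr <- c(r1, r2); break }
    }
    if (is.null(th))
      stop("retry budget exhausted while drawing an optimal junction")
    w <- .random_perp(u0)
    # theta2 = angle(J->V0, J->V1), theta1 = angle(J->V0, J->V2); opposite
    # sides of u0, so the three chord directions balance the cost gradient
    u1 <- cos(th[["theta2"]]) * u0 + sin(th[["theta2"]]) * w
    u2 <- cos(th[["theta1"]]) * u0 - sin(th[["theta1"]]) * w
    c1 <- v$chord * stats::runif(1L, spec$length_ratio_range[1L],
                                 spec$length_ratio_range[2L])
    c2 <- v$chord * stats::runif(1L, spec$length_ratio_range[1L],
                                 spec$length_ratio_range[2L])
    for (k in 1:2) {
      ui <- if (k == 1L) u1 else u2
      ci <- if (k == 1L) c1 else c2
      idx <- new_vessel(v$vessel_id, J, J + ui * ci, rr[k], ci)
      queue[[length(queue) + 1L]] <- list(idx = idx, gen = cur$gen + 1L)
    }
    n_split <- n_split + 1L
  }
  sp <- spec; sp$tortuosity_factor <- 1
  .rows_to_network(rows, sp)
}

#' Jitter junction positions
#'
#' Adds isotropic Gaussian noise to every bifurcation junction coordinate;
#' terminal tips, the source point and the topology are untouched. Each
#' moved vessel keeps its tortuosity: its length is rescaled by the ratio of
#' new to old chord. `sd = 0` returns the network unchanged.
#'
#' @param network a `vascular_network`.
#' @param sd positional noise standard deviation (length units).
#' @param seed integer seed.
#' @return a `vascular_network`.
#' @export
perturb_network <- function(network, sd, seed = 1L) {
  stopifnot(sd >= 0)
  if (sd == 0) return(network)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  v <- network$vessels
  jf <- junction_frame(network)
  if (nrow(jf) == 0L) return(network)
  J <- as.matrix(jf[, c("jx", "jy", "jz")]) +
    matrix(stats::rnorm(3L * nrow(jf), 0, sd), nrow(jf), 3L)
  tort <- v$length / pmax(sqrt((v$x_dist - v$x_prox)^2 +
                               (v$y_dist - v$y_prox)^2 +
                               (v$z_dist - v$z_prox)^2), 1e-300)
  prow <- match(jf$parent_id, v$vessel_id)
  d1row <- match(jf$d1_id, v$vessel_id)
  d2row <- match(jf$d2_id, v$vessel_id)
  v[prow, c("x_dist", "y_dist", "z_dist")] <- J
  v[d1row, c("x_prox", "y_prox", "z_prox")] <- J
  v[d2row, c("x_prox", "y_prox", "z_prox")] <- J
  chord <- sqrt((v$x_dist - v$x_prox)^2 + (v$y_dist - v$y_prox)^2 +
                (v$z_dist - v$z_prox)^2)
  v$length <- chord * tort
  vascular_network(v, validate = FALSE)
}
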