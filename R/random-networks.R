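# Constrained-random resampling of branching junctions: fixed topology,
# terminal tips and source; junction positions redrawn inside regions that
# range from the local endpoint triangle to the whole-network sphere.

#' Uniform samples from a triangle
#'
#' Area-uniform sampling by the barycentric square-root construction.
#'
#' @param n number of samples.
#' @param A,B,C triangle vertices (3-vectors).
#' @return n x 3 matrix of points.
#' @export
sample_uniform_triangle <- function(n, A, B, C) {
  if (.norm3(.plane_cross(B - A, C - A)) == 0) stop("degenerate triangle")
  r1 <- sqrt(stats::runif(n))
  r2 <- stats::runif(n)
  w <- cbind(1 - r1, r1 * (1 - r2), r1 * r2)
  w %*% rbind(A, B, C)
}

.plane_cross <- function(u, v) {
  c(u[2L] * v[3L] - u[3L] * v[2L],
    u[3L] * v[1L] - u[1L] * v[3L],
    u[1L] * v[2L] - u[2L] * v[1L])
}

#' Uniform samples from a ball
#'
#' @param n number of samples.
#' @param center 3-vector.
#' @param radius positive radius.
#' @return n x 3 matrix of points.
#' @export
sample_uniform_ball <- function(n, center, radius) {
  if (!(radius > 0)) stop("radius must be positive")
  g <- matrix(stats::rnorm(3L * n), n, 3L)
  nrm <- sqrt(rowSums(g^2))
  u <- stats::runif(n)^(1 / 3)
  sweep(g / nrm * (radius * u), 2L, center, `+`)
}

# Precompute the simulation structure: junction table, dependency indices
# (which junction supplies V0/V1/V2, NA = fixed point), dependency depths,
# and the global enclosing sphere.
.sim_structure <- function(network) {
  v <- network$vessels
  jf <- junction_frame(network)
  nj <- nrow(jf)
  jmap <- stats::setNames(seq_len(nj), jf$parent_id)
  grand <- v$parent_id[match(jf$parent_id, v$vessel_id)]
  v0_src <- unname(jmap[grand])         # NA when fixed (source/pass-through)
  v1_src <- unname(jmap[jf$d1_id])      # NA when daughter is tip/pass-through
  v2_src <- unname(jmap[jf$d2_id])
  depth <- integer(nj)
  remaining <- is.na(v0_src)
  depth[remaining] <- 0L
  cur <- which(remaining)
  d <- 0L
  assigned <- remaining
  while (any(!assigned)) {
    d <- d + 1L
    nxt <- which(!assigned & v0_src %in% cur)
    if (length(nxt) == 0L) stop("junction dependency graph is not a forest")
    depth[nxt] <- d
    assigned[nxt] <- TRUE
    cur <- nxt
  }
  nodes <- unique(rbind(
    unname(as.matrix(v[is.na(v$parent_id), c("x_prox", "y_prox", "z_prox")])),
    unname(as.matrix(v[, c("x_dist", "y_dist", "z_dist")]))))
  list(network = network, jf = jf, nj = nj,
       J0 = as.matrix(jf[, c("jx", "jy", "jz")]),
       V0o = as.matrix(jf[, c("v0x", "v0y", "v0z")]),
       V1o = as.matrix(jf[, c("v1x", "v1y", "v1z")]),
       V2o = as.matrix(jf[, c("v2x", "v2y", "v2z")]),
       v0_src = v0_src, v1_src = v1_src, v2_src = v2_src, depth = depth,
       sphere = min_enclosing_sphere(nodes))
}

# Draw new junction coordinates for one realization. Returns nj x 3 matrix.
.simulate_coords <- function(struct, scheme) {
  nj <- struct$nj
  if (nj == 0L) return(struct$J0)
  switch(scheme,
    local = {
      r1 <- sqrt(stats::runif(nj)); r2 <- stats::runif(nj)
      w1 <- 1 - r1; w2 <- r1 * (1 - r2); w3 <- r1 * r2
      w1 * struct$V0o + w2 * struct$V1o + w3 * struct$V2o
    },
    global = {
      sph <- struct$sphere
      sample_uniform_ball(nj, sph$center, sph$radius)
    },
    intermediate1 = {
      J <- struct$J0
      V0used <- struct$V0o
      for (d in sort(unique(struct$depth))) {
        idx <- which(struct$depth == d)
        V0c <- struct$V0o[idx, , drop = FALSE]
        has <- !is.na(struct$v0_src[idx])
        if (any(has)) V0c[has, ] <- J[struct$v0_src[idx][has], , drop = FALSE]
        V0used[idx, ] <- V0c
        r1 <- sqrt(stats::runif(length(idx))); r2 <- stats::runif(length(idx))
        J[idx, ] <- (1 - r1) * V0c +
          (r1 * (1 - r2)) * struct$V1o[idx, , drop = FALSE] +
          (r1 * r2) * struct$V2o[idx, , drop = FALSE]
      }
      # sampling-time triangle (V0used, V1o, V2o): each junction is exactly
      # coplanar with it by construction
      attr(J, "V0_used") <- V0used
      J
    },
    intermediate2 = {
      J <- struct$J0
      ctr_used <- struct$J0 * NA_real_
      rad_used <- rep(NA_real_, nrow(J))
      for (d in sort(unique(struct$depth), decreasing = TRUE)) {
        idx <- which(struct$depth == d)
        V1c <- struct$V1o[idx, , drop = FALSE]
        V2c <- struct$V2o[idx, , drop = FALSE]
        h1 <- !is.na(struct$v1_src[idx]); h2 <- !is.na(struct$v2_src[idx])
        if (any(h1)) V1c[h1, ] <- J[struct$v1_src[idx][h1], , drop = FALSE]
        if (any(h2)) V2c[h2, ] <- J[struct$v2_src[idx][h2], , drop = FALSE]
        ctr <- (V1c + V2c) / 2
        rad <- sqrt(rowSums((V1c - V2c)^2))
        ctr_used[idx, ] <- ctr
        rad_used[idx] <- rad
        ok <- rad > 0          # coincident daughter endpoints: keep original
        if (any(ok)) {
          g <- matrix(stats::rnorm(3L * sum(ok)), sum(ok), 3L)
          g <- g / sqrt(rowSums(g^2))
          u <- stats::runif(sum(ok))^(1 / 3)
          J[idx[ok], ] <- ctr[ok, , drop = FALSE] + g * (rad[ok] * u)
        }
      }
      # sampling-time constraint balls (center, radius) per junction
      attr(J, "center_used") <- ctr_used
      attr(J, "radius_used") <- rad_used
      J
    },
    stop("unknown scheme: ", scheme))
}

# Rebuild a full network from resampled junction coordinates; vessel lengths
# become endpoint chords (simulated vessels carry no centerline tortuosity).
.rebuild_network <- function(struct, J) {
  net <- struct$network
  v <- net$vessels
  jf <- struct$jf
  prow <- match(jf$parent_id, v$vessel_id)
  d1row <- match(jf$d1_id, v$vessel_id)
  d2row <- match(jf$d2_id, v$vessel_id)
  v[prow, c("x_dist", "y_dist", "z_dist")] <- J
  v[d1row, c("x_prox", "y_prox", "z_prox")] <- J
  v[d2row, c("x_prox", "y_prox", "z_prox")] <- J
  v$length <- sqrt((v$x_dist - v$x_prox)^2 + (v$y_dist - v$y_prox)^2 +
                   (v$z_dist - v$z_prox)^2)
  v$length[v$length == 0] <- .Machine$double.xmin  # degenerate draw guard
  vascular_network(v, validate = FALSE)
}

.scheme_index <- c(local = 1L, intermediate1 = 2L, intermediate2 = 3L,
                   global = 4L)

.realization_seed <- function(seed, scheme, realization) {
  # one 32-bit substream seed per (master seed, scheme, realization)
  (as.numeric(seed) %% 524286) * 4096 + .scheme_index[[scheme]] * 1024 +
    (as.numeric(realization) %% 1024)
}

#' Simulate one constrained-random realization
#'
#' Resamples every bifurcation junction of `network` inside its scheme's
#' constraint region, keeping topology, terminal tips and the source point
#' fixed:
#' \describe{
#'   \item{local}{each junction uniform in its original endpoint triangle
#'     (V0, V1, V2 as in the input network), independently.}
#'   \item{intermediate1}{top-down sweep; each junction uniform in the
#'     triangle of its parent's already-updated proximal endpoint and the
#'     daughters' not-yet-updated distal endpoints. Junctions are exactly
#'     planar by construction.}
#'   \item{intermediate2}{bottom-up sweep; each junction uniform in the ball
#'     centered at the midpoint of the daughters' current distal endpoints
#'     with radius equal to their separation. The upstream endpoint has no
#'     influence.}
#'   \item{global}{each junction uniform in the minimum enclosing sphere of
#'     all the original network's nodes.}
#' }
#' Vessel lengths of the realization are endpoint chords.
#'
#' @param network a `vascular_network`.
#' @param scheme one of `"local"`, `"intermediate1"`, `"intermediate2"`,
#'   `"global"`.
#' @param seed master integer seed.
#' @param realization realization index (1-based); together with `seed` and
#'   `scheme` it determines the draw exactly.
#' @return a `vascular_network` with attributes `scheme`,
#'   `realization_index`, `seed_used`.
#' @export
simulate_network <- function(network,
                             scheme = c("local", "intermediate1",
                                        "intermediate2", "global"),
                             seed = 1L, realization = 1L) {
  scheme <- match.arg(scheme)
  struct <- .sim_structure(network)
  simulate_from_structure(struct, scheme, seed, realization)
}

#' @rdname simulate_network
#' @param struct precomputed structure (internal use via [run_ensemble()]).
#' @export
simulate_from_structure <- function(struct, scheme, seed = 1L,
                                    realization = 1L) {
  sd_used <- .realization_seed(seed, scheme, realization)
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(sd_used)
  J <- .simulate_coords(struct, scheme)
  out <- .rebuild_network(struct, J)
  attr(out, "scheme") <- scheme
  attr(out, "realization_index") <- realization
  attr(out, "seed_used") <- sd_used
  out
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' @rdname simulate_network
#' @export
simulate_local <- function(network, seed = 1L, realization = 1L)
  simulate_network(network, "local", seed, realization)

#' @rdname simulate_network
#' @export
simulate_intermediate1 <- function(network, seed = 1L, realization = 1L)
  simulate_network(network, "intermediate1", seed, realization)

#' @rdname simulate_network
#' @export
simulate_intermediate2 <- function(network, seed = 1L, realization = 1L)
  simulate_network(network, "intermediate2", seed, realization)

#' @rdname simulate_network
#' @export
simulate_global <- function(network, seed = 1L, realization = 1L)
  simulate_network(network, "global", seed, realization)

#' Ensemble of constrained-random realizations
#'
#' Runs `n_realizations` of one scheme, recomputes branching angles and
#' asymmetry ratios at every junction of every realization (daughter lengths
#' as chords), and returns the pooled junction-level measurements together
#' with across-realization summaries.
#'
#' @param network a `vascular_network`.
#' @param scheme simulation scheme (see [simulate_network()]).
#' @param n_realizations number of realizations (paper-style default 100).
#' @param seed master integer seed.
#' @return list: `measurements` (pooled data.frame with realization,
#'   junction_id, theta0..2, lambda_r, lambda_l, lambda_theta),
#'   `per_realization` (one row per realization with the mean, sd and
#'   skewness of lambda_l and lambda_theta), `summary` (across-realization
#'   mean and SE of those statistics), `scheme`, `seed`.
#' @export
run_ensemble <- function(network, scheme, n_realizations = 100L, seed = 1L) {
  stopifnot(n_realizations >= 1L)
  struct <- .sim_structure(network)
  lam_r <- pmin(struct$jf$r1, struct$jf$r2) / pmax(struct$jf$r1, struct$jf$r2)
  meas <- vector("list", n_realizations)
  per <- vector("list", n_realizations)
  for (rr in seq_len(n_realizations)) {
    sd_used <- .realization_seed(seed, scheme, rr)
    old <- .save_rng()
    set.seed(sd_used)
    J <- .simulate_coords(struct, scheme)
    .restore_rng(old)
    g <- .geometry_from_coords(struct, J)
    meas[[rr]] <- data.frame(realization = rr,
                             junction_id = struct$jf$parent_id,
                             theta0 = g$theta0, theta1 = g$theta1,
                             theta2 = g$theta2, lambda_r = lam_r,
                             lambda_l = g$lambda_l,
                             lambda_theta = g$lambda_theta,
                             stringsAsFactors = FALSE)
    per[[rr]] <- data.frame(realization = rr,
                            mean_lambda_l = mean(g$lambda_l),
                            sd_lambda_l = stats::sd(g$lambda_l),
                            skew_lambda_l = .skewness(g$lambda_l),
                            mean_lambda_theta = mean(g$lambda_theta),
                            sd_lambda_theta = stats::sd(g$lambda_theta),
                            skew_lambda_theta = .skewness(g$lambda_theta))
  }
  per <- do.call(rbind, per)
  sumstat <- function(x) c(mean = mean(x), se = stats::sd(x) / sqrt(length(x)))
  summary <- do.call(rbind, lapply(
    c("mean_lambda_l", "sd_lambda_l", "skew_lambda_l",
      "mean_lambda_theta", "sd_lambda_theta", "skew_lambda_theta"),
    function(nm) data.frame(statistic = nm, t(sumstat(per[[nm]])))))
  list(measurements = do.call(rbind, meas), per_realization = per,
       summary = summary, scheme = scheme, seed = seed)
}

# angles + ratios from resampled junction coordinates, fully vectorized
.geometry_from_coords <- function(struct, J) {
  V0 <- struct$V0o; V1 <- struct$V1o; V2 <- struct$V2o
  h0 <- !is.na(struct$v0_src); h1 <- !is.na(struct$v1_src)
  h2 <- !is.na(struct$v2_src)
  if (any(h0)) V0[h0, ] <- J[struct$v0_src[h0], , drop = FALSE]
  if (any(h1)) V1[h1, ] <- J[struct$v1_src[h1], , drop = FALSE]
  if (any(h2)) V2[h2, ] <- J[struct$v2_src[h2], , drop = FALSE]
  jf2 <- data.frame(v0x = V0[, 1L], v0y = V0[, 2L], v0z = V0[, 3L],
                    jx = J[, 1L], jy = J[, 2L], jz = J[, 3L],
                    v1x = V1[, 1L], v1y = V1[, 2L], v1z = V1[, 3L],
                    v2x = V2[, 1L], v2y = V2[, 2L], v2z = V2[, 3L])
  ang <- branching_angles_table(jf2)
  l1 <- sqrt(rowSums((V1 - J)^2)); l2 <- sqrt(rowSums((V2 - J)^2))
  data.frame(theta0 = ang$theta0, theta1 = ang$theta1, theta2 = ang$theta2,
             lambda_l = pmin(l1, l2) / pmax(l1, l2),
             lambda_theta = pmin(ang$theta1, ang$theta2) /
               pmax(ang$theta1, ang$theta2))
}
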