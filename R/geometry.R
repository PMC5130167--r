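# Junction-level geometry: branching angles, asymmetry ratios, planarity,
# plane projection, minimum enclosing sphere.

.norm3 <- function(x) sqrt(sum(x * x))

.angle_between <- function(u, v) {
  nu <- .norm3(u); nv <- .norm3(v)
  if (nu == 0 || nv == 0) stop("degenerate geometry: coincident points")
  acos(max(-1, min(1, sum(u * v) / (nu * nv))))
}

#' Branching angles at a junction
#'
#' The three unsigned angles at the junction point J between the chords to
#' the unshared endpoints, indexed by the non-adjacent vessel: `theta0` is
#' the angle between the two daughter chords J->V1 and J->V2, `theta1`
#' between J->V0 and J->V2, and `theta2` between J->V0 and J->V1. Only
#' magnitudes are computed, so the same definition applies to planar optima
#' and to non-planar empirical junctions. For an exactly planar junction the
#' three angles sum to 2*pi.
#'
#' @param junction a junction record from [extract_junctions()], or any list
#'   with 3-vectors `J`, `V0`, `V1`, `V2`.
#' @return named numeric vector `c(theta0, theta1, theta2)` in radians.
#' @export
branching_angles <- function(junction) {
  J <- junction$J
  a0 <- junction$V0 - J; a1 <- junction$V1 - J; a2 <- junction$V2 - J
  c(theta0 = .angle_between(a1, a2),
    theta1 = .angle_between(a0, a2),
    theta2 = .angle_between(a0, a1))
}

#' Vectorized branching angles over a junction table
#'
#' @param jf data.frame from [junction_frame()] (or with the same coordinate
#'   columns).
#' @return data.frame with columns `theta0`, `theta1`, `theta2`.
#' @export
branching_angles_table <- function(jf) {
  ang <- function(ux, uy, uz, vx, vy, vz) {
    nu <- sqrt(ux^2 + uy^2 + uz^2); nv <- sqrt(vx^2 + vy^2 + vz^2)
    acos(pmax(-1, pmin(1, (ux * vx + uy * vy + uz * vz) / (nu * nv))))
  }
  a0x <- jf$v0x - jf$jx; a0y <- jf$v0y - jf$jy; a0z <- jf$v0z - jf$jz
  a1x <- jf$v1x - jf$jx; a1y <- jf$v1y - jf$jy; a1z <- jf$v1z - jf$jz
  a2x <- jf$v2x - jf$jx; a2y <- jf$v2y - jf$jy; a2z <- jf$v2z - jf$jz
  data.frame(theta0 = ang(a1x, a1y, a1z, a2x, a2y, a2z),
             theta1 = ang(a0x, a0y, a0z, a2x, a2y, a2z),
             theta2 = ang(a0x, a0y, a0z, a1x, a1y, a1z))
}

#' Sibling asymmetry ratios
#'
#' Smaller-over-larger ratios between the two daughters of a bifurcation:
#' `lambda_r` for radius, `lambda_l` for length, and `lambda_theta` for the
#' two parent-daughter branching angles (theta1, theta2). Each lies in
#' (0, 1]; 1 means perfect symmetry. The convention is invariant under
#' swapping the daughter labels.
#'
#' @param junction a junction record (fields `r`, `l`).
#' @param angles optional angle triple from [branching_angles()]; computed
#'   if missing.
#' @return named numeric vector `c(lambda_r, lambda_l, lambda_theta)`.
#' @export
asymmetry_ratios <- function(junction, angles = branching_angles(junction)) {
  r1 <- junction$r[2L]; r2 <- junction$r[3L]
  l1 <- junction$l[2L]; l2 <- junction$l[3L]
  t1 <- angles[["theta1"]]; t2 <- angles[["theta2"]]
  if (any(c(r1, r2, l1, l2, t1, t2) <= 0))
    stop("asymmetry ratios need positive radii, lengths and angles")
  c(lambda_r = min(r1, r2) / max(r1, r2),
    lambda_l = min(l1, l2) / max(l1, l2),
    lambda_theta = min(t1, t2) / max(t1, t2))
}

#' Scaled planarity distance of a junction
#'
#' Perpendicular distance of the junction point J from the plane through the
#' three unshared endpoints V0, V1, V2, divided by the mean chord length
#' mean(|JV0|, |JV1|, |JV2|). Zero iff the junction is perfectly planar;
#' larger values mean stronger deviation from planarity. The denominator
#' (mean chord) is this package's dimensionless scaling choice.
#'
#' @param junction a junction record.
#' @return non-negative scalar.
#' @export
planarity_scaled_distance <- function(junction) {
  nrm <- .plane_normal(junction$V0, junction$V1, junction$V2)
  d <- abs(sum((junction$J - junction$V0) * nrm))
  m <- mean(c(.norm3(junction$J - junction$V0),
              .norm3(junction$J - junction$V1),
              .norm3(junction$J - junction$V2)))
  if (m == 0) stop("degenerate geometry: junction coincides with all endpoints")
  d / m
}

.plane_normal <- function(V0, V1, V2) {
  n <- c((V1 - V0)[2L] * (V2 - V0)[3L] - (V1 - V0)[3L] * (V2 - V0)[2L],
         (V1 - V0)[3L] * (V2 - V0)[1L] - (V1 - V0)[1L] * (V2 - V0)[3L],
         (V1 - V0)[1L] * (V2 - V0)[2L] - (V1 - V0)[2L] * (V2 - V0)[1L])
  nn <- .norm3(n)
  if (nn < 1e-12 * max(.norm3(V1 - V0), .norm3(V2 - V0), 1e-300))
    stop("undefined plane: V0, V1, V2 are collinear")
  n / nn
}

#' Isometric projection onto the plane of three points
#'
#' Builds an orthonormal in-plane frame from `V0`, `V1`, `V2` and projects
#' arbitrary 3-D points into 2-D coordinates in that frame. Distances between
#' in-plane points are preserved exactly; out-of-plane points are
#' orthogonally projected. The returned `back` function maps 2-D coordinates
#' to 3-D points in the plane.
#'
#' @param points numeric matrix (n x 3) or a single 3-vector.
#' @param V0,V1,V2 3-vectors spanning the plane.
#' @return list with `xy` (n x 2 matrix), `back` (function 2-D -> 3-D), and
#'   the frame (`origin`, `e1`, `e2`).
#' @export
project_to_plane <- function(points, V0, V1, V2) {
  e1 <- V1 - V0
  n1 <- .norm3(e1)
  if (n1 == 0) stop("undefined plane: V0 and V1 coincide")
  e1 <- e1 / n1
  e2 <- (V2 - V0) - sum((V2 - V0) * e1) * e1
  n2 <- .norm3(e2)
  if (n2 < 1e-12 * max(n1, .norm3(V2 - V0)))
    stop("undefined plane: V0, V1, V2 are collinear")
  e2 <- e2 / n2
  pts <- if (is.matrix(points)) points else matrix(points, ncol = 3L)
  rel <- sweep(pts, 2L, V0)
  xy <- cbind(rel %*% e1, rel %*% e2)
  colnames(xy) <- c("u", "v")
  back <- function(uv) {
    uv <- if (is.matrix(uv)) uv else matrix(uv, ncol = 2L)
    t(apply(uv, 1L, function(p) V0 + p[1L] * e1 + p[2L] * e2))
  }
  list(xy = xy, back = back, origin = V0, e1 = e1, e2 = e2)
}

#' Minimum enclosing sphere of a point set
#'
#' Exact smallest sphere containing all points, by Welzl's randomized
#' incremental algorithm (expected linear time), with a deterministic
#' internal shuffle so results are reproducible. Used as the global spatial
#' constraint region for random-branching simulations.
#'
#' @param points numeric matrix (n x 3), or a 3-vector for a single point.
#' @return list with `center` (3-vector) and `radius`.
#' @export
min_enclosing_sphere <- function(points) {
  pts <- if (is.matrix(points)) points else matrix(points, ncol = 3L)
  if (nrow(pts) == 0L) stop("empty point set")
  pts <- unique(pts)
  n <- nrow(pts)
  # deterministic permutation (fixed LCG, independent of the user RNG)
  perm <- .lcg_permutation(n)
  pts <- pts[perm, , drop = FALSE]
  s <- .welzl_ball(pts, matrix(numeric(0), ncol = 3L))
  # guard: tiny numeric slack
  s$radius <- max(s$radius, 0)
  s
}

.lcg_permutation <- function(n) {
  if (n == 1L) return(1L)
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(703721L)  # fixed internal stream, isolated from the user RNG
  sample.int(n)
}

# Welzl's algorithm, iterative over points; recursion only on the boundary
# set (depth <= 4), so large point sets cannot exhaust the call stack.
.welzl_ball <- function(P, R) {
  if (nrow(R) == 4L) return(.ball_from_boundary(R))
  D <- .ball_from_boundary(R)
  for (i in seq_len(nrow(P))) {
    p <- P[i, ]
    if (nrow(R) == 0L && i == 1L ||
        .norm3(p - D$center) > D$radius + 1e-9 * (D$radius + 1)) {
      D <- .welzl_ball(P[seq_len(i - 1L), , drop = FALSE], rbind(R, p))
    }
  }
  D
}

.ball_from_boundary <- function(R) {
  k <- nrow(R)
  if (k == 0L) return(list(center = c(0, 0, 0), radius = -Inf))
  if (k == 1L) return(list(center = R[1L, ], radius = 0))
  if (k == 2L) {
    c0 <- (R[1L, ] + R[2L, ]) / 2
    return(list(center = c0, radius = .norm3(R[1L, ] - c0)))
  }
  # circumsphere of k=3 or k=4 points within their affine hull:
  # solve for center = R[1,] + A' w minimizing nothing (exact interpolation)
  A <- sweep(R[-1L, , drop = FALSE], 2L, R[1L, ])  # (k-1) x 3
  b <- 0.5 * rowSums(A * A)
  G <- A %*% t(A)
  w <- tryCatch(solve(G, b), error = function(e) NULL)
  if (is.null(w)) {  # degenerate (collinear/coplanar duplicates): drop a point
    return(.ball_from_boundary(R[-nrow(R), , drop = FALSE]))
  }
  center <- R[1L, ] + drop(t(A) %*% w)
  list(center = center, radius = .norm3(R[1L, ] - center))
}

#' Per-junction geometry table
#'
#' Computes branching angles, asymmetry ratios and the scaled planarity
#' distance for every bifurcation of a network.
#'
#' @param network a `vascular_network`.
#' @param use_chord_lengths logical; if `TRUE`, `lambda_l` uses endpoint
#'   chords instead of the stored (centerline) lengths. Simulated networks
#'   carry chords; empirical ones centerlines.
#' @return data.frame: junction_id, theta0..2, lambda_r, lambda_l,
#'   lambda_theta, planarity.
#' @export
junction_geometry <- function(network, use_chord_lengths = FALSE) {
  jf <- junction_frame(network)
  ang <- branching_angles_table(jf)
  l1 <- jf$l1; l2 <- jf$l2
  if (use_chord_lengths) {
    l1 <- sqrt((jf$v1x - jf$jx)^2 + (jf$v1y - jf$jy)^2 + (jf$v1z - jf$jz)^2)
    l2 <- sqrt((jf$v2x - jf$jx)^2 + (jf$v2y - jf$jy)^2 + (jf$v2z - jf$jz)^2)
  }
  planarity <- vapply(seq_len(nrow(jf)), function(i) {
    planarity_scaled_distance(list(
      V0 = c(jf$v0x[i], jf$v0y[i], jf$v0z[i]),
      J = c(jf$jx[i], jf$jy[i], jf$jz[i]),
      V1 = c(jf$v1x[i], jf$v1y[i], jf$v1z[i]),
      V2 = c(jf$v2x[i], jf$v2y[i], jf$v2z[i])))
  }, numeric(1L))
  out <- data.frame(junction_id = jf$parent_id,
                    theta0 = ang$theta0, theta1 = ang$theta1,
                    theta2 = ang$theta2,
                    lambda_r = pmin(jf$r1, jf$r2) / pmax(jf$r1, jf$r2),
                    lambda_l = pmin(l1, l2) / pmax(l1, l2),
                    lambda_theta = pmin(ang$theta1, ang$theta2) /
                      pmax(ang$theta1, ang$theta2),
                    planarity = planarity,
                    stringsAsFactors = FALSE)
  attr(out, "n_skipped") <- attr(jf, "n_skipped")
  out
}
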