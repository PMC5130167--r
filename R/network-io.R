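# Canonical column order of the angicart-style vessel table.
.vessel_cols <- c("vessel_id", "parent_id",
                  "x_prox", "y_prox", "z_prox",
                  "x_dist", "y_dist", "z_dist",
                  "radius", "length", "n_children")

#' Construct a vascular network from a vessel table
#'
#' A `vascular_network` is a rooted tree of cylindrical vessel segments
#' embedded in 3-D. Each vessel stores both its proximal (heart-ward) and
#' distal endpoint, its radius, its centerline length (which may exceed the
#' straight-line chord for tortuous vessels) and its observed number of
#' children. Exactly one vessel (the root) has no parent.
#'
#' @param vessels data.frame with columns `vessel_id`, `parent_id` (NA for the
#'   root), `x_prox`,`y_prox`,`z_prox`, `x_dist`,`y_dist`,`z_dist`, `radius`,
#'   `length`, `n_children`. All coordinates must share one length unit.
#' @param validate logical; run [validate_network()]?
#' @param tol coordinate-continuity tolerance (length units).
#' @return object of class `vascular_network`: a list with elements `vessels`
#'   (the table, row order preserved) and `root_id`.
#' @export
vascular_network <- function(vessels, validate = TRUE, tol = 1e-6) {
  stopifnot(is.data.frame(vessels))
  missing_cols <- setdiff(.vessel_cols, names(vessels))
  if (length(missing_cols) > 0L)
    stop("vessel table is missing columns: ", paste(missing_cols, collapse = ", "))
  vessels <- as.data.frame(vessels)[, .vessel_cols]
  vessels$vessel_id <- as.character(vessels$vessel_id)
  vessels$parent_id <- as.character(vessels$parent_id)
  vessels$parent_id[!is.na(vessels$parent_id) & vessels$parent_id == ""] <- NA_character_
  rownames(vessels) <- NULL
  root <- vessels$vessel_id[is.na(vessels$parent_id)]
  if (length(root) != 1L)
    stop("network must have exactly one root vessel; found ", length(root))
  net <- structure(list(vessels = vessels, root_id = root),
                   class = "vascular_network")
  if (validate) validate_network(net, tol = tol)
  net
}

#' @export
print.vascular_network <- function(x, ...) {
  v <- x$vessels
  nb <- sum(v$n_children == 2L)
  cat("Vascular network: ", nrow(v), " vessels, ", nb, " bifurcations, ",
      sum(v$n_children == 0L), " terminal tips (root: ", x$root_id, ")\n",
      sep = "")
  invisible(x)
}

#' Validate a vascular network
#'
#' Checks that ids are unique, parents exist, the graph is one connected
#' rooted tree without cycles, radii and lengths are positive, the centerline
#' length is at least the endpoint chord (up to `tol`), the proximal point of
#' every non-root vessel coincides with its parent's distal point within
#' `tol`, and `n_children` matches the observed child counts.
#'
#' @param network a `vascular_network`.
#' @param tol tolerance for coordinate continuity and the chord check.
#' @return `network`, invisibly. Errors describe the offending vessel.
#' @export
validate_network <- function(network, tol = 1e-6) {
  v <- network$vessels
  if (anyNA(v$vessel_id) || anyDuplicated(v$vessel_id))
    stop("vessel ids must be unique and non-missing")
  idx <- match(v$parent_id, v$vessel_id)
  orphan <- !is.na(v$parent_id) & is.na(idx)
  if (any(orphan))
    stop("vessel(s) reference a nonexistent parent: ",
         paste(v$vessel_id[orphan], collapse = ", "))
  bad <- which(!(v$radius > 0) | !(v$length > 0))
  if (length(bad) > 0L)
    stop("non-positive radius or length at vessel(s): ",
         paste(v$vessel_id[bad], collapse = ", "))
  # connectivity/acyclicity: every vessel must reach the root by parent hops
  n <- nrow(v)
  for (i in seq_len(n)) {
    seen <- 0L
    j <- i
    while (!is.na(v$parent_id[j])) {
      j <- match(v$parent_id[j], v$vessel_id)
      seen <- seen + 1L
      if (seen > n) stop("cycle detected in parent references")
    }
    if (v$vessel_id[j] != network$root_id)
      stop("vessel ", v$vessel_id[i], " is disconnected from the root")
  }
  chord <- sqrt((v$x_dist - v$x_prox)^2 + (v$y_dist - v$y_prox)^2 +
                (v$z_dist - v$z_prox)^2)
  short <- which(v$length < chord - tol)
  if (length(short) > 0L)
    stop("length shorter than endpoint chord at vessel(s): ",
         paste(v$vessel_id[short], collapse = ", "))
  nonroot <- which(!is.na(v$parent_id))
  pi_ <- idx[nonroot]
  dd <- sqrt((v$x_prox[nonroot] - v$x_dist[pi_])^2 +
             (v$y_prox[nonroot] - v$y_dist[pi_])^2 +
             (v$z_prox[nonroot] - v$z_dist[pi_])^2)
  if (any(dd > tol))
    stop("proximal point does not match parent's distal point at vessel(s): ",
         paste(v$vessel_id[nonroot[dd > tol]], collapse = ", "))
  counts <- table(factor(v$parent_id, levels = v$vessel_id))
  if (any(v$n_children != as.integer(counts)))
    stop("n_children does not match observed child counts at vessel(s): ",
         paste(v$vessel_id[v$n_children != as.integer(counts)], collapse = ", "))
  invisible(network)
}

#' Read a vascular network table
#'
#' Supports two dialects: `"angicart_csv"`, a comma-separated table with the
#' exact header `vessel_id,parent_id,x_prox,...,n_children` (empty
#' `parent_id` marks the root), and `"swc"`, the standard neuron-morphology
#' format (`id type x y z radius parent`, parent -1 for the root). SWC nodes
#' are mapped to vessels as the edge from the parent node to the node, with
#' length equal to the chord. The SWC root node supplies the source point
#' when it has one child; a root node that is itself a branch point gets a
#' synthetic upstream source stub (id prefixed `swc_root_`) so the table
#' remains a single-rooted tree.
#'
#' @param source path to the file.
#' @param dialect `"angicart_csv"` or `"swc"`.
#' @param tol validation tolerance.
#' @return a [vascular_network()].
#' @export
read_network <- function(source, dialect = c("angicart_csv", "swc"), tol = 1e-6) {
  dialect <- match.arg(dialect)
  if (!file.exists(source)) stop("file not found: ", source)
  if (dialect == "angicart_csv") {
    tab <- utils::read.csv(source, colClasses = c(vessel_id = "character",
                                                  parent_id = "character"))
    vascular_network(tab, tol = tol)
  } else {
    .read_swc(source, tol = tol)
  }
}

.read_swc <- function(source, tol = 1e-6) {
  lines <- readLines(source)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) == 0L) stop("empty SWC file: ", source)
  m <- do.call(rbind, lapply(strsplit(trimws(lines), "\\s+"), function(x) {
    if (length(x) != 7L) stop("malformed SWC line: expected 7 fields")
    x
  }))
  nodes <- data.frame(id = m[, 1L],
                      x = as.numeric(m[, 3L]), y = as.numeric(m[, 4L]),
                      z = as.numeric(m[, 5L]), radius = as.numeric(m[, 6L]),
                      parent = m[, 7L], stringsAsFactors = FALSE)
  if (anyDuplicated(nodes$id)) stop("duplicate node ids in SWC file")
  root <- nodes$id[nodes$parent == "-1"]
  if (length(root) != 1L) stop("SWC file must have exactly one root node")
  child <- nodes[nodes$parent != "-1", , drop = FALSE]
  pidx <- match(child$parent, nodes$id)
  if (anyNA(pidx)) stop("SWC node references a nonexistent parent")
  # one vessel per non-root node: edge parent-node -> node
  chord <- sqrt((child$x - nodes$x[pidx])^2 + (child$y - nodes$y[pidx])^2 +
                (child$z - nodes$z[pidx])^2)
  vparent <- ifelse(child$parent == root, NA_character_, child$parent)
  tab <- data.frame(vessel_id = child$id,
                    parent_id = vparent,
                    x_prox = nodes$x[pidx], y_prox = nodes$y[pidx],
                    z_prox = nodes$z[pidx],
                    x_dist = child$x, y_dist = child$y, z_dist = child$z,
                    radius = child$radius, length = chord,
                    n_children = 0L, stringsAsFactors = FALSE)
  n_top <- sum(is.na(tab$parent_id))
  if (n_top == 0L) stop("SWC root has no children")
  if (n_top > 1L) {
    # SWC root is itself a branch point: synthesize an upstream source stub
    # so the table stays a single-rooted vessel tree
    rn <- nodes[nodes$id == root, ]
    top <- which(is.na(tab$parent_id))
    ctr <- c(mean(tab$x_dist[top]), mean(tab$y_dist[top]),
             mean(tab$z_dist[top]))
    dir <- c(rn$x, rn$y, rn$z) - ctr
    nd <- sqrt(sum(dir^2))
    if (nd == 0) dir <- c(0, 0, 1) else dir <- dir / nd
    stub_len <- mean(tab$length[top])
    src <- c(rn$x, rn$y, rn$z) + dir * stub_len
    tab <- rbind(data.frame(vessel_id = paste0("swc_root_", root),
                            parent_id = NA_character_,
                            x_prox = src[1L], y_prox = src[2L],
                            z_prox = src[3L],
                            x_dist = rn$x, y_dist = rn$y, z_dist = rn$z,
                            radius = rn$radius, length = stub_len,
                            n_children = 0L, stringsAsFactors = FALSE),
                 tab)
    orphans <- setdiff(which(is.na(tab$parent_id)), 1L)
    tab$parent_id[orphans] <- paste0("swc_root_", root)
  }
  cnt <- table(factor(tab$parent_id, levels = tab$vessel_id))
  tab$n_children <- as.integer(cnt)
  vascular_network(tab, tol = tol)
}

#' Write a vascular network table
#'
#' `angicart_csv` round-trips field-for-field. Writing `swc` is lossy by
#' construction: centerline lengths are replaced by chords (SWC carries only
#' node coordinates) and vessel ids are renumbered to integers.
#'
#' @param network a `vascular_network`.
#' @param path destination file.
#' @param dialect `"angicart_csv"` or `"swc"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path, dialect = c("angicart_csv", "swc")) {
  dialect <- match.arg(dialect)
  v <- network$vessels
  if (dialect == "angicart_csv") {
    out <- v
    out$parent_id[is.na(out$parent_id)] <- ""
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  } else {
    # node 1 = source (root proximal); node per vessel = its distal point
    num <- seq_len(nrow(v)) + 1L
    names(num) <- v$vessel_id
    pnum <- ifelse(is.na(v$parent_id), 1L, num[v$parent_id])
    root_row <- which(is.na(v$parent_id))
    hdr <- "# SWC export"
    src <- sprintf("1 0 %.10g %.10g %.10g %.10g -1",
                   v$x_prox[root_row], v$y_prox[root_row], v$z_prox[root_row],
                   v$radius[root_row])
    body <- sprintf("%d 0 %.10g %.10g %.10g %.10g %d",
                    num, v$x_dist, v$y_dist, v$z_dist, v$radius, pnum)
    writeLines(c(hdr, src, body), path)
  }
  invisible(path)
}

#' Extract bifurcation junctions
#'
#' Returns one junction record per vessel with exactly two children: the
#' junction point J (the parent's distal endpoint), the three unshared
#' endpoints V0 (parent proximal), V1, V2 (daughter distal), radii r0, r1, r2
#' and lengths l0, l1, l2. Vessels with a different number of children
#' (terminal tips, pass-through segments, trifurcations) are skipped and
#' counted; the framework is strictly bifurcating. Daughters are ordered by
#' vessel id, junctions by parent vessel id.
#'
#' @param network a `vascular_network`.
#' @return a list of junction records (class `vascular_junction`, fields
#'   `parent_id`, `d1_id`, `d2_id`, `V0`, `J`, `V1`, `V2`, `r` (length 3),
#'   `l` (length 3)), with attribute `n_skipped` counting non-bifurcating
#'   internal vessels (those with 1 or >2 children).
#' @export
extract_junctions <- function(network) {
  jf <- junction_frame(network)
  out <- lapply(seq_len(nrow(jf)), function(i) {
    structure(list(parent_id = jf$parent_id[i],
                   d1_id = jf$d1_id[i], d2_id = jf$d2_id[i],
                   V0 = c(jf$v0x[i], jf$v0y[i], jf$v0z[i]),
                   J  = c(jf$jx[i],  jf$jy[i],  jf$jz[i]),
                   V1 = c(jf$v1x[i], jf$v1y[i], jf$v1z[i]),
                   V2 = c(jf$v2x[i], jf$v2y[i], jf$v2z[i]),
                   r = c(jf$r0[i], jf$r1[i], jf$r2[i]),
                   l = c(jf$l0[i], jf$l1[i], jf$l2[i])),
              class = "vascular_junction")
  })
  attr(out, "n_skipped") <- attr(jf, "n_skipped")
  out
}

#' Junction table (vectorized form)
#'
#' Flat data.frame view of [extract_junctions()], one row per bifurcation,
#' with coordinates of V0, J, V1, V2, radii and lengths as columns. Used by
#' the vectorized geometry and simulation code.
#'
#' @param network a `vascular_network`.
#' @return data.frame with attribute `n_skipped`.
#' @export
junction_frame <- function(network) {
  v <- network$vessels
  pidx <- match(v$parent_id, v$vessel_id)
  kids <- split(seq_len(nrow(v)), factor(v$parent_id, levels = v$vessel_id))
  bif <- which(v$n_children == 2L)
  bif <- bif[order(v$vessel_id[bif])]
  n_skipped <- sum(v$n_children != 2L & v$n_children != 0L)
  rows <- lapply(bif, function(i) {
    ch <- kids[[v$vessel_id[i]]]
    ch <- ch[order(v$vessel_id[ch])]
    data.frame(parent_id = v$vessel_id[i],
               d1_id = v$vessel_id[ch[1L]], d2_id = v$vessel_id[ch[2L]],
               v0x = v$x_prox[i], v0y = v$y_prox[i], v0z = v$z_prox[i],
               jx = v$x_dist[i], jy = v$y_dist[i], jz = v$z_dist[i],
               v1x = v$x_dist[ch[1L]], v1y = v$y_dist[ch[1L]], v1z = v$z_dist[ch[1L]],
               v2x = v$x_dist[ch[2L]], v2y = v$y_dist[ch[2L]], v2z = v$z_dist[ch[2L]],
               r0 = v$radius[i], r1 = v$radius[ch[1L]], r2 = v$radius[ch[2L]],
               l0 = v$length[i], l1 = v$length[ch[1L]], l2 = v$length[ch[2L]],
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows) > 0L) do.call(rbind, rows) else
    stats::setNames(data.frame(matrix(nrow = 0L, ncol = 21L)),
                    c("parent_id", "d1_id", "d2_id",
                      "v0x", "v0y", "v0z", "jx", "jy", "jz",
                      "v1x", "v1y", "v1z", "v2x", "v2y", "v2z",
                      "r0", "r1", "r2", "l0", "l1", "l2"))
  rownames(out) <- NULL
  attr(out, "n_skipped") <- n_skipped
  out
}
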