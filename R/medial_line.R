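#' Order a width-1 skeleton into a polyline
#'
#' Walks the unique 26-connected path between the two endpoints of a
#' simple-curve skeleton and returns the voxel centres in order. The walk
#' starts at the lexicographically smaller endpoint index triple so the
#' orientation is deterministic.
#'
#' @param skel a [binary_volume()] skeleton: a width-1 curve with exactly
#'   two endpoints (voxels with one black 26-neighbour) and a single
#'   endpoint-to-endpoint walk visiting every voxel once (corners of
#'   digital curves may have extra diagonal contacts; the walk prefers
#'   the nearest unvisited neighbour, faces before edges before
#'   corners).
#' @return numeric matrix of ordered 3D world coordinates (mm), one row
#'   per skeleton voxel.
#' @export
order_skeleton <- function(skel) {
  pts <- black_points(skel)
  if (nrow(pts) < 2L) stop("not a simple curve: fewer than 2 voxels")
  cnt <- neighbor_counts(skel)
  deg <- cnt[pts + 1L]
  ends <- which(deg == 1L)
  if (length(ends) != 2L)
    stop(sprintf("not a simple curve: %d endpoints", length(ends)))
  key <- pts[, 1] * 1e12 + pts[, 2] * 1e6 + pts[, 3]
  start <- ends[which.min(key[ends])]
  occ <- skel$occupancy
  path <- integer(nrow(pts))
  visited <- rep(FALSE, nrow(pts))
  lookup <- new.env(parent = emptyenv())
  for (r in seq_len(nrow(pts)))
    assign(paste(pts[r, ], collapse = ","), r, envir = lookup)
  cur <- start
  for (step in seq_len(nrow(pts))) {
    path[step] <- cur
    visited[cur] <- TRUE
    if (step == nrow(pts)) break
    nb <- adjacency(pts[cur, ], 26)
    d2 <- rowSums(sweep(nb, 2, pts[cur, ])^2)
    cand <- integer(0); cand_d <- numeric(0)
    for (r in seq_len(nrow(nb))) {
      q <- nb[r, ]
      if (any(q < 0L) || any(q >= skel$shape)) next
      if (!occ[q[1] + 1L, q[2] + 1L, q[3] + 1L]) next
      i <- get(paste(q, collapse = ","), envir = lookup)
      if (!visited[i]) { cand <- c(cand, i); cand_d <- c(cand_d, d2[r]) }
    }
    if (length(cand) == 0L)
      stop("not a simple curve: walk stranded before covering all voxels")
    cur <- cand[order(cand_d, key[cand])][1]
  }
  if (any(!visited)) stop("not a simple curve: disconnected voxels")
  voxel_centers(skel, pts[path, , drop = FALSE])
}

#' Extract a medial polyline from an arbitrary skeleton
#'
#' Robust companion to [order_skeleton()] used inside the profiling
#' pipeline: when thinning leaves short spurs or staircase voxels with
#' more than two neighbours, the medial line is taken as the longest
#' shortest path (graph diameter path) through the skeleton's 26-adjacency
#' graph, with edges weighted by Euclidean distance between voxel
#' centres. For a clean simple curve this coincides with the endpoint-to-
#' endpoint walk.
#'
#' @param skel a [binary_volume()] skeleton.
#' @return numeric matrix of ordered 3D world coordinates (mm).
#' @export
skeleton_to_polyline <- function(skel) {
  pts <- black_points(skel)
  n <- nrow(pts)
  if (n < 2L) stop("skeleton has fewer than 2 voxels")
  xyz <- voxel_centers(skel, pts)
  # 26-adjacency edges
  ei <- integer(0); ej <- integer(0)
  ord <- order(pts[, 3], pts[, 2], pts[, 1])
  key <- new.env(parent = emptyenv())
  for (r in seq_len(n)) assign(paste(pts[r, ], collapse = ","), r, envir = key)
  for (r in seq_len(n)) {
    nb <- adjacency(pts[r, ], 26)
    for (s in seq_len(nrow(nb))) {
      k <- paste(nb[s, ], collapse = ",")
      if (exists(k, envir = key, inherits = FALSE)) {
        q <- get(k, envir = key)
        if (q > r) { ei <- c(ei, r); ej <- c(ej, q) }
      }
    }
  }
  if (length(ei) == 0L) stop("skeleton voxels are not connected")
  w <- sqrt(rowSums((xyz[ei, , drop = FALSE] - xyz[ej, , drop = FALSE])^2))
  g <- igraph::graph_from_edgelist(cbind(ei, ej), directed = FALSE)
  igraph::E(g)$weight <- w
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  comp <- igraph::components(g)
  main <- which.max(comp$csize)
  in_main <- which(comp$membership == main)
  # double sweep: farthest node from the lexicographically first voxel,
  # then farthest node from that one; ties broken by voxel order
  lexi <- in_main[order(pts[in_main, 1], pts[in_main, 2], pts[in_main, 3])][1]
  d0 <- igraph::distances(g, v = lexi, to = in_main)[1, ]
  a <- in_main[which.max(d0)]
  d1 <- igraph::distances(g, v = a, to = in_main)[1, ]
  b <- in_main[which.max(d1)]
  path <- igraph::shortest_paths(g, from = a, to = b)$vpath[[1]]
  xyz[as.integer(path), , drop = FALSE]
}

# chord-length parameters for ordered sample points: t_0 = 0, t_m = 1
chord_params <- function(points) {
  points <- as.matrix(points)
  seg <- sqrt(rowSums((points[-1, , drop = FALSE] -
                       points[-nrow(points), , drop = FALSE])^2))
  c(0, cumsum(seg)) / sum(seg)
}

# clamped knot vector with uniformly spaced interior knots on [0, 1]
clamped_knots <- function(n_ctrl, degree) {
  n_int <- n_ctrl - degree - 1L
  interior <- if (n_int > 0L) seq_len(n_int) / (n_int + 1) else numeric(0)
  c(rep(0, degree + 1L), interior, rep(1, degree + 1L))
}

new_bspline <- function(degree, knots, control) {
  structure(list(degree = as.integer(degree), knots = as.numeric(knots),
                 control = as.matrix(control)),
            class = "bspline_curve")
}

#' @export
print.bspline_curve <- function(x, ...) {
  cat(sprintf("<bspline_curve degree %d, %d control points>\n",
              x$degree, nrow(x$control)))
  invisible(x)
}

#' Least-squares B-spline fit to an ordered polyline
#'
#' Fits a clamped B-spline curve `X(t) = sum_i U_{i,d}(t) Q_i` to ordered
#' data points by minimising the summed squared residual over the control
#' points Q. Sample parameters `t_k` are assigned by normalised chord
#' length (`t_0 = 0`, `t_m = 1`); the normal equations `A'A Q = A'P` are
#' solved through the Cholesky factorization of the banded symmetric
#' positive-definite matrix `A'A`.
#'
#' @param points numeric matrix of ordered 3D points (mm); consecutive
#'   points must be distinct.
#' @param n_ctrl number of control points, at least `degree + 1` and at
#'   most the number of data points.
#' @param degree spline degree (default 3).
#' @return A `bspline_curve` with fields `degree`, `knots`, `control`.
#' @export
fit_bspline <- function(points, n_ctrl = max(4L, round(nrow(points) / 4)),
                        degree = 3L) {
  points <- as.matrix(points)
  m <- nrow(points)
  if (m < 2L) stop("need at least 2 points")
  seg <- sqrt(rowSums((points[-1, , drop = FALSE] -
                       points[-m, , drop = FALSE])^2))
  if (any(seg == 0)) stop("consecutive points must be distinct")
  n_ctrl <- as.integer(n_ctrl)
  degree <- as.integer(degree)
  if (n_ctrl < degree + 1L) stop("n_ctrl must be at least degree + 1")
  if (m < n_ctrl) stop("need at least n_ctrl data points")
  tk <- chord_params(points)
  knots <- clamped_knots(n_ctrl, degree)
  A <- splines::splineDesign(knots, tk, ord = degree + 1L)
  M <- crossprod(A)
  R <- tryCatch(chol(M), error = function(e)
    stop("normal equations are rank deficient (duplicate parameters or ",
         "too many control points for the data); reduce n_ctrl"))
  Q <- backsolve(R, forwardsolve(t(R), crossprod(A, points)))
  new_bspline(degree, knots, Q)
}

#' Evaluate a B-spline curve
#'
#' @param curve a `bspline_curve`.
#' @param t numeric vector of parameters in `[0, 1]`.
#' @return numeric matrix of curve points, one row per `t`.
#' @export
eval_bspline <- function(curve, t) {
  t <- pmin(pmax(t, 0), 1)
  B <- splines::splineDesign(curve$knots, t, ord = curve$degree + 1L)
  B %*% curve$control
}

#' Derivative of a B-spline curve
#'
#' The derivative of a degree-`d` B-spline is a degree-`d-1` B-spline with
#' control points `d (Q_{i+1} - Q_i) / (u_{i+d+1} - u_{i+1})` and the first
#' and last knot removed.
#'
#' @param curve a `bspline_curve` of degree at least 1.
#' @return A `bspline_curve` of one lower degree evaluating to `dX/dt`.
#' @export
derivative_curve <- function(curve) {
  d <- curve$degree
  if (d < 1L) stop("cannot differentiate a degree-0 curve")
  n <- nrow(curve$control)
  u <- curve$knots
  denom <- u[seq_len(n - 1L) + d + 1L] - u[seq_len(n - 1L) + 1L]
  if (any(denom == 0)) stop("degenerate knot spacing")
  dq <- d * (curve$control[-1L, , drop = FALSE] -
             curve$control[-n, , drop = FALSE]) / denom
  new_bspline(d - 1L, u[-c(1L, length(u))], dq)
}

# speed |dX/dt| at parameters t, given the precomputed derivative curve
curve_speed <- function(dcurve, t) {
  sqrt(rowSums(eval_bspline(dcurve, t)^2))
}

#' Arc length of a B-spline curve
#'
#' @param curve a `bspline_curve`.
#' @param t1 upper parameter (default 1).
#' @param tol quadrature tolerance in mm.
#' @return numeric arc length from `t = 0` to `t = t1`.
#' @export
arc_length <- function(curve, t1 = 1, tol = 1e-6) {
  dcurve <- derivative_curve(curve)
  integrate(function(tt) curve_speed(dcurve, tt), 0, t1,
            rel.tol = tol, abs.tol = tol,
            subdivisions = 500L)$value
}

#' Slice frames at regular arc-length intervals
#'
#' Places frames (point + unit tangent) at arc lengths `0, h, 2h, ...` up
#' to the total curve length, the endpoint frame included when the length
#' is an exact multiple of the spacing. Arc length is computed by adaptive
#' quadrature of the speed `|dX/dt|`; parameters for intermediate arc
#' lengths are found on a dense cumulative grid refined by root bracketing.
#'
#' @param curve a `bspline_curve`.
#' @param spacing_mm positive slice spacing (mm).
#' @return data.frame with columns `s_mm`, `t`, `x`, `y`, `z`,
#'   `tx`, `ty`, `tz` (unit tangent).
#' @export
sample_slices <- function(curve, spacing_mm = 2) {
  if (spacing_mm <= 0) stop("spacing_mm must be positive")
  dcurve <- derivative_curve(curve)
  total <- arc_length(curve)
  if (total < spacing_mm) {
    warning("curve shorter than slice spacing; returning a single frame")
    s <- 0
  } else {
    s <- spacing_mm * (0:floor(total / spacing_mm + 1e-9))
  }
  # dense cumulative arc length (trapezoid on a fine grid), then refine
  tg <- seq(0, 1, length.out = 2001L)
  sp <- curve_speed(dcurve, tg)
  cs <- c(0, cumsum((sp[-1] + sp[-length(sp)]) / 2 * diff(tg)))
  cs <- cs * (total / cs[length(cs)])
  tt <- vapply(s, function(si) {
    if (si <= 0) return(0)
    if (si >= total) return(1)
    i <- findInterval(si, cs)
    lo <- tg[i]; hi <- tg[min(i + 1L, length(tg))]
    if (hi <= lo) return(lo)
    uniroot(function(u) {
      cs[i] + integrate(function(v) curve_speed(dcurve, v), lo, u,
                        rel.tol = 1e-8, abs.tol = 1e-8)$value - si
    }, c(lo, hi), tol = 1e-10)$root
  }, numeric(1))
  pts <- eval_bspline(curve, tt)
  der <- eval_bspline(dcurve, tt)
  tan <- der / sqrt(rowSums(der^2))
  data.frame(s_mm = s, t = tt,
             x = pts[, 1], y = pts[, 2], z = pts[, 3],
             tx = tan[, 1], ty = tan[, 2], tz = tan[, 3])
}

#' Cut a cross-sectional slab from a bundle
#'
#' Collects the black voxels whose centre lies within half a slab
#' thickness of the frame's cutting plane and that are 26-connected,
#' within the slab, to the voxel containing the frame point (seed search
#' is widened by one voxel to absorb rounding of the frame point onto the
#' grid). The slab thickness equals the largest voxel spacing, so slabs
#' cut at a spacing larger than one voxel never share voxels and folded
#' tract segments crossing the same plane far away are excluded.
#'
#' @param bundle a [binary_volume()].
#' @param frame one row of the data.frame returned by [sample_slices()].
#' @return integer matrix of 0-based voxel index triples (possibly with
#'   zero rows when the plane misses the bundle).
#' @export
cut_cross_section <- function(bundle, frame) {
  thick <- max(bundle$spacing_mm)
  pts <- black_points(bundle)
  if (nrow(pts) == 0L) return(pts)
  ctr <- voxel_centers(bundle, pts)
  p0 <- c(frame$x, frame$y, frame$z)
  tn <- c(frame$tx, frame$ty, frame$tz)
  dist_plane <- abs(as.numeric(sweep(ctr, 2, p0, `-`) %*% tn))
  slab <- which(dist_plane <= thick / 2 + 1e-9)
  if (length(slab) == 0L) return(pts[0, , drop = FALSE])
  sub <- pts[slab, , drop = FALSE]
  # connectivity restricted to the slab
  m <- array(FALSE, dim = bundle$shape)
  m[sub + 1L] <- TRUE
  lab <- cpp_label_components(as.logical(m), as.integer(bundle$shape), 26L)
  lab <- array(lab, dim = bundle$shape)
  seed_vox <- round(p0 / bundle$spacing_mm)
  cheb <- apply(abs(sweep(sub, 2, seed_vox, `-`)), 1, max)
  seeds <- sub[cheb <= 1, , drop = FALSE]
  if (nrow(seeds) == 0L) return(pts[0, , drop = FALSE])
  keep_labs <- unique(lab[seeds + 1L])
  sub[lab[sub + 1L] %in% keep_labs, , drop = FALSE]
}

#' Serialize a B-spline curve to JSON
#'
#' @param curve a `bspline_curve`.
#' @param path optional file to write to.
#' @return JSON string (invisibly when written to a file).
#' @export
bspline_to_json <- function(curve, path = NULL) {
  js <- jsonlite::toJSON(list(degree = curve$degree, knots = curve$knots,
                              control = curve$control),
                         digits = NA, auto_unbox = TRUE)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}

#' @rdname bspline_to_json
#' @param json JSON string or file path produced by [bspline_to_json()].
#' @export
bspline_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  new_bspline(x$degree, x$knots, x$control)
}
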