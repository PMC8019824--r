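#' Confidence ellipse about the mean axis of a Bingham fit
#'
#' The large-sample confidence region for the mean axis of a fitted
#' Bingham distribution is an ellipse on the sphere around the leading
#' axis `mu_1`, with angular semi-axes
#' `e_m = sqrt( chi2_{1-alpha, 2} / (2 N (kappa_1 - kappa_m)(w_1 - w_m)) )`
#' toward `mu_m` (`m = 2, 3`), where `w` are the scatter-matrix
#' eigenvalues of the fitted sample and `N` its size. A larger
#' concentration gap toward an axis tightens the ellipse in that
#' direction, so the region is elongated toward the axis of weaker
#' concentration.
#'
#' @param model a fitted `bingham_model` (needs `scatter` and `n_fit`).
#' @param alpha error rate of the region (default 0.01 for a 99% region).
#' @return An `ellipse_ci`: list with `mean_axis`, `semi_axis_dirs`
#'   (columns toward `mu_2`, `mu_3`), `e2`, `e3` (angular semi-axes,
#'   radians) and `alpha`.
#' @export
confidence_ellipse <- function(model, alpha = 0.01) {
  if (!inherits(model, "bingham_model")) stop("need a bingham_model")
  if (is.null(model$scatter)) stop("model carries no sample scatter")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  N <- model$n_fit
  w <- model$scatter$values
  kap <- model$kappas
  d2 <- (kap[1] - kap[2]) * (w[1] - w[2])
  d3 <- (kap[1] - kap[3]) * (w[1] - w[3])
  if (d2 <= 0 || d3 <= 0) stop("ellipse undefined: degenerate spectrum")
  x2 <- qchisq(1 - alpha, df = 2)
  structure(list(
    mean_axis = model$U[, 1],
    semi_axis_dirs = model$U[, 2:3, drop = FALSE],
    e2 = sqrt(x2 / (2 * N * d2)),
    e3 = sqrt(x2 / (2 * N * d3)),
    alpha = alpha
  ), class = "ellipse_ci")
}

#' @export
print.ellipse_ci <- function(x, ...) {
  cat(sprintf(
    "<ellipse_ci alpha = %g, semi-axes %.3f / %.3f deg>\n",
    x$alpha, x$e2 * 180 / pi, x$e3 * 180 / pi))
  invisible(x)
}

# angular radius of the ellipse along the tangent direction whose
# components on (dir2, dir3) are (c2, c3); standard polar form of an
# ellipse with semi-axes e2, e3
ellipse_radius_toward <- function(ci, c2, c3) {
  nrm <- sqrt(c2^2 + c3^2)
  if (nrm < 1e-15) return(max(ci$e2, ci$e3))
  c2 <- c2 / nrm; c3 <- c3 / nrm
  1 / sqrt((c2 / ci$e2)^2 + (c3 / ci$e3)^2)
}

#' Does a confidence ellipse contain a given axis?
#'
#' @param ci an `ellipse_ci`.
#' @param axis unit 3-vector (axial: the sign is ignored).
#' @return logical.
#' @export
ellipse_contains <- function(ci, axis) {
  axis <- axis / sqrt(sum(axis^2))
  if (sum(axis * ci$mean_axis) < 0) axis <- -axis
  psi <- acos(min(1, max(-1, sum(axis * ci$mean_axis))))
  if (psi == 0) return(TRUE)
  tang <- axis - sum(axis * ci$mean_axis) * ci$mean_axis
  tang <- tang / sqrt(sum(tang^2))
  a2 <- psi * sum(tang * ci$semi_axis_dirs[, 1])
  a3 <- psi * sum(tang * ci$semi_axis_dirs[, 2])
  (a2 / ci$e2)^2 + (a3 / ci$e3)^2 <= 1
}

#' Two-group mean-axis separation test
#'
#' Separated-cones criterion: the groups differ when the angular
#' separation between the two fitted mean axes (taken in `[0, pi/2]` by
#' antipodal symmetry) exceeds the sum of the two ellipse radii measured
#' along the great circle joining the means. Overlapping cones indicate
#' an insignificant difference.
#'
#' @param a,b `ellipse_ci` objects at the same alpha.
#' @return logical: `TRUE` when the groups are significantly different.
#' @export
groups_differ <- function(a, b) {
  if (abs(a$alpha - b$alpha) > 1e-12)
    stop("ellipses must share the same alpha")
  ma <- a$mean_axis; mb <- b$mean_axis
  if (sum(ma * mb) < 0) mb <- -mb
  dot <- min(1, max(-1, sum(ma * mb)))
  psi <- acos(dot)
  if (psi == 0) return(FALSE)
  ta <- mb - dot * ma; ta <- ta / sqrt(sum(ta^2))
  tb <- ma - dot * mb; tb <- tb / sqrt(sum(tb^2))
  ra <- ellipse_radius_toward(a, sum(ta * a$semi_axis_dirs[, 1]),
                              sum(ta * a$semi_axis_dirs[, 2]))
  rb <- ellipse_radius_toward(b, sum(tb * b$semi_axis_dirs[, 1]),
                              sum(tb * b$semi_axis_dirs[, 2]))
  psi > ra + rb
}
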