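#' Canonicalize axial data
#'
#' Axial observations (principal diffusion directions) identify `x` with
#' `-x`. `axial_sample` normalises each vector to unit length and fixes
#' the antipodal representative so that the first nonzero coordinate is
#' positive, making downstream summaries sign-deterministic.
#'
#' @param x numeric matrix with one 3-vector per row (or a single vector).
#' @return An object of class `axial_sample`: a unit-row matrix with the
#'   canonical hemisphere convention applied.
#' @export
axial_sample <- function(x) {
  x <- rbind(x)
  storage.mode(x) <- "double"
  if (ncol(x) != 3L) stop("expected 3-vectors")
  nrm <- sqrt(rowSums(x^2))
  if (any(!is.finite(nrm)) || any(nrm == 0)) stop("zero or non-finite vector")
  x <- x / nrm
  x <- canonical_signs(x)
  structure(x, class = c("axial_sample", "matrix", "array"))
}

# flip rows so the first coordinate that is nonzero (|.| > tol) is positive
canonical_signs <- function(x, tol = 1e-12) {
  s <- sign(x[, 1])
  z1 <- abs(x[, 1]) <= tol
  s[z1] <- sign(x[z1, 2])
  z2 <- z1 & abs(x[, 2]) <= tol
  s[z2] <- sign(x[z2, 3])
  s[s == 0] <- 1
  x * s
}

#' @export
print.axial_sample <- function(x, ...) {
  cat(sprintf("<axial_sample, n = %d>\n", nrow(x)))
  invisible(x)
}

#' Scatter (orientation) matrix of an axial sample
#'
#' Computes `T = (1/n) sum_i x_i x_i'` together with its descending
#' eigendecomposition. Eigenvector signs are fixed (first nonzero
#' component positive) so the decomposition is deterministic.
#'
#' @param s an [axial_sample()] (or a unit-row matrix).
#' @return list with `T` (3x3), `values` (descending eigenvalues, sum 1)
#'   and `vectors` (orthonormal columns matching `values`).
#' @export
scatter_matrix <- function(s) {
  s <- rbind(s)
  T <- crossprod(s) / nrow(s)
  e <- eigen(T, symmetric = TRUE)
  v <- t(canonical_signs(t(e$vectors)))
  list(T = T, values = e$values, vectors = v)
}

# rotation matrix sending unit vector a to unit vector b (Rodrigues)
rotation_between <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  v <- c(a[2] * b[3] - a[3] * b[2],
         a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  c_ <- sum(a * b)
  if (c_ < -1 + 1e-12) {
    # antipodal: rotate pi about any axis orthogonal to a
    axis <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    axis <- axis - sum(axis * a) * a
    axis <- axis / sqrt(sum(axis^2))
    return(rotation_about(axis, pi))
  }
  V <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + V + V %*% V / (1 + c_)
}

# rotation by angle theta about unit axis u
rotation_about <- function(u, theta) {
  u <- u / sqrt(sum(u^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

# deterministic orthonormal basis (b1, b2) completing unit vector u
orthonormal_complement <- function(u) {
  u <- u / sqrt(sum(u^2))
  a <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  b1 <- a - sum(a * u) * u
  b1 <- b1 / sqrt(sum(b1^2))
  b2 <- c(u[2] * b1[3] - u[3] * b1[2],
          u[3] * b1[1] - u[1] * b1[3],
          u[1] * b1[2] - u[2] * b1[1])
  cbind(b1, b2)
}
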