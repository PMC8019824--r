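#' Kummer's confluent hypergeometric function M(a, b, x)
#'
#' Direct Taylor series with term recurrence for `x >= 0`; for negative
#' arguments the Kummer transformation `M(a, b, x) = exp(x) M(b-a, b, -x)`
#' keeps every term of the sum positive, avoiding cancellation. Arguments
#' with `x > 700` would overflow the double exponential range and raise an
#' error.
#'
#' @param a,b function parameters; `b` must not be a nonpositive integer.
#' @param x real argument (vectorised).
#' @param tol relative tolerance of the series.
#' @return numeric vector of `M(a, b, x)` values.
#' @export
kummer_M <- function(a, b, x, tol = 1e-12) {
  if (b <= 0 && b == round(b)) stop("b must not be a nonpositive integer")
  vapply(x, function(xi) {
    if (!is.finite(xi)) stop("x must be finite")
    if (xi > 700)
      stop(sprintf("kummer_M overflow: exp(%g) exceeds double range", xi))
    if (xi < 0) return(exp(xi) * kummer_M(b - a, b, -xi, tol))
    term <- 1; acc <- 1
    for (n in 0:10000) {
      term <- term * (a + n) / (b + n) * xi / (n + 1)
      acc <- acc + term
      if (abs(term) < tol * abs(acc) && n > xi) return(acc)
    }
    stop("kummer_M series did not converge")
  }, numeric(1))
}

# log M(1/2, 3/2, kappa), stable for large positive kappa through the
# integral representation M(1/2, 3/2, k) = int_0^1 exp(k t^2) dt
log_M_half <- function(kappa) {
  vapply(kappa, function(k) {
    if (k <= 500) log(kummer_M(0.5, 1.5, k))
    else k + log(integrate(function(t) exp(k * (t^2 - 1)), 0, 1,
                           rel.tol = 1e-12)$value)
  }, numeric(1))
}

#' Watson moment function D3 and its inverse
#'
#' `watson_D3(kappa)` is the logarithmic derivative of
#' `M(1/2, 3/2, kappa)`: the expected squared cosine between a Watson
#' axis and its mean axis. It increases strictly from 0 (kappa -> -Inf)
#' through 1/3 at kappa = 0 towards 1 (kappa -> +Inf). Computed as the
#' Kummer ratio `M(3/2, 5/2, k) / (3 M(1/2, 3/2, k))` for moderate
#' arguments and through a stable scaled integral representation
#' elsewhere.
#'
#' @param kappa concentration (vectorised).
#' @return numeric vector of moments in (0, 1).
#' @export
watson_D3 <- function(kappa) {
  vapply(kappa, function(k) {
    if (abs(k) <= 500) {
      kummer_M(1.5, 2.5, k) / (3 * kummer_M(0.5, 1.5, k))
    } else {
      # E[t^2] under density on [0,1] proportional to exp(k t^2),
      # integrands scaled by the max of the exponent
      f_num <- function(t) t^2 * exp(k * (t^2 - (k > 0)))
      f_den <- function(t) exp(k * (t^2 - (k > 0)))
      integrate(f_num, 0, 1, rel.tol = 1e-10)$value /
        integrate(f_den, 0, 1, rel.tol = 1e-10)$value
    }
  }, numeric(1))
}

# derivative of D3: Var of t^2 = M''/M - (M'/M)^2 with
# M'' = (3/8)/(15/8) ... for a = 1/2, b = 3/2: a(a+1)/(b(b+1)) = 1/5
watson_D3_prime <- function(kappa) {
  vapply(kappa, function(k) {
    if (abs(k) <= 500) {
      m0 <- kummer_M(0.5, 1.5, k)
      d <- kummer_M(1.5, 2.5, k) / (3 * m0)
      kummer_M(2.5, 3.5, k) / (5 * m0) - d^2
    } else {
      f <- function(p) {
        integrate(function(t) t^p * exp(k * (t^2 - (k > 0))), 0, 1,
                  rel.tol = 1e-10)$value
      }
      den <- f(0)
      f(4) / den - (f(2) / den)^2
    }
  }, numeric(1))
}

# circular (2D axial) moment function D2(k) = d/dk log M(1/2, 1, k) and
# its inverse on the girdle branch (r <= 1/2 -> kappa <= 0)
circular_D2 <- function(kappa) {
  vapply(kappa, function(k) {
    kummer_M(1.5, 2, k) / (2 * kummer_M(0.5, 1, k))
  }, numeric(1))
}

circular_kappa_solve <- function(r, kappa_max = 700) {
  r <- min(max(r, 1e-12), 0.5)
  if (r >= 0.5) return(0)
  if (circular_D2(-kappa_max) >= r) {
    warning("concentration capped at -kappa_max")
    return(-kappa_max)
  }
  uniroot(function(k) circular_D2(k) - r, c(-kappa_max, 0),
          tol = 1e-10)$root
}

#' Invert the Watson moment function
#'
#' Solves `watson_D3(kappa) = r` for `kappa` by Newton-Raphson with a
#' maintained bracket (bisection fallback). Values of `r` so close to the
#' degenerate limits that the solution would exceed `kappa_max` in
#' magnitude are capped with a warning.
#'
#' @param r target moment in (0, 1).
#' @param tol convergence tolerance on `r`.
#' @param max_iter iteration cap.
#' @param kappa_max magnitude cap (default 700, the double-exponential
#'   overflow guard).
#' @return numeric kappa.
#' @export
watson_kappa_solve <- function(r, tol = 1e-8, max_iter = 100L,
                               kappa_max = 700) {
  if (!is.finite(r) || r <= 0 || r >= 1) stop("moment must be in (0, 1)")
  if (watson_D3(kappa_max) <= r) {
    warning("concentration capped at +kappa_max")
    return(kappa_max)
  }
  if (watson_D3(-kappa_max) >= r) {
    warning("concentration capped at -kappa_max")
    return(-kappa_max)
  }
  lo <- -kappa_max; hi <- kappa_max
  k <- 0
  for (it in seq_len(max_iter)) {
    f <- watson_D3(k) - r
    if (abs(f) < tol) return(k)
    if (f > 0) hi <- k else lo <- k
    dk <- f / watson_D3_prime(k)
    k_new <- k - dk
    if (!is.finite(k_new) || k_new <= lo || k_new >= hi)
      k_new <- (lo + hi) / 2
    k <- k_new
  }
  stop(sprintf("watson_kappa_solve did not converge; bracket [%g, %g]",
               lo, hi))
}
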