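#' Watson axial distribution: maximum-likelihood fit
#'
#' The Watson density on the sphere is
#' `W(x; mu, kappa) = c(kappa) exp(kappa (mu' x)^2)` with
#' `c(kappa) = Gamma(3/2) / (2 pi^{3/2} M(1/2, 3/2, kappa))`. The MLE of
#' the mean axis is the leading scatter eigenvector for a bipolar sample
#' (largest eigenvalue above 1/2) and the trailing eigenvector for a
#' girdle sample; the concentration solves `D3(kappa) = mu' T mu` by
#' Newton-Raphson (see [watson_kappa_solve()]).
#'
#' @param s an [axial_sample()] with at least 3 observations.
#' @param case `"auto"` picks bipolar when the leading scatter eigenvalue
#'   exceeds 1/2 and girdle otherwise; `"bipolar"` or `"girdle"` force
#'   the branch (useful to test how badly a bipolar model fits girdle
#'   data).
#' @return A `watson_model` with fields `mu` (unit mean axis), `kappa`,
#'   `n_fit` and `scatter` (the eigen-decomposed scatter matrix).
#' @export
watson_mle <- function(s, case = c("auto", "bipolar", "girdle")) {
  case <- match.arg(case)
  s <- axial_sample(s)
  if (nrow(s) < 3L) stop("need at least 3 axes")
  sc <- scatter_matrix(s)
  bipolar <- switch(case, auto = sc$values[1] > 0.5,
                    bipolar = TRUE, girdle = FALSE)
  mu <- if (bipolar) sc$vectors[, 1] else sc$vectors[, 3]
  r <- as.numeric(t(mu) %*% sc$T %*% mu)
  r <- min(max(r, 1e-12), 1 - 1e-12)
  kappa <- watson_kappa_solve(r)
  structure(list(mu = mu, kappa = kappa, n_fit = nrow(s), scatter = sc),
            class = "watson_model")
}

#' @export
print.watson_model <- function(x, ...) {
  cat(sprintf("<watson_model kappa = %.3f (%s), n = %d>\n", x$kappa,
              if (x$kappa >= 0) "bipolar" else "girdle", x$n_fit))
  invisible(x)
}

#' Watson log density
#'
#' @param x unit 3-vector or matrix of unit rows.
#' @param model a `watson_model` (or a list with `mu` and `kappa`).
#' @return numeric log densities on the unit sphere.
#' @export
watson_logpdf <- function(x, model) {
  x <- rbind(x)
  log_c <- lgamma(1.5) - log(2) - 1.5 * log(pi) - log_M_half(model$kappa)
  as.numeric(log_c + model$kappa * (x %*% model$mu)^2)
}
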