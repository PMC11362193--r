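#' Disattenuate a correlation matrix for measurement error
#'
#' Measurement error shrinks observed trait correlations toward zero. Under
#' classical test theory the true-score correlation is recovered by dividing
#' each observed correlation by the geometric mean of the two traits'
#' reliabilities: `r*_ij = r_ij / sqrt(rel_i * rel_j)`. Corrected entries are
#' clipped to `[-1, 1]` and, if the result is no longer positive
#' semi-definite, projected to the nearest correlation matrix by flooring
#' eigenvalues at `1e-8` and renormalizing the diagonal.
#'
#' @param R_obs Observed correlation matrix (symmetric, unit diagonal).
#' @param reliabilities Numeric vector in (0, 1], one entry per trait.
#' @return A valid correlation matrix of the same dimension.
#' @export
disattenuate_correlation <- function(R_obs, reliabilities) {
  p <- ncol(R_obs)
  rel <- as.numeric(reliabilities)
  if (length(rel) != p) abort("One reliability per trait is required.")
  if (any(!is.finite(rel) | rel <= 0 | rel > 1)) {
    abort("Reliabilities must lie in (0, 1].")
  }
  scale <- 1 / sqrt(rel)
  R_star <- R_obs * tcrossprod(scale)
  R_star <- pmin(pmax(R_star, -1), 1)
  diag(R_star) <- 1
  R_star <- (R_star + t(R_star)) / 2
  nearest_correlation(R_star)
}

# eigenvalue floor + diagonal renormalization; identity on PSD input
nearest_correlation <- function(R, floor = 1e-8) {
  e <- eigen(R, symmetric = TRUE)
  if (min(e$values) >= floor) return(R)
  vals <- pmax(e$values, floor)
  R2 <- e$vectors %*% diag(vals, nrow = length(vals)) %*% t(e$vectors)
  d <- sqrt(diag(R2))
  R2 <- R2 / tcrossprod(d)
  diag(R2) <- 1
  (R2 + t(R2)) / 2
}

#' Correct a standardized data matrix for measurement error
#'
#' A data-matrix analogue of correlation disattenuation: the within-sex
#' deviations of the standardized data are rotated by
#' `R_obs^(-1/2) R*^(1/2)` (symmetric matrix square roots), so that the
#' pooled within-sex correlation of the output equals the disattenuated
#' target `R*` exactly, and then shrunk per trait by `sqrt(rel_j)` so each
#' trait's pooled within-sex variance equals its true-score variance
#' `rel_j`. Sex-mean differences are left untouched in trait units, so
#' refitting on the corrected data yields larger standardized sex
#' differences and a larger Mahalanobis distance between centroids — the
#' expected effect of removing attenuation. The transform reduces to the
#' identity when every reliability is 1.
#'
#' @param z N x p matrix of standardized observed scores (from
#'   [standardize()]: pooled within-sex variance 1 per column).
#' @param sex Length-N factor with levels `female`, `male`, aligned with the
#'   rows of `z`.
#' @param reliabilities Numeric vector in (0, 1], one entry per trait (named
#'   or in column order).
#' @return The corrected N x p matrix.
#' @export
dmd_transform <- function(z, sex, reliabilities) {
  z <- as.matrix(z)
  p <- ncol(z)
  if (nrow(z) <= p) {
    warn("Fewer observations than traits + 1; the corrected correlation target is poorly determined.")
  }
  rel <- as.numeric(reliabilities)
  if (length(rel) != p || any(!is.finite(rel) | rel <= 0 | rel > 1)) {
    abort("Reliabilities must lie in (0, 1] with one entry per trait.")
  }

  mu_m <- colMeans(z[sex == "male", , drop = FALSE])
  mu_f <- colMeans(z[sex == "female", , drop = FALSE])
  dev <- z
  dev[sex == "male", ] <- sweep(z[sex == "male", , drop = FALSE], 2, mu_m)
  dev[sex == "female", ] <- sweep(z[sex == "female", , drop = FALSE], 2, mu_f)

  n <- nrow(z)
  R_obs <- crossprod(dev) / (n - 2)
  R_obs <- (R_obs + t(R_obs)) / 2
  D <- sqrt(diag(R_obs))
  R_obs <- R_obs / tcrossprod(D); diag(R_obs) <- 1
  dev <- sweep(dev, 2, D, "/")

  R_star <- disattenuate_correlation(R_obs, rel)
  Tmat <- matrix_sqrt(R_obs, inverse = TRUE) %*% matrix_sqrt(R_star)
  dev_c <- dev %*% Tmat
  dev_c <- sweep(dev_c, 2, D * sqrt(rel), "*")

  out <- dev_c
  out[sex == "male", ] <- sweep(dev_c[sex == "male", , drop = FALSE], 2, mu_m, "+")
  out[sex == "female", ] <- sweep(dev_c[sex == "female", , drop = FALSE], 2, mu_f, "+")
  dimnames(out) <- dimnames(z)
  out
}

matrix_sqrt <- function(S, inverse = FALSE, tol = 1e-10) {
  e <- eigen(S, symmetric = TRUE)
  if (min(e$values) < tol) {
    if (inverse) abort("Matrix is numerically singular; cannot form inverse square root.")
    e$values <- pmax(e$values, tol)
  }
  pow <- if (inverse) -0.5 else 0.5
  e$vectors %*% diag(e$values^pow, nrow = length(e$values)) %*% t(e$vectors)
}
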