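#' Standardize trait profiles to the pooled within-sex z-space
#'
#' All index equations operate in a common z-space: each trait is centered on
#' the unweighted mean of the male and female trait means (the centroid
#' midpoint, *not* the grand mean — the two differ when group sizes are
#' unequal) and divided by its pooled within-sex standard deviation. In this
#' space the male and female centroids sit at +d/2 and -d/2, where d is the
#' vector of Cohen's d values, and both classification and directional
#' boundaries pass through the origin under equal priors.
#'
#' The pooled SD uses the two-group formula with denominator
#' `n_male + n_female - 2`.
#'
#' @param profiles An [mf_profiles()] table.
#' @return A list with components
#'   \describe{
#'     \item{std}{the standardization model: `pooled_sd`, `mean_male`,
#'       `mean_female`, `midpoint` (named length-p vectors) and `traits`.}
#'     \item{z}{the N x p matrix of standardized scores.}
#'     \item{sex}{the sex factor, aligned with the rows of `z`.}
#'   }
#' @export
standardize <- function(profiles) {
  stopifnot(inherits(profiles, "mf_profiles"))
  x <- trait_matrix(profiles)
  sex <- profiles$sex
  n_m <- sum(sex == "male")
  n_f <- sum(sex == "female")
  if (n_m < 2L || n_f < 2L) {
    abort("At least 2 individuals per sex are required to pool SDs.")
  }

  mean_male   <- colMeans(x[sex == "male", , drop = FALSE])
  mean_female <- colMeans(x[sex == "female", , drop = FALSE])
  midpoint <- (mean_male + mean_female) / 2

  ss_m <- colSums(sweep(x[sex == "male", , drop = FALSE], 2, mean_male)^2)
  ss_f <- colSums(sweep(x[sex == "female", , drop = FALSE], 2, mean_female)^2)
  pooled_sd <- sqrt((ss_m + ss_f) / (n_m + n_f - 2))

  if (any(pooled_sd <= 0 | !is.finite(pooled_sd))) {
    bad <- trait_names(profiles)[pooled_sd <= 0 | !is.finite(pooled_sd)]
    abort(paste0("Constant trait(s) with zero pooled within-sex SD: ",
                 paste(bad, collapse = ", "),
                 ". Remove them before fitting."))
  }

  z <- sweep(sweep(x, 2, midpoint), 2, pooled_sd, "/")
  std <- list(pooled_sd = pooled_sd, mean_male = mean_male,
              mean_female = mean_female, midpoint = midpoint,
              traits = trait_names(profiles))
  list(std = std, z = z, sex = sex)
}

#' Per-trait sex differences and the pooled within-sex correlation matrix
#'
#' Summarizes the sex difference structure of a standardized sample:
#' Cohen's d per trait (positive = higher male mean), its Euclidean norm
#' (the standardized Euclidean distance between centroids), and the pooled
#' within-sex correlation matrix R. R is computed by centering each sex at
#' its own mean, concatenating the residuals, and taking the cross-product
#' with denominator `n - 2`; because the z columns have pooled within-sex
#' variance exactly 1 this matrix has an exactly unit diagonal.
#'
#' @param std_out The list returned by [standardize()].
#' @return A list with `d`, `d_norm`, `R`, `n_male`, `n_female`, and
#'   `singular` (logical: is R numerically singular, condition number
#'   > 1e10).
#' @export
effect_summary <- function(std_out) {
  z <- std_out$z
  sex <- std_out$sex
  std <- std_out$std
  d <- (std$mean_male - std$mean_female) / std$pooled_sd
  names(d) <- std$traits

  resid <- z
  resid[sex == "male", ] <-
    sweep(z[sex == "male", , drop = FALSE], 2,
          colMeans(z[sex == "male", , drop = FALSE]))
  resid[sex == "female", ] <-
    sweep(z[sex == "female", , drop = FALSE], 2,
          colMeans(z[sex == "female", , drop = FALSE]))
  n <- nrow(z)
  R <- crossprod(resid) / (n - 2)
  # guard tiny asymmetries from floating point
  R <- (R + t(R)) / 2
  dimnames(R) <- list(std$traits, std$traits)

  kappa_R <- tryCatch(kappa(R, exact = ncol(R) <= 50), error = function(e) Inf)
  list(d = d, d_norm = sqrt(sum(d^2)), R = R,
       n_male = sum(sex == "male"), n_female = sum(sex == "female"),
       singular = !is.finite(kappa_R) || kappa_R > 1e10)
}
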