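#' Fit a masculinity-femininity scoring model
#'
#' Estimates everything the four M-F indices need from a sample of trait
#' profiles: the standardization model (pooled within-sex SDs and the centroid
#' midpoint), the Cohen's d vector, the pooled within-sex correlation matrix
#' R, the discriminant coefficients `a = R^-1 d`, and the Mahalanobis distance
#' between the sex centroids `D_M = sqrt(d' R^-1 d)` together with its
#' small-sample bias-corrected counterpart `D_Mu`.
#'
#' With `method = "lda"` the discriminant direction comes from the closed-form
#' linear discriminant solution under equal within-sex covariance matrices.
#' With `method = "logistic"` a logistic regression of sex on the standardized
#' traits is fitted by maximum likelihood; its un-normalized linear predictor
#' replaces the discriminant score in the probability index, and is rescaled
#' to unit pooled within-sex variance for the typicality index. The two
#' methods are structurally equivalent but logistic regression does not assume
#' multivariate normality.
#'
#' If per-trait `reliabilities` are supplied, the standardized data are first
#' corrected for measurement error by data-matrix disattenuation
#' (see [dmd_transform()]) and the model is fitted on the corrected data.
#'
#' @param profiles An [mf_profiles()] table.
#' @param method `"lda"` (default) or `"logistic"`.
#' @param reliabilities Optional numeric vector of per-trait reliabilities in
#'   (0, 1], either unnamed (in trait order) or named by trait.
#' @return An object of class `mf_model`.
#' @seealso [mf_scores()], [tidy.mf_model()], [glance.mf_model()]
#' @examples
#' prof <- simulate_population(diag(2), d_true = c(0.8, -0.4), n = 200)
#' fit <- fit_mf(prof)
#' glance(fit)
#' @export
fit_mf <- function(profiles, method = c("lda", "logistic"),
                   reliabilities = NULL) {
  method <- match.arg(method)
  s <- standardize(profiles)
  correction <- NULL

  if (!is.null(reliabilities)) {
    rel <- check_reliabilities(reliabilities, s$std$traits)
    z_corr <- dmd_transform(s$z, s$sex, rel)
    # refit the z-space on the corrected data: within-sex spread is now
    # sqrt(rel), so Cohen's d and D_M grow relative to the raw fit
    corr_prof <- mf_profiles(
      data.frame(sex = s$sex, z_corr, check.names = FALSE),
      sex = "sex", traits = s$std$traits, male = "male", female = "female")
    corr_prof$id <- profiles$id
    s_outer <- s
    s <- standardize(corr_prof)
    correction <- list(reliabilities = rel, outer_std = s_outer$std)
  }

  eff <- effect_summary(s)
  if (eff$singular) {
    abort(paste0(
      "Pooled within-sex correlation matrix is singular or near-singular ",
      "(condition number > 1e10). Reduce or aggregate collinear traits ",
      "before fitting."))
  }
  a <- drop(solve(eff$R, eff$d))
  names(a) <- s$std$traits
  DM2 <- sum(eff$d * a)
  D_M <- sqrt(DM2)

  logistic <- NULL
  if (method == "logistic") {
    df <- data.frame(.y = as.integer(s$sex == "male"), s$z,
                     check.names = FALSE)
    fml <- stats::as.formula(paste(
      ".y ~", paste(sprintf("`%s`", s$std$traits), collapse = " + ")))
    fit <- suppressWarnings(glm(fml, family = binomial(), data = df))
    b <- coef(fit)
    logistic <- list(intercept = unname(b[1L]), slopes = unname(b[-1L]),
                     converged = fit$converged)
    if (!fit$converged || any(!is.finite(b))) {
      warn("Logistic fit did not converge (possibly separable data); scores may saturate.")
    }
  }

  structure(list(
    std = s$std, eff = eff, a = a,
    D_M = D_M,
    D_Mu = unbiased_DM(D_M, p = length(a),
                       n_male = eff$n_male, n_female = eff$n_female),
    method = method, logistic = logistic,
    correction = correction,
    z = s$z, sex = s$sex, id = profiles$id
  ), class = "mf_model")
}

check_reliabilities <- function(rel, traits) {
  if (!is.null(names(rel)) && all(nzchar(names(rel)))) {
    missing <- setdiff(traits, names(rel))
    if (length(missing) > 0L) {
      abort(paste0("Missing reliabilities for trait(s): ",
                   paste(missing, collapse = ", ")))
    }
    rel <- rel[traits]
  }
  if (length(rel) != length(traits)) {
    abort(sprintf("Expected %d reliabilities, got %d.",
                  length(traits), length(rel)))
  }
  if (any(!is.finite(rel) | rel <= 0 | rel > 1)) {
    abort("Reliabilities must lie in (0, 1].")
  }
  setNames(as.numeric(rel), traits)
}

#' Mahalanobis distance between sex centroids, with bias correction
#'
#' `D_M = sqrt(d' R^-1 d)` overestimates the population centroid separation
#' in finite samples. The corrected value applies the standard unbiased
#' estimator of the squared distance,
#' `D_Mu^2 = ((n - p - 3)/(n - 2)) D_M^2 - p (1/n_male + 1/n_female)`,
#' floored at zero before the square root.
#'
#' @param eff An effect summary from [effect_summary()], or an `mf_model`.
#' @return Named numeric vector `c(D_M, D_Mu)`.
#' @export
mahalanobis_centroid_distance <- function(eff) {
  if (inherits(eff, "mf_model")) {
    return(c(D_M = eff$D_M, D_Mu = eff$D_Mu))
  }
  a <- drop(solve(eff$R, eff$d))
  D_M <- sqrt(sum(eff$d * a))
  c(D_M = D_M,
    D_Mu = unbiased_DM(D_M, p = length(eff$d),
                       n_male = eff$n_male, n_female = eff$n_female))
}

unbiased_DM <- function(D_M, p, n_male, n_female) {
  n <- n_male + n_female
  sq <- ((n - p - 3) / (n - 2)) * D_M^2 - p * (1 / n_male + 1 / n_female)
  sqrt(max(0, sq))
}

#' Angle between the centroid and discriminant axes
#'
#' The centroid axis (direction of the Cohen's d vector) and the discriminant
#' axis (direction of `a = R^-1 d`) coincide when traits are uncorrelated and
#' diverge as trait correlations grow. A wider angle means a weaker
#' correlation between sex-directionality and sex-typicality scores, and a
#' larger expected share of discordant profiles.
#'
#' @param model An `mf_model` fitted with `method = "lda"`.
#' @return The angle in degrees, in `[0, 90]`.
#' @export
axis_angle <- function(model) {
  stopifnot(inherits(model, "mf_model"))
  d <- model$eff$d
  a <- model$a
  nd <- sqrt(sum(d^2)); na <- sqrt(sum(a^2))
  if (nd == 0 || na == 0) abort("Zero-length axis: no sex difference to orient on.")
  cosang <- sum(d * a) / (nd * na)
  acos(min(1, max(-1, cosang))) * 180 / pi
}

#' @export
print.mf_model <- function(x, ...) {
  cat(sprintf("<mf_model> %s fit: %d traits, %d males, %d females\n",
              x$method, length(x$a), x$eff$n_male, x$eff$n_female))
  cat(sprintf("  ||d|| = %.3f, D_M = %.3f, D_Mu = %.3f, axis angle = %.1f deg\n",
              x$eff$d_norm, x$D_M, x$D_Mu, axis_angle(x)))
  if (!is.null(x$correction)) {
    cat("  fitted on DMD-corrected data\n")
  }
  invisible(x)
}

#' Tidy per-trait summary of a fitted M-F model
#'
#' @param x An `mf_model`.
#' @param ... Unused.
#' @return A tibble with one row per trait: Cohen's `d`, discriminant
#'   coefficient `a`, pooled within-sex SD, and the sex means.
#' @method tidy mf_model
#' @export
tidy.mf_model <- function(x, ...) {
  tibble::tibble(
    trait = x$std$traits,
    d = unname(x$eff$d),
    coefficient = unname(x$a),
    pooled_sd = unname(x$std$pooled_sd),
    mean_male = unname(x$std$mean_male),
    mean_female = unname(x$std$mean_female)
  )
}

#' One-row summary of a fitted M-F model
#'
#' @param x An `mf_model`.
#' @param ... Unused.
#' @return A one-row tibble: group sizes, trait count, `d_norm` (standardized
#'   Euclidean centroid distance), `D_M`, `D_Mu`, the centroid/discriminant
#'   axis angle, and the fitting method.
#' @method glance mf_model
#' @export
glance.mf_model <- function(x, ...) {
  tibble::tibble(
    n_male = x$eff$n_male,
    n_female = x$eff$n_female,
    p = length(x$a),
    d_norm = x$eff$d_norm,
    D_M = x$D_M,
    D_Mu = x$D_Mu,
    axis_angle = axis_angle(x),
    method = x$method,
    corrected = !is.null(x$correction)
  )
}
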