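#' Draw a random correlation matrix with the vine method
#'
#' C-vine construction: partial correlations are drawn independently as
#' `2 * Beta(beta, beta) - 1` and composed layer by layer into a full
#' correlation matrix, which is valid (symmetric, unit diagonal, positive
#' definite) by construction. Larger `beta` concentrates the partials — and
#' hence the resulting correlations — around zero; `beta = 4` gives mean
#' absolute off-diagonal correlations around .20–.25 for 5 to 30 traits,
#' a realistic level for batteries of psychological or morphological traits.
#'
#' @param p Number of traits (>= 2).
#' @param beta Shape parameter of the symmetric Beta distribution (> 0).
#' @return A p x p correlation matrix.
#' @examples
#' set.seed(1)
#' R <- sample_vine_correlation(5, beta = 4)
#' eigen(R, only.values = TRUE)$values
#' @export
sample_vine_correlation <- function(p, beta = 4) {
  stopifnot(p >= 2, beta > 0)
  P <- matrix(0, p, p)   # partial correlations, layer k in row k
  R <- diag(p)
  for (k in seq_len(p - 1)) {
    for (i in seq(k + 1, p)) {
      P[k, i] <- 2 * rbeta(1, beta, beta) - 1
      rho <- P[k, i]
      if (k > 1) {
        for (l in seq(k - 1, 1)) {
          rho <- rho * sqrt((1 - P[l, i]^2) * (1 - P[l, k]^2)) + P[l, i] * P[l, k]
        }
      }
      R[k, i] <- R[i, k] <- rho
    }
  }
  R
}

#' Simulate a two-sex multivariate-normal trait sample
#'
#' Generates error-free ("true score") profiles in standardized units: males
#' are drawn from `MVN(+d/2, R)` and females from `MVN(-d/2, R)`, so each
#' trait has unit within-sex variance, population Cohen's d equal to
#' `d_true`, and population centroid distance `sqrt(d' R^-1 d)`. Group sizes
#' follow `prop_female` deterministically (females first, `round(n *
#' prop_female)` of them).
#'
#' @param R_true Within-sex correlation matrix (positive definite).
#' @param d_true Length-p vector of population Cohen's d values.
#' @param n Total sample size.
#' @param prop_female Fraction of females (default 0.5).
#' @param seed Optional integer seed for reproducibility.
#' @return An [mf_profiles()] tibble with traits `t1 ... tp`.
#' @export
simulate_population <- function(R_true, d_true, n, prop_female = 0.5,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  R_true <- as.matrix(R_true)
  p <- ncol(R_true)
  stopifnot(length(d_true) == p, n >= 4)
  ev <- eigen(R_true, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) abort("R_true is not positive semi-definite.")
  n_f <- round(n * prop_female)
  n_m <- n - n_f
  if (n_f < 2 || n_m < 2) abort("Need at least 2 individuals per sex.")

  mu <- d_true / 2
  x_f <- MASS::mvrnorm(n_f, mu = -mu, Sigma = R_true)
  x_m <- MASS::mvrnorm(n_m, mu = +mu, Sigma = R_true)
  x <- rbind(x_f, x_m)
  colnames(x) <- paste0("t", seq_len(p))
  df <- data.frame(sex = rep(c("female", "male"), c(n_f, n_m)), x)
  mf_profiles(df, sex = "sex", male = "male", female = "female")
}

#' Add classical-test-theory measurement error to true-score profiles
#'
#' Adds independent Gaussian noise with variance `(1 - rel_j) / rel_j` to
#' trait j, calibrated to the generator's unit within-sex true-score
#' variance so that the observed reliability — the ratio of true-score to
#' observed variance — equals `rel_j`. Noise is independent of trait values
#' and of sex.
#'
#' @param profiles True-score profiles from [simulate_population()].
#' @param reliabilities Numeric vector in (0, 1], recycled to the trait
#'   count if scalar.
#' @param seed Optional integer seed.
#' @return An `mf_profiles` tibble of observed (noisy) profiles.
#' @export
add_measurement_error <- function(profiles, reliabilities, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  traits <- trait_names(profiles)
  p <- length(traits)
  rel <- rep_len(as.numeric(reliabilities), p)
  if (any(!is.finite(rel) | rel <= 0 | rel > 1)) {
    abort("Reliabilities must lie in (0, 1].")
  }
  x <- trait_matrix(profiles)
  noise_sd <- sqrt((1 - rel) / rel)
  noise <- sweep(matrix(rnorm(length(x)), nrow(x), p), 2, noise_sd, "*")
  out <- profiles
  out[traits] <- tibble::as_tibble(x + noise)
  out
}

#' Phi coefficient of agreement between two binary classifications
#'
#' The Pearson correlation of two binary variables, computed from the 2x2
#' contingency table as `(ad - bc) / sqrt((a+b)(c+d)(a+c)(b+d))`. When either
#' margin is degenerate (a classification with only one class) the
#' coefficient is undefined and `NA` is returned with a warning.
#'
#' @param true_flags,obs_flags Equal-length logical vectors.
#' @return A single number in `[-1, 1]`, or `NA`.
#' @export
phi_coefficient <- function(true_flags, obs_flags) {
  if (length(true_flags) != length(obs_flags)) {
    abort("Flag vectors must have equal length.")
  }
  a <- sum(true_flags & obs_flags)
  b <- sum(true_flags & !obs_flags)
  c_ <- sum(!true_flags & obs_flags)
  d <- sum(!true_flags & !obs_flags)
  denom <- sqrt(a + b) * sqrt(c_ + d) * sqrt(a + c_) * sqrt(b + d)
  if (denom == 0) {
    warn("Degenerate margin in 2x2 table; phi is undefined.")
    return(NA_real_)
  }
  (a * d - b * c_) / denom
}

#' Configuration for a reliability-validity experiment
#'
#' Bundles the design of a Monte-Carlo study of how trait reliability
#' degrades index validity. Defaults follow the study conditions used for
#' the figures in the accompanying analyses: a fresh vine correlation matrix
#' (`beta = 4`) and Cohen's d vector (`N(0, d_sd^2)`) per replicate,
#' samples of `n` individuals with 50% females, and reliability levels from
#' .50 to .99.
#'
#' @param p Number of traits.
#' @param n Sample size per replicate.
#' @param prop_female Fraction of females.
#' @param d_sd SD of the normal distribution generating true Cohen's d
#'   values (the reference designs pair p = 5/10/30 with d_sd =
#'   0.70/0.50/0.05, giving average centroid distances of roughly 2/3/4).
#' @param vine_beta Beta parameter of the vine sampler.
#' @param reliabilities Reliability levels to cross with each replicate.
#' @param n_reps Number of Monte-Carlo replicates.
#' @param correct Logical: also compute indices after DMD correction of the
#'   noisy data with the true (generating) reliabilities.
#' @param seed Integer seed for the whole experiment.
#' @return A list of class `validity_config`.
#' @export
validity_config <- function(p = 10, n = 2000, prop_female = 0.5,
                            d_sd = 0.50, vine_beta = 4,
                            reliabilities = c(0.50, 0.70, 0.90, 0.99),
                            n_reps = 100, correct = FALSE, seed = 1) {
  stopifnot(p >= 2, n >= 8, n_reps >= 1,
            all(reliabilities > 0 & reliabilities <= 1))
  structure(list(p = p, n = n, prop_female = prop_female, d_sd = d_sd,
                 vine_beta = vine_beta, reliabilities = reliabilities,
                 n_reps = n_reps, correct = correct, seed = as.integer(seed)),
            class = "validity_config")
}

#' Run a Monte-Carlo study of index validity under measurement error
#'
#' Per replicate: draw a vine correlation matrix and a Cohen's d vector,
#' simulate an error-free sample, and fit the scoring model on it to obtain
#' each individual's "true" index scores. Then, for each reliability level,
#' add measurement noise, refit on the observed data, recompute the indices,
#' and record for each index its validity — the correlation between observed
#' and true scores. Also recorded per cell: the observed correlation between
#' directionality and typicality scores (whole-sample `r` and sex-partialled
#' `r_p`), the phi coefficient between true and observed
#' concordant/discordant classifications, the observed proportion
#' discordant, and the realized (true-fit) and observed `D_M`. With
#' `correct = TRUE` each noisy sample is additionally DMD-corrected with the
#' generating reliabilities and scored again (`corrected = TRUE` rows).
#'
#' Replicates in which a fit fails (e.g., a singular observed correlation
#' matrix) are skipped and counted in the `skipped` attribute.
#'
#' @param config A [validity_config()].
#' @return A tidy tibble, one row per replicate x reliability (x correction
#'   state), with columns `rep`, `reliability`, `corrected`,
#'   `validity_mfd/mft/mfp/mfc`, `r_obs_dt`, `rp_obs_dt`, `phi_concordance`,
#'   `prop_discordant_obs`, `D_M_true`, `D_M_obs`.
#' @examples
#' \donttest{
#' res <- run_validity_experiment(validity_config(p = 5, n = 500,
#'   d_sd = 0.7, n_reps = 3, seed = 42))
#' dplyr::group_by(res, reliability) |>
#'   dplyr::summarise(dplyr::across(dplyr::starts_with("validity"), median))
#' }
#' @export
run_validity_experiment <- function(config) {
  stopifnot(inherits(config, "validity_config"))
  set.seed(config$seed)
  skipped <- 0L

  one_rep <- function(rep_i) {
    R_true <- sample_vine_correlation(config$p, config$vine_beta)
    d_true <- rnorm(config$p, 0, config$d_sd)
    true_prof <- simulate_population(R_true, d_true, config$n,
                                     config$prop_female)
    fit_true <- tryCatch(fit_mf(true_prof), error = function(e) NULL)
    if (is.null(fit_true)) return(NULL)
    sc_true <- mf_scores(fit_true)
    s_true <- as.numeric(sc_true$sex == "male")
    r_true <- cor(sc_true$mfd, sc_true$mft)
    r_ds_t <- cor(sc_true$mfd, s_true); r_ts_t <- cor(sc_true$mft, s_true)
    rp_true <- (r_true - r_ds_t * r_ts_t) /
      sqrt((1 - r_ds_t^2) * (1 - r_ts_t^2))

    purrr::map_dfr(config$reliabilities, function(rel) {
      obs_prof <- add_measurement_error(true_prof, rel)
      score_one <- function(reliab) {
        fit_obs <- tryCatch(fit_mf(obs_prof, reliabilities = reliab),
                            error = function(e) NULL)
        if (is.null(fit_obs)) return(NULL)
        sc_obs <- mf_scores(fit_obs)
        dt <- cor(sc_obs$mfd, sc_obs$mft)
        s_ind <- as.numeric(sc_obs$sex == "male")
        r_ds <- cor(sc_obs$mfd, s_ind); r_ts <- cor(sc_obs$mft, s_ind)
        tibble::tibble(
          reliability = rel,
          corrected = !is.null(reliab),
          validity_mfd = cor(sc_true$mfd, sc_obs$mfd),
          validity_mft = cor(sc_true$mft, sc_obs$mft),
          validity_mfp = cor(sc_true$mfp, sc_obs$mfp),
          validity_mfc = cor(sc_true$mfc, sc_obs$mfc),
          r_obs_dt = dt,
          rp_obs_dt = (dt - r_ds * r_ts) /
            sqrt((1 - r_ds^2) * (1 - r_ts^2)),
          phi_concordance = suppressWarnings(
            phi_coefficient(sc_true$discordant, sc_obs$discordant)),
          prop_discordant_obs = mean(sc_obs$discordant),
          prop_discordant_true = mean(sc_true$discordant),
          r_true_dt = r_true,
          rp_true_dt = rp_true,
          D_M_true = fit_true$D_M,
          D_M_obs = fit_obs$D_M
        )
      }
      rows <- score_one(NULL)
      if (isTRUE(config$correct)) {
        rows <- dplyr::bind_rows(rows, score_one(rep(rel, config$p)))
      }
      rows
    }) |> dplyr::mutate(rep = rep_i, .before = 1)
  }

  out <- purrr::map(seq_len(config$n_reps), one_rep)
  skipped <- sum(vapply(out, is.null, logical(1)))
  if (skipped > 0) {
    inform(sprintf("Skipped %d replicate(s) with failed fits.", skipped))
  }
  res <- dplyr::bind_rows(out)
  attr(res, "config") <- config
  attr(res, "skipped") <- skipped
  res
}
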