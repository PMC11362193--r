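#' Compute the four M-F indices for a sample of profiles
#'
#' Given a fitted [fit_mf()] model, returns per-individual scores on the four
#' indices:
#' \describe{
#'   \item{mfd}{sex-directionality, `z' d / ||d||`: projection on the
#'     centroid axis, each trait weighted by its univariate Cohen's d.}
#'   \item{mft}{sex-typicality, `z' a / D_M`: projection on the discriminant
#'     axis, normalized so its pooled within-sex variance equals 1 on the
#'     training sample.}
#'   \item{mfp}{sex-probability, `plogis(z' a)`: the estimated probability of
#'     being male under equal priors, driven by the un-normalized
#'     discriminant score (or the logistic linear predictor).}
#'   \item{mfc}{sex-centrality, the difference between Mahalanobis distances
#'     to the female and male centroids, normalized by the centroid distance
#'     so the male centroid scores +1 and the female centroid -1.}
#' }
#' A profile is flagged `discordant` when its directionality and typicality
#' scores have strictly opposite signs (e.g., female-directional but
#' male-typical); exact zeros sit on a boundary and are never discordant.
#'
#' @param model An `mf_model` from [fit_mf()].
#' @param newdata Optional profiles to score with the frozen standardization
#'   of the training fit: an [mf_profiles()] table or a data frame containing
#'   the model's trait columns. Defaults to the training sample. Models
#'   fitted with measurement-error correction can only score their training
#'   sample, because the correction acts on within-sex deviations.
#' @return A tibble of class `mf_scores` with columns `id`, `sex`, `mfd`,
#'   `mft`, `mfp`, `mfc`, `discordant`. The fitted model travels along as an
#'   attribute for [summarize_indices()] and [autoplot()].
#' @examples
#' R <- matrix(c(1, -0.5, -0.5, 1), 2)
#' prof <- simulate_population(R, d_true = c(0.6, -0.6), n = 400, seed = 1)
#' scores <- mf_scores(fit_mf(prof))
#' summarize_indices(scores)
#' @export
mf_scores <- function(model, newdata = NULL) {
  stopifnot(inherits(model, "mf_model"))
  if (is.null(newdata)) {
    z <- model$z
    sex <- model$sex
    id <- model$id
  } else {
    if (!is.null(model$correction)) {
      abort(paste0(
        "Models fitted with measurement-error correction cannot score new ",
        "data; refit including the new individuals."))
    }
    if (inherits(newdata, "mf_profiles")) {
      x <- trait_matrix(newdata)
      sex <- newdata$sex
      id <- newdata$id
    } else {
      missing <- setdiff(model$std$traits, names(newdata))
      if (length(missing) > 0L) {
        abort(paste0("newdata lacks trait column(s): ",
                     paste(missing, collapse = ", ")))
      }
      x <- as.matrix(newdata[, model$std$traits, drop = FALSE])
      sex <- if ("sex" %in% names(newdata)) {
        factor(as.character(newdata$sex), levels = c("female", "male"))
      } else factor(rep(NA_character_, nrow(x)), levels = c("female", "male"))
      id <- if ("id" %in% names(newdata)) as.character(newdata$id) else
        as.character(seq_len(nrow(x)))
    }
    z <- sweep(sweep(x, 2, model$std$midpoint), 2, model$std$pooled_sd, "/")
  }

  mfd <- mfd_scores(z, model$eff)
  mft <- mft_scores(z, model)
  mfp <- mfp_scores(z, model)
  mfc <- mfc_scores(z, model)
  conc <- classify_concordance(mfd, mft)

  out <- tibble::tibble(id = id, sex = sex, mfd = mfd, mft = mft,
                        mfp = mfp, mfc = mfc,
                        discordant = conc$discordant)
  structure(out, class = c("mf_scores", class(out)), model = model)
}

#' Sex-directionality scores
#'
#' `z' d / ||d||`: the projection of each standardized profile on the
#' centroid axis. Positive scores are male-directional.
#'
#' @param z N x p matrix of standardized profiles (from [standardize()]).
#' @param eff Effect summary (from [effect_summary()] or a model's `$eff`).
#' @return Numeric vector of length N.
#' @export
mfd_scores <- function(z, eff) {
  if (eff$d_norm <= 0) {
    abort("Cohen's d vector is zero: no dimorphism axis to project on.")
  }
  drop(z %*% eff$d) / eff$d_norm
}

#' Sex-typicality scores
#'
#' The projection on the discriminant axis, normalized so that its pooled
#' within-sex variance equals 1 on the training sample. For the linear
#' discriminant fit the normalizer is `sqrt(a' R a) = D_M`; for the logistic
#' fit the linear predictor is rescaled by its pooled within-sex SD,
#' `sqrt(b' R b)`. A score of zero puts the profile on the classification
#' boundary.
#'
#' @inheritParams mfd_scores
#' @param model An `mf_model`.
#' @return Numeric vector of length N.
#' @export
mft_scores <- function(z, model) {
  raw <- raw_discriminant(z, model)
  scale <- attr(raw, "within_sd")
  if (scale <= 0 || !is.finite(scale)) {
    abort("Centroid separation is zero: sex-typicality is undefined.")
  }
  as.numeric(raw) / scale
}

#' Sex-probability scores
#'
#' The inverse-logit of the un-normalized discriminant score (equal priors
#' for the two sexes), or of the logistic linear predictor. Values are
#' clamped to the open unit interval so downstream logits stay finite.
#'
#' @inheritParams mft_scores
#' @return Numeric vector in (0, 1).
#' @export
mfp_scores <- function(z, model) {
  p <- plogis(as.numeric(raw_discriminant(z, model)))
  eps <- .Machine$double.xmin
  pmin(pmax(p, eps), 1 - .Machine$double.eps)
}

raw_discriminant <- function(z, model) {
  if (model$method == "logistic") {
    lp <- model$logistic$intercept + drop(z %*% model$logistic$slopes)
    b <- model$logistic$slopes
    within_sd <- sqrt(drop(t(b) %*% model$eff$R %*% b))
    structure(lp, within_sd = within_sd)
  } else {
    structure(drop(z %*% model$a), within_sd = model$D_M)
  }
}

#' Sex-centrality scores
#'
#' `(D(z, f) - D(z, m)) / D(m, f)` where distances are Mahalanobis with
#' metric `R^-1` and the centroids sit at `m = d/2`, `f = -d/2` in z-space.
#' The male centroid scores +1, the female centroid -1, and the zero contour
#' is the classification boundary, so the sign of sex-centrality always
#' agrees with that of sex-typicality.
#'
#' @inheritParams mft_scores
#' @return Numeric vector of length N.
#' @export
mfc_scores <- function(z, model) {
  if (model$D_M <= 0) abort("Centroid separation is zero: sex-centrality is undefined.")
  m <- model$eff$d / 2
  W <- solve(model$eff$R)
  qf <- function(dev) rowSums((dev %*% W) * dev)
  dev_m <- sweep(z, 2, m)
  dev_f <- sweep(z, 2, -m)
  (sqrt(pmax(qf(dev_f), 0)) - sqrt(pmax(qf(dev_m), 0))) / model$D_M
}

#' Classify concordant versus discordant profiles
#'
#' A profile is discordant when its sex-directionality and sex-typicality
#' scores have strictly opposite signs: it lies between the directional and
#' classification boundaries, e.g. female-directional yet male-typical.
#' Profiles with an exactly zero score sit on a boundary and count as
#' concordant.
#'
#' @param mfd,mft Equal-length numeric score vectors.
#' @return A list with `discordant` (logical vector) and `proportion`.
#' @export
classify_concordance <- function(mfd, mft) {
  stopifnot(length(mfd) == length(mft))
  discordant <- sign(mfd) * sign(mft) < 0
  list(discordant = discordant, proportion = mean(discordant))
}

#' Summarize a table of M-F index scores
#'
#' Reports the quantities used to compare indices across datasets: pairwise
#' Pearson correlations among the four indices in the whole sample (`r`) and
#' partial correlations controlling for sex (`r_p`, computed analytically by
#' partialling out the binary sex indicator), the percentage of discordant
#' profiles, per-sex means and SDs of each index, and the centroid distances
#' `D_M` / `D_Mu` when the fitted model is attached.
#'
#' Partial correlations are usually the more informative comparison because
#' whole-sample correlations are inflated by the mean sex difference that all
#' four indices share.
#'
#' @param scores An `mf_scores` table (or any data frame with columns `sex`,
#'   `mfd`, `mft`, `mfp`, `mfc`, `discordant`).
#' @return A list of class `mf_summary`: `correlations` (tibble with one row
#'   per index pair: `r`, `r_p`), `percent_discordant`, `by_sex` (tibble of
#'   per-sex means and SDs), `n_male`, `n_female`, `D_M`, `D_Mu`, `method`.
#' @export
summarize_indices <- function(scores) {
  idx <- c("mfd", "mft", "mfp", "mfc")
  stopifnot(all(c(idx, "sex", "discordant") %in% names(scores)))
  counts <- table(scores$sex)
  if (any(counts < 3L)) {
    abort("Need at least 3 individuals per sex to summarize correlations.")
  }

  x <- as.matrix(as.data.frame(scores)[, idx])
  s_ind <- as.numeric(scores$sex == "male")
  sds <- apply(x, 2, sd)
  if (any(sds == 0)) {
    warn(paste0("Zero-variance score column(s): ",
                paste(idx[sds == 0], collapse = ", "),
                "; correlations undefined (NA)."))
  }

  r_mat <- suppressWarnings(cor(x))
  r_s <- suppressWarnings(as.numeric(cor(x, s_ind)))
  pairs <- utils::combn(idx, 2)
  correlations <- purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    i <- match(pairs[1, k], idx); j <- match(pairs[2, k], idx)
    r <- r_mat[i, j]
    denom <- sqrt((1 - r_s[i]^2) * (1 - r_s[j]^2))
    tibble::tibble(index_x = pairs[1, k], index_y = pairs[2, k],
                   r = r,
                   r_p = if (is.na(denom) || denom <= 0) NA_real_ else
                     (r - r_s[i] * r_s[j]) / denom)
  })

  by_sex <- tibble::as_tibble(scores) |>
    dplyr::select(dplyr::all_of(c("sex", idx))) |>
    tidyr::pivot_longer(dplyr::all_of(idx), names_to = "index") |>
    dplyr::group_by(.data$sex, .data$index) |>
    dplyr::summarise(mean = mean(.data$value), sd = sd(.data$value),
                     .groups = "drop")

  model <- attr(scores, "model")
  structure(list(
    correlations = correlations,
    percent_discordant = 100 * mean(scores$discordant),
    by_sex = by_sex,
    n_male = unname(counts[["male"]]),
    n_female = unname(counts[["female"]]),
    D_M = if (!is.null(model)) model$D_M else NA_real_,
    D_Mu = if (!is.null(model)) model$D_Mu else NA_real_,
    method = if (!is.null(model)) model$method else NA_character_
  ), class = "mf_summary")
}

#' @export
print.mf_summary <- function(x, ...) {
  cat(sprintf("<mf_summary> %d males, %d females\n", x$n_male, x$n_female))
  if (is.finite(x$D_M)) {
    cat(sprintf("  D_M = %.3f (bias-corrected D_Mu = %.3f)\n", x$D_M, x$D_Mu))
  }
  cat(sprintf("  discordant profiles: %.1f%%\n", x$percent_discordant))
  cat("  correlations (r) and sex-partialled correlations (r_p):\n")
  print(as.data.frame(x$correlations), digits = 3, row.names = FALSE)
  invisible(x)
}
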