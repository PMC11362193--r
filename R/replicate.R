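#' Residualize columns on a covariate
#'
#' Replaces each listed column by its residual from a pooled linear
#' regression (single intercept and slope) on the covariate. Used by the
#' body-morphology example to remove overall adiposity from circumference
#' measures before computing M-F indices. Optionally the regression can be
#' fitted within each sex.
#'
#' @param data A data frame.
#' @param columns Character vector of columns to residualize.
#' @param on Name of the covariate column.
#' @param by_sex Fit separate regressions per sex (requires a `sex` column);
#'   default `FALSE` (pooled fit).
#' @return `data` with the listed columns replaced by residuals.
#' @export
residualize_on <- function(data, columns, on, by_sex = FALSE) {
  stopifnot(on %in% names(data), all(columns %in% names(data)))
  resid_fit <- function(df) {
    for (cl in columns) {
      df[[cl]] <- residuals(lm(df[[cl]] ~ df[[on]]))
    }
    df
  }
  if (by_sex) {
    stopifnot("sex" %in% names(data))
    parts <- split(data, data$sex)
    data <- do.call(rbind, lapply(parts, resid_fit))
    rownames(data) <- NULL
    data
  } else {
    resid_fit(data)
  }
}

#' Run a full index analysis in the style of the worked examples
#'
#' End-to-end driver composing the package's building blocks for the three
#' kinds of datasets used as worked examples: `"body"` (anthropometry:
#' circumference variables are residualized on BMI before analysis),
#' `"brain"` (an already-reduced component table, e.g. rotated principal
#' components of regional gray-matter volumes), and `"personality"`
#' (scale scores, optionally corrected for measurement error when per-scale
#' reliabilities are supplied). The datasets themselves are not bundled; the
#' caller supplies a file path or a data frame.
#'
#' @param example One of `"body"`, `"brain"`, `"personality"`.
#' @param data A data frame, or a path to a delimited file readable by
#'   [read_profile_table()].
#' @param sex,male,female,traits,id Column mapping, as in [mf_profiles()].
#' @param bmi For `"body"`: name of the BMI column (required).
#' @param residualize For `"body"`: columns to residualize on BMI (defaults
#'   to every trait column whose name contains "circ").
#' @param reliabilities For `"personality"`: optional per-trait reliability
#'   vector; triggers DMD-style error correction.
#' @param method Fitting method, `"lda"` (default) or `"logistic"`.
#' @param plot_path Optional file path; if given, the summary plot is saved
#'   there.
#' @return A list with `scores` (the [mf_scores()] tibble), `summary` (the
#'   [summarize_indices()] record), and `model`.
#' @export
replicate_example <- function(example = c("body", "brain", "personality"),
                              data, sex = "sex", male = "male",
                              female = "female", traits = NULL, id = NULL,
                              bmi = NULL, residualize = NULL,
                              reliabilities = NULL,
                              method = c("lda", "logistic"),
                              plot_path = NULL) {
  example <- match.arg(example)
  method <- match.arg(method)
  if (is.character(data) && length(data) == 1L) {
    data <- as.data.frame(readr::read_delim(
      data, delim = if (grepl("\\.tsv$", data)) "\t" else ",",
      show_col_types = FALSE, progress = FALSE))
  }
  stopifnot(is.data.frame(data))

  if (example == "body") {
    if (is.null(bmi) || !bmi %in% names(data)) {
      abort("The body example requires a `bmi` column name present in `data`.")
    }
    if (is.null(traits)) {
      traits <- setdiff(names(data)[vapply(data, is.numeric, logical(1))],
                        c(bmi, id))
    }
    if (is.null(residualize)) {
      residualize <- grep("circ", traits, value = TRUE, ignore.case = TRUE)
    }
    if (length(residualize) > 0L) {
      data <- residualize_on(data, residualize, on = bmi)
    }
  }
  if (example != "personality" && !is.null(reliabilities)) {
    warn("Reliability correction is only applied in the personality example; ignoring.")
    reliabilities <- NULL
  }

  prof <- mf_profiles(data, sex = sex, traits = traits, male = male,
                      female = female, id = id)
  model <- fit_mf(prof, method = method, reliabilities = reliabilities)
  scores <- mf_scores(model)
  smry <- summarize_indices(scores)
  if (!is.null(plot_path)) save_summary_plot(scores, plot_path)
  list(scores = scores, summary = smry, model = model)
}
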