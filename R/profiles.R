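#' Assemble a profile table of trait values and sex labels
#'
#' A profile table is the universal input of the package: one row per
#' individual, one numeric column per trait, plus a binary sex label. Labels
#' are mapped to `"male"`/`"female"` internally; by the package's sign
#' convention positive index scores are masculine (male-directional,
#' male-typical, ...), so the male group anchors the positive pole.
#'
#' Rows containing missing values in the selected columns are dropped
#' (complete-case analysis; a message reports the count). At least two
#' individuals per sex are required so that pooled within-sex standard
#' deviations are estimable.
#'
#' @param data A data frame with one row per individual.
#' @param sex Name of the column holding sex labels (string).
#' @param traits Character vector of trait column names. Defaults to every
#'   numeric column other than `sex` and `id`.
#' @param male,female The labels in `data[[sex]]` denoting males and females.
#' @param id Optional name of an identifier column, carried through to score
#'   tables.
#'
#' @return A tibble of class `mf_profiles` with columns `id`, `sex`
#'   (factor with levels `female`, `male`) and one column per trait.
#' @examples
#' d <- data.frame(sex = rep(c("M", "F"), each = 5),
#'                 height = c(rnorm(5, 176, 7), rnorm(5, 163, 6)),
#'                 grip   = c(rnorm(5, 48, 8), rnorm(5, 30, 6)))
#' mf_profiles(d, sex = "sex", male = "M", female = "F")
#' @export
mf_profiles <- function(data, sex = "sex", traits = NULL,
                        male = "male", female = "female", id = NULL) {
  stopifnot(is.data.frame(data))
  if (!sex %in% names(data)) {
    abort(sprintf("Sex column '%s' not found in `data`.", sex))
  }
  if (is.null(traits)) {
    candidates <- setdiff(names(data), c(sex, id))
    traits <- candidates[vapply(data[candidates], is.numeric, logical(1))]
  }
  if (length(traits) < 1L) abort("No numeric trait columns found.")
  missing_traits <- setdiff(traits, names(data))
  if (length(missing_traits) > 0L) {
    abort(paste0("Trait column(s) not found: ",
                 paste(missing_traits, collapse = ", ")))
  }
  non_numeric <- traits[!vapply(data[traits], is.numeric, logical(1))]
  if (length(non_numeric) > 0L) {
    abort(paste0("Trait column(s) are not numeric: ",
                 paste(non_numeric, collapse = ", ")))
  }

  labels <- as.character(data[[sex]])
  known <- labels %in% c(male, female) & !is.na(labels)
  if (any(!known)) {
    bad <- unique(labels[!known])
    abort(paste0("Unknown sex label(s): ",
                 paste(encodeString(bad, quote = '"'), collapse = ", "),
                 ". Expected \"", male, "\" or \"", female, "\"."))
  }

  ids <- if (is.null(id)) as.character(seq_len(nrow(data))) else
    as.character(data[[id]])

  out <- tibble::tibble(
    id = ids,
    sex = factor(ifelse(labels == male, "male", "female"),
                 levels = c("female", "male"))
  )
  out <- dplyr::bind_cols(out, tibble::as_tibble(data[traits]))

  keep <- complete.cases(out[traits])
  if (any(!keep)) {
    inform(sprintf("Dropped %d row(s) with missing trait values.", sum(!keep)))
    out <- out[keep, , drop = FALSE]
  }

  counts <- table(out$sex)
  if (nrow(out) < 4L || any(counts < 2L)) {
    abort(sprintf(
      "Need at least 2 individuals per sex (got %d female, %d male).",
      counts[["female"]], counts[["male"]]))
  }

  structure(out, class = c("mf_profiles", class(out)),
            traits = traits)
}

#' Read a profile table from a delimited text file
#'
#' Reads a CSV/TSV file with a header row, maps the sex labels, coerces trait
#' columns to numeric and applies complete-case filtering via
#' [mf_profiles()].
#'
#' @param path Path to a delimited file with a header row.
#' @param sex,traits,male,female,id Passed to [mf_profiles()].
#' @param delim Field delimiter; `NULL` (default) auto-detects comma vs tab
#'   from the header line.
#' @return An `mf_profiles` tibble.
#' @export
read_profile_table <- function(path, sex = "sex", traits = NULL,
                               male = "male", female = "female",
                               id = NULL, delim = NULL) {
  if (is.null(delim)) {
    header <- readLines(path, n = 1L)
    delim <- if (grepl("\t", header)) "\t" else ","
  }
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  if (is.null(traits)) {
    traits <- setdiff(names(raw), c(sex, id))
  }
  for (tr in traits) {
    if (!is.numeric(raw[[tr]])) {
      coerced <- suppressWarnings(as.numeric(raw[[tr]]))
      introduced <- is.na(coerced) & !is.na(raw[[tr]])
      if (any(introduced)) {
        abort(sprintf("Trait column '%s' is not numeric.", tr))
      }
      raw[[tr]] <- coerced
    }
  }
  mf_profiles(raw, sex = sex, traits = traits, male = male,
              female = female, id = id)
}

#' Write a score table to CSV
#'
#' @param scores A score table from [mf_scores()].
#' @param path Output file path.
#' @return `scores`, invisibly.
#' @export
write_scores <- function(scores, path) {
  readr::write_csv(as.data.frame(scores), path)
  invisible(scores)
}

trait_names <- function(profiles) attr(profiles, "traits")

trait_matrix <- function(profiles) {
  as.matrix(as.data.frame(profiles)[, trait_names(profiles), drop = FALSE])
}

#' @export
print.mf_profiles <- function(x, ...) {
  counts <- table(x$sex)
  cat(sprintf("<mf_profiles> %d individuals (%d male, %d female), %d trait(s)\n",
              nrow(x), counts[["male"]], counts[["female"]],
              length(trait_names(x))))
  NextMethod()
}
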