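# Fixture builders shared across test files. All randomness is seeded at the
# call sites.

`%||%` <- function(x, y) if (is.null(x)) y else x

sym_sqrt <- function(S, inverse = FALSE) {
  e <- eigen(S, symmetric = TRUE)
  pow <- if (inverse) -0.5 else 0.5
  e$vectors %*% diag(e$values^pow, nrow = length(e$values)) %*% t(e$vectors)
}

# Two-sex sample whose *sample* pooled within-sex correlation equals R and
# whose sample Cohen's d vector equals d exactly (empirical whitening then
# recoloring, means set to +/- d/2). Lets oracle tests work with known
# population quantities through the real fitting path.
exact_sample <- function(R, d, n_per_sex = 50) {
  p <- ncol(R)
  draw <- function(n) {
    x <- matrix(rnorm(n * p), n, p)
    sweep(x, 2, colMeans(x))
  }
  res_m <- draw(n_per_sex)
  res_f <- draw(n_per_sex)
  pooled <- crossprod(rbind(res_m, res_f)) / (2 * n_per_sex - 2)
  Tm <- sym_sqrt(pooled, inverse = TRUE) %*% sym_sqrt(R)
  res_m <- res_m %*% Tm
  res_f <- res_f %*% Tm
  x <- rbind(sweep(res_m, 2, d / 2, "+"), sweep(res_f, 2, -d / 2, "+"))
  colnames(x) <- paste0("t", seq_len(p))
  mf_profiles(data.frame(sex = rep(c("male", "female"), each = n_per_sex), x),
              sex = "sex")
}

# independent random correlation matrix: normalized Wishart, guaranteed PD
random_corr <- function(p, df = p + 5) {
  x <- matrix(rnorm(df * p), df, p)
  S <- crossprod(x) + diag(p) * 0.1
  D <- sqrt(diag(S))
  S / tcrossprod(D)
}

# four-trait sample used by several structural tests
toy_scores <- function(seed = 42, n = 300) {
  set.seed(seed)
  R <- matrix(0.4, 3, 3); diag(R) <- 1
  prof <- simulate_population(R, d_true = c(0.8, -0.3, 0.2), n = n)
  mf_scores(fit_mf(prof))
}

write_profile_fixture <- function(path, n = 6, missing_cell = FALSE,
                                  bad_label = FALSE, sep = ",") {
  df <- data.frame(
    sex = rep(c("M", "F"), length.out = n),
    height = round(seq(150, 190, length.out = n), 1),
    mass = round(seq(50, 90, length.out = n), 1)
  )
  if (bad_label) df$sex[2] <- "X"
  if (missing_cell) df$mass[3] <- NA
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  path
}
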