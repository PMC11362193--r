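test_that("discriminant coefficients and centroid distance match the closed form", {
  # R = I: a = d, D_M = ||d||
  set.seed(11)
  prof <- exact_sample(diag(2), c(0.6, -0.8), n_per_sex = 30)
  m <- fit_mf(prof)
  expect_equal(unname(m$a), c(0.6, -0.8), tolerance = 1e-10)
  expect_equal(m$D_M, 1, tolerance = 1e-10)

  # explicit 2x2 inverse oracle
  R <- matrix(c(1, -0.5, -0.5, 1), 2)
  prof2 <- exact_sample(R, c(0.5, -0.5), n_per_sex = 30)
  m2 <- fit_mf(prof2)
  expect_equal(unname(m2$a), c(1 / 3, -1 / 3), tolerance = 1e-9)
  expect_equal(m2$D_M, sqrt(1 / 3), tolerance = 1e-9)
  # residual of the defining linear system
  expect_lt(max(abs(m2$eff$R %*% m2$a - m2$eff$d)), 1e-8)

  # duplicate column -> singularity error
  df <- data.frame(sex = rep(c("male", "female"), each = 10),
                   t1 = rnorm(20))
  df$t2 <- df$t1
  expect_error(fit_mf(mf_profiles(df, sex = "sex")), "singular")
})

test_that("directionality scores are the d-weighted projection", {
  set.seed(12)
  prof <- exact_sample(diag(2), c(0.6, -0.8), n_per_sex = 30)
  m <- fit_mf(prof)
  # profile at the centroid midpoint scores zero
  expect_equal(mfd_scores(matrix(0, 1, 2), m$eff), 0)
  # one-trait projection of the male centroid is ||d||/2
  prof1 <- exact_sample(matrix(1), 1, n_per_sex = 10)
  m1 <- fit_mf(prof1)
  expect_equal(mfd_scores(matrix(0.5), m1$eff), 0.5, tolerance = 1e-10)
  # direct evaluation
  expect_equal(mfd_scores(matrix(c(1, -1), 1), m$eff), 1.4, tolerance = 1e-9)
  # zero d vector has no axis
  prof0 <- mf_profiles(data.frame(sex = rep(c("male", "female"), each = 3),
                                  t1 = rep(c(1, 2, 3), 2)), sex = "sex")
  expect_error(mfd_scores(matrix(0, 1, 1),
                          effect_summary(standardize(prof0))),
               "zero")
})

test_that("typicality scores have unit pooled within-sex variance and honor the linear-solve oracle", {
  R <- matrix(c(1, -0.5, -0.5, 1), 2)
  set.seed(13)
  prof <- exact_sample(R, c(0.5, -0.5), n_per_sex = 40)
  m <- fit_mf(prof)
  expect_equal(mft_scores(matrix(0, 1, 2), m), 0)
  expect_equal(mft_scores(matrix(c(1, -1), 1), m), (2 / 3) / sqrt(1 / 3),
               tolerance = 1e-9)
  # unit pooled within-sex variance on the training sample
  sc <- mf_scores(m)
  resid <- unlist(tapply(sc$mft, sc$sex, function(v) v - mean(v)))
  expect_equal(sum(resid^2) / (nrow(sc) - 2), 1, tolerance = 1e-6)
})

test_that("probability scores are the logistic transform of the un-normalized discriminant score", {
  set.seed(14)
  prof <- exact_sample(diag(2), c(1, 0), n_per_sex = 25)
  m <- fit_mf(prof)
  # score 0 -> 0.5; score 1 -> e/(1+e)
  expect_equal(mfp_scores(matrix(0, 1, 2), m), 0.5)
  expect_equal(mfp_scores(matrix(c(1, 0), 1), m), exp(1) / (1 + exp(1)),
               tolerance = 1e-9)
  # saturation stays inside the open unit interval
  huge <- mfp_scores(matrix(c(1e4, 0), 1), m)
  expect_true(huge < 1 && huge > 0.999)
  expect_true(mfp_scores(matrix(c(-1e4, 0), 1), m) > 0)
})

test_that("centrality is +1 / -1 / 0 at the male centroid, female centroid, and boundary", {
  R <- matrix(c(1, -0.5, -0.5, 1), 2)
  set.seed(15)
  prof <- exact_sample(R, c(0.8, -0.6), n_per_sex = 40)
  m <- fit_mf(prof)
  d <- m$eff$d
  expect_equal(mfc_scores(matrix(d / 2, 1), m), 1, tolerance = 1e-10)
  expect_equal(mfc_scores(matrix(-d / 2, 1), m), -1, tolerance = 1e-10)
  expect_equal(mfc_scores(matrix(0, 1, 2), m), 0, tolerance = 1e-12)
})

test_that("bias-corrected centroid distance follows the unbiased plug-in formula", {
  # p = 5, n_M = n_F = 50, D_M = 1 -> sqrt(92/98 - 0.2)
  set.seed(16)
  d <- rep(1 / sqrt(5), 5)
  prof <- exact_sample(diag(5), d, n_per_sex = 50)
  dd <- mahalanobis_centroid_distance(fit_mf(prof))
  expect_equal(unname(dd["D_M"]), 1, tolerance = 1e-9)
  expect_equal(unname(dd["D_Mu"]), sqrt(92 / 98 - 0.2), tolerance = 1e-6)

  # large-N consistency
  eff_big <- list(R = diag(2), d = c(0.6, 0.8), n_male = 1e6, n_female = 1e6)
  dd_big <- mahalanobis_centroid_distance(eff_big)
  expect_equal(unname(dd_big["D_Mu"]), unname(dd_big["D_M"]), tolerance = 1e-3)

  # tiny separation with small n floors at zero
  eff_small <- list(R = diag(5), d = rep(0.01, 5), n_male = 10, n_female = 10)
  expect_equal(unname(mahalanobis_centroid_distance(eff_small)["D_Mu"]), 0)
})

test_that("concordance flags strict sign disagreement only", {
  expect_true(classify_concordance(-0.2, 0.3)$discordant)
  expect_false(classify_concordance(0, -5)$discordant)   # boundary is concordant
  set.seed(17)
  mfd <- rnorm(200); mft <- rnorm(200)
  cc <- classify_concordance(mfd, mft)
  expect_equal(cc$discordant, (mfd > 0 & mft < 0) | (mfd < 0 & mft > 0))
  expect_equal(cc$proportion, mean(cc$discordant))
})

test_that("axis angle is zero for orthogonal traits and grows with trait correlation", {
  set.seed(18)
  expect_equal(axis_angle(fit_mf(exact_sample(diag(3), c(0.5, 0.3, -0.2),
                                              n_per_sex = 20))), 0,
               tolerance = 1e-6)
  d <- c(0.7, -0.2)
  angles <- vapply(c(0, -0.3, -0.6, -0.8), function(r) {
    R <- matrix(c(1, r, r, 1), 2)
    m <- fit_mf(exact_sample(R, d, n_per_sex = 30))
    # arccos oracle from explicit inversion
    a <- solve(R) %*% d
    expect_equal(axis_angle(m),
                 acos(sum(d * a) / sqrt(sum(d^2) * sum(a^2))) * 180 / pi,
                 tolerance = 1e-4)
    axis_angle(m)
  }, numeric(1))
  expect_true(all(diff(angles) > 0))  # stronger correlation widens the angle
})

test_that("brute-force oracles reproduce coefficients, distances, and all four scores", {
  set.seed(19)
  for (rep_i in 1:25) {
    p <- sample(2:4, 1)
    R <- random_corr(p)
    d <- rnorm(p, 0, 0.6)
    prof <- exact_sample(R, d, n_per_sex = 20)
    m <- fit_mf(prof)
    sc <- mf_scores(m)
    z <- m$z

    Rinv <- solve(m$eff$R)               # explicit inversion oracle
    a_or <- unname(drop(Rinv %*% m$eff$d))
    DM_or <- sqrt(drop(t(m$eff$d) %*% Rinv %*% m$eff$d))
    expect_equal(unname(m$a), a_or, tolerance = 1e-10)
    expect_equal(m$D_M, DM_or, tolerance = 1e-10)

    mfd_or <- drop(z %*% m$eff$d) / sqrt(sum(m$eff$d^2))
    mft_or <- drop(z %*% a_or) / DM_or
    mfp_or <- 1 / (1 + exp(-drop(z %*% a_or)))
    qf <- function(v, c0) drop(t(v - c0) %*% Rinv %*% (v - c0))
    mfc_or <- apply(z, 1, function(v)
      (sqrt(qf(v, -m$eff$d / 2)) - sqrt(qf(v, m$eff$d / 2))) / DM_or)

    expect_equal(sc$mfd, mfd_or, tolerance = 1e-10)
    expect_equal(sc$mft, mft_or, tolerance = 1e-10)
    expect_equal(sc$mfp, mfp_or, tolerance = 1e-10)
    expect_equal(sc$mfc, unname(mfc_or), tolerance = 1e-10)
  }
})

test_that("logistic fits give the same boundary structure as the discriminant fit", {
  set.seed(20)
  R <- matrix(c(1, 0.4, 0.4, 1), 2)
  prof <- simulate_population(R, c(0.8, -0.5), n = 600)
  m <- fit_mf(prof, method = "logistic")
  sc <- mf_scores(m)
  # probability and typicality agree in direction around their boundary
  expect_true(all(sign(sc$mfp - 0.5) == sign(sc$mft) | sc$mft == 0))
  # the logistic typicality analogue has unit pooled within-sex variance
  resid <- unlist(tapply(sc$mft, sc$sex, function(v) v - mean(v)))
  expect_equal(sum(resid^2) / (nrow(sc) - 2), 1, tolerance = 1e-6)
  # LDA and logistic scores agree closely under multivariate normality
  sc_lda <- mf_scores(fit_mf(prof))
  expect_gt(cor(sc$mft, sc_lda$mft), 0.99)
  # probabilities track the inverse logit of the raw linear predictor
  expect_true(all(sc$mfp > 0 & sc$mfp < 1))
})

test_that("scoring new data uses the frozen training standardization", {
  set.seed(22)
  prof <- simulate_population(diag(2), c(1, -0.5), n = 300)
  m <- fit_mf(prof)
  new_df <- data.frame(t1 = c(0, 1), t2 = c(0, -1))
  # trait values equal to the training midpoint must land on every boundary
  new_df[1, ] <- m$std$midpoint
  sc <- mf_scores(m, newdata = new_df)
  expect_equal(sc$mfd[1], 0, tolerance = 1e-12)
  expect_equal(sc$mft[1], 0, tolerance = 1e-12)
  expect_equal(sc$mfp[1], 0.5, tolerance = 1e-12)
  expect_equal(sc$mfc[1], 0, tolerance = 1e-12)
  expect_error(mf_scores(m, newdata = data.frame(t1 = 1)), "t2")
})

test_that("index summaries report r, sex-partialled r_p, and discordance", {
  sc <- toy_scores()
  smry <- summarize_indices(sc)
  # r_p matches the two-stage regression (residual-on-residual) oracle
  s_ind <- as.numeric(sc$sex == "male")
  r1 <- residuals(lm(sc$mfd ~ s_ind))
  r2 <- residuals(lm(sc$mft ~ s_ind))
  row <- smry$correlations[smry$correlations$index_x == "mfd" &
                             smry$correlations$index_y == "mft", ]
  expect_equal(row$r_p, cor(r1, r2), tolerance = 1e-10)
  expect_equal(row$r, cor(sc$mfd, sc$mft), tolerance = 1e-12)
  expect_equal(smry$percent_discordant, 100 * mean(sc$discordant))
  expect_equal(smry$D_M, attr(sc, "model")$D_M)

  # identical scores give r = r_p = 1
  sc2 <- sc
  sc2$mft <- sc2$mfd
  row2 <- summarize_indices(sc2)$correlations
  expect_equal(row2$r[row2$index_x == "mfd" & row2$index_y == "mft"], 1)
  expect_equal(row2$r_p[row2$index_x == "mfd" & row2$index_y == "mft"], 1)

  # a covariate uncorrelated with both scores changes nothing: build scores
  # orthogonal to sex, then r_p = r
  set.seed(30)
  sc3 <- sc
  for (v in c("mfd", "mft", "mfp", "mfc")) {
    sc3[[v]] <- residuals(lm(sc[[v]] ~ s_ind))
  }
  smry3 <- summarize_indices(sc3)
  expect_equal(smry3$correlations$r, smry3$correlations$r_p,
               tolerance = 1e-10)
})
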