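test_that("bivariate correlations recover exact and null relationships", {
  ds <- generate_spectrum_dataset(small_config(seed = 21))
  x <- ds$profiles
  y <- x[, 3]
  pat <- bivariate_correlations(x, y)
  expect_equal(pat$estimate[3], 1, tolerance = 1e-12)
  expect_true(all(pat$ci_low <= pat$estimate & pat$estimate <= pat$ci_high))
  # symmetry of r
  expect_equal(cor(x[, 1], y), cor(y, x[, 1]))

  # Fisher-z interval covers a true null close to its nominal rate
  hits <- withr::with_seed(31, vapply(1:100, function(i) {
    xi <- rnorm(200); yi <- rnorm(200)
    p <- bivariate_correlations(matrix(xi, ncol = 1), yi)
    p$ci_low[1] <= 0 && 0 <= p$ci_high[1]
  }, logical(1)))
  expect_gte(mean(hits), 0.88)

  const <- cbind(x, fixed = rep(2, nrow(x)))
  flagged <- bivariate_correlations(const, y)
  expect_true(is.na(flagged$estimate[ncol(const)]))
  expect_identical(attr(flagged, "undefined"), "fixed")
})

test_that("multiple regression matches the normal-equations oracle", {
  withr::with_seed(5, {
    x <- matrix(rnorm(300), 60, 5, dimnames = list(NULL, paste0("b", 1:5)))
    y <- drop(x %*% c(1, -2, 0, 0.5, 0)) + rnorm(60, sd = 0.3)
  })
  pat <- fit_mlr(x, y)
  d <- cbind(1, x)
  oracle <- drop(solve(crossprod(d), crossprod(d, y)))[-1]
  expect_equal(pat$estimate, unname(oracle), tolerance = 1e-8)
  expect_true(all(pat$ci_low < pat$estimate & pat$estimate < pat$ci_high))

  # noise-free single predictor: coefficient exactly 2 (the perfect fit
  # makes lm's summary warn; that is expected here)
  y2 <- 2 * x[, 1]
  pat2 <- suppressWarnings(fit_mlr(x, y2))
  expect_equal(pat2$estimate[1], 2, tolerance = 1e-10)
  expect_equal(pat2$model_r2[1], 1, tolerance = 1e-10)
})

test_that("closed proportions trigger an explicit singularity error", {
  ds <- generate_spectrum_dataset(small_config(seed = 6))
  prop <- ds$profiles / rowSums(ds$profiles)
  expect_error(fit_mlr(prop, ds$outcome), class = "singularity_error")
  expect_error(fit_mlr(prop, ds$outcome), "singular")
})

test_that("ilr regression fits one model per part and all fit the same subspace", {
  ds <- generate_spectrum_dataset(small_config(seed = 9))
  pat <- fit_ilr_mlr(ds$profiles, ds$outcome)
  expect_equal(nrow(pat), 6)
  expect_equal(attr(pat, "n_fits"), 6)

  # fitted values agree across permutations: rotations of one subspace
  comp <- close_composition(ds$profiles)
  perms <- all_first_permutations(6)
  f1 <- fitted(lm(ds$outcome ~ ilr_pivot(comp, perms[[1]])))
  f4 <- fitted(lm(ds$outcome ~ ilr_pivot(comp, perms[[4]])))
  expect_equal(f1, f4, tolerance = 1e-8)
})

test_that("spectrum and traditional descriptions give 23 and 4 ilr fits", {
  ds23 <- generate_spectrum_dataset(synthetic_config(n_participants = 120,
                                                     seed = 3))
  expect_equal(attr(fit_ilr_mlr(ds23$profiles, ds23$outcome), "n_fits"), 23)

  ds4 <- generate_spectrum_dataset(
    synthetic_config(n_participants = 120,
                     scheme = bin_scheme("traditional"), seed = 3))
  expect_equal(attr(fit_ilr_mlr(ds4$profiles, ds4$outcome), "n_fits"), 4)
})

test_that("PLS reduces to least squares in the known limits", {
  withr::with_seed(11, {
    x <- matrix(rnorm(400), 80, 5)
    y <- drop(x %*% c(0.5, 1, 0, -1, 2)) + rnorm(80)
  })
  # univariate X, one component = simple regression
  m1 <- fit_pls(x[, 1, drop = FALSE], y, 1)
  ls <- lm(y ~ x[, 1])
  expect_equal(predict(m1, x[, 1, drop = FALSE]), unname(fitted(ls)),
               tolerance = 1e-10)
  # p components on full-rank X = OLS
  mp <- fit_pls(x, y, 5)
  d <- cbind(1, x)
  ols_pred <- drop(d %*% solve(crossprod(d), crossprod(d, y)))
  expect_equal(predict(mp, x), ols_pred, tolerance = 1e-8)
  expect_true(mp$fitted_r2 >= 0 && mp$fitted_r2 <= 1)
  # score orthogonality
  g <- crossprod(mp$scores)
  expect_lt(max(abs(g[upper.tri(g)])), 1e-8)
})

test_that("PLS tolerates duplicated (perfectly collinear) columns", {
  withr::with_seed(12, {
    x <- matrix(rnorm(200), 50, 4)
    x <- cbind(x, x[, 2])
    y <- x[, 2] + rnorm(50, sd = 0.5)
  })
  m <- fit_pls(x, y, 3)
  b <- m$regression_vector
  expect_equal(b[2], b[5], tolerance = 1e-10)
})

test_that("Monte Carlo CV is deterministic and conservative under pure noise", {
  withr::with_seed(14, {
    x <- matrix(rnorm(1000), 100, 10)
    y <- rnorm(100)
  })
  a <- monte_carlo_cv(x, y, reps = 100, seed = 8)
  b <- monte_carlo_cv(x, y, reps = 100, seed = 8)
  expect_identical(a$rmsep, b$rmsep)
  expect_equal(a$n_components, 1)
  expect_lte(a$q2, 0)
})

test_that("CV finds at least two components when two latent directions drive y", {
  hits <- vapply(1:12, function(s) {
    withr::with_seed(100 + s, {
      n <- 150
      t1 <- rnorm(n); t2 <- rnorm(n)
      load1 <- rnorm(10); load2 <- rnorm(10)
      x <- outer(t1, load1) + outer(t2, load2) +
        matrix(rnorm(n * 10, sd = 0.1), n, 10)
      y <- t1 + 2 * t2 + rnorm(n, sd = 0.1)
    })
    monte_carlo_cv(x, y, reps = 60, max_components = 5,
                   seed = s)$n_components >= 2
  }, logical(1))
  expect_gte(sum(hits), 11)
})

test_that("target projection preserves the model's predictions exactly", {
  ds <- generate_spectrum_dataset(small_config(seed = 17))
  m <- fit_pls(ds$profiles, ds$outcome, 3)
  tp <- target_projection(m)
  expect_equal(sum(tp$tp_weights^2), 1, tolerance = 1e-12)
  # prediction from the single TP component equals the full model
  b_norm <- sqrt(sum(m$regression_vector^2))
  expect_equal(tp$tp_scores * b_norm, drop(m$X_std %*% m$regression_vector),
               tolerance = 1e-10)
  expect_true(all(tp$explained_variance <= tp$total_variance + 1e-8))

  # a 1-component model's TP component is that component up to sign
  m1 <- fit_pls(ds$profiles, ds$outcome, 1)
  tp1 <- target_projection(m1)
  al <- cor(tp1$tp_scores, m1$scores[, 1])
  expect_equal(abs(al), 1, tolerance = 1e-10)
})

test_that("TP weights align with per-variable covariance for orthogonal X", {
  withr::with_seed(19, {
    x <- matrix(rnorm(600), 120, 5)
    xs <- scale(x)
    xo <- xs %*% solve(chol(crossprod(xs)))  # orthonormal, mean-zero cols
    y <- drop(xo %*% c(1, -0.5, 0.2, 0, 0.8)) + rnorm(120, sd = 0.2)
  })
  m <- fit_pls(xo, y, 1)
  tp <- target_projection(m)
  covs <- drop(crossprod(scale(xo), scale(y)))
  expect_equal(abs(cor(tp$tp_weights, covs)), 1, tolerance = 1e-10)
})

test_that("selectivity ratios are signed, bounded, and vanish for null variables", {
  withr::with_seed(23, {
    x <- matrix(rnorm(5000 * 4), 5000, 4)
    y <- x[, 1]  # noise-free: column 1 is the outcome
  })
  m <- fit_pls(x, y, 4)
  sr <- selectivity_ratio(target_projection(m))
  expect_equal(abs(sr$sr[1]), 1, tolerance = 1e-8)
  expect_lt(abs(sr$sr[4]), 0.02)  # independent column at large n
  # bound holds across random datasets
  for (s in 1:5) {
    ds <- generate_spectrum_dataset(small_config(seed = 30 + s))
    sr_s <- selectivity_ratio(target_projection(
      fit_pls(ds$profiles, ds$outcome, 2)))
    expect_true(all(abs(sr_s$sr) <= 1 + 1e-12))
  }
})

test_that("SR confidence intervals are reproducible and shrink without noise", {
  eff <- c(0, 0, 0.9, 0, 0, 0)
  small_n <- generate_spectrum_dataset(small_config(n = 100, effect = eff,
                                                    noise_sd = 0, seed = 44))
  large_n <- generate_spectrum_dataset(small_config(n = 500, effect = eff,
                                                    noise_sd = 0, seed = 44))
  ci_s <- sr_confidence_intervals(small_n$profiles, small_n$outcome, 2,
                                  reps = 80, seed = 1)
  ci_l <- sr_confidence_intervals(large_n$profiles, large_n$outcome, 2,
                                  reps = 80, seed = 1)
  expect_lt(mean(ci_l$ci_high - ci_l$ci_low),
            mean(ci_s$ci_high - ci_s$ci_low))
  ci_s2 <- sr_confidence_intervals(small_n$profiles, small_n$outcome, 2,
                                   reps = 80, seed = 1)
  expect_identical(ci_s$ci_low, ci_s2$ci_low)
  # point estimates mostly inside their own intervals
  inside <- ci_l$ci_low <= ci_l$sr & ci_l$sr <= ci_l$ci_high
  expect_gte(mean(inside), 0.95)
})
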