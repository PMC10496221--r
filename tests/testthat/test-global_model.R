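test_that("exact linear data is fit exactly, with the scale floored", {
  x <- 1:20
  y <- 3 - 0.5 * x
  fit <- huber_irls(cbind(intercept = 1, x = x), y)
  expect_equal(unname(fit$coefficients), c(3, -0.5), tolerance = 1e-10)
  expect_lte(fit$scale, 1e-10)
  expect_true(all(fit$ci[, "lower"] <= fit$coefficients &
                  fit$coefficients <= fit$ci[, "upper"]))
})

test_that("without outliers Huber matches OLS; with one it resists", {
  set.seed(31)
  n <- 200
  x <- runif(n)
  y <- 1 + 2 * x + rnorm(n)
  X <- cbind(intercept = 1, x = x)
  # closed-form OLS oracle
  ols <- drop(solve(crossprod(X), crossprod(X, y)))
  fit <- huber_irls(X, y)
  expect_lt(max(abs(fit$coefficients - ols) / fit$se), 2)

  # gross outlier at a high-leverage point: robust slope stays closer to
  # the truth than OLS
  y2 <- y; y2[which.max(x)] <- y2[which.max(x)] + 50
  ols2 <- drop(solve(crossprod(X), crossprod(X, y2)))
  fit2 <- huber_irls(X, y2)
  expect_lt(abs(fit2$coefficients["x"] - 2), abs(ols2[2] - 2))

  # independent implementation agrees
  rlm_fit <- MASS::rlm(y2 ~ x, psi = MASS::psi.huber, k = 1.345,
                       scale.est = "MAD", maxit = 200, acc = 1e-10)
  expect_equal(unname(fit2$coefficients), unname(coef(rlm_fit)),
               tolerance = 1e-5)
})

test_that("huber limits and equivariance hold", {
  set.seed(12)
  x <- runif(60); y <- 2 + x + rt(60, df = 3)
  X <- cbind(intercept = 1, x = x)
  # k_tune -> Inf recovers OLS
  ols <- drop(solve(crossprod(X), crossprod(X, y)))
  expect_equal(unname(huber_irls(X, y, k_tune = 1e8)$coefficients),
               unname(ols), tolerance = 1e-6)
  # scale equivariance: c * y scales coefficients by c
  f1 <- huber_irls(X, y)
  f2 <- huber_irls(X, 10 * y)
  expect_equal(unname(f2$coefficients), unname(10 * f1$coefficients),
               tolerance = 1e-6)
})

test_that("information criteria use the documented penalty arithmetic", {
  x <- 1:30
  y <- 2 + 0.3 * x            # exact fit under both designs
  set.seed(5); z <- rnorm(30)
  f1 <- huber_irls(cbind(intercept = 1, x = x), y)
  f2 <- huber_irls(cbind(intercept = 1, x = x, z = z), y)
  # identical fit: the larger model pays exactly 2 more AIC per parameter
  expect_equal(unname(f2$aic - f1$aic), 2)
  expect_equal(unname(f2$bic - f1$bic), log(30))
  ic <- information_criteria(f1)
  expect_equal(unname(ic["aic"]), unname(-2 * f1$loglik + 2 * (f1$k + 1)))
  expect_equal(unname(ic["bic"]),
               unname(-2 * f1$loglik + (f1$k + 1) * log(f1$n)))
})

test_that("null storage effect is covered and real decay is detected", {
  # r = 0: the reduced-model storage CI covers 0 in at least 90% of runs
  covered <- 0L
  for (s in 1:50) {
    d <- small_dataset(seed = s, n_cpgs = 300, n_samples = 126, r = 0)
    gm <- mean_global_methylation(beta_to_m(d$beta))
    fit <- huber_irls(model_design(d$sheet), gm[d$sheet$sample_id])
    ci <- fit$ci["storage_dna_years", ]
    covered <- covered + (ci["lower"] <= 0 && 0 <= ci["upper"])
  }
  expect_gte(covered, 45L)

  # strong global decay: the reduced-model storage slope is negative
  d <- small_dataset(seed = 77, n_cpgs = 300, n_samples = 126, r = 0.05)
  gm <- mean_global_methylation(beta_to_m(d$beta))
  fit <- huber_irls(model_design(d$sheet), gm[d$sheet$sample_id])
  expect_lt(fit$coefficients["storage_dna_years"], 0)
  expect_lt(fit$p_value["storage_dna_years"], 0.05)
})

test_that("cell-mixture-driven data makes cell terms significant and favors the full model", {
  wins <- 0L
  for (s in 1:5) {
    d <- generate_dataset(generator_config(
      n_cpgs = 2000, n_samples = 126, seed = 100 + s, deamination_rate = 0,
      noise_sd_m = 0.1, discriminating_fraction = 0.3, reference_sep = 0.5,
      dirichlet_alpha = c(CD8T = 2, CD4T = 2, NK = 2, Bcell = 2, Mono = 2,
                          Gran = 2)))
    props <- suppressWarnings(
      estimate_cell_proportions(d$beta, d$truth$reference))
    gm <- fit_global_models(mean_global_methylation(beta_to_m(d$beta)),
                            d$sheet, props)
    if (s == 1) {
      cell_p <- gm$full$p_value[CELL_TYPES]
      expect_true(all(cell_p < 0.05))
    }
    wins <- wins + (gm$comparison$aic[2] < gm$comparison$aic[1])
  }
  expect_gte(wins, 3L)   # full model preferred in the majority of runs
})
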