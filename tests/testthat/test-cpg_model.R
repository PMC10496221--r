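test_that("per-CpG least squares matches the normal-equations oracle", {
  set.seed(21)
  n <- 12
  tt <- seq(1, 4, length.out = n)
  X <- cbind(intercept = 1, storage_dna_years = tt)
  Y <- matrix(rnorm(5 * n), 5, n,
              dimnames = list(sprintf("cg%02d", 1:5), sprintf("s%02d", 1:n)))
  Y[1, ] <- 0.7 - 0.1 * tt          # exact line
  Y[3, c(2, 5, 9)] <- NA            # per-CpG complete-case handling
  mat <- methylation_matrix(Y, "M")
  fit <- fit_cpg_linear(mat, X)

  expect_equal(fit$slope[1], -0.1, tolerance = 1e-12)
  expect_equal(fit$sigma[1], 0, tolerance = 1e-10)
  expect_equal(fit$df_residual, c(10, 10, 7, 10, 10))
  for (g in 1:5) {
    ok <- !is.na(Y[g, ])
    beta <- solve(crossprod(X[ok, ]), crossprod(X[ok, ], Y[g, ok]))
    expect_equal(fit$slope[g], as.numeric(beta)[2], tolerance = 1e-10)
  }
  expect_error(fit_cpg_linear(mat, cbind(X, dup = X[, 2])), "rank deficient")
})

test_that("variance squeezing recovers known hyperparameters and handles edge cases", {
  # degenerate: equal variances collapse to the d0 = Inf branch
  sq0 <- squeeze_var(rep(0.2, 10), 5)
  expect_identical(sq0$df_prior, Inf)
  expect_equal(sq0$var_post, rep(0.2, 10))

  # forcing d0 = Inf returns the prior variance everywhere
  set.seed(2)
  s2 <- rchisq(50, 5) / 5
  sqInf <- squeeze_var(s2, 5, df_prior = Inf)
  expect_true(all(sqInf$var_post == sqInf$var_prior))

  # simulation recovery: variances from a scaled F with d0 = 4, s0^2 = 0.01
  set.seed(7)
  d0 <- 4; s0_sq <- 0.01; dg <- 10; m <- 10000
  s2 <- (s0_sq * d0 / rchisq(m, d0)) * rchisq(m, dg) / dg
  sq <- squeeze_var(s2, dg)
  expect_lt(abs(sq$df_prior - d0) / d0, 0.25)
  expect_lt(abs(sq$var_prior - s0_sq) / s0_sq, 0.10)

  # independent implementation agrees
  lv <- limma::squeezeVar(s2, dg)
  expect_equal(sq$df_prior, lv$df.prior, tolerance = 1e-6)
  expect_equal(sq$var_post, lv$var.post, tolerance = 1e-9)

  expect_error(squeeze_var(0.1, 5), "at least 2")
})

test_that("moderated t behaves at its limits and without moderation", {
  mt <- moderated_t(0, 0.1, 0.04, 4, 10)
  expect_identical(mt$t, 0)
  expect_identical(mt$p_value, 1)

  # negating slopes negates t and preserves p
  mt1 <- moderated_t(c(0.3, -0.3), 0.1, c(0.02, 0.02), 4, c(10, 10))
  expect_equal(mt1$t[1], -mt1$t[2])
  expect_equal(mt1$p_value[1], mt1$p_value[2])

  # the unmoderated analysis reproduces the ordinary regression t-test
  set.seed(13)
  n <- 15
  tt <- runif(n, 1, 4)
  y <- 0.5 - 0.2 * tt + rnorm(n, sd = 0.3)
  mat <- methylation_matrix(
    matrix(y, 1, n, dimnames = list("cg1", sprintf("s%02d", 1:n))), "M")
  sheet <- sample_sheet(sprintf("s%02d", 1:n), tt, rep(50, n))
  res <- run_cpg_analysis(mat, sheet, moderation = FALSE, pi0 = 1)
  ref <- summary(lm(y ~ tt))$coefficients["tt", ]
  expect_equal(res$t, unname(ref["t value"]), tolerance = 1e-9)
  expect_equal(res$p_value, unname(ref["Pr(>|t|)"]), tolerance = 1e-9)
})

test_that("storey q-values reduce to BH at pi0 = 1 and estimate pi0 near 1 on null p", {
  expect_equal(storey_qvalue(c(0.01, 0.04), pi0 = 1),
               c(0.02, 0.04), ignore_attr = TRUE)

  set.seed(3)
  p <- runif(2000)
  q <- storey_qvalue(p, pi0 = 1)
  expect_equal(as.numeric(q), p.adjust(p, "BH"), tolerance = 1e-12)

  # all p = 1 collapse to pi0
  q1 <- storey_qvalue(rep(1, 200))
  expect_true(all(q1 == attr(q1, "pi0")))
  expect_lte(max(q1), 1)

  # uniform p: pi0-hat close to 1
  set.seed(14)
  q2 <- storey_qvalue(runif(10000))
  expect_gte(attr(q2, "pi0"), 0.9)
  expect_lte(attr(q2, "pi0"), 1)

  # q is monotone non-decreasing in p
  o <- order(p)
  expect_true(all(diff(as.numeric(q)[o]) >= 0))
  expect_error(storey_qvalue(c(0.5, 1.2)), "\\[0,1\\]")
})

test_that("directional counting uses a strict threshold and slope sign", {
  empty <- data.frame(q_value = numeric(0), slope = numeric(0))
  expect_identical(count_directional(empty), c(n_hypo = 0L, n_hyper = 0L))
  res <- data.frame(q_value = c(0.04, 0.05, 0.06), slope = c(-1, -1, 1))
  expect_identical(unname(count_directional(res)), c(1L, 0L))
})

test_that("run_cpg_analysis output satisfies its invariants on both scales", {
  d <- small_dataset(seed = 42, n_cpgs = 400, n_samples = 60, r = 0.01)
  for (mat in list(beta_to_m(d$beta), d$beta)) {
    res <- run_cpg_analysis(mat, d$sheet)
    expect_true(all(res$p_value >= 0 & res$p_value <= 1))
    expect_true(all(res$q_value >= 0 & res$q_value <= 1))
    expect_identical(res$direction == "hypo", res$slope < 0)
    o <- order(res$p_value)
    expect_true(all(diff(res$q_value[o]) >= 0))
    cnt <- count_directional(res)
    expect_gt(cnt[["n_hypo"]], cnt[["n_hyper"]])
  }
})

test_that("the permutation null erases the storage signal", {
  d <- small_dataset(seed = 55, n_cpgs = 2000, n_samples = 126, r = 0.002)
  m <- beta_to_m(d$beta)
  # the unpermuted data does carry signal
  obs <- run_cpg_analysis(m, d$sheet)
  expect_gt(sum(count_directional(obs)), 0)

  perm <- permutation_null(m, d$sheet, seed = 17)
  perm2 <- permutation_null(m, d$sheet, seed = 17)
  expect_identical(perm$p_value, perm2$p_value)   # seed-reproducible
  expect_identical(unname(count_directional(perm)), c(0L, 0L))

  # permuting already-null data leaves p uniform
  d0 <- small_dataset(seed = 56, n_cpgs = 2000, n_samples = 60, r = 0)
  p0 <- permutation_null(beta_to_m(d0$beta), d0$sheet, seed = 4)$p_value
  expect_gt(stats::ks.test(p0, "punif")$p.value, 0.01)
})

test_that("mean information criteria penalize pure-noise covariates on null data", {
  d <- small_dataset(seed = 66, n_cpgs = 500, n_samples = 50, r = 0)
  m <- beta_to_m(d$beta)
  # identical designs give identical means
  ic <- mean_information_criteria(m, d$sheet, models = c("reduced", "reduced"))
  expect_equal(ic$mean_aic[1], ic$mean_aic[2])
  # the full design adds uninformative covariates (r = 0): mean AIC rises
  ic2 <- mean_information_criteria(m, d$sheet)
  expect_gt(ic2$mean_aic[ic2$model == "full"],
            ic2$mean_aic[ic2$model == "reduced"])
})
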