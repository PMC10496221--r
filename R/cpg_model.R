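#' Per-CpG linear model fits
#'
#' Fits the design to every CpG by least squares. Missing values are
#' handled per CpG by complete-case omission, so the residual degrees of
#' freedom `df_residual = n_g - k` vary by CpG; CpGs with fewer than one
#' residual degree of freedom are flagged (`usable = FALSE`) and excluded
#' from moderation and testing downstream.
#'
#' @param matrix a `meth_matrix` (M or beta scale) with samples matching
#'   the design rows.
#' @param design design matrix from [model_design()] (intercept first).
#' @param coef name of the term whose slope is tested; default
#'   `"storage_dna_years"`.
#' @return data.frame: `cpg_id`, `slope` (change in methylation value per
#'   year of storage), `sigma` (residual SD), `df_residual`,
#'   `stdev_unscaled` (design-dependent standard-error factor), `usable`.
#' @export
fit_cpg_linear <- function(matrix, design, coef = "storage_dna_years") {
  Y <- unclass(matrix)
  X <- as.matrix(design)
  if (ncol(Y) != nrow(X)) stop("matrix samples and design rows differ")
  if (!coef %in% colnames(X)) stop("design has no '", coef, "' column")
  qx <- qr(X)
  if (qx$rank < ncol(X)) stop("design matrix is rank deficient")
  n <- nrow(X); k <- ncol(X)
  ci <- match(coef, colnames(X))
  m <- nrow(Y)
  slope <- sigma <- rep(NA_real_, m)
  dfres <- rep(NA_real_, m)
  u <- rep(NA_real_, m)

  complete <- !rowSums(is.na(Y))
  if (any(complete)) {
    XtXi <- chol2inv(chol(crossprod(X)))
    coefs <- Y[complete, , drop = FALSE] %*% X %*% XtXi
    res <- Y[complete, , drop = FALSE] - coefs %*% t(X)
    slope[complete] <- coefs[, ci]
    dfres[complete] <- n - k
    sigma[complete] <- sqrt(rowSums(res^2) / (n - k))
    u[complete] <- sqrt(XtXi[ci, ci])
  }
  for (g in which(!complete)) {
    ok <- !is.na(Y[g, ])
    ng <- sum(ok)
    dfres[g] <- ng - k
    if (ng <= k) next
    Xg <- X[ok, , drop = FALSE]
    if (qr(Xg)$rank < k) { dfres[g] <- 0; next }
    fit <- stats::lm.fit(Xg, Y[g, ok])
    slope[g] <- fit$coefficients[ci]
    sigma[g] <- sqrt(sum(fit$residuals^2) / (ng - k))
    u[g] <- sqrt(chol2inv(chol(crossprod(Xg)))[ci, ci])
  }
  data.frame(cpg_id = rownames(Y), slope = slope, sigma = sigma,
             df_residual = dfres, stdev_unscaled = u,
             usable = !is.na(slope) & dfres >= 1,
             stringsAsFactors = FALSE)
}

# Inverse of the trigamma function by Newton iteration on 1/trigamma,
# which is nearly linear; standard numerics for the moment estimator below.
.trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:75) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2L)
    x <- x + dif
    if (abs(dif / x) < 1e-10) break
  }
  x
}

#' Empirical-Bayes squeezing of per-CpG variances
#'
#' Models the per-CpG sample variances as scaled F draws around a prior
#' variance `s0^2` with prior degrees of freedom `d0`, estimating
#' `(d0, s0^2)` by matching the mean and variance of
#' `log s_g^2` to their theoretical values via the digamma/trigamma moment
#' equations, and returns the posterior (squeezed) variances
#' `(d0 s0^2 + d_g s_g^2) / (d0 + d_g)`. When the observed log-variances
#' are no more dispersed than chance (`d0 = Inf`) every posterior variance
#' equals `s0^2`.
#'
#' @param s2 per-CpG sample variances.
#' @param df per-CpG residual degrees of freedom (recycled if scalar).
#' @param df_prior optionally force `d0` (e.g. `Inf`) instead of
#'   estimating it.
#' @return list: `df_prior` (d0), `var_prior` (s0^2), `var_post`
#'   (squeezed variances, same length as `s2`).
#' @export
squeeze_var <- function(s2, df, df_prior = NULL) {
  df <- rep_len(df, length(s2))
  est <- is.finite(s2) & s2 > 0 & df >= 1
  if (sum(est) < 2L) stop("need at least 2 positive finite variances")
  if (is.null(df_prior)) {
    z <- log(s2[est])
    e <- z - digamma(df[est] / 2) + log(df[est] / 2)
    emean <- mean(e)
    evar <- sum((e - emean)^2) / (sum(est) - 1)
    excess <- evar - mean(trigamma(df[est] / 2))
    if (excess > 0) {
      d0 <- 2 * .trigamma_inverse(excess)
      s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
    } else {
      # log-variances no more dispersed than chance: all true variances equal,
      # best estimated by the plain mean of the sample variances
      d0 <- Inf
      s0_sq <- mean(s2[est])
    }
  } else {
    d0 <- df_prior
    if (d0 <= 0) stop("df_prior must be positive")
    z <- log(s2[est])
    e <- z - digamma(df[est] / 2) + log(df[est] / 2)
    s0_sq <- if (is.finite(d0))
      exp(mean(e) + digamma(d0 / 2) - log(d0 / 2)) else mean(s2[est])
  }
  var_post <- if (is.finite(d0))
    (d0 * s0_sq + df * pmax(s2, 0)) / (d0 + df)
  else rep(s0_sq, length(s2))
  var_post[!est & !(is.finite(s2) & s2 == 0 & df >= 1)] <- NA_real_
  list(df_prior = d0, var_prior = s0_sq, var_post = var_post)
}

#' Moderated t-statistics
#'
#' t = slope / (sqrt(var_post) * stdev_unscaled), referred to a t
#' distribution on `df_residual + df_prior` degrees of freedom (normal when
#' the prior degrees of freedom are infinite).
#'
#' @param slope per-CpG slopes.
#' @param stdev_unscaled design-dependent standard-error factors.
#' @param var_post squeezed variances from [squeeze_var()].
#' @param df_prior prior degrees of freedom d0.
#' @param df_residual per-CpG residual degrees of freedom.
#' @return list: `t`, `p_value` (two-sided), `df_total`.
#' @export
moderated_t <- function(slope, stdev_unscaled, var_post, df_prior,
                        df_residual) {
  se <- sqrt(var_post) * stdev_unscaled
  t <- ifelse(se > 0, slope / se, sign(slope) * Inf)
  t[slope == 0] <- 0
  df_total <- df_residual + df_prior
  p <- 2 * stats::pt(-abs(t), df = df_total)
  list(t = t, p_value = p, df_total = df_total)
}

#' Storey q-values
#'
#' Estimates the null proportion pi0 from `pi0(lambda) = #[p > lambda] /
#' (m (1 - lambda))` over `lambda = 0.05, 0.10, ..., 0.95`, smoothed by a
#' cubic smoothing spline (3 degrees of freedom) and evaluated at
#' `lambda = 0.95`, clipped into (0, 1]. Then
#' `q_(i) = min_{j >= i} pi0 * m * p_(j) / j`, so q is monotone
#' non-decreasing in p and tied p-values share one q-value.
#'
#' @param p p-values in \[0,1\].
#' @param lambda grid for pi0 estimation.
#' @param smooth_df spline degrees of freedom.
#' @param pi0 optionally force pi0 (e.g. 1 for the Benjamini-Hochberg
#'   special case) instead of estimating it.
#' @return q-values in the input order, with the pi0 used attached as
#'   attribute `"pi0"`.
#' @export
storey_qvalue <- function(p, lambda = seq(0.05, 0.95, by = 0.05),
                          smooth_df = 3, pi0 = NULL) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0,1] with no missing values")
  m <- length(p)
  if (is.null(pi0)) {
    if (m < 2L * length(lambda)) {
      pi0 <- 1
    } else {
      pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
      fit <- stats::smooth.spline(lambda, pi0_l, df = smooth_df)
      pi0 <- stats::predict(fit, x = max(lambda))$y
    }
  }
  pi0 <- min(max(pi0, 1e-8), 1)
  o <- order(p)
  q <- pi0 * m * p[o] / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  attr(out, "pi0") <- pi0
  out
}

#' Count hypo- and hypermethylated CpGs at a q-value threshold
#'
#' @param results a CpG result table with `q_value` and `direction` (or
#'   `slope`) columns.
#' @param q_threshold significance threshold; strictly `q < q_threshold`.
#' @return named integer vector `c(n_hypo, n_hyper)`.
#' @export
count_directional <- function(results, q_threshold = 0.05) {
  if (nrow(results) == 0L) return(c(n_hypo = 0L, n_hyper = 0L))
  sig <- !is.na(results$q_value) & results$q_value < q_threshold
  hypo <- if (!is.null(results$direction)) results$direction == "hypo"
          else results$slope < 0
  c(n_hypo = sum(sig & hypo), n_hyper = sum(sig & !hypo))
}

#' Differential methylation across storage duration, per CpG
#'
#' The per-CpG analysis: least-squares fit of methylation on storage
#' duration (plus covariates for the full model), empirical-Bayes variance
#' moderation, two-sided moderated-t p-values, Storey q-values and
#' direction calls. Runs on whichever scale the input matrix declares (M by
#' default in practice; beta-scale runs are supported and preserve the
#' directional analysis).
#'
#' @param matrix a `meth_matrix`.
#' @param sheet a [sample_sheet()] (samples are aligned to the matrix).
#' @param props optional cell-type proportions for the full model.
#' @param model `"reduced"` or `"full"`.
#' @param moderation use the moderated t (default); `FALSE` gives the
#'   ordinary per-CpG t-test.
#' @param pi0 optional forced pi0 for [storey_qvalue()].
#' @return data.frame of class `cpg_results`: `cpg_id`, `slope`, `sigma`,
#'   `df_residual`, `t`, `p_value`, `q_value`, `direction`; attributes
#'   `scale`, `df_prior`, `var_prior`, `pi0`.
#' @export
run_cpg_analysis <- function(matrix, sheet, props = NULL,
                             model = c("reduced", "full"),
                             moderation = TRUE, pi0 = NULL) {
  model <- match.arg(model)
  al <- align_dataset(matrix, sheet)
  X <- .build_design(al$sheet, props, model)
  fit <- fit_cpg_linear(al$matrix, X)
  res <- fit[fit$usable, , drop = FALSE]
  if (nrow(res) == 0L) stop("no CpGs with enough residual degrees of freedom")
  if (moderation) {
    sq <- squeeze_var(res$sigma^2, res$df_residual)
    mt <- moderated_t(res$slope, res$stdev_unscaled, sq$var_post,
                      sq$df_prior, res$df_residual)
    d0 <- sq$df_prior; s0 <- sq$var_prior
  } else {
    se <- res$sigma * res$stdev_unscaled
    t <- ifelse(se > 0, res$slope / se, sign(res$slope) * Inf)
    t[res$slope == 0] <- 0
    mt <- list(t = t,
               p_value = 2 * stats::pt(-abs(t), df = res$df_residual))
    d0 <- 0; s0 <- NA_real_
  }
  q <- storey_qvalue(mt$p_value, pi0 = pi0)
  out <- data.frame(cpg_id = res$cpg_id, slope = res$slope,
                    sigma = res$sigma, df_residual = res$df_residual,
                    t = mt$t, p_value = mt$p_value, q_value = as.numeric(q),
                    direction = ifelse(res$slope < 0, "hypo", "hyper"),
                    stringsAsFactors = FALSE)
  attr(out, "scale") <- meth_scale(matrix)
  attr(out, "df_prior") <- d0
  attr(out, "var_prior") <- s0
  attr(out, "pi0") <- attr(q, "pi0")
  class(out) <- c("cpg_results", "data.frame")
  out
}

#' Permutation null for the per-CpG analysis
#'
#' Randomly reassigns storage duration as DNA across samples (all other
#' covariates stay attached to their samples) and reruns the full per-CpG
#' pipeline. Destroying the storage-methylation link this way should yield
#' no differentially methylated CpGs; a single permutation is the default
#' diagnostic, `n_perm > 1` supports calibration studies.
#'
#' @param matrix a `meth_matrix`.
#' @param sheet a [sample_sheet()].
#' @param seed RNG seed for the permutation(s).
#' @param n_perm number of permutations.
#' @param ... passed to [run_cpg_analysis()].
#' @return a `cpg_results` table (or a list of them when `n_perm > 1`).
#' @export
permutation_null <- function(matrix, sheet, seed, n_perm = 1, ...) {
  set.seed(seed)
  runs <- lapply(seq_len(n_perm), function(i) {
    perm_sheet <- sheet
    perm_sheet$storage_dna_years <- sample(sheet$storage_dna_years)
    run_cpg_analysis(matrix, perm_sheet, ...)
  })
  if (n_perm == 1L) runs[[1L]] else runs
}

#' Mean per-CpG information criteria for competing designs
#'
#' Per-CpG Gaussian AIC and BIC (maximum-likelihood variance; the variance
#' counts as a parameter) averaged over CpGs, for each requested design --
#' the summary used to ask whether covariates earn their complexity in the
#' per-CpG models.
#'
#' @param matrix a `meth_matrix`.
#' @param sheet a [sample_sheet()].
#' @param props optional cell-type proportions (full model).
#' @param models character vector of designs to compare.
#' @return data.frame: `model`, `mean_aic`, `mean_bic`, `n_cpgs`.
#' @export
mean_information_criteria <- function(matrix, sheet, props = NULL,
                                      models = c("reduced", "full")) {
  al <- align_dataset(matrix, sheet)
  rows <- lapply(models, function(mod) {
    X <- .build_design(al$sheet, props, mod)
    fit <- fit_cpg_linear(al$matrix, X)
    ok <- fit$usable & fit$sigma > 0
    k <- ncol(X)
    ng <- fit$df_residual[ok] + k
    rss <- fit$sigma[ok]^2 * fit$df_residual[ok]
    ll <- -ng / 2 * (log(2 * pi * rss / ng) + 1)
    data.frame(model = mod,
               mean_aic = mean(-2 * ll + 2 * (k + 1)),
               mean_bic = mean(-2 * ll + (k + 1) * log(ng)),
               n_cpgs = sum(ok), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
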