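#' Huber robust linear regression via IRLS
#'
#' M-estimation with the Huber loss, fit by iteratively reweighted least
#' squares. The scale is re-estimated at every iteration as the median
#' absolute residual times the Gaussian consistency factor 1.4826, floored
#' at `scale_floor` so exact fits do not divide by zero. Iteration stops
#' when the largest coefficient change drops below `tol`.
#'
#' Standard errors use the asymptotic covariance of the Huber estimator,
#' `s^2 * [sum psi(u)^2 / (n - k)] / [mean psi'(u)]^2 * (X'X)^{-1}`, with
#' Wald 95 percent confidence intervals and p-values from the normal
#' approximation. As `k_tune` grows the fit converges to ordinary least
#' squares.
#'
#' Near-collinear designs (the six cell proportions plus intercept sum to
#' about 1) are fit as-is; only if the design is numerically rank deficient
#' (condition number above 1e10) is the last dependent column dropped, with
#' a warning.
#'
#' @param X design matrix (first column the intercept).
#' @param y response vector.
#' @param k_tune Huber tuning constant; default 1.345 (95 percent Gaussian
#'   efficiency).
#' @param tol convergence tolerance on coefficients.
#' @param max_iter maximum IRLS iterations; non-convergence is an error
#'   carrying the iteration trace.
#' @param scale_floor lower bound for the robust scale.
#' @return a `robust_fit` list: `coefficients`, `se`, `ci` (2-column
#'   matrix), `p_value`, `scale`, `aic`, `bic`, `n`, `k`, `residuals`,
#'   `fitted`, `weights`, `iterations`, `dropped_terms`.
#' @export
huber_irls <- function(X, y, k_tune = 1.345, tol = 1e-8, max_iter = 200,
                       scale_floor = 1e-10) {
  X <- as.matrix(X)
  keep <- stats::complete.cases(X, y)
  X <- X[keep, , drop = FALSE]
  y <- y[keep]
  n <- nrow(X)
  dropped <- character(0)
  # drop dependent columns only when the design is numerically singular
  sv <- svd(scale(X, center = FALSE, scale = sqrt(colSums(X^2))))$d
  if (min(sv) <= 0 || max(sv) / min(sv) > 1e10) {
    qx <- qr(X)
    if (qx$rank == ncol(X))
      stop("design is numerically singular")
    bad <- qx$pivot[-seq_len(qx$rank)]
    dropped <- colnames(X)[bad]
    warning("dropping collinear term(s): ", paste(dropped, collapse = ", "))
    X <- X[, -bad, drop = FALSE]
  }
  k <- ncol(X)
  if (n <= k) stop("need more observations than parameters")
  beta <- stats::lm.fit(X, y)$coefficients
  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  s <- scale_floor
  for (iter in seq_len(max_iter)) {
    r <- y - drop(X %*% beta)
    s <- max(stats::median(abs(r)) * 1.4826, scale_floor)
    w <- pmin(1, k_tune * s / pmax(abs(r), .Machine$double.eps))
    fit <- stats::lm.wfit(X, y, w)
    delta <- max(abs(fit$coefficients - beta))
    beta <- fit$coefficients
    trace <- c(trace, delta)
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    err <- simpleError(sprintf(
      "Huber IRLS did not converge in %d iterations (last delta %.3g)",
      max_iter, trace[length(trace)]))
    err$trace <- trace
    stop(err)
  }
  r <- y - drop(X %*% beta)
  u <- r / s
  psi <- pmax(-k_tune, pmin(k_tune, u))
  psi_prime <- as.numeric(abs(u) <= k_tune)
  denom <- mean(psi_prime)^2
  tau2 <- s^2 * sum(psi^2) / (n - k) / max(denom, .Machine$double.eps)
  XtX_inv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(tau2 * diag(XtX_inv))
  z <- beta / se
  p <- 2 * stats::pnorm(-abs(z))
  ci <- cbind(lower = beta - stats::qnorm(0.975) * se,
              upper = beta + stats::qnorm(0.975) * se)
  ic <- .gaussian_ic(r, s, n, k)
  structure(list(coefficients = beta, se = se, ci = ci, p_value = p,
                 scale = s, aic = ic["aic"], bic = ic["bic"], n = n, k = k,
                 loglik = ic["loglik"], residuals = r,
                 fitted = drop(X %*% beta), weights = w,
                 iterations = iter, dropped_terms = dropped,
                 k_tune = k_tune),
            class = "robust_fit")
}

# Gaussian log-likelihood at the supplied coefficients and scale, and the
# derived information criteria. The scale counts as one extra parameter.
.gaussian_ic <- function(residuals, sigma, n, k) {
  sigma <- max(sigma, 1e-10)
  loglik <- -n / 2 * log(2 * pi) - n * log(sigma) -
    sum(residuals^2) / (2 * sigma^2)
  c(loglik = loglik,
    aic = -2 * loglik + 2 * (k + 1),
    bic = -2 * loglik + (k + 1) * log(n))
}

#' Information criteria of a robust fit
#'
#' AIC and BIC from the Gaussian log-likelihood evaluated at the robust
#' coefficients and robust scale: `AIC = -2 l + 2 (k + 1)`,
#' `BIC = -2 l + (k + 1) log n`, counting the scale as a parameter. A
#' documented convention -- robust fits have no canonical likelihood -- that
#' is monotone in the residual sum of squares and supports nested-model
#' comparison.
#'
#' @param fit a `robust_fit`.
#' @return named vector `c(aic, bic)`.
#' @export
information_criteria <- function(fit) {
  stopifnot(inherits(fit, "robust_fit"))
  c(aic = unname(fit$aic), bic = unname(fit$bic))
}

#' @export
print.robust_fit <- function(x, ...) {
  cat(sprintf("Huber robust fit: n = %d, k = %d, scale = %.4g, AIC = %.1f, BIC = %.1f\n",
              x$n, x$k, x$scale, x$aic, x$bic))
  tab <- data.frame(estimate = x$coefficients,
                    ci_lower = x$ci[, "lower"], ci_upper = x$ci[, "upper"],
                    p_value = signif(x$p_value, 2))
  print(tab, digits = 4)
  invisible(x)
}

# Build the covariate design shared by the global and per-CpG models.
# reduced: intercept + storage as DNA.
# full: adds storage as buffy coat (years, when recorded), age, and the six
# cell-type proportions.
.build_design <- function(sheet, props = NULL,
                          model = c("reduced", "full")) {
  model <- match.arg(model)
  X <- cbind(intercept = rep(1, nrow(sheet)),
             storage_dna_years = sheet$storage_dna_years)
  if (model == "full") {
    if (!is.null(sheet$storage_buffy_days))
      X <- cbind(X, storage_buffy_years =
                   sheet$storage_buffy_days / DAYS_PER_YEAR)
    X <- cbind(X, age_years = sheet$age_years)
    if (!is.null(props)) {
      props <- props[match(sheet$sample_id, rownames(props)), ,
                     drop = FALSE]
      if (anyNA(props))
        stop("cell proportions missing for some samples")
      X <- cbind(X, props[, CELL_TYPES, drop = FALSE])
    }
  }
  rownames(X) <- sheet$sample_id
  X
}

#' Design matrix for the storage-duration models
#'
#' The reduced model regresses on storage duration as DNA alone; the full
#' model additionally adjusts for storage as buffy coat (when recorded),
#' age, and the six estimated cell-type proportions. All durations and ages
#' enter in years.
#'
#' @param sheet a [sample_sheet()].
#' @param props optional sample x cell-type proportion matrix.
#' @param model `"reduced"` or `"full"`.
#' @return numeric design matrix with named columns, intercept first.
#' @export
model_design <- function(sheet, props = NULL,
                         model = c("reduced", "full")) {
  .build_design(sheet, props, match.arg(model))
}

#' Fit reduced and full global-methylation models
#'
#' Robustly regresses per-sample mean global methylation on storage
#' duration as DNA (reduced model) and on storage plus covariates (full
#' model), on the identical sample set, and reports coefficients, Wald
#' intervals, p-values and information criteria for both.
#'
#' @param global_meth named per-sample response, typically from
#'   [mean_global_methylation()].
#' @param sheet a [sample_sheet()].
#' @param props optional sample x cell-type proportions for the full model.
#' @param ... passed to [huber_irls()].
#' @return list with elements `reduced` and `full` (each a `robust_fit`)
#'   and `comparison` (data.frame of AIC/BIC).
#' @export
fit_global_models <- function(global_meth, sheet, props = NULL, ...) {
  y <- global_meth[sheet$sample_id]
  X_full <- .build_design(sheet, props, "full")
  X_red <- .build_design(sheet, props, "reduced")
  ok <- stats::complete.cases(X_full, y)   # identical sample set for both
  reduced <- huber_irls(X_red[ok, , drop = FALSE], y[ok], ...)
  full <- huber_irls(X_full[ok, , drop = FALSE], y[ok], ...)
  comparison <- data.frame(model = c("reduced", "full"),
                           aic = c(reduced$aic, full$aic),
                           bic = c(reduced$bic, full$bic))
  list(reduced = reduced, full = full, comparison = comparison)
}
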