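#' Reference-based cell-type deconvolution
#'
#' Estimates six blood leukocyte proportions (CD8T, CD4T, NK, Bcell, Mono,
#' Gran) per sample by constrained projection of the sample's beta profile
#' onto cell-type reference profiles: for each sample,
#' `w = argmin ||y - B w||^2` subject to `w_k >= 0`. No sum-to-one
#' constraint is imposed -- estimates need not sum exactly to 1, which is
#' why downstream models include all six terms plus an intercept -- but
#' sums far outside \[0.9, 1.1\] trigger a warning.
#'
#' @param profiles beta-scale matrix (CpG x sample) or `meth_matrix`;
#'   restricted to the CpGs shared with the reference.
#' @param reference CpG x cell-type matrix of reference betas with the six
#'   [CELL_TYPES] as columns and no missing values.
#' @return sample x cell-type matrix of non-negative weights.
#' @export
estimate_cell_proportions <- function(profiles, reference) {
  if (inherits(profiles, "meth_matrix") && meth_scale(profiles) != "beta")
    stop("deconvolution operates on the beta scale")
  if (is.null(colnames(reference)) ||
      !setequal(colnames(reference), CELL_TYPES))
    stop("reference columns must be exactly the six blood cell types")
  reference <- reference[, CELL_TYPES, drop = FALSE]
  if (anyNA(reference)) stop("reference matrix must have no missing entries")
  if (is.null(dim(profiles)))
    profiles <- matrix(profiles, ncol = 1L,
                       dimnames = list(names(profiles), "sample1"))
  shared <- intersect(rownames(reference), rownames(profiles))
  if (length(shared) < 2L * ncol(reference))
    stop("too few CpGs shared with the reference (", length(shared),
         "); need at least ", 2L * ncol(reference))
  B <- reference[shared, , drop = FALSE]
  if (qr(B)$rank < ncol(B))
    stop("reference matrix is rank deficient; cell types are not separable")
  Y <- unclass(profiles)[shared, , drop = FALSE]
  W <- matrix(NA_real_, nrow = ncol(Y), ncol = ncol(B),
              dimnames = list(colnames(Y), colnames(B)))
  for (i in seq_len(ncol(Y))) {
    y <- Y[, i]
    ok <- !is.na(y)
    if (sum(ok) < 2L * ncol(B))
      stop("sample '", colnames(Y)[i], "' has too few non-missing reference CpGs")
    W[i, ] <- pracma::lsqnonneg(B[ok, , drop = FALSE], y[ok])$x
  }
  sums <- rowSums(W)
  off <- sums < 0.9 | sums > 1.1
  if (any(off))
    warning(sum(off), " sample(s) have estimated proportions summing ",
            "outside [0.9, 1.1]")
  W
}
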