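#' Convert beta values to M values
#'
#' M = log2(b / (1 - b)) after clipping b into \[epsilon, 1 - epsilon\].
#' Clipping keeps M finite for fully (un)methylated CpGs with negligible
#' distortion elsewhere. Missing values stay missing.
#'
#' @param beta numeric vector/matrix or a `meth_matrix` on the beta scale.
#' @param epsilon clipping bound, in (0, 0.5); default `1e-6`.
#' @return same shape as the input, on the M scale.
#' @export
beta_to_m <- function(beta, epsilon = 1e-6) {
  if (epsilon <= 0 || epsilon >= 0.5) stop("epsilon must lie in (0, 0.5)")
  is_mm <- inherits(beta, "meth_matrix")
  if (is_mm && meth_scale(beta) != "beta")
    stop("matrix is not on the beta scale")
  x <- unclass(beta)
  if (any(!is.na(x) & (x < 0 | x > 1))) stop("beta values must lie in [0,1]")
  m <- log2(pmin(pmax(x, epsilon), 1 - epsilon) /
              (1 - pmin(pmax(x, epsilon), 1 - epsilon)))
  if (is.matrix(x)) dimnames(m) <- dimnames(x)
  if (is_mm) m <- methylation_matrix(m, "M")
  m
}

#' Convert M values to beta values
#'
#' beta = 2^M / (1 + 2^M), the inverse of [beta_to_m()] away from the
#' clipping bounds.
#'
#' @param m numeric vector/matrix or a `meth_matrix` on the M scale.
#' @return same shape as the input, on the beta scale.
#' @export
m_to_beta <- function(m) {
  is_mm <- inherits(m, "meth_matrix")
  if (is_mm && meth_scale(m) != "M") stop("matrix is not on the M scale")
  x <- unclass(m)
  b <- 1 / (1 + 2^(-x))
  if (is.matrix(x)) dimnames(b) <- dimnames(x)
  if (is_mm) b <- methylation_matrix(b, "beta")
  b
}

#' Remove probes named on exclusion lists
#'
#' Drops every CpG whose id appears on any of the supplied lists (e.g.
#' cross-reactive probes, SNP-proximal probes). The number removed per list
#' is reported and attached as the `"filter_log"` attribute.
#'
#' @param matrix a `meth_matrix`.
#' @param ... one or more character vectors of CpG ids; names are used in the
#'   log.
#' @return the filtered matrix.
#' @export
filter_probe_lists <- function(matrix, ...) {
  lists <- list(...)
  if (length(lists) == 1L && is.list(lists[[1L]]) &&
      !is.character(lists[[1L]]))
    lists <- lists[[1L]]
  if (is.null(names(lists)) || any(!nzchar(names(lists))))
    names(lists) <- paste0("list", seq_along(lists))
  log <- integer(0)
  for (nm in names(lists)) {
    hit <- rownames(matrix) %in% lists[[nm]]
    log[nm] <- sum(hit)
    if (any(hit)) matrix <- matrix[!hit, , drop = FALSE]
  }
  if (length(log))
    message("probe filter removed: ",
            paste(sprintf("%s=%d", names(log), log), collapse = ", "))
  attr(matrix, "filter_log") <- log
  matrix
}

#' Remove poorly detected probes
#'
#' A CpG is dropped iff its detection p-value exceeds `threshold` in at
#' least one sample (the "any sample" rule; strictly greater, so ties at the
#' threshold are kept).
#'
#' @param matrix a `meth_matrix`.
#' @param detp detection p-value matrix with the same CpG/sample ids.
#' @param threshold detection p-value cut-off; default 0.01.
#' @return the filtered matrix, with the number removed in attribute
#'   `"n_detection_removed"`.
#' @export
filter_detection <- function(matrix, detp, threshold = 0.01) {
  if (!all(rownames(matrix) %in% rownames(detp)))
    stop("detection p matrix is missing some CpGs")
  if (!all(colnames(matrix) %in% colnames(detp)))
    stop("detection p matrix is missing some samples")
  d <- detp[rownames(matrix), colnames(matrix), drop = FALSE]
  bad <- rowSums(d > threshold, na.rm = TRUE) > 0L
  out <- matrix[!bad, , drop = FALSE]
  if (any(bad))
    message(sprintf("detection filter removed %d CpG(s)", sum(bad)))
  attr(out, "n_detection_removed") <- sum(bad)
  out
}

#' Per-sample mean global methylation
#'
#' Column means of the M-value matrix over non-missing entries: the
#' single-number global methylation summary regressed on storage duration.
#'
#' @param matrix a `meth_matrix` on the M scale (pass the beta matrix
#'   through [beta_to_m()] first).
#' @return named numeric vector, one mean per sample.
#' @export
mean_global_methylation <- function(matrix) {
  if (meth_scale(matrix) != "M")
    stop("global methylation is summarized on the M scale; convert first")
  colMeans(unclass(matrix), na.rm = TRUE)
}
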