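.logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Noncentral hypergeometric log point probabilities for cell 'a' over its
# support, given margins (row1 = a+b, row2 = c+d, col1 = a+c) and log odds
# ratio. Computed via log-gamma (lchoose) so large tables stay exact;
# support size is bounded by the smallest margin.
.nchg_logprob <- function(m1, m2, n1, log_or = 0) {
  lo <- max(0, n1 - m2)
  hi <- min(n1, m1)
  x <- lo:hi
  lp <- lchoose(m1, x) + lchoose(m2, n1 - x) + x * log_or
  list(x = x, logp = lp - .logsumexp(lp), lo = lo, hi = hi)
}

#' Fisher's exact test for a 2x2 table
#'
#' Exact inference for the odds ratio of a 2x2 contingency table under the
#' noncentral hypergeometric model, following the conventions of the
#' standard exact-test report: the two-sided p-value sums the hypergeometric
#' point probabilities no larger than that of the observed table (the
#' point-probability criterion, not doubling), the odds ratio is the
#' conditional maximum-likelihood estimate given all margins, and the
#' 95 percent confidence interval inverts the two one-sided exact tests.
#' Probabilities are computed from log-gamma functions so large tables stay
#' exact. The cross-product sample odds ratio `ad / bc` is also reported.
#'
#' @param a,b,c,d the table cells (`a` = in-category and in-list), or pass a
#'   2x2 matrix / length-4 vector as `a`.
#' @param conf_level confidence level for the interval.
#' @param estimate compute the CMLE odds ratio and its interval (default);
#'   `FALSE` returns the p-value and sample odds ratio only, which is much
#'   faster when scanning many tables.
#' @return list: `p_value`, `odds_ratio` (CMLE; 0 or Inf at the support
#'   edges), `conf_int`, `sample_or`, `table`.
#' @export
fisher_exact <- function(a, b = NULL, c = NULL, d = NULL,
                         conf_level = 0.95, estimate = TRUE) {
  if (is.null(b)) {
    cells <- as.vector(a)
    if (length(cells) != 4L) stop("need a 2x2 table")
    a <- cells[1L]; b <- cells[2L]; c <- cells[3L]; d <- cells[4L]
  }
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != round(cells)))
    stop("table cells must be non-negative integers")
  m1 <- a + b; m2 <- c + d; n1 <- a + c; n2 <- b + d
  if (min(m1, m2, n1, n2) == 0)
    stop("all table margins must be positive for odds-ratio estimation")

  null <- .nchg_logprob(m1, m2, n1, 0)
  obs <- which(null$x == a)
  # relative tolerance guards against ties broken by floating-point noise
  p_value <- sum(exp(null$logp[null$logp <= null$logp[obs] + 1e-7]))
  p_value <- min(p_value, 1)
  sample_or <- (a * d) / (b * c)
  if (!estimate)
    return(list(p_value = p_value, odds_ratio = NA_real_,
                conf_int = c(lower = NA_real_, upper = NA_real_),
                sample_or = sample_or, table = cells))

  cond_mean <- function(log_or) {
    g <- .nchg_logprob(m1, m2, n1, log_or)
    sum(g$x * exp(g$logp))
  }
  p_upper_tail <- function(log_or) {  # P(X >= a)
    g <- .nchg_logprob(m1, m2, n1, log_or)
    exp(.logsumexp(g$logp[g$x >= a]))
  }
  p_lower_tail <- function(log_or) {  # P(X <= a)
    g <- .nchg_logprob(m1, m2, n1, log_or)
    exp(.logsumexp(g$logp[g$x <= a]))
  }
  solve_log_or <- function(f, target, increasing) {
    root <- stats::uniroot(function(t) f(t) - target, c(-5, 5),
                           extendInt = if (increasing) "upX" else "downX",
                           tol = 1e-10, maxiter = 2000)
    root$root
  }
  odds_ratio <- if (a == null$lo) 0 else if (a == null$hi) Inf else
    exp(solve_log_or(cond_mean, a, increasing = TRUE))
  alpha <- (1 - conf_level) / 2
  ci_lower <- if (a == null$lo) 0 else
    exp(solve_log_or(p_upper_tail, alpha, increasing = TRUE))
  ci_upper <- if (a == null$hi) Inf else
    exp(solve_log_or(p_lower_tail, alpha, increasing = FALSE))
  list(p_value = p_value, odds_ratio = odds_ratio,
       conf_int = c(lower = ci_lower, upper = ci_upper),
       sample_or = sample_or, table = cells)
}

#' Replicated hypomethylated CpGs across two cohorts
#'
#' Builds the list of CpGs hypomethylated (negative slope) at
#' `q < q_threshold` in the discovery cohort and at `p < p_threshold` in
#' the validation cohort, over the CpGs shared by both result tables, and
#' cross-classifies the shared CpGs by the two criteria into a 2x2 table
#' testing whether discovery hits replicate more often than chance.
#'
#' @param discovery,validation `cpg_results` tables.
#' @param q_threshold discovery q-value threshold.
#' @param p_threshold validation p-value threshold.
#' @return list: `ids` (replicated CpGs), `table` (named cells: `a` = hypo
#'   in both, `b` = discovery only, `c` = validation only, `d` = neither),
#'   `test` (the [fisher_exact()] result; an infinite odds ratio is
#'   reported as such).
#' @export
replicated_hypo_list <- function(discovery, validation,
                                 q_threshold = 0.05, p_threshold = 0.05) {
  shared <- intersect(discovery$cpg_id, validation$cpg_id)
  if (length(shared) == 0L) stop("no CpGs shared between the two cohorts")
  disc <- discovery[match(shared, discovery$cpg_id), ]
  val <- validation[match(shared, validation$cpg_id), ]
  disc_hit <- disc$slope < 0 & disc$q_value < q_threshold
  val_hit <- val$slope < 0 & val$p_value < p_threshold
  a <- sum(disc_hit & val_hit)
  b <- sum(disc_hit & !val_hit)
  c <- sum(!disc_hit & val_hit)
  d <- sum(!disc_hit & !val_hit)
  test <- tryCatch(fisher_exact(a, b, c, d), error = function(e) NULL)
  list(ids = shared[disc_hit & val_hit],
       table = c(a = a, b = b, c = c, d = d),
       test = test)
}

#' Enrichment of a CpG list by relation-to-island category
#'
#' For each of the six genomic-locus categories, cross-classifies all
#' tested CpGs by category membership and membership in the
#' (e.g. replicated-hypomethylated) list, and applies [fisher_exact()] per
#' category. Raw p-values are reported without multiplicity adjustment.
#' Categories with no tested CpGs are skipped with a warning.
#'
#' @param hypo_ids CpG ids in the list of interest.
#' @param tested_ids all tested CpG ids (the universe).
#' @param annotation a [probe_annotation()] covering the tested CpGs.
#' @return data.frame, one row per category: tested and validated counts,
#'   CMLE odds ratio with 95 percent CI, sample odds ratio, p-value.
#' @export
loci_enrichment <- function(hypo_ids, tested_ids, annotation) {
  tested_ids <- unique(tested_ids)
  rel <- annotation$relation_to_island[match(tested_ids, annotation$cpg_id)]
  if (anyNA(rel)) {
    message(sum(is.na(rel)), " tested CpG(s) missing from the annotation; dropped")
    tested_ids <- tested_ids[!is.na(rel)]
    rel <- rel[!is.na(rel)]
  }
  hypo_ids <- intersect(hypo_ids, tested_ids)
  in_list <- tested_ids %in% hypo_ids
  n_total <- length(tested_ids)
  n_list <- length(hypo_ids)
  rows <- list()
  for (cat in RELATION_CATEGORIES) {
    in_cat <- rel == cat
    n_cat <- sum(in_cat)
    if (n_cat == 0L) {
      warning("category '", cat, "' has no tested CpGs; skipped")
      next
    }
    a <- sum(in_cat & in_list)
    b <- n_cat - a
    c <- n_list - a
    d <- n_total - n_cat - c
    ft <- tryCatch(fisher_exact(a, b, c, d), error = function(e) {
      warning("category '", cat, "': ", conditionMessage(e))
      list(p_value = NA_real_, odds_ratio = NA_real_,
           conf_int = c(lower = NA_real_, upper = NA_real_),
           sample_or = NA_real_)
    })
    rows[[cat]] <- data.frame(
      category = cat,
      n_tested_in_category = n_cat, n_total_tested = n_total,
      n_validated_in_category = a, n_validated_total = n_list,
      odds_ratio = ft$odds_ratio,
      ci_lower = ft$conf_int[["lower"]], ci_upper = ft$conf_int[["upper"]],
      sample_or = ft$sample_or, p_value = ft$p_value,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
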