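# Small in-code fixtures shared across test files.

# A tiny beta matrix with known values.
tiny_beta <- function() {
  m <- matrix(c(0, 0.5, 1, 0.2, 0.8, 0.5), nrow = 3,
              dimnames = list(c("cg01", "cg02", "cg03"), c("A", "B")))
  methylation_matrix(m, "beta")
}

# Write a delimited table to a temp file and return its path.
write_tmp <- function(df, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  utils::write.table(df, path, sep = if (ext == ".csv") "," else "\t",
                     quote = FALSE, row.names = FALSE)
  path
}

# A small generated cohort used by several tests.
small_dataset <- function(seed = 1, n_cpgs = 800, n_samples = 40, r = 7e-4,
                          ...) {
  generate_dataset(generator_config(n_cpgs = n_cpgs, n_samples = n_samples,
                                    seed = seed, deamination_rate = r, ...))
}

# Exhaustive active-set NNLS oracle: tries every support subset, keeps
# feasible (w >= 0) candidates, returns the least-squares-best one.
nnls_oracle <- function(B, y) {
  k <- ncol(B)
  best <- rep(0, k)
  best_rss <- sum(y^2)
  for (code in seq_len(2^k) - 1L) {
    S <- which(bitwAnd(code, 2^(seq_len(k) - 1L)) > 0)
    if (length(S) == 0L) next
    w_S <- tryCatch(qr.solve(B[, S, drop = FALSE], y),
                    error = function(e) NULL)
    if (is.null(w_S) || any(w_S < -1e-10)) next
    w <- rep(0, k)
    w[S] <- pmax(w_S, 0)
    rss <- sum((y - B %*% w)^2)
    if (rss < best_rss - 1e-12) { best <- w; best_rss <- rss }
  }
  names(best) <- colnames(B)
  best
}
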