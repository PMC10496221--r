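#' Default per-category baseline beta distributions
#'
#' Mixture-of-Beta shapes for baseline (storage time zero) methylation,
#' stratified by relation to CpG island. They encode the canonical bulk
#' methylome: island CpGs mostly unmethylated; shore CpGs switch-like
#' bimodal (either fully methylated or fully unmethylated, reflecting sharp
#' methylation boundaries at island edges); shelf and open-sea CpGs highly
#' but partially methylated (imperfect maintenance in bulk tissue keeps
#' measured beta around 0.8--0.9 rather than at 1).
#'
#' Each element is a list of mixture components `list(weight, shape1,
#' shape2)`.
#'
#' @export
DEFAULT_BASELINE_SHAPES <- list(
  Island  = list(list(weight = 1.0, shape1 = 0.5, shape2 = 8)),
  N_Shore = list(list(weight = 0.5, shape1 = 0.8, shape2 = 10),
                 list(weight = 0.5, shape1 = 40,  shape2 = 1.2)),
  S_Shore = list(list(weight = 0.5, shape1 = 0.8, shape2 = 10),
                 list(weight = 0.5, shape1 = 40,  shape2 = 1.2)),
  N_Shelf = list(list(weight = 1.0, shape1 = 12,  shape2 = 2.5)),
  S_Shelf = list(list(weight = 1.0, shape1 = 12,  shape2 = 2.5)),
  OpenSea = list(list(weight = 1.0, shape1 = 20,  shape2 = 4))
)

#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the discovery cohort of the motivating study design:
#' n = 126 samples whose DNA was stored at -20 degrees C for 2.79--4.17
#' years (33.5--50.1 months), ages 38--72 years, buffy-coat storage of
#' 1--77 days before extraction, and six-cell-type blood mixtures dominated
#' by granulocytes.
#'
#' @param n_cpgs number of CpGs.
#' @param n_samples number of samples.
#' @param seed RNG seed; all randomness in [generate_dataset()] derives
#'   from it.
#' @param deamination_rate per-year rate r of hydrolytic deamination of
#'   5-methylcytosine; the methylated fraction decays as exp(-r t). The
#'   default 7e-4/year is calibrated so that roughly 0.5 percent of CpGs
#'   reach q < 0.05 at n = 126 under the default noise level, matching the
#'   magnitude of storage effects the pipeline is designed to detect.
#' @param storage_range_years min/max storage duration as DNA, years.
#' @param age_range_years min/max subject age, years.
#' @param buffy_range_days min/max storage as buffy coat, days, or `NULL`
#'   for cohorts without a buffy-coat stage.
#' @param noise_sd_m homoscedastic measurement noise SD on the M scale.
#' @param island_fractions named proportions of the six relation categories
#'   (must sum to 1); defaults follow the category composition of a typical
#'   post-QC EPIC array.
#' @param dirichlet_alpha six positive Dirichlet parameters for cell-type
#'   mixing proportions (order [CELL_TYPES]).
#' @param reference_sep beta-scale effect size separating cell-type
#'   reference profiles at discriminating CpGs.
#' @param discriminating_fraction fraction of CpGs that discriminate one
#'   cell type from the rest.
#' @param baseline_shapes per-category Beta-mixture specs; see
#'   [DEFAULT_BASELINE_SHAPES].
#' @param epsilon beta clipping bound used for M-scale noise injection.
#' @param cohort label recorded in the generated sample sheet.
#' @return a validated list of class `generator_config`.
#' @export
generator_config <- function(n_cpgs = 10000,
                             n_samples = 126,
                             seed = 1,
                             deamination_rate = 7e-4,
                             storage_range_years = c(2.79, 4.17),
                             age_range_years = c(38.1, 71.5),
                             buffy_range_days = c(1, 77),
                             noise_sd_m = 0.25,
                             island_fractions = c(Island = 0.190,
                                                  N_Shore = 0.097,
                                                  S_Shore = 0.083,
                                                  N_Shelf = 0.036,
                                                  S_Shelf = 0.034,
                                                  OpenSea = 0.560),
                             dirichlet_alpha = c(CD8T = 4, CD4T = 7.5,
                                                 NK = 2.5, Bcell = 2.5,
                                                 Mono = 4, Gran = 29.5),
                             reference_sep = 0.4,
                             discriminating_fraction = 0.02,
                             baseline_shapes = DEFAULT_BASELINE_SHAPES,
                             epsilon = 1e-6,
                             cohort = "synthetic") {
  stopifnot(n_cpgs >= 1, n_samples >= 3)
  if (deamination_rate < 0) stop("deamination rate must be >= 0")
  if (noise_sd_m < 0) stop("noise_sd_m must be >= 0")
  .check_range <- function(r, nm) {
    if (length(r) != 2L || any(is.na(r)) || r[1L] > r[2L] || r[1L] < 0)
      stop("invalid ", nm)
  }
  .check_range(storage_range_years, "storage_range_years")
  .check_range(age_range_years, "age_range_years")
  if (!is.null(buffy_range_days)) .check_range(buffy_range_days, "buffy_range_days")
  if (is.null(names(island_fractions)))
    names(island_fractions) <- RELATION_CATEGORIES
  if (!setequal(names(island_fractions), RELATION_CATEGORIES))
    stop("island_fractions must be named by the six relation categories")
  island_fractions <- island_fractions[RELATION_CATEGORIES]
  if (abs(sum(island_fractions) - 1) > 1e-8)
    stop("island_fractions must sum to 1")
  if (any(island_fractions < 0)) stop("island_fractions must be non-negative")
  if (is.null(names(dirichlet_alpha))) names(dirichlet_alpha) <- CELL_TYPES
  if (!setequal(names(dirichlet_alpha), CELL_TYPES) ||
      any(dirichlet_alpha <= 0))
    stop("dirichlet_alpha must be six positive values named by cell type")
  dirichlet_alpha <- dirichlet_alpha[CELL_TYPES]
  if (reference_sep < 0) stop("reference_sep must be >= 0")
  if (discriminating_fraction < 0 || discriminating_fraction > 1)
    stop("discriminating_fraction must lie in [0,1]")
  if (!all(RELATION_CATEGORIES %in% names(baseline_shapes)))
    stop("baseline_shapes must cover all six relation categories")
  structure(list(
    n_cpgs = as.integer(n_cpgs), n_samples = as.integer(n_samples),
    seed = seed, deamination_rate = deamination_rate,
    storage_range_years = storage_range_years,
    age_range_years = age_range_years,
    buffy_range_days = buffy_range_days,
    noise_sd_m = noise_sd_m, island_fractions = island_fractions,
    dirichlet_alpha = dirichlet_alpha, reference_sep = reference_sep,
    discriminating_fraction = discriminating_fraction,
    baseline_shapes = baseline_shapes, epsilon = epsilon,
    cohort = cohort), class = "generator_config")
}

# Draw n baseline betas from a Beta-mixture spec.
.draw_baseline <- function(n, components) {
  w <- vapply(components, `[[`, numeric(1), "weight")
  comp <- sample.int(length(components), n, replace = TRUE, prob = w)
  vapply(seq_len(n), function(i) {
    cmp <- components[[comp[i]]]
    stats::rbeta(1L, cmp$shape1, cmp$shape2)
  }, numeric(1))
}

#' Generate per-cell-type baseline reference profiles
#'
#' Assigns each CpG a relation-to-island category, draws its baseline beta
#' from the category's Beta mixture, and perturbs a discriminating subset of
#' CpGs so that one cell type differs from the rest by `reference_sep` on
#' the beta scale (mimicking the differentially methylated marker CpGs used
#' for reference-based deconvolution). With `reference_sep = 0` all
#' cell-type columns are identical.
#'
#' @param config a [generator_config()]. If `config$seed` is non-`NULL` the
#'   RNG is seeded with it, making repeated calls identical.
#' @return list with `baseline_beta` (CpG x cell-type matrix),
#'   `annotation` (a [probe_annotation()]) and `discriminating`
#'   (character ids of the marker CpGs).
#' @export
generate_reference <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_cpgs
  cpg_ids <- sprintf("cg%08d", seq_len(n))
  relation <- sample(RELATION_CATEGORIES, n, replace = TRUE,
                     prob = config$island_fractions)
  base <- numeric(n)
  for (cat in RELATION_CATEGORIES) {
    idx <- which(relation == cat)
    if (length(idx))
      base[idx] <- .draw_baseline(length(idx), config$baseline_shapes[[cat]])
  }
  B <- matrix(base, nrow = n, ncol = length(CELL_TYPES),
              dimnames = list(cpg_ids, CELL_TYPES))
  n_disc <- round(config$discriminating_fraction * n)
  disc <- character(0)
  if (n_disc > 0L) {
    disc_idx <- sample.int(n, n_disc)
    disc <- cpg_ids[disc_idx]
    target <- rep_len(seq_along(CELL_TYPES), n_disc)
    sep <- config$reference_sep
    for (j in seq_len(n_disc)) {
      g <- disc_idx[j]
      # push the target cell type away from the shared baseline, toward the
      # farther beta bound so the full separation is realized
      dir <- if (base[g] < 0.5) 1 else -1
      B[g, target[j]] <- min(max(base[g] + dir * sep, 0.001), 0.999)
    }
  }
  list(baseline_beta = B,
       annotation = probe_annotation(cpg_ids, relation),
       discriminating = disc)
}

#' Mix cell types and apply deamination decay
#'
#' Expected beta for CpG g in sample i is
#' `exp(-r * t_i) * sum_k w_ik * B_gk`: spontaneous hydrolytic deamination
#' of 5-methylcytosine converts methylated cytosines so they read as
#' unmethylated, so only the methylated fraction decays (a deaminated
#' unmethylated cytosine still reads unmethylated), with first-order
#' kinetics in storage time.
#'
#' @param baseline_beta CpG x cell-type matrix of baseline betas.
#' @param proportions sample x cell-type matrix of mixing weights.
#' @param storage_years per-sample storage durations (years).
#' @param r per-year deamination rate (>= 0).
#' @return CpG x sample matrix of expected (noise-free) betas.
#' @export
mix_and_degrade <- function(baseline_beta, proportions, storage_years, r) {
  if (r < 0) stop("deamination rate must be >= 0")
  if (ncol(baseline_beta) != ncol(proportions))
    stop("baseline and proportions disagree on cell types")
  if (nrow(proportions) != length(storage_years))
    stop("proportions and storage_years disagree on samples")
  mixture <- baseline_beta %*% t(proportions)
  decay <- exp(-r * storage_years)
  sweep(mixture, 2L, decay, `*`)
}

#' Add measurement noise on the M scale
#'
#' Expected betas are clipped into `[epsilon, 1 - epsilon]`, transformed to
#' M values, perturbed with iid Gaussian noise of SD `noise_sd_m`
#' (homoscedastic on the M scale, the scale on which linear modelling is
#' performed), and transformed back, so observed betas stay inside (0, 1).
#'
#' @param expected_beta CpG x sample matrix of expected betas (dimnames
#'   required).
#' @param noise_sd_m noise SD in M-value units (>= 0).
#' @param seed optional seed for reproducibility.
#' @param epsilon beta clipping bound.
#' @return a [methylation_matrix()] on the beta scale.
#' @export
add_noise <- function(expected_beta, noise_sd_m, seed = NULL,
                      epsilon = 1e-6) {
  if (noise_sd_m < 0) stop("noise_sd_m must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  m <- beta_to_m(expected_beta, epsilon)
  if (noise_sd_m > 0)
    m <- m + stats::rnorm(length(m), sd = noise_sd_m)
  b <- m_to_beta(m)
  dimnames(b) <- dimnames(expected_beta)
  methylation_matrix(b, "beta")
}

# Dirichlet draw via independent gammas.
.rdirichlet <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = alpha),
              nrow = n, byrow = TRUE)
  w <- g / rowSums(g)
  colnames(w) <- names(alpha)
  w
}

#' Generate a complete synthetic cohort
#'
#' Draws storage durations and ages uniformly over their configured ranges,
#' cell-type proportions from a Dirichlet, baseline profiles via
#' [generate_reference()], applies deamination decay via
#' [mix_and_degrade()], adds M-scale noise via [add_noise()], and records
#' the full ground truth for recovery tests. A single seed
#' (`config$seed`) determines every draw; derived sub-seeds keep the
#' reference, sample-level, and noise streams reproducible.
#'
#' @param config a [generator_config()].
#' @return list with `beta` (a beta-scale [methylation_matrix()]),
#'   `sheet` (a [sample_sheet()]), `annotation`, `proportions` (true
#'   sample x cell-type weights) and `truth` (baseline profiles,
#'   deamination rate, expected decayed betas, the discriminating-CpG
#'   reference matrix for deconvolution).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  ref <- generate_reference(config)   # seeds with config$seed
  set.seed(config$seed + 1L)
  n <- config$n_samples
  sample_ids <- sprintf("S%04d", seq_len(n))
  storage <- stats::runif(n, config$storage_range_years[1L],
                          config$storage_range_years[2L])
  ages <- stats::runif(n, config$age_range_years[1L],
                       config$age_range_years[2L])
  buffy <- if (is.null(config$buffy_range_days)) NULL else
    stats::runif(n, config$buffy_range_days[1L], config$buffy_range_days[2L])
  W <- .rdirichlet(n, config$dirichlet_alpha)
  rownames(W) <- sample_ids
  expected <- mix_and_degrade(ref$baseline_beta, W, storage,
                              config$deamination_rate)
  colnames(expected) <- sample_ids
  beta <- add_noise(expected, config$noise_sd_m,
                    seed = config$seed + 2L, epsilon = config$epsilon)
  sheet <- sample_sheet(sample_ids, storage, ages,
                        storage_buffy_days = buffy,
                        cohort = rep(config$cohort, n))
  reference <- ref$baseline_beta[ref$discriminating, , drop = FALSE]
  list(beta = beta,
       sheet = sheet,
       annotation = ref$annotation,
       proportions = W,
       truth = list(baseline_beta = ref$baseline_beta,
                    true_proportions = W,
                    deamination_rate = config$deamination_rate,
                    expected_beta = expected,
                    reference = reference,
                    discriminating = ref$discriminating,
                    config = config))
}

#' Write a generated dataset to a directory of delimited tables
#'
#' Emits `beta.tsv`, `sheet.tsv`, `annotation.tsv`, `true_proportions.tsv`,
#' `reference.tsv` (discriminating-CpG cell-type profiles for
#' deconvolution) and `truth.yaml` (scalar ground-truth parameters).
#'
#' @param dataset output of [generate_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_methylation_matrix(dataset$beta, file.path(dir, "beta.tsv"))
  write_sample_sheet(dataset$sheet, file.path(dir, "sheet.tsv"))
  utils::write.table(as.data.frame(dataset$annotation),
                     file.path(dir, "annotation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  props <- data.frame(sample_id = rownames(dataset$proportions),
                      dataset$proportions, check.names = FALSE)
  utils::write.table(props, file.path(dir, "true_proportions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  ref <- data.frame(cpg_id = rownames(dataset$truth$reference),
                    dataset$truth$reference, check.names = FALSE)
  utils::write.table(ref, file.path(dir, "reference.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  yaml::write_yaml(list(deamination_rate = dataset$truth$deamination_rate,
                        seed = dataset$truth$config$seed,
                        noise_sd_m = dataset$truth$config$noise_sd_m),
                   file.path(dir, "truth.yaml"))
  invisible(dir)
}
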