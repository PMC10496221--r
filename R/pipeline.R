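#' Pipeline configuration
#'
#' Assembles and validates the configuration for [run_pipeline()]. Each
#' cohort entry supplies either loaded objects or file paths for: `beta`
#' (beta-scale methylation matrix), `sheet`, and optionally `annotation`,
#' `detp` (detection p-values), `exclude` (probe exclusion lists), and
#' `reference` (cell-type reference profiles enabling deconvolution).
#'
#' @param cohorts named list of cohort input sets.
#' @param scale scale for the per-CpG and global analyses, `"M"` (default)
#'   or `"beta"`.
#' @param model per-CpG design, `"reduced"` or `"full"`.
#' @param q_threshold,p_threshold,detp_threshold significance and detection
#'   thresholds, each in (0,1).
#' @param epsilon beta clipping bound for the M transform.
#' @param seed seed recorded in the run log.
#' @param out_dir optional directory to write result tables and the run log.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(cohorts, scale = c("M", "beta"),
                            model = c("reduced", "full"),
                            q_threshold = 0.05, p_threshold = 0.05,
                            detp_threshold = 0.01, epsilon = 1e-6,
                            seed = 1, out_dir = NULL) {
  scale <- match.arg(scale)
  model <- match.arg(model)
  for (thr in c(q_threshold, p_threshold, detp_threshold))
    if (!is.numeric(thr) || thr <= 0 || thr >= 1)
      stop("thresholds must lie in (0,1)")
  if (length(cohorts) < 1L || length(cohorts) > 2L)
    stop("supply one or two cohorts")
  if (is.null(names(cohorts)))
    names(cohorts) <- paste0("cohort", seq_along(cohorts))
  for (nm in names(cohorts)) {
    if (is.null(cohorts[[nm]]$beta) || is.null(cohorts[[nm]]$sheet))
      stop("cohort '", nm, "' needs at least 'beta' and 'sheet' inputs")
  }
  structure(list(cohorts = cohorts, scale = scale, model = model,
                 q_threshold = q_threshold, p_threshold = p_threshold,
                 detp_threshold = detp_threshold, epsilon = epsilon,
                 seed = seed, out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' The YAML file holds the fields of [pipeline_config()], with cohort
#' inputs given as file paths (resolved relative to the YAML file's
#' directory).
#'
#' @param path YAML file path.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    ifelse(file.exists(p), p, file.path(base, p))
  }
  cohorts <- lapply(cfg$cohorts, function(co) {
    for (field in c("beta", "sheet", "annotation", "detp", "reference"))
      if (!is.null(co[[field]])) co[[field]] <- resolve(co[[field]])
    if (!is.null(co$exclude)) co$exclude <- lapply(co$exclude, resolve)
    co
  })
  pipeline_config(cohorts,
                  scale = cfg$scale %||% "M",
                  model = cfg$model %||% "reduced",
                  q_threshold = cfg$q_threshold %||% 0.05,
                  p_threshold = cfg$p_threshold %||% 0.05,
                  detp_threshold = cfg$detp_threshold %||% 0.01,
                  epsilon = cfg$epsilon %||% 1e-6,
                  seed = cfg$seed %||% 1,
                  out_dir = cfg$out_dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.load_cohort <- function(co) {
  if (is.character(co$beta))
    co$beta <- read_methylation_matrix(co$beta, "beta")
  if (is.character(co$sheet)) co$sheet <- read_sample_sheet(co$sheet)
  if (is.character(co$annotation))
    co$annotation <- read_probe_annotation(co$annotation)
  if (is.character(co$detp)) co$detp <- read_detection_p(co$detp)
  if (!is.null(co$exclude))
    co$exclude <- lapply(co$exclude,
                         function(x) if (is.character(x) && length(x) == 1L &&
                                         file.exists(x)) read_probe_list(x) else x)
  if (is.character(co$reference)) {
    tab <- .read_table(co$reference)
    ref <- as.matrix(tab[, -1L, drop = FALSE])
    rownames(ref) <- as.character(tab[[1L]])
    co$reference <- ref
  }
  co
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

# Run preprocess -> deconvolution -> global model -> per-CpG model for one
# cohort; returns results plus a per-stage count log.
.run_cohort <- function(co, config) {
  co <- .stage("load", .load_cohort(co))
  log <- list(n_cpgs_input = nrow(co$beta), n_samples = ncol(co$beta))
  mat <- co$beta
  if (!is.null(co$exclude)) {
    mat <- .stage("probe_filter", filter_probe_lists(mat, co$exclude))
    log$probe_filter_removed <- attr(mat, "filter_log")
  }
  if (!is.null(co$detp)) {
    mat <- .stage("detection_filter",
                  filter_detection(mat, co$detp, config$detp_threshold))
    log$detection_removed <- attr(mat, "n_detection_removed")
  }
  al <- .stage("align", align_dataset(mat, co$sheet, co$annotation))
  log$n_cpgs_analyzable <- nrow(al$matrix)
  props <- NULL
  if (!is.null(co$reference))
    props <- .stage("deconvolution",
                    estimate_cell_proportions(al$matrix, co$reference))
  m_mat <- .stage("transform", beta_to_m(al$matrix, config$epsilon))
  analysis_mat <- if (config$scale == "M") m_mat else al$matrix
  global <- .stage("global_model", fit_global_models(
    mean_global_methylation(m_mat), al$sheet, props))
  cpg <- .stage("cpg_model", run_cpg_analysis(
    analysis_mat, al$sheet, props = props, model = config$model))
  counts <- count_directional(cpg, config$q_threshold)
  log$n_hypo <- counts[["n_hypo"]]
  log$n_hyper <- counts[["n_hyper"]]
  list(results = cpg, global = global, proportions = props,
       annotation = al$annotation, log = log)
}

#' Run the full analysis on one or two cohorts
#'
#' Per cohort: probe-list and detection filtering, alignment,
#' (optional) reference-based deconvolution, robust global-methylation
#' models, and the per-CpG differential methylation analysis. Cohorts are
#' processed separately and independently (no cross-cohort normalization).
#' With two cohorts the first is treated as discovery and the second as
#' validation: the replicated hypomethylated list and its
#' relation-to-island enrichment are additionally computed.
#'
#' @param config a [pipeline_config()] or path to a YAML file for
#'   [read_pipeline_config()].
#' @return list: `cohorts` (per-cohort results, global fits, proportions,
#'   stage logs), and for two-cohort runs `replication` (the
#'   [replicated_hypo_list()] output) and `enrichment` (the
#'   [loci_enrichment()] table). Result tables are also written to
#'   `config$out_dir` when set.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  cohort_res <- lapply(names(config$cohorts), function(nm) {
    message("== cohort: ", nm, " ==")
    .run_cohort(config$cohorts[[nm]], config)
  })
  names(cohort_res) <- names(config$cohorts)
  out <- list(cohorts = cohort_res, config = config)
  if (length(cohort_res) == 2L) {
    disc <- cohort_res[[1L]]; val <- cohort_res[[2L]]
    out$replication <- .stage("replication", replicated_hypo_list(
      disc$results, val$results,
      q_threshold = config$q_threshold, p_threshold = config$p_threshold))
    ann <- disc$annotation %||% val$annotation
    if (length(out$replication$ids) == 0L) {
      message("replicated hypomethylated list is empty; enrichment skipped")
    } else if (!is.null(ann)) {
      shared <- intersect(disc$results$cpg_id, val$results$cpg_id)
      out$enrichment <- .stage("enrichment", loci_enrichment(
        out$replication$ids, shared, ann))
    }
  }
  if (!is.null(config$out_dir)) .write_pipeline_outputs(out, config)
  out
}

.write_pipeline_outputs <- function(out, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name)
    utils::write.table(df, file.path(config$out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  for (nm in names(out$cohorts)) {
    co <- out$cohorts[[nm]]
    wt(as.data.frame(co$results), paste0(nm, "_cpg_results.tsv"))
    if (!is.null(co$proportions))
      wt(data.frame(sample_id = rownames(co$proportions), co$proportions),
         paste0(nm, "_cell_proportions.tsv"))
    for (mod in c("reduced", "full")) {
      fit <- co$global[[mod]]
      wt(data.frame(term = names(fit$coefficients),
                    estimate = fit$coefficients,
                    ci_lower = fit$ci[, "lower"], ci_upper = fit$ci[, "upper"],
                    p_value = fit$p_value,
                    aic = unname(fit$aic), bic = unname(fit$bic)),
         paste0(nm, "_global_", mod, ".tsv"))
    }
  }
  if (!is.null(out$replication))
    writeLines(out$replication$ids,
               file.path(config$out_dir, "replicated_hypo_cpgs.txt"))
  if (!is.null(out$enrichment))
    wt(out$enrichment, "loci_enrichment.tsv")
  log <- list(seed = config$seed, scale = config$scale,
              model = config$model,
              thresholds = list(q = config$q_threshold,
                                p = config$p_threshold,
                                detp = config$detp_threshold),
              package_version = as.character(utils::packageVersion("cryomethyl")),
              cohort_logs = lapply(out$cohorts, `[[`, "log"))
  yaml::write_yaml(log, file.path(config$out_dir, "run_log.yaml"))
  invisible(NULL)
}
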