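#' @keywords internal
"_PACKAGE"

#' Relation-to-island categories
#'
#' The six concentric annotation categories around CpG islands used throughout
#' the package: islands, their flanking shores (within 2 kb), shelves
#' (2--4 kb) and the remaining open sea, with N/S marking the upstream and
#' downstream flank.
#'
#' @export
RELATION_CATEGORIES <- c("Island", "N_Shore", "S_Shore",
                         "N_Shelf", "S_Shelf", "OpenSea")

#' Blood leukocyte cell types
#'
#' Column order used for all reference matrices and cell-proportion estimates.
#'
#' @export
CELL_TYPES <- c("CD8T", "CD4T", "NK", "Bcell", "Mono", "Gran")

# Days per year used for all duration conversions.
DAYS_PER_YEAR <- 365.25

#' Construct a methylation matrix
#'
#' A methylation matrix is a numeric CpG-by-sample matrix carrying a declared
#' measurement scale: `"beta"` (proportion methylated, in \[0,1\]) or `"M"`
#' (logit2 of beta). Row names are CpG identifiers, column names sample
#' identifiers; both must be unique. Missing entries are allowed.
#'
#' @param values numeric matrix, rows = CpGs, columns = samples, with
#'   dimnames set.
#' @param scale `"beta"` or `"M"`.
#' @return a `meth_matrix`: the input matrix with a `meth_scale` attribute.
#' @export
methylation_matrix <- function(values, scale = c("beta", "M")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("methylation matrix requires CpG row names and sample column names")
  if (anyDuplicated(rownames(values)))
    stop("duplicated CpG ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicated sample ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "))
  if (scale == "beta") {
    bad <- which(!is.na(values) & (values < 0 | values > 1))
    if (length(bad)) {
      i <- arrayInd(bad[1L], dim(values))
      stop(sprintf(
        "beta value %.6g outside [0,1] at CpG '%s', sample '%s'",
        values[bad[1L]], rownames(values)[i[1L]], colnames(values)[i[2L]]))
    }
  } else {
    if (any(is.infinite(values)))
      stop("M values must be finite")
  }
  structure(values, meth_scale = scale, class = c("meth_matrix", "matrix", "array"))
}

#' Measurement scale of a methylation matrix
#' @param x a `meth_matrix`.
#' @return `"beta"` or `"M"`.
#' @export
meth_scale <- function(x) {
  s <- attr(x, "meth_scale")
  if (is.null(s)) stop("not a methylation matrix: no scale attribute")
  s
}

#' @export
`[.meth_matrix` <- function(x, i, j, ..., drop = FALSE) {
  scale <- attr(x, "meth_scale")
  out <- NextMethod(drop = drop)
  if (is.matrix(out))
    out <- structure(out, meth_scale = scale,
                     class = c("meth_matrix", "matrix", "array"))
  out
}

#' @export
print.meth_matrix <- function(x, ...) {
  cat(sprintf("Methylation matrix (%s scale): %d CpGs x %d samples, %d missing\n",
              meth_scale(x), nrow(x), ncol(x), sum(is.na(x))))
  invisible(x)
}

# Delimiter by file extension: comma for .csv, tab otherwise.
.delim_for <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

NA_TOKENS <- c("", "NA", "NaN")

.read_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = .delim_for(path),
                    na.strings = NA_TOKENS, check.names = FALSE,
                    stringsAsFactors = FALSE, comment.char = "",
                    quote = "\"")
}

#' Read a CpG-by-sample methylation matrix from delimited text
#'
#' Expects a header row of sample ids and a first column of CpG ids. The
#' delimiter is sniffed from the extension (`.csv` comma, otherwise tab);
#' empty cells, `NA` and `NaN` are treated as missing.
#'
#' @param path file path.
#' @param scale declared scale of the stored values, `"beta"` or `"M"`.
#' @return a [methylation_matrix()].
#' @export
read_methylation_matrix <- function(path, scale = c("beta", "M")) {
  scale <- match.arg(scale)
  tab <- .read_table(path)
  ids <- as.character(tab[[1L]])
  if (anyDuplicated(ids))
    stop("duplicated CpG ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- ids
  methylation_matrix(vals, scale)
}

#' Write a methylation matrix to delimited text
#'
#' Inverse of [read_methylation_matrix()]; round trips are value-identical
#' to well below 1e-12.
#'
#' @param x a `meth_matrix`.
#' @param path output path; `.csv` writes comma-separated, otherwise tab.
#' @param id_column name for the CpG id column.
#' @export
write_methylation_matrix <- function(x, path, id_column = "cpg_id") {
  df <- data.frame(rownames(x), format(unclass(x), digits = 17, trim = TRUE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c(id_column, colnames(x))
  utils::write.table(df, path, sep = .delim_for(path), quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a per-probe detection p-value matrix
#'
#' Same layout as [read_methylation_matrix()]; values must lie in \[0,1\].
#'
#' @param path file path.
#' @return numeric matrix of detection p-values.
#' @export
read_detection_p <- function(path) {
  tab <- .read_table(path)
  ids <- as.character(tab[[1L]])
  if (anyDuplicated(ids)) stop("duplicated CpG ids in ", path)
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- ids
  if (any(!is.na(vals) & (vals < 0 | vals > 1)))
    stop("detection p-values must lie in [0,1]")
  vals
}

#' Assemble a sample sheet
#'
#' Per-sample exposures and covariates for the storage-duration models. All
#' durations and ages are encoded in years before modelling; storage as
#' buffy coat is additionally kept in days (the unit it is recorded in).
#'
#' @param sample_id character vector of unique sample ids.
#' @param storage_dna_years storage duration as extracted DNA, in years
#'   (non-negative, required for all samples).
#' @param storage_buffy_days optional storage duration as buffy coat before
#'   extraction, in days; `NULL` when the cohort has none.
#' @param age_years subject age at draw, in years (positive).
#' @param cohort optional cohort label.
#' @return a `data.frame` of class `sample_sheet`.
#' @export
sample_sheet <- function(sample_id, storage_dna_years, age_years,
                         storage_buffy_days = NULL, cohort = NULL) {
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id))
    stop("duplicated sample ids: ",
         paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "))
  if (any(is.na(storage_dna_years)))
    stop("storage_dna_years must be present for every sample")
  if (any(storage_dna_years < 0)) stop("negative storage duration")
  if (any(!is.na(age_years) & age_years <= 0)) stop("age must be positive")
  df <- data.frame(sample_id = sample_id,
                   storage_dna_years = as.numeric(storage_dna_years),
                   age_years = as.numeric(age_years),
                   stringsAsFactors = FALSE)
  if (!is.null(storage_buffy_days)) {
    if (any(!is.na(storage_buffy_days) & storage_buffy_days < 0))
      stop("negative storage duration")
    df$storage_buffy_days <- as.numeric(storage_buffy_days)
  }
  if (!is.null(cohort)) df$cohort <- as.character(cohort)
  class(df) <- c("sample_sheet", "data.frame")
  df
}

#' Read a sample sheet from delimited text
#'
#' Requires a `sample_id` column and a storage-as-DNA column. Durations
#' recorded in days are converted to years when the column is named with a
#' `_days` suffix (`storage_dna_days`, `age_days`); storage as buffy coat is
#' kept in days, matching how it is recorded. A sheet without any buffy-coat
#' column is valid (cohorts whose DNA was extracted directly from blood have
#' none).
#'
#' @param path file path.
#' @return a [sample_sheet()].
#' @export
read_sample_sheet <- function(path) {
  tab <- .read_table(path)
  if (is.null(tab$sample_id)) stop("sample sheet needs a 'sample_id' column")
  if (!is.null(tab$storage_dna_days) && is.null(tab$storage_dna_years))
    tab$storage_dna_years <- tab$storage_dna_days / DAYS_PER_YEAR
  if (is.null(tab$storage_dna_years))
    stop("sample sheet needs a 'storage_dna_years' (or 'storage_dna_days') column")
  if (!is.null(tab$age_days) && is.null(tab$age_years))
    tab$age_years <- tab$age_days / DAYS_PER_YEAR
  if (is.null(tab$age_years)) stop("sample sheet needs an 'age_years' column")
  sample_sheet(tab$sample_id, tab$storage_dna_years, tab$age_years,
               storage_buffy_days = tab$storage_buffy_days,
               cohort = tab$cohort)
}

#' Write a sample sheet
#' @param sheet a `sample_sheet`.
#' @param path output path.
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.table(as.data.frame(sheet), path, sep = .delim_for(path),
                     quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Construct a probe annotation table
#'
#' Maps each CpG to one of the six relation-to-island categories. The
#' annotation is purely categorical; no genomic coordinates are used anywhere
#' in the pipeline.
#'
#' @param cpg_id unique CpG ids.
#' @param relation_to_island one of [RELATION_CATEGORIES] per CpG.
#' @return a `data.frame` of class `probe_annotation`.
#' @export
probe_annotation <- function(cpg_id, relation_to_island) {
  cpg_id <- as.character(cpg_id)
  relation_to_island <- as.character(relation_to_island)
  if (anyDuplicated(cpg_id)) stop("duplicated CpG ids in annotation")
  bad <- setdiff(unique(relation_to_island), RELATION_CATEGORIES)
  if (length(bad))
    stop("unknown relation_to_island categories: ", paste(bad, collapse = ", "))
  df <- data.frame(cpg_id = cpg_id, relation_to_island = relation_to_island,
                   stringsAsFactors = FALSE)
  class(df) <- c("probe_annotation", "data.frame")
  df
}

#' Read a probe annotation table
#' @param path delimited text with `cpg_id` and `relation_to_island` columns.
#' @return a [probe_annotation()].
#' @export
read_probe_annotation <- function(path) {
  tab <- .read_table(path)
  if (is.null(tab$cpg_id) || is.null(tab$relation_to_island))
    stop("annotation needs 'cpg_id' and 'relation_to_island' columns")
  probe_annotation(tab$cpg_id, tab$relation_to_island)
}

#' Read a probe exclusion list (one id per line)
#' @param path file path.
#' @return character vector of CpG ids.
#' @export
read_probe_list <- function(path) {
  ids <- readLines(path)
  ids <- trimws(ids)
  ids[nzchar(ids)]
}

#' Align a methylation matrix with a sample sheet and annotation
#'
#' Reorders matrix columns to the sheet's sample order (restricting both to
#' their common samples) and, when an annotation is given, restricts CpGs to
#' those annotated. Counts of dropped samples and CpGs are reported in the
#' returned object and via [message()].
#'
#' @param matrix a `meth_matrix`.
#' @param sheet a `sample_sheet`.
#' @param annotation optional `probe_annotation`.
#' @return list with elements `matrix`, `sheet`, `annotation` (aligned) and
#'   `dropped` (named counts).
#' @export
align_dataset <- function(matrix, sheet, annotation = NULL) {
  common <- intersect(sheet$sample_id, colnames(matrix))
  if (length(common) == 0L)
    stop("no samples shared between matrix and sample sheet")
  dropped_sheet <- nrow(sheet) - length(common)
  dropped_cols <- ncol(matrix) - length(common)
  sheet <- sheet[match(common, sheet$sample_id), , drop = FALSE]
  matrix <- matrix[, common, drop = FALSE]
  dropped_cpgs <- 0L
  if (!is.null(annotation)) {
    keep <- intersect(rownames(matrix), annotation$cpg_id)
    if (length(keep) == 0L)
      stop("no CpGs shared between matrix and annotation")
    dropped_cpgs <- nrow(matrix) - length(keep)
    matrix <- matrix[keep, , drop = FALSE]
    annotation <- annotation[match(keep, annotation$cpg_id), , drop = FALSE]
  }
  dropped <- c(samples_from_sheet = dropped_sheet,
               samples_from_matrix = dropped_cols,
               cpgs_unannotated = dropped_cpgs)
  if (any(dropped > 0L))
    message(sprintf(
      "align: dropped %d sheet sample(s), %d matrix sample(s), %d unannotated CpG(s)",
      dropped_sheet, dropped_cols, dropped_cpgs))
  list(matrix = matrix, sheet = sheet, annotation = annotation,
       dropped = dropped)
}
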