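# Interchange formats: tab-delimited text for the beta matrix (CpG rows,
# sample columns, header row) and the sample sheet, YAML for run
# configuration.  Identifiers round-trip byte-exact; values are validated
# on read so downstream stages can assume a clean matrix.

#' Write a beta matrix as tab-delimited text
#'
#' @param betas CpG x sample matrix with dimnames.
#' @param path Output path (".gz" suffix compresses).
#' @export
write_beta_matrix <- function(betas, path) {
  dt <- data.table::data.table(cpg_id = rownames(betas))
  dt <- cbind(dt, data.table::as.data.table(betas))
  data.table::fwrite(dt, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Read a beta matrix from tab-delimited text
#'
#' Validates that every non-missing cell is numeric and lies in [0, 1];
#' a violation is an error naming the CpG and sample. Missing values are
#' allowed and are masked per CpG by downstream fits.
#'
#' @param path Path to a table written by [write_beta_matrix()] (first
#'   column `cpg_id`, one column per sample).
#' @return Numeric CpG x sample matrix with dimnames.
#' @export
read_beta_matrix <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = 1))
  ids <- dt[[1]]
  m <- as.matrix(dt[, -1])
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(array(as.numeric(m), dim(m)))) & !is.na(m),
                 arr.ind = TRUE)[1, ]
    stopf("non-numeric beta value at CpG %s, sample %s",
          ids[bad[1]], colnames(m)[bad[2]])
  }
  rownames(m) <- ids
  out <- which(!is.na(m) & (m < 0 | m > 1), arr.ind = TRUE)
  if (nrow(out) > 0)
    stopf("beta value %.4g outside [0, 1] at CpG %s, sample %s",
          m[out[1, 1], out[1, 2]], ids[out[1, 1]], colnames(m)[out[1, 2]])
  m
}

#' Write / read the sample sheet
#'
#' Tab-delimited with the canonical columns (`sample_id`, `child_id`,
#' `cohort`, `age`, `sex`, `plate_id`, `gestational_age`, `cd4t`, `cd8t`,
#' `nk`, `b`, `mono`, `gran`). Reading validates the sheet's invariants
#' (ages in [0, 20], fractions in [0, 1] summing to 1, unique sample ids,
#' each child in one cohort).
#'
#' @param meta Sample sheet data.frame.
#' @param path File path.
#' @return `read_sample_sheet()` returns the validated data.frame.
#' @export
write_sample_sheet <- function(meta, path) {
  data.table::fwrite(as.data.frame(meta)[, META_COLS], path, sep = "\t",
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_sample_sheet
#' @export
read_sample_sheet <- function(path) {
  meta <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE,
                                          colClasses = list(
                                            character = c("sample_id", "child_id",
                                                          "cohort", "sex",
                                                          "plate_id"))))
  check_meta(meta)
  meta
}

#' Read a pipeline run configuration from YAML
#'
#' Validates the basic invariants: referenced paths exist, `alpha` lies in
#' (0, 1), knots are strictly increasing.
#'
#' @param path YAML file with fields such as `paths:` (betas,
#'   sample_sheet, annotation, output_dir), `models:`, `knots:`, `alpha:`,
#'   `m_tests:`, `seed:`.
#' @return The configuration list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (p in unlist(cfg$paths[c("betas", "sample_sheet", "annotation")])) {
    if (!is.null(p) && !file.exists(p)) stopf("configured path not found: %s", p)
  }
  alpha <- cfg$alpha %||% 0.05
  if (alpha <= 0 || alpha >= 1) stopf("alpha must lie in (0, 1)")
  knots <- cfg$knots %||% c(6, 9)
  if (is.unsorted(knots, strictly = TRUE))
    stopf("knots must be strictly increasing")
  cfg$alpha <- alpha
  cfg$knots <- knots
  cfg
}

#' Sample and child bookkeeping per cohort
#'
#' Counts samples, children and plates per cohort and overall; the totals
#' are the denominators quoted for a combined two-cohort analysis set.
#'
#' @param meta Sample sheet data.frame.
#' @return data.frame with one row per cohort plus a `total` row.
#' @export
cohort_summary <- function(meta) {
  meta <- as.data.frame(meta)
  per <- do.call(rbind, lapply(split(meta, meta$cohort), function(m)
    data.frame(cohort = m$cohort[1], n_samples = nrow(m),
               n_children = length(unique(m$child_id)),
               n_plates = length(unique(m$plate_id)))))
  tot <- data.frame(cohort = "total", n_samples = nrow(meta),
                    n_children = length(unique(meta$child_id)),
                    n_plates = length(unique(meta$plate_id)))
  rbind(per, tot)
}
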