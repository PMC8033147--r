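# Design construction for the three trajectory models:
#   M1  linear change:        age fixed + random, child intercept, plate
#   M2  piecewise change:     adds (age-6)^+ and (age-9)^+ fixed + random
#   M3  sex-specific change:  M1 fixed terms + sex x age interaction
# Sex, cohort, z-scored gestational age and five z-scored white-blood-cell
# fractions are always fixed covariates (granulocytes, the largest
# fraction, is dropped to break compositional collinearity).

CELL_COLS <- c("cd4t", "cd8t", "nk", "b", "mono", "gran")
META_COLS <- c("sample_id", "child_id", "cohort", "age", "sex", "plate_id",
               "gestational_age", CELL_COLS)

check_meta <- function(meta) {
  miss <- setdiff(META_COLS, names(meta))
  if (length(miss))
    stopf("sample sheet is missing column(s): %s", paste(miss, collapse = ", "))
  if (anyDuplicated(meta$sample_id))
    stopf("duplicate sample_id(s): %s",
          paste(unique(meta$sample_id[duplicated(meta$sample_id)]), collapse = ", "))
  if (any(meta$age < 0 | meta$age > 20))
    stopf("ages must lie in [0, 20] years")
  fr <- as.matrix(meta[, CELL_COLS])
  if (any(fr < 0 | fr > 1)) stopf("cell fractions must lie in [0, 1]")
  rs <- rowSums(fr)
  if (any(rs < 0.98 | rs > 1.02))
    stopf("cell fractions must sum to 1 (within [0.98, 1.02])")
  mixed <- tapply(meta$cohort, meta$child_id, function(x) length(unique(x)))
  if (any(mixed > 1)) stopf("a child_id appears in more than one cohort")
  invisible(meta)
}

#' Build the fixed and random design for one trajectory model
#'
#' Constructs the covariate matrix and random-effect structure for models
#' M1 (linear change), M2 (piecewise-linear change with slope changes at the
#' knots) or M3 (sex-by-age interaction). Continuous covariates
#' (gestational age and the five retained cell fractions) are z-score
#' standardized on the analysis set; sex is coded F = 0, M = 1 and cohort
#' A = 0, B = 1. With a single cohort in the input the cohort term is
#' dropped with a warning. Every random slope term also enters as a fixed
#' term.
#'
#' @param meta Sample sheet data.frame with columns `sample_id`, `child_id`,
#'   `cohort`, `age` (years), `sex` ("F"/"M"), `plate_id`,
#'   `gestational_age` (weeks) and cell fractions `cd4t`, `cd8t`, `nk`,
#'   `b`, `mono`, `gran`.
#' @param model_id One of `"M1"`, `"M2"`, `"M3"`.
#' @param knots Slope-change ages in years for M2 (default `c(6, 9)`); must
#'   be strictly increasing and inside the observed age range.
#' @param plate_random Include the crossed sample-plate random intercept.
#' @return An object of class `methtraj_design` with the fixed matrix `X`,
#'   random-effect `blocks`, `random_terms`, index vectors and counts.
#' @export
build_design <- function(meta, model_id = c("M1", "M2", "M3"),
                         knots = c(6, 9), plate_random = TRUE) {
  model_id <- match.arg(model_id)
  meta <- as.data.frame(meta)
  check_meta(meta)
  if (model_id == "M2") {
    if (is.unsorted(knots, strictly = TRUE))
      stopf("knots must be strictly increasing")
    if (any(knots <= min(meta$age)) || any(knots >= max(meta$age)))
      stopf("knots must lie strictly inside the observed age range [%.2f, %.2f]",
            min(meta$age), max(meta$age))
  }
  n <- nrow(meta)
  age <- meta$age
  sex01 <- as.numeric(meta$sex == "M")
  cols <- list(intercept = rep(1, n), age = age)
  if (model_id == "M2") {
    cols$age6p <- age_knot(age, knots[1])
    cols$age9p <- age_knot(age, knots[2])
  }
  cols$sex <- sex01
  if (model_id == "M3") cols$sex_age <- sex01 * age
  if (length(unique(meta$cohort)) > 1) {
    cols$cohort <- as.numeric(meta$cohort == sort(unique(meta$cohort))[2])
  } else {
    warning("single cohort in input; dropping the cohort term", call. = FALSE)
  }
  cols$gestational_age <- zscore(meta$gestational_age)
  for (cc in setdiff(CELL_COLS, "gran")) cols[[cc]] <- zscore(meta[[cc]])
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)

  child_lev <- unique(meta$child_id)
  child_idx <- match(meta$child_id, child_lev)
  plate_lev <- unique(meta$plate_id)
  plate_idx <- match(meta$plate_id, plate_lev)

  blocks <- list(
    child_intercept = list(name = "child_intercept", j = child_idx,
                           x = rep(1, n), nlev = length(child_lev)),
    age = list(name = "age", j = child_idx, x = age, nlev = length(child_lev)))
  if (model_id == "M2") {
    blocks$age6p <- list(name = "age6p", j = child_idx, x = cols$age6p,
                         nlev = length(child_lev))
    blocks$age9p <- list(name = "age9p", j = child_idx, x = cols$age9p,
                         nlev = length(child_lev))
  }
  if (plate_random) {
    blocks$plate <- list(name = "plate", j = plate_idx, x = rep(1, n),
                         nlev = length(plate_lev))
  }
  structure(list(
    model_id = model_id, knots = knots, X = X, terms = colnames(X),
    blocks = blocks, random_terms = names(blocks),
    child_idx = child_idx, plate_idx = plate_idx,
    sample_id = meta$sample_id,
    n_samples = n, n_children = length(child_lev),
    n_plates = length(plate_lev)), class = "methtraj_design")
}

#' @export
print.methtraj_design <- function(x, ...) {
  cat(sprintf("Design %s: %d samples, %d children, %d plates\n",
              x$model_id, x$n_samples, x$n_children, x$n_plates))
  cat("Fixed terms:  ", paste(x$terms, collapse = ", "), "\n")
  cat("Random terms: ", paste(x$random_terms, collapse = ", "), "\n")
  invisible(x)
}
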