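# Cross-cohort comparability of longitudinal methylation: per-CpG
# concordance between the two early time points shared by both cohorts
# (relative concordance by Spearman correlation, absolute concordance by a
# one-way random-effects intra-class correlation), per-cohort change
# estimates from the linear model, and across-CpG agreement of those
# stability estimates between cohorts.

#' Residualize beta values on the technical and biological covariates
#'
#' Within each cohort, replaces each CpG's values by the residuals of an
#' ordinary least-squares fit on sex, z-scored gestational age, the five
#' retained cell fractions and plate (categorical fixed effect) --
#' everything in the longitudinal models except cohort and, by default,
#' age. Residuals are mean-zero per cohort by construction.
#'
#' @param betas CpG x sample matrix.
#' @param meta Aligned sample sheet.
#' @param include_age Also residualize on age (default `FALSE`: concordance
#'   is computed between visits, within which age varies little).
#' @return A matrix of residuals, same dimnames as `betas`.
#' @export
residualize <- function(betas, meta, include_age = FALSE) {
  meta <- as.data.frame(meta)
  check_alignment(betas, meta)
  out <- betas
  for (co in unique(meta$cohort)) {
    idx <- which(meta$cohort == co)
    m <- meta[idx, , drop = FALSE]
    cols <- list(intercept = rep(1, nrow(m)),
                 sex = as.numeric(m$sex == "M"),
                 gestational_age = zscore(m$gestational_age))
    for (cc in setdiff(CELL_COLS, "gran")) cols[[cc]] <- zscore(m[[cc]])
    if (include_age) cols$age <- m$age
    X <- do.call(cbind, cols)
    if (length(unique(m$plate_id)) > 1)
      X <- cbind(X, stats::model.matrix(~ factor(plate_id), m)[, -1, drop = FALSE])
    qrX <- qr(X)
    # residuals of Y' on X for all CpGs at once: Y' - X (X'X)^-1 X'Y'
    Yt <- t(betas[, idx, drop = FALSE])
    res <- Yt - qr.fitted(qrX, Yt)
    out[, idx] <- t(res)
  }
  out
}

#' One-way random-effects intra-class correlation (single measurement)
#'
#' The absolute-concordance ICC for paired repeated measures:
#' `(MSB - MSW) / (MSB + (k - 1) * MSW)` with `k = 2` measurements per
#' child, from the one-way ANOVA decomposition.
#'
#' @param x1,x2 Paired numeric vectors (one value per child per visit).
#' @return The ICC, in (-1, 1]; `NA` when fewer than 3 complete pairs.
#' @export
icc_oneway <- function(x1, x2) {
  ok <- is.finite(x1) & is.finite(x2)
  x1 <- x1[ok]; x2 <- x2[ok]
  n <- length(x1)
  if (n < 3) return(NA_real_)
  m <- (x1 + x2) / 2
  grand <- mean(c(x1, x2))
  msb <- 2 * sum((m - grand)^2) / (n - 1)
  msw <- sum((x1 - m)^2 + (x2 - m)^2) / n
  if (msb + msw <= 0) return(NA_real_)
  (msb - msw) / (msb + msw)
}

#' Per-CpG concordance between two visits
#'
#' For children observed at both visits, computes per CpG the Spearman
#' correlation (average-rank ties; relative concordance) and the one-way
#' ICC (absolute concordance) between the two visits' residualized values.
#'
#' @param res1,res2 CpG x child matrices of residualized beta values whose
#'   columns are the same children in the same order.
#' @return data.frame with `cpg_id`, `spearman_rho`, `icc`, `n_paired`.
#' @export
concordance <- function(res1, res2) {
  stopifnot(nrow(res1) == nrow(res2), ncol(res1) == ncol(res2))
  n <- ncol(res1)
  rho <- vapply(seq_len(nrow(res1)), function(g) {
    if (n < 3) return(NA_real_)
    stats::cor(res1[g, ], res2[g, ], method = "spearman",
               use = "complete.obs")
  }, numeric(1))
  icc <- vapply(seq_len(nrow(res1)), function(g)
    icc_oneway(res1[g, ], res2[g, ]), numeric(1))
  data.frame(cpg_id = rownames(res1) %||% as.character(seq_len(nrow(res1))),
             spearman_rho = rho, icc = icc, n_paired = n)
}

#' Extract paired visit matrices for one cohort
#'
#' Picks, for each child with samples at both target visits, the sample
#' nearest each visit age, and returns the two aligned CpG x child
#' matrices.
#'
#' @param betas CpG x sample matrix (typically residualized).
#' @param meta Aligned sample sheet.
#' @param cohort Cohort to extract.
#' @param visit_ages Two target ages in years (default birth and 6.5).
#' @param tol Maximum distance in years from a target age.
#' @return List with matrices `v1`, `v2` and the `children` used.
#' @export
pair_visits <- function(betas, meta, cohort, visit_ages = c(0, 6.5),
                        tol = 3) {
  meta <- as.data.frame(meta)
  check_alignment(betas, meta)
  idx <- which(meta$cohort == cohort)
  pick <- function(target) {
    cand <- idx[abs(meta$age[idx] - target) <= tol]
    split_by <- meta$child_id[cand]
    vapply(split(cand, split_by), function(ii)
      ii[which.min(abs(meta$age[ii] - target))], integer(1))
  }
  s1 <- pick(visit_ages[1]); s2 <- pick(visit_ages[2])
  kids <- intersect(names(s1), names(s2))
  list(v1 = betas[, s1[kids], drop = FALSE],
       v2 = betas[, s2[kids], drop = FALSE], children = kids)
}

#' Per-cohort stability table
#'
#' The full first-stage workflow for one cohort: residualize, pair the two
#' shared visits, compute per-CpG Spearman and ICC concordance, and add
#' per-CpG annual change estimates from the linear mixed model fitted
#' within the cohort (cohort term dropped).
#'
#' @param betas CpG x sample matrix.
#' @param meta Aligned sample sheet.
#' @param cohort Cohort label.
#' @param visit_ages Two visit ages shared across cohorts.
#' @param tol Age-matching tolerance in years.
#' @param ... Passed to [run_epigenome()] (e.g. `control`).
#' @return data.frame with `cpg_id`, `spearman_rho`, `icc`, `n_paired`,
#'   `change_estimate`, `cohort`.
#' @export
stability_table <- function(betas, meta, cohort, visit_ages = c(0, 6.5),
                            tol = 3, ...) {
  meta <- as.data.frame(meta)
  check_alignment(betas, meta)
  res <- residualize(betas, meta)
  pv <- pair_visits(res, meta, cohort, visit_ages, tol)
  conc <- concordance(pv$v1, pv$v2)
  keep <- which(meta$cohort == cohort &
                (abs(meta$age - visit_ages[1]) <= tol |
                 abs(meta$age - visit_ages[2]) <= tol))
  fits <- suppressWarnings(
    run_epigenome(betas[, keep, drop = FALSE], meta[keep, , drop = FALSE],
                  "M1", lrt = FALSE, ...))
  conc$change_estimate <- fits$est_age[match(conc$cpg_id, fits$cpg_id)]
  conc$cohort <- cohort
  conc
}

#' Cross-cohort agreement of stability estimates
#'
#' Correlates the per-CpG stability estimates of two cohorts over their
#' shared CpGs: Spearman for the concordance-type quantities (not normally
#' distributed), Pearson for the change estimates.
#'
#' @param tab_a,tab_b [stability_table()] outputs for the two cohorts.
#' @return List with `rho_spearman_concordance`, `rho_icc`,
#'   `r_change`, and `n_cpgs` shared.
#' @export
cross_cohort_agreement <- function(tab_a, tab_b) {
  m <- merge(tab_a, tab_b, by = "cpg_id", suffixes = c("_a", "_b"))
  list(
    rho_spearman_concordance = stats::cor(m$spearman_rho_a, m$spearman_rho_b,
                                          method = "spearman",
                                          use = "complete.obs"),
    rho_icc = stats::cor(m$icc_a, m$icc_b, method = "spearman",
                         use = "complete.obs"),
    r_change = stats::cor(m$change_estimate_a, m$change_estimate_b,
                          method = "pearson", use = "complete.obs"),
    n_cpgs = nrow(m))
}
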