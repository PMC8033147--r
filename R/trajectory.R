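# Epigenome-scale model runs and trajectory interpretation.  The three
# models share one design per run, so the expensive pre-computations
# (cross-products, symbolic Cholesky pattern) are built once and reused for
# every CpG; only the per-CpG response changes.

#' Verify beta-matrix / sample-sheet alignment
#'
#' Columns of the beta matrix must match `meta$sample_id` exactly and in
#' order; misalignment is a hard error naming the offenders, never a silent
#' reordering.
#'
#' @param betas CpG x sample matrix.
#' @param meta Sample sheet data.frame.
#' @return Invisibly `TRUE`.
#' @export
check_alignment <- function(betas, meta) {
  cn <- colnames(betas)
  if (is.null(cn)) stopf("beta matrix has no sample column names")
  if (length(cn) != nrow(meta) || any(cn != meta$sample_id)) {
    off <- which(cn[seq_len(min(length(cn), nrow(meta)))] !=
                 meta$sample_id[seq_len(min(length(cn), nrow(meta)))])
    stopf("beta matrix and sample sheet are misaligned (%d columns vs %d rows); first offenders: %s",
          length(cn), nrow(meta),
          paste(utils::head(cn[off], 5), collapse = ", "))
  }
  invisible(TRUE)
}

#' Fit one trajectory model across an epigenome
#'
#' Runs the requested model (M1 linear, M2 piecewise, M3 sex-by-age) for
#' every CpG row of the beta matrix: maximum-likelihood fit, z-tests for
#' the fixed effects, likelihood-ratio refits for each random slope
#' variance, and the model-specific derived quantities (per-segment slopes
#' and trajectory labels for M2; sex patterns for M3). Results are
#' deterministic given the input order.
#'
#' @param betas CpG x sample matrix of beta values in [0, 1] (`NA`s are
#'   masked per CpG).
#' @param meta Sample sheet aligned with `betas` (checked, never reordered).
#' @param model_id `"M1"`, `"M2"` or `"M3"`.
#' @param threshold Significance threshold used for classification (default
#'   the genome-wide Bonferroni threshold 1e-7; desk-scale runs should pass
#'   [bonferroni_threshold()] for their own test count).
#' @param knots Slope-change ages for M2.
#' @param lrt Refit without each random slope and attach likelihood-ratio
#'   p-values (set `FALSE` to skip the refits).
#' @param plate_random Include the crossed plate random intercept.
#' @param control [lmm_control()] settings.
#' @return A data.frame with one row per CpG: estimates, standard errors,
#'   z and p per fixed term (`est_*`, `se_*`, `z_*`, `p_*`), variance
#'   components (`var_*`), LRT p-values (`lrt_p_*`), convergence and size
#'   bookkeeping, and for M2 the segment slopes (`seg_*`), `trajectory`
#'   label and `nonlinear` flag, for M3 the sex pattern columns.
#' @export
run_epigenome <- function(betas, meta, model_id = c("M1", "M2", "M3"),
                          threshold = 1e-7, knots = c(6, 9), lrt = TRUE,
                          plate_random = TRUE, control = lmm_control()) {
  model_id <- match.arg(model_id)
  meta <- as.data.frame(meta)
  check_alignment(betas, meta)
  design <- build_design(meta, model_id, knots = knots,
                         plate_random = plate_random)
  ctx_full <- lmm_context(design$X, design$blocks[design$random_terms])
  slope_terms <- intersect(c("age", "age6p", "age9p"), design$random_terms)
  ctx_red <- if (lrt) {
    stats::setNames(lapply(slope_terms, function(t)
      lmm_context(design$X, design$blocks[setdiff(design$random_terms, t)])),
      slope_terms)
  } else list()

  rows <- vector("list", nrow(betas))
  for (g in seq_len(nrow(betas))) {
    y <- betas[g, ]
    id <- rownames(betas)[g] %||% as.character(g)
    fit <- fit_lmm(y, design, control = control, cpg_id = id,
                   context = if (anyNA(y)) NULL else ctx_full)
    if (lrt && fit$converged) {
      lp <- vapply(slope_terms, function(t) {
        red <- fit_lmm(y, design,
                       random_terms = setdiff(design$random_terms, t),
                       control = control, cpg_id = id,
                       context = if (anyNA(y)) NULL else ctx_red[[t]])
        if (red$converged) as.numeric(lrt_random_term(fit, red)) else NA_real_
      }, numeric(1))
      fit$lrt_p <- lp
    }
    rows[[g]] <- epigenome_row(fit, model_id, threshold)
  }
  out <- data.table::rbindlist(rows, fill = TRUE)
  data.table::setDF(out)
  out
}

# flatten one fit (plus derived classifications) into a result row
epigenome_row <- function(fit, model_id, threshold) {
  row <- list(cpg_id = fit$cpg_id, model = model_id,
              converged = fit$converged, n_samples = fit$n_samples,
              n_children = fit$n_children, n_plates = fit$n_plates,
              loglik = fit$loglik)
  for (i in seq_len(nrow(fit$fixed))) {
    t <- fit$fixed$term[i]
    row[[paste0("est_", t)]] <- fit$fixed$beta[i]
    row[[paste0("se_", t)]] <- fit$fixed$se[i]
    row[[paste0("z_", t)]] <- fit$fixed$z[i]
    row[[paste0("p_", t)]] <- fit$fixed$p[i]
  }
  for (v in names(fit$varcomp)) row[[paste0("var_", sub("sigma2_", "", v))]] <-
    fit$varcomp[[v]]
  for (t in names(fit$lrt_p)) row[[paste0("lrt_p_", t)]] <- fit$lrt_p[[t]]
  if (model_id == "M2" && fit$converged) {
    seg <- segment_slopes(fit)
    lab <- classify_trajectory(seg, fit, threshold)
    segn <- c("birth_6", "y6_9", "y9_18")
    for (i in 1:3) {
      row[[paste0("seg_", segn[i], "_est")]] <- seg$estimate[i]
      row[[paste0("seg_", segn[i], "_se")]] <- seg$se[i]
      row[[paste0("seg_", segn[i], "_p")]] <- seg$p[i]
    }
    row$trajectory <- lab$label
    row$nonlinear <- lab$nonlinear
  }
  if (model_id == "M3" && fit$converged) {
    sx <- classify_sex(fit, threshold)
    row$sex_stable <- sx$stable
    row$sex_stable_dir <- sx$stable_direction
    row$sex_change <- sx$change
    row$sex_change_dir <- sx$change_direction
  }
  row
}

#' Per-age-segment slopes from a piecewise fit
#'
#' Derives the average change in beta value per year over the three age
#' segments (birth to first knot, between knots, last knot onward) as
#' linear contrasts of the piecewise coefficients: `b1`, `b1 + b2` and
#' `b1 + b2 + b3`, with standard errors from the fixed-effect covariance.
#'
#' @param fit A converged M2 `methtraj_fit`.
#' @return data.frame with `segment`, `estimate`, `se`, `z`, `p`.
#' @export
segment_slopes <- function(fit) {
  stopifnot(inherits(fit, "methtraj_fit"))
  if (fit$model_id != "M2") stopf("segment slopes require an M2 fit")
  idx <- match(c("age", "age6p", "age9p"), fit$terms)
  if (anyNA(idx)) stopf("fit lacks the piecewise age terms")
  segs <- list(birth_6 = idx[1], y6_9 = idx[1:2], y9_18 = idx)
  out <- lapply(names(segs), function(s) {
    cvec <- numeric(length(fit$terms))
    cvec[segs[[s]]] <- 1
    ct <- fixed_contrast(fit, cvec)
    data.frame(segment = s, estimate = ct$estimate, se = ct$se,
               z = ct$z, p = ct$p)
  })
  do.call(rbind, out)
}

#' Classify a qualitative trajectory from segment slopes
#'
#' Each segment gets state `Positive` or `Negative` when its slope is
#' significant at `threshold` (sign-directed), else `Neutral`. A segment
#' whose sign matches the preceding non-Neutral segment is upgraded to
#' `More`/`Less` of that direction when the corresponding slope-change
#' coefficient (`b2` for the middle segment, `b3` for the last) is itself
#' significant: `More` when the change pushes further in the segment's
#' direction, `Less` when it pulls back. Consecutive identical states
#' collapse to a single token, e.g. `Positive-Neutral`.
#'
#' @param segments Output of [segment_slopes()].
#' @param fit The M2 fit the segments derive from (supplies `b2`/`b3`
#'   tests).
#' @param threshold Significance threshold.
#' @return A list with `states` (length 3), `label` (collapsed hyphenated
#'   string), `nonlinear` (`b2` or `b3` significant) and `variation_flags`
#'   (random-slope LRT significance, when available).
#' @export
classify_trajectory <- function(segments, fit, threshold = 1e-7) {
  base <- ifelse(segments$p < threshold,
                 ifelse(segments$estimate > 0, "Positive", "Negative"),
                 "Neutral")
  chg <- fit$fixed[match(c("age6p", "age9p"), fit$fixed$term), ]
  states <- base
  for (i in 2:3) {
    if (states[i] == "Neutral") next
    prev <- rev(base[seq_len(i - 1)])
    prev <- prev[prev != "Neutral"][1]
    if (is.na(prev) || prev != states[i]) next
    co <- chg[i - 1, ]
    if (is.na(co$p) || co$p >= threshold) next
    dir <- if (sign(co$beta) == sign(segments$estimate[i])) "More" else "Less"
    states[i] <- paste(dir, states[i])
  }
  runs <- rle(states)$values
  nl <- any(chg$p < threshold, na.rm = TRUE)
  vf <- if (length(fit$lrt_p)) fit$lrt_p < threshold else logical(0)
  list(states = states, label = paste(runs, collapse = "-"),
       nonlinear = nl, variation_flags = vf)
}

#' Classify sex-specific methylation patterns from an M3 fit
#'
#' A stable sex difference is a significant sex main effect; a sex
#' difference in change is a significant sex-by-age interaction. With sex
#' coded F = 0, M = 1, positive coefficients mean higher (or faster-
#' increasing) methylation in boys; directions are reported in words.
#'
#' @param fit A converged M3 `methtraj_fit`.
#' @param threshold Significance threshold.
#' @return List with `stable`, `stable_direction`, `change`,
#'   `change_direction`.
#' @export
classify_sex <- function(fit, threshold = 1e-7) {
  stopifnot(inherits(fit, "methtraj_fit"))
  if (fit$model_id != "M3") stopf("sex patterns require an M3 fit")
  main <- fit$fixed[fit$fixed$term == "sex", ]
  inter <- fit$fixed[fit$fixed$term == "sex_age", ]
  stable <- isTRUE(main$p < threshold)
  change <- isTRUE(inter$p < threshold)
  list(stable = stable,
       stable_direction = if (!stable) NA_character_
         else if (main$beta > 0) "higher in boys" else "higher in girls",
       change = change,
       change_direction = if (!change) NA_character_
         else if (inter$beta > 0) "faster increase in boys"
         else "faster increase in girls")
}

#' Partition estimated inter-individual variation
#'
#' Expresses each estimated variance component (child intercept, each
#' random slope, plate and residual) as a percentage of their raw sum.
#' Slope variances are in per-year-squared units, so the raw sum mixes
#' units; this matches the conventional summary reported for such models
#' and is documented as such.
#'
#' @param fit A `methtraj_fit`.
#' @return Named numeric vector of percentages summing to 100.
#' @export
variance_partition <- function(fit) {
  v <- fit$varcomp
  100 * v / sum(v)
}

# kernel-density mode with Silverman's rule-of-thumb bandwidth
density_mode <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 3) return(NA_real_)
  d <- stats::density(x, bw = "nrd0")
  d$x[which.max(d$y)]
}

#' Summarize an epigenome-wide result table
#'
#' Computes the headline quantities for a model run: percentages of CpGs
#' significant per category at `threshold`, the kernel-density mode and SD
#' of the annual-change estimates, and the implied total change over the
#' follow-up period (per CpG and for the mode).
#'
#' @param results A [run_epigenome()] table.
#' @param threshold Significance threshold (default genome-wide Bonferroni
#'   1e-7).
#' @param years Follow-up period for the total-change conversion.
#' @return A list of summaries; contents depend on the model's columns.
#' @export
summarize_epigenome <- function(results, threshold = 1e-7, years = 18) {
  ok <- results[results$converged, , drop = FALSE]
  out <- list(n_cpgs = nrow(results), n_converged = nrow(ok),
              threshold = threshold)
  pct <- function(flag) 100 * mean(flag, na.rm = TRUE)
  if ("p_age" %in% names(ok)) {
    sig <- ok$p_age < threshold
    out$pct_change <- pct(sig)
    out$pct_decreasing <- pct(sig & ok$est_age < 0)
    out$pct_increasing <- pct(sig & ok$est_age > 0)
    out$mode_change <- density_mode(ok$est_age)
    out$sd_change <- stats::sd(ok$est_age, na.rm = TRUE)
    out$mode_total_change <- annual_to_total_change(out$mode_change, years)
    out$total_change <- annual_to_total_change(ok$est_age, years)
  }
  for (t in c("age", "age6p", "age9p")) {
    cl <- paste0("lrt_p_", t)
    if (cl %in% names(ok)) out[[paste0("pct_var_", t)]] <-
      pct(ok[[cl]] < threshold)
  }
  if ("nonlinear" %in% names(ok)) {
    out$pct_nonlinear <- pct(ok$nonlinear)
    out$trajectory_pct <- sort(100 * table(ok$trajectory) / nrow(ok),
                               decreasing = TRUE)
  }
  if ("sex_stable" %in% names(ok)) {
    out$pct_sex_stable <- pct(ok$sex_stable)
    out$pct_sex_change <- pct(ok$sex_change)
  }
  out
}
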