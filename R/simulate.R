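# Synthetic two-cohort longitudinal methylation generator.  The sampling
# design mirrors a two-birth-cohort study with four time points overall:
# cohort A is seen near birth, 6 and 10 years, cohort B near birth, 7.5 and
# 17 years, so neither cohort alone covers the full age range and the late
# segment is informed by one cohort only -- a confounding the analysis
# models must live with, reproduced here on purpose.  Beta values are
# generated directly on the proportion scale from the piecewise-linear
# mixed model (child random intercept and uncorrelated random slopes,
# plate random intercept, Gaussian residual) and truncated to [0, 1];
# truncation events are counted because they bias variance recovery near
# the boundaries.

# typical whole-blood leukocyte composition used as the Dirichlet centre
BLOOD_PROPS <- c(cd4t = 0.15, cd8t = 0.08, nk = 0.05, b = 0.08,
                 mono = 0.09, gran = 0.55)

#' Default per-CpG effect/variance table for the simulator
#'
#' One row per simulated CpG: fixed trajectory coefficients (`beta0`
#' intercept, `beta1` slope per year, `beta2`/`beta3` slope changes at the
#' knots) and the variance components of the generating mixed model (beta
#' value units; slope variances per year squared).
#'
#' @param n_cpgs Number of CpGs.
#' @param beta0,beta1,beta2,beta3 Fixed coefficients, recycled to `n_cpgs`.
#' @param sigma2_intercept,sigma2_age,sigma2_age6p,sigma2_age9p Child-level
#'   variance components.
#' @param sigma2_plate Plate (batch) intercept variance.
#' @param sigma2_resid Residual variance.
#' @return A data.frame with one row per CpG.
#' @export
archetype_table <- function(n_cpgs = 10, beta0 = 0.5, beta1 = 0,
                            beta2 = 0, beta3 = 0,
                            sigma2_intercept = 1e-3, sigma2_age = 1e-6,
                            sigma2_age6p = 0, sigma2_age9p = 0,
                            sigma2_plate = 1e-4, sigma2_resid = 2.5e-4) {
  data.frame(cpg_id = sprintf("cg%07d", seq_len(n_cpgs)),
             beta0 = rep_len(beta0, n_cpgs), beta1 = rep_len(beta1, n_cpgs),
             beta2 = rep_len(beta2, n_cpgs), beta3 = rep_len(beta3, n_cpgs),
             sigma2_intercept = rep_len(sigma2_intercept, n_cpgs),
             sigma2_age = rep_len(sigma2_age, n_cpgs),
             sigma2_age6p = rep_len(sigma2_age6p, n_cpgs),
             sigma2_age9p = rep_len(sigma2_age9p, n_cpgs),
             sigma2_plate = rep_len(sigma2_plate, n_cpgs),
             sigma2_resid = rep_len(sigma2_resid, n_cpgs))
}

#' Simulation configuration for the two-cohort design
#'
#' Defaults emulate the published two-cohort sampling frame: visit ages
#' 0, 6.0 (SD 0.5) and 9.8 (SD 0.3) years in cohort A and 0, 7.5 (SD 0.2)
#' and 17.1 (SD 1.0) years in cohort B, partial longitudinal overlap via
#' per-visit attendance probabilities, plate batches filled in order of 96
#' samples, and child-level random intercepts and slopes. Covariate effects
#' (sex, sex-by-age, gestational age) default to zero so model-recovery
#' experiments isolate the age structure.
#'
#' @param n_children Named vector `c(A = ..., B = ...)` of children per
#'   cohort.
#' @param visit_age_means,visit_age_sds Per-cohort lists of visit age means
#'   and SDs in years.
#' @param attendance Per-cohort lists of per-visit attendance probabilities
#'   in (0, 1].
#' @param archetypes Per-CpG effect/variance table from
#'   [archetype_table()].
#' @param knots Slope-change ages used by the generative model.
#' @param plate_size Samples per plate within cohort.
#' @param effect_sex,effect_sex_age,effect_gestational_age Optional fixed
#'   covariate effects (beta-value units; sex coded F = 0, M = 1;
#'   gestational age effect per z-score unit).
#' @param truncate Clip generated values to [0, 1] (counted and reported).
#' @param seed Integer seed; the same seed reproduces the dataset exactly.
#' @return A validated configuration list of class `methtraj_config`.
#' @export
sim_config <- function(n_children = c(A = 300, B = 250),
                       visit_age_means = list(A = c(0, 6.0, 9.8),
                                              B = c(0, 7.5, 17.1)),
                       visit_age_sds = list(A = c(0, 0.5, 0.3),
                                            B = c(0, 0.2, 1.0)),
                       attendance = list(A = c(0.60, 0.55, 0.55),
                                         B = c(0.95, 0.95, 0.93)),
                       archetypes = archetype_table(),
                       knots = c(6, 9), plate_size = 96,
                       effect_sex = 0, effect_sex_age = 0,
                       effect_gestational_age = 0,
                       truncate = TRUE, seed = 1L) {
  cfg <- list(n_children = n_children, visit_age_means = visit_age_means,
              visit_age_sds = visit_age_sds, attendance = attendance,
              archetypes = archetypes, knots = knots,
              plate_size = plate_size, effect_sex = effect_sex,
              effect_sex_age = effect_sex_age,
              effect_gestational_age = effect_gestational_age,
              truncate = truncate, seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "methtraj_config"
  cfg
}

validate_sim_config <- function(cfg) {
  if (any(cfg$n_children <= 0))
    stopf("n_children must be positive for every cohort")
  if (is.null(names(cfg$n_children)))
    stopf("n_children must be a named vector of cohorts")
  for (co in names(cfg$n_children)) {
    att <- cfg$attendance[[co]]
    if (any(att <= 0 | att > 1))
      stopf("attendance probabilities must lie in (0, 1]")
    if (length(cfg$visit_age_means[[co]]) != length(att) ||
        length(cfg$visit_age_sds[[co]]) != length(att))
      stopf("visit age means, SDs and attendance must have equal length")
  }
  vc <- c("sigma2_intercept", "sigma2_age", "sigma2_age6p", "sigma2_age9p",
          "sigma2_plate", "sigma2_resid")
  a <- cfg$archetypes
  for (v in vc) if (any(a[[v]] < 0))
    stopf("negative variance component in archetype table: %s", v)
  invisible(cfg)
}

#' Simulate a two-cohort longitudinal beta-value dataset
#'
#' Draws, per child: sex, gestational age, cell fractions (Dirichlet around
#' typical whole-blood composition), visit ages and attendance; assigns
#' plates within cohort in fill order; then generates, per CpG, child
#' random effects (mutually independent), plate effects and residuals, and
#' evaluates the piecewise-linear predictor. Values are truncated to
#' [0, 1] when `truncate = TRUE` and truncation events are counted.
#'
#' @param config A [sim_config()] object.
#' @return A list with `betas` (CpG x sample matrix with dimnames), `meta`
#'   (sample sheet data.frame), `truncation` (`count` and `fraction`) and
#'   the `config` used.
#' @export
simulate_cohort <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  metas <- lapply(names(config$n_children), function(co)
    simulate_meta_cohort(config, co))
  meta <- do.call(rbind, metas)
  rownames(meta) <- NULL

  a <- config$archetypes
  n_cpgs <- nrow(a)
  n <- nrow(meta)
  k1 <- config$knots[1]; k2 <- config$knots[2]
  age <- meta$age
  a6 <- age_knot(age, k1); a9 <- age_knot(age, k2)
  child_lev <- unique(meta$child_id)
  ci <- match(meta$child_id, child_lev)
  plate_lev <- unique(meta$plate_id)
  pi_ <- match(meta$plate_id, plate_lev)
  sex01 <- as.numeric(meta$sex == "M")
  gaz <- zscore(meta$gestational_age)
  covar <- config$effect_sex * sex01 + config$effect_sex_age * sex01 * age +
    config$effect_gestational_age * gaz

  nch <- length(child_lev); npl <- length(plate_lev)
  betas <- matrix(NA_real_, n_cpgs, n,
                  dimnames = list(a$cpg_id, meta$sample_id))
  n_trunc <- 0L
  for (g in seq_len(n_cpgs)) {
    u0 <- stats::rnorm(nch, 0, sqrt(a$sigma2_intercept[g]))
    u1 <- stats::rnorm(nch, 0, sqrt(a$sigma2_age[g]))
    u2 <- stats::rnorm(nch, 0, sqrt(a$sigma2_age6p[g]))
    u3 <- stats::rnorm(nch, 0, sqrt(a$sigma2_age9p[g]))
    up <- stats::rnorm(npl, 0, sqrt(a$sigma2_plate[g]))
    eps <- stats::rnorm(n, 0, sqrt(a$sigma2_resid[g]))
    mu <- a$beta0[g] + u0[ci] + (a$beta1[g] + u1[ci]) * age +
      (a$beta2[g] + u2[ci]) * a6 + (a$beta3[g] + u3[ci]) * a9 +
      up[pi_] + covar + eps
    if (config$truncate) {
      out <- mu < 0 | mu > 1
      n_trunc <- n_trunc + sum(out)
      mu <- pmin(pmax(mu, 0), 1)
    }
    betas[g, ] <- mu
  }
  list(betas = betas, meta = meta,
       truncation = list(count = n_trunc,
                         fraction = n_trunc / (n_cpgs * n)),
       config = config)
}

# child-level draws and the visit/plate layout for one cohort
simulate_meta_cohort <- function(config, co) {
  nch <- config$n_children[[co]]
  mu_v <- config$visit_age_means[[co]]
  sd_v <- config$visit_age_sds[[co]]
  att <- config$attendance[[co]]
  child_id <- sprintf("%s%05d", co, seq_len(nch))
  sex <- sample(c("F", "M"), nch, replace = TRUE)
  ga <- pmin(pmax(stats::rnorm(nch, 39.7, 1.5), 28), 43)
  alpha <- 200 * BLOOD_PROPS
  cells <- t(vapply(seq_len(nch), function(i) {
    g <- stats::rgamma(length(alpha), shape = alpha)
    g / sum(g)
  }, numeric(length(alpha))))
  colnames(cells) <- names(BLOOD_PROPS)

  rows <- list()
  for (v in seq_along(mu_v)) {
    attends <- stats::runif(nch) <= att[v]
    idx <- which(attends)
    if (!length(idx)) next
    ages <- if (sd_v[v] > 0) stats::rnorm(length(idx), mu_v[v], sd_v[v])
            else rep(mu_v[v], length(idx))
    ages <- pmin(pmax(ages, 0), 20)
    rows[[v]] <- data.frame(
      sample_id = sprintf("%s_v%d", child_id[idx], v),
      child_id = child_id[idx], cohort = co, age = ages,
      sex = sex[idx], gestational_age = ga[idx],
      cells[idx, , drop = FALSE])
  }
  meta <- do.call(rbind, rows)
  meta <- meta[order(meta$child_id, meta$age), ]
  meta$plate_id <- sprintf("%s_P%02d",
                           co, (seq_len(nrow(meta)) - 1) %/% config$plate_size + 1)
  meta[, META_COLS]
}

#' Qualitative trajectory archetypes and their generating coefficients
#'
#' Returns the panel of trajectory archetypes used for end-to-end
#' classification checks, with fixed-effect sizes calibrated so that each
#' generating label is recoverable under the default panel design. The base
#' slope (5e-3 beta per year) sits in the upper range of annual changes
#' seen at strongly age-related CpGs (the most extreme observed slopes are
#' several-fold larger), a clearly detectable but realistic effect.
#'
#' @return A data.frame with `label`, `beta1`, `beta2`, `beta3`.
#' @export
trajectory_archetypes <- function() {
  s <- 5e-3
  data.frame(
    label = c("Neutral", "Positive", "Negative",
              "Positive-Neutral", "Negative-Neutral", "Neutral-Positive",
              "Positive-More Positive-Less Positive",
              "Negative-More Negative-Less Negative"),
    beta1 = c(0, s, -s, 2 * s, -2 * s, 0, s, -s),
    beta2 = c(0, 0, 0, -2 * s, 2 * s, 1.5 * s, s, -s),
    beta3 = c(0, 0, 0, 0, 0, 0, -s, s),
    stringsAsFactors = FALSE)
}

#' Simulate a labelled panel of trajectory archetypes
#'
#' Generates one CpG per requested archetype under the two-cohort design,
#' with slope random effects switched off and the batch component kept
#' small so classification power reflects the fixed trajectory shapes. The
#' `truth` attribute carries the generating labels; `calibration` records
#' the effect sizes and design used.
#'
#' @param labels Archetype labels, a subset of
#'   `trajectory_archetypes()$label`.
#' @param config Base [sim_config()]; its archetype table is replaced by
#'   the panel.
#' @return As [simulate_cohort()], plus a `truth` data.frame
#'   (`cpg_id`, `label`) and a `calibration` element.
#' @export
simulate_trajectory_panel <- function(labels = trajectory_archetypes()$label,
                                      config = sim_config()) {
  arch <- trajectory_archetypes()
  bad <- setdiff(labels, arch$label)
  if (length(bad))
    stopf("unknown archetype label(s): %s", paste(bad, collapse = ", "))
  arch <- arch[match(labels, arch$label), ]
  tab <- archetype_table(n_cpgs = nrow(arch), beta0 = 0.5,
                         beta1 = arch$beta1, beta2 = arch$beta2,
                         beta3 = arch$beta3,
                         sigma2_intercept = 1e-3, sigma2_age = 0,
                         sigma2_age6p = 0, sigma2_age9p = 0,
                         sigma2_plate = 1e-5, sigma2_resid = 2.5e-4)
  config$archetypes <- tab
  sim <- simulate_cohort(config)
  sim$truth <- data.frame(cpg_id = tab$cpg_id, label = arch$label)
  sim$calibration <- list(
    base_slope = 5e-3, sigma2_resid = 2.5e-4,
    n_children = config$n_children,
    note = paste("effect sizes chosen so each label is recoverable with",
                 "probability >= 0.95 at the panel Bonferroni threshold"))
  sim
}
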