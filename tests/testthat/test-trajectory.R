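# Design construction, piecewise segment slopes, trajectory and sex
# classification, variance partitioning and epigenome summaries.

test_that("truncated age terms and covariate standardization are correct", {
  expect_equal(age_knot(5, 6), 0)
  expect_equal(age_knot(9, 6), 3)
  expect_equal(age_knot(9, 9), 0)
  meta <- tiny_meta()
  d <- build_design(meta, "M2")
  expect_equal(unname(d$X[meta$age == 9.8, "age6p"][1]), 3.8)
  gz <- d$X[, "gestational_age"]
  expect_equal(mean(gz), 0, tolerance = 1e-12)
  expect_equal(stats::sd(gz), 1, tolerance = 1e-12)
  # granulocytes dropped; remaining design is full rank
  expect_false("gran" %in% colnames(d$X))
  expect_equal(qr(d$X)$rank, ncol(d$X))
  # M2 adds the knot terms to both fixed and random parts
  expect_true(all(c("age6p", "age9p") %in% colnames(d$X)))
  expect_true(all(c("age6p", "age9p") %in% d$random_terms))
})

test_that("single-cohort input drops the cohort term with a warning", {
  meta <- tiny_meta()
  meta <- meta[meta$cohort == "A", ]
  expect_warning(d <- build_design(meta, "M1"), "cohort")
  expect_false("cohort" %in% colnames(d$X))
})

test_that("knots must be increasing and inside the observed ages", {
  meta <- tiny_meta()
  expect_error(build_design(meta, "M2", knots = c(9, 6)), "increasing")
  expect_error(build_design(meta, "M2", knots = c(6, 30)), "inside")
})

test_that("segment slopes are the contrasts b1, b1+b2, b1+b2+b3", {
  mkfit <- function(b1, b2, b3) {
    terms <- c("intercept", "age", "age6p", "age9p", "sex")
    V <- diag(c(1e-6, 4e-8, 6e-8, 5e-8, 1e-6))
    structure(list(model_id = "M2", terms = terms, converged = TRUE,
                   fixed = data.frame(term = terms,
                                      beta = c(0.5, b1, b2, b3, 0),
                                      se = sqrt(diag(V)), z = 0, p = 1),
                   vcov_fixed = V, knots = c(6, 9),
                   lrt_p = setNames(numeric(0), character(0))),
              class = "methtraj_fit")
  }
  seg <- segment_slopes(mkfit(2e-3, -2e-3, 0))
  expect_equal(seg$estimate, c(2e-3, 0, 0))
  # b2 = b3 = 0: every segment equals b1
  seg2 <- segment_slopes(mkfit(1.5e-3, 0, 0))
  expect_equal(seg2$estimate, rep(1.5e-3, 3))
  # piecewise mean prediction is continuous at both knots
  b <- c(0.5, 2e-3, -1e-3, 5e-4)
  f <- function(a) b[1] + b[2] * a + b[3] * age_knot(a, 6) + b[4] * age_knot(a, 9)
  expect_equal(f(6 - 1e-9), f(6 + 1e-9), tolerance = 1e-10)
  expect_equal(f(9 - 1e-9), f(9 + 1e-9), tolerance = 1e-10)
})

test_that("segment estimates and SEs match a reparameterized refit", {
  sim <- small_sim()
  design <- build_design(sim$meta, "M2")
  y <- sim$betas[2, ]
  fit <- fit_lmm(y, design)
  seg <- segment_slopes(fit)
  # refit with a basis whose coefficients ARE the segment slopes:
  # min(age,6), clamp(age-6,0,3), (age-9)^+ ; the random structure is
  # untouched so the marginal model is identical
  age <- sim$meta$age
  design2 <- design
  design2$X[, "age"] <- pmin(age, 6)
  design2$X[, "age6p"] <- pmin(age_knot(age, 6), 3)
  design2$X[, "age9p"] <- age_knot(age, 9)
  fit2 <- fit_lmm(y, design2, control = lmm_control(reltol = 1e-12))
  expect_equal(fit$loglik, fit2$loglik, tolerance = 1e-6)
  for (i in 1:3) {
    t <- c("age", "age6p", "age9p")[i]
    expect_lt(abs(seg$estimate[i] - fit2$fixed$beta[fit2$fixed$term == t]),
              1e-6)
    expect_lt(abs(seg$se[i] - fit2$fixed$se[fit2$fixed$term == t]), 1e-6)
  }
})

test_that("trajectory labels follow the segment-state taxonomy", {
  mkseg <- function(est, p) data.frame(segment = c("birth_6", "y6_9", "y9_18"),
                                       estimate = est, se = 1, z = 0, p = p)
  mkfit <- function(b2, p2, b3, p3) structure(
    list(model_id = "M2",
         terms = c("intercept", "age", "age6p", "age9p"),
         fixed = data.frame(term = c("intercept", "age", "age6p", "age9p"),
                            beta = c(0.5, 0, b2, b3), se = 1, z = 0,
                            p = c(1, 1, p2, p3)),
         lrt_p = setNames(numeric(0), character(0))),
    class = "methtraj_fit")
  thr <- 0.01
  lab <- function(est, p, b2 = 0, p2 = 1, b3 = 0, p3 = 1)
    classify_trajectory(mkseg(est, p), mkfit(b2, p2, b3, p3), thr)$label
  expect_equal(lab(c(1, 0, 0), c(1e-5, 1, 1)), "Positive-Neutral")
  expect_equal(lab(c(-1, 0, 0), c(1e-5, 1, 1)), "Negative-Neutral")
  expect_equal(lab(c(0, 0, 0), c(1, 1, 1)), "Neutral")
  expect_equal(lab(c(1, 1, 1), c(1e-5, 1e-5, 1e-5)), "Positive")
  expect_equal(lab(c(1, 2, 1), c(1e-5, 1e-5, 1e-5), b2 = 1, p2 = 1e-5,
                   b3 = -1, p3 = 1e-5),
               "Positive-More Positive-Less Positive")
  expect_equal(lab(c(0, 1, 1), c(1, 1e-5, 1e-5)), "Neutral-Positive")
  # a significant slope-change without a sign match stays a plain state
  expect_equal(lab(c(-1, 1, 1), c(1e-5, 1e-5, 1e-5), b2 = 2, p2 = 1e-5),
               "Negative-Positive")
  lt <- classify_trajectory(mkseg(c(1, 1, 0), c(1e-5, 1e-5, 1)),
                            mkfit(0, 1, 0, 1), thr)
  expect_equal(lt$label, "Positive-Neutral")
  expect_false(lt$nonlinear)
})

test_that("loosening the threshold never turns a state Neutral", {
  sim <- simulate_trajectory_panel(config = sim_config(seed = 91))
  res_tight <- run_epigenome(sim$betas, sim$meta, "M2", threshold = 1e-5,
                             lrt = FALSE)
  res_loose <- run_epigenome(sim$betas, sim$meta, "M2", threshold = 1e-2,
                             lrt = FALSE)
  for (g in seq_len(nrow(res_tight))) {
    tight <- strsplit(res_tight$trajectory[g], "-")[[1]]
    loose <- strsplit(res_loose$trajectory[g], "-")[[1]]
    if (any(tight != "Neutral"))
      expect_true(any(loose != "Neutral"),
                  info = paste("CpG", g, res_tight$trajectory[g], "->",
                               res_loose$trajectory[g]))
  }
})

test_that("sex patterns are detected with the right direction", {
  base <- sim_config(n_children = c(A = 250, B = 250),
                     attendance = list(A = c(1, 1, 1), B = c(1, 1, 1)),
                     archetypes = archetype_table(n_cpgs = 1,
                       sigma2_age = 0, sigma2_plate = 1e-5),
                     effect_sex = 0.05, seed = 17)
  sim <- simulate_cohort(base)
  thr <- 1e-3
  res <- run_epigenome(sim$betas, sim$meta, "M3", threshold = thr,
                       lrt = FALSE)
  expect_true(res$sex_stable)
  expect_equal(res$sex_stable_dir, "higher in boys")
  expect_false(res$sex_change)
  # interaction only: boys change faster, no stable offset
  base$effect_sex <- 0
  base$effect_sex_age <- 2e-3
  sim2 <- simulate_cohort(base)
  res2 <- run_epigenome(sim2$betas, sim2$meta, "M3", threshold = thr,
                        lrt = FALSE)
  expect_false(res2$sex_stable)
  expect_true(res2$sex_change)
  expect_equal(res2$sex_change_dir, "faster increase in boys")
})

test_that("variance shares are normalized percentages of the components", {
  mkfit <- function(v) structure(list(varcomp = v), class = "methtraj_fit")
  v1 <- c(sigma2_intercept = 0, sigma2_age = 0, sigma2_plate = 0,
          sigma2_resid = 3e-4)
  expect_equal(unname(variance_partition(mkfit(v1))), c(0, 0, 0, 100))
  v2 <- c(sigma2_intercept = 2, sigma2_age = 2, sigma2_plate = 2,
          sigma2_resid = 2)
  expect_equal(unname(variance_partition(mkfit(v2))), rep(25, 4))
  set.seed(2)
  for (i in 1:20) {
    v <- setNames(rexp(4), names(v1))
    expect_equal(sum(variance_partition(mkfit(v))), 100, tolerance = 1e-9)
  }
})

test_that("annual change converts to total change over the period", {
  expect_equal(annual_to_total_change(-9.24e-4), -1.6632)
  expect_equal(annual_to_total_change(0), 0)
  expect_equal(annual_to_total_change(2e-3, years = 10), 2)
})

test_that("duplicate CpG rows give identical result rows", {
  sim <- small_sim()
  betas <- sim$betas[c(1, 1), ]
  rownames(betas) <- c("cg_a", "cg_b")
  res <- run_epigenome(betas, sim$meta, "M1", lrt = FALSE)
  r1 <- unlist(res[1, -1])
  r2 <- unlist(res[2, -1])
  expect_identical(unname(r1), unname(r2))
})

test_that("misaligned samples are a hard error naming offenders", {
  sim <- small_sim()
  betas <- sim$betas[, c(2, 1, seq(3, ncol(sim$betas)))]
  expect_error(run_epigenome(betas, sim$meta, "M1"), "misaligned")
  expect_error(check_alignment(unname(sim$betas), sim$meta), "no sample")
})

test_that("epigenome summaries report percentages and modes", {
  sim <- small_sim()
  res <- run_epigenome(sim$betas, sim$meta, "M1", threshold = 0.05,
                       lrt = FALSE)
  sm <- summarize_epigenome(res, threshold = 0.05)
  expect_equal(sm$n_cpgs, 4)
  expect_true(sm$pct_change >= 0 && sm$pct_change <= 100)
  expect_equal(sm$pct_change, sm$pct_increasing + sm$pct_decreasing)
  expect_equal(sm$mode_total_change,
               annual_to_total_change(sm$mode_change))
})
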