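# Maximum-likelihood mixed-model core: closed-form limits, independent
# likelihood oracles, cross-checks against lme4, and numerical invariants.

test_that("constant response gives the boundary fit: exact mean, zero variances", {
  meta <- tiny_meta()
  design <- build_design(meta, "M1")
  y <- rep(0.7, nrow(meta))
  fit <- fit_lmm(y, design)
  expect_true(fit$converged)
  expect_equal(fit$fixed$beta[fit$fixed$term == "intercept"], 0.7,
               tolerance = 1e-8)
  expect_lt(max(fit$varcomp), 1e-10)
})

test_that("a noiseless linear signal is recovered to numerical precision", {
  cfg <- sim_config(n_children = c(A = 30, B = 25),
                    archetypes = archetype_table(n_cpgs = 1, beta0 = 0.2,
                      beta1 = 0.01, sigma2_intercept = 0, sigma2_age = 0,
                      sigma2_plate = 0, sigma2_resid = 0),
                    seed = 3)
  sim <- simulate_cohort(cfg)
  design <- build_design(sim$meta, "M1")
  fit <- fit_lmm(sim$betas[1, ], design)
  expect_equal(fit$fixed$beta[fit$fixed$term == "intercept"], 0.2,
               tolerance = 1e-6)
  expect_equal(fit$fixed$beta[fit$fixed$term == "age"], 0.01,
               tolerance = 1e-6)
})

test_that("attained likelihood matches a dense grid-search oracle", {
  # 8 children x 2 visits, random intercept + residual only
  set.seed(42)
  n_ch <- 8
  meta <- tiny_meta(n_per_cohort = 4, visits = list(A = c(0, 6), B = c(0, 7.5)))
  # break the near-collinearity of the tiny deterministic covariates
  n <- nrow(meta)
  meta$cd4t <- 0.14 + 0.002 * seq_len(n)
  meta$cd8t <- 0.08 + 0.0015 * (seq_len(n) %% 5)
  meta$nk <- 0.05 + 0.001 * (seq_len(n) %% 3)
  meta$b <- 0.08 + 0.0012 * (seq_len(n) %% 7)
  meta$mono <- 0.09 + 0.0008 * (seq_len(n) %% 4)
  meta$gran <- 1 - (meta$cd4t + meta$cd8t + meta$nk + meta$b + meta$mono)
  meta$gestational_age <- 36 + (seq_len(n) %% 6)
  design <- build_design(meta, "M1")
  u <- rnorm(n_ch, 0, sqrt(2e-3))
  ci <- design$child_idx
  y <- 0.5 + u[ci] + rnorm(nrow(meta), 0, sqrt(5e-4))
  fit <- fit_lmm(y, design, random_terms = "child_intercept")
  expect_true(fit$converged)

  Z0 <- matrix(0, nrow(meta), n_ch)
  Z0[cbind(seq_len(nrow(meta)), ci)] <- 1
  oracle <- function(lo0, hi0, loe, hie, m = 25) {
    g <- expand.grid(s0 = exp(seq(log(lo0), log(hi0), length.out = m)),
                     se = exp(seq(log(loe), log(hie), length.out = m)))
    ll <- mapply(function(s0, se)
      dense_loglik(y, design$X, list(Z0), s0, se), g$s0, g$se)
    g[which.max(ll), ]
  }
  # nested grid refinement around the coarse optimum
  b <- oracle(1e-6, 1e-1, 1e-6, 1e-2)
  for (i in 1:3) b <- oracle(b$s0 / 3, b$s0 * 3, b$se / 3, b$se * 3)
  ll_grid <- dense_loglik(y, design$X, list(Z0), b$s0, b$se)
  expect_equal(fit$loglik, ll_grid, tolerance = 1e-4)
  expect_gte(fit$loglik, ll_grid - 1e-4)
})

test_that("structured deviance equals the sparse-matrix reference", {
  sim <- small_sim()
  design <- build_design(sim$meta, "M2")
  ctx <- methtraj:::lmm_context(design$X, design$blocks[design$random_terms])
  y <- sim$betas[2, ]
  ydat <- methtraj:::lmm_ydata(ctx, y)
  set.seed(9)
  for (i in 1:6) {
    th <- rnorm(5, -3, 2)
    expect_equal(methtraj:::lmm_eval(th, ctx, ydat),
                 methtraj:::lmm_eval_ref(th, design$X,
                                         design$blocks[design$random_terms], y),
                 tolerance = 1e-9)
  }
})

test_that("fit agrees with lme4 maximum likelihood on the same model", {
  skip_if_not_installed("lme4")
  sim <- small_sim()
  design <- build_design(sim$meta, "M1")
  y <- sim$betas[1, ]
  fit <- fit_lmm(y, design)
  df <- sim$meta
  df$y <- y
  df$gaz <- scale(df$gestational_age)[, 1]
  for (cc in c("cd4t", "cd8t", "nk", "b", "mono"))
    df[[paste0(cc, "z")]] <- scale(df[[cc]])[, 1]
  df$sex01 <- as.numeric(df$sex == "M")
  df$cohB <- as.numeric(df$cohort == "B")
  m <- suppressMessages(lme4::lmer(
    y ~ age + sex01 + cohB + gaz + cd4tz + cd8tz + nkz + bz + monoz +
      (1 | child_id) + (0 + age | child_id) + (1 | plate_id),
    data = df, REML = FALSE))
  expect_equal(fit$loglik, as.numeric(stats::logLik(m)), tolerance = 1e-6)
  expect_equal(fit$fixed$beta[fit$fixed$term == "age"],
               unname(lme4::fixef(m)["age"]), tolerance = 1e-4)
})

test_that("with no random terms the fit reduces to OLS with ML variance", {
  sim <- small_sim()
  design <- build_design(sim$meta, "M1")
  y <- sim$betas[3, ]
  fit <- fit_lmm(y, design, random_terms = character(0))
  ols <- stats::lm.fit(design$X, y)
  expect_equal(unname(fit$fixed$beta), unname(ols$coefficients),
               tolerance = 1e-8)
  expect_equal(unname(fit$varcomp["sigma2_resid"]),
               mean(ols$residuals^2), tolerance = 1e-8)
})

test_that("adding a random term never decreases the attained likelihood", {
  sim <- small_sim()
  design <- build_design(sim$meta, "M2")
  y <- sim$betas[1, ]
  full <- fit_lmm(y, design)
  for (drop in c("age", "age6p", "age9p")) {
    red <- fit_lmm(y, design,
                   random_terms = setdiff(design$random_terms, drop))
    expect_gte(full$loglik, red$loglik - 1e-6)
  }
})

test_that("estimates are invariant to sample order", {
  sim <- small_sim()
  y <- sim$betas[1, ]
  design <- build_design(sim$meta, "M1")
  fit1 <- fit_lmm(y, design)
  set.seed(5)
  perm <- sample(length(y))
  design2 <- build_design(sim$meta[perm, ], "M1")
  fit2 <- fit_lmm(y[perm], design2)
  expect_equal(fit1$loglik, fit2$loglik, tolerance = 1e-8)
  expect_equal(fit1$fixed$beta, fit2$fixed$beta, tolerance = 1e-7)
})

test_that("likelihood-ratio helper follows the chi-square(1) tail", {
  mk <- function(ll, terms) structure(
    list(loglik = ll, converged = TRUE, random_terms = terms),
    class = "methtraj_fit")
  full <- mk(-100, c("child_intercept", "age", "plate"))
  red <- mk(-100, c("child_intercept", "plate"))
  p <- lrt_random_term(full, red)
  expect_equal(as.numeric(p), 1)
  expect_equal(attr(p, "statistic"), 0)
  # ll difference of 2 -> statistic 4; expected p computed independently
  # from the chi-square(1) survival function
  p2 <- lrt_random_term(mk(-98, full$random_terms), red)
  expect_equal(attr(p2, "statistic"), 4)
  expect_equal(as.numeric(p2),
               stats::integrate(function(x) stats::dchisq(x, 1), 4, Inf,
                                rel.tol = 1e-12)$value, tolerance = 1e-8)
  # reduced likelihood above full (numerical noise) clips at 0
  p3 <- lrt_random_term(mk(-100.001, full$random_terms), red)
  expect_equal(attr(p3, "statistic"), 0)
  expect_error(lrt_random_term(full, mk(-100, "child_intercept")),
               "nested")
})

test_that("contrasts reproduce single-term tests and reject empty ones", {
  sim <- small_sim()
  design <- build_design(sim$meta, "M1")
  fit <- fit_lmm(sim$betas[1, ], design)
  i <- which(fit$fixed$term == "age")
  cv <- as.numeric(seq_along(fit$terms) == i)
  ct <- fixed_contrast(fit, cv)
  expect_equal(ct$estimate, fit$fixed$beta[i])
  expect_equal(ct$se, fit$fixed$se[i])
  expect_equal(ct$p, fit$fixed$p[i])
  expect_error(fixed_contrast(fit, numeric(length(fit$terms))), "all-zero")
  expect_error(fixed_contrast(fit, c(1, 1)), "length")
})

test_that("missing responses are masked and counted per fit", {
  sim <- small_sim()
  design <- build_design(sim$meta, "M1")
  y <- sim$betas[1, ]
  drop <- seq(3, length(y), by = 20)
  y[drop] <- NA
  fit <- fit_lmm(y, design)
  expect_true(fit$converged)
  expect_equal(fit$n_samples, length(y) - length(drop))
})

test_that("a rank-deficient fixed design is rejected naming the term", {
  meta <- tiny_meta()
  meta$gestational_age <- 39  # constant -> zero column after z-scoring
  design <- build_design(meta, "M1")
  expect_error(fit_lmm(rep(0.5, nrow(meta)) + 0.001 * meta$age, design),
               "gestational_age")
})
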