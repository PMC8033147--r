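# Deterministic fixtures built in code (no stored data).

# small hand-built sample sheet with non-degenerate covariates
tiny_meta <- function(n_per_cohort = 12,
                      visits = list(A = c(0, 6, 9.8), B = c(0, 7.5, 17.1))) {
  rows <- list()
  for (co in names(visits)) {
    for (i in seq_len(n_per_cohort)) {
      cid <- sprintf("%s%03d", co, i)
      for (v in seq_along(visits[[co]])) {
        cd4t <- 0.15 + 0.01 * sin(i + v)
        cd8t <- 0.08 + 0.008 * cos(2 * i)
        nk <- 0.05 + 0.005 * sin(3 * i)
        b <- 0.08 + 0.006 * cos(i + 2 * v)
        mono <- 0.09 + 0.004 * sin(5 * i)
        rows[[length(rows) + 1]] <- data.frame(
          sample_id = sprintf("%s_v%d", cid, v), child_id = cid, cohort = co,
          age = visits[[co]][v], sex = if (i %% 2 == 0) "F" else "M",
          plate_id = sprintf("%s_P%d", co, 1 + (i > n_per_cohort / 2)),
          gestational_age = 38 + (i %% 5), cd4t = cd4t, cd8t = cd8t,
          nk = nk, b = b, mono = mono,
          gran = 1 - (cd4t + cd8t + nk + b + mono))
      }
    }
  }
  do.call(rbind, rows)
}

# a small shared simulated dataset reused across test files
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_children = c(A = 50, B = 40),
                        archetypes = archetype_table(n_cpgs = 4, beta1 = 1e-3),
                        seed = 20260901)
      cache <<- simulate_cohort(cfg)
    }
    cache
  }
})

# independent dense marginal log-likelihood for small problems:
# V = sum_t s2_t Z_t Z_t' + s2_e I, beta profiled by GLS
dense_loglik <- function(y, X, Zmats, s2, s2e) {
  n <- length(y)
  V <- diag(s2e, n)
  for (t in seq_along(Zmats)) V <- V + s2[t] * tcrossprod(Zmats[[t]])
  Vi <- solve(V)
  XtVi <- t(X) %*% Vi
  beta <- solve(XtVi %*% X, XtVi %*% y)
  r <- y - X %*% beta
  as.numeric(-0.5 * (n * log(2 * pi) + determinant(V)$modulus +
                       t(r) %*% Vi %*% r))
}
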