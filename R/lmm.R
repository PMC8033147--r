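# Maximum-likelihood estimation for the Gaussian linear mixed models used
# throughout the trajectory analysis:
#
#   y = X beta + Z_1 u_1 + ... + Z_k u_k + eps,   u_t ~ N(0, sigma2_t I),
#                                                 eps ~ N(0, sigma2_e I)
#
# with a child-level random intercept, child-level random slopes that are
# mutually uncorrelated and uncorrelated with the intercept (diagonal
# random-effects covariance), and a crossed sample-plate random intercept.
#
# The marginal covariance is sigma2_e * W with W = I + sum_t gamma_t Z_t Z_t',
# gamma_t = sigma2_t / sigma2_e.  beta and sigma2_e are profiled out in
# closed form; the profiled ML deviance is minimized numerically over
# log(gamma).
#
# The deviance evaluation exploits the model structure instead of a
# generic sparse solver: without the plate term, W is block-diagonal by
# child, and each child block inverts through an r x r core (r = number of
# child-level random terms, at most 4), so all children are processed at
# once with vectorized small-matrix Cholesky factorizations; the crossed
# plate intercept is then folded in by a Woodbury correction in plate
# space (tens of plates).  Everything that does not depend on the variance
# parameters or on the response is precomputed once per design, so per-CpG
# fits across an epigenome are cheap.  A sparse-matrix reference
# implementation of the same likelihood is kept for cross-validation.

#' Optimizer control for mixed-model fits
#'
#' @param reltol Relative convergence tolerance on the profiled deviance.
#' @param maxit Maximum iterations per optimizer run.
#' @param restarts Number of polishing restarts from the current optimum
#'   (a deterministic perturbed restart is added automatically when the
#'   first run fails).
#' @return A list of control settings for [fit_lmm()].
#' @export
lmm_control <- function(reltol = 1e-8, maxit = 1000, restarts = 1) {
  stopifnot(reltol > 0, maxit >= 1, restarts >= 0)
  list(reltol = reltol, maxit = maxit, restarts = restarts)
}

# ---------------------------------------------------------------------------
# design context: everything reusable across CpGs for one design
#
# blocks: named list, each list(name, j = level index per row, x = covariate
# per row, nlev).  Child-level blocks share j; an optional block named
# "plate" is treated as the crossed intercept.
lmm_context <- function(X, blocks, keep = NULL) {
  if (!is.null(keep)) {
    X <- X[keep, , drop = FALSE]
    blocks <- lapply(blocks, function(b) {
      j <- b$j[keep]
      lev <- sort(unique(j))
      list(name = b$name, j = match(j, lev), x = b$x[keep], nlev = length(lev))
    })
  }
  n <- nrow(X)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[setdiff(seq_len(ncol(X)), qrX$pivot[seq_len(qrX$rank)])]
    stopf("fixed design is rank deficient; collinear term(s): %s",
          paste(bad, collapse = ", "))
  }
  ctx <- new.env(parent = emptyenv())
  ctx$X <- X
  ctx$n <- n
  ctx$p <- ncol(X)
  has_plate <- "plate" %in% names(blocks)
  child <- blocks[setdiff(names(blocks), "plate")]
  ctx$names <- c(vapply(child, `[[`, "", "name"),
                 if (has_plate) "plate")
  ctx$k <- length(blocks)
  ctx$r <- length(child)
  ctx$has_plate <- has_plate
  if (has_plate) {
    pb <- blocks$plate
    ctx$npl <- pb$nlev
    Zp <- matrix(0, n, pb$nlev)
    Zp[cbind(seq_len(n), pb$j)] <- pb$x
  } else {
    ctx$npl <- 0L
    Zp <- NULL
  }
  ctx$T0 <- if (is.null(Zp)) X else cbind(X, Zp)
  ctx$m0 <- ncol(ctx$T0)
  ctx$TT0 <- crossprod(ctx$T0)
  if (ctx$r > 0) {
    ctx$ci <- child[[1]]$j
    ctx$nch <- child[[1]]$nlev
    ctx$u <- lapply(child, `[[`, "x")
    # per-child r x r cross-product entries, stored as nch-vectors
    ctx$G <- vector("list", ctx$r * ctx$r)
    dim(ctx$G) <- c(ctx$r, ctx$r)
    for (s in seq_len(ctx$r)) for (t in seq_len(s)) {
      g <- rowsum(ctx$u[[s]] * ctx$u[[t]], ctx$ci)[, 1]
      ctx$G[[s, t]] <- ctx$G[[t, s]] <- g
    }
    # per-child cross products of each random covariate with [X, Zp]
    ctx$H0 <- lapply(ctx$u, function(us) rowsum(ctx$T0 * us, ctx$ci))
  }
  ctx
}

# per-response cross products reused across deviance evaluations
lmm_ydata <- function(ctx, y) {
  list(Ty = as.numeric(crossprod(ctx$T0, y)), yy = sum(y * y),
       hy = if (ctx$r > 0) lapply(ctx$u, function(us)
         rowsum(us * y, ctx$ci)[, 1]) else NULL)
}

# One profiled-deviance evaluation at theta = log(gamma), theta ordered as
# ctx$names (child terms, then plate).  Returns the deviance; with
# want_fit = TRUE also beta-hat, its covariance and sigma2_e.
lmm_eval <- function(theta, ctx, ydat, want_fit = FALSE) {
  n <- ctx$n; p <- ctx$p; r <- ctx$r; npl <- ctx$npl
  gam <- exp(pmin(pmax(theta, -45), 25))
  m <- ctx$m0 + 1                          # columns of T = [X, Zp, y]
  TT <- rbind(cbind(ctx$TT0, ydat$Ty), c(ydat$Ty, ydat$yy))
  logdetW <- 0
  if (r > 0) {
    sg <- sqrt(gam[seq_len(r)])
    # batched Cholesky of K_i = I_r + D G_i D across children
    L <- vector("list", r * r); dim(L) <- c(r, r)
    for (j in seq_len(r)) {
      d <- 1 + gam[j] * ctx$G[[j, j]]
      if (j > 1) for (k in seq_len(j - 1)) d <- d - L[[j, k]]^2
      L[[j, j]] <- sqrt(pmax(d, 1e-300))
      if (j < r) for (i in (j + 1):r) {
        o <- sg[i] * sg[j] * ctx$G[[i, j]]
        if (j > 1) for (k in seq_len(j - 1)) o <- o - L[[i, k]] * L[[j, k]]
        L[[i, j]] <- o / L[[j, j]]
      }
      logdetW <- logdetW + 2 * sum(log(L[[j, j]]))
    }
    # forward substitution of the scaled per-child cross products
    corr <- matrix(0, m, m)
    Fs <- vector("list", r)
    for (j in seq_len(r)) {
      Hj <- cbind(ctx$H0[[j]], ydat$hy[[j]]) * sg[j]
      if (j > 1) for (k in seq_len(j - 1)) Hj <- Hj - L[[j, k]] * Fs[[k]]
      Fs[[j]] <- Hj / L[[j, j]]
      corr <- corr + crossprod(Fs[[j]])
    }
    TT <- TT - corr
  }
  if (ctx$has_plate) {
    gp <- gam[r + 1]
    ip <- p + seq_len(npl)
    ixy <- c(seq_len(p), m)
    Cp <- diag(npl) + gp * TT[ip, ip]
    Rp <- tryCatch(chol(Cp), error = function(e) NULL)
    if (is.null(Rp)) return(if (want_fit) NULL else Inf)
    logdetW <- logdetW + 2 * sum(log(diag(Rp)))
    Q <- TT[ip, ixy, drop = FALSE]
    TTxy <- TT[ixy, ixy] - gp * crossprod(backsolve(Rp, Q, transpose = TRUE))
  } else {
    ixy <- c(seq_len(p), m)
    TTxy <- TT[ixy, ixy]
  }
  XtWiX <- TTxy[seq_len(p), seq_len(p), drop = FALSE]
  XtWiy <- TTxy[seq_len(p), p + 1]
  yWiy <- TTxy[p + 1, p + 1]
  XtWiX <- (XtWiX + t(XtWiX)) / 2
  R <- tryCatch(chol(XtWiX), error = function(e) NULL)
  if (is.null(R)) return(if (want_fit) NULL else Inf)
  beta <- backsolve(R, backsolve(R, XtWiy, transpose = TRUE))
  rss <- max(yWiy - sum(beta * XtWiy), 0)
  sigma2 <- max(rss / n, 1e-30)
  dev <- n * log(2 * pi * sigma2) + logdetW + n
  if (!want_fit) return(dev)
  list(dev = dev, beta = as.numeric(beta), sigma2 = sigma2,
       vcov = sigma2 * chol2inv(R), logdetW = logdetW, gamma = gam)
}

# ---------------------------------------------------------------------------
# sparse-matrix reference implementation of the same profiled deviance
# (generic W = I + Z Gamma Z'); used to cross-validate the structured
# evaluation in the test-suite and for nothing else.
lmm_eval_ref <- function(theta, X, blocks, y) {
  n <- nrow(X); p <- ncol(X)
  gam <- exp(theta)
  Zs <- lapply(blocks, function(b)
    Matrix::sparseMatrix(i = seq_along(b$j), j = b$j, x = b$x,
                         dims = c(n, b$nlev)))
  Z <- do.call(cbind, Zs)
  s <- sqrt(rep(gam, vapply(blocks, `[[`, 0L, "nlev")))
  A <- Matrix::forceSymmetric(Matrix::Diagonal(ncol(Z)) +
    Matrix::Diagonal(x = s) %*% Matrix::crossprod(Z) %*% Matrix::Diagonal(x = s))
  ch <- Matrix::Cholesky(A, LDL = FALSE, perm = TRUE)
  logdetW <- 2 * c(Matrix::determinant(ch, sqrt = TRUE)$modulus)
  B <- cbind(as.matrix(Matrix::Diagonal(x = s) %*% Matrix::crossprod(Z, X)),
             s * as.numeric(Matrix::crossprod(Z, y)))
  AiB <- as.matrix(Matrix::solve(ch, B, system = "A"))
  CB <- crossprod(B, AiB)
  XtWiX <- crossprod(X) - CB[seq_len(p), seq_len(p)]
  XtWiy <- as.numeric(crossprod(X, y)) - CB[seq_len(p), p + 1]
  yWiy <- sum(y * y) - CB[p + 1, p + 1]
  beta <- solve(XtWiX, XtWiy)
  sigma2 <- max((yWiy - sum(beta * XtWiy)) / n, 1e-30)
  n * log(2 * pi * sigma2) + logdetW + n
}

# Default optimizer starting values on the log variance-ratio scale, chosen
# by role: random intercepts start near the residual variance, slopes (per
# year^2 units) and the plate batch component start smaller.
lmm_start <- function(names) {
  th <- ifelse(names == "child_intercept", 0,
        ifelse(names == "plate", log(0.1), log(0.01)))
  stats::setNames(th, names)
}

# Core fitting loop on a prepared context; never throws on optimizer
# trouble, reports converged = FALSE instead.
lmm_fit_core <- function(ctx, y, control = lmm_control(), start = NULL) {
  ydat <- lmm_ydata(ctx, y)
  devfun <- function(th) {
    d <- lmm_eval(th, ctx, ydat)
    if (!is.finite(d)) 1e300 else d
  }
  converged <- TRUE
  if (ctx$k == 0) {
    th <- numeric(0)
  } else {
    th0 <- start %||% lmm_start(ctx$names)
    if (ctx$k == 1) {
      op <- tryCatch(stats::optimize(devfun, interval = c(-40, 20),
                                     tol = 1e-9),
                     error = function(e) NULL)
      if (is.null(op)) { th <- th0; converged <- FALSE }
      else th <- stats::setNames(op$minimum, ctx$names)
    } else {
      run <- function(p0) tryCatch(
        stats::optim(p0, devfun, method = "Nelder-Mead",
                     control = list(maxit = control$maxit,
                                    reltol = control$reltol)),
        error = function(e) NULL)
      op <- run(th0)
      if (is.null(op)) {
        # deterministic perturbed restart keeps repeat runs bit-identical
        op <- run(th0 + 0.5 * sin(seq_len(ctx$k)))
      }
      if (is.null(op)) { th <- th0; converged <- FALSE } else {
        # gradient-based polish tightens the simplex optimum so that nested
        # fits respect likelihood monotonicity to high precision
        for (i in seq_len(control$restarts)) {
          op2 <- tryCatch(
            stats::optim(op$par, devfun, method = "BFGS",
                         control = list(maxit = 200, reltol = 1e-13,
                                        ndeps = rep(1e-5, ctx$k))),
            error = function(e) NULL)
          if (!is.null(op2) && op2$value <= op$value) op <- op2
        }
        # boundary collapse: variance ratios that vanished (log gamma below
        # -20, i.e. a negligible component) flatten the deviance and stall
        # the simplex; pin them to the floor and re-optimize the rest
        bnd <- op$par < -20
        if (any(bnd)) {
          thb <- op$par
          thb[bnd] <- -45
          free <- which(!bnd)
          vb <- if (length(free) == 0) devfun(thb) else {
            subfun <- function(pf) { t <- thb; t[free] <- pf; devfun(t) }
            if (length(free) == 1) {
              ob <- stats::optimize(subfun, interval = c(-40, 20), tol = 1e-10)
              thb[free] <- ob$minimum
              ob$objective
            } else {
              ob <- stats::optim(op$par[free], subfun, method = "Nelder-Mead",
                                 control = list(maxit = control$maxit,
                                                reltol = 1e-12))
              thb[free] <- ob$par
              ob$value
            }
          }
          if (vb <= op$value) { op$par <- thb; op$value <- vb }
        }
        th <- op$par
        converged <- is.finite(op$value)
      }
    }
  }
  ev <- lmm_eval(th, ctx, ydat, want_fit = TRUE)
  if (is.null(ev)) {
    return(list(converged = FALSE, theta = th, eval = NULL))
  }
  list(converged = converged, theta = th, eval = ev)
}

#' Fit a per-CpG linear mixed model by maximum likelihood
#'
#' Fits the Gaussian mixed model defined by a [build_design()] object to one
#' CpG's beta values: fixed effects plus a child-level random intercept,
#' uncorrelated child-level random slopes, and (optionally) a crossed
#' sample-plate random intercept. Estimation maximizes the marginal
#' likelihood with fixed effects and the residual variance profiled out and
#' the remaining variance ratios optimized on the log scale, so boundary
#' (zero) variances are represented by vanishingly small estimates rather
#' than failures. Fixed-effect p-values are two-sided z-tests.
#'
#' @param y Numeric vector of beta values, aligned with `design`; `NA`s are
#'   dropped (the corresponding rows of the design are masked).
#' @param design A design object from [build_design()].
#' @param random_terms Character vector naming the random terms to include,
#'   a subset of `design$random_terms`. Defaults to all of them.
#' @param control Optimizer settings from [lmm_control()].
#' @param cpg_id Optional identifier stored in the result.
#' @param context Optional pre-built numerical context (internal, used by
#'   [run_epigenome()] to share design pre-computation across CpGs). Only
#'   valid when `y` has no missing values.
#' @return An object of class `methtraj_fit`: a list with elements `fixed`
#'   (data.frame of term, beta, se, z, p), `varcomp` (named variances,
#'   including `sigma2_resid`), `loglik`, `converged`, `n_samples`,
#'   `n_children`, `n_plates`, `lrt_p` (filled by [lrt_random_term()] /
#'   [run_epigenome()]), `vcov_fixed`, `model_id`, and `random_terms`.
#' @seealso [lrt_random_term()], [fixed_contrast()], [run_epigenome()]
#' @export
fit_lmm <- function(y, design, random_terms = design$random_terms,
                    control = lmm_control(), cpg_id = NA_character_,
                    context = NULL) {
  stopifnot(inherits(design, "methtraj_design"))
  if (length(y) != nrow(design$X))
    stopf("length(y) = %d does not match the design (%d samples)",
          length(y), nrow(design$X))
  bad <- setdiff(random_terms, design$random_terms)
  if (length(bad))
    stopf("unknown random term(s): %s", paste(bad, collapse = ", "))
  keep <- which(is.finite(y))
  y_obs <- y[keep]
  if (any(y_obs < 0 | y_obs > 1))
    stopf("beta values outside [0, 1] for %s", cpg_id)
  child <- design$child_idx[keep]
  if (sum(table(child) >= 2) < 2)
    stopf("need at least 2 children with repeated measures to fit")
  if (is.null(context) || length(keep) < length(y)) {
    ctx <- lmm_context(design$X, design$blocks[random_terms],
                       keep = if (length(keep) < length(y)) keep else NULL)
  } else ctx <- context
  core <- lmm_fit_core(ctx, y_obs, control = control)
  new_lmm_fit(core, ctx, design, random_terms, keep, cpg_id)
}

# Assemble the user-facing fit object from the optimizer output.
new_lmm_fit <- function(core, ctx, design, random_terms, keep, cpg_id) {
  ev <- core$eval
  terms <- colnames(design$X)
  base <- list(cpg_id = cpg_id, model_id = design$model_id,
               n_samples = ctx$n,
               n_children = length(unique(design$child_idx[keep])),
               n_plates = length(unique(design$plate_idx[keep])),
               lrt_p = stats::setNames(numeric(0), character(0)),
               random_terms = random_terms, terms = terms,
               knots = design$knots)
  if (is.null(ev)) {
    fit <- c(base, list(
      fixed = data.frame(term = terms, beta = NA_real_, se = NA_real_,
                         z = NA_real_, p = NA_real_),
      varcomp = stats::setNames(rep(NA_real_, length(random_terms) + 1),
                                c(varcomp_name(random_terms), "sigma2_resid")),
      loglik = NA_real_, converged = FALSE, vcov_fixed = NULL))
    class(fit) <- "methtraj_fit"
    return(fit)
  }
  se <- sqrt(pmax(diag(ev$vcov), 0))
  z <- ifelse(se > 0, ev$beta / se, 0)
  fixed <- data.frame(term = terms, beta = ev$beta, se = se, z = z,
                      p = 2 * stats::pnorm(-abs(z)))
  sig2 <- ev$sigma2
  varcomp <- stats::setNames(c(ev$gamma * sig2, sig2),
                             c(varcomp_name(random_terms), "sigma2_resid"))
  fit <- c(base, list(fixed = fixed, varcomp = varcomp,
                      loglik = -ev$dev / 2, converged = core$converged,
                      vcov_fixed = ev$vcov))
  class(fit) <- "methtraj_fit"
  fit
}

varcomp_name <- function(random_terms) {
  map <- c(child_intercept = "sigma2_intercept", age = "sigma2_age",
           age6p = "sigma2_age6p", age9p = "sigma2_age9p",
           plate = "sigma2_plate")
  unname(map[random_terms])
}

#' @export
print.methtraj_fit <- function(x, ...) {
  cat(sprintf("Mixed-model fit (%s)%s: %d samples, %d children, %d plates\n",
              x$model_id, if (is.na(x$cpg_id)) "" else paste0(" for ", x$cpg_id),
              x$n_samples, x$n_children, x$n_plates))
  cat(sprintf("logLik = %.4f, converged = %s\n", x$loglik, x$converged))
  print(x$fixed, digits = 4)
  cat("Variance components:\n")
  print(signif(x$varcomp, 4))
  invisible(x)
}

#' Likelihood-ratio test for one random slope variance
#'
#' Compares a full fit with a reduced fit identical except for the removal
#' of exactly one random slope term. The statistic is
#' `max(0, 2 * (logLik_full - logLik_reduced))` and the p-value comes from a
#' chi-square distribution with 1 degree of freedom. Testing a variance on
#' its boundary (zero) makes this construction conservative; no boundary
#' mixture correction is applied.
#'
#' @param full,reduced `methtraj_fit` objects with nested random terms.
#' @return The p-value, with the statistic and the tested term as
#'   attributes.
#' @export
lrt_random_term <- function(full, reduced) {
  stopifnot(inherits(full, "methtraj_fit"), inherits(reduced, "methtraj_fit"))
  dropped <- setdiff(full$random_terms, reduced$random_terms)
  extra <- setdiff(reduced$random_terms, full$random_terms)
  if (length(dropped) != 1 || length(extra) != 0)
    stopf("models are not nested by exactly one random term")
  if (!isTRUE(full$converged) || !isTRUE(reduced$converged))
    stopf("both fits must have converged")
  stat <- max(0, 2 * (full$loglik - reduced$loglik))
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  structure(p, statistic = stat, term = dropped)
}

#' General linear hypothesis (contrast) on the fixed effects
#'
#' Tests `H0: c' beta = 0` for a converged fit: the estimate is `c' beta`,
#' its standard error `sqrt(c' V c)` with `V` the estimated fixed-effect
#' covariance, and the p-value a two-sided z-test. Used to derive per-age-
#' segment slopes from the piecewise model.
#'
#' @param fit A converged `methtraj_fit`.
#' @param cvec Numeric contrast vector, one entry per fixed term (in the
#'   order of `fit$fixed$term`).
#' @return A list with `estimate`, `se`, `z`, `p`.
#' @export
fixed_contrast <- function(fit, cvec) {
  stopifnot(inherits(fit, "methtraj_fit"))
  if (!isTRUE(fit$converged)) stopf("fit did not converge")
  if (length(cvec) != nrow(fit$fixed))
    stopf("contrast length %d != number of fixed terms %d",
          length(cvec), nrow(fit$fixed))
  if (all(cvec == 0)) stopf("all-zero contrast defines no hypothesis")
  est <- sum(cvec * fit$fixed$beta)
  se <- sqrt(max(as.numeric(t(cvec) %*% fit$vcov_fixed %*% cvec), 0))
  z <- if (se > 0) est / se else 0
  list(estimate = est, se = se, z = z, p = 2 * stats::pnorm(-abs(z)))
}
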