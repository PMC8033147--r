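# Enrichment follow-up: 2x2 tests of trajectory classes against CpG
# annotation categories (Pearson chi-square of unequal proportions, no
# continuity correction) and against published EWAS hit lists (two-sided
# Fisher's exact test by the probability-mass rule), plus the Bonferroni
# threshold helper and the clustered trajectory-by-study enrichment grid.

#' Bonferroni-corrected significance threshold
#'
#' `alpha / m`. The exact value is returned for testing; for display,
#' round to 3 significant figures (`signif(x, 3)`).
#'
#' @param alpha Family-wise error rate, in (0, 1).
#' @param m Number of tests, a positive integer.
#' @return The exact threshold `alpha / m`.
#' @examples
#' signif(bonferroni_threshold(0.05, 152), 3) # 3.29e-4
#' @export
bonferroni_threshold <- function(alpha, m) {
  if (alpha <= 0 || alpha >= 1) stopf("alpha must lie in (0, 1)")
  if (m < 1) stopf("m must be a positive count")
  alpha / m
}

# assemble and sanity-check the 2x2 table: rows = in/out of the trajectory
# class, columns = in/out of the annotation (or hit list)
build_2x2 <- function(traj, annot) {
  stopifnot(is.logical(traj), is.logical(annot))
  if (length(traj) != length(annot))
    stopf("flag vectors must cover the same CpG universe")
  tab <- matrix(c(sum(traj & annot), sum(traj & !annot),
                  sum(!traj & annot), sum(!traj & !annot)),
                2, 2, byrow = TRUE,
                dimnames = list(traj = c("in", "out"),
                                annot = c("in", "out")))
  tab
}

#' Chi-square enrichment of a trajectory class in an annotation category
#'
#' Pearson chi-square test of unequal proportions (1 df, no continuity
#' correction) on the 2x2 table of trajectory membership against annotation
#' membership. Reports the proportion of annotated and non-annotated CpGs
#' that follow the trajectory, the form in which such contrasts are usually
#' quoted (e.g. "19.0 versus 15.6%").
#'
#' @param traj_flags,annot_flags Equal-length logical vectors over the same
#'   CpG universe.
#' @return A `ContingencyResult` list: `table`, `statistic`, `p`,
#'   `prop_in`, `prop_out`, `test = "chi2"`.
#' @export
chi2_enrichment <- function(traj_flags, annot_flags) {
  tab <- build_2x2(traj_flags, annot_flags)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stopf("degenerate table: a margin is zero")
  ht <- stats::chisq.test(tab, correct = FALSE)
  list(table = tab, statistic = unname(ht$statistic), p = unname(ht$p.value),
       prop_in = tab[1, 1] / sum(tab[, 1]),
       prop_out = tab[1, 2] / sum(tab[, 2]),
       test = "chi2")
}

#' Fisher's exact enrichment of a trajectory class in a hit list
#'
#' Two-sided exact test (sum of hypergeometric probabilities of tables at
#' most as probable as the observed one). The reported odds ratio is the
#' sample odds ratio `ad/bc`, not the conditional-MLE estimate.
#'
#' @param traj_flags,hit_flags Equal-length logical vectors over the same
#'   CpG universe.
#' @return A `ContingencyResult` list: `table`, `p`, `odds_ratio`,
#'   `prop_in`, `prop_out`, `test = "fisher"`.
#' @export
fisher_enrichment <- function(traj_flags, hit_flags) {
  tab <- build_2x2(traj_flags, hit_flags)
  ht <- stats::fisher.test(tab)
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  list(table = tab, p = unname(ht$p.value), odds_ratio = or,
       prop_in = if (sum(tab[, 1]) > 0) tab[1, 1] / sum(tab[, 1]) else NA_real_,
       prop_out = if (sum(tab[, 2]) > 0) tab[1, 2] / sum(tab[, 2]) else NA_real_,
       test = "fisher")
}

#' Clustered grid of trajectory-by-study enrichments
#'
#' Runs [fisher_enrichment()] for every trajectory class against every
#' study hit list and orders rows and columns by hierarchical clustering
#' (average linkage, Euclidean distance) of `-log10(p)`, capped at 50 to
#' avoid infinite distances from underflowing p-values.
#'
#' @param traj_sets Named list of logical vectors (one per trajectory
#'   class) over the CpG universe.
#' @param study_sets Named list of logical vectors (one per study).
#' @param cap Cap applied to `-log10(p)` before clustering.
#' @return List with matrices `p`, `odds_ratio`, `neglog10p` (capped), and
#'   `row_order`, `col_order` (names in clustered order).
#' @export
enrichment_matrix <- function(traj_sets, study_sets, cap = 50) {
  stopifnot(length(traj_sets) > 0, length(study_sets) > 0)
  p <- or <- matrix(NA_real_, length(traj_sets), length(study_sets),
                    dimnames = list(names(traj_sets), names(study_sets)))
  for (i in seq_along(traj_sets)) for (j in seq_along(study_sets)) {
    fr <- fisher_enrichment(traj_sets[[i]], study_sets[[j]])
    p[i, j] <- fr$p
    or[i, j] <- fr$odds_ratio
  }
  nl <- pmin(-log10(pmax(p, 1e-300)), cap)
  ord <- function(m) {
    if (nrow(m) < 3) return(rownames(m))
    rownames(m)[stats::hclust(stats::dist(m), method = "average")$order]
  }
  list(p = p, odds_ratio = or, neglog10p = nl,
       row_order = ord(nl), col_order = ord(t(nl)))
}
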