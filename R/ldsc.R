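# Genome-wide SNP-heritability and cross-trait genetic correlation by
# regression of association statistics on LD scores, with block-jackknife
# standard errors.
#
# Regression weights are 1/max(l, 1) in a single step; the intercept is
# always estimated freely (absorbing confounding and sample overlap).

#' LD scores of a block-partitioned reference
#'
#' The LD score of a SNP is the sum of squared correlations with the SNPs
#' of its own block (cross-block LD is zero by construction), the
#' regressor of LD score regression.
#'
#' @param blocks An `ld_blocks` tibble.
#' @return Tibble `snp_id`, `block_id`, `ell`, in genome order.
#' @export
ld_scores <- function(blocks) {
  rows <- purrr::map(seq_len(nrow(blocks)), function(b) {
    tibble::tibble(
      snp_id = blocks$snps[[b]]$snp_id,
      block_id = blocks$block_id[b],
      ell = rowSums(blocks$R[[b]]^2)
    )
  })
  dplyr::bind_rows(rows)
}

# Per-jackknife-group weighted sufficient statistics for a y ~ x regression,
# plus vectorized delete-one slopes/intercepts.
jackknife_wls <- function(x, y, w, group) {
  mat <- cbind(w, w * x, w * y, w * x * x, w * x * y)
  gs <- rowsum(mat, group, reorder = FALSE)
  tot <- colSums(gs)
  full <- wls_from_sums(tot[1], tot[2], tot[3], tot[4], tot[5])
  del <- sweep(-gs, 2, tot, "+")  # totals minus each group
  loo <- wls_from_sums(del[, 1], del[, 2], del[, 3], del[, 4], del[, 5])
  list(full = full, loo = loo, n_groups = nrow(gs))
}

# Contiguous jackknife group assignment over n SNPs (genome order).
jackknife_groups <- function(n, n_blocks) {
  if (n < 2L * n_blocks) {
    n_blocks <- max(2L, n %/% 2L)
    warning(sprintf("too few SNPs; jackknife reduced to %d blocks", n_blocks))
  }
  sort(rep_len(seq_len(n_blocks), n))
}

#' SNP-heritability by LD score regression
#'
#' Regresses squared Z-scores on LD scores with a free intercept;
#' `h2 = slope * M / N` with `N` the median sample size.  Standard errors
#' come from a delete-one-block jackknife over contiguous SNP blocks.
#'
#' @param table A summary-statistics tibble (needs `snp_id`, `z`, `n`).
#' @param ldscores Tibble from [ld_scores()].
#' @param M Number of SNPs the heritability refers to; defaults to the
#'   number of regression SNPs.
#' @param n_jackknife Number of jackknife blocks.
#' @return An `h2_estimate` object: fields `h2`, `se`, `intercept`,
#'   `intercept_se`, `n`, `M`, `method = "ldsc"`, `n_jackknife`, and the
#'   leave-one-out estimates `h2_loo` used by downstream ratio statistics.
#' @export
ldsc_h2 <- function(table, ldscores, M = NULL, n_jackknife = 200) {
  check_columns(table, c("snp_id", "z", "n"), "sumstats table")
  d <- dplyr::inner_join(
    dplyr::select(table, "snp_id", "z", "n"),
    dplyr::select(ldscores, "snp_id", "ell"),
    by = "snp_id"
  )
  M <- M %||% nrow(d)
  n_med <- stats::median(d$n)
  group <- jackknife_groups(nrow(d), n_jackknife)
  jk <- jackknife_wls(d$ell, d$z^2, 1 / pmax(d$ell, 1), group)
  scale <- M / n_med
  h2_loo <- jk$loo$slope * scale
  out <- list(
    h2 = jk$full$slope * scale,
    se = jackknife_se(h2_loo),
    intercept = jk$full$intercept,
    intercept_se = jackknife_se(jk$loo$intercept),
    n = n_med, M = M, method = "ldsc",
    n_jackknife = jk$n_groups,
    h2_loo = h2_loo
  )
  class(out) <- "h2_estimate"
  out
}

#' Cross-trait genetic correlation by LD score regression
#'
#' Regresses the Z-score product of two traits on LD scores (free
#' intercept absorbs sample overlap); the genetic covariance is
#' `slope * M / sqrt(N1 N2)` and the genetic correlation is the covariance
#' over the geometric mean of the two LD-score-regression heritabilities,
#' all computed on the intersection of the two tables.  The standard error
#' jackknifes the full ratio statistic over contiguous SNP blocks shared by
#' the three regressions; p is the two-tailed Wald test of `rg / se`.
#'
#' A trait regressed against itself gives `rg = 1` exactly.  If either
#' heritability estimate is non-positive, `rg` is reported as `NA` with a
#' diagnostic.
#'
#' @param table1,table2 Summary-statistics tibbles for the two traits.
#' @param ldscores Tibble from [ld_scores()].
#' @param M Number of SNPs; defaults to the size of the intersection.
#' @param n_jackknife Number of jackknife blocks.
#' @return An `rg_estimate` object: `rg`, `se`, `p`, `gcov`, `gcov_se`,
#'   per-trait `h2_1`/`h2_2` (`h2_estimate` objects), `M`, `n_jackknife`.
#' @export
ldsc_rg <- function(table1, table2, ldscores, M = NULL, n_jackknife = 200) {
  d <- dplyr::inner_join(
    dplyr::select(table1, "snp_id", z1 = "z", n1 = "n"),
    dplyr::select(table2, "snp_id", z2 = "z", n2 = "n"),
    by = "snp_id"
  )
  d <- dplyr::inner_join(d, dplyr::select(ldscores, "snp_id", "ell"),
                         by = "snp_id")
  if (nrow(d) < 2L * 2L) stop("too few shared SNPs", call. = FALSE)
  M <- M %||% nrow(d)
  n1 <- stats::median(d$n1)
  n2 <- stats::median(d$n2)
  group <- jackknife_groups(nrow(d), n_jackknife)
  w <- 1 / pmax(d$ell, 1)

  jk1 <- jackknife_wls(d$ell, d$z1^2, w, group)
  jk2 <- jackknife_wls(d$ell, d$z2^2, w, group)
  jk12 <- jackknife_wls(d$ell, d$z1 * d$z2, w, group)

  h2_1 <- jk1$full$slope * M / n1
  h2_2 <- jk2$full$slope * M / n2
  gcov <- jk12$full$slope * M / sqrt(n1 * n2)
  gcov_loo <- jk12$loo$slope * M / sqrt(n1 * n2)

  rg_of <- function(g, h1, h2) {
    # a trait paired with itself gives three identical regressions; short-
    # circuit so the ratio is exactly one rather than x/sqrt(x*x)
    ifelse(g == h1 & g == h2 & g > 0, 1,
           ifelse(h1 > 0 & h2 > 0, g / sqrt(h1 * h2), NA_real_))
  }
  rg <- rg_of(gcov, h2_1, h2_2)
  rg_loo <- rg_of(gcov_loo, jk1$loo$slope * M / n1, jk2$loo$slope * M / n2)
  se <- jackknife_se(rg_loo)
  p <- if (is.na(rg) || is.na(se)) NA_real_ else two_tailed_p(rg / se)

  diagnostic <- NULL
  if (is.na(rg)) {
    diagnostic <- sprintf(
      "undefined rg: non-positive heritability estimate (h2_1 = %.4g, h2_2 = %.4g)",
      h2_1, h2_2
    )
  }

  mk_h2 <- function(jk, n, loo_scale) {
    out <- list(
      h2 = jk$full$slope * M / n, se = jackknife_se(jk$loo$slope * M / n),
      intercept = jk$full$intercept,
      intercept_se = jackknife_se(jk$loo$intercept),
      n = n, M = M, method = "ldsc", n_jackknife = jk$n_groups,
      h2_loo = jk$loo$slope * M / n
    )
    class(out) <- "h2_estimate"
    out
  }
  out <- list(
    rg = rg, se = se, p = p,
    gcov = gcov, gcov_se = jackknife_se(gcov_loo),
    h2_1 = mk_h2(jk1, n1), h2_2 = mk_h2(jk2, n2),
    M = M, n_jackknife = jk12$n_groups,
    method = "ldsc", diagnostic = diagnostic
  )
  class(out) <- "rg_estimate"
  out
}
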