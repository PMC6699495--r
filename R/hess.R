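# Local SNP-heritability and local genetic correlation per approximately
# independent LD block, via truncated quadratic forms of the block Z-score
# vectors.
#
# Eigen-truncation: retain the top-k eigenvalues reaching >= 99.5% of the
# cumulative LD variance, capped at min(n_snps, 50).  The cap controls the
# noise the quadratic form accumulates per retained eigen-direction.

truncated_eigen <- function(R, max_k = 50L, var_frac = 0.995) {
  e <- eigen(R, symmetric = TRUE)
  lam <- e$values
  pos <- lam > 1e-8
  cum <- cumsum(lam) / sum(lam)
  k <- which(cum >= var_frac)[1]
  if (is.na(k)) k <- sum(pos)
  k <- min(k, max_k, sum(pos), nrow(R))
  list(U = e$vectors[, seq_len(k), drop = FALSE], lam = lam[seq_len(k)],
       k = k)
}

# q = z' V_k^+ z via the truncated eigendecomposition
quad_form <- function(te, z1, z2 = z1) {
  a1 <- crossprod(te$U, z1)
  a2 <- if (identical(z1, z2)) a1 else crossprod(te$U, z2)
  sum(a1 * a2 / te$lam)
}

#' Local SNP-heritability of one LD block
#'
#' With `q = z' V^+ z` the quadratic form under the rank-k truncated
#' pseudo-inverse of the block LD matrix, the local heritability estimator
#' is `(q - k) / (n - k)`.  It is centered at zero under the null
#' (`E[q] = k`) and may be negative.
#'
#' @param z Z-score vector over the block's SNPs, in block order.
#' @param block One-row `ld_blocks` tibble.
#' @param n GWAS sample size.
#' @param max_k,var_frac Eigen-truncation rule (see module notes).
#' @return List with `h2`, `k`, `q`, `n_snps`.
#' @export
local_h2 <- function(z, block, n, max_k = 50L, var_frac = 0.995) {
  R <- block$R[[1]]
  if (nrow(R) < 1L) stop("block has no SNPs", call. = FALSE)
  stopifnot(length(z) == nrow(R))
  te <- truncated_eigen(R, max_k, var_frac)
  if (n <= te$k) stop("sample size must exceed retained rank k", call. = FALSE)
  q <- quad_form(te, z)
  list(h2 = (q - te$k) / (n - te$k), k = te$k, q = q, n_snps = nrow(R))
}

#' Local genetic covariance and correlation of one LD block
#'
#' The local genetic covariance is `rho = z1' V^+ z2 / sqrt(n1 n2)`; its
#' variance under the no-covariance null is
#' `(k + n1 h2_1^+ + n2 h2_2^+) / (n1 n2)` with `h2^+` the local
#' heritabilities truncated at zero, giving a two-tailed Wald p-value.  The
#' local genetic correlation `rho / sqrt(h2_1 h2_2)` is reported as `NA`
#' when either local heritability is non-positive.  Assumes the two
#' studies share no samples.
#'
#' @param z1,z2 Z-score vectors over the block's SNPs, in block order.
#' @param block One-row `ld_blocks` tibble.
#' @param n1,n2 GWAS sample sizes.
#' @param max_k,var_frac Eigen-truncation rule.
#' @return A one-row tibble (`local_estimate`): `block_id`, `n_snps`, `k`,
#'   `h2_1`, `h2_2`, `rho`, `rho_var`, `rg`, `p`.
#' @export
local_rho <- function(z1, z2, block, n1, n2, max_k = 50L, var_frac = 0.995) {
  R <- block$R[[1]]
  stopifnot(length(z1) == nrow(R), length(z2) == nrow(R))
  te <- truncated_eigen(R, max_k, var_frac)
  if (n1 <= te$k || n2 <= te$k) {
    stop("sample sizes must exceed retained rank k", call. = FALSE)
  }
  k <- te$k
  q1 <- quad_form(te, z1)
  q2 <- quad_form(te, z2)
  h2_1 <- (q1 - k) / (n1 - k)
  h2_2 <- (q2 - k) / (n2 - k)
  rho <- quad_form(te, z1, z2) / sqrt(n1 * n2)
  rho_var <- (k + n1 * max(h2_1, 0) + n2 * max(h2_2, 0)) / (n1 * n2)
  eps <- 1e-8
  rg <- if (h2_1 > 0 && h2_2 > 0) {
    rho / sqrt(max(h2_1, eps) * max(h2_2, eps))
  } else {
    NA_real_
  }
  tibble::tibble(
    block_id = block$block_id, n_snps = nrow(R), k = k,
    h2_1 = h2_1, h2_2 = h2_2, rho = rho, rho_var = rho_var,
    rg = rg, p = two_tailed_p(rho / sqrt(rho_var))
  )
}

#' Genome scan of local heritability and genetic correlation
#'
#' Applies the local estimators to every LD block covered by one or two
#' harmonized summary-statistics tables.  Blocks containing no analyzed
#' SNP are dropped and counted.  Genome totals are sums of the local
#' values; when an external anchor heritability is supplied (for example a
#' more stable genome-wide LD-score-regression estimate), the local
#' heritabilities are rescaled so their totals match the anchor exactly.
#' Per-block significance uses the Bonferroni threshold
#' `0.05 / n_analyzed_blocks`.
#'
#' @param table1 Harmonized summary-statistics tibble for trait 1.
#' @param table2 Optional tibble for trait 2; when `NULL` the scan is
#'   heritability-only.
#' @param blocks An `ld_blocks` tibble.
#' @param n1,n2 Sample sizes (default: median of each table's `n`).
#' @param anchor_h2 Optional external per-trait heritability anchor
#'   (length 1 without `table2`, else length 2); must be positive.
#' @param alpha Family-wise level for the per-block Bonferroni threshold.
#' @param max_k,var_frac Eigen-truncation rule.
#' @return A `local_scan` tibble, one row per analyzed block (columns of
#'   [local_rho()] plus `chrom`, `start`, `end`, `min_p1`, `min_p2`,
#'   `significant`), with attributes `totals` (summed `h2_1`, `h2_2`,
#'   `gcov` and the genome correlation `rg` they imply), `n_dropped`,
#'   `threshold`, `anchored`, `method`.
#' @export
local_scan <- function(table1, table2 = NULL, blocks,
                       n1 = NULL, n2 = NULL, anchor_h2 = NULL,
                       alpha = 0.05, max_k = 50L, var_frac = 0.995) {
  two <- !is.null(table2)
  n1 <- n1 %||% stats::median(table1$n)
  if (two) n2 <- n2 %||% stats::median(table2$n)
  if (!is.null(anchor_h2) && any(anchor_h2 <= 0)) {
    stop("anchor_h2 must be positive", call. = FALSE)
  }

  nb <- nrow(blocks)
  used <- logical(nb)
  n_snps_v <- integer(nb)
  k_v <- integer(nb)
  h1_v <- h2_v <- rho_v <- var_v <- rg_v <- p_v <- rep(NA_real_, nb)
  mp1_v <- mp2_v <- rep(NA_real_, nb)
  eps <- 1e-8
  # many synthetic blocks share a correlation matrix; memoize eigen work
  eig_cache <- list()
  cached_eigen <- function(R) {
    for (e in eig_cache) if (identical(e$R, R)) return(e$te)
    te <- truncated_eigen(R, max_k, var_frac)
    if (length(eig_cache) < 64L) {
      eig_cache[[length(eig_cache) + 1L]] <<- list(R = R, te = te)
    }
    te
  }
  n_dropped <- 0L
  for (b in seq_len(nb)) {
    ids <- blocks$snps[[b]]$snp_id
    pos1 <- match(ids, table1$snp_id)
    pos2 <- if (two) match(ids, table2$snp_id) else NULL
    keep <- !is.na(pos1)
    if (two) keep <- keep & !is.na(pos2)
    if (!any(keep)) {
      n_dropped <- n_dropped + 1L
      next
    }
    R <- blocks$R[[b]]
    if (!all(keep)) R <- R[keep, keep, drop = FALSE]
    te <- cached_eigen(R)
    k <- te$k
    if (n1 <= k || (two && n2 <= k)) {
      stop("sample sizes must exceed retained rank k", call. = FALSE)
    }
    z1 <- table1$z[pos1[keep]]
    q1 <- quad_form(te, z1)
    used[b] <- TRUE
    n_snps_v[b] <- nrow(R)
    k_v[b] <- k
    h1_v[b] <- (q1 - k) / (n1 - k)
    mp1_v[b] <- min(two_tailed_p(z1))
    if (two) {
      z2 <- table2$z[pos2[keep]]
      q2 <- quad_form(te, z2)
      h2_v[b] <- (q2 - k) / (n2 - k)
      rho_v[b] <- quad_form(te, z1, z2) / sqrt(n1 * n2)
      var_v[b] <- (k + n1 * max(h1_v[b], 0) + n2 * max(h2_v[b], 0)) /
        (n1 * n2)
      rg_v[b] <- if (h1_v[b] > 0 && h2_v[b] > 0) {
        rho_v[b] / sqrt(max(h1_v[b], eps) * max(h2_v[b], eps))
      } else {
        NA_real_
      }
      p_v[b] <- two_tailed_p(rho_v[b] / sqrt(var_v[b]))
      mp2_v[b] <- min(two_tailed_p(z2))
    }
  }
  if (!any(used)) stop("no block contains analyzed SNPs", call. = FALSE)
  out <- tibble::tibble(
    block_id = blocks$block_id[used], chrom = blocks$chrom[used],
    start = blocks$start[used], end = blocks$end[used],
    n_snps = n_snps_v[used], k = k_v[used],
    h2_1 = h1_v[used], h2_2 = h2_v[used],
    rho = rho_v[used], rho_var = var_v[used], rg = rg_v[used],
    p = p_v[used], min_p1 = mp1_v[used], min_p2 = mp2_v[used]
  )

  anchored <- !is.null(anchor_h2)
  if (anchored) {
    anchor_h2 <- rep_len(anchor_h2, if (two) 2L else 1L)
    tot1 <- sum(out$h2_1)
    if (tot1 == 0) stop("cannot anchor: total local h2 is zero", call. = FALSE)
    out$h2_1 <- out$h2_1 * (anchor_h2[1] / tot1)
    if (two) {
      tot2 <- sum(out$h2_2)
      if (tot2 == 0) stop("cannot anchor: total local h2 is zero", call. = FALSE)
      out$h2_2 <- out$h2_2 * (anchor_h2[2] / tot2)
      eps <- 1e-8
      out$rg <- ifelse(out$h2_1 > 0 & out$h2_2 > 0,
                       out$rho / sqrt(pmax(out$h2_1, eps) *
                                        pmax(out$h2_2, eps)),
                       NA_real_)
    }
  }

  threshold <- alpha / nrow(out)
  out$significant <- if (two) !is.na(out$p) & out$p <= threshold else NA
  tot <- c(
    h2_1 = sum(out$h2_1),
    h2_2 = if (two) sum(out$h2_2) else NA_real_,
    gcov = if (two) sum(out$rho) else NA_real_
  )
  tot["rg"] <- if (two && tot["h2_1"] > 0 && tot["h2_2"] > 0) {
    tot[["gcov"]] / sqrt(tot[["h2_1"]] * tot[["h2_2"]])
  } else {
    NA_real_
  }
  attr(out, "totals") <- tot
  attr(out, "n_dropped") <- n_dropped
  attr(out, "threshold") <- threshold
  attr(out, "anchored") <- anchored
  attr(out, "method") <- if (anchored) "hess-anchored" else "hess-sum"
  class(out) <- c("local_scan", class(out))
  out
}

#' Genome-wide heritability from a local scan
#'
#' Sums the per-block local heritabilities into a genome-wide estimate with
#' a delete-one-block jackknife standard error.
#'
#' @param scan A `local_scan` tibble.
#' @param trait Which trait, `1` or `2`.
#' @return An `h2_estimate` object with method `"hess-sum"` or
#'   `"hess-anchored"`.
#' @export
total_h2 <- function(scan, trait = 1L) {
  col <- paste0("h2_", match.arg(as.character(trait), c("1", "2")))
  x <- scan[[col]]
  g <- length(x)
  loo <- (sum(x) - x)  # delete-one-block totals
  out <- list(
    h2 = sum(x), se = jackknife_se(loo),
    intercept = NA_real_, intercept_se = NA_real_,
    n = NA_real_, M = sum(scan$n_snps),
    method = attr(scan, "method") %||% "hess-sum",
    n_jackknife = g, h2_loo = loo
  )
  class(out) <- "h2_estimate"
  out
}
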