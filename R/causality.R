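# Putative-causality contrast: partition LD blocks by trait-specific GWAS
# significance and compare summed local correlations across partitions.
# If trait 1 causally influences trait 2, regions that are
# GWAS-significant only for trait 1 should carry a strong genetic
# correlation with trait 2, while trait-2-specific regions should not.

#' Partition LD blocks by trait-specific GWAS significance
#'
#' Labels each block by whether it harbors a genome-wide significant SNP
#' (`p <= p_thresh`) for trait 1 only, trait 2 only, both, or neither.
#'
#' @param table1,table2 Harmonized summary-statistics tibbles.
#' @param blocks An `ld_blocks` tibble.
#' @param p_thresh Genome-wide significance threshold.
#' @return Tibble `block_id`, `min_p1`, `min_p2`, `label` with label in
#'   `trait1_specific`, `trait2_specific`, `both`, `neither`.
#' @export
partition_blocks <- function(table1, table2, blocks, p_thresh = 5e-8) {
  p1 <- if ("p" %in% names(table1)) table1$p else two_tailed_p(table1$z)
  p2 <- if ("p" %in% names(table2)) table2$p else two_tailed_p(table2$z)
  nb <- nrow(blocks)
  m1 <- m2 <- numeric(nb)
  for (b in seq_len(nb)) {
    ids <- blocks$snps[[b]]$snp_id
    m1[b] <- suppressWarnings(min(p1[match(ids, table1$snp_id)], na.rm = TRUE))
    m2[b] <- suppressWarnings(min(p2[match(ids, table2$snp_id)], na.rm = TRUE))
  }
  s1 <- is.finite(m1) & m1 <= p_thresh
  s2 <- is.finite(m2) & m2 <= p_thresh
  tibble::tibble(
    block_id = blocks$block_id, min_p1 = m1, min_p2 = m2,
    label = dplyr::case_when(
      s1 & s2 ~ "both",
      s1 ~ "trait1_specific",
      s2 ~ "trait2_specific",
      .default = "neither"
    )
  )
}

# Set-level correlation of a subset of local estimates:
# sum(rho) / sqrt(sum(h2_1+) * sum(h2_2+)), with delete-one-region
# jackknife.  Returns estimate NA when a truncated denominator is zero.
set_correlation <- function(locals) {
  est_of <- function(rho, h1, h2) {
    d <- sum(pmax(h1, 0)) * sum(pmax(h2, 0))
    if (length(rho) == 0L || d <= 0) return(NA_real_)
    sum(rho) / sqrt(d)
  }
  g <- nrow(locals)
  est <- est_of(locals$rho, locals$h2_1, locals$h2_2)
  if (g < 2L) {
    return(list(count = g, estimate = est, se = NA_real_))
  }
  loo <- vapply(seq_len(g), function(i) {
    est_of(locals$rho[-i], locals$h2_1[-i], locals$h2_2[-i])
  }, numeric(1))
  list(count = g, estimate = est, se = jackknife_se(loo))
}

#' Putative-causality contrast from partitioned local estimates
#'
#' For each partition the local genetic covariances are summed into a
#' set-level correlation with a delete-one-region jackknife standard error
#' and a `estimate +/- 1.96 se` confidence interval.  The verdict is
#' `consistent_T1_causes_T2` when both trait-specific partitions contain
#' more than `min_regions` regions, the trait-1-specific interval excludes
#' zero, the trait-2-specific interval includes zero, and the two
#' intervals do not overlap (mirrored for the opposite direction);
#' `not_tested` when either trait-specific count is `<= min_regions`;
#' otherwise `inconclusive`.
#'
#' @param locals A `local_scan` tibble covering the partitioned blocks.
#' @param partition Tibble from [partition_blocks()].
#' @param min_regions Minimum trait-specific region count; the test is
#'   only attempted with strictly more than this many regions per trait.
#' @return A `causality_contrast` object: `partitions` tibble (`label`,
#'   `count`, `estimate`, `se`, `ci_lo`, `ci_hi`) and `verdict`.
#' @export
causality_contrast <- function(locals, partition, min_regions = 10L) {
  labels <- c("trait1_specific", "trait2_specific", "both", "neither")
  sets <- purrr::map(labels, function(lab) {
    ids <- partition$block_id[partition$label == lab]
    s <- set_correlation(locals[locals$block_id %in% ids, , drop = FALSE])
    tibble::tibble(
      label = lab, count = s$count, estimate = s$estimate, se = s$se,
      ci_lo = s$estimate - 1.96 * s$se, ci_hi = s$estimate + 1.96 * s$se
    )
  })
  parts <- dplyr::bind_rows(sets)

  t1 <- parts[parts$label == "trait1_specific", ]
  t2 <- parts[parts$label == "trait2_specific", ]
  ci_ok <- function(x) !is.na(x$ci_lo) && !is.na(x$ci_hi)
  excludes0 <- function(x) ci_ok(x) && (x$ci_lo > 0 || x$ci_hi < 0)
  includes0 <- function(x) ci_ok(x) && x$ci_lo <= 0 && x$ci_hi >= 0
  disjoint <- function(x, y) {
    ci_ok(x) && ci_ok(y) && (x$ci_hi < y$ci_lo || y$ci_hi < x$ci_lo)
  }

  verdict <- if (t1$count <= min_regions || t2$count <= min_regions) {
    "not_tested"
  } else if (excludes0(t1) && includes0(t2) && disjoint(t1, t2)) {
    "consistent_T1_causes_T2"
  } else if (excludes0(t2) && includes0(t1) && disjoint(t1, t2)) {
    "consistent_T2_causes_T1"
  } else {
    "inconclusive"
  }

  out <- list(partitions = parts, verdict = verdict,
              min_regions = min_regions)
  class(out) <- "causality_contrast"
  out
}

#' @export
print.causality_contrast <- function(x, ...) {
  cat("Putative-causality contrast\n")
  print(x$partitions)
  cat("verdict:", x$verdict, "\n")
  invisible(x)
}

#' Write a causality contrast as TSV
#'
#' One row per partition plus a trailing verdict line (as a comment).
#'
#' @param contrast A `causality_contrast` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_contrast_tsv <- function(contrast, path) {
  readr::write_tsv(contrast$partitions, path)
  cat(sprintf("# verdict\t%s\n", contrast$verdict),
      file = path, append = TRUE)
  invisible(path)
}
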