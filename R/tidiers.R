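# broom-style tidy()/glance() methods and print methods for the fitted
# objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a heritability estimate
#'
#' @param x An `h2_estimate` object.
#' @param ... Unused.
#' @return One-row tibble: `term`, `estimate`, `std.error`, plus the
#'   intercept row when estimated.
#' @export
tidy.h2_estimate <- function(x, ...) {
  out <- tibble::tibble(
    term = c("h2", "intercept"),
    estimate = c(x$h2, x$intercept),
    std.error = c(x$se, x$intercept_se)
  )
  out[!is.na(out$estimate), ]
}

#' @rdname tidy.h2_estimate
#' @export
glance.h2_estimate <- function(x, ...) {
  tibble::tibble(
    h2 = x$h2, se = x$se, intercept = x$intercept, method = x$method,
    n = x$n, M = x$M, n_jackknife = x$n_jackknife
  )
}

#' @export
print.h2_estimate <- function(x, ...) {
  cat(sprintf("SNP-heritability estimate (%s)\n", x$method))
  cat(sprintf("  h2 = %.4f (SE %.4f)\n", x$h2, x$se))
  if (!is.na(x$intercept)) {
    cat(sprintf("  intercept = %.4f (SE %.4f)\n", x$intercept,
                x$intercept_se))
  }
  cat(sprintf("  M = %d SNPs, %d jackknife blocks\n", x$M, x$n_jackknife))
  invisible(x)
}

#' Tidy a genetic-correlation estimate
#'
#' @param x An `rg_estimate` object.
#' @param ... Unused.
#' @return One-row tibble: `rg`, `se`, `p`, `gcov`, per-trait
#'   heritabilities and their standard errors.
#' @export
tidy.rg_estimate <- function(x, ...) {
  tibble::tibble(
    rg = x$rg, se = x$se, p = x$p, gcov = x$gcov,
    h2_1 = x$h2_1$h2, h2_1_se = x$h2_1$se,
    h2_2 = x$h2_2$h2, h2_2_se = x$h2_2$se
  )
}

#' @rdname tidy.rg_estimate
#' @export
glance.rg_estimate <- function(x, ...) {
  tibble::tibble(rg = x$rg, se = x$se, p = x$p, M = x$M,
                 n_jackknife = x$n_jackknife, method = x$method)
}

#' @export
print.rg_estimate <- function(x, ...) {
  cat("Cross-trait genetic correlation (LD score regression)\n")
  if (is.na(x$rg)) {
    cat("  rg undefined:", x$diagnostic %||% "", "\n")
  } else {
    cat(sprintf("  rg = %.4f (SE %.4f), p = %.3g\n", x$rg, x$se, x$p))
  }
  cat(sprintf("  h2_1 = %.4f (SE %.4f); h2_2 = %.4f (SE %.4f); M = %d\n",
              x$h2_1$h2, x$h2_1$se, x$h2_2$h2, x$h2_2$se, x$M))
  invisible(x)
}

#' Tidy a causality contrast
#'
#' @param x A `causality_contrast` object.
#' @param ... Unused.
#' @return The per-partition tibble with a `verdict` column appended.
#' @export
tidy.causality_contrast <- function(x, ...) {
  dplyr::mutate(x$partitions, verdict = x$verdict)
}

#' Glance at a local scan
#'
#' @param x A `local_scan` tibble.
#' @param ... Unused.
#' @return One-row tibble of genome totals, significant-block count and
#'   the per-block Bonferroni threshold.
#' @export
glance.local_scan <- function(x, ...) {
  tot <- attr(x, "totals")
  tibble::tibble(
    h2_1_total = tot[["h2_1"]], h2_2_total = tot[["h2_2"]],
    gcov_total = tot[["gcov"]], rg_total = tot[["rg"]],
    n_blocks = nrow(x),
    n_significant = sum(x$significant, na.rm = TRUE),
    threshold = attr(x, "threshold"),
    method = attr(x, "method")
  )
}
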