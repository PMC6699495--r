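# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Two-tailed normal p-value
#'
#' Converts a Z-score to its two-tailed standard-normal p-value.
#'
#' @param z Numeric vector of Z-scores.
#' @return Numeric vector of p-values in (0, 1].
#' @export
two_tailed_p <- function(z) {
  2 * stats::pnorm(-abs(z))
}

# Derive a child seed from a root seed; stays below 2^31 so it is a valid
# R integer seed.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + 104729 * as.numeric(offset)) %% 2147483647)
}

# Delete-one jackknife standard error from the vector of leave-one-out
# estimates.
jackknife_se <- function(theta) {
  theta <- theta[is.finite(theta)]
  g <- length(theta)
  if (g < 2L) return(NA_real_)
  sqrt((g - 1) / g * sum((theta - mean(theta))^2))
}

# Weighted least squares slope/intercept from sufficient statistics.
# Sums must be weighted: sw = sum(w), swx = sum(w*x), ...
wls_from_sums <- function(sw, swx, swy, swxx, swxy) {
  denom <- sw * swxx - swx^2
  slope <- (sw * swxy - swx * swy) / denom
  intercept <- (swy - slope * swx) / sw
  list(slope = unname(slope), intercept = unname(intercept))
}

# Assert a tibble has the named columns; used by the data-frame-first API
# to fail early with a readable message.
check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stop(sprintf(
      "%s is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ), call. = FALSE)
  }
  invisible(df)
}
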