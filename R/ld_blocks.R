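# Reference LD blocks: the primitive every summary-statistics method here
# consumes.  A genome is a tibble of approximately independent blocks; each
# block carries an ordered SNP manifest and a correlation matrix.

#' Simulate reference LD blocks
#'
#' Generates a synthetic genome organised as approximately independent LD
#' blocks.  Each block holds an ordered set of SNPs and a positive
#' semi-definite correlation matrix; correlation between SNPs in different
#' blocks is zero by construction, mirroring how downstream estimators treat
#' an external block-partitioned LD reference.
#'
#' Two LD models are available: `"ar1"` gives the closed-form
#' autoregressive structure `R[i, j] = rho^|i - j|` (testable analytically),
#' and `"random_psd"` draws a random positive-definite matrix via random
#' orthogonal mixing of positive eigenvalues (a stress-test structure).
#'
#' @param n_blocks Number of blocks to generate.
#' @param block_size Number of SNPs per block; scalar or vector recycled to
#'   `n_blocks`.
#' @param model LD model, `"ar1"` or `"random_psd"`.
#' @param rho AR(1) adjacent-SNP correlation, in `[0, 0.99]`; scalar or
#'   vector recycled across blocks (heterogeneous LD across blocks is what
#'   gives LD scores their spread, as in real genomes). Ignored by
#'   `"random_psd"`.
#' @param chrom Chromosome label(s) for the blocks, recycled to `n_blocks`.
#' @param spacing_bp Base-pair spacing between adjacent SNPs in a block.
#' @param gap_bp Base-pair gap between consecutive blocks on a chromosome.
#' @param seed Integer seed; all randomness in the generator flows from it.
#' @return A tibble of class `ld_blocks` with one row per block and columns
#'   `block_id`, `chrom`, `start`, `end`, list-column `snps` (per-SNP
#'   tibbles with `snp_id`, `bp`, `a1`, `a2`), list-column `R` (correlation
#'   matrix) and `R_chol` (its upper Cholesky factor, cached for fast
#'   simulation).
#' @examples
#' blocks <- simulate_ld_blocks(n_blocks = 3, block_size = 4, seed = 1)
#' blocks$R[[1]][1, 2]  # 0.5 under the AR(1) default
#' @export
simulate_ld_blocks <- function(n_blocks = 100,
                               block_size = 100,
                               model = c("ar1", "random_psd"),
                               rho = 0.5,
                               chrom = "1",
                               spacing_bp = 1000,
                               gap_bp = 10000,
                               seed) {
  model <- match.arg(model)
  if (n_blocks < 1L) stop("n_blocks must be >= 1", call. = FALSE)
  sizes <- rep_len(as.integer(block_size), n_blocks)
  if (any(sizes < 1L)) stop("block sizes must be >= 1", call. = FALSE)
  if (!is.numeric(rho) || any(rho < 0) || any(rho > 0.99)) {
    stop("LD parameter rho must be in [0, 0.99]", call. = FALSE)
  }
  rhos <- rep_len(rho, n_blocks)
  if (missing(seed)) stop("seed is required", call. = FALSE)
  withr::local_seed(seed)

  chroms <- rep_len(as.character(chrom), n_blocks)
  snp_counter <- 0L
  pos_on_chrom <- stats::setNames(rep(0, length(unique(chroms))), unique(chroms))

  rows <- vector("list", n_blocks)
  for (b in seq_len(n_blocks)) {
    m <- sizes[b]
    ch <- chroms[b]
    start <- pos_on_chrom[[ch]] + gap_bp + 1
    bp <- start + (seq_len(m) - 1L) * spacing_bp
    pos_on_chrom[[ch]] <- bp[m]
    ids <- sprintf("rs%d", snp_counter + seq_len(m))
    snp_counter <- snp_counter + m

    R <- switch(model,
      ar1 = rhos[b]^abs(outer(seq_len(m), seq_len(m), "-")),
      random_psd = random_psd_corr(m)
    )
    R <- (R + t(R)) / 2
    diag(R) <- 1
    U <- safe_chol(R)

    rows[[b]] <- tibble::tibble(
      block_id = sprintf("block_%d", b),
      chrom = ch,
      start = bp[1],
      end = bp[m],
      snps = list(tibble::tibble(
        snp_id = ids, bp = bp, a1 = "A", a2 = "G"
      )),
      R = list(R),
      R_chol = list(U)
    )
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("ld_blocks", class(out))
  out
}

# Random correlation matrix via random orthogonal mixing: Q diag(lambda) Q'
# with positive eigenvalues, rescaled to unit diagonal.
random_psd_corr <- function(m) {
  if (m == 1L) return(matrix(1, 1, 1))
  Q <- qr.Q(qr(matrix(stats::rnorm(m * m), m, m)))
  lambda <- stats::rexp(m) + 0.05
  S <- Q %*% (lambda * t(Q))
  stats::cov2cor(S)
}

# Upper Cholesky factor with an eigenvalue fallback for semi-definite input.
safe_chol <- function(R) {
  out <- tryCatch(chol(R), error = function(e) NULL)
  if (is.null(out)) {
    e <- eigen(R, symmetric = TRUE)
    lam <- pmax(e$values, 0)
    out <- t(e$vectors %*% (sqrt(lam) * t(e$vectors)))
    # not triangular, but crossprod(out, x) still has covariance R
  }
  out
}

#' SNP manifest of an LD block set
#'
#' Flattens an `ld_blocks` tibble into one row per SNP, in genome order.
#' This table is the allele reference used for harmonization and the
#' SNP-to-block map used by clumping and local analyses.
#'
#' @param blocks An `ld_blocks` tibble.
#' @return Tibble with columns `snp_id`, `block_id`, `chrom`, `bp`,
#'   `a1`, `a2`.
#' @export
ld_snps <- function(blocks) {
  check_columns(blocks, c("block_id", "chrom", "snps"), "blocks")
  blocks |>
    dplyr::select("block_id", "chrom", "snps") |>
    tidyr::unnest("snps") |>
    dplyr::select("snp_id", "block_id", "chrom", "bp", "a1", "a2")
}

#' Validate LD block invariants
#'
#' Checks symmetry, unit diagonal, positive semi-definiteness (smallest
#' eigenvalue >= -1e-8), dimension consistency with the SNP manifest, and
#' non-overlap/ordering of blocks within a chromosome.
#'
#' @param blocks An `ld_blocks` tibble.
#' @return `TRUE` invisibly; stops with a message on the first violation.
#' @export
validate_ld_blocks <- function(blocks) {
  for (b in seq_len(nrow(blocks))) {
    R <- blocks$R[[b]]
    m <- nrow(blocks$snps[[b]])
    if (!all(dim(R) == c(m, m))) stop("R dimension does not match snp count")
    if (max(abs(R - t(R))) > 1e-10) stop("R is not symmetric")
    if (max(abs(diag(R) - 1)) > 1e-10) stop("R diagonal is not 1")
    if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
      stop("R is not positive semi-definite")
    }
  }
  by_chrom <- split(blocks, blocks$chrom)
  for (bc in by_chrom) {
    if (nrow(bc) > 1L) {
      bc <- bc[order(bc$start), ]
      if (any(bc$start[-1] <= bc$end[-nrow(bc)])) {
        stop("blocks overlap within a chromosome")
      }
    }
  }
  invisible(TRUE)
}

#' Write an LD block set to flat files
#'
#' Emits a tab-separated manifest (`BLOCK_ID`, `CHR`, `START`, `END`,
#' `SNPLIST_PATH`, `MATRIX_PATH`; coordinates 1-based inclusive) plus one
#' SNP-list TSV and one dense plain-text matrix file per block.
#'
#' @param blocks An `ld_blocks` tibble.
#' @param dir Output directory (created if absent).
#' @return The manifest path, invisibly.
#' @export
write_ld_blocks <- function(blocks, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  manifest <- blocks |>
    dplyr::mutate(
      SNPLIST_PATH = sprintf("%s.snps.tsv", .data$block_id),
      MATRIX_PATH = sprintf("%s.ld.txt", .data$block_id)
    ) |>
    dplyr::select(
      BLOCK_ID = "block_id", CHR = "chrom", START = "start", END = "end",
      "SNPLIST_PATH", "MATRIX_PATH"
    )
  readr::write_tsv(manifest, file.path(dir, "manifest.tsv"))
  for (b in seq_len(nrow(blocks))) {
    readr::write_tsv(
      dplyr::rename(blocks$snps[[b]], SNP = "snp_id", BP = "bp",
                    A1 = "a1", A2 = "a2"),
      file.path(dir, sprintf("%s.snps.tsv", blocks$block_id[b]))
    )
    utils::write.table(
      blocks$R[[b]], file.path(dir, sprintf("%s.ld.txt", blocks$block_id[b])),
      row.names = FALSE, col.names = FALSE
    )
  }
  invisible(file.path(dir, "manifest.tsv"))
}

#' Read an LD block set written by [write_ld_blocks()]
#'
#' @param manifest_path Path to the manifest TSV.
#' @return An `ld_blocks` tibble.
#' @export
read_ld_blocks <- function(manifest_path) {
  dir <- dirname(manifest_path)
  manifest <- readr::read_tsv(manifest_path, show_col_types = FALSE)
  rows <- purrr::pmap(manifest, function(BLOCK_ID, CHR, START, END,
                                         SNPLIST_PATH, MATRIX_PATH) {
    snps <- readr::read_tsv(file.path(dir, SNPLIST_PATH),
                            show_col_types = FALSE) |>
      dplyr::rename(snp_id = "SNP", bp = "BP", a1 = "A1", a2 = "A2")
    R <- as.matrix(utils::read.table(file.path(dir, MATRIX_PATH)))
    dimnames(R) <- NULL
    U <- safe_chol(R)
    tibble::tibble(
      block_id = as.character(BLOCK_ID), chrom = as.character(CHR),
      start = START, end = END,
      snps = list(snps), R = list(R), R_chol = list(U)
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("ld_blocks", class(out))
  out
}
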