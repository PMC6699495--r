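# Two-trait genetic architectures and GWAS summary statistics simulated on
# top of an LD block set.  Genotypes are standardized implicitly: every
# downstream statistic consumes only Z, N and the block correlation
# matrices, so allele frequencies are never modelled.

#' Simulate per-SNP causal effects for two traits
#'
#' Draws standardized-scale causal effect pairs with a requested
#' SNP-heritability per trait and cross-trait genetic covariance
#' `rg * sqrt(h2[1] * h2[2]) / M_shared` per shared causal SNP, so the
#' genome-wide genetic correlation equals `rg` in expectation.
#'
#' Under the `"polygenic"` architecture every SNP is causal for both
#' traits.  Under `"oligogenic"` the trait-1 causal SNPs are confined to
#' `n_causal_blocks` blocks (trait 2 stays polygenic), emulating a trait
#' whose association signal concentrates in a couple of dozen loci.
#'
#' @param blocks An `ld_blocks` tibble.
#' @param h2 Length-2 vector of per-trait SNP-heritabilities in `[0, 1]`.
#' @param rg Target genetic correlation in `[-1, 1]`.
#' @param architecture `"polygenic"` or `"oligogenic"` (trait 1 only).
#' @param n_causal_blocks Number of causal blocks for an oligogenic
#'   trait 1; the default 24 mirrors the region count of a strongly
#'   oligogenic fibrotic-disease GWAS.
#' @param causal_blocks Optional explicit character vector of block ids to
#'   use as the trait-1 causal set (overrides random sampling).
#' @param exact_scaling If `TRUE` (default), each trait's effect vector is
#'   rescaled so that the sum of squared effects equals `h2` exactly.
#' @param seed Integer seed.
#' @return A `sim_truth` tibble with columns `snp_id`, `block_id`,
#'   `beta1`, `beta2` and attributes `h2`, `rg`, `architecture`,
#'   `causal_blocks`, `seed`.
#' @export
simulate_effects <- function(blocks,
                             h2 = c(0.5, 0.5),
                             rg = 0,
                             architecture = c("polygenic", "oligogenic"),
                             n_causal_blocks = 24,
                             causal_blocks = NULL,
                             exact_scaling = TRUE,
                             seed) {
  architecture <- match.arg(architecture)
  h2 <- rep_len(h2, 2L)
  if (any(h2 < 0 | h2 > 1)) stop("h2 must be in [0, 1]", call. = FALSE)
  if (abs(rg) > 1) stop("|rg| must be <= 1", call. = FALSE)
  if (missing(seed)) stop("seed is required", call. = FALSE)
  withr::local_seed(seed)

  snps <- ld_snps(blocks)
  M <- nrow(snps)

  if (architecture == "oligogenic") {
    if (is.null(causal_blocks)) {
      causal_blocks <- sample(blocks$block_id,
                              min(n_causal_blocks, nrow(blocks)))
    }
    in1 <- snps$block_id %in% causal_blocks
  } else {
    causal_blocks <- blocks$block_id
    in1 <- rep(TRUE, M)
  }
  M1 <- sum(in1)
  M2 <- M
  M_shared <- M1  # trait-1 causal set is a subset of the trait-2 set

  sigma1 <- if (h2[1] > 0) sqrt(h2[1] / M1) else 0
  sigma2 <- if (h2[2] > 0) sqrt(h2[2] / M2) else 0

  if (sigma1 > 0 && sigma2 > 0) {
    # per shared SNP: cov = rg * sqrt(h2_1 h2_2) / M_shared
    rho_snp <- rg * sqrt(h2[1] * h2[2]) / M_shared / (sigma1 * sigma2)
    if (abs(rho_snp) > 1 + 1e-12) {
      stop(sprintf(
        paste0("requested rg = %.3g is not attainable: the implied per-SNP ",
               "effect correlation %.3g exceeds 1 under this architecture"),
        rg, rho_snp
      ), call. = FALSE)
    }
    rho_snp <- max(-1, min(1, rho_snp))
  } else {
    rho_snp <- 0
  }

  x <- stats::rnorm(M)
  y <- stats::rnorm(M)
  beta1 <- ifelse(in1, sigma1 * x, 0)
  beta2 <- sigma2 * ifelse(in1,
                           rho_snp * x + sqrt(1 - rho_snp^2) * y,
                           y)

  if (exact_scaling) {
    if (h2[1] > 0 && sum(beta1^2) > 0) {
      beta1 <- beta1 * sqrt(h2[1] / sum(beta1^2))
    }
    if (h2[2] > 0 && sum(beta2^2) > 0) {
      beta2 <- beta2 * sqrt(h2[2] / sum(beta2^2))
    }
  }

  out <- tibble::tibble(
    snp_id = snps$snp_id, block_id = snps$block_id,
    beta1 = beta1, beta2 = beta2
  )
  attr(out, "h2") <- h2
  attr(out, "rg") <- rg
  attr(out, "architecture") <- architecture
  attr(out, "causal_blocks") <- causal_blocks
  attr(out, "seed") <- seed
  class(out) <- c("sim_truth", class(out))
  out
}

#' Assemble a truth table from explicit effect vectors
#'
#' Low-level constructor for composite architectures (for instance a trait
#' whose effects are a causal transmission `c * beta1` plus independent
#' effects of its own).  Vectors must be in the SNP order of
#' `ld_snps(blocks)`.
#'
#' @param blocks An `ld_blocks` tibble.
#' @param beta1,beta2 Numeric effect vectors, one entry per SNP.
#' @return A `sim_truth` tibble.
#' @export
as_sim_truth <- function(blocks, beta1, beta2) {
  snps <- ld_snps(blocks)
  stopifnot(length(beta1) == nrow(snps), length(beta2) == nrow(snps))
  out <- tibble::tibble(
    snp_id = snps$snp_id, block_id = snps$block_id,
    beta1 = as.numeric(beta1), beta2 = as.numeric(beta2)
  )
  attr(out, "h2") <- c(sum(beta1^2), sum(beta2^2))
  class(out) <- c("sim_truth", class(out))
  out
}

#' Per-block generative truth
#'
#' Realized local genetic variance and covariance of a truth table:
#' `h2 = beta' V beta` and `gcov = beta1' V beta2` within each block, the
#' quantities the local estimators target.
#'
#' @param truth A `sim_truth` tibble.
#' @param blocks The `ld_blocks` tibble it was simulated on.
#' @return Tibble with `block_id`, `h2_1`, `h2_2`, `gcov` and attribute
#'   `totals` (genome-wide sums).
#' @export
truth_local <- function(truth, blocks) {
  rows <- purrr::map(seq_len(nrow(blocks)), function(b) {
    ids <- blocks$snps[[b]]$snp_id
    i <- match(ids, truth$snp_id)
    if (anyNA(i)) stop("truth/blocks SNP mismatch", call. = FALSE)
    R <- blocks$R[[b]]
    b1 <- truth$beta1[i]
    b2 <- truth$beta2[i]
    Rb1 <- as.vector(R %*% b1)
    tibble::tibble(
      block_id = blocks$block_id[b],
      h2_1 = sum(b1 * Rb1),
      h2_2 = sum(b2 * as.vector(R %*% b2)),
      gcov = sum(b2 * Rb1)
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "totals") <- c(
    h2_1 = sum(out$h2_1), h2_2 = sum(out$h2_2), gcov = sum(out$gcov)
  )
  out
}

#' Simulate GWAS summary statistics
#'
#' Draws per-SNP Z-scores from the standard summary-statistics generative
#' model, block by block: `z = sqrt(n) V beta + e`, `e ~ MVN(0, V)` with
#' `V` the block LD matrix.  Residual variance is fixed at `V` (the
#' small-per-block-heritability regime, where `1 - h2_local` is
#' indistinguishable from 1).
#'
#' @param truth A `sim_truth` tibble over the same blocks.
#' @param blocks An `ld_blocks` tibble.
#' @param n GWAS sample size (scalar).
#' @param trait Which trait's effect vector to use, `1` or `2`.
#' @param seed Integer seed.
#' @return A summary-statistics tibble with columns `snp_id`, `chrom`,
#'   `bp`, `a1`, `a2`, `z`, `n`, `p`.
#' @export
simulate_sumstats <- function(truth, blocks, n, trait = 1L, seed) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (missing(seed)) stop("seed is required", call. = FALSE)
  trait <- match.arg(as.character(trait), c("1", "2"))
  beta_col <- paste0("beta", trait)
  withr::local_seed(seed)

  z_parts <- vector("list", nrow(blocks))
  for (b in seq_len(nrow(blocks))) {
    snps <- blocks$snps[[b]]
    i <- match(snps$snp_id, truth$snp_id)
    if (anyNA(i)) stop("truth/blocks SNP mismatch", call. = FALSE)
    beta <- truth[[beta_col]][i]
    R <- blocks$R[[b]]
    U <- blocks$R_chol[[b]] %||% safe_chol(R)
    mu <- sqrt(n) * as.vector(R %*% beta)
    z_parts[[b]] <- mu + as.vector(crossprod(U, stats::rnorm(nrow(R))))
  }
  manifest <- ld_snps(blocks)
  out <- tibble::tibble(
    snp_id = manifest$snp_id, chrom = manifest$chrom, bp = manifest$bp,
    a1 = manifest$a1, a2 = manifest$a2,
    z = unlist(z_parts), n = as.numeric(n)
  )
  out$p <- two_tailed_p(out$z)
  out
}

#' Inject QC decoy records into a summary-statistics table
#'
#' Adds or mutates records so the table contains known quality-control
#' violations: strand-ambiguous allele pairs (A/T, C/G), multi-allelic
#' duplicates (same rsID, different allele pair), and identifiers that are
#' not rsIDs.  Used to exercise [qc_sumstats()].
#'
#' @param table A summary-statistics tibble.
#' @param n_ambiguous,n_multiallelic,n_norsid Number of decoys of each kind.
#' @param seed Integer seed.
#' @return The table with decoys applied (multi-allelic decoys append rows).
#' @export
add_qc_decoys <- function(table, n_ambiguous = 0, n_multiallelic = 0,
                          n_norsid = 0, seed) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  withr::local_seed(seed)
  n_mod <- n_ambiguous + n_norsid
  if (n_mod + n_multiallelic > nrow(table)) {
    stop("more decoys requested than rows available", call. = FALSE)
  }
  idx <- sample(nrow(table), n_mod + n_multiallelic)
  take <- function(k) {
    out <- idx[seq_len(k)]
    idx <<- idx[-seq_len(k)]
    out
  }
  if (n_ambiguous > 0) {
    i <- take(n_ambiguous)
    pair <- sample(c("AT", "CG"), n_ambiguous, replace = TRUE)
    table$a1[i] <- substr(pair, 1, 1)
    table$a2[i] <- substr(pair, 2, 2)
  }
  if (n_norsid > 0) {
    i <- take(n_norsid)
    table$snp_id[i] <- sprintf("%s:%d", table$chrom[i], table$bp[i])
  }
  if (n_multiallelic > 0) {
    i <- take(n_multiallelic)
    dup <- table[i, ]
    dup$a2 <- ifelse(dup$a2 == "C", "G", "C")  # different, non-ambiguous pair
    table <- dplyr::bind_rows(table, dup)
  }
  table
}
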