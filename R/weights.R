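# Sparse cis-eQTL expression weight models: per gene x tissue-panel weight
# vectors over the SNPs of one LD block, with a recorded cis-heritability.

#' Simulate expression weight models
#'
#' Generates sparse cis-eQTL weight models, each confined to a single LD
#' block.  A model has a transcription start/end site inside its block, a
#' subset of nonzero SNP weights, and a cis-heritability drawn uniformly
#' from `cis_h2_range` (defaults span the 0.01-0.68 range typical of
#' significant expression models across reference tissue panels).
#'
#' @param blocks An `ld_blocks` tibble.
#' @param n_genes Number of gene models.
#' @param n_panels Number of tissue panel labels to cycle through.
#' @param sparsity Expected fraction of cis SNPs with zero weight, in
#'   `[0, 1)`; at least one weight is always nonzero.
#' @param cis_h2_range Length-2 range for the cis-heritability, in `[0, 1]`.
#' @param cis_window_bp Half-width of the cis window around the TSS that
#'   model SNPs must fall in.
#' @param seed Integer seed.
#' @return A `weight_models` tibble with one row per model: `gene_id`,
#'   `panel_id`, `chrom`, `tss`, `tes`, `cis_h2`, `block_id` and
#'   list-column `weights` (tibbles with `snp_id`, `a1`, `a2`, `weight`).
#' @export
simulate_weight_models <- function(blocks,
                                   n_genes = 50,
                                   n_panels = 5,
                                   sparsity = 0.5,
                                   cis_h2_range = c(0.01, 0.68),
                                   cis_window_bp = 5e5,
                                   seed) {
  if (any(cis_h2_range < 0 | cis_h2_range > 1)) {
    stop("cis_h2_range must lie within [0, 1]", call. = FALSE)
  }
  if (sparsity < 0 || sparsity >= 1) {
    stop("sparsity must be in [0, 1)", call. = FALSE)
  }
  if (missing(seed)) stop("seed is required", call. = FALSE)
  withr::local_seed(seed)

  panels <- sprintf("panel_%d", seq_len(n_panels))
  rows <- vector("list", n_genes)
  for (g in seq_len(n_genes)) {
    b <- sample(nrow(blocks), 1L)
    snps <- blocks$snps[[b]]
    tss <- sample(snps$bp, 1L)
    tes <- tss + sample(5000:50000, 1L)
    cis <- snps[abs(snps$bp - tss) <= cis_window_bp, ]

    w <- draw_sparse_weights(nrow(cis), sparsity)
    rows[[g]] <- tibble::tibble(
      gene_id = sprintf("gene_%d", g),
      panel_id = panels[(g - 1L) %% n_panels + 1L],
      chrom = blocks$chrom[b],
      tss = tss, tes = tes,
      cis_h2 = stats::runif(1, cis_h2_range[1], cis_h2_range[2]),
      block_id = blocks$block_id[b],
      weights = list(tibble::tibble(
        snp_id = cis$snp_id, a1 = cis$a1, a2 = cis$a2, weight = w
      ))
    )
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("weight_models", class(out))
  out
}

# Sparse weight vector with at least one nonzero entry; bounded retries
# before giving up (an all-zero model is invalid).
draw_sparse_weights <- function(m, sparsity, max_tries = 50L) {
  for (i in seq_len(max_tries)) {
    keep <- stats::runif(m) >= sparsity
    if (any(keep)) {
      w <- numeric(m)
      w[keep] <- stats::rnorm(sum(keep))
      if (any(w != 0)) return(w)
    }
  }
  stop("failed to draw a weight vector with a nonzero entry", call. = FALSE)
}

#' Write a weight model to a flat file
#'
#' Format: `#` header lines `GENE`, `PANEL`, `CHR`, `TSS`, `TES`, `CIS_H2`,
#' then tab-separated rows `SNP A1 A2 WEIGHT`.
#'
#' @param model One row of a `weight_models` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_weight_model <- function(model, path) {
  stopifnot(nrow(model) == 1L)
  hdr <- sprintf(
    "#%s\t%s",
    c("GENE", "PANEL", "CHR", "TSS", "TES", "CIS_H2"),
    c(model$gene_id, model$panel_id, model$chrom,
      model$tss, model$tes, format(model$cis_h2, digits = 15))
  )
  writeLines(hdr, path)
  w <- dplyr::rename(model$weights[[1]], SNP = "snp_id", A1 = "a1",
                     A2 = "a2", WEIGHT = "weight")
  readr::write_tsv(w, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read a weight model written by [write_weight_model()]
#'
#' @param path Path to the weight file.
#' @param blocks Optional `ld_blocks` tibble used to recover the model's
#'   block id from its SNPs.
#' @return A one-row `weight_models` tibble.
#' @export
read_weight_model <- function(path, blocks = NULL) {
  lines <- readLines(path)
  hdr_lines <- lines[startsWith(lines, "#")]
  hdr <- do.call(rbind, strsplit(sub("^#", "", hdr_lines), "\t"))
  meta <- stats::setNames(hdr[, 2], hdr[, 1])
  w <- readr::read_tsv(I(lines[!startsWith(lines, "#")]),
                       show_col_types = FALSE) |>
    dplyr::rename(snp_id = "SNP", a1 = "A1", a2 = "A2", weight = "WEIGHT")
  block_id <- NA_character_
  if (!is.null(blocks)) {
    manifest <- ld_snps(blocks)
    block_id <- manifest$block_id[match(w$snp_id[1], manifest$snp_id)]
  }
  out <- tibble::tibble(
    gene_id = meta[["GENE"]], panel_id = meta[["PANEL"]],
    chrom = meta[["CHR"]],
    tss = as.numeric(meta[["TSS"]]), tes = as.numeric(meta[["TES"]]),
    cis_h2 = as.numeric(meta[["CIS_H2"]]),
    block_id = block_id, weights = list(w)
  )
  class(out) <- c("weight_models", class(out))
  out
}
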