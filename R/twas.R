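# Transcriptome-wide association: weight-vector x GWAS-Z statistics under
# reference LD, permutation robustness, conditional GWAS traces, novelty
# classification against known risk regions, and the per-tissue chi-square
# summary.

# Align a weight model's SNPs with a block and a harmonized table; returns
# w, z, V restricted to the model's SNPs.
align_model <- function(model, table, block) {
  w_tbl <- model$weights[[1]]
  ids <- w_tbl$snp_id
  bpos <- match(ids, block$snps[[1]]$snp_id)
  if (anyNA(bpos)) {
    stop(sprintf("model %s has SNPs absent from its LD block", model$gene_id),
         call. = FALSE)
  }
  tpos <- match(ids, table$snp_id)
  if (anyNA(tpos)) {
    stop(sprintf("model %s has SNPs absent from the summary statistics",
                 model$gene_id), call. = FALSE)
  }
  list(
    w = w_tbl$weight,
    z = table$z[tpos],
    V = block$R[[1]][bpos, bpos, drop = FALSE]
  )
}

twas_z <- function(w, z, V, gene_id = "model") {
  wVw <- as.numeric(t(w) %*% V %*% w)
  if (wVw < 1e-8) {
    stop(sprintf("degenerate weight model for gene %s: w'Vw = %.3g < 1e-8",
                 gene_id, wVw), call. = FALSE)
  }
  sum(w * z) / sqrt(wVw)
}

#' Association between predicted expression and a trait
#'
#' Computes the expression-trait association statistic
#' `z = w'z_gwas / sqrt(w'Vw)` for one weight model, where `w` is the
#' cis-eQTL weight vector, `z_gwas` the GWAS Z-scores at the model's SNPs
#' and `V` the reference LD among them, with a two-tailed standard-normal
#' p-value.  The statistic is invariant to positive rescaling of the
#' weights and flips sign when the weights are negated.
#'
#' @param model One row of a `weight_models` tibble.
#' @param table A harmonized summary-statistics tibble.
#' @param block The one-row `ld_blocks` tibble containing the model's SNPs.
#' @param cis_window_bp Half-width of the cis window (around the TSS) in
#'   which the strongest local GWAS SNP is reported.
#' @return A one-row tibble: `gene_id`, `panel_id`, `chrom`, `tss`, `tes`,
#'   `cis_h2`, `n_snps`, `z_twas`, `p_twas`, `best_gwas_snp`,
#'   `best_gwas_z`, `best_gwas_p`.
#' @export
twas_association <- function(model, table, block, cis_window_bp = 5e5) {
  a <- align_model(model, table, block)
  z_twas <- twas_z(a$w, a$z, a$V, model$gene_id)

  cis <- table[table$chrom == model$chrom &
                 abs(table$bp - model$tss) <= cis_window_bp, ]
  if (!"p" %in% names(cis)) cis$p <- two_tailed_p(cis$z)
  if (nrow(cis) > 0L) {
    best <- cis[which.min(cis$p), ]
    best_snp <- best$snp_id
    best_z <- best$z
    best_p <- best$p
  } else {
    best_snp <- NA_character_
    best_z <- NA_real_
    best_p <- NA_real_
  }

  tibble::tibble(
    gene_id = model$gene_id, panel_id = model$panel_id,
    chrom = model$chrom, tss = model$tss, tes = model$tes,
    cis_h2 = model$cis_h2, n_snps = length(a$w),
    z_twas = z_twas, p_twas = two_tailed_p(z_twas),
    best_gwas_snp = best_snp, best_gwas_z = best_z, best_gwas_p = best_p
  )
}

#' Transcriptome-wide association scan
#'
#' Runs [twas_association()] for every model and flags significance at the
#' Bonferroni-corrected threshold `alpha / m`, where `m` is the number of
#' tissue-specific models tested.  Models that fail (degenerate weights,
#' missing SNPs) are skipped and logged.
#'
#' @param models A `weight_models` tibble.
#' @param table A harmonized summary-statistics tibble.
#' @param blocks An `ld_blocks` tibble.
#' @param alpha Family-wise significance level.
#' @param cis_window_bp Passed to [twas_association()].
#' @return A `twas_scan` tibble with one row per tested model, a
#'   `significant` column (`p_twas <= alpha/m`), and attributes `m`,
#'   `threshold`, `skipped` (named character vector of error messages).
#' @export
twas_scan <- function(models, table, blocks, alpha = 0.05,
                      cis_window_bp = 5e5) {
  skipped <- character(0)
  rows <- vector("list", nrow(models))
  for (i in seq_len(nrow(models))) {
    model <- models[i, ]
    bi <- match(model$block_id, blocks$block_id)
    rows[[i]] <- tryCatch(
      twas_association(model, table, blocks[bi, ], cis_window_bp),
      error = function(e) {
        skipped[[paste(model$gene_id, model$panel_id, sep = ":")]] <<-
          conditionMessage(e)
        NULL
      }
    )
  }
  out <- dplyr::bind_rows(rows)
  m <- nrow(out)
  if (m < 1L) stop("no weight model could be tested", call. = FALSE)
  threshold <- bonferroni_threshold(alpha, m)
  out$significant <- out$p_twas <= threshold
  attr(out, "m") <- m
  attr(out, "threshold") <- threshold
  attr(out, "skipped") <- skipped
  class(out) <- c("twas_scan", class(out))
  out
}

#' Permutation test for a TWAS association
#'
#' Shuffles the weight values across the model's SNP positions `B` times,
#' keeping the GWAS statistics and LD fixed, and recomputes the statistic.
#' The add-one estimator `(1 + #{|z_perm| >= |z_obs|}) / (B + 1)` keeps the
#' p-value in `(0, 1]`; a single-SNP model is invariant under permutation
#' and returns 1.
#'
#' @param model One row of a `weight_models` tibble.
#' @param table A harmonized summary-statistics tibble.
#' @param block The model's LD block (one-row `ld_blocks` tibble).
#' @param B Number of permutations.
#' @param seed Integer seed.
#' @return The permutation p-value, in `[1/(B+1), 1]`.
#' @export
twas_permutation <- function(model, table, block, B = 1000, seed) {
  stopifnot(B >= 1)
  if (missing(seed)) stop("seed is required", call. = FALSE)
  withr::local_seed(seed)
  a <- align_model(model, table, block)
  z_obs <- twas_z(a$w, a$z, a$V, model$gene_id)
  hits <- 0L
  for (b in seq_len(B)) {
    w_perm <- sample(a$w)
    z_perm <- tryCatch(twas_z(w_perm, a$z, a$V), error = function(e) NA_real_)
    if (!is.na(z_perm) && abs(z_perm) >= abs(z_obs)) hits <- hits + 1L
  }
  (1 + hits) / (B + 1)
}

#' GWAS statistics conditioned on an expression model
#'
#' Residualizes each SNP's GWAS Z-score on the model's predicted-expression
#' association: with `r_j = (Vw)_j / sqrt(w'Vw)` the correlation between
#' SNP j and the predicted expression, the conditioned score is
#' `(z_j - r_j z_twas) / sqrt(1 - r_j^2)`; SNPs collinear with the model
#' (`r_j^2 >= 1 - 1e-10`) are set to 0.
#'
#' @param model One row of a `weight_models` tibble.
#' @param table A harmonized summary-statistics tibble.
#' @param block The model's LD block (one-row `ld_blocks` tibble).
#' @return Tibble over the block's SNPs: `snp_id`, `bp`, `z`, `r`,
#'   `z_cond`.
#' @export
conditional_gwas <- function(model, table, block) {
  w_tbl <- model$weights[[1]]
  snps <- block$snps[[1]]
  R <- block$R[[1]]
  w_full <- numeric(nrow(snps))
  wpos <- match(w_tbl$snp_id, snps$snp_id)
  if (anyNA(wpos)) stop("model SNPs absent from block", call. = FALSE)
  w_full[wpos] <- w_tbl$weight

  wVw <- as.numeric(t(w_full) %*% R %*% w_full)
  if (wVw < 1e-8) {
    stop(sprintf("degenerate weight model for gene %s", model$gene_id),
         call. = FALSE)
  }
  r <- as.vector(R %*% w_full) / sqrt(wVw)

  tpos <- match(snps$snp_id, table$snp_id)
  z <- table$z[tpos]
  z_twas <- sum(w_full * z) / sqrt(wVw)

  z_cond <- ifelse(r^2 >= 1 - 1e-10, 0,
                   (z - r * z_twas) / sqrt(pmax(1 - r^2, 1e-300)))
  tibble::tibble(snp_id = snps$snp_id, bp = snps$bp, z = z, r = r,
                 z_cond = z_cond)
}

#' Classify TWAS associations as novel
#'
#' A TWAS association marks a novel risk region at window `W` when (1) the
#' strongest GWAS SNP in the gene's cis region is not genome-wide
#' significant (minimum local p `>= gwas_thresh`) and (2) the gene's TSS
#' lies at least `W` base pairs from every known risk region.
#'
#' @param assoc A `twas_scan` tibble (or any tibble with `gene_id`,
#'   `panel_id`, `chrom`, `tss`).
#' @param known_regions Tibble of known risk regions (`chrom`, `start`,
#'   `end`, 1-based inclusive), e.g. from [read_bed()] or [clump_regions()].
#' @param table A harmonized summary-statistics tibble.
#' @param windows_bp Distance windows to evaluate.
#' @param gwas_thresh Genome-wide significance threshold.
#' @param cis_window_bp Half-width of the gene's cis region around its TSS.
#' @return A long tibble: `gene_id`, `panel_id`, `window_bp`,
#'   `best_local_p`, `dist_to_known`, `novel`.
#' @export
classify_novelty <- function(assoc, known_regions, table,
                             windows_bp = c(5e5, 1e6, 2e6),
                             gwas_thresh = 5e-8, cis_window_bp = 5e5) {
  rows <- purrr::map(seq_len(nrow(assoc)), function(i) {
    g <- assoc[i, ]
    local_p <- min_p_in_interval(table, g$chrom,
                                 g$tss - cis_window_bp, g$tss + cis_window_bp)
    same <- known_regions[known_regions$chrom == g$chrom, , drop = FALSE]
    dist <- if (nrow(same) == 0L) Inf else {
      min(pmax(0, pmax(same$start - g$tss, g$tss - same$end)))
    }
    tibble::tibble(
      gene_id = g$gene_id, panel_id = g$panel_id,
      window_bp = windows_bp,
      best_local_p = local_p, dist_to_known = dist,
      novel = local_p >= gwas_thresh & dist >= windows_bp
    )
  })
  dplyr::bind_rows(rows)
}

#' Per-tissue mean chi-square of significant TWAS models
#'
#' Averages the squared association statistic over the significant models
#' within each tissue panel, a crude ranking of which panel carries the
#' most association signal.
#'
#' @param assoc A `twas_scan` tibble with a `significant` column.
#' @return Tibble `panel_id`, `n_models`, `mean_chi2`, sorted descending;
#'   empty when nothing is significant.
#' @export
tissue_chi2_summary <- function(assoc) {
  assoc |>
    dplyr::filter(.data$significant) |>
    dplyr::group_by(.data$panel_id) |>
    dplyr::summarise(n_models = dplyr::n(),
                     mean_chi2 = mean(.data$z_twas^2), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$mean_chi2))
}
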