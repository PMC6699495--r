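# Orchestration: multiple-testing helpers, estimator comparison, and the
# end-to-end simulate -> QC -> clump -> TWAS -> rg -> local-rg -> causality
# pipeline with flat-file outputs.

#' Bonferroni-corrected per-test threshold
#'
#' @param alpha Family-wise significance level, in (0, 1).
#' @param m Number of tests, `>= 1`.
#' @return `alpha / m`.
#' @examples
#' signif(bonferroni_threshold(0.05, 98147), 3)  # 5.09e-07
#' @export
bonferroni_threshold <- function(alpha, m) {
  if (length(m) != 1L || is.na(m) || m < 1) {
    stop("m must be a single value >= 1", call. = FALSE)
  }
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  alpha / m
}

#' Benjamini-Hochberg selection mask
#'
#' Step-up false-discovery-rate control at level `q`.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @param q FDR level.
#' @return Logical mask of selected hypotheses.
#' @export
bh_fdr <- function(pvals, q = 0.1) {
  stopifnot(all(pvals >= 0 & pvals <= 1, na.rm = TRUE))
  stats::p.adjust(pvals, method = "BH") <= q
}

#' Pearson agreement between two estimator's results
#'
#' Standard Pearson correlation between paired genetic-correlation
#' estimates from two methods (for example LD score regression versus the
#' local-sum estimator across trait pairs).
#'
#' @param x,y Paired numeric vectors, at least 3 pairs.
#' @return Pearson's r, or `NA` when either vector has zero variance.
#' @export
compare_rg_methods <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Default pipeline configuration
#'
#' Builds the nested configuration list for [run_pipeline()].  The
#' defaults describe a desk-scale two-trait study: an oligogenic trait 1
#' whose signal is confined to 24 LD blocks, a polygenic trait 2, a
#' genome-wide genetic correlation of -0.2 between them, and Bonferroni
#' families matching the per-stage test counts.
#'
#' @param seed Root seed; every stage derives its own stream from it.
#' @param ... Named overrides merged over the defaults (one level deep:
#'   pass whole sub-lists, e.g. `traits = list(...)`).
#' @return A nested configuration list.
#' @export
pipeline_config <- function(seed, ...) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  config <- list(
    seed = as.integer(seed),
    blocks = list(n_blocks = 200L, block_size = 50L, model = "ar1",
                  rho = 0.5),
    traits = list(h2 = c(0.5, 0.25), rg = -0.2,
                  architecture = "oligogenic", n_causal_blocks = 24L,
                  n = c(50000, 50000)),
    weights = list(n_genes = 60L, n_panels = 5L, sparsity = 0.5,
                   cis_h2_range = c(0.01, 0.68)),
    decoys = list(n_ambiguous = 20L, n_multiallelic = 10L, n_norsid = 10L),
    thresholds = list(gwas = 5e-8, twas_alpha = 0.05, rg_alpha = 0.05,
                      fdr_q = 0.1)
  )
  overrides <- list(...)
  for (nm in names(overrides)) {
    if (is.list(config[[nm]]) && is.list(overrides[[nm]])) {
      config[[nm]][names(overrides[[nm]])] <- overrides[[nm]]
    } else {
      config[[nm]] <- overrides[[nm]]
    }
  }
  config
}

#' Read / write a pipeline configuration
#'
#' Configurations are stored as structured YAML text.
#'
#' @param path File path.
#' @return For `read_pipeline_config`, the configuration list.
#' @export
read_pipeline_config <- function(path) {
  yaml::read_yaml(path)
}

#' @rdname read_pipeline_config
#' @param config A configuration list.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Run the full summary-statistics pipeline
#'
#' Executes simulate -> QC -> harmonize -> clump -> TWAS -> genome-wide rg
#' -> local scan -> causality contrast on a simulated two-trait study and
#' writes every stage's result as TSV into `out_dir`, together with a
#' config echo and a run report of per-stage counts.  Identical
#' config and seed give byte-identical outputs.
#'
#' @param config Configuration list from [pipeline_config()] (or a YAML
#'   path).
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, a list with every stage's in-memory result and the
#'   `report` tibble of per-stage counts.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (is.null(config$seed)) stop("config$seed is required", call. = FALSE)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  seed <- config$seed
  log_lines <- character(0)
  log_stage <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
  }

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  # simulate
  blocks <- stage("simulate", simulate_ld_blocks(
    n_blocks = config$blocks$n_blocks, block_size = config$blocks$block_size,
    model = config$blocks$model, rho = config$blocks$rho,
    seed = derive_seed(seed, 1)
  ))
  truth <- stage("simulate", simulate_effects(
    blocks, h2 = config$traits$h2, rg = config$traits$rg,
    architecture = config$traits$architecture,
    n_causal_blocks = config$traits$n_causal_blocks,
    seed = derive_seed(seed, 2)
  ))
  raw1 <- stage("simulate", simulate_sumstats(
    truth, blocks, n = config$traits$n[1], trait = 1,
    seed = derive_seed(seed, 3)
  ))
  raw2 <- stage("simulate", simulate_sumstats(
    truth, blocks, n = config$traits$n[2], trait = 2,
    seed = derive_seed(seed, 4)
  ))
  raw1 <- stage("simulate", add_qc_decoys(
    raw1, n_ambiguous = config$decoys$n_ambiguous,
    n_multiallelic = config$decoys$n_multiallelic,
    n_norsid = config$decoys$n_norsid, seed = derive_seed(seed, 5)
  ))
  models <- stage("simulate", simulate_weight_models(
    blocks, n_genes = config$weights$n_genes,
    n_panels = config$weights$n_panels,
    sparsity = config$weights$sparsity,
    cis_h2_range = config$weights$cis_h2_range,
    seed = derive_seed(seed, 6)
  ))
  log_stage("simulate: %d blocks, %d SNPs, %d weight models",
            nrow(blocks), nrow(ld_snps(blocks)), nrow(models))

  # qc + harmonize
  qc1 <- stage("qc", qc_sumstats(raw1))
  qc2 <- stage("qc", qc_sumstats(raw2))
  t1 <- stage("qc", harmonize_alleles(qc1, blocks))
  t2 <- stage("qc", harmonize_alleles(qc2, blocks))
  log_stage("qc: trait1 %d -> %d SNPs, trait2 %d -> %d SNPs",
            nrow(raw1), nrow(t1), nrow(raw2), nrow(t2))

  # clump
  regions <- stage("clump", clump_regions(
    t1, blocks, p_thresh = config$thresholds$gwas
  ))
  log_stage("clump: %d independent risk regions", nrow(regions))

  # twas (+ novelty against the clumped regions)
  twas <- stage("twas", twas_scan(models, t1, blocks,
                                  alpha = config$thresholds$twas_alpha))
  novelty <- if (any(twas$significant)) {
    stage("twas", classify_novelty(
      twas[twas$significant, , drop = FALSE], regions, t1,
      gwas_thresh = config$thresholds$gwas
    ))
  } else {
    tibble::tibble(gene_id = character(), panel_id = character(),
                   window_bp = numeric(), best_local_p = numeric(),
                   dist_to_known = numeric(), novel = logical())
  }
  chi2 <- stage("twas", if (any(twas$significant)) {
    tissue_chi2_summary(twas)
  } else {
    tibble::tibble(panel_id = character(), n_models = integer(),
                   mean_chi2 = numeric())
  })
  log_stage("twas: %d models tested, %d significant at %.3g",
            attr(twas, "m"), sum(twas$significant), attr(twas, "threshold"))

  # genome-wide rg
  scores <- stage("rg", ld_scores(blocks))
  rg <- stage("rg", ldsc_rg(t1, t2, scores))
  log_stage("rg: ldsc rg = %.4f (se %.4f, p %.3g)", rg$rg, rg$se, rg$p)

  # local scan (anchored on the LDSC heritabilities when positive)
  anchor <- c(rg$h2_1$h2, rg$h2_2$h2)
  anchor <- if (all(anchor > 0)) anchor else NULL
  scan <- stage("local-rg", local_scan(t1, t2, blocks,
                                       n1 = config$traits$n[1],
                                       n2 = config$traits$n[2],
                                       anchor_h2 = anchor))
  log_stage("local-rg: %d blocks analyzed, %d significant at %.3g",
            nrow(scan), sum(scan$significant, na.rm = TRUE),
            attr(scan, "threshold"))

  # causality
  partition <- stage("causality", partition_blocks(
    t1, t2, blocks, p_thresh = config$thresholds$gwas
  ))
  contrast <- stage("causality", causality_contrast(scan, partition))
  log_stage("causality: verdict %s", contrast$verdict)

  # comparison of the two genome-wide estimators for this pair
  hess_rg <- attr(scan, "totals")[["rg"]]
  log_stage("compare: ldsc rg %.4f vs local-sum rg %.4f", rg$rg, hess_rg)

  report <- tibble::tibble(
    stage = c("snps_simulated", "snps_qc_trait1", "snps_qc_trait2",
              "risk_regions", "twas_models", "twas_significant",
              "rg_significant", "local_blocks", "local_significant",
              "causality_verdict"),
    value = c(nrow(raw1), nrow(t1), nrow(t2),
              nrow(regions), attr(twas, "m"), sum(twas$significant),
              as.integer(!is.na(rg$p) &&
                           rg$p <= config$thresholds$rg_alpha),
              nrow(scan), sum(scan$significant, na.rm = TRUE),
              contrast$verdict)
  )

  # flat-file bundle
  write_pipeline_config(config, file.path(out_dir, "config.yaml"))
  write_sumstats(t1, file.path(out_dir, "sumstats_trait1.tsv"))
  write_sumstats(t2, file.path(out_dir, "sumstats_trait2.tsv"))
  readr::write_tsv(qc_report(qc1), file.path(out_dir, "qc_report_trait1.tsv"))
  readr::write_tsv(
    dplyr::select(regions, Chr = "chrom", Start = "start", End = "end",
                  IndexSNP = "index_snp", nSNPs = "n_snps", MinP = "min_p"),
    file.path(out_dir, "regions.tsv")
  )
  readr::write_tsv(
    dplyr::select(twas, Gene = "gene_id", Chr = "chrom", TSS = "tss",
                  TES = "tes", BestGWASSNP = "best_gwas_snp",
                  ZGWAS = "best_gwas_z", Panel = "panel_id",
                  CisH2 = "cis_h2", ZTWAS = "z_twas", PTWAS = "p_twas",
                  Significant = "significant"),
    file.path(out_dir, "twas.tsv")
  )
  readr::write_tsv(novelty, file.path(out_dir, "twas_novelty.tsv"))
  readr::write_tsv(chi2, file.path(out_dir, "twas_tissue_chi2.tsv"))
  readr::write_tsv(generics::tidy(rg), file.path(out_dir, "rg.tsv"))
  readr::write_tsv(
    scan |>
      dplyr::mutate(se = sqrt(.data$rho_var)) |>
      dplyr::select(Chr = "chrom", Start = "start", End = "end",
                    nSNPs = "n_snps", MinP1 = "min_p1", MinP2 = "min_p2",
                    H2_1 = "h2_1", H2_2 = "h2_2", Rho = "rho", Rg = "rg",
                    SE = "se", Pregion = "p", Significant = "significant"),
    file.path(out_dir, "local.tsv")
  )
  write_contrast_tsv(contrast, file.path(out_dir, "causality.tsv"))
  readr::write_tsv(report, file.path(out_dir, "report.tsv"))
  writeLines(log_lines, file.path(out_dir, "run.log"))

  invisible(list(
    blocks = blocks, truth = truth, sumstats = list(t1, t2),
    regions = regions, twas = twas, novelty = novelty, chi2 = chi2,
    rg = rg, scan = scan, partition = partition, contrast = contrast,
    report = report
  ))
}
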