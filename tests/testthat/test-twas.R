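# Expression-trait association statistic, permutation test, conditional
# GWAS, novelty classification, tissue chi-square summary.

test_that("single-SNP and identity-LD associations match hand values", {
  blocks <- make_blocks(list(diag(1), diag(2)))
  tab <- make_table(blocks, z = c(2.5, 3, 4))

  m1 <- make_model(blocks, 1, "rs1", 1)
  a1 <- twas_association(m1, tab, blocks[1, ])
  expect_equal(a1$z_twas, 2.5)

  m2 <- make_model(blocks, 2, c("rs2", "rs3"), c(1, 1))
  a2 <- twas_association(m2, tab, blocks[2, ])
  expect_equal(a2$z_twas, 7 / sqrt(2))
  expect_equal(a2$p_twas, two_tailed_p(7 / sqrt(2)))
})

test_that("the statistic is scale-invariant and sign-equivariant in weights", {
  set.seed(101)
  blocks <- simulate_ld_blocks(n_blocks = 1, block_size = 8,
                               model = "random_psd", seed = 51)
  tab <- make_table(blocks, z = rnorm(8, sd = 2))
  ids <- blocks$snps[[1]]$snp_id[2:6]
  w <- rnorm(5)
  base <- twas_association(make_model(blocks, 1, ids, w), tab, blocks[1, ])
  for (c in c(0.01, 3, 1e4)) {
    scaled <- twas_association(make_model(blocks, 1, ids, c * w),
                               tab, blocks[1, ])
    expect_equal(scaled$z_twas, base$z_twas, tolerance = 1e-10)
  }
  neg <- twas_association(make_model(blocks, 1, ids, -w), tab, blocks[1, ])
  expect_equal(neg$z_twas, -base$z_twas, tolerance = 1e-10)
})

test_that("association equals the direct formula on random instances", {
  set.seed(102)
  for (i in 1:100) {
    m <- sample(1:10, 1)
    blocks <- simulate_ld_blocks(n_blocks = 1, block_size = m,
                                 model = "random_psd", seed = 3000 + i)
    z <- rnorm(m, sd = 2)
    tab <- make_table(blocks, z = z)
    w <- rnorm(m)
    got <- twas_association(make_model(blocks, 1, blocks$snps[[1]]$snp_id, w),
                            tab, blocks[1, ])
    expect_equal(got$z_twas, oracle_twas_z(w, z, blocks$R[[1]]),
                 tolerance = 1e-10)
  }
})

test_that("degenerate weight models error with the gene named", {
  blocks <- make_blocks(list(diag(2)))
  tab <- make_table(blocks, z = c(1, 2))
  m <- make_model(blocks, 1, c("rs1", "rs2"), c(1e-9, 0), gene_id = "geneZ")
  expect_error(twas_association(m, tab, blocks[1, ]), "geneZ")
})

test_that("scan flags significance at alpha/m with a <= boundary", {
  blocks <- make_blocks(list(diag(1), diag(1), diag(1)))
  tab <- make_table(blocks, z = c(3, 2.9, 1))
  models <- dplyr::bind_rows(
    make_model(blocks, 1, "rs1", 1, gene_id = "g1"),
    make_model(blocks, 2, "rs2", 1, gene_id = "g2"),
    make_model(blocks, 3, "rs3", 1, gene_id = "g3")
  )
  # alpha chosen so the per-test threshold lands exactly on g1's p-value:
  # the <= boundary convention must flag it
  p1 <- two_tailed_p(3)
  scan <- twas_scan(models[1, ], tab, blocks, alpha = p1)
  expect_equal(attr(scan, "m"), 1L)
  expect_true(scan$significant)

  scan3 <- twas_scan(models, tab, blocks, alpha = 0.05)
  expect_equal(attr(scan3, "m"), 3L)
  expect_equal(attr(scan3, "threshold"), 0.05 / 3)
  expect_equal(scan3$significant, tab$z^2 >= qnorm(0.05 / 6)^2)
})

test_that("models with missing SNPs are skipped and logged", {
  blocks <- make_blocks(list(diag(2)))
  tab <- make_table(blocks, z = c(3, 1))
  tab <- tab[1, ]  # rs2 missing from the table
  models <- dplyr::bind_rows(
    make_model(blocks, 1, "rs1", 1, gene_id = "ok"),
    make_model(blocks, 1, "rs2", 1, gene_id = "broken")
  )
  scan <- twas_scan(models, tab, blocks)
  expect_equal(attr(scan, "m"), 1L)
  expect_match(names(attr(scan, "skipped")), "broken")
})

test_that("a gene aligned with causal effects is detected across seeds", {
  blocks <- simulate_ld_blocks(n_blocks = 30, block_size = 25,
                               rho = rho_grid(), seed = 61)
  truth <- simulate_effects(blocks, h2 = c(0.05, 0), rg = 0,
                            architecture = "oligogenic",
                            causal_blocks = blocks$block_id[1],
                            seed = 62)
  idx <- truth$block_id == blocks$block_id[1]
  aligned <- make_model(blocks, 1, truth$snp_id[idx], truth$beta1[idx],
                        gene_id = "causal_gene")
  null_model <- make_model(blocks, 5, blocks$snps[[5]]$snp_id,
                           rnorm(25), gene_id = "null_gene")
  models <- dplyr::bind_rows(aligned, null_model)
  hits <- vapply(1:20, function(r) {
    ss <- simulate_sumstats(truth, blocks, n = 50000, trait = 1,
                            seed = 700 + r)
    scan <- twas_scan(models, ss, blocks)
    scan$significant[scan$gene_id == "causal_gene"]
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("null associations have standard-normal spread", {
  # 5,000 null loci via five simulated genomes of 1,000 single-gene blocks
  blocks <- simulate_ld_blocks(n_blocks = 1000, block_size = 5,
                               rho = rho_grid(), seed = 63)
  truth <- simulate_effects(blocks, h2 = c(0, 0), rg = 0, seed = 64)
  set.seed(65)
  models <- dplyr::bind_rows(lapply(seq_len(1000), function(b) {
    make_model(blocks, b, blocks$snps[[b]]$snp_id, rnorm(5),
               gene_id = sprintf("g%d", b))
  }))
  zs <- unlist(lapply(1:5, function(r) {
    ss <- simulate_sumstats(truth, blocks, n = 1000, trait = 1,
                            seed = 800 + r)
    twas_scan(models, ss, blocks)$z_twas
  }))
  expect_length(zs, 5000)
  expect_lt(abs(mean(zs)), 0.05)
  expect_gt(var(zs), 0.9)
  expect_lt(var(zs), 1.1)
})

test_that("permutation p-values respect their degenerate cases and bounds", {
  blocks <- make_blocks(list(diag(1), diag(2)))
  tab <- make_table(blocks, z = c(4, 1, -1))

  single <- make_model(blocks, 1, "rs1", 1)
  expect_equal(twas_permutation(single, tab, blocks[1, ], B = 50, seed = 1), 1)

  # w'z = 0 by construction: observed statistic 0, everything beats it
  balanced <- make_model(blocks, 2, c("rs2", "rs3"), c(1, 1))
  expect_equal(twas_permutation(balanced, tab, blocks[2, ], B = 50, seed = 2),
               1)

  set.seed(3)
  blocksr <- simulate_ld_blocks(n_blocks = 1, block_size = 6,
                                model = "random_psd", seed = 4)
  tabr <- make_table(blocksr, z = rnorm(6))
  m <- make_model(blocksr, 1, blocksr$snps[[1]]$snp_id, rnorm(6))
  p <- twas_permutation(m, tabr, blocksr[1, ], B = 99, seed = 5)
  expect_gte(p, 1 / 100)
  expect_lte(p, 1)
})

test_that("conditioning removes the model signal and obeys the formula", {
  blocks <- make_blocks(list(diag(3)))
  tab <- make_table(blocks, z = c(4, 2, 1))
  m <- make_model(blocks, 1, "rs1", 1)
  cond <- conditional_gwas(m, tab, blocks[1, ])
  expect_equal(cond$z_cond[1], 0)          # self-conditioning
  expect_equal(cond$z_cond[2:3], c(2, 1))  # r = 0 SNPs unchanged

  # r_j = 0.5, z_j = 4, z_twas = 4 -> (4 - 2)/sqrt(0.75)
  R <- diag(2); R[1, 2] <- R[2, 1] <- 0.5
  blocks2 <- make_blocks(list(R))
  tab2 <- make_table(blocks2, z = c(4, 4))
  m2 <- make_model(blocks2, 1, "rs1", 1)
  cond2 <- conditional_gwas(m2, tab2, blocks2[1, ])
  expect_equal(cond2$z_cond[2], (4 - 0.5 * 4) / sqrt(1 - 0.25))
})

test_that("conditioning residualizes signal-dominated loci at the
           top-correlated SNP", {
  # when the GWAS signal is driven by the expression model (z proportional
  # to V w plus small noise), conditioning must shrink the most correlated
  # SNP toward zero
  set.seed(110)
  for (i in 1:20) {
    blocks <- simulate_ld_blocks(n_blocks = 1, block_size = 8,
                                 model = "random_psd", seed = 5000 + i)
    w <- rnorm(8)
    z <- 6 * as.vector(blocks$R[[1]] %*% w) /
      sqrt(sum(w * (blocks$R[[1]] %*% w))) + rnorm(8, sd = 0.1)
    tab <- make_table(blocks, z = z)
    m <- make_model(blocks, 1, blocks$snps[[1]]$snp_id, w)
    cond <- conditional_gwas(m, tab, blocks[1, ])
    top <- which.max(abs(cond$r))
    expect_lt(abs(cond$z_cond[top]), abs(cond$z[top]))
  }
})

test_that("novelty classification follows the two printed criteria", {
  blocks <- simulate_ld_blocks(n_blocks = 1, block_size = 2, seed = 70)
  known <- tibble::tibble(chrom = "1", start = 2e6, end = 3e6)

  assoc <- tibble::tibble(gene_id = "g", panel_id = "p", chrom = "1",
                          tss = 2e6 - 4e5)  # 0.4 Mb from the region
  tab <- tibble::tibble(snp_id = "rs1", chrom = "1", bp = 2e6 - 4e5,
                        a1 = "A", a2 = "G", z = 1, n = 10, p = 1e-6)
  nov <- classify_novelty(assoc, known, tab)
  expect_false(nov$novel[nov$window_bp == 5e5])

  assoc2 <- tibble::tibble(gene_id = "g", panel_id = "p", chrom = "1",
                           tss = 2e6 - 6e5)  # 0.6 Mb away
  tab2 <- tibble::tibble(snp_id = "rs1", chrom = "1", bp = 2e6 - 6e5,
                         a1 = "A", a2 = "G", z = 1, n = 10, p = 1e-6)
  nov2 <- classify_novelty(assoc2, known, tab2)
  expect_true(nov2$novel[nov2$window_bp == 5e5])
  expect_false(nov2$novel[nov2$window_bp == 1e6])

  tab3 <- dplyr::mutate(tab2, p = 1e-9)  # local GWAS already significant
  nov3 <- classify_novelty(assoc2, known, tab3)
  expect_false(any(nov3$novel))
})

test_that("tissue chi-square summary averages squared statistics", {
  assoc <- tibble::tibble(
    gene_id = c("a", "b", "c", "d"),
    panel_id = c("p1", "p1", "p1", "p2"),
    z_twas = c(1, 2, 3, -2),
    significant = c(TRUE, TRUE, TRUE, TRUE)
  )
  out <- tissue_chi2_summary(assoc)
  expect_equal(out$mean_chi2[out$panel_id == "p1"], 14 / 3)
  expect_equal(out$mean_chi2[out$panel_id == "p2"], 4)  # sign-invariant

  none <- dplyr::mutate(assoc, significant = FALSE)
  expect_equal(nrow(tissue_chi2_summary(none)), 0L)
})
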