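# Effect-size and summary-statistics generators: degenerate cases, moment
# recovery, null calibration, determinism.

test_that("zero heritability yields exactly zero effects", {
  blocks <- simulate_ld_blocks(n_blocks = 5, block_size = 10, seed = 1)
  truth <- simulate_effects(blocks, h2 = c(0, 0.3), rg = 0, seed = 2)
  expect_true(all(truth$beta1 == 0))
  expect_true(any(truth$beta2 != 0))
})

test_that("perfect genetic correlation with equal h2 gives identical effects", {
  blocks <- simulate_ld_blocks(n_blocks = 5, block_size = 10, seed = 1)
  truth <- simulate_effects(blocks, h2 = c(0.4, 0.4), rg = 1, seed = 3)
  expect_equal(truth$beta1, truth$beta2)
})

test_that("effect pairs recover the requested genetic correlation", {
  # M = 10,000 SNPs, rg = -0.2: empirical correlation within +/- 0.03
  blocks <- simulate_ld_blocks(n_blocks = 200, block_size = 50, seed = 11)
  truth <- simulate_effects(blocks, h2 = c(0.5, 0.25), rg = -0.2, seed = 12)
  expect_lt(abs(stats::cor(truth$beta1, truth$beta2) - (-0.2)), 0.03)
})

test_that("exact scaling makes the summed squared effects match h2", {
  blocks <- simulate_ld_blocks(n_blocks = 20, block_size = 20, seed = 4)
  truth <- simulate_effects(blocks, h2 = c(0.37, 0.11), rg = 0.3, seed = 5)
  expect_equal(sum(truth$beta1^2), 0.37, tolerance = 1e-6)
  expect_equal(sum(truth$beta2^2), 0.11, tolerance = 1e-6)
})

test_that("oligogenic architecture confines trait-1 effects to causal blocks", {
  blocks <- simulate_ld_blocks(n_blocks = 50, block_size = 10, seed = 6)
  truth <- simulate_effects(blocks, h2 = c(0.5, 0.5), rg = 0,
                            architecture = "oligogenic",
                            n_causal_blocks = 24, seed = 7)
  causal <- attr(truth, "causal_blocks")
  expect_length(causal, 24)
  expect_true(all(truth$beta1[!truth$block_id %in% causal] == 0))
  expect_true(any(truth$beta2[!truth$block_id %in% causal] != 0))
})

test_that("invalid correlation or architecture requests error", {
  blocks <- simulate_ld_blocks(n_blocks = 50, block_size = 10, seed = 6)
  expect_error(simulate_effects(blocks, h2 = c(0.5, 0.5), rg = 1.5, seed = 1),
               "rg")
  # oligogenic with rg too large for the implied per-SNP correlation
  expect_error(
    simulate_effects(blocks, h2 = c(0.5, 0.5), rg = -0.9,
                     architecture = "oligogenic", n_causal_blocks = 5,
                     seed = 1),
    "not attainable"
  )
  expect_error(simulate_effects(blocks, h2 = c(1.5, 0.5), rg = 0, seed = 1),
               "h2")
})

test_that("null summary statistics are calibrated", {
  # 10,000 SNPs with beta = 0: mean, variance and tail mass of Z
  blocks <- simulate_ld_blocks(n_blocks = 200, block_size = 50,
                               rho = rho_grid(), seed = 21)
  truth <- simulate_effects(blocks, h2 = c(0, 0), rg = 0, seed = 22)
  ss <- simulate_sumstats(truth, blocks, n = 20000, trait = 1, seed = 23)
  expect_equal(nrow(ss), 10000)
  expect_lt(abs(mean(ss$z)), 3 / sqrt(2000))
  expect_gt(stats::var(ss$z), 0.9)
  expect_lt(stats::var(ss$z), 1.1)
  expect_gt(mean(abs(ss$z) > 1.96), 0.04)
  expect_lt(mean(abs(ss$z) > 1.96), 0.06)
  expect_true(all(is.finite(ss$z)))
})

test_that("summary statistics are deterministic for a fixed seed", {
  blocks <- simulate_ld_blocks(n_blocks = 5, block_size = 8, seed = 1)
  truth <- simulate_effects(blocks, h2 = c(0.2, 0.2), rg = 0.5, seed = 2)
  a <- simulate_sumstats(truth, blocks, n = 5000, trait = 1, seed = 9)
  b <- simulate_sumstats(truth, blocks, n = 5000, trait = 1, seed = 9)
  expect_identical(a, b)
})

test_that("replicate mean of Z matches the generative mean sqrt(n) V beta", {
  blocks <- simulate_ld_blocks(n_blocks = 2, block_size = 5, rho = 0.6,
                               seed = 31)
  truth <- simulate_effects(blocks, h2 = c(0.01, 0), rg = 0, seed = 32)
  n <- 10000
  snp <- 3L  # an arbitrary SNP of block 1
  mu <- sqrt(n) * as.vector(blocks$R[[1]] %*% truth$beta1[1:5])[snp]
  zs <- vapply(1:200, function(r) {
    simulate_sumstats(truth, blocks, n = n, trait = 1, seed = 100 + r)$z[snp]
  }, numeric(1))
  mc_se <- stats::sd(zs) / sqrt(length(zs))
  expect_lt(abs(mean(zs) - mu), 3 * mc_se)
})

test_that("mismatched truth and blocks are rejected", {
  blocks <- simulate_ld_blocks(n_blocks = 3, block_size = 4, seed = 1)
  other <- simulate_ld_blocks(n_blocks = 3, block_size = 5, seed = 2)
  truth <- simulate_effects(blocks, h2 = c(0.1, 0.1), rg = 0, seed = 3)
  expect_error(simulate_sumstats(truth, other, n = 1000, trait = 1, seed = 4),
               "mismatch")
})

test_that("realized local truth sums to the genome-wide architecture", {
  blocks <- simulate_ld_blocks(n_blocks = 30, block_size = 10, seed = 41)
  truth <- simulate_effects(blocks, h2 = c(0.5, 0.2), rg = -0.4, seed = 42)
  loc <- truth_local(truth, blocks)
  tot <- attr(loc, "totals")
  expect_equal(sum(loc$h2_1), tot[["h2_1"]])
  # beta' V beta fluctuates around the requested h2 (unit LD diagonal)
  expect_lt(abs(tot[["h2_1"]] - 0.5), 0.15)
})
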