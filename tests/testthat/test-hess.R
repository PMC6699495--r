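# Local heritability and local genetic correlation: quadratic-form
# identities, the dense-algebra oracle, anchoring, family-wise nulls.

test_that("local heritability follows (q - k)/(n - k) exactly", {
  blocks <- make_blocks(list(diag(10)))
  # identity LD: k = 10 and q = sum(z^2)
  z_null <- rep(1, 10)           # q = 10 = k
  out <- local_h2(z_null, blocks[1, ], n = 1000)
  expect_equal(out$k, 10L)
  expect_equal(out$h2, 0)

  z <- sqrt(rep(2, 10))          # q = 20
  out2 <- local_h2(z, blocks[1, ], n = 1000)
  expect_equal(out2$h2, 10 / 990)

  expect_error(local_h2(z, blocks[1, ], n = 5), "exceed")
})

test_that("a single strong block recovers its simulated local heritability", {
  blocks <- simulate_ld_blocks(n_blocks = 1, block_size = 40, rho = 0.4,
                               seed = 30)
  R <- blocks$R[[1]]
  set.seed(31)
  v <- rnorm(40)
  tau <- 0.02
  beta <- v * sqrt(tau / sum(v * (R %*% v)))  # beta' V beta = 0.02 exactly
  truth <- as_sim_truth(blocks, beta, beta)
  n <- 50000
  ests <- vapply(1:200, function(r) {
    ss <- simulate_sumstats(truth, blocks, n = n, trait = 1, seed = 100 + r)
    local_h2(ss$z, blocks[1, ], n = n)$h2
  }, numeric(1))
  mc_se <- sd(ests) / sqrt(length(ests))
  # eigen-truncation discards a sliver of signal variance; allow 3 MC SEs
  # around the retained-signal expectation
  expect_lt(abs(mean(ests) - tau), 3 * mc_se + 0.005 * tau + 1e-4)
})

test_that("local covariance matches the dense pseudo-inverse oracle", {
  set.seed(32)
  for (i in 1:40) {
    m <- sample(2:8, 1)
    blocks <- simulate_ld_blocks(n_blocks = 1, block_size = m,
                                 model = "random_psd", seed = 6000 + i)
    z1 <- rnorm(m, sd = 2)
    z2 <- rnorm(m, sd = 2)
    n1 <- 1000; n2 <- 2000
    est <- local_rho(z1, z2, blocks[1, ], n1, n2)
    expected <- oracle_pinv_quad(blocks$R[[1]], z1, z2, est$k) / sqrt(n1 * n2)
    expect_equal(est$rho, expected, tolerance = 1e-10)
  }
})

test_that("a zero Z vector gives zero covariance with p = 1", {
  blocks <- simulate_ld_blocks(n_blocks = 1, block_size = 6, seed = 33)
  z1 <- rnorm(6)
  est <- local_rho(z1, rep(0, 6), blocks[1, ], 1000, 1000)
  expect_equal(est$rho, 0)
  expect_equal(est$p, 1)
})

test_that("local covariance is symmetric and bilinear", {
  blocks <- simulate_ld_blocks(n_blocks = 1, block_size = 7,
                               model = "random_psd", seed = 34)
  set.seed(35)
  z1 <- rnorm(7); z2 <- rnorm(7); z3 <- rnorm(7)
  b <- blocks[1, ]
  expect_equal(local_rho(z1, z2, b, 1000, 1000)$rho,
               local_rho(z2, z1, b, 1000, 1000)$rho, tolerance = 1e-10)
  expect_equal(local_rho(3 * z1, z2, b, 1000, 1000)$rho,
               3 * local_rho(z1, z2, b, 1000, 1000)$rho, tolerance = 1e-10)
  expect_equal(local_rho(z1 + z3, z2, b, 1000, 1000)$rho,
               local_rho(z1, z2, b, 1000, 1000)$rho +
                 local_rho(z3, z2, b, 1000, 1000)$rho, tolerance = 1e-10)
})

test_that("anchored scans reproduce the anchor exactly and validate it", {
  blocks <- simulate_ld_blocks(n_blocks = 30, block_size = 20,
                               rho = rho_grid(), seed = 36)
  truth <- simulate_effects(blocks, h2 = c(0.4, 0.2), rg = 0.1, seed = 37)
  s1 <- simulate_sumstats(truth, blocks, n = 20000, trait = 1, seed = 38)
  s2 <- simulate_sumstats(truth, blocks, n = 20000, trait = 2, seed = 39)
  scan <- local_scan(s1, s2, blocks, anchor_h2 = c(0.67, 0.25))
  tot <- attr(scan, "totals")
  expect_equal(tot[["h2_1"]], 0.67, tolerance = 1e-12)
  expect_equal(tot[["h2_2"]], 0.25, tolerance = 1e-12)
  expect_identical(attr(scan, "method"), "hess-anchored")
  expect_error(local_scan(s1, s2, blocks, anchor_h2 = c(-0.1, 0.2)),
               "anchor")
})

test_that("blocks without analyzed SNPs are dropped and counted", {
  blocks <- simulate_ld_blocks(n_blocks = 4, block_size = 10, seed = 40)
  truth <- simulate_effects(blocks, h2 = c(0.2, 0.2), rg = 0, seed = 41)
  s1 <- simulate_sumstats(truth, blocks, n = 5000, trait = 1, seed = 42)
  s2 <- simulate_sumstats(truth, blocks, n = 5000, trait = 2, seed = 43)
  drop_ids <- blocks$snps[[2]]$snp_id
  s1 <- s1[!s1$snp_id %in% drop_ids, ]
  scan <- local_scan(s1, s2, blocks)
  expect_equal(nrow(scan), 3L)
  expect_equal(attr(scan, "n_dropped"), 1L)
  expect_equal(attr(scan, "threshold"), 0.05 / 3)
})

test_that("an all-null genome yields no block past the family threshold", {
  blocks <- simulate_ld_blocks(n_blocks = 150, block_size = 10,
                               rho = rho_grid(), seed = 44)
  truth <- simulate_effects(blocks, h2 = c(0, 0), rg = 0, seed = 45)
  s1 <- simulate_sumstats(truth, blocks, n = 10000, trait = 1, seed = 46)
  s2 <- simulate_sumstats(truth, blocks, n = 10000, trait = 2, seed = 47)
  scan <- local_scan(s1, s2, blocks)
  expect_equal(sum(scan$significant), 0L)
})

test_that("summed local heritability carries a jackknife standard error", {
  blocks <- simulate_ld_blocks(n_blocks = 25, block_size = 15,
                               rho = rho_grid(), seed = 48)
  truth <- simulate_effects(blocks, h2 = c(0.4, 0.1), rg = 0, seed = 49)
  ss <- simulate_sumstats(truth, blocks, n = 20000, trait = 1, seed = 50)
  scan <- local_scan(ss, NULL, blocks)
  est <- total_h2(scan, trait = 1)
  expect_equal(est$h2, sum(scan$h2_1))
  expect_gt(est$se, 0)
  expect_identical(est$method, "hess-sum")
})
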