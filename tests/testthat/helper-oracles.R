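# Independent oracles and small fixture builders shared across tests.
# Every oracle is a direct, unoptimized transcription of the defining
# computation, kept independent of the package's code paths.

# --- TWAS: direct formula evaluation --------------------------------------
oracle_twas_z <- function(w, z, V) {
  as.numeric(t(w) %*% z) / sqrt(as.numeric(t(w) %*% V %*% w))
}

# --- quadratic forms: dense pseudo-inverse from an explicit
#     eigendecomposition at a given rank -----------------------------------
oracle_pinv_quad <- function(V, z1, z2, k) {
  e <- eigen(V, symmetric = TRUE)
  Vp <- e$vectors[, 1:k, drop = FALSE] %*%
    diag(1 / e$values[1:k], k) %*% t(e$vectors[, 1:k, drop = FALSE])
  as.numeric(t(z1) %*% Vp %*% z2)
}

# --- clumping: literal greedy specification over explicit loops -----------
# sig: data frame with snp_id, chrom, bp, p; r2_fun(id_i, id_j) -> r^2.
# Returns a list of regions, each a sorted character vector of members.
oracle_clump <- function(sig, r2_fun, r2_within, r2_between, window_bp) {
  ord <- order(sig$p, sig$chrom, sig$bp, sig$snp_id)
  sig <- sig[ord, , drop = FALSE]
  n <- nrow(sig)
  clump <- rep(NA_integer_, n)
  idx <- integer(0)
  for (i in seq_len(n)) {
    if (!is.na(clump[i])) next
    idx <- c(idx, i)
    k <- length(idx)
    clump[i] <- k
    for (j in seq_len(n)) {
      if (is.na(clump[j]) &&
          sig$chrom[j] == sig$chrom[i] &&
          abs(sig$bp[j] - sig$bp[i]) <= window_bp &&
          r2_fun(sig$snp_id[i], sig$snp_id[j]) >= r2_within) {
        clump[j] <- k
      }
    }
  }
  # merge clumps by index-SNP LD, to transitive closure
  nc <- length(idx)
  region <- seq_len(nc)
  repeat {
    changed <- FALSE
    for (a in seq_len(nc)) {
      for (b in seq_len(nc)) {
        ia <- idx[a]; ib <- idx[b]
        if (region[a] != region[b] &&
            sig$chrom[ia] == sig$chrom[ib] &&
            abs(sig$bp[ia] - sig$bp[ib]) <= window_bp &&
            r2_fun(sig$snp_id[ia], sig$snp_id[ib]) >= r2_between) {
          region[region == region[b]] <- region[a]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  members <- split(sig$snp_id, region[clump])
  unname(lapply(members, sort))
}

# --- BH step-up, traced directly from its definition ----------------------
oracle_bh <- function(p, q) {
  n <- length(p)
  ord <- order(p)
  k_max <- 0L
  for (k in seq_len(n)) {
    if (p[ord[k]] <= q * k / n) k_max <- k
  }
  mask <- rep(FALSE, n)
  if (k_max > 0L) mask[ord[seq_len(k_max)]] <- TRUE
  mask
}

# --- fixture builders -----------------------------------------------------

# A hand-built ld_blocks tibble from explicit correlation matrices.
make_blocks <- function(mats, chrom = "1", start_bp = 1e5, spacing = 1000,
                        gap = 50000, snp_prefix = "rs") {
  rows <- list()
  pos <- start_bp
  counter <- 0L
  for (b in seq_along(mats)) {
    R <- mats[[b]]
    m <- nrow(R)
    bp <- pos + (seq_len(m) - 1L) * spacing
    pos <- bp[m] + gap
    ids <- sprintf("%s%d", snp_prefix, counter + seq_len(m))
    counter <- counter + m
    rows[[b]] <- tibble::tibble(
      block_id = sprintf("block_%d", b), chrom = chrom,
      start = bp[1], end = bp[m],
      snps = list(tibble::tibble(snp_id = ids, bp = bp, a1 = "A", a2 = "G")),
      R = list(R),
      R_chol = list(tryCatch(chol(R), error = function(e) NULL))
    )
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("ld_blocks", class(out))
  out
}

# A minimal harmonized sumstats tibble over given blocks with supplied z.
make_table <- function(blocks, z, n = 10000) {
  manifest <- crosstrait::ld_snps(blocks)
  tibble::tibble(
    snp_id = manifest$snp_id, chrom = manifest$chrom, bp = manifest$bp,
    a1 = manifest$a1, a2 = manifest$a2, z = z, n = n,
    p = crosstrait::two_tailed_p(z)
  )
}

# A one-row weight_models tibble with explicit weights on given SNPs.
make_model <- function(blocks, block_idx, snp_ids, weights,
                       gene_id = "geneX", panel_id = "panelA",
                       cis_h2 = 0.2, tss = NULL) {
  snps <- blocks$snps[[block_idx]]
  stopifnot(all(snp_ids %in% snps$snp_id))
  tss <- tss %||% snps$bp[match(snp_ids[1], snps$snp_id)]
  out <- tibble::tibble(
    gene_id = gene_id, panel_id = panel_id,
    chrom = blocks$chrom[block_idx], tss = tss, tes = tss + 10000,
    cis_h2 = cis_h2, block_id = blocks$block_id[block_idx],
    weights = list(tibble::tibble(
      snp_id = snp_ids,
      a1 = snps$a1[match(snp_ids, snps$snp_id)],
      a2 = snps$a2[match(snp_ids, snps$snp_id)],
      weight = weights
    ))
  )
  class(out) <- c("weight_models", class(out))
  out
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Per-block shared effect vector with exact local strength tau, used by the
# pleiotropy simulations.
shared_block_effects <- function(blocks, tau, causal_idx) {
  snps <- crosstrait::ld_snps(blocks)
  beta <- numeric(nrow(snps))
  for (b in causal_idx) {
    idx <- which(snps$block_id == blocks$block_id[b])
    R <- blocks$R[[b]]
    v <- stats::rnorm(length(idx))
    beta[idx] <- v * sqrt(tau / sum(v * (R %*% v)))
  }
  beta
}

# Heterogeneous-LD rho grid used as the default simulation condition.
rho_grid <- function() seq(0.1, 0.9, length.out = 8)
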