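# Independent risk regions from LD- and distance-based clumping, plus
# interval utilities for known-region BED files.

#' Clump significant SNPs into independent risk regions
#'
#' Greedy clumping followed by clump merging.  Significant SNPs
#' (`p <= p_thresh`) are processed in ascending p order (ties broken by
#' chromosome, position, then rsID): each unassigned SNP becomes the index
#' of a new clump and absorbs every unassigned significant SNP with
#' `r^2 >= r2_within` to it within `window_bp` on the same chromosome.
#' Clumps whose index SNPs have `r^2 >= r2_between` within `window_bp` are
#' then merged (transitively) into one region.  Cross-block `r^2` is zero
#' under a block-partitioned LD reference.
#'
#' @param table A harmonized summary-statistics tibble.
#' @param blocks An `ld_blocks` tibble supplying the LD.
#' @param p_thresh Genome-wide significance level (default `5e-8`).
#' @param r2_within r-squared threshold for SNP-to-clump assignment.
#' @param r2_between r-squared threshold for clump-to-region merging.
#' @param window_bp Distance window for both steps.
#' @return A `risk_regions` tibble: `chrom`, `start`, `end`, `index_snp`,
#'   `min_p`, `n_snps` and list-column `snps`; attribute `n_missing_ld`
#'   counts significant SNPs absent from the LD reference.
#' @export
clump_regions <- function(table, blocks, p_thresh = 5e-8,
                          r2_within = 0.25, r2_between = 0.3,
                          window_bp = 1e6) {
  stopifnot(p_thresh > 0, p_thresh <= 1,
            r2_within > 0, r2_within <= 1,
            r2_between > 0, r2_between <= 1,
            window_bp > 0)
  if (!"p" %in% names(table)) table$p <- two_tailed_p(table$z)

  sig <- dplyr::filter(table, .data$p <= p_thresh)
  empty <- tibble::tibble(
    chrom = character(), start = numeric(), end = numeric(),
    index_snp = character(), min_p = numeric(), n_snps = integer(),
    snps = list()
  )
  manifest <- ld_snps(blocks)
  sig <- dplyr::inner_join(
    sig, dplyr::select(manifest, "snp_id", "block_id"), by = "snp_id"
  )
  n_missing <- sum(!(dplyr::filter(table, .data$p <= p_thresh)$snp_id
                     %in% manifest$snp_id))
  if (n_missing > 0) {
    warning(sprintf("%d significant SNP(s) absent from LD reference", n_missing))
  }
  if (nrow(sig) == 0L) {
    attr(empty, "n_missing_ld") <- n_missing
    class(empty) <- c("risk_regions", class(empty))
    return(empty)
  }

  sig <- sig[order(sig$p, sig$chrom, sig$bp, sig$snp_id), ]
  pos_in_block <- integer(nrow(sig))
  for (i in seq_len(nrow(sig))) {
    pos_in_block[i] <- match(sig$snp_id[i], blocks$snps[[
      match(sig$block_id[i], blocks$block_id)]]$snp_id)
  }
  r2 <- function(i, j) {
    if (sig$block_id[i] != sig$block_id[j]) return(0)
    R <- blocks$R[[match(sig$block_id[i], blocks$block_id)]]
    R[pos_in_block[i], pos_in_block[j]]^2
  }

  # greedy assignment
  clump <- rep(NA_integer_, nrow(sig))
  index_of <- integer(0)
  for (i in seq_len(nrow(sig))) {
    if (!is.na(clump[i])) next
    k <- length(index_of) + 1L
    index_of[k] <- i
    clump[i] <- k
    for (j in seq_len(nrow(sig))) {
      if (!is.na(clump[j])) next
      if (sig$chrom[j] == sig$chrom[i] &&
          abs(sig$bp[j] - sig$bp[i]) <= window_bp &&
          r2(i, j) >= r2_within) {
        clump[j] <- k
      }
    }
  }

  # merge clumps whose index SNPs are in LD (transitive closure, union-find)
  n_clump <- length(index_of)
  parent <- seq_len(n_clump)
  find <- function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  if (n_clump > 1L) {
    for (a in seq_len(n_clump - 1L)) {
      for (b in (a + 1L):n_clump) {
        ia <- index_of[a]; ib <- index_of[b]
        if (sig$chrom[ia] == sig$chrom[ib] &&
            abs(sig$bp[ia] - sig$bp[ib]) <= window_bp &&
            r2(ia, ib) >= r2_between) {
          parent[find(b)] <- find(a)
        }
      }
    }
  }
  region_of_clump <- vapply(seq_len(n_clump), find, integer(1))
  region_id <- region_of_clump[clump]

  out <- sig |>
    dplyr::mutate(.region = region_id) |>
    dplyr::group_by(.data$.region) |>
    dplyr::group_map(function(g, key) {
      top <- g[order(g$p, g$chrom, g$bp, g$snp_id), ][1, ]
      tibble::tibble(
        chrom = top$chrom,
        start = min(g$bp), end = max(g$bp),
        index_snp = top$snp_id, min_p = top$p,
        n_snps = nrow(g), snps = list(sort(g$snp_id))
      )
    }) |>
    dplyr::bind_rows() |>
    dplyr::arrange(.data$chrom, .data$start)
  attr(out, "n_missing_ld") <- n_missing
  class(out) <- c("risk_regions", class(out))
  out
}

#' Minimum association p-value in a genomic interval
#'
#' @param table A summary-statistics tibble (a `p` column is computed from
#'   `z` if absent).
#' @param chrom Chromosome label.
#' @param start,end 1-based inclusive bounds.
#' @return The minimum p over SNPs in the interval, or `Inf` when the
#'   interval contains no SNP.
#' @export
min_p_in_interval <- function(table, chrom, start, end) {
  stopifnot(start <= end)
  if (!"p" %in% names(table)) table$p <- two_tailed_p(table$z)
  hit <- table$chrom == as.character(chrom) &
    table$bp >= start & table$bp <= end
  if (!any(hit)) return(Inf)
  min(table$p[hit])
}

#' Read a BED interval file
#'
#' BED is 0-based half-open on disk; intervals are converted to 1-based
#' inclusive in memory, matching every other coordinate in the package.
#'
#' @param path Path to a 3+ column BED file (no header).
#' @return Tibble with `chrom`, `start`, `end` (1-based inclusive).
#' @export
read_bed <- function(path) {
  bed <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE)
  tibble::tibble(
    chrom = as.character(bed[[1]]),
    start = as.numeric(bed[[2]]) + 1,
    end = as.numeric(bed[[3]])
  )
}

#' Write intervals as BED
#'
#' Converts 1-based inclusive intervals back to 0-based half-open.
#'
#' @param intervals Tibble with `chrom`, `start`, `end` (1-based inclusive).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  out <- tibble::tibble(
    chrom = intervals$chrom,
    start = format(intervals$start - 1, scientific = FALSE, trim = TRUE),
    end = format(intervals$end, scientific = FALSE, trim = TRUE)
  )
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}
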