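# GWAS summary-statistics tables: file IO, quality control and allele
# harmonization against a reference manifest.

#' Read a GWAS summary-statistics file
#'
#' Expects a tab-separated file with header `SNP CHR BP A1 A2 Z N` and an
#' optional `P` column; coordinates are 1-based.
#'
#' @param path Path to the file.
#' @return Tibble with columns `snp_id`, `chrom`, `bp`, `a1`, `a2`, `z`,
#'   `n` and (if present) `p`.
#' @export
read_sumstats <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(CHR = readr::col_character())) |>
    dplyr::rename(snp_id = "SNP", chrom = "CHR", bp = "BP",
                  a1 = "A1", a2 = "A2", z = "Z", n = "N") |>
    dplyr::rename_with(~"p", dplyr::any_of("P"))
}

#' Write a GWAS summary-statistics file
#'
#' @param table A summary-statistics tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(table, path) {
  out <- dplyr::rename(table, SNP = "snp_id", CHR = "chrom", BP = "bp",
                       A1 = "a1", A2 = "a2", Z = "z", N = "n")
  if ("p" %in% names(out)) out <- dplyr::rename(out, P = "p")
  readr::write_tsv(out, path)
  invisible(path)
}

#' Quality-control filter for summary statistics
#'
#' Removes records that break the assumptions of reference-LD methods:
#' identifiers that are not rsIDs (`rs` followed by digits), indel-length
#' or non-ACGT alleles, strand-ambiguous pairs (A/T, C/G), rsIDs observed
#' with more than one distinct allele pair (multi-allelic), and exact
#' duplicate records beyond the first.  All rules are evaluated against the
#' input table and the union of violations is removed, each record counted
#' once under the first rule it matches; a second application is therefore
#' a no-op.
#'
#' When no `p` column is present one is computed from `z` on output.
#'
#' @param table A summary-statistics tibble.
#' @return The filtered tibble, with a `qc_report` attribute (see
#'   [qc_report()]).
#' @export
qc_sumstats <- function(table) {
  check_columns(table, c("snp_id", "a1", "a2", "z"), "sumstats table")
  n_in <- nrow(table)

  a1 <- toupper(table$a1)
  a2 <- toupper(table$a2)
  table$a1 <- a1
  table$a2 <- a2
  bases <- c("A", "C", "G", "T")

  bad_rsid <- !grepl("^rs[0-9]+$", table$snp_id)
  indel <- nchar(a1) != 1L | nchar(a2) != 1L
  invalid <- !indel & (!(a1 %in% bases) | !(a2 %in% bases) | a1 == a2)
  pair <- paste(a1, a2)
  ambiguous <- pair %in% c("A T", "T A", "C G", "G C")
  multi_by_id <- tapply(pair, table$snp_id, function(x) length(unique(x)) > 1L)
  multi <- indel | unname(multi_by_id[table$snp_id])
  dup <- duplicated(paste(table$snp_id, pair))

  # first matching rule wins for the per-rule counts
  rule <- rep(NA_character_, n_in)
  assign_rule <- function(rule, mask, name) {
    ifelse(is.na(rule) & mask, name, rule)
  }
  rule <- assign_rule(rule, bad_rsid, "missing_rsid")
  rule <- assign_rule(rule, invalid, "invalid_alleles")
  rule <- assign_rule(rule, ambiguous, "strand_ambiguous")
  rule <- assign_rule(rule, multi, "multi_allelic")
  rule <- assign_rule(rule, dup, "duplicate")

  out <- table[is.na(rule), , drop = FALSE]
  if (!"p" %in% names(out)) {
    out$p <- two_tailed_p(out$z)
  } else {
    out$p[is.na(out$p)] <- two_tailed_p(out$z[is.na(out$p)])
  }

  rules <- c("missing_rsid", "invalid_alleles", "strand_ambiguous",
             "multi_allelic", "duplicate")
  counts <- as.integer(table(factor(rule, levels = rules)))
  report <- tibble::tibble(rule = rules, n_removed = counts)
  attr(report, "n_in") <- n_in
  attr(report, "n_out") <- nrow(out)
  attr(out, "qc_report") <- report
  out
}

#' Retrieve the QC report of a filtered table
#'
#' @param table A tibble returned by [qc_sumstats()].
#' @return Tibble of per-rule removal counts with attributes `n_in` and
#'   `n_out`; counts sum to `n_in - n_out`.
#' @export
qc_report <- function(table) {
  attr(table, "qc_report")
}

#' Harmonize summary-statistics alleles to a reference
#'
#' Aligns the sign convention of Z-scores to a reference allele order.
#' Records whose alleles match the reference order pass unchanged; records
#' with swapped alleles have `z` negated and alleles swapped; records whose
#' alleles are incompatible with the reference, or which are absent from
#' it, are dropped and counted.
#'
#' @param table A QC-filtered summary-statistics tibble.
#' @param reference Either an `ld_blocks` tibble or a tibble with columns
#'   `snp_id`, `a1`, `a2` giving the reference allele order.
#' @return The harmonized tibble with a `harmonize_report` attribute
#'   (named counts: `n_matched`, `n_flipped`, `n_mismatch`, `n_absent`).
#' @export
harmonize_alleles <- function(table, reference) {
  if (inherits(reference, "ld_blocks")) reference <- ld_snps(reference)
  check_columns(reference, c("snp_id", "a1", "a2"), "reference")
  ref <- dplyr::select(reference, "snp_id", ref_a1 = "a1", ref_a2 = "a2")

  joined <- dplyr::left_join(table, ref, by = "snp_id")
  absent <- is.na(joined$ref_a1)
  same <- !absent & joined$a1 == joined$ref_a1 & joined$a2 == joined$ref_a2
  swapped <- !absent & joined$a1 == joined$ref_a2 & joined$a2 == joined$ref_a1
  mismatch <- !absent & !same & !swapped

  out <- joined[same | swapped, , drop = FALSE]
  flip <- swapped[same | swapped]
  out$z[flip] <- -out$z[flip]
  tmp <- out$a1[flip]
  out$a1[flip] <- out$a2[flip]
  out$a2[flip] <- tmp
  out <- dplyr::select(out, -"ref_a1", -"ref_a2")

  attr(out, "harmonize_report") <- c(
    n_matched = sum(same), n_flipped = sum(swapped),
    n_mismatch = sum(mismatch), n_absent = sum(absent)
  )
  out
}

#' Retrieve the harmonization report
#'
#' @param table A tibble returned by [harmonize_alleles()].
#' @return Named integer vector of match/flip/drop counts.
#' @export
harmonize_report <- function(table) {
  attr(table, "harmonize_report")
}
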