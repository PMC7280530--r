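.COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

#' Build the allele-harmonized effect table
#'
#' Orients every exposure's effect estimate to the outcome's reference
#' allele: for each SNP, each lipid exposure's major allele is compared with
#' the outcome (CAD) major allele, and where the letters differ the exposure
#' beta's sign is flipped (and that exposure's allele pair swapped, so the
#' operation is idempotent). The outcome beta is never altered; standard
#' errors, p-values and sample sizes pass through unchanged.
#'
#' Comparison is by allele letter only — no strand-complement resolution is
#' attempted; strand-ambiguous (palindromic) SNPs are flagged, not removed,
#' by [flag_palindromes()]. An exposure allele that matches neither the
#' outcome's major or minor allele nor their complements cannot describe the
#' same variant and raises an error listing the SNPs.
#'
#' @param merged A selected merged table.
#' @param strict When `TRUE` (default), irreconcilable alleles raise an
#'   error; `FALSE` skips the check and applies the letter rule regardless
#'   (used for simulated null rows whose per-trait alleles are independent
#'   permutations).
#' @return The merged table with exposure betas harmonized, plus logical
#'   columns `flipped_ldl`, `flipped_hdl`, `flipped_tg` and `palindromic`.
#' @export
build_beta_table <- function(merged, strict = TRUE) {
  bt <- merged
  bad_ids <- character(0)
  for (tr in .EXPOSURES) {
    a1x <- bt[[paste0("a1_", tr)]]
    if (strict) {
      reconcilable <- a1x == bt$a1_cad | a1x == bt$a2_cad |
        unname(.COMPLEMENT[a1x]) == bt$a1_cad |
        unname(.COMPLEMENT[a1x]) == bt$a2_cad
      reconcilable[is.na(reconcilable)] <- FALSE
      bad_ids <- union(bad_ids, bt$snp_id[!reconcilable])
    }
    flip <- a1x != bt$a1_cad
    bt[[paste0("beta_", tr)]] <- ifelse(flip, -bt[[paste0("beta_", tr)]],
                                        bt[[paste0("beta_", tr)]])
    a2x <- bt[[paste0("a2_", tr)]]
    bt[[paste0("a1_", tr)]] <- ifelse(flip, a2x, a1x)
    bt[[paste0("a2_", tr)]] <- ifelse(flip, a1x, a2x)
    bt[[paste0("flipped_", tr)]] <- flip
  }
  if (length(bad_ids))
    stop("build_beta_table: irreconcilable alleles for SNP(s): ",
         paste(utils::head(sort(bad_ids), 10), collapse = ", "))
  flag_palindromes(bt)
}

#' Flag strand-ambiguous (palindromic) SNPs
#'
#' Marks rows whose outcome allele pair is A/T or C/G. Such SNPs cannot be
#' strand-checked from allele letters alone; they are flagged for the
#' analyst's attention but never removed, because harmonization here
#' compares allele letters only.
#'
#' @param table A merged or harmonized table with `a1_cad`/`a2_cad`.
#' @return The table with a logical `palindromic` column.
#' @export
flag_palindromes <- function(table) {
  pair <- paste0(table$a1_cad, table$a2_cad)
  table$palindromic <- pair %in% c("AT", "TA", "CG", "GC")
  table
}
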