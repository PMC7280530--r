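#' Classify each SNP's exposure associations
#'
#' A SNP is deemed associated with an exposure when its p-value for that
#' exposure is `<= p_threshold` (inclusive). These memberships are the raw
#' material of the shared/unique dissection.
#'
#' @param table A merged or harmonized table with `p_ldl, p_hdl, p_tg`.
#' @param p_threshold Association cutoff (default genome-wide 5e-08).
#' @return A data.frame with `snp_id` and logical columns `ldl, hdl, tg`.
#' @export
classify_associations <- function(table, p_threshold = 5e-08) {
  data.frame(snp_id = table$snp_id,
             ldl = table$p_ldl <= p_threshold,
             hdl = table$p_hdl <= p_threshold,
             tg = table$p_tg <= p_threshold,
             stringsAsFactors = FALSE)
}

#' Partition instruments into shared and unique subsets
#'
#' SNPs associated with exactly one exposure are *unique* (also called
#' restricted) instruments; SNPs associated with two or all three exposures
#' are *shared* instruments carrying potential pleiotropic effects. The
#' seven Venn region counts over \{LDL, HDL, TG\} are returned alongside the
#' id subsets. A SNP with no membership cannot have survived a selection at
#' the same threshold and raises an error.
#'
#' @param membership Output of [classify_associations()].
#' @return A list with `unique_ldl, unique_hdl, unique_tg, unique, shared`
#'   (character id vectors), `venn` (named counts for regions `ldl, hdl,
#'   tg, ldl_hdl, ldl_tg, hdl_tg, ldl_hdl_tg`), and `membership`.
#' @export
partition_shared_unique <- function(membership) {
  m <- as.matrix(membership[, c("ldl", "hdl", "tg")])
  k <- rowSums(m)
  if (any(k == 0))
    stop("partition_shared_unique: SNP(s) with no exposure membership: ",
         paste(utils::head(membership$snp_id[k == 0], 5), collapse = ", "))
  id <- membership$snp_id
  venn <- c(
    ldl = sum(m[, "ldl"] & !m[, "hdl"] & !m[, "tg"]),
    hdl = sum(!m[, "ldl"] & m[, "hdl"] & !m[, "tg"]),
    tg = sum(!m[, "ldl"] & !m[, "hdl"] & m[, "tg"]),
    ldl_hdl = sum(m[, "ldl"] & m[, "hdl"] & !m[, "tg"]),
    ldl_tg = sum(m[, "ldl"] & !m[, "hdl"] & m[, "tg"]),
    hdl_tg = sum(!m[, "ldl"] & m[, "hdl"] & m[, "tg"]),
    ldl_hdl_tg = sum(m[, "ldl"] & m[, "hdl"] & m[, "tg"])
  )
  list(
    unique_ldl = id[k == 1 & m[, "ldl"]],
    unique_hdl = id[k == 1 & m[, "hdl"]],
    unique_tg = id[k == 1 & m[, "tg"]],
    unique = id[k == 1],
    shared = id[k >= 2],
    venn = venn,
    membership = membership
  )
}

#' Pairwise overlap counts between two SNP id sets
#'
#' @param a,b Character vectors of SNP ids.
#' @return A named integer vector `common`, `a_only`, `b_only`.
#' @export
venn_counts <- function(a, b) {
  a <- unique(a); b <- unique(b)
  c(common = length(intersect(a, b)),
    a_only = length(setdiff(a, b)),
    b_only = length(setdiff(b, a)))
}
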