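#' Column dialects for GWAS summary-statistic tables
#'
#' Named mappings from the standard internal column names to the headers used
#' by the two consortium table styles this package reads: the Willer et al.
#' lipid meta-analysis tables and the CARDIoGRAMplusC4D coronary-artery-disease
#' table. The `generic` dialect is the package's own canonical layout (what
#' [write_gwas_table()] emits). Unknown layouts require an explicit `colmap`.
#'
#' @return A named list of named character vectors (internal name -> file
#'   column name).
#' @export
gwas_dialects <- function() {
  list(
    willer = c(snp_id = "SNPID", a1 = "A1", a2 = "A2", beta = "beta",
               se = "se", n = "N", p = "P-value"),
    cardiogram = c(snp_id = "markername", a1 = "allele1", a2 = "allele2",
                   beta = "log_odds", se = "log_odds_se", p = "p_value",
                   n_case = "N_case", n_control = "N_control"),
    generic = c(snp_id = "snp_id", chrom = "chrom", pos = "pos",
                a1 = "a1", a2 = "a2", beta = "beta", se = "se",
                p = "p", n = "n")
  )
}

#' Derive a standard error from an effect estimate and its p-value
#'
#' Inverts the two-sided Wald test: `se = |beta| / z` where `z` is the upper
#' `1 - p/2` standard-normal quantile. Used as a documented fallback when a
#' summary table reports beta and p but omits the standard error (the IVW,
#' Egger and multivariable estimators all need per-SNP weights).
#'
#' @param beta Numeric vector of effect estimates; must be non-zero.
#' @param p Numeric vector of two-sided p-values, strictly inside (0, 1).
#' @return Numeric vector of standard errors. Recomputing
#'   `2 * pnorm(-abs(beta)/se)` returns `p`.
#' @examples
#' derive_se_from_p(1.96, 0.05) # ~1
#' @export
derive_se_from_p <- function(beta, p) {
  stopifnot(length(beta) == length(p))
  if (any(!is.finite(p) | p <= 0 | p >= 1))
    stop("derive_se_from_p: p must lie strictly in (0, 1)")
  if (any(beta == 0))
    stop("derive_se_from_p: a zero effect has no finite SE derivable from p")
  abs(beta) / qnorm(p / 2, lower.tail = FALSE)
}

#' Read one trait's GWAS summary-statistic table
#'
#' Reads a tab-separated summary table for a single trait, maps its columns to
#' the standard internal layout, validates each row, and returns a trait
#' table. Rows violating the record invariants (p outside (0, 1], n < 1,
#' identical alleles, non-positive SE) are dropped with a warning giving the
#' count. Rows with a missing SE get one derived from beta and p via
#' [derive_se_from_p()] and are flagged in the `se_from_p` column.
#'
#' Chromosome and position are taken from explicit columns when mapped,
#' otherwise parsed from `snp_id` when it has the form `chr:pos`; otherwise
#' they are `NA` (distance-based thinning then refuses to run). SNP ids are
#' normalized to lower case.
#'
#' @param path Path to a tab-separated file with a header.
#' @param trait One of `"ldl"`, `"hdl"`, `"tg"`, `"cad"`.
#' @param dialect Name of a mapping from [gwas_dialects()], default
#'   `"generic"`.
#' @param colmap Optional explicit named character vector (internal name ->
#'   file column) overriding `dialect`.
#' @return A `data.frame` with columns `snp_id, chrom, pos, a1, a2, beta, se,
#'   p, n, se_from_p` and attribute `trait`.
#' @export
read_trait_table <- function(path, trait, dialect = "generic", colmap = NULL) {
  trait <- match.arg(tolower(trait), .TRAITS)
  if (!file.exists(path)) stop("read_trait_table: no such file: ", path)
  if (is.null(colmap)) {
    dialects <- gwas_dialects()
    if (!dialect %in% names(dialects))
      stop("read_trait_table: unknown dialect '", dialect,
           "'; supply an explicit colmap")
    colmap <- dialects[[dialect]]
  }
  raw <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  mandatory <- intersect(names(colmap),
                         c("snp_id", "a1", "a2", "beta", "p"))
  for (f in mandatory)
    if (!colmap[[f]] %in% names(raw))
      stop("read_trait_table: missing mandatory column '", colmap[[f]], "'")
  as_tt_df(raw, trait, colmap)
}

# Map a raw data.frame into a validated trait table.
as_tt_df <- function(raw, trait, colmap) {
  get_col <- function(f) {
    if (f %in% names(colmap) && colmap[[f]] %in% names(raw))
      raw[[colmap[[f]]]] else NULL
  }
  n <- get_col("n")
  if (is.null(n)) {
    nc <- get_col("n_case"); nk <- get_col("n_control")
    # Outcome tables report cases and controls separately; the sample-size
    # proportion filter needs one scalar per SNP.
    if (!is.null(nc) && !is.null(nk)) n <- nc + nk
  }
  if (is.null(n))
    stop("read_trait_table: no sample-size column (n, or n_case + n_control)")
  tt <- data.frame(
    snp_id = tolower(as.character(get_col("snp_id"))),
    a1 = toupper(as.character(get_col("a1"))),
    a2 = toupper(as.character(get_col("a2"))),
    beta = as.numeric(get_col("beta")),
    p = as.numeric(get_col("p")),
    n = as.numeric(n),
    stringsAsFactors = FALSE
  )
  se <- get_col("se")
  tt$se <- if (is.null(se)) NA_real_ else as.numeric(se)
  chrom <- get_col("chrom"); pos <- get_col("pos")
  if (is.null(chrom) || is.null(pos)) {
    cp <- parse_chr_pos(tt$snp_id)
    chrom <- cp$chrom; pos <- cp$pos
  }
  tt$chrom <- as.character(chrom)
  tt$pos <- as.numeric(pos)

  dup <- duplicated(tt$snp_id)
  if (any(dup))
    stop("read_trait_table: duplicate snp_id (first offender: '",
         tt$snp_id[which(dup)[1]], "')")

  bad <- !is.finite(tt$p) | tt$p <= 0 | tt$p > 1 |
    !is.finite(tt$n) | tt$n < 1 |
    !is.finite(tt$beta) |
    tt$a1 == tt$a2 |
    (!is.na(tt$se) & tt$se <= 0)
  if (any(bad)) {
    warning(sum(bad), " row(s) rejected for invariant violations in ",
            trait, " table")
    tt <- tt[!bad, , drop = FALSE]
  }
  tt$se_from_p <- is.na(tt$se)
  if (any(tt$se_from_p))
    tt$se[tt$se_from_p] <- derive_se_from_p(tt$beta[tt$se_from_p],
                                            pmin(tt$p[tt$se_from_p],
                                                 1 - 1e-16))
  rownames(tt) <- NULL
  tt <- tt[, c("snp_id", "chrom", "pos", "a1", "a2", "beta", "se", "p", "n",
               "se_from_p")]
  attr(tt, "trait") <- trait
  tt
}

parse_chr_pos <- function(ids) {
  m <- regmatches(ids, regexec("^(?:chr)?([0-9xym]+):([0-9]+)$", ids))
  chrom <- vapply(m, function(x) if (length(x) == 3) x[2] else NA_character_,
                  character(1))
  pos <- vapply(m, function(x) if (length(x) == 3) as.numeric(x[3]) else
    NA_real_, numeric(1))
  list(chrom = chrom, pos = pos)
}

#' Build a trait table from an in-memory data.frame
#'
#' Convenience wrapper around the same validation path as
#' [read_trait_table()], for programmatically constructed tables (fixtures,
#' simulations). The input must already use the canonical column names.
#'
#' @param df A data.frame with columns `snp_id, a1, a2, beta, p, n` and
#'   optionally `se, chrom, pos`.
#' @inheritParams read_trait_table
#' @return A validated trait table.
#' @export
trait_table <- function(df, trait) {
  as_tt_df(df, match.arg(tolower(trait), .TRAITS), gwas_dialects()$generic)
}

#' Merge the four traits' summary tables by SNP id
#'
#' Inner join of the three lipid exposure tables and the outcome table on
#' `snp_id`. Per-trait fields are suffixed with the trait label (`beta_ldl`,
#' `se_cad`, ...). Chromosome and position are coalesced across traits in the
#' order given.
#'
#' @param ldl,hdl,tg,cad Trait tables from [read_trait_table()] or
#'   [trait_table()].
#' @return A merged `data.frame` keyed by `snp_id` with columns `snp_id,
#'   chrom, pos` and, for each trait, `beta_*, se_*, p_*, n_*, a1_*, a2_*`.
#' @export
merge_by_snpid <- function(ldl, hdl, tg, cad) {
  tabs <- list(ldl = ldl, hdl = hdl, tg = tg, cad = cad)
  pieces <- lapply(names(tabs), function(tr) {
    tt <- tabs[[tr]]
    out <- tt[, c("snp_id", "beta", "se", "p", "n", "a1", "a2")]
    names(out)[-1] <- trait_cols(tr)
    out[[paste0(".chrom_", tr)]] <- tt$chrom
    out[[paste0(".pos_", tr)]] <- tt$pos
    out
  })
  merged <- Reduce(function(a, b) merge(a, b, by = "snp_id"), pieces)
  if (nrow(merged) == 0)
    stop("merge_by_snpid: the four tables share no SNP ids")
  chrom <- rep(NA_character_, nrow(merged))
  pos <- rep(NA_real_, nrow(merged))
  for (tr in .TRAITS) {
    cc <- merged[[paste0(".chrom_", tr)]]
    pp <- merged[[paste0(".pos_", tr)]]
    take <- is.na(chrom) & !is.na(cc)
    chrom[take] <- cc[take]
    pos[is.na(pos) & !is.na(pp)] <- pp[is.na(pos) & !is.na(pp)]
  }
  merged <- merged[, !grepl("^\\.(chrom|pos)_", names(merged))]
  merged$chrom <- chrom
  merged$pos <- pos
  cols <- c("snp_id", "chrom", "pos",
            unlist(lapply(.TRAITS, trait_cols), use.names = FALSE))
  merged <- merged[order(merged$snp_id), cols]
  rownames(merged) <- NULL
  merged
}

#' Write a summary table as tab-separated text
#'
#' Writes any of the package's tables (trait, merged, beta, result) with a
#' fixed, canonical column order: `snp_id, chrom, pos` first when present,
#' remaining columns in alphabetical order. Numeric values are written with
#' 15 significant digits so a read/write round trip preserves them to
#' within 1e-12 relative error.
#'
#' @param table A non-empty data.frame.
#' @param path Output path.
#' @export
write_gwas_table <- function(table, path) {
  if (!is.data.frame(table) || nrow(table) == 0)
    stop("write_gwas_table: refusing to write an empty table")
  lead <- intersect(c("snp_id", "chrom", "pos"), names(table))
  rest <- sort(setdiff(names(table), lead))
  out <- table[, c(lead, rest), drop = FALSE]
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x) format(x, digits = 15,
                                                  trim = TRUE,
                                                  scientific = NA))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a merged (wide) summary table
#'
#' Counterpart of [write_gwas_table()] for merged tables written by this
#' package.
#'
#' @param path Path to a tab-separated merged table.
#' @return A merged `data.frame` as produced by [merge_by_snpid()].
#' @export
read_merged_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("snp_id", unlist(lapply(.TRAITS, trait_cols), use.names = FALSE))
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("read_merged_table: missing column(s): ", paste(miss, collapse = ", "))
  df$snp_id <- tolower(df$snp_id)
  if (!"chrom" %in% names(df)) df$chrom <- NA_character_
  if (!"pos" %in% names(df)) df$pos <- NA_real_
  df[, c("snp_id", "chrom", "pos", setdiff(need, "snp_id"))]
}
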