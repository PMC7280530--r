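#' Selection thresholds
#'
#' Bundles the four cutoffs of the three-stage instrument selection: `p_v`,
#' the ceiling on a SNP's minimum exposure p-value; `p_c` and `p_d`, floors
#' on the exposure and outcome sample-size proportions; and `ail`, the
#' minimum adjacent interval length in base pairs between retained SNPs
#' (0 disables distance thinning).
#'
#' @param p_v P-value cutoff in (0, 1]; stage 1 keeps SNPs with minimum
#'   exposure p-value `<= p_v` (inclusive).
#' @param p_c,p_d Sample-size-proportion cutoffs in \[0, 1\]; stage 2 keeps
#'   SNPs with proportions strictly greater than the cutoffs.
#' @param ail Minimum distance in bp between retained SNPs on a chromosome.
#' @return A list of class `mr_thresholds`.
#' @export
thresholds <- function(p_v = 5e-08, p_c = 0, p_d = 0, ail = 0) {
  stopifnot(is.numeric(p_v), p_v > 0, p_v <= 1,
            p_c >= 0, p_c <= 1, p_d >= 0, p_d <= 1, ail >= 0)
  structure(list(p_v = p_v, p_c = p_c, p_d = p_d, ail = ail),
            class = "mr_thresholds")
}

#' Minimum exposure p-value per SNP
#'
#' For each SNP, the smallest p-value across the three lipid exposures; the
#' outcome p-value is ignored. This is the statistic thresholded in stage 1:
#' a small value means the SNP is associated with at least one exposure.
#'
#' @param merged A merged table from [merge_by_snpid()].
#' @return Numeric vector, one value per row.
#' @export
compute_pvj <- function(merged) {
  pmin(merged$p_ldl, merged$p_hdl, merged$p_tg)
}

#' Sample-size proportions per SNP
#'
#' `p_cj` is the ratio of a SNP's summed exposure sample size
#' (`n_ldl + n_hdl + n_tg`) to the largest such sum in the table; `p_dj` is
#' the analogous ratio for the outcome sample size. Both lie in (0, 1] and a
#' SNP attaining the maximum scores exactly 1. SNPs genotyped in smaller
#' sub-studies score low and are removed by stage 2.
#'
#' @param merged A merged table.
#' @return A data.frame with columns `p_cj` and `p_dj`.
#' @export
compute_pcj_pdj <- function(merged) {
  nsum <- merged$n_ldl + merged$n_hdl + merged$n_tg
  mx_c <- max(nsum); mx_d <- max(merged$n_cad)
  if (mx_c <= 0 || mx_d <= 0)
    stop("compute_pcj_pdj: degenerate table (max sample size is zero)")
  data.frame(p_cj = nsum / mx_c, p_dj = merged$n_cad / mx_d)
}

#' Stage 1: keep SNPs associated with at least one exposure
#'
#' Keeps rows whose minimum exposure p-value is `<= p_v` (inclusive).
#'
#' @param merged A merged table.
#' @param p_v P-value cutoff.
#' @return The filtered merged table (possibly empty).
#' @export
select_stage1 <- function(merged, p_v = 5e-08) {
  out <- merged[compute_pvj(merged) <= p_v, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Stage 2: keep SNPs with high sample-size proportions
#'
#' Keeps rows whose exposure and outcome sample-size proportions are
#' strictly greater than `p_c` and `p_d`. The proportions are computed on
#' `reference` (by default the full merged table the stage-1 input came
#' from), so that the per-column maxima are not distorted by earlier
#' filtering; pass `reference = table` to use the post-stage-1 maxima
#' instead.
#'
#' @param table A merged table (typically stage-1 output).
#' @param p_c,p_d Proportion cutoffs.
#' @param reference Table on which the per-column maxima are taken.
#' @return The filtered merged table.
#' @export
select_stage2 <- function(table, p_c = 0, p_d = 0, reference = table) {
  props_ref <- compute_pcj_pdj(reference)
  idx <- match(table$snp_id, reference$snp_id)
  if (anyNA(idx))
    stop("select_stage2: table contains SNPs absent from reference")
  keep <- props_ref$p_cj[idx] > p_c & props_ref$p_dj[idx] > p_d
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Stage 3: adjacent-interval-length thinning
#'
#' Within each chromosome, retains a subset of SNPs whose positions are
#' pairwise at least `ail` base pairs apart. The greedy scan works in order
#' of instrument strength: the SNP with the smallest minimum exposure
#' p-value is retained first (ties broken by the smaller position) and all
#' SNPs closer than `ail` to a retained SNP are dropped — so whenever two
#' candidates conflict, the stronger association survives. `ail = 0`
#' returns the input unchanged. This removes redundant instruments sitting
#' in the same linkage block without requiring a reference panel.
#'
#' @param table A merged table with `chrom`/`pos` for every row.
#' @param ail Minimum distance in base pairs.
#' @return The thinned merged table, in the original row order.
#' @export
select_ail <- function(table, ail = 0) {
  if (ail == 0 || nrow(table) <= 1) return(table)
  bad <- is.na(table$chrom) | is.na(table$pos)
  if (any(bad))
    stop("select_ail: missing coordinates for SNP(s): ",
         paste(utils::head(table$snp_id[bad], 5), collapse = ", "))
  pv <- compute_pvj(table)
  keep <- logical(nrow(table))
  for (ch in unique(table$chrom)) {
    idx <- which(table$chrom == ch)
    idx <- idx[order(pv[idx], table$pos[idx])]
    kept_pos <- numeric(0)
    for (i in idx) {
      if (all(abs(table$pos[i] - kept_pos) >= ail)) {
        keep[i] <- TRUE
        kept_pos <- c(kept_pos, table$pos[i])
      }
    }
  }
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the full three-stage selection
#'
#' Applies stages 1 (minimum exposure p-value), 2 (sample-size proportions,
#' with maxima taken on the full input table) and 3 (distance thinning), in
#' that fixed order.
#'
#' @param merged The full merged table.
#' @param th An [thresholds()] object.
#' @param proportions_on `"full"` (default) computes the stage-2 proportions
#'   on the full merged table; `"stage1"` on the stage-1 survivors.
#' @return The selected merged table.
#' @export
select_instruments <- function(merged, th = thresholds(),
                               proportions_on = c("full", "stage1")) {
  proportions_on <- match.arg(proportions_on)
  s1 <- select_stage1(merged, th$p_v)
  ref <- if (proportions_on == "full") merged else s1
  s2 <- if (nrow(s1)) select_stage2(s1, th$p_c, th$p_d, reference = ref)
        else s1
  select_ail(s2, th$ail)
}

#' Threshold-grid convergence scan
#'
#' For each grid point, runs the three selection stages, harmonizes alleles
#' and fits the multivariable MR model, recording the number of selected
#' SNPs and the three exposure effect estimates. The causal estimates
#' fluctuate while the instrument set is unstable and settle once enough
#' well-powered SNPs are retained; the returned `stability` column (maximum
#' absolute change of any exposure beta to a neighbouring grid point, on the
#' grid as ordered) quantifies this, and the grid point minimizing it is
#' reported in the `"suggested"` attribute. The choice of operating point is
#' deliberately left to the user.
#'
#' Grid points selecting fewer than 4 SNPs are flagged
#' `"insufficient instruments"` and carry `NA` estimates.
#'
#' @param merged The full merged table.
#' @param grid A list of [thresholds()] objects.
#' @return A data.frame with one row per grid point: `p_v, p_c, p_d, ail,
#'   n_snps, beta_ldl, beta_hdl, beta_tg, stability, flag`.
#' @export
scan_grid <- function(merged, grid) {
  if (!length(grid)) stop("scan_grid: empty grid")
  if (inherits(grid, "mr_thresholds")) grid <- list(grid)
  rows <- lapply(grid, function(th) {
    sel <- select_instruments(merged, th)
    out <- data.frame(p_v = th$p_v, p_c = th$p_c, p_d = th$p_d,
                      ail = th$ail, n_snps = nrow(sel),
                      beta_ldl = NA_real_, beta_hdl = NA_real_,
                      beta_tg = NA_real_, flag = "")
    if (nrow(sel) < 4) {
      out$flag <- "insufficient instruments"
      return(out)
    }
    bt <- build_beta_table(sel)
    est <- tryCatch(mr_mvmr(bt), error = function(e) NULL)
    if (is.null(est)) { out$flag <- "collinear"; return(out) }
    out$beta_ldl <- est$beta[est$exposure == "ldl"]
    out$beta_hdl <- est$beta[est$exposure == "hdl"]
    out$beta_tg <- est$beta[est$exposure == "tg"]
    out
  })
  curve <- do.call(rbind, rows)
  b <- as.matrix(curve[, c("beta_ldl", "beta_hdl", "beta_tg")])
  k <- nrow(curve)
  stab <- rep(NA_real_, k)
  if (k > 1) {
    for (i in seq_len(k)) {
      nb <- c(i - 1, i + 1); nb <- nb[nb >= 1 & nb <= k]
      d <- suppressWarnings(max(abs(b[rep(i, length(nb)), , drop = FALSE] -
                                      b[nb, , drop = FALSE])))
      stab[i] <- if (is.finite(d)) d else NA_real_
    }
  }
  curve$stability <- stab
  ok <- which(is.finite(stab))
  attr(curve, "suggested") <- if (length(ok)) ok[which.min(stab[ok])] else NA
  curve
}

#' Preset threshold grids
#'
#' Two named grids over the sample-size-proportion and distance cutoffs,
#' mirroring the two published scanning schemes: scheme A varies the
#' `(p_c, p_d)` pair over `(0.95, 0.972), (0.972, 0.972), (0.979, 0.979),
#' (0.98, 0.98), (0.99, 0.99)` with no distance thinning; scheme B fixes
#' `p_c = p_d = 0.979` (preceded by `0.972`) and varies the adjacent
#' interval length over 1--25 kbp. `p_v = 5e-08` throughout.
#'
#' @param scheme `"A"` or `"B"`.
#' @return A list of [thresholds()] objects.
#' @export
scheme_grid <- function(scheme = c("A", "B")) {
  scheme <- match.arg(scheme)
  if (scheme == "A") {
    pcpd <- list(c(0.95, 0.972), c(0.972, 0.972), c(0.979, 0.979),
                 c(0.98, 0.98), c(0.99, 0.99))
    lapply(pcpd, function(x) thresholds(5e-08, x[1], x[2], 0))
  } else {
    c(list(thresholds(5e-08, 0.972, 0.972, 0)),
      lapply(c(0, 1e3, 5e3, 10e3, 15e3, 20e3, 25e3),
             function(a) thresholds(5e-08, 0.979, 0.979, a)))
  }
}
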