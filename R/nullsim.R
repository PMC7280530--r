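#' Configuration for the null-GWAS embedding simulation
#'
#' Controls the simulation that calibrates the instrument-selection
#' procedure: a *null* summary table is synthesized from the moments of a
#' mother dataset, a real (or synthetic) test SNP set is embedded into it
#' with its pleiotropy broken apart, selection is re-run over a grid of
#' sample-size-proportion cutoffs, and the false discovery rate — the
#' fraction of selected SNPs that are null background rather than embedded
#' test content — is measured.
#'
#' @param M Null SNP count; defaults to the mother table's size (allele
#'   multisets are preserved exactly only in that case).
#' @param p_low Lower bound of the uniform null p-value range. With the
#'   default 1e-07 no null SNP can pass a 5e-08 cutoff, so FDR is exactly
#'   0; 1e-12 lets null SNPs through and produces positive FDR.
#' @param p_v Stage-1 p-value cutoff.
#' @param grid_pc,grid_pd Vectors of stage-2 cutoffs; the grid is their
#'   cross product.
#' @param replicates Simulations per grid cell (default 10).
#' @param seed Master seed; replicate r derives its own substream.
#' @param ail Stage-3 distance (default 0: null SNPs carry no linkage).
#' @param proportions_on Reference set for the stage-2 sample-size
#'   proportions: `"stage1"` (default) takes the per-column maxima over the
#'   stage-1 survivors, `"full"` over the whole simulated table. The
#'   stage-1 convention is the one under which high-proportion grid cells
#'   retain instruments (the synthetic null sample sizes, drawn from
#'   normal tails, otherwise dominate the maxima and empty the top cells).
#' @return A list of class `nullsim_config`.
#' @export
nullsim_config <- function(M = NULL, p_low = 1e-07, p_v = 5e-08,
                           grid_pc = c(0.9, 0.95, 0.97, 0.98, 0.99),
                           grid_pd = c(0.97, 0.98, 0.99),
                           replicates = 10, seed = 1, ail = 0,
                           proportions_on = c("stage1", "full")) {
  stopifnot(p_low > 0, p_low < 1, replicates >= 1,
            length(grid_pc) >= 1, length(grid_pd) >= 1)
  structure(list(M = M, p_low = p_low, p_v = p_v, grid_pc = grid_pc,
                 grid_pd = grid_pd, replicates = replicates, seed = seed,
                 ail = ail, proportions_on = match.arg(proportions_on)),
            class = "nullsim_config")
}

#' Build a null summary-statistic table from mother-data moments
#'
#' Per trait: null betas are drawn from a normal with the mother data's
#' beta mean and variance; null p-values are uniform on `[p_low, 1]`
#' (independent of the betas — the nulls carry no real association); the
#' allele pairs are a permutation of the mother's (sampling with
#' replacement when `M` differs from the mother size); null sample sizes
#' come from a normal with the mother's moments, rounded and floored at 1.
#' SEs are back-derived from each null beta and p so downstream weighting
#' is defined. Coordinates are uniform over 22 chromosomes.
#'
#' Draws come from the caller's RNG stream; seed upstream for
#' reproducibility.
#'
#' @param mother A merged table supplying the moments.
#' @param M Null SNP count (default `nrow(mother)`).
#' @param p_low Lower bound of the null p-value range.
#' @return A merged-format table of `M` null rows with an `is_test` column
#'   set to `FALSE`.
#' @export
build_null_profiles <- function(mother, M = nrow(mother), p_low = 1e-07) {
  stopifnot(nrow(mother) > 0, M >= 1)
  null <- data.frame(snp_id = sprintf("null_%06d", seq_len(M)),
                     chrom = as.character(sample.int(22, M, replace = TRUE)),
                     pos = sample.int(2.4e8, M, replace = TRUE),
                     stringsAsFactors = FALSE)
  for (tr in .TRAITS) {
    b <- rnorm(M, mean(mother[[paste0("beta_", tr)]]),
               sd(mother[[paste0("beta_", tr)]]))
    p <- runif(M, p_low, 1)
    n <- pmax(round(rnorm(M, mean(mother[[paste0("n_", tr)]]),
                          sd(mother[[paste0("n_", tr)]]))), 1)
    perm <- if (M == nrow(mother)) sample.int(M)
            else sample.int(nrow(mother), M, replace = TRUE)
    se <- abs(b) / qnorm(p / 2, lower.tail = FALSE)
    se[se == 0] <- .Machine$double.xmin
    null[[paste0("beta_", tr)]] <- b
    null[[paste0("se_", tr)]] <- se
    null[[paste0("p_", tr)]] <- p
    null[[paste0("n_", tr)]] <- n
    null[[paste0("a1_", tr)]] <- mother[[paste0("a1_", tr)]][perm]
    null[[paste0("a2_", tr)]] <- mother[[paste0("a2_", tr)]][perm]
  }
  null$is_test <- FALSE
  null
}

#' Embed a test SNP set into a null table, breaking its pleiotropy
#'
#' For every test SNP and every exposure it is associated with (p at or
#' below `p_threshold`), one distinct null row — chosen at random without
#' replacement — has its record for that exposure *and* for the outcome
#' replaced by the test SNP's values (beta, SE, p, n, both alleles). A SNP
#' associated with two or three exposures is therefore duplicated or
#' triplicated to separate random genomic locations, each carrying exactly
#' one exposure association: the exposure--outcome relationships of the
#' test data are preserved row by row, while any cross-exposure pleiotropy
#' is dismantled.
#'
#' @param null_table Output of [build_null_profiles()].
#' @param test_set A merged-format table of test SNPs.
#' @param p_threshold Association cutoff defining the memberships.
#' @return A list: `table` (the simulated table, `is_test` marking
#'   embedded rows) and `truth` (data.frame `row`, `source`, `exposure`).
#' @export
embed_test_set <- function(null_table, test_set, p_threshold = 5e-08) {
  memb <- classify_associations(test_set, p_threshold)
  pairs <- do.call(rbind, lapply(.EXPOSURES, function(tr) {
    sel <- which(memb[[tr]])
    if (!length(sel)) return(NULL)
    data.frame(j = sel, exposure = tr, stringsAsFactors = FALSE)
  }))
  if (is.null(pairs) || nrow(pairs) == 0)
    return(list(table = null_table,
                truth = data.frame(row = integer(0), source = character(0),
                                   exposure = character(0))))
  M <- nrow(null_table)
  if (nrow(pairs) > M)
    stop("embed_test_set: null table too small for ", nrow(pairs),
         " placements")
  if (nrow(test_set) / M > 0.005)
    warning("embed_test_set: test-set/null ratio exceeds 0.005; embedded ",
            "SNPs may land close enough to recreate pleiotropy")
  target <- sample.int(M, nrow(pairs))
  sim <- null_table
  for (i in seq_len(nrow(pairs))) {
    j <- pairs$j[i]; tr <- pairs$exposure[i]; row <- target[i]
    for (f in c("beta", "se", "p", "n", "a1", "a2")) {
      sim[row, paste(f, tr, sep = "_")] <- test_set[j, paste(f, tr,
                                                             sep = "_")]
      sim[row, paste(f, "cad", sep = "_")] <- test_set[j, paste(f, "cad",
                                                                sep = "_")]
    }
    sim$is_test[row] <- TRUE
  }
  truth <- data.frame(row = target, source = test_set$snp_id[pairs$j],
                      exposure = pairs$exposure, stringsAsFactors = FALSE)
  list(table = sim, truth = truth)
}

#' False discovery rate of a selection against truth labels
#'
#' The fraction of selected SNPs that are not labeled as embedded test
#' content. An empty selection returns 0 with a warning.
#'
#' @param selected Character vector of selected SNP ids (or a logical
#'   vector of per-selected-row test flags).
#' @param test_ids Character vector of ids labeled as test content;
#'   ignored when `selected` is logical.
#' @return The FDR in \[0, 1\].
#' @export
compute_fdr <- function(selected, test_ids = NULL) {
  if (is.logical(selected)) {
    n_sel <- length(selected); n_false <- sum(!selected)
  } else {
    n_sel <- length(selected); n_false <- sum(!(selected %in% test_ids))
  }
  if (n_sel == 0) {
    warning("compute_fdr: empty selection; FDR defined as 0")
    return(0)
  }
  n_false / n_sel
}

#' Run the embedding simulation over the threshold grid
#'
#' For each replicate: build a fresh null table from the mother moments,
#' embed the test set, then for every `(p_c, p_d)` grid cell run the
#' selection stages at `p_v`, measure the FDR, harmonize the selected rows
#' and fit the multivariable MR model. Cell results are averaged over
#' replicates by [summarize_replicates()].
#'
#' @param mother Merged table supplying the null moments.
#' @param test_set Merged-format table of test SNPs.
#' @param config A [nullsim_config()].
#' @return A `SimSummary` data.frame (one row per grid cell; see
#'   [summarize_replicates()]), with the per-replicate results in
#'   attribute `"replicates"`.
#' @export
run_simulation_grid <- function(mother, test_set, config = nullsim_config()) {
  M <- if (is.null(config$M)) nrow(mother) else config$M
  cells <- expand.grid(p_c = config$grid_pc, p_d = config$grid_pd,
                       KEEP.OUT.ATTRS = FALSE)
  rep_rows <- list()
  for (r in seq_len(config$replicates)) {
    rep_rows[[r]] <- with_seed(config$seed + r, {
      null <- build_null_profiles(mother, M = M, p_low = config$p_low)
      emb <- embed_test_set(null, test_set, p_threshold = config$p_v)
      sim <- emb$table
      s1 <- select_stage1(sim, config$p_v)
      out <- cells
      out$replicate <- r
      out$n_selected <- 0L; out$n_false <- 0L; out$fdr <- NA_real_
      for (tr in .EXPOSURES) out[[paste0("n_", tr)]] <- 0L
      for (tr in .EXPOSURES) {
        out[[paste0("beta_", tr)]] <- NA_real_
        out[[paste0("p_", tr)]] <- NA_real_
      }
      out$flag <- ""
      ref <- if (identical(config$proportions_on, "full")) sim else s1
      for (i in seq_len(nrow(cells))) {
        sel <- if (nrow(s1)) select_stage2(s1, cells$p_c[i], cells$p_d[i],
                                           reference = ref) else s1
        sel <- select_ail(sel, config$ail)
        out$n_selected[i] <- nrow(sel)
        out$n_false[i] <- sum(!sel$is_test)
        out$fdr[i] <- suppressWarnings(compute_fdr(sel$is_test))
        for (tr in .EXPOSURES)
          out[[paste0("n_", tr)]][i] <-
            sum(sel[[paste0("p_", tr)]] <= config$p_v)
        if (nrow(sel) < 4) { out$flag[i] <- "insufficient instruments"; next }
        est <- tryCatch(mr_mvmr(build_beta_table(sel, strict = FALSE)),
                        error = function(e) NULL)
        if (is.null(est)) { out$flag[i] <- "collinear"; next }
        for (tr in .EXPOSURES) {
          out[[paste0("beta_", tr)]][i] <- est$beta[est$exposure == tr]
          out[[paste0("p_", tr)]][i] <- est$p[est$exposure == tr]
        }
      }
      out
    })
  }
  summarize_replicates(do.call(rbind, rep_rows))
}

#' Average per-cell simulation results over replicates
#'
#' Arithmetic means, per `(p_c, p_d)` grid cell, of the selected and false
#' SNP counts, the FDR, the per-exposure association counts and the
#' per-exposure multivariable estimates and p-values. Cells where a
#' replicate produced no fit average over the non-missing replicates. The
#' input per-replicate rows are retained in attribute `"replicates"`.
#'
#' @param rep_results A data.frame of per-replicate per-cell rows as built
#'   by [run_simulation_grid()].
#' @return The averaged `SimSummary` data.frame.
#' @export
summarize_replicates <- function(rep_results) {
  stopifnot(nrow(rep_results) >= 1)
  num_cols <- setdiff(names(rep_results)[vapply(rep_results, is.numeric,
                                                logical(1))],
                      c("p_c", "p_d", "replicate"))
  agg <- stats::aggregate(rep_results[num_cols],
                          by = rep_results[c("p_c", "p_d")],
                          FUN = function(x) mean(x, na.rm = TRUE))
  agg <- agg[order(agg$p_c, agg$p_d), ]
  rownames(agg) <- NULL
  attr(agg, "replicates") <- rep_results
  agg
}
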