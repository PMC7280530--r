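#' Run the end-to-end MR pipeline
#'
#' Sequences the analysis stages on a merged summary table: instrument
#' selection, allele harmonization, shared/unique dissection, the MR
#' estimator suite on the total, shared and unique instrument subsets, and
#' optionally the null-embedding simulation. Output is a pure function of
#' `(merged, arguments, seed)`.
#'
#' When `out_dir` is given, one tab-separated file per stage is written
#' (`selected.tsv`, `beta_table.tsv`, `venn.tsv`, `mr_results.tsv`,
#' `sim_summary.tsv` when simulated) plus a `manifest.tsv` of key-value
#' provenance (thresholds, seed, row counts, package version).
#'
#' @param merged A merged table from [merge_by_snpid()] or
#'   [generate_mother_data()].
#' @param th Selection [thresholds()].
#' @param partition_p Association cutoff for the shared/unique dissection.
#' @param methods Estimators to run (see [mr_all()]).
#' @param sim Optional [nullsim_config()]; when given, the simulation is
#'   run with the selected instruments as the embedded test set.
#' @param out_dir Optional output directory (created if needed).
#' @param seed Seed for the median bootstrap streams.
#' @param n_boot Bootstrap resamples for the median estimators.
#' @return A list: `selected`, `beta_table`, `partition`, `results`
#'   (stacked estimate rows with a `subset` column), `sim_summary` (or
#'   `NULL`), `manifest`.
#' @export
run_mr_pipeline <- function(merged, th = thresholds(),
                            partition_p = 5e-08,
                            methods = c("ivw", "simple_median",
                                        "weighted_median", "egger", "mvmr"),
                            sim = NULL, out_dir = NULL, seed = 1,
                            n_boot = 10000) {
  stage <- "selection"
  res <- tryCatch({
    selected <- select_instruments(merged, th)
    if (nrow(selected) < 4)
      stop("only ", nrow(selected), " instruments selected")
    stage <- "harmonization"
    bt <- build_beta_table(selected)
    stage <- "partition"
    part <- partition_shared_unique(classify_associations(bt, partition_p))
    stage <- "mr"
    subsets <- list(total = bt,
                    shared = bt[bt$snp_id %in% part$shared, ],
                    unique = bt[bt$snp_id %in% part$unique, ])
    results <- do.call(rbind, lapply(names(subsets), function(s) {
      tab <- subsets[[s]]
      if (nrow(tab) < 4)
        return(NULL)
      mr_all(tab, methods = methods, subset = s, n_boot = n_boot,
             seed = seed)
    }))
    stage <- "simulation"
    sim_summary <- if (!is.null(sim))
      run_simulation_grid(merged, bt, sim) else NULL
    list(selected = selected, beta_table = bt, partition = part,
         results = results, sim_summary = sim_summary)
  }, error = function(e) {
    stop("run_mr_pipeline: stage '", stage, "' failed: ",
         conditionMessage(e), call. = FALSE)
  })
  res$manifest <- data.frame(
    key = c("p_v", "p_c", "p_d", "ail", "partition_p", "seed", "n_input",
            "n_selected", "n_shared", "n_unique", "package_version"),
    value = c(th$p_v, th$p_c, th$p_d, th$ail, partition_p, seed,
              nrow(merged), nrow(res$selected), length(res$partition$shared),
              length(res$partition$unique),
              as.character(utils::packageVersion("mrdissect"))),
    stringsAsFactors = FALSE
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_gwas_table(res$selected, file.path(out_dir, "selected.tsv"))
    write_gwas_table(res$beta_table, file.path(out_dir, "beta_table.tsv"))
    venn <- data.frame(region = names(res$partition$venn),
                       count = as.integer(res$partition$venn))
    write.table(venn, file.path(out_dir, "venn.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(res$results, file.path(out_dir, "mr_results.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(res$sim_summary))
      write.table(res$sim_summary, file.path(out_dir, "sim_summary.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(res$manifest, file.path(out_dir, "manifest.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  res
}
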