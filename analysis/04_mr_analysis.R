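#!/usr/bin/env Rscript
# The causal-estimator suite on the total, shared and unique instrument
# subsets: IVW, simple/weighted median, MR-Egger per lipid fraction, and
# the multivariable model, with odds-ratio forest tables. Then the two
# recovery experiments: how well the multivariable model recovers the
# planted causal effects, and the spurious-triglyceride mechanism (TG
# flagged by single-variable MR through HDL-TG pleiotropy, cleared by the
# unique-subset multivariable model).

source("analysis/00_common.R")

bundle <- run_mr_pipeline(get_mother()$table, th = ANALYSIS_THRESHOLDS,
                          seed = ANALYSIS_SEED)
res <- bundle$results
print(res[res$method == "mvmr",
          c("subset", "exposure", "n_snps", "beta", "se", "p", "or",
            "ci_low", "ci_high")], digits = 3)
tg <- res[res$exposure == "tg" & res$method %in% c("ivw", "mvmr"), ]
message("triglycerides across subsets and methods:")
print(tg[, c("method", "subset", "beta", "p")], digits = 3)
write_tsv(res, "results/04_mr_results.tsv")

rec <- recovery_experiment(synth_config(), replicates = 20,
                           seed = ANALYSIS_SEED + 1)
message("multivariable recovery of the planted causal vector (20 replicates):")
print(rec$summary, digits = 3)
write_tsv(rec$summary, "results/04_recovery.tsv")

tgc <- tg_confounding_experiment(replicates = 20, seed = ANALYSIS_SEED + 2)
message(sprintf("spurious-TG mechanism: full-set IVW flags TG in %.0f%% of replicates; unique-subset MVMR clears it in %.0f%%",
                100 * tgc$rates[["ivw_flags_tg"]],
                100 * tgc$rates[["mvmr_clears_tg"]]))
write_tsv(tgc$per_replicate, "results/04_tg_confounding.tsv")
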