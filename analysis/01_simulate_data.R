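#!/usr/bin/env Rscript
# Generate the synthetic mother dataset: a merged lipid/CAD GWAS
# summary-statistic table of 20,000 SNPs emulating the structure of a
# metabochip lipid meta-analysis joined to a CAD case-control GWAS.
# 338 SNPs are truly associated with LDL-c, HDL-c and/or TG (the published
# 338-instrument Venn architecture), the outcome log odds follow the
# planted causal vector theta = (0.4, -0.3, 0), and HDL/TG effects of
# shared SNPs are strongly discordant.

source("analysis/00_common.R")

mother <- get_mother()
tab <- mother$table

message(sprintf("mother table: %d SNPs x %d columns", nrow(tab), ncol(tab)))
message(sprintf("truly associated SNPs: %d (planted theta: ldl %.2f, hdl %.2f, tg %.2f)",
                nrow(mother$truth$membership), mother$truth$theta[["ldl"]],
                mother$truth$theta[["hdl"]], mother$truth$theta[["tg"]]))

# per-trait summary of the generated table
summ <- do.call(rbind, lapply(c("ldl", "hdl", "tg", "cad"), function(tr) {
  data.frame(trait = tr,
             mean_beta = mean(tab[[paste0("beta_", tr)]]),
             sd_beta = sd(tab[[paste0("beta_", tr)]]),
             median_se = median(tab[[paste0("se_", tr)]]),
             mean_n = mean(tab[[paste0("n_", tr)]]),
             n_genomewide = sum(tab[[paste0("p_", tr)]] <= 5e-08))
}))
print(summ, digits = 3)
write_tsv(summ, "results/01_mother_summary.tsv")

# full table to scratch for interactive inspection (bulk, regenerable)
write_gwas_table(tab, "scratch/mother.tsv")
write_tsv(mother$truth$membership, "scratch/truth_membership.tsv")
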