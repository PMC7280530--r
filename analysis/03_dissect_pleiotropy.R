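#!/usr/bin/env Rscript
# Harmonize the selected instruments to the outcome reference allele and
# dissect them into shared (pleiotropic: associated with two or more lipid
# fractions) and unique (single-fraction) subsets, with Venn counts and
# the per-fraction genotype-class variance ratio.

source("analysis/00_common.R")

sel <- get_selected()
bt <- build_beta_table(sel)
message(sprintf("harmonized %d instruments; %d exposure records sign-flipped; %d palindromic",
                nrow(bt), sum(bt$flipped_ldl) + sum(bt$flipped_hdl) +
                  sum(bt$flipped_tg), sum(bt$palindromic)))

part <- partition_shared_unique(classify_associations(bt, 5e-08))
venn <- data.frame(region = names(part$venn),
                   count = as.integer(part$venn))
print(venn)
message(sprintf("shared: %d  unique: %d (ldl %d, hdl %d, tg %d)",
                length(part$shared), length(part$unique),
                length(part$unique_ldl), length(part$unique_hdl),
                length(part$unique_tg)))
write_tsv(venn, "results/03_venn.tsv")

r2 <- do.call(rbind, lapply(c("ldl", "hdl", "tg"), function(tr) {
  memb_ids <- part$membership$snp_id[part$membership[[tr]]]
  rows <- bt[bt$snp_id %in% memb_ids, ]
  data.frame(exposure = tr, n_snps = nrow(rows),
             r_squared = r_squared(rows[[paste0("beta_", tr)]],
                                   rows[[paste0("a1_", tr)]],
                                   rows[[paste0("a2_", tr)]]))
}))
print(r2, digits = 3)
write_tsv(r2, "results/03_r_squared.tsv")

write_gwas_table(bt, "scratch/beta_table.tsv")
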