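# Shared setup for the analysis drivers. Every driver is independently
# runnable from the repository root: the synthetic mother dataset is
# regenerated deterministically from ANALYSIS_SEED instead of being passed
# between scripts as a bulk file.

suppressPackageStartupMessages(library(mrdissect))

ANALYSIS_SEED <- 2026

dir.create("results", showWarnings = FALSE)
dir.create("scratch", showWarnings = FALSE)

get_mother <- function() generate_mother_data(synth_config(),
                                              seed = ANALYSIS_SEED)

# Operating point used throughout the downstream analyses: genome-wide
# stage-1 threshold, mild sample-size-proportion filtering, no distance
# thinning (the synthetic SNPs carry no linkage).
ANALYSIS_THRESHOLDS <- thresholds(p_v = 5e-08, p_c = 0.9, p_d = 0.9,
                                  ail = 0)

get_selected <- function(mother = get_mother())
  select_instruments(mother$table, ANALYSIS_THRESHOLDS)

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  message("  wrote ", path)
}
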