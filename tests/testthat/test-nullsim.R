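make_mother <- function(seed = 51) generate_mother_data(small_synth(),
                                                        seed = seed)$table

test_that("null profiles honor the p floor, allele multisets and moments", {
  mother <- make_mother()
  set.seed(5)
  null <- build_null_profiles(mother, p_low = 1e-07)
  expect_equal(nrow(null), nrow(mother))
  for (tr in c("ldl", "hdl", "tg", "cad")) {
    expect_gte(min(null[[paste0("p_", tr)]]), 1e-07)
    # permutation preserves each trait's allele-pair multiset
    expect_equal(sort(paste(null[[paste0("a1_", tr)]],
                            null[[paste0("a2_", tr)]])),
                 sort(paste(mother[[paste0("a1_", tr)]],
                            mother[[paste0("a2_", tr)]])))
    expect_true(all(null[[paste0("n_", tr)]] >= 1))
    expect_true(all(null[[paste0("n_", tr)]] ==
                      round(null[[paste0("n_", tr)]])))
    # moment matching within 3 standard errors
    M <- nrow(null)
    mb <- mother[[paste0("beta_", tr)]]; nb <- null[[paste0("beta_", tr)]]
    expect_lt(abs(mean(nb) - mean(mb)), 3 * sd(mb) / sqrt(M))
    expect_lt(abs(sd(nb) - sd(mb)), 3 * sd(mb) / sqrt(M))
  }
  expect_true(all(null$chrom %in% as.character(1:22)))
})

test_that("embedding breaks pleiotropy while preserving per-row tuples", {
  mother <- make_mother()
  test_set <- select_instruments(mother, thresholds())
  set.seed(9)
  null <- build_null_profiles(mother, p_low = 1e-07)
  emb <- suppressWarnings(embed_test_set(null, test_set))
  memb <- classify_associations(test_set)
  n_placements <- sum(memb$ldl) + sum(memb$hdl) + sum(memb$tg)
  expect_equal(nrow(emb$truth), n_placements)
  expect_equal(sum(emb$table$is_test), n_placements)  # distinct rows

  # a single-exposure SNP lands once; a triple SNP three times
  k <- rowSums(memb[, c("ldl", "hdl", "tg")])
  placed <- table(emb$truth$source)
  expect_equal(unname(placed[memb$snp_id[which(k == 1)[1]]]), 1L)
  if (any(k == 3))
    expect_equal(unname(placed[memb$snp_id[which(k == 3)[1]]]), 3L)

  # the (exposure, outcome) tuple of each placement is carried unchanged
  for (i in sample(nrow(emb$truth), 10)) {
    row <- emb$truth$row[i]; tr <- emb$truth$exposure[i]
    src <- which(test_set$snp_id == emb$truth$source[i])
    for (f in c("beta", "se", "p", "n", "a1", "a2")) {
      expect_identical(emb$table[row, paste(f, tr, sep = "_")],
                       test_set[src, paste(f, tr, sep = "_")])
      expect_identical(emb$table[row, paste0(f, "_cad")],
                       test_set[src, paste0(f, "_cad")])
    }
  }

  # empty test set embeds nothing
  e0 <- embed_test_set(null, test_set[0, ])
  expect_equal(sum(e0$table$is_test), 0)
})

test_that("the FDR is a direct false-fraction with a defined empty case", {
  expect_equal(compute_fdr(rep(TRUE, 10)), 0)
  expect_equal(compute_fdr(c(rep(TRUE, 7), rep(FALSE, 3))), 0.3)
  expect_equal(compute_fdr(sprintf("s%d", 1:10), sprintf("s%d", 1:7)), 0.3)
  expect_warning(f0 <- compute_fdr(logical(0)), "empty")
  expect_equal(f0, 0)
  set.seed(14)
  for (i in 1:5) {
    lab <- runif(50) < 0.6
    expect_equal(compute_fdr(lab), sum(!lab) / 50)
  }
})

test_that("no null SNP survives when the p floor exceeds the cutoff", {
  mother <- make_mother()
  test_set <- select_instruments(mother, thresholds())
  for (seed in c(3, 17, 29)) {
    cfg <- nullsim_config(p_low = 1e-07, p_v = 5e-08,
                          grid_pc = c(0.5, 0.9), grid_pd = c(0.5, 0.9),
                          replicates = 2, seed = seed)
    ss <- suppressWarnings(run_simulation_grid(mother, test_set, cfg))
    expect_true(all(ss$fdr == 0))
    expect_true(all(ss$n_false == 0))
    expect_true(any(ss$n_selected > 0))
  }
  # and with no embedding the selection is empty
  cfg <- nullsim_config(p_low = 1e-07, grid_pc = 0.5, grid_pd = 0.5,
                        replicates = 1, seed = 1)
  ss0 <- suppressWarnings(run_simulation_grid(mother, mother[0, ], cfg))
  expect_equal(ss0$n_selected, 0)
})

test_that("null SNPs leak in, and more so at laxer cutoffs, when they can pass", {
  mother <- make_mother()
  test_set <- select_instruments(mother, thresholds())
  # a stage-1 cutoff inside the null support lets background SNPs through
  cfg <- nullsim_config(p_low = 1e-12, p_v = 1e-03,
                        grid_pc = 0, grid_pd = 0, replicates = 4, seed = 8)
  ss <- suppressWarnings(run_simulation_grid(mother, test_set, cfg))
  expect_gt(ss$fdr, 0)
  # tightening the stage-1 cutoff admits fewer background SNPs
  cfg2 <- nullsim_config(p_low = 1e-12, p_v = 1e-05,
                         grid_pc = 0, grid_pd = 0, replicates = 4, seed = 8)
  ss2 <- suppressWarnings(run_simulation_grid(mother, test_set, cfg2))
  expect_lt(ss2$fdr, ss$fdr)
})

test_that("the simulation is bit-reproducible for a fixed seed and config", {
  mother <- make_mother()
  test_set <- select_instruments(mother, thresholds())
  cfg <- nullsim_config(p_low = 1e-07, grid_pc = c(0.5, 0.9),
                        grid_pd = 0.9, replicates = 2, seed = 77)
  s1 <- suppressWarnings(run_simulation_grid(mother, test_set, cfg))
  s2 <- suppressWarnings(run_simulation_grid(mother, test_set, cfg))
  expect_identical(s1, s2)
})

test_that("replicate summaries are plain arithmetic means per cell", {
  rep1 <- data.frame(p_c = c(0.9, 0.9), p_d = c(0.9, 0.95),
                     replicate = 1, n_selected = c(10, 6),
                     fdr = c(0.1, 0.5))
  # a single replicate summarizes to itself
  s1 <- summarize_replicates(rep1)
  expect_equal(s1$fdr, c(0.1, 0.5))
  # identical replicates: same mean, zero spread
  reps <- rbind(rep1, transform(rep1, replicate = 2))
  s2 <- summarize_replicates(reps)
  expect_equal(s2$fdr, c(0.1, 0.5))
  expect_equal(s2$n_selected, c(10, 6))
  # random replicate sets vs a direct mean
  set.seed(4)
  r3 <- do.call(rbind, lapply(1:4, function(r)
    data.frame(p_c = 0.9, p_d = 0.9, replicate = r, n_selected = r,
               fdr = runif(1))))
  s3 <- summarize_replicates(r3)
  expect_equal(s3$fdr, mean(r3$fdr))
  expect_equal(s3$n_selected, 2.5)
})
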