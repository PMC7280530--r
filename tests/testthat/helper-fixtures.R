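# Code-built fixtures shared across test files.

# A minimal valid trait data.frame (canonical column names).
make_trait_df <- function(ids, beta, p, n = 1e5, a1 = "A", a2 = "G",
                          se = NULL, chrom = "1",
                          pos = seq(1e6, by = 1e6,
                                    length.out = length(ids))) {
  df <- data.frame(snp_id = ids, chrom = chrom, pos = pos,
                   a1 = a1, a2 = a2, beta = beta, p = p, n = n,
                   stringsAsFactors = FALSE)
  if (!is.null(se)) df$se <- se
  df
}

# A small deterministic merged table with consistent alleles and SEs.
tiny_merged <- function(n = 6, seed = 99) {
  with_seed <- get("with_seed", envir = asNamespace("mrdissect"))
  with_seed(seed, {
    ids <- sprintf("rs%03d", seq_len(n))
    tab <- data.frame(snp_id = ids, chrom = rep("1", n),
                      pos = seq(1e6, by = 5e5, length.out = n),
                      stringsAsFactors = FALSE)
    for (tr in c("ldl", "hdl", "tg", "cad")) {
      beta <- round(stats::rnorm(n, 0, 0.1), 4)
      se <- round(stats::runif(n, 0.01, 0.05), 4)
      tab[[paste0("beta_", tr)]] <- beta
      tab[[paste0("se_", tr)]] <- se
      tab[[paste0("p_", tr)]] <- 2 * stats::pnorm(-abs(beta / se))
      tab[[paste0("n_", tr)]] <- sample(5e4:1e5, n)
      tab[[paste0("a1_", tr)]] <- rep("A", n)
      tab[[paste0("a2_", tr)]] <- rep("G", n)
    }
    tab
  })
}

# A small synthetic-architecture config that keeps tests fast.
small_synth <- function(...) {
  synth_config(M = 4000,
               n_unique = c(ldl = 25, hdl = 30, tg = 25),
               n_pairs = c(ldl_hdl = 1, ldl_tg = 6, hdl_tg = 15),
               n_triple = 5, ...)
}

# Independent weighted-least-squares oracle via explicit normal equations.
wls_oracle <- function(X, y, w) {
  A <- t(X * w) %*% X
  b <- t(X * w) %*% y
  est <- solve(A, b)
  resid <- y - X %*% est
  df <- nrow(X) - ncol(X)
  sigma2 <- sum(w * resid^2) / df
  se <- sqrt(diag(solve(A)) * sigma2)
  list(est = as.numeric(est), se = as.numeric(se), df = df)
}
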