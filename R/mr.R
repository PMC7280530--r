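#' Convert a log-scale effect to an odds ratio with 95% CI
#'
#' @param beta Effect on the log-odds scale.
#' @param se Standard error of `beta` (>= 0).
#' @return A data.frame with `or`, `ci_low`, `ci_high`:
#'   `exp(beta)` and `exp(beta -/+ 1.959964 * se)`.
#' @examples
#' to_or_ci(0.396, 0.034)
#' @export
to_or_ci <- function(beta, se) {
  stopifnot(all(se >= 0))
  z <- 1.959964
  data.frame(or = exp(beta), ci_low = exp(beta - z * se),
             ci_high = exp(beta + z * se))
}

mr_estimate <- function(method, exposure, n_snps, beta, se, p) {
  ci <- to_or_ci(beta, se)
  data.frame(method = method, exposure = exposure, n_snps = n_snps,
              beta = beta, se = se, p = p,
              or = ci$or, ci_low = ci$ci_low, ci_high = ci$ci_high,
              stringsAsFactors = FALSE)
}

#' Inverse-variance-weighted estimator
#'
#' Slope of the no-intercept regression of the outcome effects `by` on the
#' exposure effects `bx`, weighted by the inverse outcome variances
#' `1/sy^2`. The causal effect of a unit (1 SD) change of the exposure on
#' the outcome log odds. SE and two-sided p come from the weighted fit
#' (t distribution, `n - 1` df); with a single instrument the estimator
#' degenerates to the Wald ratio `by/bx` with delta-method SE `sy/|bx|`.
#'
#' @param bx,by Exposure and outcome per-SNP effect estimates.
#' @param sy Outcome standard errors (> 0).
#' @param exposure Label recorded in the result row.
#' @return A one-row estimate data.frame (`method, exposure, n_snps, beta,
#'   se, p, or, ci_low, ci_high`).
#' @export
mr_ivw <- function(bx, by, sy, exposure = "exposure") {
  stopifnot(length(bx) >= 1, length(bx) == length(by),
            length(bx) == length(sy), all(sy > 0))
  if (all(bx == 0)) stop("mr_ivw: all exposure effects are zero; ",
                         "the slope is not identifiable")
  n <- length(bx)
  if (n == 1) {
    beta <- by / bx
    se <- sy / abs(bx)
    p <- 2 * pnorm(-abs(beta / se))
    return(mr_estimate("ivw", exposure, 1, beta, se, p))
  }
  fit <- lm(by ~ 0 + bx, weights = 1 / sy^2)
  cf <- summary(fit)$coefficients
  beta <- cf[1, 1]; se <- cf[1, 2]
  p <- 2 * pt(-abs(beta / se), df = n - 1)
  mr_estimate("ivw", exposure, n, beta, se, p)
}

#' MR-Egger regression
#'
#' Weighted regression of outcome on exposure effects *with* an intercept,
#' after orienting every SNP so its exposure effect is non-negative (the
#' outcome effect is flipped together with it). The slope is the causal
#' estimate; a non-zero intercept indicates directional (unbalanced)
#' horizontal pleiotropy. Weights are `1/sy^2`; SEs and two-sided p-values
#' use the t distribution with `n - 2` df.
#'
#' @inheritParams mr_ivw
#' @return A list with elements `slope` and `intercept`, each a one-row
#'   estimate data.frame (the intercept's `or` columns are on the exp scale
#'   of the intercept and are of diagnostic use only).
#' @export
mr_egger <- function(bx, by, sy, exposure = "exposure") {
  n <- length(bx)
  if (n < 3) stop("mr_egger: at least 3 instruments are required")
  stopifnot(length(by) == n, length(sy) == n, all(sy > 0))
  s <- ifelse(bx < 0, -1, 1)
  bx <- bx * s; by <- by * s
  fit <- lm(by ~ bx, weights = 1 / sy^2)
  cf <- summary(fit)$coefficients
  pvals <- 2 * pt(-abs(cf[, 1] / cf[, 2]), df = n - 2)
  list(
    slope = mr_estimate("egger", exposure, n, cf["bx", 1], cf["bx", 2],
                        pvals["bx"]),
    intercept = mr_estimate("egger_intercept", exposure, n,
                            cf["(Intercept)", 1], cf["(Intercept)", 2],
                            pvals["(Intercept)"])
  )
}

# Weighted median of `x` with weights `w`: linear interpolation of the
# standardized cumulative weight (cum - w/2)/sum(w) at the 50% point.
weighted_median_point <- function(x, w) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  s <- (cumsum(w) - w / 2) / sum(w)
  if (s[1] >= 0.5) return(x[1])
  n <- length(x)
  if (s[n] <= 0.5) return(x[n])
  k <- max(which(s <= 0.5))
  if (s[k] == 0.5) return(x[k])
  x[k] + (x[k + 1] - x[k]) * (0.5 - s[k]) / (s[k + 1] - s[k])
}

boot_se <- function(stat, n, n_boot, seed) {
  with_seed(seed, {
    reps <- vapply(seq_len(n_boot),
                   function(i) stat(sample.int(n, n, replace = TRUE)),
                   numeric(1))
    sd(reps)
  })
}

#' Simple median estimator
#'
#' Median of the per-SNP Wald ratios `by/bx` (midpoint of the two central
#' ratios for even counts). The SE is estimated by a seeded nonparametric
#' bootstrap over SNPs; the p-value is the normal two-sided p for
#' `beta/se`.
#'
#' @inheritParams mr_ivw
#' @param n_boot Bootstrap resamples for the SE (default 10000).
#' @param seed Seed for the bootstrap stream (restored afterwards).
#' @return A one-row estimate data.frame.
#' @export
mr_simple_median <- function(bx, by, sy = NULL, exposure = "exposure",
                             n_boot = 10000, seed = 1) {
  n <- length(bx)
  if (n < 3) stop("mr_simple_median: at least 3 instruments are required")
  if (any(bx == 0)) stop("mr_simple_median: zero exposure effect makes a ",
                         "ratio undefined")
  r <- by / bx
  beta <- median(r)
  se <- boot_se(function(idx) median(r[idx]), n, n_boot, seed)
  p <- 2 * pnorm(-abs(beta / se))
  mr_estimate("simple_median", exposure, n, beta, se, p)
}

#' Weighted median estimator
#'
#' Weighted median of the per-SNP Wald ratios, with weights proportional to
#' `(bx/sy)^2` (the inverse of the ratio's leading-order variance) and
#' linear interpolation of the standardized cumulative weight at the 50%
#' point. Reduces to [mr_simple_median()] under equal weights. SE by seeded
#' bootstrap, as for the simple median.
#'
#' @inheritParams mr_simple_median
#' @export
mr_weighted_median <- function(bx, by, sy, exposure = "exposure",
                               n_boot = 10000, seed = 1) {
  n <- length(bx)
  if (n < 3) stop("mr_weighted_median: at least 3 instruments are required")
  if (any(bx == 0)) stop("mr_weighted_median: zero exposure effect makes a ",
                         "ratio undefined")
  stopifnot(length(sy) == n, all(sy > 0))
  r <- by / bx
  w <- (bx / sy)^2
  beta <- weighted_median_point(r, w)
  se <- boot_se(function(idx) weighted_median_point(r[idx], w[idx]),
                n, n_boot, seed)
  p <- 2 * pnorm(-abs(beta / se))
  mr_estimate("weighted_median", exposure, n, beta, se, p)
}

#' Multivariable MR
#'
#' Joint regression of the outcome effects on the three exposures' effect
#' columns across instruments: by default a weighted (`1/se_cad^2`),
#' no-intercept fit, so that with a single exposure it reduces exactly to
#' [mr_ivw()]. Per-exposure t-tests (df = n - k - intercept) give the
#' p-values. Including several exposures jointly adjusts each effect for
#' the instruments' associations with the other exposures, which is what
#' separates genuine causal effects from pleiotropy-driven ones.
#'
#' @param beta_table A harmonized table from [build_beta_table()].
#' @param exposures Exposure columns to include (default all three lipids).
#' @param weighted Use `1/se_cad^2` weights (default `TRUE`).
#' @param intercept Include an intercept (default `FALSE`).
#' @return An estimate data.frame with one row per exposure, `method =
#'   "mvmr"`.
#' @export
mr_mvmr <- function(beta_table, exposures = .EXPOSURES, weighted = TRUE,
                    intercept = FALSE) {
  n <- nrow(beta_table)
  k <- length(exposures) + as.integer(intercept)
  if (n < max(4, k + 1)) stop("mr_mvmr: need at least ", max(4, k + 1),
                              " instruments, got ", n)
  X <- as.matrix(beta_table[, paste0("beta_", exposures), drop = FALSE])
  y <- beta_table$beta_cad
  w <- if (weighted) 1 / beta_table$se_cad^2 else rep(1, n)
  Xw <- sweep(cbind(if (intercept) 1, X), 1, sqrt(w), `*`)
  if (qr(Xw)$rank < k) {
    stop("mr_mvmr: collinear exposure effect columns among: ",
         paste(exposures, collapse = ", "))
  }
  fm <- if (intercept) y ~ X else y ~ 0 + X
  fit <- lm(fm, weights = w)
  cf <- summary(fit)$coefficients
  rows <- seq_along(exposures) + as.integer(intercept)  # column order
  est <- cf[rows, 1]; se <- cf[rows, 2]
  p <- 2 * pt(-abs(est / se), df = n - k)
  out <- mr_estimate("mvmr", exposures, n, unname(est), unname(se),
                     unname(p))
  rownames(out) <- NULL
  out
}

#' Genotype-class variance ratio
#'
#' Groups one exposure's per-SNP effect estimates by allele-pair class
#' (constructed from alleles 1 and 2) and returns the share of the total
#' variance explained by the classes: the one-way ANOVA decomposition
#' `R^2 = SS_between / SS_total`, in \[0, 1\].
#'
#' @param beta Per-SNP effect estimates for one exposure.
#' @param a1,a2 Allele vectors defining the genotype classes.
#' @return The variance ratio.
#' @export
r_squared <- function(beta, a1, a2) {
  cls <- paste(a1, a2, sep = "/")
  if (length(unique(cls)) < 2)
    stop("r_squared: need at least 2 distinct genotype classes")
  sst <- sum((beta - mean(beta))^2)
  if (sst == 0) stop("r_squared: zero total variance; ratio undefined")
  mu <- tapply(beta, cls, mean)
  sse <- sum((beta - mu[cls])^2)
  (sst - sse) / sst
}

#' Run the estimator suite on a harmonized table
#'
#' Applies the requested single-variable methods to each exposure and the
#' multivariable model to all three jointly, returning one combined result
#' table (the MR-Egger intercept rows are labeled `egger_intercept`).
#'
#' @param beta_table A harmonized table.
#' @param methods Any of `"ivw"`, `"simple_median"`, `"weighted_median"`,
#'   `"egger"`, `"mvmr"`.
#' @param subset Provenance label stored in the `subset` column.
#' @param n_boot,seed Bootstrap controls for the median methods.
#' @return An estimate data.frame.
#' @export
mr_all <- function(beta_table,
                   methods = c("ivw", "simple_median", "weighted_median",
                               "egger", "mvmr"),
                   subset = "total", n_boot = 10000, seed = 1) {
  methods <- match.arg(methods, several.ok = TRUE)
  res <- list()
  for (tr in .EXPOSURES) {
    bx <- beta_table[[paste0("beta_", tr)]]
    by <- beta_table$beta_cad
    sy <- beta_table$se_cad
    if ("ivw" %in% methods)
      res <- c(res, list(mr_ivw(bx, by, sy, tr)))
    if ("simple_median" %in% methods)
      res <- c(res, list(mr_simple_median(bx, by, sy, tr, n_boot, seed)))
    if ("weighted_median" %in% methods)
      res <- c(res, list(mr_weighted_median(bx, by, sy, tr, n_boot, seed)))
    if ("egger" %in% methods) {
      eg <- mr_egger(bx, by, sy, tr)
      res <- c(res, list(eg$slope, eg$intercept))
    }
  }
  if ("mvmr" %in% methods)
    res <- c(res, list(mr_mvmr(beta_table)))
  out <- do.call(rbind, res)
  out$subset <- subset
  rownames(out) <- NULL
  out
}
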