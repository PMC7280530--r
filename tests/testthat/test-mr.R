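test_that("odds-ratio conversion matches the log-scale closed form", {
  z <- to_or_ci(0, 0.1)
  expect_equal(z$or, 1)
  expect_equal(z$ci_low * z$ci_high, 1, tolerance = 1e-12)  # log-symmetric
  expect_equal(to_or_ci(0.396, 0.03)$or, 1.486, tolerance = 2e-3)
  expect_equal(to_or_ci(-0.315, 0.03)$or, 0.729, tolerance = 2e-3)
})

test_that("IVW equals the closed-form weighted regression through the origin", {
  # single instrument: the Wald ratio
  e1 <- mr_ivw(0.5, 0.25, 0.1)
  expect_equal(e1$beta, 0.5)
  expect_equal(e1$se, 0.1 / 0.5)

  # identical per-SNP ratios give that ratio under any weights
  bx <- c(0.2, 0.5, 0.8); r <- 0.37
  e2 <- mr_ivw(bx, r * bx, c(0.1, 0.02, 0.3))
  expect_equal(e2$beta, r, tolerance = 1e-12)

  expect_error(mr_ivw(c(0, 0), c(0.1, 0.2), c(0.1, 0.1)),
               "not identifiable")

  # random instances vs the normal-equations oracle
  set.seed(11)
  for (i in 1:50) {
    n <- sample(4:30, 1)
    bx <- rnorm(n, 0, 0.2); by <- 0.4 * bx + rnorm(n, 0, 0.05)
    sy <- runif(n, 0.01, 0.1)
    est <- mr_ivw(bx, by, sy)
    o <- wls_oracle(matrix(bx), by, 1 / sy^2)
    expect_equal(est$beta, o$est, tolerance = 1e-10)
    expect_equal(est$se, o$se, tolerance = 1e-10)
    expect_equal(est$p, 2 * pt(-abs(o$est / o$se), df = n - 1),
                 tolerance = 1e-10)
  }
})

test_that("Egger regression fits an intercept after orienting instruments", {
  # three oriented points on y = 0.1 + 0.4 x: exact affine fit
  bx <- c(0.2, 0.5, 0.8); by <- 0.1 + 0.4 * bx
  # zero-residual fixture: lm warns that the fit is exact
  eg <- suppressWarnings(mr_egger(bx, by, rep(0.1, 3)))
  expect_equal(eg$slope$beta, 0.4, tolerance = 1e-10)
  expect_equal(eg$intercept$beta, 0.1, tolerance = 1e-10)

  # adding a constant to every by shifts only the intercept
  set.seed(4)
  bx <- rnorm(10, 0.3, 0.2); by <- 0.1 * bx + rnorm(10, 0, 0.02)
  sy <- runif(10, 0.01, 0.1)
  e0 <- mr_egger(bx, by, sy)
  e1 <- mr_egger(bx, by + 0.05 * sign(bx), sy)  # constant after orientation
  expect_equal(e1$slope$beta, e0$slope$beta, tolerance = 1e-10)
  expect_equal(e1$intercept$beta, e0$intercept$beta + 0.05,
               tolerance = 1e-10)

  expect_error(mr_egger(bx[1:2], by[1:2], sy[1:2]), "at least 3")

  # random instances vs the two-column normal-equations oracle
  for (i in 1:50) {
    n <- sample(5:30, 1)
    bx <- rnorm(n, 0, 0.3); by <- 0.05 + 0.3 * bx + rnorm(n, 0, 0.05)
    sy <- runif(n, 0.01, 0.1)
    s <- ifelse(bx < 0, -1, 1)
    o <- wls_oracle(cbind(1, bx * s), by * s, 1 / sy^2)
    eg <- mr_egger(bx, by, sy)
    expect_equal(eg$intercept$beta, o$est[1], tolerance = 1e-10)
    expect_equal(eg$slope$beta, o$est[2], tolerance = 1e-10)
    expect_equal(eg$slope$se, o$se[2], tolerance = 1e-10)
  }
})

test_that("median estimators follow the order-statistic conventions", {
  bx <- rep(1, 3)
  expect_equal(mr_simple_median(bx, c(0.1, 0.5, 0.9), n_boot = 50)$beta, 0.5)
  # even count: midpoint of the two central ratios
  expect_equal(mr_simple_median(rep(1, 4), c(0.1, 0.2, 0.4, 0.9),
                                n_boot = 50)$beta, 0.3)
  expect_error(mr_simple_median(c(1, 0, 1), c(1, 1, 1), n_boot = 10),
               "zero exposure")

  # equal weights reduce the weighted median to the simple median
  by <- c(0.12, 0.55, 0.31, 0.77)
  sm <- mr_simple_median(rep(1, 4), by, n_boot = 50, seed = 5)
  wm <- mr_weighted_median(rep(1, 4), by, rep(0.1, 4), n_boot = 50, seed = 5)
  expect_equal(wm$beta, sm$beta)

  # a SNP whose weight interval crosses 50% exactly returns its own ratio
  bx <- c(0.1, 0.8, 0.1); sy <- rep(0.1, 3)  # weights prop to (1, 64, 1)/...
  by <- c(0.01, 0.4, 0.09)                   # ratios 0.1, 0.5, 0.9
  wm2 <- mr_weighted_median(bx, by, sy, n_boot = 50)
  expect_equal(wm2$beta, 0.5)

  # interpolation oracle: expand integer-scaled weights and take a median
  set.seed(9)
  for (i in 1:20) {
    n <- sample(4:15, 1)
    bx <- runif(n, 0.1, 1); by <- rnorm(n, 0.3, 0.2) * bx
    sy <- runif(n, 0.05, 0.2)
    wm <- mr_weighted_median(bx, by, sy, n_boot = 10)
    r <- by / bx; w <- (bx / sy)^2
    # the interpolated value must sit within one ratio of the step median
    o <- order(r); rs <- r[o]; cw <- cumsum(w[o]) / sum(w)
    k <- which(cw >= 0.5)[1]
    expect_gte(wm$beta, rs[max(1, k - 1)])
    expect_lte(wm$beta, rs[min(n, k + 1)])
    # and near the median of an integer-expanded weight approximation
    expanded <- rep(rs, pmax(round(w[o] / sum(w) * 1e5), 1))
    expect_lt(abs(wm$beta - median(expanded)),
              max(diff(rs)) + 1e-12)
  }
})

test_that("bootstrap SEs stabilize across seeds at 10,000 resamples", {
  set.seed(12)
  bx <- runif(25, 0.2, 1); by <- 0.3 * bx + rnorm(25, 0, 0.1)
  sy <- runif(25, 0.05, 0.15)
  s1 <- mr_simple_median(bx, by, seed = 1)$se
  s2 <- mr_simple_median(bx, by, seed = 2)$se
  expect_lt(abs(s1 - s2) / s1, 0.1)
  w1 <- mr_weighted_median(bx, by, sy, seed = 1)$se
  w2 <- mr_weighted_median(bx, by, sy, seed = 2)$se
  expect_lt(abs(w1 - w2) / w1, 0.1)
})

test_that("estimators are invariant to re-orienting any instrument", {
  set.seed(6)
  n <- 12
  bx <- rnorm(n, 0.2, 0.3); by <- 0.25 * bx + rnorm(n, 0, 0.03)
  sy <- runif(n, 0.02, 0.1)
  flip <- rep(1, n); flip[c(2, 5, 9)] <- -1
  for (f in list(
    function(a, b, s) mr_ivw(a, b, s)$beta,
    function(a, b, s) mr_egger(a, b, s)$slope$beta,
    function(a, b, s) mr_simple_median(a, b, s, n_boot = 10)$beta,
    function(a, b, s) mr_weighted_median(a, b, s, n_boot = 10)$beta)) {
    expect_equal(f(bx * flip, by * flip, sy), f(bx, by, sy),
                 tolerance = 1e-12)
  }
})

test_that("multivariable MR reduces to IVW and honors orthogonal designs", {
  m <- tiny_merged(n = 8)
  mv1 <- mr_mvmr(m, exposures = "ldl")
  ivw <- mr_ivw(m$beta_ldl, m$beta_cad, m$se_cad)
  expect_equal(mv1$beta, ivw$beta, tolerance = 1e-12)
  expect_equal(mv1$se, ivw$se, tolerance = 1e-12)

  # orthogonal exposure columns under constant weights: each coefficient
  # equals that exposure's own projection (Walsh sign patterns)
  m2 <- tiny_merged(n = 8)
  m2$beta_ldl <- c(1, 1, 1, 1, -1, -1, -1, -1) * 0.1
  m2$beta_hdl <- c(1, 1, -1, -1, 1, 1, -1, -1) * 0.2
  m2$beta_tg <- c(1, -1, 1, -1, 1, -1, 1, -1) * 0.15
  stopifnot(sum(m2$beta_ldl * m2$beta_hdl) == 0,
            sum(m2$beta_ldl * m2$beta_tg) == 0,
            sum(m2$beta_hdl * m2$beta_tg) == 0)
  m2$se_cad <- 0.05
  set.seed(8); m2$beta_cad <- rnorm(8, 0, 0.1)
  mv <- mr_mvmr(m2)
  for (tr in c("ldl", "hdl", "tg")) {
    bx <- m2[[paste0("beta_", tr)]]
    expect_equal(mv$beta[mv$exposure == tr],
                 sum(bx * m2$beta_cad) / sum(bx^2), tolerance = 1e-10)
  }

  # collinear exposures are refused by name
  m3 <- tiny_merged(n = 8)
  m3$beta_hdl <- 2 * m3$beta_ldl
  expect_error(mr_mvmr(m3), "collinear")

  # random instances vs the three-column normal-equations oracle
  set.seed(10)
  for (i in 1:20) {
    mm <- tiny_merged(n = sample(6:25, 1), seed = 100 + i)
    mv <- mr_mvmr(mm)
    X <- as.matrix(mm[, c("beta_ldl", "beta_hdl", "beta_tg")])
    o <- wls_oracle(X, mm$beta_cad, 1 / mm$se_cad^2)
    expect_equal(mv$beta, o$est, tolerance = 1e-10)
    expect_equal(mv$se, o$se, tolerance = 1e-10)
  }
})

test_that("variance ratio equals the one-way ANOVA decomposition", {
  # all class means equal: nothing between classes
  beta <- c(0.1, 0.3, 0.1, 0.3)
  a1 <- c("A", "A", "C", "C"); a2 <- c("G", "G", "T", "T")
  expect_equal(r_squared(beta, a1, a2), 0)
  # one observation per class: everything between classes
  expect_equal(r_squared(c(0.1, 0.4, 0.9), c("A", "C", "G"),
                         c("G", "T", "A")), 1)
  expect_error(r_squared(c(0.1, 0.1), c("A", "C"), c("G", "T")),
               "zero total variance")
  expect_error(r_squared(c(0.1, 0.2), c("A", "A"), c("G", "G")),
               "2 distinct")

  set.seed(3)
  for (i in 1:10) {
    n <- sample(10:40, 1)
    a1 <- sample(c("A", "C", "G"), n, replace = TRUE)
    a2 <- sample(c("T", "G"), n, replace = TRUE)
    beta <- rnorm(n)
    fit <- lm(beta ~ factor(paste(a1, a2)))
    expect_equal(r_squared(beta, a1, a2), summary(fit)$r.squared,
                 tolerance = 1e-12)
  }
})

test_that("the estimate container keeps OR and CI consistent", {
  m <- tiny_merged(n = 10)
  res <- mr_all(m, n_boot = 200, seed = 3)
  expect_true(all(res$ci_low <= res$or & res$or <= res$ci_high))
  expect_equal(res$or, exp(res$beta))
  expect_true(all(res$p > 0 & res$p <= 1))
  # at most one estimate per (method, exposure)
  expect_false(any(duplicated(res[, c("method", "exposure")])))
})
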