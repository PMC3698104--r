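test_that("direct counts give the binomial proportion and standard error", {
  est <- prop_from_counts(5, 10)
  expect_equal(est$p_hat, 0.5)
  expect_equal(est$se, sqrt(0.025))
  expect_equal(c(est$y_eff, est$n_eff), c(5, 10))
  # continuity constant only at the boundaries
  expect_equal(prop_from_counts(0, 20)$p_hat, 0.5 / 21)
  expect_equal(prop_from_counts(20, 20)$p_hat, 20.5 / 21)
  expect_equal(prop_from_counts(7, 10)$p_hat, 0.7)
  expect_error(prop_from_counts(5, 0), "n must be")
  expect_error(prop_from_counts(11, 10), "0 <= y <= n")
})

test_that("binomial se matches a bootstrap oracle within 2 percent", {
  set.seed(401)
  est <- prop_from_counts(7, 10)
  boot_sd <- sd(rbinom(1e6, 10, 0.7) / 10)
  expect_lt(abs(est$se - boot_sd) / boot_sd, 0.02)
})

test_that("a statistic at the threshold returns exactly 0.5 under normality", {
  expect_equal(prop_from_mean_sd(80, 40, 30, 80, "NORMAL")$p_hat, 0.5)
  expect_equal(prop_from_median_range(80, 20, 140, 25, 80,
                                      "NORMAL")$p_hat, 0.5)
  expect_equal(prop_from_median_iqr(100, 60, 140, 40, 100,
                                    "NORMAL")$p_hat, 0.5)
})

test_that("mean/SD proportions match Monte-Carlo draws of the family", {
  set.seed(402)
  est <- prop_from_mean_sd(170, 60, 30, 80, "NORMAL")
  expect_equal(est$p_hat, pnorm(-1.5))
  emp <- mean(rnorm(1e6, 170, 60) < 80)
  expect_lt(abs(est$p_hat - emp), 3 * sqrt(emp * (1 - emp) / 1e6))

  est <- prop_from_mean_sd(170, 60, 30, 80, "LOGNORMAL")
  # independent moment matching for the oracle draws
  s2 <- log(1 + (60 / 170)^2)
  emp <- mean(rlnorm(1e6, log(170) - s2 / 2, sqrt(s2)) < 80)
  expect_lt(abs(est$p_hat - emp), 3 * sqrt(emp * (1 - emp) / 1e6))
})

test_that("delta-method se matches the sampling spread of the estimate", {
  # simulate arms, estimate each, compare the analytic se with the
  # realised spread of p_hat
  set.seed(403)
  m <- 170; s <- 60; n <- 40
  p_hats <- replicate(3000, {
    x <- rnorm(n, m, s)
    prop_from_mean_sd(mean(x), sd(x), n, 80, "NORMAL")$p_hat
  })
  est <- prop_from_mean_sd(m, s, n, 80, "NORMAL")
  expect_lt(abs(est$se - sd(p_hats)) / sd(p_hats), 0.15)
})

test_that("median-based estimators are consistent for the latent proportion", {
  # with population quantiles as input, the recovered proportion is close
  # to the true below-threshold probability
  set.seed(404)
  for (fam in c("NORMAL", "LOGNORMAL")) {
    for (i in 1:20) {
      if (fam == "NORMAL") {
        mu <- runif(1, 100, 250); sig <- runif(1, 30, 90)
        q <- qnorm(c(0.25, 0.5, 0.75), mu, sig)
        truth <- pnorm(80, mu, sig)
      } else {
        mu <- runif(1, log(100), log(250)); sig <- runif(1, 0.2, 0.6)
        q <- qlnorm(c(0.25, 0.5, 0.75), mu, sig)
        truth <- plnorm(80, mu, sig)
      }
      est <- prop_from_median_iqr(q[2], q[1], q[3], 50, 80, fam)
      expect_lt(abs(est$p_hat - truth), 0.02)
    }
  }
  # range form: expected order statistics in, truth within bias allowance
  mu <- 150; sig <- 90; n <- 25
  sims <- replicate(2000, {
    x <- rnorm(n, mu, sig)
    c(median(x), min(x), max(x))
  })
  avg <- rowMeans(sims)
  est <- prop_from_median_range(avg[1], avg[2], avg[3], n, 80, "NORMAL")
  expect_lt(abs(est$p_hat - pnorm(80, mu, sig)), 0.03)
})

test_that("proportions respond monotonically to location and spread", {
  p_of_mean <- vapply(seq(100, 250, by = 25), function(m) {
    prop_from_mean_sd(m, 60, 30, 80, "LOGNORMAL")$p_hat
  }, numeric(1))
  expect_true(all(diff(p_of_mean) < 0))
  # wider spread at a median below threshold pulls p towards 0.5
  lo <- prop_from_median_iqr(150, 120, 190, 40, 80, "NORMAL")
  hi <- prop_from_median_iqr(150, 80, 220, 40, 80, "NORMAL")
  expect_gt(hi$p_hat, lo$p_hat)
  expect_lt(hi$p_hat, 0.5)
})

test_that("effective counts invert the binomial standard error", {
  obs <- prop_from_mean_sd(170, 60, 30, 80, "NORMAL")
  out <- to_effective_counts(obs)
  expect_equal(out$n_eff, obs$p_hat * (1 - obs$p_hat) / obs$se^2)
  expect_equal(out$y_eff, out$p_hat * out$n_eff)
  # the estimator itself caps the effective size at the arm size
  expect_lte(obs$n_eff, 30)
  # direct counts pass through unchanged
  direct <- to_effective_counts(prop_from_counts(5, 10))
  expect_equal(c(direct$y_eff, direct$n_eff), c(5, 10))
  # inversion of a known binomial se
  syn <- data.frame(p_hat = 0.5, se = sqrt(0.025), y_eff = NA_real_,
                    n_eff = NA_real_, provenance = "FROM_MEAN_SD")
  out <- to_effective_counts(syn)
  expect_equal(out$n_eff, 10, tolerance = 1e-12)
  expect_equal(out$y_eff, 5, tolerance = 1e-12)
  # halving the se quadruples the effective sample size
  syn2 <- syn; syn2$se <- syn$se / 2
  expect_equal(to_effective_counts(syn2)$n_eff, 40, tolerance = 1e-12)
  syn$se <- 0
  expect_error(to_effective_counts(syn), "se must be")
})

test_that("count conversion round-trips through effective counts", {
  for (y in c(1, 7, 19)) {
    obs <- prop_from_counts(y, 20)
    obs$provenance <- "FROM_MEAN_SD" # force recomputation from (p, se)
    out <- to_effective_counts(obs)
    expect_equal(out$n_eff, 20, tolerance = 1e-9)
    expect_equal(out$y_eff, y, tolerance = 1e-9)
  }
})

test_that("PBAC and MBL paths are identical up to the threshold", {
  a <- prop_from_mean_sd(150, 50, 30, 80, "LOGNORMAL")
  b <- prop_from_mean_sd(150 * 100 / 80, 50 * 100 / 80, 30, 100, "LOGNORMAL")
  expect_equal(a$p_hat, b$p_hat, tolerance = 1e-12)
})

test_that("degenerate and unsupported inputs raise errors", {
  expect_error(prop_from_mean_sd(100, 0, 30, 80), "sd must be")
  expect_error(prop_from_mean_sd(-5, 10, 30, 80, "LOGNORMAL"),
               "mean > 0")
  expect_error(prop_from_median_range(100, 100, 100, 25, 80),
               "degenerate")
  expect_error(prop_from_median_iqr(90, 90, 90, 25, 80), "degenerate")
  expect_error(prop_from_median_range(100, 120, 150, 25, 80),
               "min <= median")
})

test_that("estimate_proportions dispatches every reporting form", {
  gen <- generate_network(generator_config(seed = 19))
  obs <- estimate_proportions(gen$network)
  expect_equal(nrow(obs), nrow(gen$network$arms))
  expect_setequal(unique(obs$provenance),
                  c("DIRECT_COUNTS", "FROM_MEAN_SD", "FROM_MEDIAN_RANGE",
                    "FROM_MEDIAN_IQR"))
  expect_true(all(obs$p_hat > 0 & obs$p_hat < 1))
  expect_true(all(obs$se > 0))
  expect_true(all(obs$n_eff > 0))
  derived <- obs$provenance != "DIRECT_COUNTS"
  expect_equal(obs$y_eff[derived], (obs$p_hat * obs$n_eff)[derived])
  expect_equal(obs$y_eff[!derived], gen$network$arms$y[!derived])
})
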