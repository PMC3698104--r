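test_that("baseline standardization centres and scales observed values", {
  raw <- c(139.64, 199.64, NA, 169.64)
  std <- standardize_baselines(raw)
  expect_equal(std$center, 169.64)
  expect_equal(std$scale, sd(c(139.64, 199.64, 169.64)))
  expect_equal(std$x[4], 0) # value at the centre
  expect_equal(mean(std$x[!std$missing_mask]), 0)
  expect_equal(std$missing_mask, c(FALSE, FALSE, TRUE, FALSE))
  expect_error(standardize_baselines(c(NA, NA, 170)), "at least 2")
  expect_error(standardize_baselines(c(170, 170)), "zero spread")
})

test_that("the linear predictor is additive in its four components", {
  model <- build_mtc_model(tiny_obs())
  p <- zero_params(model)
  expect_equal(linear_predictor(p, model, "A", "LNG_IUS", 3), 0)
  p["alpha0"] <- 1
  p["eta[A]"] <- -0.5
  p["theta[A:LNG_IUS]"] <- 0.25
  p["gamma[LNG_IUS:3]"] <- 0.25
  expect_equal(linear_predictor(p, model, "A", "LNG_IUS", 3), 1.0)
  # same (study, class) at two times differs only through gamma
  p2 <- zero_params(model)
  p2["eta[A]"] <- 0.3
  p2["theta[A:PLACEBO]"] <- -0.2
  p2["gamma[PLACEBO:3]"] <- 0.7
  p2["gamma[PLACEBO:6]"] <- -0.1
  expect_equal(linear_predictor(p2, model, "A", "PLACEBO", 3) -
                 linear_predictor(p2, model, "A", "PLACEBO", 6),
               0.7 - (-0.1))
  expect_error(linear_predictor(p, model, "A", "TXA", 3), "not indexed")
})

test_that("the log-likelihood matches closed forms and an independent sum", {
  obs <- tiny_obs()[1, ]
  obs$y_eff <- 5; obs$n_eff <- 10
  obs$baseline_mean <- 150
  model <- build_mtc_model(rbind(obs, within(tiny_obs()[2, ], {
    baseline_mean <- 210
  })))
  p <- zero_params(model)
  expect_equal(log_likelihood(p, model),
               log(choose(10, 5)) + 10 * log(0.5) +
                 log(choose(20, 4)) + 4 * log(0.5) + 16 * log(0.5))
  # empty data sums to zero
  empty <- model
  empty$obs <- empty$obs[0, ]
  expect_equal(log_likelihood(p, empty), 0)
  # independent reimplementation on a richer fixture with nonzero effects
  model <- build_mtc_model(tiny_obs())
  set.seed(31)
  p <- zero_params(model)
  p[] <- p + rnorm(length(p), 0, 0.4)
  p[grep("^tau\\[", names(p))] <- abs(p[grep("^tau\\[", names(p))]) + 0.5
  p["sigma_eta"] <- 0.8
  oracle <- 0
  for (k in seq_len(nrow(model$obs))) {
    o <- model$obs[k, ]
    eta <- p[paste0("eta[", o$study_id, "]")]
    th <- p[paste0("theta[", o$study_id, ":", o$class, "]")]
    ga <- p[paste0("gamma[", o$class, ":", o$time_months, "]")]
    pp <- plogis(p["alpha0"] + eta + th + ga)
    oracle <- oracle + lgamma(o$n_eff + 1) - lgamma(o$y_eff + 1) -
      lgamma(o$n_eff - o$y_eff + 1) +
      o$y_eff * log(pp) + (o$n_eff - o$y_eff) * log(1 - pp)
  }
  expect_equal(log_likelihood(p, model), unname(oracle), tolerance = 1e-10)
})

test_that("the log-prior matches a term-by-term independent oracle", {
  model <- build_mtc_model(tiny_obs())
  set.seed(32)
  p <- zero_params(model)
  p[] <- p + rnorm(length(p), 0, 0.3)
  taus <- grep("^tau\\[", names(p))
  p[taus] <- abs(p[taus]) + 0.4
  p["sigma_eta"] <- 1.3
  p["alpha1"] <- 0.8

  sc <- model$sc
  x <- sc$x
  x[!sc$x_obs] <- p[paste0("x[", sc$study_id[!sc$x_obs], ":",
                           sc$class[!sc$x_obs], "]")]
  oracle <- dnorm(p["alpha0"], 0, 100, log = TRUE) +
    dunif(p["alpha1"], -5, 5, log = TRUE) +
    dgamma(1 / p["sigma_eta"]^2, 0.1, rate = 0.1, log = TRUE) +
    sum(dnorm(p[paste0("x[", sc$study_id[!sc$x_obs], ":",
                       sc$class[!sc$x_obs], "]")], 0, 1, log = TRUE))
  for (cl in model$classes) {
    oracle <- oracle + dnorm(p[paste0("delta[", cl, "]")], 0, 100,
                             log = TRUE) +
      dunif(p[paste0("tau[", cl, "]")], 0, 100, log = TRUE)
  }
  for (k in seq_len(nrow(model$ct))) {
    oracle <- oracle + dnorm(p[paste0("gamma[", model$ct$class[k], ":",
                                      model$ct$time[k], "]")], 0, 10,
                             log = TRUE)
  }
  for (s in model$studies) {
    oracle <- oracle + dnorm(p[paste0("eta[", s, "]")], 0, p["sigma_eta"],
                             log = TRUE)
  }
  for (k in seq_len(nrow(sc))) {
    oracle <- oracle +
      dnorm(p[paste0("theta[", sc$study_id[k], ":", sc$class[k], "]")],
            p[paste0("delta[", sc$class[k], "]")] + p["alpha1"] * x[k],
            p[paste0("tau[", sc$class[k], "]")], log = TRUE)
  }
  expect_equal(log_prior(p, model), unname(oracle), tolerance = 1e-10)
})

test_that("support violations return -Inf", {
  model <- build_mtc_model(tiny_obs())
  p <- zero_params(model)
  p["alpha1"] <- 6
  expect_equal(log_prior(p, model), -Inf)
  p <- zero_params(model)
  p["tau[PLACEBO]"] <- -1
  expect_equal(log_prior(p, model), -Inf)
  p <- zero_params(model)
  p["tau[PLACEBO]"] <- 150
  expect_equal(log_prior(p, model), -Inf)
  p <- zero_params(model)
  p["sigma_eta"] <- -0.5
  expect_equal(log_prior(p, model), -Inf)
  # interior of the support is finite
  expect_true(is.finite(log_prior(zero_params(model), model) +
                          log_likelihood(zero_params(model), model)))
  # Gaussian kernel arithmetic: doubling one eta at unit sd
  p <- zero_params(model)
  p["eta[A]"] <- 1
  p2 <- p
  p2["eta[A]"] <- 2
  expect_equal(log_prior(p2, model) - log_prior(p, model),
               -(4 - 1) / 2)
})

test_that("the intercept/class-effect shift leaves the likelihood intact", {
  model <- build_mtc_model(tiny_obs())
  set.seed(33)
  p <- zero_params(model)
  p[] <- p + rnorm(length(p), 0, 0.5)
  p[grep("^tau\\[", names(p))] <- 1
  p["sigma_eta"] <- 1
  shift <- 3.7
  p2 <- p
  p2["alpha0"] <- p["alpha0"] + shift
  th <- grep("^theta\\[", names(p))
  de <- grep("^delta\\[", names(p))
  p2[th] <- p[th] - shift
  p2[de] <- p[de] - shift
  expect_equal(log_likelihood(p2, model), log_likelihood(p, model),
               tolerance = 1e-12)
  # the theta-prior term is also invariant (delta shifts with theta)
  expect_equal(log_prior(p2, model) - log_prior(p, model),
               unname(sum(dnorm(p2[de], 0, 100, log = TRUE) -
                            dnorm(p[de], 0, 100, log = TRUE)) +
                        dnorm(p2["alpha0"], 0, 100, log = TRUE) -
                        dnorm(p["alpha0"], 0, 100, log = TRUE)),
               tolerance = 1e-12)
})

test_that("with a zero slope the model ignores the covariate", {
  model <- build_mtc_model(tiny_obs())
  p <- zero_params(model)
  stopifnot(any(!model$sc$x_obs))
  model2 <- model
  model2$sc$x[model2$sc$x_obs] <- model2$sc$x[model2$sc$x_obs] + 2.5
  expect_equal(log_prior(p, model), log_prior(p, model2))
  expect_equal(log_likelihood(p, model), log_likelihood(p, model2))
})

test_that("same-class arms pool by summing effective counts", {
  obs <- tiny_obs()[c(1, 1), ]
  obs$arm <- c(1L, 2L)
  obs$y_eff <- c(3, 4)
  obs$n_eff <- c(10, 10)
  obs$p_hat <- c(0.3, 0.4)
  pooled <- pool_same_class_arms(obs)
  expect_equal(nrow(pooled), 1L)
  expect_equal(pooled$y_eff, 7)
  expect_equal(pooled$n_eff, 20)
  expect_equal(pooled$p_hat, 0.35)
  expect_match(pooled$provenance, "POOLED")
  # arms in different classes are untouched
  expect_equal(pool_same_class_arms(tiny_obs()), tiny_obs())
  # pooled proportion always lies between the constituents
  for (y1 in c(1, 5, 9)) {
    for (y2 in c(2, 8)) {
      obs$y_eff <- c(y1, y2)
      obs$p_hat <- obs$y_eff / 10
      p <- pool_same_class_arms(obs)$p_hat
      expect_gte(p, min(y1, y2) / 10)
      expect_lte(p, max(y1, y2) / 10)
    }
  }
})

test_that("the corner constraint fixes reference parameters at zero", {
  model <- build_mtc_model(tiny_obs(), constrain = TRUE)
  expect_true("delta[PLACEBO]" %in% names(model$fixed))
  expect_true("gamma[PLACEBO:3]" %in% names(model$fixed))
  expect_false("delta[PLACEBO]" %in% model$par_names)
  # fixed values resolve through the parameter lookup
  p <- zero_params(model)
  expect_equal(linear_predictor(p, model, "A", "PLACEBO", 3), 0)
})

test_that("model specifications round-trip through JSON", {
  model <- build_mtc_model(tiny_obs(), constrain = TRUE)
  path <- tempfile(fileext = ".json")
  model_to_json(model, path)
  re <- model_from_json(path)
  expect_equal(re$par_names, model$par_names)
  expect_equal(re$center, model$center)
  expect_equal(re$scale, model$scale)
  expect_equal(re$fixed, model$fixed)
})
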