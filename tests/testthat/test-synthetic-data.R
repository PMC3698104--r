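test_that("generation is deterministic in the seed", {
  g1 <- generate_network(generator_config(seed = 71))
  g2 <- generate_network(generator_config(seed = 71))
  expect_identical(g1$network$arms, g2$network$arms)
  expect_identical(g1$truth$cells, g2$truth$cells)
  g3 <- generate_network(generator_config(seed = 72))
  expect_false(identical(g1$network$arms, g3$network$arms))
})

test_that("generated networks emulate the stated study conditions", {
  gen <- generate_network(generator_config(seed = 73))
  arms <- gen$network$arms
  expect_equal(length(unique(arms$study_id)), 34L)
  expect_true(all(arms$time_months %in% follow_up_menu()))
  expect_true(all(arms$n >= 9 & arms$n <= 164))
  bl <- arms$baseline_mean[!is.na(arms$baseline_mean)]
  expect_true(all(bl >= 90.3 & bl <= 300))
  expect_true(all(arms$scale %in% c("MBL", "PBAC")))
  # generated data feeds the whole pipeline with zero rejects
  expect_silent(obs <- estimate_proportions(gen$network))
  expect_true(all(obs$p_hat > 0 & obs$p_hat < 1))
  # and round-trips through the file loader unchanged
  path <- tempfile(fileext = ".csv")
  write_network(gen$network, path)
  expect_equal(load_network(path)$arms$n, arms$n)
})

test_that("baseline missingness is independent of the outcomes", {
  # same seed, different missingness rate: outcomes identical, only the
  # baseline mask changes (missing-at-random by construction)
  cfg_all <- generator_config(seed = 74, baseline_missing_rate = 0)
  cfg_half <- generator_config(seed = 74)
  full <- generate_network(cfg_all)$network$arms
  masked <- generate_network(cfg_half)$network$arms
  expect_identical(full$y, masked$y)
  expect_identical(full$mean, masked$mean)
  expect_identical(full$median, masked$median)
  expect_gt(sum(is.na(masked$baseline_mean)), 0)
  expect_equal(sum(is.na(full$baseline_mean)), 0)
  keep <- !is.na(masked$baseline_mean)
  expect_equal(masked$baseline_mean[keep], full$baseline_mean[keep])
})

test_that("with pure counts and no noise the empirical rates match truth", {
  truth <- mtc_truth()
  truth$alpha1 <- 0
  truth$sigma_eta <- 0
  truth$tau[] <- 0
  cfg <- generator_config(
    seed = 75, truth = truth,
    reporting_mix = c(counts_mbl = 1, mean_sd = 0, median_forms = 0,
                      counts_pbac = 0),
    arm_size_range = c(2000L, 4000L))
  gen <- generate_network(cfg)
  arms <- gen$network$arms
  cells <- gen$truth$cells
  for (k in seq_len(nrow(arms))) {
    tp <- cells$true_p[cells$class == arms$class[k] &
                         cells$time == arms$time_months[k]]
    se <- sqrt(tp * (1 - tp) / arms$n[k])
    expect_lt(abs(arms$y[k] / arms$n[k] - tp), 3 * se + 1 / arms$n[k])
  }
})

test_that("the estimator chain recovers latent proportions as arms grow", {
  truth <- mtc_truth()
  truth$alpha1 <- 0
  truth$sigma_eta <- 0
  truth$tau[] <- 0
  mix <- c(counts_mbl = 0, mean_sd = 1, median_forms = 0, counts_pbac = 0)
  mae <- vapply(c(50L, 1500L), function(nsz) {
    cfg <- generator_config(seed = 76, truth = truth, reporting_mix = mix,
                            arm_size_range = c(nsz, nsz + 10L))
    gen <- generate_network(cfg)
    obs <- estimate_proportions(gen$network)
    cells <- gen$truth$cells
    tp <- vapply(seq_len(nrow(obs)), function(k) {
      cells$true_p[cells$class == obs$class[k] &
                     cells$time == obs$time_months[k]]
    }, numeric(1))
    mean(abs(obs$p_hat - tp))
  }, numeric(1))
  expect_lt(mae[2], mae[1]) # consistency: error shrinks with arm size
  expect_lt(mae[2], 0.03)
})

test_that("the published-network fixture realises the printed structure", {
  net <- table1_fixture()
  tab <- direct_comparison_table(net)
  expect_equal(nrow(tab), 11L)
  expect_equal(tab$total_patients[tab$pair == "ABLATION & LNG_IUS"], 422)
  # the intrauterine-system vs tranexamic-acid trial reported the two
  # arms at disjoint times: a row with no per-time comparison
  lngtxa <- tab[tab$pair == "LNG_IUS & TXA", ]
  expect_equal(lngtxa$n_rcts, 1L)
  expect_equal(sum(lngtxa[paste0("t", follow_up_menu())]), 0L)
})

test_that("recovery experiments report coverage, bias and failures", {
  cfg <- generator_config(n_studies = 10L, seed = 77)
  rec <- recovery_experiment(cfg, n_replicates = 3L,
                             sampler = list(chains = 1L, burn_in = 300L,
                                            draws = 300L),
                             seed = 78)
  expect_s3_class(rec, "mtc_recovery")
  expect_equal(rec$n_replicates_done, 3L)
  expect_true(all(c("replicate", "class", "time", "true_sum", "covered",
                    "bias_pct", "ci_width_pct") %in% names(rec$cells)))
  expect_true(rec$coverage >= 0 && rec$coverage <= 1)
  expect_true(all(c("class", "coverage") %in% names(rec$per_class)))
  expect_equal(length(rec$errors), 0L)
})

test_that("larger trials shrink the credible intervals", {
  truth <- mtc_truth()
  sm <- generator_config(n_studies = 10L, seed = 79, truth = truth,
                         arm_size_range = c(9L, 30L))
  lg <- generator_config(n_studies = 10L, seed = 79, truth = truth,
                         arm_size_range = c(300L, 600L))
  sampler <- list(chains = 1L, burn_in = 400L, draws = 400L)
  rec_sm <- recovery_experiment(sm, n_replicates = 2L, sampler = sampler,
                                seed = 80)
  rec_lg <- recovery_experiment(lg, n_replicates = 2L, sampler = sampler,
                                seed = 80)
  expect_lt(rec_lg$mean_ci_width_pct, rec_sm$mean_ci_width_pct)
})
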