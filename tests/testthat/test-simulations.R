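test_that("solve_criteria handles the symmetric and degenerate cases", {
  cfg <- sim_config(d1_true = 0, sd_grammatical = 1,
                    p_judge_grammatical = 0.5,
                    p_guess_given_grammatical_judgment = 0.5,
                    p_guess_given_ungrammatical_judgment = 0.5)
  cr <- solve_criteria(cfg)
  expect_equal(cr$decision_criterion, 0, tolerance = 1e-10)
  expect_equal(cr$upper_threshold, qnorm(0.75), tolerance = 1e-8)
  expect_equal(cr$lower_threshold, -cr$upper_threshold, tolerance = 1e-8)
  # zero guess proportions collapse both thresholds onto the criterion
  cr0 <- solve_criteria(cfg, probs = c(0.5, 0, 0))
  expect_equal(cr0$lower_threshold, cr0$decision_criterion)
  expect_equal(cr0$upper_threshold, cr0$decision_criterion)
  expect_true(cr$lower_threshold <= cr$decision_criterion)
  expect_true(cr$decision_criterion <= cr$upper_threshold)
})

test_that("solved criteria reproduce the target response proportions forward", {
  # default config at 1e6 trials, then random configs (binomial 99% CI)
  check_forward <- function(cfg, n = 1e6, tol = 0) {
    cr <- solve_criteria(cfg)
    x <- c(rnorm(n / 2, cfg$d1_true, cfg$sd_grammatical), rnorm(n / 2))
    p_g <- mean(x > cr$decision_criterion)
    p_guess_g <- mean(x[x > cr$decision_criterion] <= cr$upper_threshold)
    p_guess_u <- mean(x[x <= cr$decision_criterion] > cr$lower_threshold)
    targets <- c(cfg$p_judge_grammatical,
                 cfg$p_guess_given_grammatical_judgment,
                 cfg$p_guess_given_ungrammatical_judgment)
    obs <- c(p_g, p_guess_g, p_guess_u)
    ns <- c(n, sum(x > cr$decision_criterion), sum(x <= cr$decision_criterion))
    ci99 <- 2.576 * sqrt(targets * (1 - targets) / ns)
    expect_true(all(abs(obs - targets) < pmax(ci99, tol)))
  }
  set.seed(21)
  check_forward(sim_config(), tol = 0.005)
  for (i in 1:12) {
    cfg <- sim_config(d1_true = runif(1, -0.5, 1),
                      sd_grammatical = runif(1, 0.7, 1.8),
                      p_judge_grammatical = runif(1, 0.3, 0.7),
                      p_guess_given_grammatical_judgment = runif(1, 0.1, 0.7),
                      p_guess_given_ungrammatical_judgment = runif(1, 0.1, 0.7))
    check_forward(cfg, n = 4e5)
  }
})

test_that("the simulated observer recovers its generating parameters", {
  set.seed(22)
  # null model: no sensitivity, equal variances, symmetric thresholds
  cfg0 <- sim_config(n_participants = 1, n_trials = 1e6, d1_true = 0,
                     sd_grammatical = 1, p_judge_grammatical = 0.5,
                     p_guess_given_grammatical_judgment = 0.4,
                     p_guess_given_ungrammatical_judgment = 0.4)
  res0 <- simulate_experiment_once(cfg0, solve_criteria(cfg0))
  expect_lt(abs(res0$group_mean_d1), 0.01)
  expect_lt(abs(res0$group_mean_d2), 0.01)
  # estimator consistency at d'1 = 0.46
  cfg1 <- sim_config(n_participants = 1, n_trials = 1e6, d1_true = 0.46,
                     sd_grammatical = 1, p_judge_grammatical = 0.5,
                     p_guess_given_grammatical_judgment = 0.4,
                     p_guess_given_ungrammatical_judgment = 0.4)
  res1 <- simulate_experiment_once(cfg1, solve_criteria(cfg1))
  expect_lt(abs(res1$group_mean_d1 - 0.46), 0.01)
})

test_that("criterion jitter attenuates d'1 by 1/sqrt(1 + sigma^2)", {
  set.seed(23)
  est <- vapply(c(0, 0.5, 1, 1.5), function(sig) {
    cfg <- sim_config(n_participants = 1, n_trials = 1e6, d1_true = 0.46,
                      sd_grammatical = 1, p_judge_grammatical = 0.5,
                      p_guess_given_grammatical_judgment = 0.4,
                      p_guess_given_ungrammatical_judgment = 0.4,
                      jitter_sd = sig)
    simulate_experiment_once(cfg, solve_criteria(cfg))$group_mean_d1
  }, numeric(1))
  predicted <- 0.46 / sqrt(1 + c(0, 0.5, 1, 1.5)^2)
  expect_true(all(abs(est - predicted) / predicted < 0.02))
  expect_true(all(diff(est) < 0))
})

test_that("identical seeds give bit-identical simulation results", {
  cfg <- sim_config(n_reps = 40, seed = 77)
  a <- run_unequal_variance_sim(cfg, 0.23)
  b <- run_unequal_variance_sim(cfg, 0.23)
  expect_identical(a$per_rep_group_mean, b$per_rep_group_mean)
  expect_identical(a$exceedance_p, b$exceedance_p)
  # early replicates do not depend on n_reps (per-replicate substreams)
  c40 <- run_unequal_variance_sim(sim_config(n_reps = 80, seed = 77), 0.23)
  expect_identical(a$per_rep_group_mean, c40$per_rep_group_mean[1:40])
})

test_that("exceedance probability hits its trivial bounds", {
  cfg <- sim_config(n_reps = 20, seed = 9)
  expect_equal(run_unequal_variance_sim(cfg, -Inf)$exceedance_p, 1)
  expect_equal(run_unequal_variance_sim(cfg, Inf)$exceedance_p, 0)
  jcfg <- sim_config(d1_true = 0.46, jitter_sd = 0, n_trials = 1000,
                     n_reps = 30, seed = 9)
  # without jitter and with ample trials, d'1 never reaches 0
  expect_equal(run_jitter_sim(jcfg, 0)$exceedance_p, 0)
})

test_that("null d'2 sampling distribution is symmetric under a symmetric model", {
  cfg <- sim_config(d1_true = 0, sd_grammatical = 1,
                    p_judge_grammatical = 0.5,
                    p_guess_given_grammatical_judgment = 0.4,
                    p_guess_given_ungrammatical_judgment = 0.4,
                    n_reps = 3000, seed = 31)
  res <- run_unequal_variance_sim(cfg, 0.23)
  d <- res$per_rep_group_mean
  mcse <- sd(d) / sqrt(length(d))
  expect_lt(abs(median(d)), 2 * mcse)
  p_up <- mean(d >= 0.23); p_dn <- mean(d <= -0.23)
  expect_lt(abs(p_up - p_dn), 0.015)
})

test_that("zero-cell policies and threshold scatter run and stay coherent", {
  cfg_c <- sim_config(n_reps = 50, seed = 13, zero_cell_policy = "correct")
  res_c <- run_unequal_variance_sim(cfg_c, 0.23)
  expect_equal(res_c$n_excluded_participants_total, 0L)
  cfg_s <- sim_config(n_reps = 20, seed = 13,
                      threshold_scatter_sd = c(0.03, 0.05, 0.04))
  res_s <- run_unequal_variance_sim(cfg_s, 0.23)
  expect_true(is.finite(res_s$grand_mean))
  expect_equal(res_s$grand_se, sd(res_s$per_rep_group_mean) / sqrt(20))
})
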