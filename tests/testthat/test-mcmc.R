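test_that("identical dataset, config and seed give bit-identical draws", {
  sds <- generate_dataset(simulation_config(n_pairs = 40, seed = 21,
                                            distance_range = c(5e3, 1e5),
                                            chrom_length = 1e6))
  cfg <- mcmc_config(chains = 2, warmup = 50, iter = 50, seed = 3)
  d1 <- run_mcmc(sds$dataset, cfg)
  d2 <- run_mcmc(sds$dataset, cfg)
  expect_identical(d1$draws, d2$draws)
  # a different seed moves the draws
  d3 <- run_mcmc(sds$dataset, mcmc_config(chains = 2, warmup = 50, iter = 50,
                                          seed = 4))
  expect_false(identical(d1$draws, d3$draws))
})

test_that("draws respect the parameter constraints", {
  sds <- generate_dataset(simulation_config(n_pairs = 30, seed = 22,
                                            distance_range = c(5e3, 1e5),
                                            chrom_length = 1e6))
  d <- run_mcmc(sds$dataset, mcmc_config(chains = 2, warmup = 100, iter = 100,
                                         seed = 5))
  expect_true(all(d$draws[, , "C"] > 0))
  w_cols <- grep("^w1\\[", dimnames(d$draws)[[3]])
  expect_true(all(d$draws[, , w_cols] > 0 & d$draws[, , w_cols] < 1))
})

test_that("split-Rhat detects stuck and disagreeing chains", {
  # all chains constant and equal: exactly 1 by the degenerate rule
  expect_equal(compute_rhat(matrix(2, 100, 4)), 1)
  # iid standard normal: close to 1
  set.seed(30)
  expect_lt(compute_rhat(matrix(rnorm(4000), 1000, 4)), 1.01)
  # chains with means 0 and 10: far above the 1.05 gate, and equal to the
  # split-Rhat formula evaluated by hand
  set.seed(31)
  m <- cbind(rnorm(1000, 0, 1), rnorm(1000, 10, 1))
  rh <- compute_rhat(m)
  expect_gt(rh, 3)
  half <- 500
  split <- cbind(m[1:500, ], m[501:1000, ])
  W <- mean(apply(split, 2, var))
  B <- half * var(colMeans(split))
  expect_equal(rh, sqrt(((half - 1) / half * W + B / half) / W),
               tolerance = 1e-12)
  expect_error(compute_rhat(matrix(1, 100, 1)), "2 chains")
  expect_error(compute_rhat(matrix(1, 3, 2)), "4 kept")
})

test_that("intercept-only posterior matches 2-D quadrature", {
  # single-seed version of the small-instance oracle check (the acceptance
  # suite runs three seeds)
  ds <- intercept_only_dataset(c(2L, 3L, 2L, 5L, 8L))
  quad <- quadrature_intercept_only(ds)
  fit <- run_mcmc(ds, mcmc_config(chains = 4, warmup = 500, iter = 1000,
                                  seed = 17, intercept_only = TRUE,
                                  sample_w1 = FALSE))
  for (par in c("beta0", "C")) {
    m <- fit$draws[, , par]
    mcse <- mcse_batch(m)
    expect_lt(abs(mean(m) - quad[[par]]), 3 * mcse + 1e-3,
              label = sprintf("posterior mean of %s (mcmc %.4f quad %.4f)",
                              par, mean(m), quad[[par]]))
  }
})

test_that("responsibilities follow the exact Bayes rule at fixed parameters", {
  ds <- intercept_only_dataset(c(2L, 4L, 9L))
  # single repeated draw: beta0 = 0 (lam0 = 1), C = 4, w1 = 0.5
  dr <- manual_draws(beta = c(0, 0, 0, 0, 0), C = 4, w1 = rep(0.5, 3))
  r <- posterior_responsibility(dr, ds)
  manual <- sapply(c(2, 4, 9), function(y) {
    p0 <- oracle_tpois(y, 1, 2); p1 <- oracle_tpois(y, 5, 2)
    0.5 * p1 / (0.5 * p0 + 0.5 * p1)
  })
  expect_equal(r, manual, tolerance = 1e-10)
  # strictly increasing in y at fixed parameters
  ds_seq <- intercept_only_dataset(2:20)
  dr_seq <- manual_draws(rep(0, 5), C = 4, w1 = rep(0.5, 19))
  expect_true(all(diff(posterior_responsibility(dr_seq, ds_seq)) > 0))
  # degenerate weight forces responsibility to 1
  dr_one <- manual_draws(rep(0, 5), C = 4, w1 = rep(1 - 1e-12, 3))
  expect_equal(posterior_responsibility(dr_one, ds), rep(1, 3),
               tolerance = 1e-9)
  # identical components (C -> 0) leave the prior weight untouched
  dr_c0 <- manual_draws(rep(0, 5), C = 1e-9, w1 = c(0.2, 0.5, 0.9))
  expect_equal(posterior_responsibility(dr_c0, ds), c(0.2, 0.5, 0.9),
               tolerance = 1e-6)
})

test_that("classification uses a strict threshold", {
  expect_identical(classify(c(0.7, 0.5, 0.0, 0.51)),
                   c("signal", "noise", "noise", "signal"))
  expect_error(classify(0.5, threshold = 1.5), "threshold")
  expect_error(classify(c(-0.1, 0.5)), "respons")
})

test_that("posterior predictive replicates live on the truncated support", {
  ds <- intercept_only_dataset(c(2L, 3L, 5L, 7L))
  dr <- manual_draws(rep(0, 5), C = 4, w1 = rep(0.4, 4))
  reps <- posterior_predictive(dr, ds, n_rep = 50, seed = 40)
  expect_equal(dim(reps), c(50L, 4L))
  expect_true(all(reps >= 2))
  expect_identical(reps, posterior_predictive(dr, ds, n_rep = 50, seed = 40))
  # replicate mean approaches the mixture mean at the fixed parameters
  big <- posterior_predictive(dr, ds, n_rep = 4000, seed = 41)
  mix_mean <- 0.6 * sum((2:400) * oracle_tpois_vec(2:400, 1, 2)) +
    0.4 * sum((2:400) * oracle_tpois_vec(2:400, 5, 2))
  expect_equal(mean(colMeans(big)), mix_mean, tolerance = 0.02)
})

test_that("the convergence gate blocks label emission until overridden", {
  sds <- generate_dataset(simulation_config(n_pairs = 40, seed = 23,
                                            distance_range = c(5e3, 1e5),
                                            chrom_length = 1e6))
  fit <- fit_interactions(sds$dataset,
                          mcmc_config(chains = 2, warmup = 30, iter = 30,
                                      seed = 6))
  fit$converged <- FALSE  # simulate a failed Rhat gate
  fit$rhat[1] <- 1.2
  expect_error(significant_interactions(fit, sds$dataset), "Rhat")
  sig <- significant_interactions(fit, sds$dataset, override_rhat_gate = TRUE)
  expect_true(all(sig$count >= 3))
  expect_error(significant_interactions(fit, sds$dataset, min_count = 1),
               "truncation point")
})
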