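# noiseless counts generated directly from the frequency model, for two
# lineages with fitness difference ds; depths large so rounding is negligible
two_lineage_counts <- function(ds, depth = 1e7, gens = c(0, 3, 6, 9, 12)) {
  f <- c(0.5, 0.5)
  s <- c(ds, 0)
  phi <- sapply(gens, function(t) {
    u <- f * exp(s * t)
    u / sum(u)            # xbar absorbs the normalization
  })
  R <- round(phi * depth)
  rownames(R) <- c("A", "B")
  R
}

test_that("a neutral pool fits to zero fitness and a flat mean-fitness curve", {
  sim <- simulate_pool(sim_config(n_bait = 4, n_prey = 4,
                                  barcodes_per_genotype = 4,
                                  fitness_map = NULL, max_fitness = 0,
                                  read_depth = 64 * 500, n_replicates = 1,
                                  seed = 41))
  fit <- fit_pool_fitness(as_trajectory_table(sim), corrected = FALSE)
  e <- fit$estimates
  expect_lt(max(abs(e$fitness), na.rm = TRUE), 0.05)
  expect_lt(max(abs(fit$meanfit$xbar)), 0.05)
})

test_that("noiseless two-lineage competition recovers the closed-form slope", {
  # oracle: ln(phi_A / phi_B) grows by exactly ds per generation
  R <- two_lineage_counts(ds = 0.1)
  gens <- c(0, 3, 6, 9, 12)
  lr <- log(R["A", ] / R["B", ])
  expect_equal(unname(diff(lr) / diff(gens)), rep(0.1, 4), tolerance = 1e-5)
  fit <- fit_pool_fitness(R, generations = gens)
  s <- coef(fit)
  expect_equal(unname(s["A"] - s["B"]), 0.1, tolerance = 1e-4)
  expect_true(all(fit$estimates$log_likelihood > -0.1))
})

test_that("estimates are invariant to a global scaling of counts and depths", {
  R <- two_lineage_counts(ds = 0.25, depth = 1e5)
  fit1 <- fit_pool_fitness(R, generations = c(0, 3, 6, 9, 12))
  fit10 <- fit_pool_fitness(R * 10, generations = c(0, 3, 6, 9, 12))
  d1 <- diff(unname(coef(fit1)))
  d10 <- diff(unname(coef(fit10)))
  expect_lt(abs(d1 - d10), 1e-3)
})

test_that("control zeroing is exact and translation invariant", {
  sim <- small_sim(seed = 43)
  traj <- as_trajectory_table(sim)
  fit <- fit_pool_fitness(traj, corrected = FALSE)
  e <- fit$estimates
  pool <- interaction(e$Condition, e$Methotrexate_selection, e$Replicate)
  for (p in levels(pool)) {
    ctrl <- e$is_control & e$used & pool == p
    expect_equal(mean(e$fitness[ctrl]), 0, tolerance = 1e-12)
  }
  # shifting all raw fitnesses by a constant cannot change the zeroed values
  fit2 <- fit
  fit2$estimates$fitness <- fit2$estimates$fitness + 0.37
  fit2 <- normalize_to_reference(fit2)
  expect_equal(fit2$estimates$fitness, fit$estimates$fitness,
               tolerance = 1e-12)
})

test_that("true fitness of non-controls is recovered within the errors", {
  sim <- small_sim(seed = 44, read_depth = 40000)
  fit <- fit_pool_fitness(as_trajectory_table(sim), corrected = FALSE)
  e <- fit$estimates[fit$estimates$used, ]
  truth <- sim$truth$s_true[match(e$barcode_pair, sim$truth$entry_id)]
  bias <- mean(e$fitness - truth)
  expect_lt(abs(bias), mean(e$se))
})

test_that("fitness recovery regression has unit slope and zero intercept", {
  # simulated pools spanning s in [0, 0.5] at experiment-scale depths
  sim <- simulate_pool(sim_config(max_fitness = 0.5, n_replicates = 1,
                                  seed = 45))
  traj <- correct_counts(as_trajectory_table(sim),
                         rate = sim$config$chimera_rate)
  fit <- fit_pool_fitness(traj)
  e <- fit$estimates[fit$estimates$used, ]
  truth <- sim$truth$s_true[match(e$barcode_pair, sim$truth$entry_id)]
  co <- stats::coef(stats::lm(e$fitness ~ truth))
  expect_lt(abs(co[2] - 1), 0.05)
  expect_lt(abs(co[1]), 0.01)
})

test_that("higher-fitness lineages carry smaller standard errors", {
  sim <- simulate_pool(sim_config(n_replicates = 1, seed = 46))
  fit <- fit_pool_fitness(as_trajectory_table(sim), corrected = FALSE)
  e <- fit$estimates
  truth <- sim$truth$s_true[match(e$barcode_pair, sim$truth$entry_id)]
  lo <- truth < stats::quantile(truth, 0.25)
  hi <- truth > stats::quantile(truth, 0.75)
  expect_lt(mean(e$se[hi], na.rm = TRUE), mean(e$se[lo], na.rm = TRUE))
})

test_that("replicate fitness estimates agree across growth replicates", {
  sim <- simulate_pool(default_experiment_config(seed = 47))
  traj <- correct_counts(as_trajectory_table(sim),
                         rate = sim$config$chimera_rate)
  fit <- fit_pool_fitness(traj)
  e <- fit$estimates[fit$estimates$used, ]
  wide <- stats::reshape(e[, c("barcode_pair", "Replicate", "fitness")],
                         idvar = "barcode_pair", timevar = "Replicate",
                         direction = "wide")
  cors <- stats::cor(wide[, -1], use = "pairwise.complete.obs")
  expect_true(all(cors[upper.tri(cors)] > 0.91))
})

test_that("a corrupted time point drives the likelihood flag", {
  sim <- small_sim(seed = 48)
  traj <- as_trajectory_table(sim)
  cols <- reads_columns(traj)
  # blow one lineage's generation-6 count up to ~100x its expectation
  victim <- which(traj$Replicate == 1)[1]
  traj[[cols[["6"]]]][victim] <- traj[[cols[["6"]]]][victim] * 100 + 5000
  fit <- fit_pool_fitness(traj, corrected = FALSE)
  e <- fit$estimates
  bad <- e$Replicate == 1 & e$barcode_pair == traj$barcode_pair[victim]
  expect_false(any(e$used[bad]))
  expect_lt(e$log_likelihood[bad][1], -10)
  # a threshold of -Inf keeps everything with a defined fitness
  all_used <- flag_trajectories(fit, threshold = -Inf)
  expect_true(all(all_used$estimates$used[
    !is.na(all_used$estimates$fitness)]))
})

test_that("missing controls raise an instructive error", {
  R <- two_lineage_counts(ds = 0.1, depth = 1e4)
  fit <- fit_pool_fitness(R, generations = c(0, 3, 6, 9, 12))
  expect_error(normalize_to_reference(fit), "control")
  # explicit reference choice works instead
  fit2 <- normalize_to_reference(fit, control_ids = "B")
  expect_equal(unname(coef(fit2)["B"]), 0, tolerance = 1e-12)
})

test_that("fit methods expose fitted values, residuals and simulations", {
  sim <- small_sim(seed = 49)
  fit <- fit_pool_fitness(as_trajectory_table(sim), corrected = FALSE)
  mu <- fitted(fit)
  expect_equal(length(mu), 2)  # two replicates
  res <- residuals(fit)
  expect_equal(dim(res[[1]]), dim(mu[[1]]))
  # Pearson residuals of a well-specified Poisson fit are centred near 0
  expect_lt(abs(mean(res[[1]])), 0.2)
  ysim <- simulate(fit, nsim = 2, seed = 1)
  expect_length(ysim, 2)
  expect_equal(dim(ysim[[1]][[1]]), dim(mu[[1]]))
  out <- utils::capture.output({ print(fit); print(summary(fit)) })
  expect_true(any(grepl("Poisson ML", out)))
})
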