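test_that("consensus is the strict majority after dropping no-calls", {
  expect_identical(consensus_call(c("AA", "AA", "NOCALL")), "AA")
  expect_identical(consensus_call(c("AA", "BB")), "TIE")
  expect_identical(consensus_call("NOCALL"), "TIE")
  expect_identical(consensus_call(c("AB", "AB", "BB")), "AB")
  expect_identical(consensus_call(c("AA", "AA", "BB", "BB", "AB")), "TIE")
  expect_error(consensus_call(character(0)), "empty")

  # permutation invariance
  set.seed(61)
  for (i in 1:20) {
    calls <- sample(c("AA", "AB", "BB", "NOCALL"), 6, replace = TRUE)
    expect_identical(consensus_call(calls),
                     consensus_call(sample(calls)))
  }
})

test_that("the worked micro-example enumerates exactly", {
  pool <- list(g = c("AA", "AA", "AA", "AA", "AB", "NOCALL"))
  ref <- c(g = "AA")
  # r = 1: 6 single-replicate draws, 4 correct (AB wrong, NOCALL -> TIE)
  expect_equal(exact_consensus_accuracy(pool, ref, r = 1), 4 / 6)
  # r = 6: the full set, AA majority 4-vs-1
  expect_equal(exact_consensus_accuracy(pool, ref, r = 6), 1.0)
  # at r = n the Monte-Carlo path agrees exactly for any seed
  set.seed(617)
  expect_equal(score_scenario(pool, ref, r = 6), 1.0)
  # and the r = 1 Monte-Carlo mean converges to 4/6
  set.seed(62)
  acc <- replicate(3000, score_scenario(pool, ref, r = 1))
  expect_lt(abs(mean(acc) - 4 / 6), 3 * sqrt((4 / 6) * (2 / 6) / 3000))
})

test_that("Monte-Carlo scenarios converge to the exact enumeration", {
  set.seed(63)
  rp <- random_pools(12, n_source = 6, p = 0.7, z = 0.15)
  for (r in c(2, 3)) {
    exact <- exact_consensus_accuracy(rp$pools, rp$references, r)
    acc <- replicate(2000, score_scenario(rp$pools, rp$references, r))
    se <- sd(acc) / sqrt(length(acc))
    expect_lt(abs(mean(acc) - exact), 3 * se + 1e-12)
  }
  # validation of pools
  expect_error(score_scenario(rp$pools, rp$references, r = 7), "1..6")
  broken <- rp$pools; broken[[1]] <- broken[[1]][-1]
  expect_error(exact_consensus_accuracy(broken, rp$references, 2),
               "exactly")
})

test_that("replacing a wrong call by the reference never hurts accuracy", {
  set.seed(64)
  for (i in 1:15) {
    rp <- random_pools(3, n_source = 4, p = 0.5, z = 0.2)
    r <- sample(1:4, 1)
    base <- exact_consensus_accuracy(rp$pools, rp$references, r)
    g <- sample(3, 1)
    wrong <- which(rp$pools[[g]] != rp$references[[g]])
    if (!length(wrong)) next
    repaired <- rp$pools
    repaired[[g]][sample(wrong, 1)] <- rp$references[[g]]
    expect_gte(exact_consensus_accuracy(repaired, rp$references, r),
               base - 1e-12)
  }
})

test_that("run_simulation is deterministic, exact at r = n, and tracks a
           known per-replicate accuracy", {
  # per-replicate correct probability p, no no-calls, r = 1: mean accuracy
  # within 3 SE of p
  set.seed(65)
  p <- 0.9
  rp <- random_pools(60, n_source = 6, p = p, z = 0,
                     samples = sprintf("IND%02d", 1:60))
  tab <- calls_table(rp$pools, rp$references, scheme_id = "S1")
  cfg <- simulation_config(replicate_levels = c(1, 6), n_scenarios = 400,
                           seed = 11)
  sim <- run_simulation(tab, cfg)
  r1 <- sim$scenarios$accuracy[sim$scenarios$replicate_level == 1]
  ex1 <- sim$summary$exact_accuracy[sim$summary$replicate_level == 1]
  se_mc <- sd(r1) / sqrt(length(r1))
  # the estimator converges to the realized pool's exact accuracy ...
  expect_lt(abs(mean(r1) - ex1), 3 * se_mc + 1e-12)
  # ... which sits within 3 binomial SE of the generating p (360 draws)
  se_gen <- sqrt(p * (1 - p) / (60 * 6))
  expect_lt(abs(mean(r1) - p), 3 * sqrt(se_gen^2 + se_mc^2))

  # closed form with a no-call rate z: accuracy (1 - z) * p at r = 1
  set.seed(66)
  z <- 0.25
  rp2 <- random_pools(60, n_source = 6, p = p, z = z,
                      samples = sprintf("IND%02d", 1:60))
  sim2 <- run_simulation(calls_table(rp2$pools, rp2$references), cfg)
  r1b <- sim2$scenarios$accuracy[sim2$scenarios$replicate_level == 1]
  target <- (1 - z) * p
  se_gen2 <- sqrt(target * (1 - target) / (60 * 6))
  se_mc2 <- sd(r1b) / sqrt(length(r1b))
  expect_lt(abs(mean(r1b) - target), 3 * sqrt(se_gen2^2 + se_mc2^2))

  # at r = n every scenario equals the exact value, whatever the seed
  r6 <- sim$scenarios$accuracy[sim$scenarios$replicate_level == 6]
  ex6 <- sim$summary$exact_accuracy[sim$summary$replicate_level == 6]
  expect_true(all(r6 == ex6))
  expect_equal(ex6, exact_consensus_accuracy(rp$pools, rp$references, 6))

  # determinism contract: identical config, identical scenario accuracies
  expect_identical(run_simulation(tab, cfg)$scenarios, sim$scenarios)
  # summary mean equals the mean of scenario accuracies
  expect_equal(sim$summary$mean_accuracy[1], mean(r1))
})

test_that("perfect replicate data is perfectly recovered at every level", {
  pools <- setNames(lapply(1:8, function(i) rep("AB", 6)),
                    paste0("IND", 1:8, ".A1"))
  refs <- setNames(rep("AB", 8), names(pools))
  sim <- run_simulation(calls_table(pools, refs),
                        simulation_config(n_scenarios = 30, seed = 2))
  expect_true(all(sim$scenarios$accuracy == 1))
  expect_true(all(sim$summary$exact_accuracy == 1))
})

test_that("genotypes with missing replicates are dropped with a warning", {
  pools <- list(IND1.A1 = rep("AA", 6), IND2.A1 = rep("AA", 5))
  refs <- c(IND1.A1 = "AA", IND2.A1 = "AA")
  tab <- calls_table(pools, refs)
  expect_warning(sim <- run_simulation(
    tab, simulation_config(replicate_levels = 1, n_scenarios = 5,
                           seed = 3)), "IND2")
  expect_identical(sim$summary$n_genotypes, 1L)
})
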