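test_that("trajectory enumeration is exhaustive with conserved weight", {
  pol <- solve_policy(sym_proc(), cue_model(0.75), T_ont = 6, T_adult = 5)
  for (start in c("stationary", "E0", "E1")) {
    traj <- enumerate_weighted_trajectories(pol, start)
    expect_equal(nrow(traj), 2^6)
    expect_equal(sum(traj$weight), 1, tolerance = 1e-12)
    expect_true(all(traj$y0 + traj$y1 + traj$waits == 6))
    expect_true(all(traj$weight >= 0))
  }
})

test_that("trajectory weights equal brute-force cue-sequence likelihoods", {
  pol <- solve_policy(asym_proc(), cue_model(0.8), T_ont = 3, T_adult = 2)
  traj <- enumerate_weighted_trajectories(pol, "E0")
  seqs <- oracle_sequences(3)
  for (i in seq_len(nrow(seqs))) {
    want <- oracle_forward(seqs[i, ], asym_proc(), 0.8, "E0")
    expect_equal(traj$weight[i], want$likelihood, tolerance = 1e-12)
    expect_equal(paste0("C", paste(seqs[i, ], collapse = "C")), traj$cues[i])
    # phenotypes agree with a plain-loop walk of the same policy
    ph <- oracle_walk(pol, as.integer(seqs[i, ]))
    expect_equal(traj$y0[i], unname(ph["y0"]))
    expect_equal(traj$y1[i], unname(ph["y1"]))
  }
})

test_that("perfectly reliable cues track the environment path exactly", {
  pol <- solve_policy(sym_proc(), cue_model(1), T_ont = 5, T_adult = 5)
  traj <- enumerate_weighted_trajectories(pol, "E0")
  # with r = 1 the cue sequence equals the state path: the all-C0 sequence
  # has the probability that the patch never switches
  expect_equal(traj$weight[traj$cues == "C0C0C0C0C0"], 0.9^4,
               tolerance = 1e-12)
  # a sequence starting with C1 is impossible when the patch starts in E0
  expect_equal(sum(traj$weight[substr(traj$cues, 1, 2) == "C1"]), 0)
})

test_that("mature phenotype distribution aggregates weights to one", {
  pol <- solve_policy(sym_proc(), cue_model(0.75), T_ont = 6, T_adult = 5)
  traj <- enumerate_weighted_trajectories(pol, "E1")
  dist <- mature_phenotype_distribution(traj)
  expect_equal(sum(dist$weight), 1, tolerance = 1e-12)
  expect_true(all(dist$y0 + dist$y1 + dist$waits == 6))
  # symmetric linear weight-1 model: organisms never wait
  expect_true(all(dist$waits == 0))
})

test_that("trajectory-weighted terminal fitness equals the DP root value", {
  for (cfg in list(list(p = sym_proc(), r = 0.75, ta = 5),
                   list(p = asym_proc(), r = 0.95, ta = 1),
                   list(p = env_process(0.4, 0.3), r = 0.55, ta = 20))) {
    pol <- solve_policy(cfg$p, cue_model(cfg$r), T_ont = 6, T_adult = cfg$ta)
    expect_equal(expected_policy_fitness(pol), pol$root_value,
                 tolerance = 1e-10)
  }
})

test_that("Monte-Carlo sampling converges to the exact enumeration", {
  pol <- solve_policy(asym_proc(), cue_model(0.75), T_ont = 6, T_adult = 5)
  traj <- enumerate_weighted_trajectories(pol, "stationary")
  exact_mean_y0 <- sum(traj$weight * traj$y0)
  n <- 3000
  sim <- sample_trajectories(pol, n, "stationary", seed = 123)
  se <- stats::sd(sim$y0) / sqrt(n)
  expect_lt(abs(mean(sim$y0) - exact_mean_y0), 4 * se)
  # conditioning on a start state shifts the distribution accordingly
  traj_e1 <- enumerate_weighted_trajectories(pol, "E1")
  sim_e1 <- sample_trajectories(pol, n, "E1", seed = 124)
  exact_e1 <- sum(traj_e1$weight * traj_e1$y1)
  expect_lt(abs(mean(sim_e1$y1) - exact_e1),
            4 * stats::sd(sim_e1$y1) / sqrt(n))
})

test_that("non-plastic strategies bound the optimal policy from below", {
  proc <- asym_proc()
  cm <- cue_model(0.75)
  opt <- solve_policy(proc, cm, T_ont = 6, T_adult = 5)
  wait <- nonplastic_strategy("always_wait", proc, cm, 6, 5)
  spec <- nonplastic_strategy("always_majority_specialist", proc, cm, 6, 5)
  # waiting forever accrues only baseline fitness (zero by default)
  expect_equal(wait$root_value, 0, tolerance = 1e-12)
  expect_gte(opt$root_value, wait$root_value - 1e-10)
  expect_gte(opt$root_value, spec$root_value - 1e-10)
  # the majority specialist is cue-independent: one mature phenotype
  dist <- mature_phenotype_distribution(
    enumerate_weighted_trajectories(spec, "stationary"))
  expect_equal(nrow(dist), 1)
  expect_equal(dist$y0, 6)  # pi(E0) = 0.6: P0 is the majority target
  # with unreliable cues and long adulthood the specialist is optimal
  opt2 <- solve_policy(proc, cue_model(0.55), T_ont = 6, T_adult = 20)
  spec2 <- nonplastic_strategy("always_majority_specialist", proc,
                               cue_model(0.55), 6, 20)
  expect_equal(opt2$root_value, spec2$root_value, tolerance = 1e-10)
})
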