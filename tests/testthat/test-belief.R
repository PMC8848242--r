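test_that("prior belief equals the stationary distribution", {
  expect_equal(prior_belief(env_process(0.1, 0.1)), 0.5)
  expect_equal(prior_belief(env_process(0.3, 0.2)), 0.4)
  expect_equal(prior_belief(suppressWarnings(env_process(0.2, 0))), 0)
})

test_that("Bayesian updating follows Bayes' theorem", {
  expect_equal(bayes_update(0.5, "C1", cue_model(0.95)), 0.95)
  expect_equal(bayes_update(0.5, "C0", cue_model(0.55)), 0.45)
  expect_equal(bayes_update(0.8, "C1", cue_model(0.75)),
               (0.8 * 0.75) / (0.8 * 0.75 + 0.2 * 0.25))
  # uninformative cues leave any belief unchanged
  for (b in c(0, 0.2, 0.5, 0.9, 1))
    for (cue in c("C0", "C1"))
      expect_equal(bayes_update(b, cue, cue_model(0.5)), b)
})

test_that("belief prediction is one-step Markov propagation", {
  expect_equal(predict_belief(1, env_process(0.1, 0.1)), 0.9)
  expect_equal(predict_belief(0.95, env_process(0.3, 0.2)),
               0.95 * 0.7 + 0.05 * 0.2)
  # the stationary belief is a fixed point
  for (proc in list(env_process(0.1, 0.1), env_process(0.3, 0.2)))
    expect_equal(predict_belief(prior_belief(proc), proc),
                 prior_belief(proc))
})

test_that("forward algorithm matches brute-force hidden-path enumeration", {
  proc <- sym_proc()
  cm <- cue_model(0.75)
  # empty sequence: prior and likelihood 1
  res <- posterior_and_likelihood(integer(0), proc, cm)
  expect_equal(res$belief, 0.5)
  expect_equal(res$likelihood, 1)
  # single uninformative cue is a fair coin flip
  res <- posterior_and_likelihood(1, proc, cue_model(0.5))
  expect_equal(res$likelihood, 0.5)
  expect_equal(res$belief, 0.5)
  # all sequences up to length 4, stationary and known-state starts
  for (t in 1:4) {
    seqs <- oracle_sequences(t)
    for (start in c("stationary", "E0", "E1")) {
      liks <- numeric(nrow(seqs))
      for (i in seq_len(nrow(seqs))) {
        got <- posterior_and_likelihood(seqs[i, ], proc, cm, start)
        want <- oracle_forward(seqs[i, ], proc, 0.75, start)
        expect_equal(got$belief, want$belief, tolerance = 1e-12)
        expect_equal(got$likelihood, want$likelihood, tolerance = 1e-12)
        liks[i] <- got$likelihood
      }
      expect_equal(sum(liks), 1, tolerance = 1e-12)
    }
  }
})

test_that("the belief lattice enumerates every cue history with conserved mass", {
  proc <- sym_proc()
  lat <- enumerate_belief_lattice(proc, cue_model(0.75), 6)
  for (t in 1:6) {
    p <- lat$periods[[t]]
    expect_length(p$belief, 2^t)
    expect_equal(sum(p$reach), 1, tolerance = 1e-12)
    if (t > 1) expect_identical(p$parent, rep(seq_len(2^(t - 1)), each = 2L))
  }
  # period 1, reliability 0.75: beliefs 0.25 / 0.75, each reached w.p. 0.5
  p1 <- lat$periods[[1]]
  expect_equal(sort(p1$belief), c(0.25, 0.75))
  expect_equal(p1$reach, c(0.5, 0.5))
  # lattice nodes agree with per-sequence forward passes
  seqs <- oracle_sequences(4)
  p4 <- lat$periods[[4]]
  for (i in seq_len(nrow(seqs))) {
    res <- posterior_and_likelihood(seqs[i, ], proc, cue_model(0.75))
    expect_equal(p4$belief[i], res$belief, tolerance = 1e-12)
    expect_equal(p4$reach[i], res$likelihood, tolerance = 1e-12)
  }
  # uninformative cues: all histories share the propagated prior
  lat5 <- enumerate_belief_lattice(env_process(0.3, 0.2), cue_model(0.5), 3)
  for (t in 1:3)
    expect_equal(lat5$periods[[t]]$belief,
                 rep(prior_belief(env_process(0.3, 0.2)), 2^t))
})

test_that("beliefs are a martingale under the cue-sequence measure", {
  proc <- env_process(0.3, 0.2)
  lat <- enumerate_belief_lattice(proc, cue_model(0.8), 6)
  start <- unname(stationary_distribution(proc))
  for (t in 1:6) {
    p <- lat$periods[[t]]
    # reach-weighted posterior equals the unconditional state probability
    expect_equal(sum(p$reach * p$belief),
                 unname(propagate(start, proc, t - 1)[["E1"]]),
                 tolerance = 1e-12)
  }
})

test_that("tidy lattice export reconstructs cue histories", {
  lat <- enumerate_belief_lattice(sym_proc(), cue_model(0.75), 3)
  df <- as.data.frame(lat)
  expect_equal(nrow(df), 2 + 4 + 8)
  expect_named(df, c("period", "node", "parent", "cue", "belief", "reach"))
  # walking parent links from leaf 6 (bits 101) recovers cues C1, C0, C1
  leaf <- df[df$period == 3 & df$node == 6, ]
  expect_equal(leaf$cue, "C1")
  mid <- df[df$period == 2 & df$node == leaf$parent, ]
  expect_equal(mid$cue, "C0")
  root <- df[df$period == 1 & df$node == mid$parent, ]
  expect_equal(root$cue, "C1")
})

test_that("adult state distributions propagate the final posterior", {
  proc <- sym_proc()
  d <- adult_state_distributions(1, proc, 3)
  expect_equal(unname(d[, "E1"]), c(1, 0.9, 0.82))
  expect_equal(unname(adult_state_distributions(0.37, proc, 1)[1, "E1"]), 0.37)
  late <- adult_state_distributions(0.9, env_process(0.1, 0.2), 200)
  expect_equal(unname(late[200, ]), c(1 / 3, 2 / 3), tolerance = 1e-9)
  expect_true(all(abs(rowSums(d) - 1) < 1e-12))
})
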