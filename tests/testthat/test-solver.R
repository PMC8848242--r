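test_that("backward induction matches exhaustive policy enumeration at T_ont = 2", {
  proc <- sym_proc()
  cm <- cue_model(0.75)
  pol <- solve_policy(proc, cm, T_ont = 2, T_adult = 5)
  bf <- brute_force_solve(proc, cm, T_ont = 2, T_adult = 5,
                          method = "enumerate")
  expect_equal(pol$root_value, bf$value, tolerance = 1e-10)
  # and the depth-first tree oracle agrees with both
  bf2 <- brute_force_solve(proc, cm, T_ont = 2, T_adult = 5, method = "tree")
  expect_equal(pol$root_value, bf2$value, tolerance = 1e-10)
})

test_that("backward induction matches the tree-search oracle on mixed configurations", {
  for (proc in list(sym_proc(), asym_proc()))
    for (r in c(0.55, 0.95)) {
      pol <- solve_policy(proc, cue_model(r), T_ont = 3, T_adult = 1)
      bf <- brute_force_solve(proc, cue_model(r), T_ont = 3, T_adult = 1)
      expect_equal(pol$root_value, bf$value, tolerance = 1e-10)
    }
  expect_error(brute_force_solve(sym_proc(), cue_model(0.75), 5, 1),
               "too large")
})

test_that("a horizon of one period reduces to the myopic argmax", {
  proc <- asym_proc()
  cm <- cue_model(0.8)
  pol <- solve_policy(proc, cm, T_ont = 1, T_adult = 4)
  for (node in 1:2) {
    q <- action_values(pol, 1, node, 0, 0)
    b <- pol$lattice$periods[[1]]$belief[node]
    want <- vapply(list(c(0, 0), c(1, 0), c(0, 1)), function(ph)
      expected_adult_fitness(ph[1], ph[2], b, proc, 4, pol$mapping, 1),
      numeric(1))
    expect_equal(unname(q), want, tolerance = 1e-12)
    expect_equal(pol$value[[1]][node, 1], max(want), tolerance = 1e-12)
  }
})

test_that("stored action values are optimal and consistent with action_values()", {
  pol <- solve_policy(sym_proc(), cue_model(0.75), T_ont = 4, T_adult = 5)
  for (t in 1:4) {
    g <- phen_grid_df(t - 1)
    for (node in c(1L, 2L^t)) {
      for (j in seq_len(nrow(g))) {
        q <- action_values(pol, t, node, g$y0[j], g$y1[j])
        a <- pol$action[[t]][node, j]
        expect_equal(unname(q[a]), pol$value[[t]][node, j], tolerance = 1e-12)
        expect_gte(q[a], max(q) - 1e-10)
      }
    }
  }
})

test_that("relabeling states, cues and targets mirrors the policy", {
  proc <- env_process(0.3, 0.2)
  mirror <- env_process(0.2, 0.3)
  cm <- cue_model(0.8)
  pol <- solve_policy(proc, cm, T_ont = 4, T_adult = 5)
  mpol <- solve_policy(mirror, cm, T_ont = 4, T_adult = 5)
  expect_equal(pol$root_value, mpol$root_value, tolerance = 1e-12)
  for (t in 1:4) {
    n <- 2^t
    # flipping every cue bit reverses the node order within a period
    mirror_nodes <- n:1
    g <- phen_grid_df(t - 1)
    for (j in seq_len(nrow(g))) {
      jm <- phen_index_oracle(g$y1[j], g$y0[j], t - 1)
      expect_equal(pol$value[[t]][, j],
                   mpol$value[[t]][mirror_nodes, jm], tolerance = 1e-10)
      # mirrored actions: wait stays, spec_P0 <-> spec_P1
      am <- mpol$action[[t]][mirror_nodes, jm]
      am[am > 1L] <- 5L - am[am > 1L]
      expect_equal(pol$action[[t]][, j], am)
    }
  }
})

test_that("expected fitness is nondecreasing in cue reliability", {
  roots <- vapply(c(0.5, 0.55, 0.65, 0.75, 0.85, 0.95, 1), function(r)
    solve_policy(sym_proc(), cue_model(r), T_ont = 6, T_adult = 5)$root_value,
    numeric(1))
  expect_true(all(diff(roots) >= -1e-10))
})

test_that("uninformative cues with asymmetric transitions give a constant policy", {
  # beliefs never move from the propagated prior; pi(E0) = 0.6 so the
  # optimal action is to specialize towards P0 in every state
  pol <- solve_policy(asym_proc(), cue_model(0.5), T_ont = 6, T_adult = 5)
  tab <- policy_table(pol)
  expect_true(all(tab$action == "spec_P0"))
  expect_equal(max(abs(tab$belief - 0.4)), 0, tolerance = 1e-12)
})

test_that("symmetric configurations with uninformative cues tie and are recorded", {
  pol <- solve_policy(sym_proc(), cue_model(0.5), T_ont = 3, T_adult = 2)
  # specializing towards P0 or P1 has equal value at the balanced root state
  q <- action_values(pol, 1, 1, 0, 0)
  expect_equal(unname(q["spec_P0"]), unname(q["spec_P1"]), tolerance = 1e-12)
  expect_gt(nrow(pol$ties), 0)
})

test_that("phenotype increments are irreversible along every trajectory", {
  pol <- solve_policy(asym_proc(), cue_model(0.75), T_ont = 6, T_adult = 5)
  tab <- policy_table(pol)
  for (t in 2:6) {
    cur <- tab[tab$period == t, ]
    prev <- tab[tab$period == t - 1, ]
    expect_true(all(cur$y0 >= prev$y0[cur$parent]))
    expect_true(all(cur$y1 >= prev$y1[cur$parent]))
    expect_true(all(cur$y0 + cur$y1 <= t - 1))
  }
})
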