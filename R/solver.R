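# Actions are coded 1 = wait, 2 = specialize one increment towards P0,
# 3 = specialize towards P1.
ACTIONS <- c("wait", "spec_P0", "spec_P1")

#' @rdname solve_policy
#' @export
action_labels <- function() ACTIONS

# ---- phenotype grids --------------------------------------------------------
#
# The phenotype is (y0, y1): counts of irreversible increments towards P0 and
# P1; waits = elapsed periods - y0 - y1.  The pre-decision grid in period t
# holds all pairs with y0 + y1 <= t - 1, enumerated y0-major.

phen_grid <- function(max_total) {
  y0 <- unlist(lapply(0:max_total, function(a) rep(a, max_total - a + 1L)))
  y1 <- unlist(lapply(0:max_total, function(a) 0:(max_total - a)))
  list(y0 = as.integer(y0), y1 = as.integer(y1))
}

phen_index <- function(y0, y1, max_total) {
  # index of (y0, y1) in phen_grid(max_total)
  as.integer(y0 * (max_total + 1L) - y0 * (y0 - 1L) / 2L + y1 + 1L)
}

# indices, in the period-(t+1) grid, of the successors of every period-t
# phenotype under each action
successor_maps <- function(t) {
  g <- phen_grid(t - 1L)
  list(phen_index(g$y0, g$y1, t),           # wait
       phen_index(g$y0 + 1L, g$y1, t),      # spec_P0
       phen_index(g$y0, g$y1 + 1L, t))      # spec_P1
}

geom_sum <- function(lambda, n) {
  # sum_{i=0}^{n-1} lambda^i
  if (abs(1 - lambda) < 1e-14) n else (1 - lambda^n) / (1 - lambda)
}

# sums over adult periods of P(E0) and P(E1) given the end-of-ontogeny
# posterior(s) b (vectorized)
adult_state_sums <- function(b, process, T_adult) {
  pi1 <- unname(stationary_distribution(process)[["E1"]])
  lambda <- lag1_autocorrelation(process)
  s1 <- T_adult * pi1 + (b - pi1) * geom_sum(lambda, T_adult)
  list(S0 = T_adult - s1, S1 = s1)
}

# terminal value matrix for the final ontogenetic period: rows = cue-history
# nodes (via their posteriors b), columns = post-action phenotypes in
# phen_grid(T_ont)
terminal_values <- function(b, process, T_adult, mapping, T_ont) {
  g <- phen_grid(T_ont)
  parts <- state_fitness_parts(g$y0, g$y1, mapping, T_ont)
  s <- adult_state_sums(b, process, T_adult)
  mapping$baseline * T_adult + outer(s$S0, parts$g0) + outer(s$S1, parts$g1)
}

# ---- backward induction -----------------------------------------------------

#' Solve for the optimal developmental policy
#'
#' Exact finite-horizon stochastic dynamic programming by backward induction
#' over `(period, cue history, phenotype)` states.  In every ontogenetic
#' period the organism samples a cue, updates its belief, and then chooses
#' one of three actions: wait, specialize one increment towards `P0`, or
#' specialize towards `P1` (increments are irreversible).  The value of the
#' final action is the expected fitness across adulthood
#' ([expected_adult_fitness()]); earlier actions weight successor values by
#' the predictive probability of each next cue given the current belief.
#' States are indexed by the full cue history (never merged by belief
#' value), so the recursion is exact.
#'
#' Tie-breaking: when action values tie within `tie_tol` (relative), the
#' preferred action is specialization towards the state with the higher
#' posterior, then `spec_P0`, then `wait`; all ties are recorded in the
#' returned object.
#'
#' @param process An [env_process()].
#' @param cue_model A [cue_model()].
#' @param T_ont Ontogeny length in periods (default 10).
#' @param T_adult Adult lifespan in periods (default 5).
#' @param mapping A [fitness_mapping()].
#' @param tie_tol Relative tolerance for recording/breaking ties.
#' @param rule Optional fixed decision rule `function(period, cue, belief,
#'   y0, y1) -> action` (one of `"wait"`, `"spec_P0"`, `"spec_P1"`).  When
#'   given, the backward pass evaluates this rule instead of optimizing;
#'   used for non-plastic comparison strategies and toy policies.
#' @return An object of class `dev_policy`: the belief lattice, per-period
#'   action and value matrices (rows = cue-history nodes, columns =
#'   pre-decision phenotypes), the tie records, and `root_value`, the
#'   expected terminal fitness of a newborn following the policy.
#' @seealso [policy_table()], [brute_force_solve()], [action_values()]
#' @export
solve_policy <- function(process, cue_model, T_ont = 10, T_adult = 5,
                         mapping = fitness_mapping(), tie_tol = 1e-12,
                         rule = NULL) {
  stopifnot(inherits(process, "env_process"), inherits(cue_model, "cue_model"),
            T_ont >= 1, T_adult >= 1)
  r <- cue_model$reliability
  lattice <- enumerate_belief_lattice(process, cue_model, T_ont, "stationary")
  action <- vector("list", T_ont)
  value <- vector("list", T_ont)
  ties <- list()

  v_next <- NULL  # value matrix of period t+1 (rows: nodes, cols: phenotypes)
  for (t in T_ont:1) {
    beliefs <- lattice$periods[[t]]$belief
    n_nodes <- length(beliefs)
    succ <- successor_maps(t)
    if (t == T_ont) {
      vterm <- terminal_values(beliefs, process, T_adult, mapping, T_ont)
      q <- lapply(succ, function(ix) vterm[, ix, drop = FALSE])
    } else {
      pred <- predict_belief(beliefs, process)
      pc1 <- pred * r + (1 - pred) * (1 - r)
      pc0 <- 1 - pc1
      k <- seq_len(n_nodes)
      child0 <- 2L * k - 1L
      child1 <- 2L * k
      q <- lapply(succ, function(ix)
        pc0 * v_next[child0, ix, drop = FALSE] +
        pc1 * v_next[child1, ix, drop = FALSE])
    }

    if (is.null(rule)) {
      vmax <- pmax(q[[1]], q[[2]], q[[3]])
      tol <- tie_tol * pmax(1, abs(vmax))
      cand <- lapply(q, function(m) m >= vmax - tol)
      prefer_p1 <- matrix(beliefs > 0.5, n_nodes, ncol(vmax))
      chosen <- ifelse(prefer_p1,
                       ifelse(cand[[3]], 3L, ifelse(cand[[2]], 2L, 1L)),
                       ifelse(cand[[2]], 2L, ifelse(cand[[3]], 3L, 1L)))
      n_cand <- cand[[1]] + cand[[2]] + cand[[3]]
      tied <- which(n_cand >= 2L, arr.ind = TRUE)
      if (nrow(tied) > 0L) {
        g <- phen_grid(t - 1L)
        ties[[length(ties) + 1L]] <- data.frame(
          period = t, node = tied[, 1L],
          y0 = g$y0[tied[, 2L]], y1 = g$y1[tied[, 2L]],
          n_tied = n_cand[tied])
      }
    } else {
      g <- phen_grid(t - 1L)
      cue_lab <- c("C0", "C1")[lattice$periods[[t]]$cue + 1L]
      chosen <- matrix(0L, n_nodes, length(g$y0))
      for (k in seq_len(n_nodes))
        for (j in seq_along(g$y0)) {
          a <- rule(t, cue_lab[k], beliefs[k], g$y0[j], g$y1[j])
          chosen[k, j] <- match(a, ACTIONS)
        }
      if (anyNA(chosen)) stop("rule returned an unknown action label")
    }

    v <- q[[1]]
    v[chosen == 2L] <- q[[2]][chosen == 2L]
    v[chosen == 3L] <- q[[3]][chosen == 3L]
    action[[t]] <- chosen
    value[[t]] <- v
    v_next <- v
  }

  # value of a newborn: expectation over the first cue, whose distribution
  # comes from the stationary prior (no transition before the first cue)
  p0 <- prior_belief(process)
  pc1 <- p0 * r + (1 - p0) * (1 - r)
  root_value <- (1 - pc1) * value[[1]][1L, 1L] + pc1 * value[[1]][2L, 1L]

  structure(list(process = process, cue_model = cue_model, T_ont = T_ont,
                 T_adult = T_adult, mapping = mapping, lattice = lattice,
                 action = action, value = value,
                 ties = if (length(ties)) do.call(rbind, ties) else
                   data.frame(period = integer(), node = integer(),
                              y0 = integer(), y1 = integer(),
                              n_tied = integer()),
                 root_value = root_value,
                 optimized = is.null(rule)),
            class = "dev_policy")
}

#' @export
print.dev_policy <- function(x, ...) {
  cat(sprintf("Developmental policy (%s): T_ont = %d, T_adult = %d\n",
              if (x$optimized) "optimal" else "fixed rule",
              x$T_ont, x$T_adult))
  cat(sprintf("  reliability = %g, P(E0|E1) = %g, P(E1|E0) = %g\n",
              x$cue_model$reliability, x$process$p_to_e0, x$process$p_to_e1))
  cat(sprintf("  expected terminal fitness at birth = %.6g\n", x$root_value))
  cat(sprintf("  tie states recorded: %d\n", nrow(x$ties)))
  invisible(x)
}

#' Action values at a single decision state
#'
#' Recomputes the expected terminal fitness of all three actions at state
#' `(period, node, y0, y1)` from the solved policy's stored continuation
#' values (the backward-induction inner step).
#'
#' @param policy A [solve_policy()] result.
#' @param period Ontogenetic period, `1..T_ont`.
#' @param node Cue-history node index at that period (`1..2^period`).
#' @param y0,y1 Pre-decision phenotype (`y0 + y1 <= period - 1`).
#' @return Named numeric vector of the three action values.
#' @export
action_values <- function(policy, period, node, y0, y1) {
  stopifnot(inherits(policy, "dev_policy"),
            period >= 1, period <= policy$T_ont,
            node >= 1, node <= 2^period, y0 >= 0, y1 >= 0,
            y0 + y1 <= period - 1)
  succ <- successor_maps(period)
  j <- phen_index(y0, y1, period - 1L)
  b <- policy$lattice$periods[[period]]$belief[node]
  if (period == policy$T_ont) {
    vterm <- terminal_values(b, policy$process, policy$T_adult,
                             policy$mapping, policy$T_ont)
    q <- vapply(succ, function(ix) vterm[1L, ix[j]], numeric(1))
  } else {
    r <- policy$cue_model$reliability
    pred <- predict_belief(b, policy$process)
    pc1 <- pred * r + (1 - pred) * (1 - r)
    v_next <- policy$value[[period + 1L]]
    q <- vapply(succ, function(ix)
      (1 - pc1) * v_next[2L * node - 1L, ix[j]] +
      pc1 * v_next[2L * node, ix[j]], numeric(1))
  }
  names(q) <- ACTIONS
  q
}

#' Tidy table of a policy along its reachable states
#'
#' Under a deterministic policy each cue history reaches exactly one
#' phenotype, so the reachable states are one row per (period, cue-history
#' node).  This is the data behind policy-lattice plots: posterior belief
#' and reach probability of each node, the pre-decision phenotype, the
#' chosen action, and its value.
#'
#' @param policy A [solve_policy()] result.
#' @return A data.frame with columns `period`, `node`, `parent`, `cue`,
#'   `belief`, `reach`, `y0`, `y1`, `waits`, `action`, `value`.
#' @export
policy_table <- function(policy) {
  stopifnot(inherits(policy, "dev_policy"))
  T_ont <- policy$T_ont
  rows <- vector("list", T_ont)
  # pre[k]: pre-decision phenotype index of node k (in phen_grid(t - 1))
  pre <- c(1L, 1L)  # both period-1 nodes start at the root phenotype (0, 0)
  for (t in seq_len(T_ont)) {
    p <- policy$lattice$periods[[t]]
    k <- seq_along(p$belief)
    g <- phen_grid(t - 1L)
    a <- policy$action[[t]][cbind(k, pre)]
    v <- policy$value[[t]][cbind(k, pre)]
    rows[[t]] <- data.frame(
      period = t, node = k, parent = p$parent,
      cue = c("C0", "C1")[p$cue + 1L],
      belief = p$belief, reach = p$reach,
      y0 = g$y0[pre], y1 = g$y1[pre], waits = t - 1L - g$y0[pre] - g$y1[pre],
      action = ACTIONS[a], value = v)
    succ <- successor_maps(t)
    post <- succ[[1L]][pre]
    post[a == 2L] <- succ[[2L]][pre][a == 2L]
    post[a == 3L] <- succ[[3L]][pre][a == 3L]
    pre <- rep(post, each = 2L)  # children inherit the post-decision phenotype
  }
  do.call(rbind, rows)
}

# ---- brute-force oracles ----------------------------------------------------

#' Brute-force optimal policy for tiny horizons
#'
#' Verification oracle for [solve_policy()], feasible for `T_ont <= 4`.  For
#' `T_ont <= 2` it exhaustively enumerates every deterministic
#' history-dependent policy (an action for each cue-history node) and scores
#' each by direct expectation over all cue sequences, with beliefs and
#' likelihoods recomputed from scratch by [posterior_and_likelihood()].  For
#' larger horizons it performs a depth-first search over the decision tree,
#' again recomputing each belief from scratch, with no shared state between
#' branches.
#'
#' @inheritParams solve_policy
#' @param method `"auto"` (enumeration when feasible), `"enumerate"` or
#'   `"tree"`.
#' @return List with `value`, the maximal expected terminal fitness.
#' @export
brute_force_solve <- function(process, cue_model, T_ont, T_adult,
                              mapping = fitness_mapping(),
                              method = c("auto", "enumerate", "tree")) {
  method <- match.arg(method)
  if (T_ont > 4) stop("horizon too large for brute force")
  if (method == "auto") method <- if (T_ont <= 2) "enumerate" else "tree"
  if (method == "enumerate" && T_ont > 2)
    stop("policy enumeration is only feasible for T_ont <= 2")
  if (method == "enumerate")
    bf_enumerate_policies(process, cue_model, T_ont, T_adult, mapping)
  else
    bf_tree_search(process, cue_model, T_ont, T_adult, mapping)
}

# all 2^T cue sequences as rows (0/1), period 1 in column 1
all_cue_sequences <- function(T) {
  seqs <- as.matrix(expand.grid(rep(list(0:1), T))[, T:1, drop = FALSE])
  dimnames(seqs) <- NULL
  seqs
}

bf_enumerate_policies <- function(process, cue_model, T_ont, T_adult, mapping) {
  # cue-history nodes in period t are prefixes of length t; a deterministic
  # policy assigns one of 3 actions to each node
  seqs <- all_cue_sequences(T_ont)
  n_seq <- nrow(seqs)
  # node id of the length-t prefix of sequence s, within period t
  node_of <- function(s, t) {
    bits <- seqs[s, seq_len(t)]
    sum(bits * 2L^((t - 1L):0)) + 1L
  }
  # per-sequence forward results (stationary start)
  fwd <- lapply(seq_len(n_seq), function(s)
    posterior_and_likelihood(seqs[s, ], process, cue_model, "stationary"))
  nodes_per_period <- 2L^seq_len(T_ont)
  n_nodes <- sum(nodes_per_period)
  offsets <- cumsum(c(0L, nodes_per_period))[seq_len(T_ont)]
  n_policies <- 3L^n_nodes
  best <- -Inf
  best_assign <- NULL
  assign <- integer(n_nodes)
  for (p in seq_len(n_policies) - 1L) {
    x <- p
    for (i in seq_len(n_nodes)) { assign[i] <- x %% 3L + 1L; x <- x %/% 3L }
    total <- 0
    for (s in seq_len(n_seq)) {
      y0 <- 0L; y1 <- 0L
      for (t in seq_len(T_ont)) {
        a <- assign[offsets[t] + node_of(s, t)]
        if (a == 2L) y0 <- y0 + 1L else if (a == 3L) y1 <- y1 + 1L
      }
      total <- total + fwd[[s]]$likelihood *
        expected_adult_fitness(y0, y1, fwd[[s]]$belief, process, T_adult,
                               mapping, T_ont)
    }
    if (total > best) { best <- total; best_assign <- assign }
  }
  list(value = best, assignment = best_assign)
}

bf_tree_search <- function(process, cue_model, T_ont, T_adult, mapping) {
  r <- cue_model$reliability
  rec <- function(cues, y0, y1) {
    t <- length(cues)
    fwd <- posterior_and_likelihood(cues, process, cue_model, "stationary")
    b <- fwd$belief
    vals <- vapply(1:3, function(a) {
      ny0 <- y0 + (a == 2L); ny1 <- y1 + (a == 3L)
      if (t == T_ont) {
        expected_adult_fitness(ny0, ny1, b, process, T_adult, mapping, T_ont)
      } else {
        pred <- predict_belief(b, process)
        pc1 <- pred * r + (1 - pred) * (1 - r)
        (1 - pc1) * rec(c(cues, 0L), ny0, ny1) +
          pc1 * rec(c(cues, 1L), ny0, ny1)
      }
    }, numeric(1))
    max(vals)
  }
  p0 <- prior_belief(process)
  pc1 <- p0 * r + (1 - p0) * (1 - r)
  list(value = (1 - pc1) * rec(0L, 0L, 0L) + pc1 * rec(1L, 0L, 0L))
}
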