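# Walk every cue history through a deterministic policy, tracking the unique
# phenotype reached along each path.  Returns, per period, the pre-decision
# phenotype index of each node and, for the leaves, the final phenotype index
# in phen_grid(T_ont).
walk_phenotypes <- function(policy) {
  T_ont <- policy$T_ont
  pre <- vector("list", T_ont)
  cur <- c(1L, 1L)  # both period-1 nodes start at (0, 0)
  for (t in seq_len(T_ont)) {
    pre[[t]] <- cur
    k <- seq_along(cur)
    a <- policy$action[[t]][cbind(k, cur)]
    succ <- successor_maps(t)
    post <- succ[[1L]][cur]
    post[a == 2L] <- succ[[2L]][cur][a == 2L]
    post[a == 3L] <- succ[[3L]][cur][a == 3L]
    cur <- if (t < T_ont) rep(post, each = 2L) else post
  }
  list(pre = pre, final = cur)
}

leaf_cue_string <- function(leaf, T_ont) {
  # bits of (leaf - 1), most significant first, are the cues of periods 1..T
  bits <- vapply(seq_len(T_ont), function(t)
    bitwAnd(bitwShiftR(leaf - 1L, T_ont - t), 1L), integer(length(leaf)))
  if (is.null(dim(bits))) bits <- matrix(bits, nrow = 1L)
  apply(bits, 1L, function(b) paste0("C", b, collapse = ""))
}

#' Enumerate all likelihood-weighted developmental trajectories
#'
#' Walks every possible cue sequence (all `2^T_ont` of them) through a
#' deterministic policy, yielding one trajectory per sequence.  Each
#' trajectory is weighted by the forward-algorithm likelihood of its cue
#' sequence conditioned on the patch's true starting environment (the
#' experimenter's frame); the organism's beliefs along the way always start
#' from the stationary prior (the organism's frame).
#'
#' @param policy A [solve_policy()] result.
#' @param start_env Conditioning start state for the weights: `"E0"`,
#'   `"E1"`, or `"stationary"` (unconditional).
#' @return A data.frame with one row per cue sequence: `leaf` (history
#'   index), `cues`, final phenotype `y0`, `y1`, `waits`, `weight`
#'   (likelihood of the sequence; sums to 1), and `final_belief` (the
#'   organism's posterior P(E1) at the end of ontogeny).
#' @export
enumerate_weighted_trajectories <- function(policy,
                                            start_env = c("stationary", "E0", "E1")) {
  stopifnot(inherits(policy, "dev_policy"))
  start_env <- match.arg(start_env)
  T_ont <- policy$T_ont
  if (T_ont > 14)
    stop("exhaustive enumeration is limited to T_ont <= 14; ",
         "use sample_trajectories() for longer ontogenies")
  w <- walk_phenotypes(policy)
  weights <-
    if (start_env == "stationary") policy$lattice$periods[[T_ont]]$reach
    else enumerate_belief_lattice(policy$process, policy$cue_model, T_ont,
                                  start_env)$periods[[T_ont]]$reach
  g <- phen_grid(T_ont)
  leaf <- seq_len(2L^T_ont)
  y0 <- g$y0[w$final]; y1 <- g$y1[w$final]
  data.frame(leaf = leaf,
             cues = leaf_cue_string(leaf, T_ont),
             y0 = y0, y1 = y1, waits = T_ont - y0 - y1,
             weight = weights,
             final_belief = policy$lattice$periods[[T_ont]]$belief)
}

#' Monte-Carlo sample of developmental trajectories
#'
#' Samples environment/cue realizations and walks them through the policy;
#' converges to [enumerate_weighted_trajectories()] as `n` grows.  Intended
#' for ontogenies too long to enumerate and for cross-checks.
#'
#' @param policy A [solve_policy()] result.
#' @param n Number of sampled organisms.
#' @param start_env `"stationary"` (start state drawn from the stationary
#'   distribution), `"E0"` or `"E1"`.
#' @param seed Optional integer seed.
#' @return A data.frame with one row per sampled organism: `y0`, `y1`,
#'   `waits`, `start_state`, `final_env`.
#' @export
sample_trajectories <- function(policy, n, start_env = "stationary",
                                seed = NULL) {
  stopifnot(inherits(policy, "dev_policy"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  T_ont <- policy$T_ont
  proc <- policy$process
  r <- policy$cue_model$reliability
  pi <- stationary_distribution(proc)
  succs <- lapply(seq_len(T_ont), successor_maps)
  g <- phen_grid(T_ont)
  out <- data.frame(y0 = integer(n), y1 = integer(n), waits = integer(n),
                    start_state = character(n), final_env = character(n))
  for (i in seq_len(n)) {
    s0 <- if (start_env == "stationary")
      sample(c("E0", "E1"), 1L, prob = pi) else start_env
    env <- sample_trajectory(proc, s0, T_ont)
    correct <- stats::runif(T_ont) < r
    cues <- ifelse(correct, as.integer(env == "E1"), as.integer(env == "E0"))
    node <- 1L
    phen <- 1L
    for (t in seq_len(T_ont)) {
      node <- if (t == 1L) cues[1L] + 1L else 2L * node - 1L + cues[t]
      a <- policy$action[[t]][node, phen]
      phen <- succs[[t]][[a]][phen]
    }
    out$y0[i] <- g$y0[phen]; out$y1[i] <- g$y1[phen]
    out$waits[i] <- T_ont - out$y0[i] - out$y1[i]
    out$start_state[i] <- s0
    out$final_env[i] <- env[T_ont]
  }
  out
}

#' Distribution of mature phenotypes
#'
#' Aggregates trajectory weights by final phenotype `(y0, y1, waits)`.
#'
#' @param trajectories Output of [enumerate_weighted_trajectories()].
#' @return A data.frame `y0`, `y1`, `waits`, `weight`, sorted by decreasing
#'   weight; weights sum to 1.
#' @export
mature_phenotype_distribution <- function(trajectories) {
  agg <- stats::aggregate(weight ~ y0 + y1 + waits, data = trajectories, FUN = sum)
  agg[order(-agg$weight), , drop = FALSE]
}

#' Non-plastic comparison strategies
#'
#' Two cue-independent policies against which the optimal policy is
#' compared: `"always_majority_specialist"` specializes every period towards
#' the state with the higher stationary probability (towards `P0` on a
#' tie), and `"always_wait"` never specializes, accruing only baseline
#' fitness.  Both are built through the same policy machinery, so their
#' expected fitness is computed identically to the optimal policy's.
#'
#' @param kind `"always_majority_specialist"` or `"always_wait"`.
#' @inheritParams solve_policy
#' @return A `dev_policy` with the fixed rule evaluated (not optimized).
#' @export
nonplastic_strategy <- function(kind = c("always_majority_specialist",
                                         "always_wait"),
                                process, cue_model, T_ont = 10, T_adult = 5,
                                mapping = fitness_mapping()) {
  kind <- match.arg(kind)
  rule <- if (kind == "always_wait") {
    function(period, cue, belief, y0, y1) "wait"
  } else {
    pi <- stationary_distribution(process)
    target <- if (pi[["E1"]] > pi[["E0"]]) "spec_P1" else "spec_P0"
    function(period, cue, belief, y0, y1) target
  }
  solve_policy(process, cue_model, T_ont, T_adult, mapping, rule = rule)
}

#' Expected terminal fitness of a policy by trajectory enumeration
#'
#' Weights every trajectory's end-of-ontogeny expected adult fitness by the
#' likelihood of its cue sequence.  For an optimal policy this equals the
#' dynamic-programming root value (a consistency check used in the test
#' suite).
#'
#' @param policy A [solve_policy()] result.
#' @return Scalar expected terminal fitness.
#' @export
expected_policy_fitness <- function(policy) {
  traj <- enumerate_weighted_trajectories(policy, "stationary")
  vals <- vapply(seq_len(nrow(traj)), function(i)
    expected_adult_fitness(traj$y0[i], traj$y1[i], traj$final_belief[i],
                           policy$process, policy$T_adult, policy$mapping,
                           policy$T_ont), numeric(1))
  sum(traj$weight * vals)
}
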