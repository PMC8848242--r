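#' Phenotype-to-fitness mapping
#'
#' Adult fitness in each period is `baseline + reward(correct) -
#' penalty_weight * penalty(incorrect)`, where `correct` is the number of
#' phenotypic increments matching the current environmental state and
#' `incorrect` the number matching the other state.  Reward and penalty
#' each use one of three marginal shapes — `"linear"`, `"increasing"`
#' (accelerating marginal returns, convex) or `"diminishing"` (decelerating,
#' concave) — and the penalty weight scales mismatch costs (0.5, 1 or 2 in
#' the study design; any positive value is accepted).
#'
#' The cumulative value of `y` increments is `T_ont * (y / T_ont)^k` with
#' `k = 1` (linear), `k = 2` (increasing) and `k = 0.5` (diminishing): zero
#' at zero increments, nondecreasing, and equal to `T_ont` at full
#' specialization, so shapes agree at both endpoints and differ in
#' curvature.
#'
#' @param reward_shape,penalty_shape One of `"linear"`, `"increasing"`,
#'   `"diminishing"`.
#' @param penalty_weight Positive scalar weight on mismatch penalties.
#' @param baseline Baseline fitness per adult period for an organism with no
#'   specializations; default 0.
#' @return Object of class `fitness_mapping`.
#' @export
fitness_mapping <- function(reward_shape = "linear", penalty_shape = "linear",
                            penalty_weight = 1, baseline = 0) {
  shapes <- c("linear", "increasing", "diminishing")
  reward_shape <- match.arg(reward_shape, shapes)
  penalty_shape <- match.arg(penalty_shape, shapes)
  stopifnot(is.numeric(penalty_weight), penalty_weight > 0,
            is.numeric(baseline), length(baseline) == 1L)
  structure(list(reward_shape = reward_shape, penalty_shape = penalty_shape,
                 penalty_weight = penalty_weight, baseline = baseline),
            class = "fitness_mapping")
}

#' Cumulative reward/penalty value of a specialization count
#'
#' @param shape `"linear"`, `"increasing"` or `"diminishing"`.
#' @param y Number of increments, `0 <= y <= T_ont` (vectorized).
#' @param T_ont Length of ontogeny (scaling constant of the mapping).
#' @return Cumulative value; 0 at `y = 0`, `T_ont` at `y = T_ont`.
#' @export
cumulative_value <- function(shape, y, T_ont) {
  shape <- match.arg(shape, c("linear", "increasing", "diminishing"))
  if (any(y < 0 | y > T_ont))
    stop("increment count out of range [0, T_ont]")
  k <- switch(shape, linear = 1, increasing = 2, diminishing = 0.5)
  T_ont * (y / T_ont)^k
}

#' Fitness accrued in a single adult period
#'
#' @param y0,y1 Increments specialized towards `P0` and `P1` (vectorized).
#' @param env Current environmental state, `"E0"` or `"E1"`.
#' @param mapping A [fitness_mapping()].
#' @param T_ont Length of ontogeny.
#' @return Per-period fitness `baseline + reward(correct) - w * penalty(incorrect)`.
#' @export
period_fitness <- function(y0, y1, env, mapping, T_ont) {
  stopifnot(inherits(mapping, "fitness_mapping"), env %in% c("E0", "E1"))
  correct <- if (env == "E0") y0 else y1
  incorrect <- if (env == "E0") y1 else y0
  mapping$baseline +
    cumulative_value(mapping$reward_shape, correct, T_ont) -
    mapping$penalty_weight *
      cumulative_value(mapping$penalty_shape, incorrect, T_ont)
}

# net fitness (excluding baseline) of phenotype (y0, y1) in each state;
# vectorized over phenotypes.  Returns list(g0 = in E0, g1 = in E1).
state_fitness_parts <- function(y0, y1, mapping, T_ont) {
  rew0 <- cumulative_value(mapping$reward_shape, y0, T_ont)
  rew1 <- cumulative_value(mapping$reward_shape, y1, T_ont)
  pen0 <- cumulative_value(mapping$penalty_shape, y0, T_ont)
  pen1 <- cumulative_value(mapping$penalty_shape, y1, T_ont)
  list(g0 = rew0 - mapping$penalty_weight * pen1,
       g1 = rew1 - mapping$penalty_weight * pen0)
}

#' Expected fitness summed across adulthood
#'
#' Total fitness is the sum of per-period fitness across `T_adult` adult
#' periods, taken in expectation over the environmental state of each adult
#' period as given by [adult_state_distributions()].  Linear in the belief
#' for a fixed phenotype.
#'
#' @param y0,y1 Mature phenotype (increments towards `P0` and `P1`).
#' @param final_belief Posterior P(E1) at the end of ontogeny.
#' @param process An [env_process()].
#' @param T_adult Number of adult periods.
#' @param mapping A [fitness_mapping()].
#' @param T_ont Length of ontogeny.
#' @return Expected total adult fitness (scalar).
#' @export
expected_adult_fitness <- function(y0, y1, final_belief, process, T_adult,
                                   mapping, T_ont) {
  dist <- adult_state_distributions(final_belief, process, T_adult)
  parts <- state_fitness_parts(y0, y1, mapping, T_ont)
  mapping$baseline * T_adult +
    sum(dist[, "E0"]) * parts$g0 + sum(dist[, "E1"]) * parts$g1
}
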