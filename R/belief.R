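#' Cue model: reliability of environmental cues
#'
#' In every ontogenetic period the organism samples one cost-free, imperfect
#' binary cue (`C0` or `C1`) to the current environmental state.  The
#' reliability is the probability of sampling the correct cue in the
#' corresponding state, P(C0|E0) = P(C1|E1); the incorrect cue has
#' probability `1 - reliability`.  Reliability 0.5 makes cues uninformative,
#' 1 makes them perfect.
#'
#' @param reliability Probability in `[0.5, 1]`.
#' @return Object of class `cue_model`.
#' @export
cue_model <- function(reliability) {
  stopifnot(is.numeric(reliability), length(reliability) == 1L)
  if (reliability < 0.5 || reliability > 1)
    stop("cue reliability must lie in [0.5, 1]")
  structure(list(reliability = reliability), class = "cue_model")
}

# cue emission likelihoods P(cue | E0), P(cue | E1); cue is 0 or 1
cue_likelihood <- function(cue, reliability) {
  if (cue == 0L) c(reliability, 1 - reliability)
  else           c(1 - reliability, reliability)
}

as_cue_int <- function(cues) {
  if (is.character(cues)) {
    stopifnot(all(cues %in% c("C0", "C1")))
    return(as.integer(cues == "C1"))
  }
  stopifnot(all(cues %in% c(0, 1)))
  as.integer(cues)
}

#' Prior belief at the onset of ontogeny
#'
#' The organism's evolutionary prior over environmental states is the
#' stationary distribution of the environment process.  Beliefs are carried
#' as the probability of currently being in `E1`.
#'
#' @param process An [env_process()].
#' @return Scalar P(E1), the prior probability of `E1`.
#' @export
prior_belief <- function(process) {
  unname(stationary_distribution(process)[["E1"]])
}

#' Bayesian belief update after observing one cue
#'
#' posterior ∝ likelihood × predictive.  With reliability 0.5 the posterior
#' equals the predictive belief (uninformative cue).
#'
#' @param belief Predictive probability P(E1) before the cue.
#' @param cue `"C0"`/`"C1"` (or 0/1).
#' @param cue_model A [cue_model()].
#' @return Posterior probability P(E1).
#' @export
bayes_update <- function(belief, cue, cue_model) {
  stopifnot(belief >= 0, belief <= 1, inherits(cue_model, "cue_model"))
  cue <- as_cue_int(cue)
  lik <- cue_likelihood(cue, cue_model$reliability)
  num <- belief * lik[2]
  den <- (1 - belief) * lik[1] + num
  if (den == 0)
    stop("cue has zero probability under the current belief")
  num / den
}

#' One-step Markov prediction of a belief
#'
#' Propagates a posterior belief one environmental transition forward: the
#' prediction step of the hidden-Markov forward recursion.
#'
#' @param belief Posterior probability P(E1).
#' @param process An [env_process()].
#' @return Predictive probability P(E1) for the next period.
#' @export
predict_belief <- function(belief, process) {
  stopifnot(belief >= 0, belief <= 1)
  belief * (1 - process$p_to_e0) + (1 - belief) * process$p_to_e1
}

start_distribution <- function(process, start_condition) {
  if (identical(start_condition, "stationary"))
    return(unname(stationary_distribution(process)))
  if (identical(start_condition, "E0")) return(c(1, 0))
  if (identical(start_condition, "E1")) return(c(0, 1))
  stop("start_condition must be \"stationary\", \"E0\" or \"E1\"")
}

#' Forward algorithm: posterior belief and cue-sequence likelihood
#'
#' Treats ontogeny as a hidden Markov model (environmental states hidden,
#' cues observed) and runs the forward recursion over a cue sequence.  The
#' period-1 predictive distribution is the start condition itself (no
#' transition is applied before the first cue); between subsequent periods
#' the environment transitions once.
#'
#' @param cues Vector of cues (`"C0"`/`"C1"` or 0/1), possibly empty.
#' @param process An [env_process()].
#' @param cue_model A [cue_model()].
#' @param start_condition `"stationary"` (the evolutionary prior) or a known
#'   start state `"E0"`/`"E1"` (the experimenter's frame, used to weight cue
#'   sequences by the patch's true initial state).
#' @return List with `belief` (posterior P(E1) after the last cue; the
#'   start-condition P(E1) for an empty sequence) and `likelihood` (marginal
#'   probability of the cue sequence).  Likelihoods over all `2^t` sequences
#'   of length `t` sum to 1.
#' @export
posterior_and_likelihood <- function(cues, process, cue_model,
                                     start_condition = "stationary") {
  stopifnot(inherits(process, "env_process"), inherits(cue_model, "cue_model"))
  cues <- as_cue_int(cues)
  alpha <- start_distribution(process, start_condition)
  if (length(cues) == 0L)
    return(list(belief = alpha[2], likelihood = 1))
  m <- transition_matrix(process)
  r <- cue_model$reliability
  for (i in seq_along(cues)) {
    if (i > 1L) alpha <- as.numeric(alpha %*% m)
    alpha <- alpha * cue_likelihood(cues[i], r)
  }
  lik <- sum(alpha)
  list(belief = alpha[2] / lik, likelihood = lik)
}

# ---- cue-history lattice ----------------------------------------------------
#
# Cue histories of length t are indexed 1..2^t: node k at period t has
# children 2k-1 (cue C0) and 2k (cue C1) at period t+1 and parent
# ceiling(k/2).  Equivalently, the bits of (k-1), most significant first,
# are the cues sampled in periods 1..t.  Nodes are never merged by belief
# value: each cue history is carried exactly.

node_cue <- function(k) 1L - (k %% 2L)  # odd node = C0, even node = C1

#' Enumerate the belief lattice over all cue histories
#'
#' Runs the forward algorithm over every cue history up to horizon `T`,
#' producing for each period the full set of `2^t` history nodes with their
#' posterior beliefs and reach probabilities (the likelihood of the cue
#' history under the start condition).
#'
#' @param process An [env_process()].
#' @param cue_model A [cue_model()].
#' @param T Horizon (number of ontogenetic periods), >= 1.
#' @param start_condition As in [posterior_and_likelihood()].
#' @return List of class `belief_lattice` with element `periods`: one list
#'   per period `t` holding numeric vectors `belief` and `reach` (length
#'   `2^t`, reach sums to 1) and integer vectors `parent` and `cue`.
#'   `as.data.frame()` turns it into a tidy table.
#' @export
enumerate_belief_lattice <- function(process, cue_model, T,
                                     start_condition = "stationary") {
  stopifnot(T >= 1, T == round(T))
  r <- cue_model$reliability
  m <- transition_matrix(process)
  start <- start_distribution(process, start_condition)
  periods <- vector("list", T)
  # alpha0/alpha1: unnormalized forward variables per node
  lik0 <- cue_likelihood(0L, r); lik1 <- cue_likelihood(1L, r)
  a0 <- c(start[1] * lik0[1], start[1] * lik1[1])
  a1 <- c(start[2] * lik0[2], start[2] * lik1[2])
  for (t in seq_len(T)) {
    if (t > 1L) {
      # predict: one environment transition, then update with this period's cue
      p0 <- a0 * m[1, 1] + a1 * m[2, 1]
      p1 <- a0 * m[1, 2] + a1 * m[2, 2]
      p0 <- rep(p0, each = 2L); p1 <- rep(p1, each = 2L)
      k <- seq_len(2L^t)
      cue_lik0 <- ifelse(node_cue(k) == 0L, lik0[1], lik1[1])
      cue_lik1 <- ifelse(node_cue(k) == 0L, lik0[2], lik1[2])
      a0 <- p0 * cue_lik0
      a1 <- p1 * cue_lik1
    }
    reach <- a0 + a1
    k <- seq_len(2L^t)
    periods[[t]] <- list(belief = a1 / reach, reach = reach,
                         parent = as.integer(ceiling(k / 2)),
                         cue = node_cue(k))
  }
  structure(list(periods = periods, T = T,
                 start_condition = start_condition),
            class = "belief_lattice")
}

#' @export
as.data.frame.belief_lattice <- function(x, ...) {
  do.call(rbind, lapply(seq_len(x$T), function(t) {
    p <- x$periods[[t]]
    data.frame(period = t, node = seq_along(p$belief),
               parent = p$parent, cue = c("C0", "C1")[p$cue + 1L],
               belief = p$belief, reach = p$reach)
  }))
}

#' Environmental state distributions across adulthood
#'
#' Adults stop sampling cues; their phenotype is fixed and the environment
#' keeps fluctuating.  The distribution over states in the first adult
#' period equals the posterior at the end of ontogeny; subsequent adult
#' periods propagate it by the transition matrix, converging towards the
#' stationary distribution.
#'
#' @param final_belief Posterior P(E1) in the final ontogenetic period.
#' @param process An [env_process()].
#' @param T_adult Number of adult periods, >= 1.
#' @return A `T_adult` x 2 matrix; row `i` is the state distribution
#'   `(P(E0), P(E1))` in adult period `i` (row 1 = the posterior itself).
#' @export
adult_state_distributions <- function(final_belief, process, T_adult) {
  stopifnot(T_adult >= 1, T_adult == round(T_adult),
            final_belief >= 0, final_belief <= 1)
  pi1 <- unname(stationary_distribution(process)[["E1"]])
  lambda <- lag1_autocorrelation(process)
  p_e1 <- pi1 + (final_belief - pi1) * lambda^(seq_len(T_adult) - 1L)
  cbind(E0 = 1 - p_e1, E1 = p_e1)
}
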