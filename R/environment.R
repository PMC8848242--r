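#' Two-state Markov environment process
#'
#' Constructs the environmental process: a patch switches stochastically
#' between two states, `E0` and `E1`, with fixed per-period transition
#' probabilities.  `p_to_e0` is the probability of switching to `E0` given the
#' patch is currently in `E1`, i.e. P(E0|E1); `p_to_e1` is P(E1|E0).
#'
#' The model's study regime uses positively autocorrelated environments, i.e.
#' both probabilities below 0.5 (switching less likely than staying).  Values
#' in `[0, 1]` are accepted, but values outside `(0, 0.5)` raise a warning
#' because they fall outside that regime (0.5 gives serially independent
#' states, larger values negative autocorrelation).
#'
#' @param p_to_e0 Probability P(E0|E1) of switching from `E1` to `E0` in one
#'   time period.
#' @param p_to_e1 Probability P(E1|E0) of switching from `E0` to `E1`.
#' @return An object of class `env_process`.
#' @examples
#' proc <- env_process(0.1, 0.1)
#' stationary_distribution(proc)
#' @export
env_process <- function(p_to_e0, p_to_e1) {
  stopifnot(is.numeric(p_to_e0), length(p_to_e0) == 1L,
            is.numeric(p_to_e1), length(p_to_e1) == 1L)
  if (p_to_e0 < 0 || p_to_e0 > 1 || p_to_e1 < 0 || p_to_e1 > 1)
    stop("transition probabilities must lie in [0, 1]")
  out_of_regime <- function(p) p <= 0 || p >= 0.5
  if (out_of_regime(p_to_e0) || out_of_regime(p_to_e1))
    warning("transition probabilities outside (0, 0.5): ",
            "environment is not positively autocorrelated with two ",
            "recurrent states", call. = FALSE)
  structure(list(p_to_e0 = p_to_e0, p_to_e1 = p_to_e1),
            class = "env_process")
}

#' @export
print.env_process <- function(x, ...) {
  cat("Two-state Markov environment\n")
  cat(sprintf("  P(E0|E1) = %g, P(E1|E0) = %g\n", x$p_to_e0, x$p_to_e1))
  cat(sprintf("  lag-1 autocorrelation = %g, asymmetry = %g\n",
              lag1_autocorrelation(x), asymmetry(x)))
  pi <- stationary_distribution(x)
  cat(sprintf("  stationary: pi(E0) = %g, pi(E1) = %g\n", pi[1], pi[2]))
  invisible(x)
}

#' Transition matrix of an environment process
#'
#' Rows are the current state (`E0`, `E1`), columns the next state.
#'
#' @param process An [env_process()].
#' @return A 2x2 row-stochastic matrix with dimnames `E0`/`E1`.
#' @export
transition_matrix <- function(process) {
  stopifnot(inherits(process, "env_process"))
  m <- rbind(c(1 - process$p_to_e1, process$p_to_e1),
             c(process$p_to_e0, 1 - process$p_to_e0))
  dimnames(m) <- list(c("E0", "E1"), c("E0", "E1"))
  m
}

#' Stationary distribution of the environment
#'
#' Long-run probability of each state:
#' pi(E0) = P(E0|E1) / (P(E0|E1) + P(E1|E0)), pi(E1) = 1 - pi(E0).
#' This distribution is the organism's evolutionary prior over states at the
#' onset of ontogeny.
#'
#' @param process An [env_process()].
#' @return Named numeric vector `c(E0 = , E1 = )` summing to 1.
#' @export
stationary_distribution <- function(process) {
  stopifnot(inherits(process, "env_process"))
  s <- process$p_to_e0 + process$p_to_e1
  if (s == 0)
    stop("degenerate chain: both transition probabilities are zero")
  c(E0 = process$p_to_e0 / s, E1 = process$p_to_e1 / s)
}

#' Asymmetry of the transition probabilities
#'
#' The signed difference P(E0|E1) - P(E1|E0).  A positive asymmetry makes
#' `E0` the more likely state in the stationary distribution.
#'
#' @param process An [env_process()].
#' @return A signed scalar in `[-1, 1]`.
#' @export
asymmetry <- function(process) {
  stopifnot(inherits(process, "env_process"))
  process$p_to_e0 - process$p_to_e1
}

#' Lag-1 autocorrelation of the environment
#'
#' For a two-state chain the lag-1 autocorrelation of the state sequence
#' (states coded 0/1) equals `1 - P(E0|E1) - P(E1|E0)`, the second eigenvalue
#' of the transition matrix.  Higher transition probabilities produce lower
#' autocorrelations.
#'
#' @param process An [env_process()].
#' @return A scalar in `(-1, 1]`.
#' @export
lag1_autocorrelation <- function(process) {
  stopifnot(inherits(process, "env_process"))
  1 - process$p_to_e0 - process$p_to_e1
}

#' Build an environment process from autocorrelation and asymmetry
#'
#' Inverts the relationship used by [lag1_autocorrelation()] and
#' [asymmetry()] so that a study can be specified as, e.g., "autocorrelation
#' 0.8, asymmetry 0.1".  The convention follows the asymmetric study design:
#' a positive `asym` sets P(E0|E1) - P(E1|E0) = `asym`, making `E0` the more
#' likely state.
#'
#' @param rho Target lag-1 autocorrelation.
#' @param asym Target asymmetry P(E0|E1) - P(E1|E0); default 0 (symmetric).
#' @return An [env_process()] with `lag1_autocorrelation(x) == rho` and
#'   `asymmetry(x) == asym`.
#' @examples
#' process_from_autocorrelation(0.8)        # symmetric (0.1, 0.1)
#' process_from_autocorrelation(0.5, 0.1)   # asymmetric (0.3, 0.2)
#' @export
process_from_autocorrelation <- function(rho, asym = 0) {
  stopifnot(is.numeric(rho), length(rho) == 1L,
            is.numeric(asym), length(asym) == 1L)
  p_to_e0 <- (1 - rho + asym) / 2
  p_to_e1 <- (1 - rho - asym) / 2
  eps <- 1e-12
  if (p_to_e0 < -eps || p_to_e0 > 1 + eps || p_to_e1 < -eps || p_to_e1 > 1 + eps)
    stop(sprintf(
      "no valid chain: autocorrelation %g with asymmetry %g requires a transition probability outside [0, 1]",
      rho, asym))
  env_process(min(max(p_to_e0, 0), 1), min(max(p_to_e1, 0), 1))
}

#' Propagate a state distribution forward in time
#'
#' Multiplies a probability distribution over `(E0, E1)` by the n-step
#' transition matrix.  As `n_steps` grows the result converges to the
#' stationary distribution.
#'
#' @param distribution Numeric pair `(P(E0), P(E1))` summing to 1.
#' @param process An [env_process()].
#' @param n_steps Number of time periods to advance (0 = identity).
#' @return Named numeric pair summing to 1.
#' @export
propagate <- function(distribution, process, n_steps) {
  stopifnot(length(distribution) == 2L, all(distribution >= 0),
            abs(sum(distribution) - 1) < 1e-9,
            n_steps >= 0, n_steps == round(n_steps))
  # closed form via the eigendecomposition: deviation from stationarity
  # shrinks by the autocorrelation each step
  pi <- stationary_distribution(process)
  lambda <- lag1_autocorrelation(process)
  p_e1 <- pi[["E1"]] + (distribution[2] - pi[["E1"]]) * lambda^n_steps
  c(E0 = 1 - p_e1, E1 = p_e1)
}

#' Sample an environmental trajectory
#'
#' Simulates a realization of the two-state chain, mainly useful as a
#' Monte-Carlo check of the closed-form quantities.
#'
#' @param process An [env_process()].
#' @param start Starting state, `"E0"` or `"E1"` (occupies period 1).
#' @param length Number of time periods (>= 1).
#' @param seed Optional integer seed for reproducibility.
#' @return Character vector of states `"E0"`/`"E1"` of length `length`.
#' @export
sample_trajectory <- function(process, start = c("E0", "E1"), length, seed = NULL) {
  start <- match.arg(start)
  stopifnot(length >= 1, length == round(length))
  if (!is.null(seed)) set.seed(seed)
  p_switch <- c(E0 = process$p_to_e1, E1 = process$p_to_e0)
  states <- integer(length)  # 0 = E0, 1 = E1
  states[1] <- if (start == "E1") 1L else 0L
  if (length > 1L) {
    u <- stats::runif(length - 1L)
    for (t in 2:length) {
      cur <- states[t - 1L]
      switch_p <- if (cur == 0L) p_switch[["E0"]] else p_switch[["E1"]]
      states[t] <- if (u[t - 1L] < switch_p) 1L - cur else cur
    }
  }
  c("E0", "E1")[states + 1L]
}
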