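# Copy's leaf index when the focal has leaf index `leaf` and the pair is
# separated at period `sep`: cues in periods sep..T_ont are flipped, i.e. the
# low (T_ont - sep + 1) bits of (leaf - 1) are inverted.
mirror_leaf <- function(leaf, sep, T_ont) {
  mask <- 2L^(T_ont - sep + 1L) - 1L
  bitwXor(leaf - 1L, mask) + 1L
}

#' Simulated adoption study at one separation time
#'
#' Simulates the twin/adoption paradigm: every possible cue sequence yields
#' one pair of clones developing under the policy.  The pair shares cues
#' (and hence phenotypic decisions) in periods `1 .. separation_time - 1`;
#' from `separation_time` onward the copy develops in a mirror patch and
#' samples the reciprocal opposite cue in every period (focal `C0` vs copy
#' `C1` and vice versa).  Plasticity is the weighted mean Euclidean distance
#' between the pairs' mature phenotype vectors `(y0, y1)`, weighted by the
#' likelihood of the focal's cue sequence given the true starting
#' environment, and normalized by the maximally attainable distance
#' `sqrt(2) * (T_ont - separation_time + 1)` so it ranges from 0 to 1.
#'
#' @param policy A [solve_policy()] result.
#' @param start_env True environmental state of the patch in period 1
#'   (`"E0"` or `"E1"`); used to weight the cue sequences.
#' @param separation_time Period `1..T_ont` from which cues diverge
#'   (inclusive); `1` means fully divergent twins, `T_ont` a single
#'   divergent cue.
#' @return Normalized weighted mean phenotypic distance in `[0, 1]`.
#' @export
run_adoption_study <- function(policy, start_env = c("E0", "E1"),
                               separation_time) {
  stopifnot(inherits(policy, "dev_policy"))
  start_env <- match.arg(start_env)
  T_ont <- policy$T_ont
  if (separation_time < 1 || separation_time > T_ont ||
      separation_time != round(separation_time))
    stop("separation_time must be an integer in 1..T_ont")
  traj <- enumerate_weighted_trajectories(policy, start_env)
  copy <- mirror_leaf(traj$leaf, separation_time, T_ont)
  d <- sqrt((traj$y0 - traj$y0[copy])^2 + (traj$y1 - traj$y1[copy])^2)
  val <- sum(traj$weight * d) / (sqrt(2) * (T_ont - separation_time + 1L))
  # the measure is bounded by construction; clamp float accumulation error
  min(1, max(0, val))
}

#' Plasticity curve across ontogeny
#'
#' Runs one adoption study per separation time `t = 1 .. T_ont` and returns
#' the normalized phenotypic distance as a function of the age at
#' separation — the model's operationalization of plasticity across
#' ontogeny.  A sensitive period is a local maximum of this curve; a
#' critical period would be a time after which the curve drops to exactly
#' zero.
#'
#' @param policy A [solve_policy()] result.
#' @param start_env `"E0"` or `"E1"`.
#' @return A data.frame of class `plasticity_curve` with columns
#'   `start_env`, `separation_time`, `distance` (all in `[0, 1]`).
#' @export
plasticity_curve <- function(policy, start_env = c("E0", "E1")) {
  start_env <- match.arg(start_env)
  T_ont <- policy$T_ont
  traj <- enumerate_weighted_trajectories(policy, start_env)
  dist <- vapply(seq_len(T_ont), function(sep) {
    copy <- mirror_leaf(traj$leaf, sep, T_ont)
    d <- sqrt((traj$y0 - traj$y0[copy])^2 + (traj$y1 - traj$y1[copy])^2)
    val <- sum(traj$weight * d) / (sqrt(2) * (T_ont - sep + 1L))
    min(1, max(0, val))  # clamp float accumulation error
  }, numeric(1))
  structure(data.frame(start_env = start_env,
                       separation_time = seq_len(T_ont),
                       distance = dist),
            class = c("plasticity_curve", "data.frame"))
}

#' Separation times of peak plasticity
#'
#' @param curve A [plasticity_curve()].
#' @param tol Absolute tolerance for membership in the argmax set.
#' @return List with `max` (the maximal distance), `times` (all separation
#'   times within `tol` of it) and `nonplastic` (`TRUE` when the whole
#'   curve is zero, in which case `times` is empty: a flat zero curve has
#'   no sensitive period).
#' @export
peak_plasticity <- function(curve, tol = 1e-9) {
  stopifnot(nrow(curve) >= 1)
  m <- max(curve$distance)
  if (m <= tol)
    return(list(max = 0, times = integer(0), nonplastic = TRUE))
  list(max = m,
       times = curve$separation_time[curve$distance >= m - tol],
       nonplastic = FALSE)
}
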