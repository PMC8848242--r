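#' Plot plasticity curves
#'
#' Draws normalized phenotypic distance against separation time, in the
#' layout used for adoption-paradigm results: autocorrelation as greyscale,
#' adult lifespan as line type, optionally faceted by reliability and
#' starting environment (when those columns are present, as in
#' [plasticity_grid()] output).
#'
#' @param curves A data.frame with columns `separation_time`, `distance`
#'   and optionally `autocorrelation`, `T_adult`, `reliability`,
#'   `start_env`.
#' @return A ggplot object.
#' @export
plot_plasticity_curves <- function(curves) {
  stopifnot(all(c("separation_time", "distance") %in% names(curves)))
  aes_args <- list(x = quote(separation_time), y = quote(distance))
  if ("autocorrelation" %in% names(curves))
    aes_args$colour <- quote(factor(autocorrelation))
  if ("T_adult" %in% names(curves))
    aes_args$linetype <- quote(factor(T_adult))
  if (all(c("autocorrelation", "T_adult") %in% names(curves)))
    aes_args$group <- quote(interaction(autocorrelation, T_adult))
  p <- ggplot2::ggplot(curves, do.call(ggplot2::aes, aes_args)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_x_continuous(breaks = unique(curves$separation_time)) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "separation time (ontogenetic period)",
                  y = "normalized phenotypic distance",
                  colour = "autocorrelation", linetype = "adult lifespan") +
    ggplot2::theme_minimal()
  if ("autocorrelation" %in% names(curves))
    p <- p + ggplot2::scale_colour_grey(start = 0.75, end = 0)
  facets <- intersect(c("reliability", "start_env"), names(curves))
  if (length(facets) == 2L)
    p <- p + ggplot2::facet_grid(reliability ~ start_env)
  else if (length(facets) == 1L)
    p <- p + ggplot2::facet_wrap(facets)
  p
}

#' Plot a policy lattice
#'
#' Belief-versus-time view of a solved policy: one point per reachable
#' cue-history state, vertical axis the posterior probability of `E1`,
#' point size the probability of reaching the state, colour the optimal
#' action, with light segments showing the developmental transitions.
#'
#' @param policy A [solve_policy()] result.
#' @return A ggplot object.
#' @export
plot_policy <- function(policy) {
  tab <- policy_table(policy)
  parents <- tab[tab$period > 1, ]
  idx <- match(paste(parents$period - 1L, parents$parent),
               paste(tab$period, tab$node))
  segs <- data.frame(x = tab$period[idx], y = tab$belief[idx],
                     xend = parents$period, yend = parents$belief)
  ggplot2::ggplot(tab, ggplot2::aes(x = period, y = belief)) +
    ggplot2::geom_segment(data = segs,
                          ggplot2::aes(x = x, y = y,
                                       xend = xend, yend = yend),
                          colour = "bisque3", linewidth = 0.2,
                          inherit.aes = FALSE) +
    ggplot2::geom_point(ggplot2::aes(size = reach, colour = action),
                        alpha = 0.85) +
    ggplot2::scale_colour_manual(values = c(wait = "black",
                                            spec_P0 = "firebrick",
                                            spec_P1 = "steelblue")) +
    ggplot2::scale_size_area(max_size = 6) +
    ggplot2::scale_x_continuous(breaks = seq_len(policy$T_ont)) +
    ggplot2::labs(x = "ontogenetic period", y = "posterior P(E1)",
                  size = "reach probability", colour = "action") +
    ggplot2::theme_minimal()
}
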