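#' Run configuration
#'
#' Bundles and validates every parameter of a model run.  The environment
#' is given either as explicit transition probabilities (`p_to_e0`,
#' `p_to_e1`) or as (`autocorrelation`, `asymmetry`); the latter is
#' converted through [process_from_autocorrelation()].
#'
#' @param p_to_e0,p_to_e1 Transition probabilities P(E0|E1), P(E1|E0).
#' @param autocorrelation,asymmetry Alternative environment specification.
#' @param reliability Cue reliability in `[0.5, 1]`.
#' @param T_ont Ontogeny length (default 10 periods).
#' @param T_adult Adult lifespan (study design uses 1, 5 or 20 periods; any
#'   positive integer is accepted).
#' @param reward_shape,penalty_shape,penalty_weight,baseline Fitness mapping
#'   parameters; see [fitness_mapping()].
#' @param seed Optional integer seed (only Monte-Carlo helpers are random;
#'   all shipped analyses are exact enumerations).
#' @return Object of class `run_config` with elements `process`,
#'   `cue_model`, `T_ont`, `T_adult`, `mapping`, `seed`.
#' @export
run_config <- function(p_to_e0 = NULL, p_to_e1 = NULL,
                       autocorrelation = NULL, asymmetry = 0,
                       reliability, T_ont = 10, T_adult = 5,
                       reward_shape = "linear", penalty_shape = "linear",
                       penalty_weight = 1, baseline = 0, seed = NULL) {
  if (!is.null(autocorrelation)) {
    if (!is.null(p_to_e0) || !is.null(p_to_e1))
      stop("give either transition probabilities or (autocorrelation, asymmetry), not both")
    process <- process_from_autocorrelation(autocorrelation, asymmetry)
  } else {
    if (is.null(p_to_e0) || is.null(p_to_e1))
      stop("environment unspecified: need p_to_e0/p_to_e1 or autocorrelation")
    process <- env_process(p_to_e0, p_to_e1)
  }
  if (!(T_ont >= 1 && T_ont == round(T_ont)))
    stop("T_ont must be a positive integer")
  if (!(T_adult >= 1 && T_adult == round(T_adult)))
    stop("T_adult must be a positive integer")
  structure(list(process = process,
                 cue_model = cue_model(reliability),
                 T_ont = as.integer(T_ont), T_adult = as.integer(T_adult),
                 mapping = fitness_mapping(reward_shape, penalty_shape,
                                           penalty_weight, baseline),
                 seed = seed),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' The file may contain any subset of the [run_config()] arguments.
#'
#' @param path Path to a YAML file.
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  spec <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(spec), known)
  if (length(unknown))
    stop("unknown configuration fields: ", paste(unknown, collapse = ", "))
  do.call(run_config, spec)
}

config_metadata <- function(config) {
  list(p_to_e0 = config$process$p_to_e0,
       p_to_e1 = config$process$p_to_e1,
       autocorrelation = lag1_autocorrelation(config$process),
       asymmetry = asymmetry(config$process),
       reliability = config$cue_model$reliability,
       T_ont = config$T_ont, T_adult = config$T_adult,
       reward_shape = config$mapping$reward_shape,
       penalty_shape = config$mapping$penalty_shape,
       penalty_weight = config$mapping$penalty_weight,
       baseline = config$mapping$baseline,
       seed = config$seed)
}

write_outputs <- function(out_dir, tables, config) {
  if (is.null(out_dir)) return(invisible(NULL))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(tables))
    utils::write.csv(tables[[nm]], file.path(out_dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  yaml::write_yaml(config_metadata(config), file.path(out_dir, "config.yaml"))
  invisible(NULL)
}

solve_config <- function(config) {
  solve_policy(config$process, config$cue_model, config$T_ont,
               config$T_adult, config$mapping)
}

#' Solve a configuration and report the policy
#'
#' @param config A [run_config()].
#' @param out_dir Optional directory; when given, writes `policy.csv`,
#'   `ties.csv` and the resolved `config.yaml`.
#' @return List with `policy` (the [solve_policy()] object), `table` (the
#'   reachable-state [policy_table()]), `root_value` and `ties`.
#' @export
run_solve <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  policy <- solve_config(config)
  tab <- policy_table(policy)
  write_outputs(out_dir, list(policy = tab, ties = policy$ties), config)
  list(policy = policy, table = tab,
       root_value = policy$root_value, ties = policy$ties)
}

#' Run the full adoption paradigm for a configuration
#'
#' Solves the policy and computes plasticity curves for both starting
#' environments across all separation times.
#'
#' @param config A [run_config()].
#' @param out_dir Optional directory; writes `plasticity.csv` and
#'   `config.yaml`.
#' @return List with `curves` (tidy data.frame `start_env`,
#'   `separation_time`, `distance`), `nonplastic` (named logical per start
#'   environment: whole curve zero), and `policy`.
#' @export
run_twin <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  policy <- solve_config(config)
  curves <- rbind(as.data.frame(plasticity_curve(policy, "E0")),
                  as.data.frame(plasticity_curve(policy, "E1")))
  nonplastic <- vapply(split(curves$distance, curves$start_env),
                       function(d) all(d <= 1e-9), logical(1))
  write_outputs(out_dir, list(plasticity = curves), config)
  list(curves = curves, nonplastic = nonplastic, policy = policy)
}

#' Compare the optimal policy against non-plastic strategies
#'
#' @param config A [run_config()].
#' @param out_dir Optional directory; writes `comparison.csv` and
#'   `config.yaml`.
#' @return A data.frame `strategy`, `expected_fitness` for the optimal
#'   policy and the two non-plastic strategies ([nonplastic_strategy()]);
#'   the optimal value is always the largest.
#' @export
run_compare <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  policy <- solve_config(config)
  strategies <- c("always_majority_specialist", "always_wait")
  fit <- vapply(strategies, function(k)
    nonplastic_strategy(k, config$process, config$cue_model, config$T_ont,
                        config$T_adult, config$mapping)$root_value,
    numeric(1))
  out <- data.frame(strategy = c("optimal", strategies),
                    expected_fitness = c(policy$root_value, unname(fit)))
  write_outputs(out_dir, list(comparison = out), config)
  out
}

#' Plasticity curves over a parameter grid
#'
#' Convenience driver for the study's default grid: every combination of
#' autocorrelation, cue reliability and adult lifespan (at fixed asymmetry
#' and fitness mapping) is solved and its plasticity curves computed for
#' both starting environments.
#'
#' @param autocorrelations,reliabilities,T_adults Numeric vectors of grid
#'   levels (defaults: the study grid 0.2/0.5/0.8, 0.55/0.75/0.95, 1/5/20).
#' @param asymmetry Asymmetry of the transition probabilities (0 =
#'   symmetric).
#' @param T_ont Ontogeny length.
#' @param mapping A [fitness_mapping()].
#' @return Tidy data.frame: `autocorrelation`, `reliability`, `T_adult`,
#'   `start_env`, `separation_time`, `distance`.
#' @export
plasticity_grid <- function(autocorrelations = c(0.2, 0.5, 0.8),
                            reliabilities = c(0.55, 0.75, 0.95),
                            T_adults = c(1, 5, 20),
                            asymmetry = 0, T_ont = 10,
                            mapping = fitness_mapping()) {
  cells <- expand.grid(autocorrelation = autocorrelations,
                       reliability = reliabilities, T_adult = T_adults)
  out <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    proc <- process_from_autocorrelation(cells$autocorrelation[i], asymmetry)
    policy <- solve_policy(proc, cue_model(cells$reliability[i]),
                           T_ont = T_ont, T_adult = cells$T_adult[i],
                           mapping = mapping)
    curves <- rbind(as.data.frame(plasticity_curve(policy, "E0")),
                    as.data.frame(plasticity_curve(policy, "E1")))
    out[[i]] <- cbind(cells[rep(i, nrow(curves)), , drop = FALSE], curves,
                      row.names = NULL)
  }
  do.call(rbind, out)
}
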