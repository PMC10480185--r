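#' Parameter grid specification
#'
#' The full factorial grid of the mean-field experiments. Defaults mirror
#' the published design: `p_m` from 0 to 0.5 in steps of 0.1, `epsilon`
#' from 0.1 to 0.5 in steps of 0.1, `gamma` 0 plus 0.5 to 1.5 in steps of
#' 0.25, population 100, 100 replicates (reducible).
#'
#' @param p_m Media-interaction probabilities.
#' @param epsilon Confidence bounds.
#' @param gamma Bias exponents.
#' @param n_runs Replicates per grid point.
#' @param n_agents Population size.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(p_m = seq(0, 0.5, by = 0.1),
                      epsilon = seq(0.1, 0.5, by = 0.1),
                      gamma = c(0, seq(0.5, 1.5, by = 0.25)),
                      n_runs = 100L, n_agents = 100L) {
  if (any(p_m < 0 | p_m > 1)) stop("p_m values must lie in [0, 1]")
  if (any(epsilon < 0 | epsilon > 1)) stop("epsilon values must lie in [0, 1]")
  if (any(gamma < 0)) stop("gamma values must be >= 0")
  if (n_runs < 1L) stop("n_runs must be >= 1")
  if (n_agents < 2L) stop("n_agents must be >= 2")
  structure(list(p_m = p_m, epsilon = epsilon, gamma = gamma,
                 n_runs = as.integer(n_runs),
                 n_agents = as.integer(n_agents)),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat("<grid_spec>", length(x$epsilon), "epsilon x", length(x$gamma),
      "gamma x", length(x$p_m), "p_m;", x$n_runs, "runs of",
      x$n_agents, "agents\n")
  invisible(x)
}

expand_grid_spec <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  expand.grid(epsilon = grid$epsilon, gamma = grid$gamma, p_m = grid$p_m,
              KEEP.OUT.ATTRS = FALSE)
}

#' Sweep one media landscape over the parameter grid
#'
#' Builds the named scenario's media landscape, runs the full ensemble
#' over the grid and returns the per-run table plus per-cell aggregates —
#' the tables behind the cluster-count / occupancy heat maps (rows gamma,
#' columns p_m, one panel per epsilon).
#'
#' @param scenario Scenario name accepted by [scenario_media()].
#' @param grid A [grid_spec()].
#' @param base_seed Integer seed origin (default 1).
#' @param stop A [stopping_rule()] (default cluster-equilibrium).
#' @param max_iterations Iteration cap (default `1e6`).
#' @return A `results_table` (see [run_ensemble()]).
#' @export
run_landscape <- function(scenario, grid, base_seed = 1L,
                          stop = stopping_rule("cluster_equilibrium"),
                          max_iterations = 1e6) {
  media <- scenario_media(scenario)
  run_ensemble(media, expand_grid_spec(grid), n_runs = grid$n_runs,
               base_seed = base_seed, n_agents = grid$n_agents,
               stop = stop, max_iterations = max_iterations,
               scenario = scenario)
}

#' Media-free baseline replication
#'
#' Runs the grid with `p_m = 0` and an empty media landscape — the
#' baseline algorithmic-bias model against which every media scenario is
#' compared.
#'
#' @inheritParams run_landscape
#' @return A `results_table`.
#' @export
baseline_replication <- function(grid, base_seed = 1L,
                                 stop = stopping_rule("cluster_equilibrium"),
                                 max_iterations = 1e6) {
  cells <- expand_grid_spec(grid)
  cells$p_m <- 0
  cells <- unique(cells)
  run_ensemble(scenario_media("none"), cells, n_runs = grid$n_runs,
               base_seed = base_seed, n_agents = grid$n_agents,
               stop = stop, max_iterations = max_iterations,
               scenario = "baseline")
}

#' Network case-study mode
#'
#' Runs the heterogeneous-bound network model on a supplied graph with
#' the case-study stopping rule (maximum opinion change below 0.01 for
#' 500 consecutive steps, cap `1e5`), then computes echo-chamber
#' statistics and the cluster partition of the final state. Peer choice
#' is restricted to graph neighbours.
#'
#' @param graph An [interaction_graph()].
#' @param attributes Data.frame with at least column `opinion` (one row
#'   per node, ordered by node index); column `epsilon` supplies
#'   per-node bounds when `epsilon` is not given.
#' @param media A [media_landscape()] — e.g. faction-average opinions
#'   from [faction_media_opinions()].
#' @param epsilon Homogeneous bound or per-node vector; default: the
#'   `epsilon` column of `attributes`.
#' @param gamma Bias exponent (default 0).
#' @param p_m Media-interaction probability (default 0.5).
#' @param mu Convergence parameter (default 0.5).
#' @param max_iterations Iteration cap (default `1e5`).
#' @param seed Optional integer seed.
#' @return List: `result` (a `run_result`), `echo`
#'   ([echo_chamber_stats()]), `partition` ([detect_clusters()]),
#'   `metrics` (one-row data.frame from [summarize_run()]).
#' @export
casestudy_mode <- function(graph, attributes, media = media_landscape(),
                           epsilon = NULL, gamma = 0, p_m = 0.5, mu = 0.5,
                           max_iterations = 1e5, seed = NULL) {
  stopifnot(inherits(graph, "interaction_graph"))
  if (!"opinion" %in% names(attributes))
    stop("attributes must have an 'opinion' column")
  if (nrow(attributes) != graph$n_nodes)
    stop("attributes rows must match node count")
  if (is.null(epsilon)) {
    if (!"epsilon" %in% names(attributes))
      stop("heterogeneous mode requested but no per-node epsilon ",
           "available: supply 'epsilon' or an attribute column")
    epsilon <- attributes$epsilon
  }
  cfg <- model_config(epsilon = epsilon, gamma = gamma, mu = mu, p_m = p_m,
                      max_iterations = max_iterations, seed = seed)
  res <- run_model(opinion_state(attributes$opinion), graph, media, cfg,
                   stop = stopping_rule("max_change"))
  x <- res$final_state$opinions
  list(result = res,
       echo = echo_chamber_stats(x, graph),
       partition = detect_clusters(x),
       metrics = summarize_run(res, media))
}

#' Media landscapes of the network case study
#'
#' The five landscapes exercised on the polarized network: a single
#' medium at the pro-faction mean (0.28), the neutral mean (0.49) or the
#' against-faction mean (0.87); the pro + against pair; or all three.
#'
#' @param name One of `"pro"`, `"neutral"`, `"against"`, `"two"`,
#'   `"three"`.
#' @return A [media_landscape()].
#' @export
casestudy_media <- function(name) {
  scenarios <- list(pro = 0.28, neutral = 0.49, against = 0.87,
                    two = c(0.28, 0.87), three = c(0.28, 0.87, 0.49))
  if (length(name) != 1L || !name %in% names(scenarios))
    stop("unknown case-study landscape '", name, "'; valid names: ",
         paste(names(scenarios), collapse = ", "))
  media_landscape(scenarios[[name]])
}
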