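#' Stopping rule
#'
#' Two ways to declare a run finished before the iteration cap:
#' \describe{
#'   \item{`cluster_equilibrium`}{the gap-threshold cluster partition is
#'     recomputed every `check_stride` steps and the run stops once
#'     `patience` consecutive checks return identical partitions
#'     (membership and count) — the population keeps exchanging opinions
#'     but its cluster configuration no longer changes. Default for
#'     mean-field experiments (stride 1000, patience 100, gap 0.01): the
#'     partition must be unchanged over a 100,000-step window, which in
#'     validation runs reproduced the configuration reached at the full
#'     iteration cap; short windows can freeze transient partitions
#'     under strongly biased (slow) dynamics.}
#'   \item{`max_change`}{the run stops once the per-step maximum absolute
#'     opinion change stays below `change_threshold` for `patience`
#'     consecutive steps. Default for network case-study mode
#'     (threshold 0.01, patience 500).}
#' }
#'
#' @param kind `"cluster_equilibrium"` or `"max_change"`.
#' @param check_stride Steps between equilibrium checks (>= 1).
#' @param patience Consecutive identical checks / below-threshold steps.
#' @param change_threshold Opinion-change threshold for `max_change`.
#' @param gap_threshold Cluster gap for `cluster_equilibrium`.
#' @return An object of class `stopping_rule`.
#' @export
stopping_rule <- function(kind = c("cluster_equilibrium", "max_change"),
                          check_stride = if (kind == "max_change") 1L else 1000L,
                          patience = if (kind == "max_change") 500L else 100L,
                          change_threshold = 0.01,
                          gap_threshold = 0.01) {
  kind <- match.arg(kind)
  if (check_stride < 1L) stop("check_stride must be >= 1")
  if (patience < 1L) stop("patience must be >= 1")
  if (change_threshold <= 0) stop("change_threshold must be > 0")
  if (gap_threshold <= 0) stop("gap_threshold must be > 0")
  structure(list(kind = kind, check_stride = as.integer(check_stride),
                 patience = as.integer(patience),
                 change_threshold = change_threshold,
                 gap_threshold = gap_threshold),
            class = "stopping_rule")
}

#' Run the model to completion
#'
#' Repeatedly applies the single-step dynamics (see [simulation_step()]
#' for the exact step and random-draw order) until the stopping rule
#' fires or `config$max_iterations` is reached. The loop runs in
#' compiled code but consumes the R random stream, so a run is
#' bit-reproducible from `(config, seed)` and seed-matched replays of the
#' pure-R step produce identical trajectories.
#'
#' @param initial An [opinion_state()] (or bare numeric opinion vector).
#' @param graph An [interaction_graph()]; node count must match.
#' @param media A [media_landscape()].
#' @param config A [model_config()]; if `config$seed` is set the RNG is
#'   seeded before the run.
#' @param stop A [stopping_rule()]; default cluster-equilibrium.
#' @param snapshot_stride Record `(time, opinions)` every this many steps
#'   (0 = off).
#' @return An object of class `run_result`: `final_state`
#'   ([opinion_state()]), `iterations`, `converged`, `stop_reason`
#'   (`"equilibrium"`, `"max_change"` or `"iteration_cap"`), `snapshots`.
#' @export
run_model <- function(initial, graph, media = media_landscape(),
                      config, stop = stopping_rule("cluster_equilibrium"),
                      snapshot_stride = 0) {
  if (is.numeric(initial)) initial <- opinion_state(initial)
  stopifnot(inherits(initial, "opinion_state"),
            inherits(graph, "interaction_graph"),
            inherits(media, "media_landscape"),
            inherits(config, "model_config"),
            inherits(stop, "stopping_rule"))
  n <- length(initial$opinions)
  if (graph$n_nodes != n)
    stop("initial state has ", n, " agents but graph has ",
         graph$n_nodes, " nodes")
  if (config$heterogeneous && length(config$epsilon) != n)
    stop("heterogeneous epsilon must have one entry per agent")
  if (!is.null(config$seed)) set.seed(config$seed)

  res <- .run_model_cpp(
    opinions0 = initial$opinions,
    epsilon = config$epsilon,
    heterogeneous = config$heterogeneous,
    gamma = config$gamma, mu = config$mu, p_m = config$p_m,
    media = media$media_opinions,
    adjacency = adjacency_for_cpp(graph),
    distance_floor = config$distance_floor,
    max_iterations = config$max_iterations,
    stop_kind = if (stop$kind == "cluster_equilibrium") 0L else 1L,
    check_stride = stop$check_stride,
    patience = stop$patience,
    change_threshold = stop$change_threshold,
    gap_threshold = stop$gap_threshold,
    snapshot_stride = as.integer(snapshot_stride))

  structure(list(
    final_state = opinion_state(res$opinions,
                                time = initial$time + res$iterations),
    iterations = res$iterations,
    converged = res$converged,
    stop_reason = res$stop_reason,
    snapshots = res$snapshots),
    class = "run_result")
}

#' @export
print.run_result <- function(x, ...) {
  cat("<run_result>", format(x$iterations), "iterations; stop:",
      x$stop_reason, "\n")
  part <- detect_clusters(x$final_state$opinions)
  cat(" final clusters:", n_clusters(part), "(sizes",
      paste(part$sizes, collapse = ", "), ")\n")
  invisible(x)
}

#' Has the cluster configuration stabilized?
#'
#' True iff the last `patience` partitions in the history are identical
#' in both membership and cluster count.
#'
#' @param partition_history List of [detect_clusters()] results (at least
#'   `patience` entries).
#' @param patience Window length (default: full history).
#' @return Logical.
#' @export
equilibrium_reached <- function(partition_history,
                                patience = length(partition_history)) {
  if (length(partition_history) < patience)
    stop("history shorter than patience")
  window <- partition_history[
    seq(length(partition_history) - patience + 1L,
        length(partition_history))]
  ref <- window[[1]]$members
  all(vapply(window, function(p) identical(p$members, ref), logical(1)))
}

#' Has the maximum opinion change stayed small?
#'
#' True iff the last `window` per-step maximum absolute changes are all
#' strictly below `threshold`.
#'
#' @param recent_changes Numeric vector of per-step maximum changes.
#' @param threshold Positive threshold.
#' @param window Number of trailing entries to examine.
#' @return Logical.
#' @export
max_change_stop <- function(recent_changes, threshold, window) {
  if (threshold <= 0) stop("threshold must be > 0")
  if (window < 1) stop("window must be >= 1")
  if (length(recent_changes) < window) return(FALSE)
  tail_vals <- recent_changes[
    seq(length(recent_changes) - window + 1L, length(recent_changes))]
  all(tail_vals < threshold)
}

#' Ensemble of independent runs over a parameter grid
#'
#' Executes `n_runs` independent replicates at each grid point with seeds
#' `base_seed + 0 .. n_runs - 1`; each replicate draws its own uniform
#' initial opinions from its own stream. Returns one metrics row per run
#' plus per-grid-point aggregates (mean and sd of every numeric metric).
#'
#' @param media A [media_landscape()] (the scenario).
#' @param grid Data.frame with columns `epsilon`, `gamma`, `p_m` (one row
#'   per grid point; non-empty).
#' @param n_runs Replicates per grid point (>= 1).
#' @param base_seed Integer seed origin.
#' @param n_agents Population size (default 100).
#' @param stop A [stopping_rule()] (default cluster-equilibrium).
#' @param max_iterations Iteration cap (default `1e6`).
#' @param mu Convergence parameter (default 0.5).
#' @param scenario Scenario name recorded in the output (default "custom").
#' @return An object of class `results_table`: list with `runs` (one row
#'   per run) and `aggregates` (one row per grid point).
#' @export
run_ensemble <- function(media, grid, n_runs, base_seed = 1L,
                         n_agents = 100L,
                         stop = stopping_rule("cluster_equilibrium"),
                         max_iterations = 1e6, mu = 0.5,
                         scenario = "custom") {
  if (!nrow(grid)) stop("empty grid")
  if (n_runs < 1L) stop("n_runs must be >= 1")
  need <- c("epsilon", "gamma", "p_m")
  if (!all(need %in% names(grid)))
    stop("grid must have columns epsilon, gamma, p_m")
  graph <- mean_field_graph(n_agents)
  rows <- vector("list", nrow(grid) * n_runs)
  k <- 0L
  for (g in seq_len(nrow(grid))) {
    for (r in seq_len(n_runs)) {
      seed <- as.integer(base_seed + r - 1L)
      cfg <- model_config(epsilon = grid$epsilon[g], gamma = grid$gamma[g],
                          mu = mu, p_m = grid$p_m[g],
                          max_iterations = max_iterations, seed = seed)
      set.seed(seed)
      init <- opinion_state(uniform_initial_opinions(n_agents))
      cfg$seed <- NULL # RNG already positioned after the initial draw
      res <- run_model(init, graph, media, cfg, stop)
      met <- summarize_run(res, media)
      k <- k + 1L
      rows[[k]] <- cbind(
        data.frame(scenario = scenario, epsilon = grid$epsilon[g],
                   gamma = grid$gamma[g], p_m = grid$p_m[g], seed = seed),
        met)
    }
  }
  runs <- do.call(rbind, rows)
  structure(list(runs = runs, aggregates = aggregate_results(runs),
                 scenario = scenario),
            class = "results_table")
}

# per-grid-point mean and sd of every numeric metric
aggregate_results <- function(runs) {
  keys <- c("scenario", "epsilon", "gamma", "p_m")
  metric_cols <- setdiff(names(runs)[vapply(runs, is.numeric, logical(1))],
                         c("epsilon", "gamma", "p_m", "seed"))
  mean_tab <- aggregate(runs[metric_cols], by = runs[keys], FUN = mean)
  sd_tab <- aggregate(runs[metric_cols], by = runs[keys],
                      FUN = function(v) if (length(v) > 1) sd(v) else 0)
  names(mean_tab)[-seq_along(keys)] <-
    paste0("mean_", metric_cols)
  names(sd_tab)[-seq_along(keys)] <- paste0("sd_", metric_cols)
  merge(mean_tab, sd_tab, by = keys, sort = TRUE)
}

#' @export
print.results_table <- function(x, ...) {
  cat("<results_table> scenario:", x$scenario, "-", nrow(x$runs),
      "runs over", nrow(x$aggregates), "grid point(s)\n")
  invisible(x)
}
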