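#' Load a run configuration from a YAML file
#'
#' Reads and validates a structured configuration. Recognised keys:
#' `n_agents` (required), `epsilon` (scalar or per-agent list), `gamma`,
#' `mu`, `p_m`, `distance_floor`, `max_iterations`, `seed`, `scenario`
#' (a [scenario_media()] name), `stopping` (`kind`, `check_stride`,
#' `patience`, `change_threshold`, `gap_threshold`), and `grid`
#' (`p_m`, `epsilon`, `gamma`, `n_runs`). Omitted keys take the
#' documented defaults (`mu` 0.5, `distance_floor` 1e-4, gap and change
#' thresholds 0.01); unknown keys are rejected by name.
#'
#' @param path Path to a YAML configuration file.
#' @return List with `config` ([model_config()]), `grid` ([grid_spec()]),
#'   `stop` ([stopping_rule()]), `scenario` (name or `NULL`), and
#'   `n_agents`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- c("n_agents", "epsilon", "gamma", "mu", "p_m", "distance_floor",
             "max_iterations", "seed", "scenario", "stopping", "grid")
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("unknown configuration key(s): ",
                        paste(bad, collapse = ", "))
  if (is.null(raw$n_agents)) stop("configuration key 'n_agents' is required")
  n <- as.integer(raw$n_agents)

  eps <- if (is.null(raw$epsilon)) 0.3 else unlist(raw$epsilon)
  if (length(eps) > 1L && length(eps) != n)
    stop("per-agent epsilon must have length n_agents (", n, ")")
  cfg <- model_config(
    epsilon = eps,
    gamma = raw$gamma %||% 0,
    mu = raw$mu %||% 0.5,
    p_m = raw$p_m %||% 0,
    distance_floor = raw$distance_floor %||% 1e-4,
    max_iterations = raw$max_iterations %||% 1e6,
    seed = raw$seed)

  st <- raw$stopping %||% list()
  stop_rule <- stopping_rule(
    kind = st$kind %||% "cluster_equilibrium",
    check_stride = st$check_stride %||%
      if ((st$kind %||% "cluster_equilibrium") == "max_change") 1L else 1000L,
    patience = st$patience %||%
      if ((st$kind %||% "cluster_equilibrium") == "max_change") 500L else 100L,
    change_threshold = st$change_threshold %||% 0.01,
    gap_threshold = st$gap_threshold %||% 0.01)

  gr <- raw$grid %||% list()
  grid <- grid_spec(
    p_m = unlist(gr$p_m) %||% seq(0, 0.5, by = 0.1),
    epsilon = unlist(gr$epsilon) %||% seq(0.1, 0.5, by = 0.1),
    gamma = unlist(gr$gamma) %||% c(0, seq(0.5, 1.5, by = 0.25)),
    n_runs = gr$n_runs %||% 100L,
    n_agents = n)

  if (!is.null(raw$scenario)) scenario_media(raw$scenario) # validate name
  list(config = cfg, grid = grid, stop = stop_rule,
       scenario = raw$scenario, n_agents = n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a results table with its manifest
#'
#' Serializes the per-run table and per-cell aggregates as CSV and a JSON
#' manifest (seed list, scenario, file paths, package version,
#' timestamp). The CSVs round-trip losslessly through [read_results()].
#'
#' @param table A `results_table` from [run_ensemble()]/[run_landscape()].
#' @param manifest Named list of extra manifest entries (e.g. the config
#'   snapshot); may be empty.
#' @param out_dir Output directory (created if needed).
#' @param prefix File-name prefix (default the scenario name).
#' @return Invisibly, the named character vector of written paths.
#' @export
write_results <- function(table, manifest = list(), out_dir,
                          prefix = table$scenario) {
  stopifnot(inherits(table, "results_table"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    runs = file.path(out_dir, paste0(prefix, "_runs.csv")),
    aggregates = file.path(out_dir, paste0(prefix, "_aggregates.csv")),
    manifest = file.path(out_dir, paste0(prefix, "_manifest.json")))
  write.csv(table$runs, paths[["runs"]], row.names = FALSE)
  write.csv(table$aggregates, paths[["aggregates"]], row.names = FALSE)
  man <- c(manifest, list(
    scenario = table$scenario,
    seeds = sort(unique(table$runs$seed)),
    n_runs = nrow(table$runs),
    files = as.list(paths[c("runs", "aggregates")]),
    package_version = as.character(utils::packageVersion("opinionmedia")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)))
  jsonlite::write_json(man, paths[["manifest"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}

#' Read back a written results table
#'
#' @param runs_path Path to the `*_runs.csv` written by [write_results()].
#' @return A `results_table` with aggregates recomputed from the runs.
#' @export
read_results <- function(runs_path) {
  runs <- read.csv(runs_path, stringsAsFactors = FALSE)
  structure(list(runs = runs, aggregates = aggregate_results(runs),
                 scenario = runs$scenario[1]),
            class = "results_table")
}
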