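#' Uniform initial opinions
#'
#' Draws the standard initial condition of the mean-field experiments:
#' independent opinions uniform on \[0, 1\]. Uses the R random stream;
#' pass `seed` (or call `set.seed()` first) for reproducibility.
#'
#' @param n Number of agents (>= 2).
#' @param seed Optional integer seed applied before drawing.
#' @return Numeric vector of length `n`.
#' @export
uniform_initial_opinions <- function(n, seed = NULL) {
  if (n < 2) stop("need at least 2 agents")
  if (!is.null(seed)) set.seed(seed)
  runif(n)
}

#' Named media landscapes
#'
#' The four media landscapes of the mean-field experiments:
#' `moderate` = (0.5), `extremist` = (0.0), `polarized` = (0.05, 0.95),
#' `balanced` = (0.05, 0.5, 0.95).
#'
#' @param name One of `"moderate"`, `"extremist"`, `"polarized"`,
#'   `"balanced"`, or `"none"` (empty landscape).
#' @return A [media_landscape()].
#' @examples
#' scenario_media("balanced")
#' @export
scenario_media <- function(name) {
  scenarios <- list(
    none      = numeric(0),
    moderate  = 0.5,
    extremist = 0.0,
    polarized = c(0.05, 0.95),
    balanced  = c(0.05, 0.5, 0.95))
  if (length(name) != 1L || !name %in% names(scenarios))
    stop("unknown scenario '", name, "'; valid names: ",
         paste(names(scenarios), collapse = ", "))
  media_landscape(scenarios[[name]])
}

#' Synthetic two-community polarized network
#'
#' Stochastic block model with two equal communities and opinions drawn
#' around per-community means (truncated normal on \[0, 1\]). Defaults
#' emulate a polarized online-discussion snapshot with faction means
#' 0.28 ("pro") and 0.87 ("against").
#'
#' @param n Total number of nodes (split into two equal communities).
#' @param intra_p Within-community edge probability (> `inter_p`).
#' @param inter_p Between-community edge probability.
#' @param means Length-2 community mean opinions.
#' @param spread Standard deviation of the opinion noise (default 0.1).
#' @param seed Optional integer seed.
#' @return List with `graph` (an [interaction_graph()]) and `attributes`
#'   (data.frame: `node`, `opinion`, `community`).
#' @export
polarized_network <- function(n, intra_p = 0.2, inter_p = 0.01,
                              means = c(0.28, 0.87), spread = 0.1,
                              seed = NULL) {
  if (any(c(intra_p, inter_p) < 0 | c(intra_p, inter_p) > 1))
    stop("edge probabilities must lie in [0, 1]")
  if (intra_p <= inter_p)
    stop("intra_p must exceed inter_p for a polarized structure")
  check_opinion(means, "means")
  if (length(means) != 2L) stop("means must have length 2")
  if (!is.null(seed)) set.seed(seed)
  sizes <- c(ceiling(n / 2), floor(n / 2))
  pref <- matrix(c(intra_p, inter_p, inter_p, intra_p), 2)
  g <- igraph::sample_sbm(n, pref.matrix = pref, block.sizes = sizes)
  graph <- as_interaction_graph(g)
  community <- rep(1:2, times = sizes)
  opinion <- rtruncnorm01(n, mean = means[community], sd = spread)
  if (n_edges(graph) == 0L)
    warning("generated graph has no edges")
  else if (any(lengths(graph$adj) == 0L))
    warning("generated graph has isolated nodes")
  list(graph = graph,
       attributes = data.frame(node = seq_len(n), opinion = opinion,
                               community = community))
}

# truncated-normal draws on [0,1] by inverse-CDF (exact, one draw each)
rtruncnorm01 <- function(n, mean, sd) {
  lo <- stats::pnorm(0, mean, sd)
  hi <- stats::pnorm(1, mean, sd)
  stats::qnorm(lo + runif(n) * (hi - lo), mean, sd)
}

#' Per-agent confidence-bound assignment
#'
#' Draws one confidence bound per agent from a described distribution,
#' standing in for bounds estimated from data in heterogeneous runs.
#'
#' @param n Number of agents.
#' @param spec Distribution description: one of
#'   `list(kind = "constant", value = v)`,
#'   `list(kind = "uniform", min = a, max = b)`, or
#'   `list(kind = "beta", shape1 = a, shape2 = b)`. Support must lie in
#'   \[0, 1\].
#' @param seed Optional integer seed.
#' @return Numeric vector of length `n` of per-agent bounds.
#' @export
heterogeneous_epsilon_assignment <- function(n, spec, seed = NULL) {
  if (!is.list(spec) || is.null(spec$kind))
    stop("spec must be a list with a 'kind' field")
  if (!is.null(seed)) set.seed(seed)
  out <- switch(spec$kind,
    constant = {
      if (spec$value < 0 || spec$value > 1)
        stop("constant value outside [0, 1]")
      rep(spec$value, n)
    },
    uniform = {
      if (spec$min < 0 || spec$max > 1 || spec$min > spec$max)
        stop("uniform support outside [0, 1]")
      runif(n, spec$min, spec$max)
    },
    beta = stats::rbeta(n, spec$shape1, spec$shape2),
    stop("unknown spec kind '", spec$kind, "'"))
  out
}

#' Read an interaction graph and node attributes from delimited files
#'
#' The edge list is two-column delimited text (whitespace or comma,
#' optional header); node ids may be arbitrary strings and are mapped to
#' 1-based indices. The attribute table must have a header with columns
#' `node_id` and `opinion` and optionally `epsilon` and `label`.
#' Duplicate edges are collapsed and self-loops dropped (with a message
#' giving the count); opinions outside \[0, 1\] and edge endpoints absent
#' from the attribute table are rejected with line numbers.
#'
#' @param edge_list_path Path to the edge-list file.
#' @param attribute_table_path Path to the node-attribute table.
#' @return List with `graph` (an [interaction_graph()]), `attributes`
#'   (data.frame ordered by internal index: `node`, `node_id`, `opinion`,
#'   optional `epsilon`, `label`), and `node_ids` (the id-to-index map).
#' @export
read_graph <- function(edge_list_path, attribute_table_path) {
  attr_tab <- read_delim_auto(attribute_table_path, header = TRUE)
  need <- c("node_id", "opinion")
  if (!all(need %in% names(attr_tab)))
    stop("attribute table must have columns node_id and opinion")
  attr_tab$node_id <- as.character(attr_tab$node_id)
  if (anyDuplicated(attr_tab$node_id))
    stop("duplicate node_id in attribute table")
  op <- suppressWarnings(as.numeric(attr_tab$opinion))
  bad <- which(!is.finite(op) | op < 0 | op > 1)
  if (length(bad))
    stop("invalid opinion at attribute line ", bad[1] + 1L, ": '",
         attr_tab$opinion[bad[1]], "' (must lie in [0, 1])")
  attr_tab$opinion <- op
  if ("epsilon" %in% names(attr_tab)) {
    ep <- suppressWarnings(as.numeric(attr_tab$epsilon))
    bad <- which(!is.finite(ep) | ep < 0 | ep > 1)
    if (length(bad))
      stop("invalid epsilon at attribute line ", bad[1] + 1L)
    attr_tab$epsilon <- ep
  }

  edges_raw <- read_edge_list(edge_list_path)
  ids <- attr_tab$node_id
  idx <- setNames(seq_along(ids), ids)
  unknown <- !(c(edges_raw[[1]], edges_raw[[2]]) %in% ids)
  if (any(unknown)) {
    line <- ((which(unknown)[1] - 1L) %% nrow(edges_raw)) + 1L
    stop("edge list line ", line, " references unknown node id '",
         c(edges_raw[[1]], edges_raw[[2]])[which(unknown)[1]], "'")
  }
  e <- cbind(idx[edges_raw[[1]]], idx[edges_raw[[2]]])
  n_loops <- sum(e[, 1] == e[, 2])
  if (n_loops) message("dropped ", n_loops, " self-loop(s)")
  graph <- interaction_graph(length(ids), edges = e)
  attributes <- cbind(data.frame(node = seq_along(ids)), attr_tab)
  list(graph = graph, attributes = attributes, node_ids = idx)
}

read_delim_auto <- function(path, header) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  out <- tryCatch(
    read.table(path, header = header, sep = sep,
               stringsAsFactors = FALSE, strip.white = TRUE,
               comment.char = "#"),
    error = function(e) stop("malformed file ", path, ": ",
                             conditionMessage(e)))
  names(out) <- tolower(names(out))
  out
}

read_edge_list <- function(path) {
  tab <- read_delim_auto(path, header = FALSE)
  if (ncol(tab) != 2L)
    stop("edge list must have exactly two columns, found ", ncol(tab))
  tab[] <- lapply(tab, as.character)
  # optional header: recognised edge-endpoint column names
  hdr <- tolower(c(tab[1, 1], tab[1, 2]))
  if (all(hdr %in% c("from", "to", "source", "target", "node1", "node2")))
    tab <- tab[-1, , drop = FALSE]
  if (!nrow(tab)) stop("edge list is empty")
  tab
}
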