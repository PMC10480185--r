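#' Gap-threshold opinion clusters
#'
#' Partitions a final opinion profile by sorting the opinions and starting
#' a new cluster whenever a consecutive gap strictly exceeds
#' `gap_threshold` (a gap exactly equal to the threshold stays in the
#' same cluster). Singletons count as clusters; the cluster count is the
#' headline fragmentation measure.
#'
#' @param opinions Non-empty numeric vector of opinions.
#' @param gap_threshold Positive gap threshold (default 0.01).
#' @return An object of class `cluster_partition`: list with `members`
#'   (list of index vectors, ascending mean opinion), `sizes`, `means`,
#'   `opinions` (the input), `gap_threshold`, and `n_agents`.
#' @examples
#' detect_clusters(c(0.1, 0.105, 0.5))
#' @export
detect_clusters <- function(opinions, gap_threshold = 0.01) {
  if (!length(opinions)) stop("opinions must be non-empty")
  if (gap_threshold <= 0) stop("gap_threshold must be > 0")
  ord <- order(opinions)
  x <- opinions[ord]
  brk <- which(diff(x) > gap_threshold)
  starts <- c(1L, brk + 1L)
  ends <- c(brk, length(x))
  members <- mapply(function(s, e) ord[s:e], starts, ends, SIMPLIFY = FALSE)
  structure(list(
    members = members,
    sizes = lengths(members),
    means = vapply(members, function(ix) mean(opinions[ix]), numeric(1)),
    opinions = opinions,
    gap_threshold = gap_threshold,
    n_agents = length(opinions)),
    class = "cluster_partition")
}

#' @export
print.cluster_partition <- function(x, ...) {
  cat("<cluster_partition>", length(x$sizes), "cluster(s) over",
      x$n_agents, "agents (gap", x$gap_threshold, ")\n")
  cat(" sizes:", paste(x$sizes, collapse = ", "), "\n")
  cat(" means:", paste(round(x$means, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Number of clusters
#' @param partition A [detect_clusters()] result.
#' @return Integer cluster count.
#' @export
n_clusters <- function(partition) {
  stopifnot(inherits(partition, "cluster_partition"))
  length(partition$sizes)
}

#' Number of major clusters
#'
#' Clusters holding at least a given fraction of the population, the
#' "main clusters" count that discards stray singletons.
#'
#' @param partition A [detect_clusters()] result.
#' @param min_frac Minimum population fraction (default 0.02).
#' @return Integer count of clusters with size >= `min_frac * N`.
#' @export
n_major_clusters <- function(partition, min_frac = 0.02) {
  stopifnot(inherits(partition, "cluster_partition"))
  sum(partition$sizes >= min_frac * partition$n_agents)
}

#' Cluster participation ratio
#'
#' `C = (sum c_i)^2 / sum c_i^2`, the effective number of equally sized
#' clusters: equals the cluster count n when all clusters have the same
#' size and approaches 1 when a single cluster dominates. Scale-invariant,
#' so sizes may be counts or fractions.
#'
#' @param partition A [detect_clusters()] result, or a numeric vector of
#'   cluster sizes.
#' @return The participation ratio in \[1, n\].
#' @examples
#' participation_ratio(c(50, 50)) # 2
#' @export
participation_ratio <- function(partition) {
  sizes <- if (inherits(partition, "cluster_partition"))
    partition$sizes else partition
  if (!length(sizes)) stop("empty partition")
  if (any(sizes <= 0)) stop("cluster sizes must be positive")
  sum(sizes)^2 / sum(sizes^2)
}

#' Media-cluster occupancy
#'
#' Percentage of agents holding opinions in the closed band
#' `[x_m - lambda, x_m + lambda]` around a media opinion.
#'
#' @param opinions Numeric opinion vector.
#' @param x_m Media opinion.
#' @param lambda Half-width of the band (default 0.01).
#' @return Percentage in \[0, 100\].
#' @export
media_cluster_occupancy <- function(opinions, x_m, lambda = 0.01) {
  if (!length(opinions)) stop("opinions must be non-empty")
  100 * mean(opinions >= x_m - lambda & opinions <= x_m + lambda)
}

#' Mean distance between opinion peaks
#'
#' Average absolute distance between cluster mean opinions over all
#' unordered cluster pairs (0 for a single cluster). With
#' `peaks = FALSE` the average is instead taken over all agent pairs.
#'
#' @param partition A [detect_clusters()] result.
#' @param peaks Logical; average over cluster means (default) or over all
#'   agent pairs.
#' @return Non-negative mean pairwise distance.
#' @export
peak_pairwise_distance <- function(partition, peaks = TRUE) {
  stopifnot(inherits(partition, "cluster_partition"))
  vals <- if (peaks) partition$means else partition$opinions
  if (length(vals) < 2L) return(0)
  mean(stats::dist(matrix(vals, ncol = 1)))
}

#' Shannon entropy of the opinion distribution
#'
#' Base-2 entropy of the histogram of opinions over `n_bins` equal bins
#' on \[0, 1\]: 0 for a degenerate distribution, at most `log2(n_bins)`.
#'
#' @param opinions Numeric opinion vector on \[0, 1\].
#' @param n_bins Number of bins (default 100).
#' @return Entropy in bits.
#' @export
opinion_entropy <- function(opinions, n_bins = 100) {
  if (n_bins < 2) stop("n_bins must be >= 2")
  check_opinion(opinions, "opinions")
  bin <- pmin(pmax(ceiling(opinions * n_bins), 1L), n_bins)
  p <- tabulate(bin, nbins = n_bins) / length(opinions)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Echo-chamber statistics
#'
#' Pairs each non-isolated node's opinion with the mean opinion of its
#' neighbours, bins the pairs on a `grid` x `grid` joint histogram over
#' the unit square, and reports the linear correlation across pairs — the
#' standard echo-chamber diagnostic (high correlation: nodes sit among
#' like-minded neighbours).
#'
#' @param opinions Numeric opinion vector, one per node.
#' @param graph An [interaction_graph()] with at least one edge.
#' @param grid Histogram resolution per axis (default 20).
#' @return An object of class `echo_chamber_stats`: `pairs` (data.frame
#'   `node`, `opinion`, `neighbor_mean`), `histogram` (grid x grid count
#'   matrix), `correlation` (scalar, `NA` when either marginal is
#'   degenerate), `correlation_defined`.
#' @export
echo_chamber_stats <- function(opinions, graph, grid = 20) {
  stopifnot(inherits(graph, "interaction_graph"))
  if (length(opinions) != graph$n_nodes)
    stop("opinions length must match node count")
  if (n_edges(graph) == 0L) stop("graph has no edges")
  nodes <- seq_len(graph$n_nodes)
  deg <- if (graph$mean_field) rep(graph$n_nodes - 1L, graph$n_nodes)
         else lengths(graph$adj)
  keep <- nodes[deg > 0L]
  nb_mean <- vapply(keep, function(i)
    mean(opinions[graph_neighbors(graph, i)]), numeric(1))
  own <- opinions[keep]
  defined <- sd(own) > 0 && sd(nb_mean) > 0
  rho <- if (defined) cor(own, nb_mean) else NA_real_
  bin <- function(v) pmin(pmax(ceiling(v * grid), 1L), grid)
  hist2 <- matrix(0L, grid, grid)
  for (k in seq_along(own))
    hist2[bin(own[k]), bin(nb_mean[k])] <-
      hist2[bin(own[k]), bin(nb_mean[k])] + 1L
  structure(list(
    pairs = data.frame(node = keep, opinion = own, neighbor_mean = nb_mean),
    histogram = hist2,
    correlation = rho,
    correlation_defined = defined),
    class = "echo_chamber_stats")
}

#' @export
print.echo_chamber_stats <- function(x, ...) {
  cat("<echo_chamber_stats>", nrow(x$pairs), "non-isolated nodes;",
      "correlation:",
      if (x$correlation_defined) round(x$correlation, 4) else "undefined",
      "\n")
  invisible(x)
}

#' Metrics bundle for one run
#'
#' Computes the full final-state metric set of a run: cluster count,
#' major-cluster count, participation ratio, per-media occupancy, peak
#' pairwise distance, entropy, iterations and stop reason.
#'
#' @param result A [run_model()] result.
#' @param media A [media_landscape()] (occupancy is reported per medium).
#' @param gap_threshold Cluster gap threshold (default 0.01).
#' @param lambda Occupancy band half-width (default 0.01).
#' @param major_frac Major-cluster fraction (default 0.02).
#' @return One-row data.frame.
#' @export
summarize_run <- function(result, media = media_landscape(),
                          gap_threshold = 0.01, lambda = 0.01,
                          major_frac = 0.02) {
  stopifnot(inherits(result, "run_result"))
  x <- result$final_state$opinions
  part <- detect_clusters(x, gap_threshold)
  out <- data.frame(
    n_clusters = n_clusters(part),
    n_major_clusters = n_major_clusters(part, major_frac),
    participation_ratio = participation_ratio(part),
    peak_distance = peak_pairwise_distance(part),
    entropy = opinion_entropy(x),
    mean_opinion = mean(x),
    iterations = result$iterations,
    converged = result$converged,
    stop_reason = result$stop_reason)
  m <- media$media_opinions
  if (length(m))
    for (k in seq_along(m))
      out[[paste0("occupancy_m", k)]] <-
        media_cluster_occupancy(x, m[k], lambda)
  out
}
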