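# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the DW oracle is a direct transcription of the
# classic pairwise-averaging model, the cluster oracle a naive gap scan.

# Naive Deffuant-Weisbuch run: uniform random pair per step, bounded
# confidence gate |x_i - x_j| <= eps, symmetric mu-update. Consumes two
# uniform draws per step (target, then peer position among the others),
# the documented draw order of the package with gamma = 0, p_m = 0.
naive_dw_run <- function(opinions, epsilon, mu, n_steps) {
  x <- opinions
  n <- length(x)
  for (s in seq_len(n_steps)) {
    i <- floor(runif(1) * n) + 1L
    pos <- floor(runif(1) * (n - 1L)) + 1L
    j <- seq_len(n)[-i][pos]
    if (abs(x[i] - x[j]) <= epsilon) {
      xi <- x[i]; xj <- x[j]
      x[i] <- xi + mu * (xj - xi)
      x[j] <- xj + mu * (xi - xj)
    }
  }
  x
}

# Brute-force gap-scan clustering: returns sorted cluster sizes.
naive_gap_clusters <- function(opinions, gap) {
  x <- sort(opinions)
  sizes <- integer(0)
  cur <- 1L
  for (k in seq_along(x)[-1]) {
    if (x[k] - x[k - 1] > gap) {
      sizes <- c(sizes, cur)
      cur <- 1L
    } else cur <- cur + 1L
  }
  c(sizes, cur)
}

# Spreadsheet-style recomputation of the leaning pipeline: plain loops
# over the annotation rows, no shared code with user_leanings().
naive_leanings <- function(annotations) {
  out <- list()
  for (u in sort(unique(annotations$user_id))) {
    rows_u <- annotations[annotations$user_id == u, ]
    ct <- c()
    for (tw in unique(rows_u$tweet_id)) {
      v <- rows_u$class_value[rows_u$tweet_id == tw]
      v <- v[v != 0]
      if (length(v)) ct <- c(ct, sum(v) / length(v))
    }
    if (!length(ct)) next
    cu <- sum(ct) / length(ct)
    op <- (cu + 3) / 6
    lab <- if (op <= 0.4) "Pro" else if (op >= 0.6) "Against" else "Neutral"
    out[[u]] <- data.frame(user_id = u, C_u = cu, opinion = op, label = lab)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

quick_equilibrium <- function(patience = 10L, stride = 200L)
  stopping_rule("cluster_equilibrium", check_stride = stride,
                patience = patience)
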