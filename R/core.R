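#' Opinion distance
#'
#' Absolute difference between two opinion values on \[0, 1\]. This is the
#' distance entering both the bounded-confidence gate and the biased
#' partner-selection kernel.
#'
#' @param x_a,x_b Opinion values in \[0, 1\] (vectorized).
#' @return Non-negative numeric, `|x_a - x_b|`.
#' @examples
#' opinion_distance(0.7, 0.4) # 0.3
#' @export
opinion_distance <- function(x_a, x_b) {
  check_opinion(x_a, "x_a")
  check_opinion(x_b, "x_b")
  abs(x_a - x_b)
}

#' Biased partner-selection weights
#'
#' Probability of approaching each candidate, proportional to
#' `d^(-gamma)` where `d` is the opinion distance clamped below by
#' `distance_floor` (so a zero distance never produces an undefined
#' weight). `gamma = 0` gives exactly uniform selection; larger `gamma`
#' concentrates probability on nearby opinions, emulating a filtering
#' recommender.
#'
#' @param focal_opinion Opinion of the selecting agent.
#' @param candidate_opinions Non-empty numeric vector of candidate opinions.
#' @param gamma Non-negative bias exponent.
#' @param distance_floor Positive lower clamp on distances (default `1e-4`).
#' @return Numeric probability vector summing to 1.
#' @examples
#' selection_weights(0.5, c(0.4, 0.3), gamma = 1) # 2/3, 1/3
#' @export
selection_weights <- function(focal_opinion, candidate_opinions, gamma,
                              distance_floor = 1e-4) {
  if (length(candidate_opinions) == 0L)
    stop("candidate_opinions must be non-empty")
  if (gamma < 0) stop("gamma must be >= 0")
  if (distance_floor <= 0) stop("distance_floor must be > 0")
  check_opinion(focal_opinion, "focal_opinion")
  check_opinion(candidate_opinions, "candidate_opinions")
  if (gamma == 0)
    return(rep(1 / length(candidate_opinions), length(candidate_opinions)))
  d <- pmax(abs(focal_opinion - candidate_opinions), distance_floor)
  w <- d^(-gamma)
  w / sum(w)
}

#' Bounded-confidence pair update (homogeneous rule)
#'
#' If the two opinions differ by at most `epsilon` both agents move a
#' fraction `mu` of the gap towards each other; with `mu = 0.5` both adopt
#' the pair mean. Outside the bound neither moves. The gate is inclusive
#' (`<=`), so a distance exactly equal to `epsilon` persuades.
#'
#' @param x_i,x_j Opinions in \[0, 1\].
#' @param epsilon Confidence bound in \[0, 1\].
#' @param mu Convergence parameter in (0, 0.5].
#' @return Numeric length-2 vector: updated `(x_i, x_j)`.
#' @examples
#' pair_update(0.2, 0.4, epsilon = 0.3, mu = 0.5) # 0.3 0.3
#' @export
pair_update <- function(x_i, x_j, epsilon, mu) {
  check_opinion(x_i, "x_i"); check_opinion(x_j, "x_j")
  check_mu(mu)
  if (abs(x_i - x_j) <= epsilon)
    c(x_i + mu * (x_j - x_i), x_j + mu * (x_i - x_j))
  else
    c(x_i, x_j)
}

#' Bounded-confidence pair update with per-agent confidence bounds
#'
#' Each side of the pair is gated by its own bound, evaluated on the
#' pre-update opinions: agent i moves iff `|x_i - x_j| < eps_i`, agent j
#' iff `|x_i - x_j| < eps_j` (strict inequality, unlike the homogeneous
#' rule). With `mu = 0.5` a moving agent adopts the pair mean; one-sided
#' moves are possible.
#'
#' @param x_i,x_j Opinions in \[0, 1\].
#' @param eps_i,eps_j Per-agent confidence bounds in \[0, 1\].
#' @param mu Convergence parameter in (0, 0.5].
#' @return Numeric length-2 vector: updated `(x_i, x_j)`.
#' @examples
#' heterogeneous_pair_update(0.2, 0.6, eps_i = 0.5, eps_j = 0.1, mu = 0.5)
#' @export
heterogeneous_pair_update <- function(x_i, x_j, eps_i, eps_j, mu) {
  if (missing(eps_i) || missing(eps_j) || is.null(eps_i) || is.null(eps_j))
    stop("per-agent confidence bounds eps_i and eps_j are required")
  check_opinion(x_i, "x_i"); check_opinion(x_j, "x_j")
  check_mu(mu)
  d <- abs(x_i - x_j)
  out_i <- if (d < eps_i) x_i + mu * (x_j - x_i) else x_i
  out_j <- if (d < eps_j) x_j + mu * (x_i - x_j) else x_j
  c(out_i, out_j)
}

#' One-sided media update
#'
#' An agent consulting a stubborn media outlet moves towards the media
#' opinion by fraction `mu` of the gap if the outlet lies within the
#' agent's confidence bound; the media opinion never changes. The gate is
#' inclusive (`<=`) under the homogeneous rule and strict (`<`) under the
#' heterogeneous rule, matching the pair rule in force.
#'
#' @param x_i Agent opinion in \[0, 1\].
#' @param x_m Media opinion in \[0, 1\].
#' @param epsilon_i The agent's confidence bound.
#' @param mu Convergence parameter in (0, 0.5].
#' @param heterogeneous Logical; use the strict gate of the per-agent rule.
#' @return Updated agent opinion (scalar).
#' @examples
#' media_update(0.4, 0.5, epsilon_i = 0.3, mu = 0.5) # 0.45
#' @export
media_update <- function(x_i, x_m, epsilon_i, mu, heterogeneous = FALSE) {
  check_opinion(x_i, "x_i"); check_opinion(x_m, "x_m")
  check_mu(mu)
  d <- abs(x_i - x_m)
  gate <- if (heterogeneous) d < epsilon_i else d <= epsilon_i
  if (gate) x_i + mu * (x_m - x_i) else x_i
}

#' Model configuration
#'
#' Bundle of scalar parameters for a run. `epsilon` may be a single value
#' (homogeneous confidence bound, inclusive gate) or one value per agent
#' (heterogeneous bounds, strict gate and one-sided averaging).
#'
#' @param epsilon Confidence bound(s) in \[0, 1\]; length 1 or N.
#' @param gamma Non-negative algorithmic-bias exponent (default 0).
#' @param mu Convergence parameter in (0, 0.5] (default 0.5).
#' @param p_m Per-step media-interaction probability in \[0, 1\] (default 0).
#' @param distance_floor Positive clamp on kernel distances (default `1e-4`).
#' @param max_iterations Non-negative iteration cap (default `1e6`).
#' @param seed Optional integer seed; when set, [run_model()] seeds the R
#'   RNG before the run.
#' @return An object of class `model_config`.
#' @export
model_config <- function(epsilon, gamma = 0, mu = 0.5, p_m = 0,
                         distance_floor = 1e-4, max_iterations = 1e6,
                         seed = NULL) {
  if (length(epsilon) < 1L || any(epsilon < 0 | epsilon > 1))
    stop("epsilon must lie in [0, 1]")
  if (length(gamma) != 1L || gamma < 0) stop("gamma must be a scalar >= 0")
  check_mu(mu)
  if (length(p_m) != 1L || p_m < 0 || p_m > 1)
    stop("p_m must lie in [0, 1]")
  if (distance_floor <= 0) stop("distance_floor must be > 0")
  if (max_iterations < 0) stop("max_iterations must be >= 0")
  structure(
    list(epsilon = as.numeric(epsilon), gamma = gamma, mu = mu, p_m = p_m,
         distance_floor = distance_floor,
         max_iterations = as.numeric(max_iterations),
         heterogeneous = length(epsilon) > 1L,
         seed = seed),
    class = "model_config")
}

#' @export
print.model_config <- function(x, ...) {
  eps <- if (x$heterogeneous)
    sprintf("per-agent (N = %d, range %.3g-%.3g)", length(x$epsilon),
            min(x$epsilon), max(x$epsilon))
  else format(x$epsilon)
  cat("<model_config> epsilon:", eps,
      " gamma:", x$gamma, " mu:", x$mu, " p_m:", x$p_m, "\n",
      " distance_floor:", x$distance_floor,
      " max_iterations:", format(x$max_iterations),
      " seed:", if (is.null(x$seed)) "unset" else x$seed, "\n")
  invisible(x)
}

#' Opinion state
#'
#' Per-agent continuous opinions plus the iteration clock.
#'
#' @param opinions Numeric vector of opinions in \[0, 1\], length >= 2.
#' @param time Non-negative integer step count (default 0).
#' @return An object of class `opinion_state`.
#' @export
opinion_state <- function(opinions, time = 0) {
  if (length(opinions) < 2L) stop("need at least 2 agents")
  check_opinion(opinions, "opinions")
  if (time < 0) stop("time must be >= 0")
  structure(list(opinions = as.numeric(opinions), time = as.numeric(time)),
            class = "opinion_state")
}

#' Media landscape
#'
#' Fixed opinions of the stubborn mass-media agents. An empty landscape
#' (`M = 0`) recovers the media-free model.
#'
#' @param media_opinions Numeric vector of media opinions in \[0, 1\];
#'   may be empty.
#' @return An object of class `media_landscape`.
#' @export
media_landscape <- function(media_opinions = numeric(0)) {
  if (length(media_opinions))
    check_opinion(media_opinions, "media_opinions")
  structure(list(media_opinions = as.numeric(media_opinions)),
            class = "media_landscape")
}

#' @export
print.media_landscape <- function(x, ...) {
  m <- x$media_opinions
  if (!length(m)) cat("<media_landscape> no media (M = 0)\n")
  else cat("<media_landscape> M =", length(m), "at",
           paste(format(m), collapse = ", "), "\n")
  invisible(x)
}

#' One simulation step
#'
#' Executes a single discrete step of the dynamics in pure R, consuming
#' the R random stream in the documented order so that trajectories are
#' replayable and seed-matched against the compiled driver used by
#' [run_model()]:
#' \enumerate{
#'   \item one uniform draw picks the target agent i;
#'   \item one uniform draw picks peer j among i's neighbours by
#'     cumulative-sum inversion of [selection_weights()];
#'   \item the pair rule in force is applied (no draw);
#'   \item only when `p_m > 0` and at least one medium exists: one uniform
#'     draw gates the media interaction, and if it fires one further draw
#'     picks the medium (again kernel-weighted); [media_update()] is then
#'     applied to agent i;
#'   \item the clock advances by one.
#' }
#' With `p_m = 0` or an empty landscape a step consumes exactly two draws
#' and is one step of the media-free algorithmic-bias model.
#'
#' @param state An [opinion_state()].
#' @param graph An [interaction_graph()].
#' @param media A [media_landscape()].
#' @param config A [model_config()].
#' @return The updated `opinion_state`.
#' @export
simulation_step <- function(state, graph, media, config) {
  stopifnot(inherits(state, "opinion_state"),
            inherits(graph, "interaction_graph"),
            inherits(media, "media_landscape"),
            inherits(config, "model_config"))
  x <- state$opinions
  n <- length(x)
  if (graph$n_nodes != n) stop("state and graph sizes differ")
  eps <- if (config$heterogeneous) config$epsilon else rep(config$epsilon, n)
  if (config$heterogeneous && length(eps) != n)
    stop("heterogeneous epsilon must have one entry per agent")

  i <- floor(runif(1) * n) + 1L
  nb <- graph_neighbors(graph, i)
  if (length(nb) == 0L) stop("agent ", i, " has no neighbours")
  j <- nb[pick_weighted(x[i], x[nb], config$gamma, config$distance_floor)]

  if (config$heterogeneous) {
    upd <- heterogeneous_pair_update(x[i], x[j], eps[i], eps[j], config$mu)
  } else {
    upd <- pair_update(x[i], x[j], eps[i], config$mu)
  }
  x[i] <- upd[1]; x[j] <- upd[2]

  m <- media$media_opinions
  if (config$p_m > 0 && length(m) >= 1L) {
    if (runif(1) < config$p_m) {
      k <- pick_weighted(x[i], m, config$gamma, config$distance_floor)
      x[i] <- media_update(x[i], m[k], eps[i], config$mu,
                           heterogeneous = config$heterogeneous)
    }
  }
  opinion_state(x, time = state$time + 1)
}

# one uniform draw -> index into candidates; plain-double accumulation to
# mirror the compiled core exactly
pick_weighted <- function(focal, candidates, gamma, distance_floor) {
  w <- (pmax(abs(focal - candidates), distance_floor))^(-gamma)
  total <- 0
  for (v in w) total <- total + v
  cut <- runif(1) * total
  acc <- 0
  for (k in seq_along(w)) {
    acc <- acc + w[k]
    if (cut < acc) return(k)
  }
  length(w)
}

check_opinion <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0 | x > 1))
    stop(name, " must lie in [0, 1]")
  invisible(TRUE)
}

check_mu <- function(mu) {
  if (length(mu) != 1L || mu <= 0 || mu > 0.5)
    stop("mu must lie in (0, 0.5]")
  invisible(TRUE)
}
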