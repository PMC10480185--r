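test_that("opinion distance is the absolute difference, with domain checks", {
  expect_equal(opinion_distance(0.7, 0.4), 0.3)
  expect_equal(opinion_distance(0.5, 0.5), 0)
  expect_equal(opinion_distance(0, 1), 1)
  expect_equal(opinion_distance(0.2, 0.9), opinion_distance(0.9, 0.2))
  expect_error(opinion_distance(1.2, 0.5), "\\[0, 1\\]")
  expect_error(opinion_distance(0.5, -0.1), "\\[0, 1\\]")
})

test_that("selection weights follow the inverse-distance kernel", {
  expect_equal(selection_weights(0.5, c(0.4, 0.3), gamma = 1),
               c(2 / 3, 1 / 3))
  expect_equal(selection_weights(0.9, c(0.1, 0.4, 0.6, 0.8), gamma = 0),
               rep(0.25, 4))
  # zero distance clamped to the floor: 1e4 vs 1/0.4 weight ratio
  w <- selection_weights(0.5, c(0.5, 0.9), gamma = 1, distance_floor = 1e-4)
  expect_equal(w, c(1e4, 2.5) / (1e4 + 2.5))
  expect_gt(w[1], 0.9997)
  expect_error(selection_weights(0.5, numeric(0), gamma = 1), "non-empty")
  expect_error(selection_weights(0.5, c(0.1), gamma = -1), ">= 0")
})

test_that("selection weights normalize and decrease with distance", {
  set.seed(7)
  for (rep in 1:50) {
    gamma <- sample(c(0, 0.5, 1, 1.5, 2), 1)
    cand <- runif(sample(2:30, 1))
    focal <- runif(1)
    w <- selection_weights(focal, cand, gamma)
    expect_true(all(w >= 0))
    expect_lt(abs(sum(w) - 1), 1e-12)
    if (gamma > 0) {
      ord <- order(abs(focal - cand))
      expect_true(all(diff(w[ord]) <= 1e-15))
    }
  }
})

test_that("homogeneous pair update averages inside the bound, inclusive", {
  expect_equal(pair_update(0.2, 0.4, epsilon = 0.3, mu = 0.5), c(0.3, 0.3))
  expect_equal(pair_update(0.1, 0.9, epsilon = 0.3, mu = 0.5), c(0.1, 0.9))
  # boundary case d == epsilon persuades
  expect_equal(pair_update(0.2, 0.5, epsilon = 0.3, mu = 0.5), c(0.35, 0.35))
  # generic mu moves each end a mu-fraction of the gap
  expect_equal(pair_update(0.2, 0.6, epsilon = 1, mu = 0.25), c(0.3, 0.5))
  # conservation and range over random accepted updates
  set.seed(11)
  for (rep in 1:100) {
    x <- runif(2)
    out <- pair_update(x[1], x[2], epsilon = 1, mu = 0.5)
    expect_lt(abs(sum(out) - sum(x)), 1e-12)
    expect_true(all(out >= 0 & out <= 1))
  }
})

test_that("heterogeneous pair update gates each side by its own bound", {
  expect_equal(heterogeneous_pair_update(0.2, 0.6, 0.5, 0.1, mu = 0.5),
               c(0.4, 0.6))
  expect_equal(heterogeneous_pair_update(0.2, 0.6, 0.1, 0.1, mu = 0.5),
               c(0.2, 0.6))
  expect_equal(heterogeneous_pair_update(0.2, 0.6, 0.5, 0.5, mu = 0.5),
               c(0.4, 0.4))
  # strict gate: d == eps does not persuade (unlike the homogeneous rule)
  expect_equal(heterogeneous_pair_update(0.2, 0.5, 0.3, 0.3, mu = 0.5),
               c(0.2, 0.5))
  expect_equal(pair_update(0.2, 0.5, epsilon = 0.3, mu = 0.5),
               c(0.35, 0.35))
  expect_error(heterogeneous_pair_update(0.2, 0.5, mu = 0.5),
               "eps_i and eps_j")
})

test_that("media update moves only the agent, never the medium", {
  expect_equal(media_update(0.4, 0.5, epsilon_i = 0.3, mu = 0.5), 0.45)
  expect_equal(media_update(0.9, 0.0, epsilon_i = 0.3, mu = 0.5), 0.9)
  expect_equal(media_update(0.0, 0.0, epsilon_i = 0.3, mu = 0.5), 0.0)
  # gate matches the rule in force: inclusive homogeneous, strict hetero
  expect_equal(media_update(0.2, 0.5, 0.3, 0.5), 0.35)
  expect_equal(media_update(0.2, 0.5, 0.3, 0.5, heterogeneous = TRUE), 0.2)
})

test_that("model_config validates parameter ranges", {
  cfg <- model_config(0.3)
  expect_s3_class(cfg, "model_config")
  expect_false(cfg$heterogeneous)
  expect_true(model_config(runif(10))$heterogeneous)
  expect_error(model_config(1.2), "epsilon")
  expect_error(model_config(0.3, gamma = -1), "gamma")
  expect_error(model_config(0.3, mu = 0.7), "mu")
  expect_error(model_config(0.3, p_m = 2), "p_m")
  expect_error(model_config(0.3, distance_floor = 0), "distance_floor")
})

test_that("a single step replays by hand from the recorded draws", {
  # N = 3, opinions (0.1, 0.2, 0.9), gamma = 0, eps = 0.3, mu = 0.5, p_m = 0
  x0 <- c(0.1, 0.2, 0.9)
  cfg <- model_config(0.3, gamma = 0, mu = 0.5, p_m = 0)
  g <- mean_field_graph(3)
  for (s in 1:25) {
    set.seed(s)
    u <- runif(2)
    i <- floor(u[1] * 3) + 1
    j <- setdiff(1:3, i)[floor(u[2] * 2) + 1]
    exp_x <- x0
    exp_x[c(i, j)] <- pair_update(x0[i], x0[j], 0.3, 0.5)
    set.seed(s)
    st <- simulation_step(opinion_state(x0), g, media_landscape(), cfg)
    expect_equal(st$opinions, exp_x)
    expect_equal(st$time, 1)
  }
})

test_that("the pure-R step and the compiled driver are seed-matched", {
  g <- mean_field_graph(20)
  media <- media_landscape(c(0.05, 0.5, 0.95))
  for (s in 1:10) {
    cfg <- model_config(0.3, gamma = 1, mu = 0.5, p_m = 0.5,
                        max_iterations = 1)
    set.seed(s)
    x0 <- runif(20)
    st <- opinion_state(x0)
    one <- simulation_step(st, g, media, cfg)
    set.seed(s)
    x0b <- runif(20)
    res <- run_model(opinion_state(x0b), g, media, cfg,
                     stop = quick_equilibrium())
    expect_identical(res$final_state$opinions, one$opinions)
  }
})

test_that("opinions stay in [0, 1] and the media-free sum is conserved", {
  set.seed(3)
  x0 <- runif(50)
  cfg <- model_config(0.4, gamma = 1, mu = 0.5, p_m = 0,
                      max_iterations = 1e4)
  res <- run_model(x0, mean_field_graph(50), media_landscape(), cfg,
                   stop = stopping_rule("cluster_equilibrium",
                                        patience = 10000L))
  x1 <- res$final_state$opinions
  expect_true(all(x1 >= 0 & x1 <= 1))
  expect_lt(abs(sum(x1) - sum(x0)), 1e-9)
})

test_that("gamma = 0, p_m = 0 dynamics match a naive DW oracle over 1e4 steps", {
  n <- 100
  cfg <- model_config(0.25, gamma = 0, mu = 0.5, p_m = 0,
                      max_iterations = 1e4)
  set.seed(2024)
  x0 <- runif(n)
  oracle <- naive_dw_run(x0, epsilon = 0.25, mu = 0.5, n_steps = 1e4)
  set.seed(2024)
  x0b <- runif(n)
  res <- run_model(x0b, mean_field_graph(n), media_landscape(), cfg,
                   stop = stopping_rule("cluster_equilibrium",
                                        patience = 10000L))
  expect_identical(res$final_state$opinions, oracle)
  expect_equal(res$iterations, 1e4)
})

test_that("with p_m = 0 the trajectory ignores the media landscape entirely", {
  cfg <- model_config(0.3, gamma = 0.5, mu = 0.5, p_m = 0,
                      max_iterations = 2000)
  set.seed(5); x0 <- runif(30)
  a <- run_model(x0, mean_field_graph(30), media_landscape(), cfg,
                 stop = quick_equilibrium(1000L))
  set.seed(5); x0 <- runif(30)
  b <- run_model(x0, mean_field_graph(30), scenario_media("balanced"), cfg,
                 stop = quick_equilibrium(1000L))
  expect_identical(a$final_state$opinions, b$final_state$opinions)
})
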