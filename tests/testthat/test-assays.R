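test_that("probes never modify network parameters", {
  set.seed(55)
  net <- random_net()
  w <- world_config()
  snapshot <- unserialize(serialize(net, NULL))
  invisible(anhedonia_probe(list(net, net), w))
  invisible(infer_discount(net, w))
  invisible(avoidance_probe(net, w))
  invisible(exploration_divergence(net, net, states = 5, world = w))
  invisible(goal_proximity_correlation(net, w, n_episodes = 2))
  expect_identical(net, snapshot)
})

test_that("discount inference inverts synthetic exponential values exactly", {
  for (g in c(0.5, 0.7, 0.9)) {
    fit <- fit_discount(1:5, 10 * g^(1:5))
    expect_equal(fit$gamma_eff, g, tolerance = 1e-12)
    expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  }
  fit <- fit_discount(1:4, 5 * 0.5^(1:4))
  expect_equal(fit$gamma_eff, 0.5, tolerance = 1e-12)
  # constant values imply no discounting
  expect_equal(fit_discount(1:5, rep(3, 5))$gamma_eff, 1)
  # non-positive values are excluded; too few left is an error
  expect_error(fit_discount(1:4, c(1, -1, 0, -2)), "fewer than 3")
  kept <- fit_discount(1:5, c(10, -1, 10 * 0.8^3, 10 * 0.8^4, 10 * 0.8^5) *
                         c(0.8, 1, 1, 1, 1))
  expect_equal(nrow(kept$data), 4)
})

test_that("anhedonia classification follows the significance criterion", {
  w <- world_config()
  # identical values for both actions in every repetition: no preference
  nets_flat <- lapply(1:6, function(i) const_net(c(0.3, 1.1, 1.1)))
  res <- anhedonia_probe(nets_flat, w)
  expect_true(res$anhedonia)

  # constant +5 preference for the detour: clearly not anhedonic
  set.seed(8)
  nets_pref <- lapply(1:20, function(i) {
    jitter <- stats::rnorm(1, sd = 0.05)
    const_net(c(0, 5 + jitter, 0 + jitter))
  })
  res <- anhedonia_probe(nets_pref, w)
  expect_false(res$anhedonia)
  expect_gt(res$mean_right - res$mean_forward, 4.9)

  # shifting every value by a constant leaves the decision unchanged
  nets_shift <- lapply(nets_pref, function(n) {
    n$b_out <- n$b_out + 100
    n
  })
  expect_false(anhedonia_probe(nets_shift, w)$anhedonia)

  expect_error(anhedonia_probe(nets_pref[1], w), "repetitions")
})

test_that("generalized avoidance is a premature significant drop", {
  # single-profile classification per the stated patterns
  prof <- function(v) tibble::tibble(rep = 1, position = 1:4, v_forward = v)
  expect_false(avoidance_flag(prof(c(1.0, 1.5, 2.0, 0.5)))$flag) # healthy shape
  expect_true(avoidance_flag(prof(c(1.0, 0.8, 0.6, 0.4)))$flag)  # generalized
  expect_false(avoidance_flag(prof(c(1, 1, 1, 1)))$flag)         # constant

  # across repetitions the drop must be statistically significant
  set.seed(12)
  reps <- 10
  rising <- purrr::map_dfr(1:reps, function(r) tibble::tibble(
    rep = r, position = 1:4,
    v_forward = c(1, 2, 3, 0.5) + stats::rnorm(4, sd = 0.1)))
  expect_false(avoidance_flag(rising)$flag)
  dropping <- purrr::map_dfr(1:reps, function(r) tibble::tibble(
    rep = r, position = 1:4,
    v_forward = c(2, 1, 0.8, 0.5) + stats::rnorm(4, sd = 0.1)))
  expect_true(avoidance_flag(dropping)$flag)
})

test_that("KL divergence matches closed forms and the Gibbs inequality", {
  expect_equal(kl_divergence(c(0.2, 0.3, 0.5), c(0.2, 0.3, 0.5)), 0)
  p <- c(0.5, 0.25, 0.25); q <- rep(1 / 3, 3)
  expect_equal(kl_divergence(p, q),
               0.5 * log(1.5) + 2 * 0.25 * log(0.75), tolerance = 1e-12)
  expect_equal(kl_divergence(p, q), 0.05889151, tolerance = 1e-6)
  set.seed(3)
  net <- random_net()
  w <- world_config()
  expect_equal(exploration_divergence(net, net, states = 20, world = w), 0)
  # KL >= 0 for arbitrary network pairs over sampled states
  for (i in 1:5) {
    n1 <- random_net(); n2 <- random_net()
    sts <- sample_world_states(8, w)
    kls <- vapply(sts, function(st) {
      kl_divergence(softmax_policy(forward_pass(n1, observe(st, w)), 1),
                    softmax_policy(forward_pass(n2, observe(st, w)), 1))
    }, numeric(1))
    expect_true(all(kls >= 0))
    expect_equal(exploration_divergence(n2, n1, sts, w), mean(kls))
  }
})

test_that("optional-goal averages and intervals match hand computations", {
  base <- tibble::tibble(episode = 1:300, steps = 10L, reward = 10,
                         hazard_hits = 0L, reached_goal = TRUE,
                         sum_delta2 = 0, sum_dw_norm = 0)
  tr2 <- dplyr::mutate(base, optional_collected = 2L)
  res <- optional_goals_per_episode(tr2, window = 200)
  expect_equal(res$mean, 2)
  expect_equal(res$upper - res$lower, 0)

  alt <- dplyr::mutate(base, optional_collected = rep(c(1L, 3L), 150))
  expect_equal(optional_goals_per_episode(alt, window = 200)$mean, 2)

  # multi-repetition: t-interval across repetition means
  multi <- dplyr::bind_rows(lapply(1:4, function(r)
    dplyr::mutate(base, rep = r, optional_collected = r)))
  res <- optional_goals_per_episode(multi, window = 100)
  expect_equal(res$mean, mean(1:4))
  s <- stats::sd(1:4)
  expect_equal(res$upper - res$mean, stats::qt(0.975, 3) * s / 2,
               tolerance = 1e-12)
  expect_error(optional_goals_per_episode(base[1:50, ] |>
                 dplyr::mutate(optional_collected = 1L), window = 200),
               "window")
})

test_that("weight change per unit loss matches one-step hand computation", {
  w <- world_config()
  # alpha = 0: no updates, the series is identically zero
  ag0 <- train_agent(w, learning_config(alpha = 0), episodes = 5, seed = 2)
  series <- weight_change_per_loss(ag0, window = 2)
  expect_true(all(series$dw_per_loss == 0))

  # a single hand-computed update
  set.seed(6)
  net <- random_net()
  obs <- as.numeric(stats::runif(100) < 0.2)
  cfg <- learning_config(alpha = 0.02, weight_decay = 0.01)
  delta <- 1.7
  g <- td_gradients(net, obs, "forward", delta)
  upd <- apply_update(net, g, cfg)
  dw <- sqrt(sum((upd$w_in - net$w_in)^2) + sum((upd$w_out - net$w_out)^2))
  trace <- tibble::tibble(episode = 1, sum_delta2 = delta^2, sum_dw_norm = dw)
  expect_equal(weight_change_per_loss(trace, window = 1)$dw_per_loss,
               dw / delta^2)

  # doubling alpha doubles the weight change at lambda = 0 (exact linearity)
  cfg1 <- learning_config(alpha = 0.01)
  cfg2 <- learning_config(alpha = 0.02)
  d1 <- apply_update(net, g, cfg1)
  d2 <- apply_update(net, g, cfg2)
  expect_equal(d2$w_in - net$w_in, 2 * (d1$w_in - net$w_in))
})

test_that("goal-proximity correlations behave at the fixtures", {
  w <- corridor_world(5)
  # constant-activation neurons get correlation 0 by convention
  net <- zero_net()
  net$b_out[3] <- 1 # drive forward so greedy rollouts reach the goal
  set.seed(9)
  r <- goal_proximity_correlation(net, w, n_episodes = 2)
  expect_equal(r, rep(0, 10))

  # one hidden unit reading the goal's position in the visual field linearly
  # in distance: |r| = 1 on the corridor
  lin <- zero_net()
  lin$b_out[3] <- 1
  eps <- 1e-6
  for (d in 1:4) {
    st <- make_world_state(w, c(5 - d, 1), "E")
    bit <- which(observe(st, w) == 1)
    goal_bit <- bit[(bit - 1) %% 4 + 1 == 3]
    lin$w_in[goal_bit, 1] <- -eps * d
  }
  set.seed(9)
  r <- goal_proximity_correlation(lin, w, n_episodes = 2)
  expect_equal(r[1], 1, tolerance = 1e-6)
  expect_true(all(r >= 0 & r <= 1))
})

test_that("bias summary measures the change in mean absolute bias", {
  set.seed(44)
  a <- random_net()
  expect_equal(bias_summary(a, a), 0)
  b <- a
  b$b_hidden <- 2 * a$b_hidden
  b$b_out <- 2 * a$b_out
  expect_equal(bias_summary(a, b), mean(abs(c(a$b_hidden, a$b_out))))
})

test_that("behavior_matrix classifies from tidy statistics reproducibly", {
  mk <- function(variant, rep, stat, value)
    tibble::tibble(variant = variant, rep = rep, statistic = stat, value = value)
  reps <- 1:6
  set.seed(15)
  healthy <- dplyr::bind_rows(
    mk("healthy", reps, "v_turn_right", 5 + stats::rnorm(6, sd = 0.1)),
    mk("healthy", reps, "v_forward", 2 + stats::rnorm(6, sd = 0.1)),
    mk("healthy", reps, "gamma_eff", 0.85 + stats::rnorm(6, sd = 0.01)),
    mk("healthy", reps, "avoid_v1", 1), mk("healthy", reps, "avoid_v2", 2),
    mk("healthy", reps, "avoid_v3", 3), mk("healthy", reps, "avoid_v4", 0.5),
    mk("healthy", reps, "kl_baseline", 0.05 + stats::rnorm(6, sd = 0.005)))
  depressed <- dplyr::bind_rows(
    mk("model_x", reps, "v_turn_right", 1 + stats::rnorm(6, sd = 0.5)),
    mk("model_x", reps, "v_forward", 1.1 + stats::rnorm(6, sd = 0.5)),
    mk("model_x", reps, "gamma_eff", 0.6 + stats::rnorm(6, sd = 0.01)),
    mk("model_x", reps, "avoid_v1", 2 + stats::rnorm(6, sd = 0.05)),
    mk("model_x", reps, "avoid_v2", 1 + stats::rnorm(6, sd = 0.05)),
    mk("model_x", reps, "avoid_v3", 0.8 + stats::rnorm(6, sd = 0.05)),
    mk("model_x", reps, "avoid_v4", 0.5 + stats::rnorm(6, sd = 0.05)),
    mk("model_x", reps, "kl", 0.5 + stats::rnorm(6, sd = 0.02)))
  stats_tbl <- dplyr::bind_rows(healthy, depressed)

  b <- behavior_matrix(stats_tbl)
  hrow <- b[b$variant == "healthy", ]
  xrow <- b[b$variant == "model_x", ]
  expect_false(hrow$anhedonia)
  expect_false(hrow$generalized_avoidance)
  expect_false(hrow$increased_discounting)
  expect_false(hrow$more_exploration)
  expect_true(xrow$anhedonia)
  expect_true(xrow$generalized_avoidance)
  expect_true(xrow$increased_discounting)
  expect_true(xrow$more_exploration)

  # pure function of the saved statistics
  expect_identical(behavior_matrix(stats_tbl), b)
  expect_error(behavior_matrix(stats_tbl[stats_tbl$statistic != "gamma_eff", ]),
               "gamma_eff")
})

test_that("sampled probe states stay inside the room and off the goal", {
  w <- world_config()
  set.seed(20)
  sts <- sample_world_states(40, w)
  expect_length(sts, 40)
  for (st in sts) {
    expect_true(all(st$agent_pos >= 1) && st$agent_pos[1] <= 9 &&
                  st$agent_pos[2] <= 9)
    expect_false(all(st$agent_pos == w$required_goal_pos))
    expect_true(st$heading %in% c("N", "E", "S", "W"))
  }
})
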