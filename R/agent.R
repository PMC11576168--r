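# The TD value-learning core: reward-prediction error, action selection,
# and the online training loop (one td_error / gradient / update cycle per
# environment step).

#' One-step TD error (reward-prediction error)
#'
#' `delta = r_eff + gamma * max_b V(s', b) - V(s, a)`, where `r_eff` is the
#' reward after asymmetric scaling ([scale_reward()]) and the bootstrap term
#' is dropped on terminal transitions (episode ended at the required goal).
#' The result is finally multiplied by `rpe_scale`, the simulated dopamine
#' scaling.
#'
#' @param transition List with `obs`, `action`, `reward`, `next_obs`,
#'   `terminal`.
#' @param net A `network_params`.
#' @param config A [learning_config()].
#' @return The scalar TD error delta.
#' @export
td_error <- function(transition, net, config) {
  v <- forward_pass(net, transition$obs)
  a <- action_index(transition$action)
  r_eff <- scale_reward(transition$reward, config)
  target <- r_eff
  if (!isTRUE(transition$terminal))
    target <- target + config$gamma * max(forward_pass(net, transition$next_obs))
  (target - v[[a]]) * config$rpe_scale
}

#' Select an action from action values
#'
#' Epsilon-greedy: the highest-value action with probability `1 - epsilon`
#' and a uniformly random action otherwise (ties broken toward the lowest
#' action index). Softmax: sampled from [softmax_policy()] at temperature
#' `tau`. Uses R's global RNG.
#'
#' @param values Numeric action-value vector of length 3.
#' @param config A [learning_config()]; `policy` picks the rule.
#' @return Action name (`"turn_left"`, `"turn_right"`, or `"forward"`).
#' @export
select_action <- function(values, config) {
  stopifnot(length(values) == 3, all(is.finite(values)))
  if (config$policy == "egreedy") {
    u <- stats::runif(1)
    if (u < config$epsilon) {
      a <- min(1L + as.integer(floor(stats::runif(1) * 3)), 3L)
    } else {
      a <- which.max(values)
    }
  } else {
    p <- softmax_policy(values, config$tau)
    cum <- cumsum(p)
    u <- stats::runif(1)
    a <- 1L
    while (a < 3L && u > cum[a]) a <- a + 1L
  }
  ACTIONS[a]
}

#' Train a TD agent in the gridworld
#'
#' Runs `episodes` of interaction. At each environment step the agent selects
#' an action from its current value estimates, observes the reward and next
#' view, computes the reward-prediction error, and applies one semi-gradient
#' update with weight decay. Fully reproducible from `seed`.
#'
#' The default engine is a C++ loop; `engine = "r"` runs an equivalent pure-R
#' loop built from [forward_pass()], [select_action()], [td_error()],
#' [td_gradients()] and [apply_update()], consuming the identical RNG draw
#' sequence (useful for inspection and as a cross-check).
#'
#' @param world A [world_config()].
#' @param config A [learning_config()] (or [variant_config()]).
#' @param episodes Number of episodes (>= 1).
#' @param seed Optional integer seed (`set.seed()` is called if given).
#' @param net Optional initial `network_params`; default is a fresh
#'   [network_init()] drawn after seeding. If `config$deletion_fraction > 0`
#'   and the network carries no masks yet, [random_deletion()] is applied.
#' @param record_updates Keep per-update `delta^2` and weight-change norms
#'   (one row per update; can be large).
#' @param snapshot_every Record a parameter snapshot every this many episodes
#'   (0 = none; the initial and final parameters are always kept).
#' @param engine `"cpp"` (fast, default) or `"r"` (reference loop).
#' @return A `td_agent` object: list with `net`, `net_initial`, `world`,
#'   `config`, `trace` (tibble, one row per episode), `updates` (tibble or
#'   `NULL`), `snapshots`, `episodes`, `seed`.
#' @examples
#' ag <- train_agent(world_config(), learning_config(), episodes = 5, seed = 1)
#' ag$trace
#' @export
train_agent <- function(world, config, episodes, seed = NULL, net = NULL,
                        record_updates = FALSE, snapshot_every = 0,
                        engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  stopifnot(inherits(world, "world_config"), inherits(config, "learning_config"))
  episodes <- as.integer(episodes)
  if (episodes < 1) stop("episodes must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(net)) net <- network_init()
  if (config$deletion_fraction > 0 && is.null(net$mask_in))
    net <- random_deletion(net, config$deletion_fraction)
  net_initial <- net

  snapshots <- list()
  run_chunk <- function(net, n_ep) {
    if (engine == "cpp") train_chunk_cpp(net, world, config, n_ep, record_updates)
    else train_chunk_r(net, world, config, n_ep, record_updates)
  }
  if (snapshot_every > 0) {
    chunks <- diff(unique(c(seq(0L, episodes, by = as.integer(snapshot_every)), episodes)))
    out <- NULL
    done_ep <- 0L
    for (n_ep in chunks) {
      res <- run_chunk(net, n_ep)
      net <- res$net
      res$trace$episode <- res$trace$episode + done_ep
      done_ep <- done_ep + n_ep
      snapshots[[length(snapshots) + 1L]] <- list(episode = done_ep, net = net)
      out <- if (is.null(out)) res else list(
        net = net,
        trace = dplyr::bind_rows(out$trace, res$trace),
        updates = if (record_updates) dplyr::bind_rows(out$updates, res$updates)
      )
    }
    res <- out
  } else {
    res <- run_chunk(net, episodes)
  }

  structure(list(
    net = res$net, net_initial = net_initial, world = world, config = config,
    trace = res$trace, updates = if (record_updates) res$updates else NULL,
    snapshots = snapshots, episodes = episodes, seed = seed
  ), class = "td_agent")
}

#' @export
print.td_agent <- function(x, ...) {
  variant <- attr(x$config, "variant")
  last <- utils::tail(x$trace, min(200L, nrow(x$trace)))
  cat(sprintf("<td_agent>%s %d episode(s), lambda=%g; final-window mean reward %.2f, optional goals/episode %.2f\n",
              if (!is.null(variant)) paste0(" [", variant, "]") else "",
              x$episodes, x$config$weight_decay,
              mean(last$reward), mean(last$optional_collected)))
  invisible(x)
}

# C++ engine wrapper ---------------------------------------------------------

train_chunk_cpp <- function(net, world, config, episodes, record_updates) {
  haz <- if (world$include_hazards && length(world$hazard_positions))
    do.call(rbind, world$hazard_positions) else matrix(0L, 0, 2)
  m_in <- if (is.null(net$mask_in)) matrix(1, nrow(net$w_in), ncol(net$w_in)) else net$mask_in
  m_out <- if (is.null(net$mask_out)) matrix(1, nrow(net$w_out), ncol(net$w_out)) else net$mask_out
  res <- train_loop_cpp(
    net$w_in, net$b_hidden, net$w_out, net$b_out, m_in, m_out,
    world$width, world$height,
    world$start_pos[1], world$start_pos[2], match(world$start_heading, HEADINGS),
    world$required_goal_pos[1], world$required_goal_pos[2],
    haz,
    if (world$include_optional) world$n_optional_goals else 0L,
    free_cells(world),
    world$reward_optional, world$reward_required, world$reward_hazard,
    world$max_steps_per_episode,
    config$alpha, config$gamma, config$weight_decay, config$epsilon,
    config$tau, match(config$policy, c("egreedy", "softmax")),
    config$rpe_scale, config$negative_reward_scale, config$positive_reward_scale,
    episodes, record_updates
  )
  new_net <- net
  new_net$w_in <- res$w_in; new_net$b_hidden <- res$b_hidden
  new_net$w_out <- res$w_out; new_net$b_out <- res$b_out
  tr <- res$trace
  trace <- tibble::tibble(
    episode = seq_len(episodes),
    steps = as.integer(tr[, 1]), reward = tr[, 2],
    optional_collected = as.integer(tr[, 3]),
    hazard_hits = as.integer(tr[, 4]),
    reached_goal = tr[, 5] > 0,
    sum_delta2 = tr[, 6], sum_dw_norm = tr[, 7]
  )
  updates <- if (record_updates)
    tibble::tibble(update = seq_along(res$delta2), episode = as.integer(res$update_episode),
                   delta2 = res$delta2, dw_norm = res$dw_norm)
  list(net = new_net, trace = trace, updates = updates)
}

# Pure-R reference engine ----------------------------------------------------

train_chunk_r <- function(net, world, config, episodes, record_updates) {
  trace <- vector("list", episodes)
  upd <- if (record_updates) list(delta2 = list(), dw = list(), ep = list())
  for (ep in seq_len(episodes)) {
    rst <- world_reset(world)
    state <- rst$state; obs <- rst$observation
    reward_sum <- 0; n_opt <- 0L; n_haz <- 0L; steps <- 0L; reached <- FALSE
    s_d2 <- 0; s_dw <- 0
    d2v <- numeric(0); dwv <- numeric(0)
    repeat {
      v <- forward_pass(net, obs)
      a <- select_action(v, config)
      st <- world_step(state, a, world)
      terminal <- st$event == "required"
      delta <- td_error(list(obs = obs, action = a, reward = st$reward,
                             next_obs = st$observation, terminal = terminal),
                        net, config)
      g <- td_gradients(net, obs, a, delta)
      old_in <- net$w_in; old_out <- net$w_out
      net <- apply_update(net, g, config)
      dw <- sqrt(sum((net$w_in - old_in)^2) + sum((net$w_out - old_out)^2))
      s_d2 <- s_d2 + delta^2; s_dw <- s_dw + dw
      if (record_updates) { d2v <- c(d2v, delta^2); dwv <- c(dwv, dw) }
      reward_sum <- reward_sum + st$reward
      if (st$event == "optional") n_opt <- n_opt + 1L
      if (st$event == "hazard") n_haz <- n_haz + 1L
      if (terminal) reached <- TRUE
      steps <- steps + 1L
      state <- st$state; obs <- st$observation
      if (st$done) break
    }
    trace[[ep]] <- tibble::tibble(
      episode = ep, steps = steps, reward = reward_sum,
      optional_collected = n_opt, hazard_hits = n_haz, reached_goal = reached,
      sum_delta2 = s_d2, sum_dw_norm = s_dw
    )
    if (record_updates) {
      upd$delta2[[ep]] <- d2v; upd$dw[[ep]] <- dwv
      upd$ep[[ep]] <- rep(ep, length(d2v))
    }
  }
  updates <- if (record_updates) {
    d2 <- unlist(upd$delta2); tibble::tibble(
      update = seq_along(d2), episode = as.integer(unlist(upd$ep)),
      delta2 = d2, dw_norm = unlist(upd$dw))
  }
  list(net = net, trace = dplyr::bind_rows(trace), updates = updates)
}

#' Roll out episodes without learning
#'
#' Runs a network's policy in the world with parameters frozen (no updates,
#' no decay) and returns a step-level trace. Useful for inspecting learned
#' behavior and for writing step-resolved episode logs.
#'
#' @param world A [world_config()].
#' @param net A `network_params` (default: a fresh random network).
#' @param config A [learning_config()]; only the policy fields are used.
#' @param episodes Number of episodes to roll out.
#' @param seed Optional seed.
#' @return Tibble with columns `episode`, `step`, `action`, `reward`, `done`.
#' @export
simulate_episodes <- function(world, net = NULL, config = learning_config(),
                              episodes = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(net)) net <- network_init()
  rows <- list()
  for (ep in seq_len(episodes)) {
    rst <- world_reset(world)
    state <- rst$state; obs <- rst$observation
    step <- 0L
    repeat {
      a <- select_action(forward_pass(net, obs), config)
      st <- world_step(state, a, world)
      step <- step + 1L
      rows[[length(rows) + 1L]] <- tibble::tibble(
        episode = ep, step = step, action = a, reward = st$reward,
        done = st$done)
      state <- st$state; obs <- st$observation
      if (st$done) break
    }
  }
  dplyr::bind_rows(rows)
}

#' Write an episode trace as CSV
#'
#' One row per episode with the columns of `agent$trace`.
#'
#' @param agent A `td_agent` (or its `trace` tibble).
#' @param path File path.
#' @export
write_trace <- function(agent, path) {
  trace <- if (inherits(agent, "td_agent")) agent$trace else agent
  readr::write_csv(trace, path)
  invisible(path)
}
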