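# Behavioral probes and network-introspection measurements. Probes are
# read-only: they evaluate forward passes on contrived scenarios and never
# update parameters.
#
# Scenario geometry (default room, goal g at (9,9)):
#  - junction: agent (5,8) facing E, optional goal at (5,9), goal diagonally
#    ahead-right at the edge of the visual field. Direct route F,F,F,F,R,F
#    reaches the goal in 6 actions; the detour R,F(collect),L,F,F,F,F takes
#    7 — collecting the bonus costs exactly one extra action, so with
#    gamma=0.9 the detour is reward-optimal (gamma*1 + gamma^6*10 >
#    gamma^5*10).
#  - discount: agent on row 9 facing E at 1..4 forward steps from the goal
#    (the goal-visible range; from 5 steps out the view is aliased with
#    deeper positions).
#  - hazard approach: agent on column 9 facing S at positions (9,4)..(9,7),
#    walking toward a hazard placed at (9,8), directly before the goal; the
#    goal enters the visual field from position 2, so forward value rises
#    through positions 1-3 for an agent that localizes the threat, and from
#    position 4 the forward action steps onto the hazard, so value drops
#    there; the sensible policy detours via column 8.

#' Contrived probe scenarios
#'
#' Deterministic world states used to expose a trained network's perceived
#' values:
#'
#' * `anhedonia_junction` — the agent approaches the required goal with an
#'   optional goal one right-turn detour off the direct path. A healthy agent
#'   values `turn_right` (collect the bonus en route) well above `forward`
#'   (bypass it); losing that preference is the anhedonia-like effect.
#' * `discount_corridor` — the agent is placed `position` forward steps from
#'   the required goal on the straight row-wise approach (no optional goals
#'   present) to measure how perceived value decays with distance.
#' * `hazard_approach` — a hazard sits directly between the agent and the
#'   required goal, guarding the cell before it; `position` 1–4 moves the
#'   agent stepwise toward the hazard (position 4 is adjacent: `forward`
#'   steps onto it).
#'
#' Layouts are anchored to the configured required-goal position and match
#' the default room, so trained networks are probed on views drawn from the
#' distribution they learned on.
#'
#' @param id Scenario name.
#' @param world A [world_config()] (default room recommended).
#' @param position Distance index: steps-to-goal for `discount_corridor`
#'   (1–4 keeps the goal in view), approach position 1–4 for
#'   `hazard_approach`; ignored for the junction.
#' @return A `world_state` (see [make_world_state()]).
#' @export
probe_scenario <- function(id = c("anhedonia_junction", "discount_corridor",
                                  "hazard_approach"),
                           world = world_config(), position = 1) {
  id <- match.arg(id)
  g <- world$required_goal_pos
  switch(id,
    anhedonia_junction = {
      # goal diagonally ahead-right; optional goal on the right-adjacent cell
      pos <- c(g[1] - 4L, g[2] - 1L)
      make_world_state(world, pos, "E",
                       optional_goals = list(c(pos[1], g[2])))
    },
    discount_corridor = {
      stopifnot(position >= 1, g[1] - position >= 1)
      make_world_state(world, c(g[1] - as.integer(position), g[2]), "E")
    },
    hazard_approach = {
      stopifnot(position >= 1, position <= 4)
      # hazard guards the cell before the goal; positions 1..4 close in on
      # it, with the goal entering the visual field from position 2
      make_world_state(world, c(g[1], g[2] - 6L + as.integer(position)), "S",
                       hazards = list(c(g[1], g[2] - 1L)))
    }
  )
}

#' Anhedonia probe: value of collecting vs bypassing a bonus reward
#'
#' Evaluates each trained network on the junction scenario and compares the
#' perceived value of `turn_right` (detour through the optional goal) against
#' `forward` (bypass it) with a Welch two-sample t-test across repetitions.
#' A model shows the anhedonia-like effect when there is *no* significant
#' preference between the two.
#'
#' @param nets A list of trained `network_params` (>= 2 for the test).
#' @param world The [world_config()] the nets were trained in.
#' @param alpha_level Significance level (default 0.05).
#' @return List with `values` (tibble: rep, v_turn_right, v_forward),
#'   `mean_right`, `mean_forward`, `p_value`, and `anhedonia` (flag).
#' @export
anhedonia_probe <- function(nets, world = world_config(), alpha_level = 0.05) {
  obs <- observe(probe_scenario("anhedonia_junction", world), world)
  vals <- purrr::map_dfr(seq_along(nets), function(i) {
    v <- forward_pass(nets[[i]], obs)
    tibble::tibble(rep = i, v_turn_right = v[["turn_right"]],
                   v_forward = v[["forward"]])
  })
  if (nrow(vals) < 2) stop("need >= 2 repetitions to test significance")
  p <- welch_p(vals$v_turn_right, vals$v_forward)
  list(values = vals,
       mean_right = mean(vals$v_turn_right),
       mean_forward = mean(vals$v_forward),
       p_value = p,
       anhedonia = is.na(p) || p >= alpha_level)
}

# Welch two-sample p-value; degenerate zero-variance samples resolve by the
# sign of the mean difference (identical means -> NA).
welch_p <- function(x, y, alternative = "two.sided") {
  if (length(x) < 2 || length(y) < 2) return(NA_real_)
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    d <- mean(x) - mean(y)
    if (isTRUE(all.equal(d, 0))) return(NA_real_)
    return(switch(alternative,
                  two.sided = 0,
                  greater = if (d > 0) 0 else 1,
                  less = if (d < 0) 0 else 1))
  }
  tryCatch(stats::t.test(x, y, alternative = alternative)$p.value,
           error = function(e) NA_real_)
}


#' Fit an effective discount factor to value-by-distance data
#'
#' Ordinary least squares on `log V(d) = c + d * log(gamma_eff)`; the
#' effective discount factor is `exp(slope)`. Distances with non-positive
#' values are excluded; at least 3 must remain.
#'
#' @param distances Integer distances to the goal.
#' @param values Perceived values at those distances.
#' @return A `discount_fit`: list with `gamma_eff`, `log_value_intercept`,
#'   `r_squared`, and `data` (tibble of the points used).
#' @export
fit_discount <- function(distances, values) {
  keep <- is.finite(values) & values > 0
  if (sum(keep) < 3)
    stop("fewer than 3 positive values; cannot infer a discount factor")
  d <- distances[keep]; v <- values[keep]
  fit <- stats::lm(log(v) ~ d)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((log(v) - mean(log(v)))^2)
  structure(list(
    gamma_eff = exp(unname(stats::coef(fit)[2])),
    log_value_intercept = unname(stats::coef(fit)[1]),
    r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 1,
    data = tibble::tibble(distance = d, value = v)
  ), class = "discount_fit")
}

#' @export
print.discount_fit <- function(x, ...) {
  cat(sprintf("<discount_fit> gamma_eff = %.4f (r^2 = %.3f, %d distances)\n",
              x$gamma_eff, x$r_squared, nrow(x$data)))
  invisible(x)
}

#' Infer an agent's effective discount factor
#'
#' Places the agent progressively closer to the required goal (the
#' `discount_corridor` scenario), records the maximum perceived action value
#' at each distance, and fits `log V(d)` against `d` ([fit_discount()]). The
#' effective discount factor can fall below the explicit `gamma` parameter —
#' the additional discounting induced by spine loss.
#'
#' @param net A trained `network_params`.
#' @param world The [world_config()].
#' @param distances Distances to probe (default 1:4, the range over which
#'   the goal is inside the visual field).
#' @return A `discount_fit`.
#' @export
infer_discount <- function(net, world = world_config(), distances = 1:4) {
  vals <- vapply(distances, function(d) {
    obs <- observe(probe_scenario("discount_corridor", world, position = d), world)
    max(forward_pass(net, obs))
  }, numeric(1))
  fit_discount(distances, vals)
}

#' Hazard-approach avoidance probe
#'
#' Records the perceived value of `forward` at the four approach positions of
#' the `hazard_approach` scenario. Healthy agents' forward value rises
#' through positions 1–3 (the goal is getting closer) and drops only at
#' position 4, where `forward` steps onto the hazard; a drop already at
#' position 2 or 3 is the inappropriately generalized avoidance.
#'
#' @param net A trained `network_params`.
#' @param world The [world_config()].
#' @return Tibble with `position` (1–4) and `v_forward`.
#' @export
avoidance_probe <- function(net, world = world_config()) {
  purrr::map_dfr(1:4, function(p) {
    obs <- observe(probe_scenario("hazard_approach", world, position = p), world)
    tibble::tibble(position = p,
                   v_forward = forward_pass(net, obs)[["forward"]])
  })
}

#' Classify generalized avoidance from repeated approach profiles
#'
#' Flags generalized avoidance when the forward value *decreases*
#' significantly (one-sided Welch test across repetitions) from position 1
#' to 2 or from position 2 to 3. With a single repetition the comparison is
#' a strict decrease of the profile itself. A drop only at position 4 is the
#' healthy pattern.
#'
#' @param profiles Tibble with columns `rep`, `position`, `v_forward` (from
#'   [avoidance_probe()] over repetitions).
#' @param alpha_level Significance level.
#' @return List with `flag`, per-transition `p_values`, and the mean profile.
#' @export
avoidance_flag <- function(profiles, alpha_level = 0.05) {
  get <- function(p) profiles$v_forward[profiles$position == p]
  if (length(get(1)) < 2) {
    prof <- vapply(1:4, function(p) get(p), numeric(1))
    return(list(flag = prof[1] > prof[2] || prof[2] > prof[3],
                p_values = c(pos1_to_2 = NA_real_, pos2_to_3 = NA_real_),
                profile = prof))
  }
  p12 <- welch_p(get(1), get(2), alternative = "greater")
  p23 <- welch_p(get(2), get(3), alternative = "greater")
  drop12 <- !is.na(p12) && p12 < alpha_level
  drop23 <- !is.na(p23) && p23 < alpha_level
  list(flag = drop12 || drop23,
       p_values = c(pos1_to_2 = p12, pos2_to_3 = p23),
       profile = vapply(1:4, function(p) mean(get(p)), numeric(1)))
}

#' Kullback-Leibler divergence between two discrete distributions
#'
#' `KL(p || q) = sum_i p_i log(p_i / q_i)` in nats; terms with `p_i = 0`
#' contribute zero.
#'
#' @param p,q Probability vectors of equal length.
#' @export
kl_divergence <- function(p, q) {
  stopifnot(length(p) == length(q))
  nz <- p > 0
  sum(p[nz] * log(p[nz] / q[nz]))
}

#' Sample random reachable world states
#'
#' Draws states with a uniformly random agent pose (any room cell except the
#' required goal, any heading) and a fresh random optional-goal placement,
#' for use as evaluation points of the exploration comparison. Uses R's
#' global RNG.
#'
#' @param n Number of states.
#' @param world A [world_config()].
#' @return List of `world_state`s.
#' @export
sample_world_states <- function(n, world = world_config()) {
  purrr::map(seq_len(n), function(i) {
    repeat {
      c_ <- sample.int(world$width, 1)
      r_ <- sample.int(world$height, 1)
      if (c_ != world$required_goal_pos[1] || r_ != world$required_goal_pos[2]) break
    }
    h <- HEADINGS[sample.int(4, 1)]
    st <- world_reset(world)$state
    st$agent_pos <- c(c_, r_)
    st$heading <- h
    st
  })
}

#' Exploration comparison by KL divergence of softmax policies
#'
#' For each supplied world state, converts both networks' action values into
#' softmax action distributions at temperature `tau` and accumulates
#' `KL(baseline || test)`; returns the mean over states. The baseline is the
#' healthy agent's distribution; divergence between different healthy agents
#' serves as the reference level.
#'
#' @param net_test,net_baseline `network_params` objects.
#' @param states List of `world_state`s (e.g. [sample_world_states()]), or an
#'   integer number of states to sample.
#' @param world The [world_config()].
#' @param tau Softmax temperature (default 1).
#' @return Mean KL divergence in nats.
#' @export
exploration_divergence <- function(net_test, net_baseline, states = 100,
                                   world = world_config(), tau = 1) {
  if (is.numeric(states)) states <- sample_world_states(states, world)
  kls <- vapply(states, function(st) {
    obs <- observe(st, world)
    p <- softmax_policy(forward_pass(net_baseline, obs), tau)
    q <- softmax_policy(forward_pass(net_test, obs), tau)
    kl_divergence(p, q)
  }, numeric(1))
  mean(kls)
}

#' Optional goals collected per episode
#'
#' Mean optional goals collected per episode over the final `window`
#' episodes. Given traces from several repetitions (a `rep` column), the
#' 95% t-interval is computed across repetition means; for a single trace it
#' is computed across the episodes in the window.
#'
#' @param trace A `td_agent` trace tibble (optionally with a `rep` column).
#' @param window Number of final episodes to average (default 200).
#' @return Tibble with `mean`, `lower`, `upper`, `n`.
#' @export
optional_goals_per_episode <- function(trace, window = 200) {
  if (inherits(trace, "td_agent")) trace <- trace$trace
  if (!"rep" %in% names(trace)) trace$rep <- 1L
  per_rep <- trace %>%
    dplyr::group_by(.data$rep) %>%
    dplyr::group_modify(function(d, g) {
      if (nrow(d) < window) stop("trace shorter than the averaging window")
      utils::tail(d, window)
    }) %>%
    dplyr::summarise(opt = mean(.data$optional_collected), .groups = "drop")
  x <- if (nrow(per_rep) > 1) per_rep$opt
       else trace$optional_collected[trace$episode > max(trace$episode) - window]
  ci <- mean_ci(x)
  dplyr::mutate(ci, n = length(x))
}

#' Network plasticity per unit loss
#'
#' For consecutive windows of episodes, the total weight change divided by
#' the total squared TD error, `sum(||dW||_2) / sum(delta^2)` — a measure of
#' how much plasticity each unit of reward-prediction error buys.
#'
#' @param trace A `td_agent` (or its trace tibble with `sum_dw_norm` and
#'   `sum_delta2` columns).
#' @param window Window length in episodes.
#' @return Tibble with `window`, `episode_end`, `dw_per_loss`.
#' @export
weight_change_per_loss <- function(trace, window = 100) {
  if (inherits(trace, "td_agent")) trace <- trace$trace
  trace %>%
    dplyr::mutate(win = ceiling(.data$episode / window)) %>%
    dplyr::group_by(win = .data$win) %>%
    dplyr::summarise(episode_end = max(.data$episode),
                     dw = sum(.data$sum_dw_norm), d2 = sum(.data$sum_delta2),
                     .groups = "drop") %>%
    dplyr::transmute(window = .data$win, episode_end = .data$episode_end,
                     dw_per_loss = ifelse(.data$d2 > 0, .data$dw / .data$d2, 0))
}

#' Correlation of hidden activations with goal proximity
#'
#' Runs greedy rollouts (no exploration, no learning) and, for each hidden
#' neuron, computes the absolute Pearson correlation between its activation
#' and the negated action distance to the required goal over all visited
#' states. High values across most neurons indicate a network devoted almost
#' entirely to the basic goal-seeking strategy. Zero-variance activations get
#' correlation 0 by convention. Uses R's global RNG (episode layouts).
#'
#' @param net A trained `network_params`.
#' @param world The [world_config()].
#' @param n_episodes Number of greedy rollouts.
#' @return Numeric vector of length `length(net$b_hidden)` in `[0, 1]`.
#' @export
goal_proximity_correlation <- function(net, world = world_config(), n_episodes = 10) {
  acts <- list(); prox <- numeric(0)
  greedy <- learning_config(epsilon = 0)
  for (ep in seq_len(n_episodes)) {
    rst <- world_reset(world)
    state <- rst$state; obs <- rst$observation
    repeat {
      acts[[length(acts) + 1L]] <- hidden_activation(net, obs)
      prox <- c(prox, -distance_to_goal(state, world))
      a <- select_action(forward_pass(net, obs), greedy)
      st <- world_step(state, a, world)
      state <- st$state; obs <- st$observation
      if (st$done) break
    }
  }
  A <- do.call(rbind, acts)
  apply(A, 2, function(x) {
    if (stats::sd(x) == 0 || stats::sd(prox) == 0) 0 else abs(stats::cor(x, prox))
  })
}

#' Change in mean absolute neuron bias
#'
#' Mean absolute hidden-plus-output bias after minus before — positive values
#' indicate the bias compensation that accompanies strong weight decay
#' (neurons becoming more sensitive to offset the shrinking input weights).
#'
#' @param net_before,net_after `network_params` snapshots.
#' @return Scalar change in mean absolute bias.
#' @export
bias_summary <- function(net_before, net_after) {
  m <- function(n) mean(abs(c(n$b_hidden, n$b_out)))
  m(net_after) - m(net_before)
}

#' Behavior matrix: depression phenotypes per variant
#'
#' Classifies each variant on the four depression-like phenotypes from tidy
#' per-repetition probe statistics:
#'
#' * `anhedonia` — no significant difference between the perceived values of
#'   turning right (collect the bonus) and moving forward (bypass it) at the
#'   junction.
#' * `generalized_avoidance` — forward value drops significantly already at
#'   approach position 2 or 3 of the hazard scenario.
#' * `increased_discounting` — inferred `gamma_eff` significantly below the
#'   healthy agents' (one-sided Welch test).
#' * `more_exploration` — mean KL divergence from the healthy policy
#'   significantly above the healthy-vs-healthy baseline (one-sided Welch
#'   test).
#'
#' The classification is a pure function of the statistics table, so it can
#' be re-run on saved results.
#'
#' @param stats Tidy tibble with columns `variant`, `rep`, `statistic`,
#'   `value`. Expected statistics per rep: `v_turn_right`, `v_forward`,
#'   `gamma_eff`, `avoid_v1`..`avoid_v4`, `kl`; plus `kl_baseline` rows
#'   (healthy-vs-healthy divergences).
#' @param alpha_level Significance level (default 0.05).
#' @return A `behavior_matrix` tibble: one row per variant with the four
#'   logical flags and supporting statistics.
#' @export
behavior_matrix <- function(stats, alpha_level = 0.05) {
  variants <- unique(stats$variant)
  pull_stat <- function(v, s) {
    out <- stats$value[stats$variant == v & stats$statistic == s]
    if (!length(out)) stop(sprintf("missing probe statistic '%s' for variant '%s'", s, v))
    out
  }
  healthy_gamma <- pull_stat("healthy", "gamma_eff")
  kl_base <- stats$value[stats$statistic == "kl_baseline"]
  if (!length(kl_base)) stop("missing probe statistic 'kl_baseline'")
  rows <- purrr::map_dfr(variants, function(v) {
    vr <- pull_stat(v, "v_turn_right"); vf <- pull_stat(v, "v_forward")
    p_anh <- welch_p(vr, vf)
    prof <- purrr::map_dfr(1:4, function(p) tibble::tibble(
      rep = seq_along(pull_stat(v, paste0("avoid_v", p))),
      position = p, v_forward = pull_stat(v, paste0("avoid_v", p))))
    av <- avoidance_flag(prof, alpha_level)
    gam <- pull_stat(v, "gamma_eff")
    p_gam <- if (v == "healthy") NA_real_
             else welch_p(gam, healthy_gamma, alternative = "less")
    kl <- if (v == "healthy") kl_base else pull_stat(v, "kl")
    p_kl <- if (v == "healthy") NA_real_
            else welch_p(kl, kl_base, alternative = "greater")
    tibble::tibble(
      variant = v,
      anhedonia = is.na(p_anh) || p_anh >= alpha_level,
      generalized_avoidance = av$flag,
      increased_discounting = !is.na(p_gam) && p_gam < alpha_level,
      more_exploration = !is.na(p_kl) && p_kl < alpha_level,
      v_turn_right = mean(vr), v_forward = mean(vf), p_anhedonia = p_anh,
      gamma_eff = mean(gam), p_discounting = p_gam,
      kl_from_healthy = mean(kl), p_exploration = p_kl
    )
  })
  class(rows) <- c("behavior_matrix", class(rows))
  rows
}

#' @export
print.behavior_matrix <- function(x, ...) {
  mark <- function(b) ifelse(b, "✔", " ")
  cat("Depression-like phenotypes by model variant\n")
  cat(sprintf("%-18s %-10s %-22s %-22s %-16s\n", "variant", "anhedonia",
              "generalized avoidance", "increased discounting", "more exploration"))
  for (i in seq_len(nrow(x))) {
    cat(sprintf("%-18s %-10s %-22s %-22s %-16s\n", x$variant[i],
                mark(x$anhedonia[i]), mark(x$generalized_avoidance[i]),
                mark(x$increased_discounting[i]), mark(x$more_exploration[i])))
  }
  invisible(x)
}
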