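# Orchestrated experiments: variant comparison with the probe battery,
# spine restoration, weight-decay sweep, simplified task, and the
# learning-curve metrics.

#' Student-t confidence interval of a mean
#'
#' @param x Numeric sample (n >= 2).
#' @param level Confidence level (default 0.95).
#' @return Tibble with `mean`, `lower`, `upper`, `half_width`.
#' @export
mean_ci <- function(x, level = 0.95) {
  n <- length(x)
  if (n < 2) stop("mean_ci() needs at least 2 samples")
  m <- mean(x)
  hw <- stats::qt(1 - (1 - level) / 2, df = n - 1) * stats::sd(x) / sqrt(n)
  tibble::tibble(mean = m, lower = m - hw, upper = m + hw, half_width = hw)
}

#' Learning-curve metrics from a cumulative reward series
#'
#' The reward rate (slope of cumulative reward vs episode) is computed for a
#' rolling window ending at each episode by least squares. The asymptotic
#' slope is the final window's slope; the time to asymptote is the first
#' episode whose window slope is within `tol` of the asymptotic slope and
#' stays within it for every later episode.
#'
#' @param cumulative Cumulative reward by episode (length >= 2 * window).
#' @param window Window length in episodes (default 200).
#' @param tol Relative tolerance for "at asymptote" (default 0.05).
#' @return Tibble with `asymptotic_slope`, `time_to_asymptote`,
#'   `final_window_mean_reward`.
#' @export
curve_metrics <- function(cumulative, window = 200, tol = 0.05) {
  n <- length(cumulative)
  if (n < 2 * window) stop("series shorter than twice the window")
  slopes <- rolling_slope(cumulative, window)
  s_inf <- slopes[n]
  ok <- abs(slopes - s_inf) <= tol * max(abs(s_inf), .Machine$double.eps)
  ok[seq_len(window - 1)] <- FALSE # windows not yet full
  bad <- which(!ok)
  t_asym <- if (length(bad)) min(max(bad) + 1L, n) else window
  tibble::tibble(
    asymptotic_slope = s_inf,
    time_to_asymptote = as.integer(t_asym),
    final_window_mean_reward = mean(diff(cumulative)[(n - window):(n - 1)])
  )
}

# OLS slope of y against 1..k over a rolling window, vectorized with
# cumulative sums; slopes[i] is for the window ending at i (NA-free: the
# first window-1 entries repeat the first full window's slope).
rolling_slope <- function(y, k) {
  n <- length(y)
  x <- seq_len(k)
  sx <- sum(x); sxx <- sum(x^2)
  den <- k * sxx - sx^2
  cy <- cumsum(y)
  cxy <- cumsum(seq_len(n) * y)
  slopes <- numeric(n)
  for (i in k:n) {
    sy <- cy[i] - if (i > k) cy[i - k] else 0
    # sum over window of (position within window) * y
    sxy <- (cxy[i] - if (i > k) cxy[i - k] else 0) - (i - k) * sy
    slopes[i] <- (k * sxy - sx * sy) / den
  }
  slopes[seq_len(k - 1)] <- slopes[k]
  slopes
}

train_variant <- function(variant, world, episodes, seed, base = learning_config(),
                          lambda_spine = 0.02) {
  cfg <- variant_config(variant, base = base, lambda_spine = lambda_spine)
  train_agent(world, cfg, episodes = episodes, seed = seed)
}

#' Compare the depression-model variants
#'
#' Trains `reps` independent agents per variant (seeds `seed + 0:(reps-1)`,
#' shared across variants so comparisons are paired), runs the full probe
#' battery on every trained network, and classifies each variant on the four
#' depression phenotypes ([behavior_matrix()]).
#'
#' @param variants Character vector of [variant_names()].
#' @param reps Repetitions per variant (>= 2 for significance tests).
#' @param episodes Training episodes per agent. The default (20000) brings
#'   every variant to its behavioral asymptote, including the reduced-RPE
#'   model whose effective learning rate is a tenth of the others'.
#' @param seed Base seed.
#' @param world A [world_config()].
#' @param window Final-window length for performance summaries.
#' @param n_states Random states for the exploration comparison.
#' @param lambda_spine Weight decay of the spine-loss variant.
#' @return A `comparison_result`: list with `runs` (per-rep summary tibble),
#'   `probes` (tidy per-rep statistics), `behavior` (the behavior matrix),
#'   `summary` (per-variant means with 95% CI), `nets`, and the plan fields.
#' @export
run_comparison <- function(variants = c("healthy", "spine_loss", "reduced_rpe",
                                        "dual_rate", "high_discount",
                                        "high_exploration"),
                           reps = 5, episodes = 20000, seed = 1,
                           world = world_config(), window = 200,
                           n_states = 100, lambda_spine = 0.02) {
  stopifnot(reps >= 1, "healthy" %in% variants)
  agents <- purrr::map(variants, function(v)
    purrr::map(seq_len(reps), function(i)
      train_variant(v, world, episodes, seed + i - 1, lambda_spine = lambda_spine)))
  names(agents) <- variants

  runs <- purrr::map_dfr(variants, function(v)
    purrr::map_dfr(seq_len(reps), function(i) {
      tr <- utils::tail(agents[[v]][[i]]$trace, window)
      tibble::tibble(variant = v, rep = i, seed = seed + i - 1,
                     final_reward = mean(tr$reward),
                     optional_per_episode = mean(tr$optional_collected),
                     goal_rate = mean(tr$reached_goal),
                     steps = mean(tr$steps))
    }))

  # shared random evaluation states for the KL comparison
  set.seed(seed * 7919 + 1)
  states <- sample_world_states(n_states, world)
  nets <- purrr::map(agents, function(as) purrr::map(as, "net"))

  probes <- purrr::map_dfr(variants, function(v)
    purrr::map_dfr(seq_len(reps), function(i) {
      net <- nets[[v]][[i]]
      jn <- observe(probe_scenario("anhedonia_junction", world), world)
      vj <- forward_pass(net, jn)
      fit <- infer_discount(net, world)
      av <- avoidance_probe(net, world)
      out <- tibble::tibble(
        variant = v, rep = i,
        statistic = c("v_turn_right", "v_forward", "gamma_eff",
                      paste0("avoid_v", 1:4), "optional_per_episode",
                      "final_reward"),
        value = c(vj[["turn_right"]], vj[["forward"]], fit$gamma_eff,
                  av$v_forward,
                  mean(utils::tail(agents[[v]][[i]]$trace, window)$optional_collected),
                  mean(utils::tail(agents[[v]][[i]]$trace, window)$reward)))
      if (v != "healthy") {
        kl <- exploration_divergence(net, nets[["healthy"]][[i]], states, world)
        out <- dplyr::bind_rows(out, tibble::tibble(
          variant = v, rep = i, statistic = "kl", value = kl))
      }
      out
    }))
  # healthy-vs-healthy baseline: divergence between different healthy agents
  if (reps >= 2) {
    base_kl <- purrr::map_dbl(seq_len(reps), function(i) {
      j <- if (i == reps) 1L else i + 1L
      exploration_divergence(nets[["healthy"]][[j]], nets[["healthy"]][[i]],
                             states, world)
    })
    probes <- dplyr::bind_rows(probes, tibble::tibble(
      variant = "healthy", rep = seq_len(reps),
      statistic = "kl_baseline", value = base_kl))
  }

  behavior <- if (reps >= 2) behavior_matrix(probes) else NULL
  summary <- runs %>%
    dplyr::group_by(.data$variant) %>%
    dplyr::summarise(dplyr::across(c("final_reward", "optional_per_episode",
                                     "goal_rate"),
                                   list(mean = mean,
                                        ci = function(x) if (length(x) > 1)
                                          mean_ci(x)$half_width else NA_real_)),
                     .groups = "drop")

  structure(list(runs = runs, probes = probes, behavior = behavior,
                 summary = summary, nets = nets,
                 plan = list(variants = variants, reps = reps,
                             episodes = episodes, seed = seed,
                             window = window, n_states = n_states,
                             lambda_spine = lambda_spine),
                 world = world),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> %d variant(s) x %d rep(s) x %d episodes\n",
              length(x$plan$variants), x$plan$reps, x$plan$episodes))
  print(x$summary)
  if (!is.null(x$behavior)) print(x$behavior)
  invisible(x)
}

#' Spine restoration experiment
#'
#' Trains each agent continuously through three phases — healthy
#' (`lambda = 0`), spine loss (`lambda = lambda_spine`), restored
#' (`lambda = 0`) — and summarises the reward rate per phase plus the
#' post-restoration dip and recovery time (episodes until the rolling
#' final-window reward regains the phase-1 level).
#'
#' @param reps Repetitions.
#' @param episodes_per_phase Episodes in each of the three phases.
#' @param seed Base seed.
#' @param world A [world_config()].
#' @param lambda_spine Weight decay applied in phase 2.
#' @param window Rolling window for reward-rate summaries.
#' @return A `restoration_result`: list with `trace` (per-episode, with
#'   `phase`), `phase_summary`, `recovery` (per-rep dip depth and recovery
#'   episode), and the plan.
#' @export
restoration_experiment <- function(reps = 5, episodes_per_phase = 1000,
                                   seed = 1, world = world_config(),
                                   lambda_spine = 0.02, window = 200) {
  lambdas <- c(0, lambda_spine, 0)
  traces <- purrr::map_dfr(seq_len(reps), function(i) {
    set.seed(seed + i - 1)
    net <- network_init()
    out <- list()
    for (ph in seq_along(lambdas)) {
      ag <- train_agent(world, learning_config(weight_decay = lambdas[ph]),
                        episodes = episodes_per_phase, net = net)
      net <- ag$net
      out[[ph]] <- dplyr::mutate(ag$trace, phase = ph,
                                 episode = .data$episode + (ph - 1) * episodes_per_phase)
    }
    dplyr::bind_rows(out) %>% dplyr::mutate(rep = i)
  })
  phase_summary <- traces %>%
    dplyr::group_by(.data$rep, .data$phase) %>%
    dplyr::summarise(final_window_reward = mean(utils::tail(.data$reward, window)),
                     .groups = "drop")
  recovery <- purrr::map_dfr(seq_len(reps), function(i) {
    tr <- traces[traces$rep == i, ]
    p1 <- mean(utils::tail(tr$reward[tr$phase == 1], window))
    r3 <- tr$reward[tr$phase == 3]
    roll <- stats::filter(r3, rep(1 / window, window), sides = 1)
    roll <- roll[!is.na(roll)]
    rec <- which(roll >= p1)
    tibble::tibble(rep = i, phase1_level = p1,
                   dip_depth = p1 - min(roll),
                   recovery_episode = if (length(rec)) window + rec[1] - 1L else NA_integer_)
  })
  structure(list(trace = traces, phase_summary = phase_summary,
                 recovery = recovery,
                 plan = list(reps = reps, episodes_per_phase = episodes_per_phase,
                             seed = seed, lambda_spine = lambda_spine,
                             window = window)),
            class = "restoration_result")
}

#' Weight-decay sweep
#'
#' Trains agents over a grid of weight-decay settings (same seeds per
#' setting) and reports the final-window mean reward per setting with its
#' 95% CI. The grid spans mild decay (normal synaptic turnover, often
#' beneficial) to extreme decay (pathological spine loss).
#'
#' @param lambdas Weight-decay grid (must include 0).
#' @param reps,episodes,seed,world,window As in [run_comparison()].
#' @return A `decay_sweep` tibble: `lambda`, `rep`, `final_reward`,
#'   `optional_per_episode`, with the per-lambda summary in
#'   `attr(, "summary")`.
#' @export
decay_sweep <- function(lambdas = c(0, 0.001, 0.005, 0.02, 0.1),
                        reps = 5, episodes = 6000, seed = 1,
                        world = world_config(), window = 200) {
  stopifnot(length(lambdas) >= 3, 0 %in% lambdas)
  res <- purrr::map_dfr(lambdas, function(lam)
    purrr::map_dfr(seq_len(reps), function(i) {
      ag <- train_agent(world, learning_config(weight_decay = lam),
                        episodes = episodes, seed = seed + i - 1)
      tr <- utils::tail(ag$trace, window)
      tibble::tibble(lambda = lam, rep = i,
                     final_reward = mean(tr$reward),
                     optional_per_episode = mean(tr$optional_collected),
                     goal_rate = mean(tr$reached_goal))
    }))
  summ <- res %>%
    dplyr::group_by(.data$lambda) %>%
    dplyr::summarise(mean_reward = mean(.data$final_reward),
                     ci = if (dplyr::n() > 1) mean_ci(.data$final_reward)$half_width
                          else NA_real_,
                     .groups = "drop")
  attr(res, "summary") <- summ
  class(res) <- c("decay_sweep", class(res))
  res
}

#' Simplified-task experiment
#'
#' Removes the optional goals and hazards, leaving only the required goal,
#' and compares healthy and spine-loss agents. In this simpler task the
#' spine-loss impairment vanishes.
#'
#' @param reps,episodes,seed,window,lambda_spine As in [run_comparison()].
#' @param world Base world; optional goals and hazards are switched off.
#' @return List with `runs` (per-rep tibble), `difference` (spine minus
#'   healthy final reward, with CI), and the plan.
#' @export
simplified_task_experiment <- function(reps = 5, episodes = 20000, seed = 1,
                                       world = world_config(), window = 200,
                                       lambda_spine = 0.02) {
  world$include_optional <- FALSE
  world$include_hazards <- FALSE
  runs <- purrr::map_dfr(c("healthy", "spine_loss"), function(v)
    purrr::map_dfr(seq_len(reps), function(i) {
      ag <- train_variant(v, world, episodes, seed + i - 1,
                          lambda_spine = lambda_spine)
      tr <- utils::tail(ag$trace, window)
      tibble::tibble(variant = v, rep = i,
                     final_reward = mean(tr$reward),
                     goal_rate = mean(tr$reached_goal),
                     optional_per_episode = mean(tr$optional_collected))
    }))
  dd <- runs$final_reward[runs$variant == "spine_loss"] -
        runs$final_reward[runs$variant == "healthy"]
  difference <- if (reps > 1) dplyr::mutate(mean_ci(dd), n = reps)
                else tibble::tibble(mean = mean(dd), lower = NA, upper = NA,
                                    half_width = NA, n = reps)
  structure(list(runs = runs, difference = difference,
                 plan = list(reps = reps, episodes = episodes, seed = seed,
                             window = window, lambda_spine = lambda_spine)),
            class = "simplified_result")
}
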