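# broom-style tidiers and ggplot2 autoplot methods for the result objects.

#' @export
tidy.td_agent <- function(x, ...) x$trace

#' @export
glance.td_agent <- function(x, ...) {
  last <- utils::tail(x$trace, min(200L, nrow(x$trace)))
  cm <- if (nrow(x$trace) >= 400)
    curve_metrics(cumsum(x$trace$reward), window = min(200L, nrow(x$trace) %/% 2))
  else NULL
  tibble::tibble(
    episodes = x$episodes,
    weight_decay = x$config$weight_decay,
    policy = x$config$policy,
    final_reward = mean(last$reward),
    optional_per_episode = mean(last$optional_collected),
    goal_rate = mean(last$reached_goal),
    asymptotic_slope = if (is.null(cm)) NA_real_ else cm$asymptotic_slope,
    time_to_asymptote = if (is.null(cm)) NA_integer_ else cm$time_to_asymptote
  )
}

#' @export
tidy.discount_fit <- function(x, ...) {
  tibble::tibble(
    term = c("log_value_intercept", "log_gamma_eff"),
    estimate = c(x$log_value_intercept, log(x$gamma_eff))
  )
}

#' @export
glance.discount_fit <- function(x, ...) {
  tibble::tibble(gamma_eff = x$gamma_eff, r_squared = x$r_squared,
                 n_distances = nrow(x$data))
}

#' Learning-curve plot for a trained agent
#'
#' Rolling-mean episode reward (and optional goals collected) by episode.
#'
#' @param object A `td_agent`.
#' @param window Rolling-mean window (episodes).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.td_agent <- function(object, window = 100, ...) {
  tr <- object$trace
  window <- max(1L, min(as.integer(window), nrow(tr)))
  roll <- function(x) as.numeric(stats::filter(x, rep(1 / window, window), sides = 1))
  df <- tibble::tibble(
    episode = rep(tr$episode, 2),
    value = c(roll(tr$reward), roll(tr$optional_collected)),
    measure = rep(c("reward / episode", "optional goals / episode"),
                  each = nrow(tr))
  )
  ggplot2::ggplot(df[!is.na(df$value), ],
                  ggplot2::aes(x = .data$episode, y = .data$value)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::facet_wrap(~measure, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "episode", y = NULL,
                  title = sprintf("TD agent, lambda = %g (rolling mean, window %d)",
                                  object$config$weight_decay, window)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.behavior_matrix <- function(object, ...) {
  df <- tidyr::pivot_longer(
    object[, c("variant", "anhedonia", "generalized_avoidance",
               "increased_discounting", "more_exploration")],
    -"variant", names_to = "phenotype", values_to = "present")
  df$variant <- factor(df$variant, levels = rev(unique(object$variant)))
  df$phenotype <- factor(df$phenotype, levels = c(
    "anhedonia", "generalized_avoidance", "increased_discounting",
    "more_exploration"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$phenotype, y = .data$variant,
                                   fill = .data$present)) +
    ggplot2::geom_tile(color = "grey40") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "firebrick",
                                          `FALSE` = "grey92"),
                               name = "phenotype\npresent") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Depression-like phenotypes by model variant") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' @export
autoplot.decay_sweep <- function(object, ...) {
  summ <- attr(object, "summary")
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$lambda, y = .data$mean_reward)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_reward - .data$ci,
                                      ymax = .data$mean_reward + .data$ci),
                         fill = "steelblue", alpha = 0.25) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::geom_point(color = "steelblue") +
    ggplot2::scale_x_sqrt() +
    ggplot2::labs(x = "weight decay (lambda)",
                  y = "final-window mean reward / episode",
                  title = "Performance across the weight-decay sweep") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.restoration_result <- function(object, window = 100, ...) {
  roll <- function(x) as.numeric(stats::filter(x, rep(1 / window, window), sides = 1))
  df <- object$trace %>%
    dplyr::group_by(.data$rep) %>%
    dplyr::arrange(.data$episode, .by_group = TRUE) %>%
    dplyr::mutate(roll_reward = roll(.data$reward)) %>%
    dplyr::ungroup() %>%
    dplyr::group_by(.data$episode, .data$phase) %>%
    dplyr::summarise(reward = mean(.data$roll_reward), .groups = "drop")
  n_phase <- object$plan$episodes_per_phase
  ggplot2::ggplot(df[!is.na(df$reward), ],
                  ggplot2::aes(x = .data$episode, y = .data$reward)) +
    ggplot2::geom_vline(xintercept = c(n_phase, 2 * n_phase),
                        linetype = "dashed", color = "grey50") +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::annotate("text", x = c(0.5, 1.5, 2.5) * n_phase, y = max(df$reward, na.rm = TRUE),
                      label = c("healthy", "spine loss", "restored"), vjust = -0.3) +
    ggplot2::labs(x = "episode", y = "reward / episode (rolling mean)",
                  title = "Spine loss and restoration") +
    ggplot2::theme_minimal()
}
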