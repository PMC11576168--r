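# Learning hyperparameters and the alternative depression-model variants.

#' Learning hyperparameters
#'
#' Houses every knob of the TD learner. Defaults are the "healthy" agent:
#' one-step semi-gradient TD with epsilon-greedy action selection and no
#' weight decay.
#'
#' @param alpha Learning rate (> 0).
#' @param gamma Explicit discount factor in `[0, 1]`.
#' @param weight_decay Weight-decay coefficient lambda (>= 0); each update
#'   shrinks every connection weight by `alpha * weight_decay * w`. Nonzero
#'   values simulate dendritic spine loss.
#' @param epsilon Exploration rate of the epsilon-greedy policy.
#' @param tau Softmax temperature (> 0; used when `policy = "softmax"`).
#' @param policy `"egreedy"` or `"softmax"`.
#' @param rpe_scale Multiplier applied to the reward-prediction error delta
#'   after it is computed (0.1 simulates reduced dopamine signaling).
#' @param negative_reward_scale,positive_reward_scale Multipliers applied to
#'   negative / positive rewards before the TD target is formed (2 and 0.5
#'   give the faster-learning-from-negative-experience variant).
#' @param deletion_fraction Fraction of connections removed by the
#'   random-deletion variant (see [random_deletion()]).
#' @return A `learning_config` object.
#' @export
learning_config <- function(alpha = 0.01, gamma = 0.9, weight_decay = 0,
                            epsilon = 0.1, tau = 1,
                            policy = c("egreedy", "softmax"),
                            rpe_scale = 1,
                            negative_reward_scale = 1,
                            positive_reward_scale = 1,
                            deletion_fraction = 0) {
  cfg <- list(alpha = alpha, gamma = gamma, weight_decay = weight_decay,
              epsilon = epsilon, tau = tau, policy = match.arg(policy),
              rpe_scale = rpe_scale,
              negative_reward_scale = negative_reward_scale,
              positive_reward_scale = positive_reward_scale,
              deletion_fraction = deletion_fraction)
  stopifnot(cfg$alpha >= 0, cfg$gamma >= 0, cfg$gamma <= 1,
            cfg$weight_decay >= 0, cfg$epsilon >= 0, cfg$epsilon <= 1,
            cfg$tau > 0, cfg$rpe_scale >= 0,
            cfg$deletion_fraction >= 0, cfg$deletion_fraction <= 1)
  class(cfg) <- "learning_config"
  cfg
}

#' @export
print.learning_config <- function(x, ...) {
  cat(sprintf(paste0("<learning_config> alpha=%g gamma=%g lambda=%g policy=%s",
                     " (epsilon=%g, tau=%g) rpe_scale=%g reward scales -:%g +:%g",
                     " deletion=%g\n"),
              x$alpha, x$gamma, x$weight_decay, x$policy, x$epsilon, x$tau,
              x$rpe_scale, x$negative_reward_scale, x$positive_reward_scale,
              x$deletion_fraction))
  invisible(x)
}

#' The depression-model variants
#'
#' Seven named configurations. Each variant differs from `healthy` by exactly
#' one mechanism:
#'
#' * `healthy` — no weight decay (`lambda = 0`).
#' * `spine_loss` — weight decay `lambda = lambda_spine` on all connection
#'   weights (the simulated-spine-loss depression model).
#' * `reduced_rpe` — reward-prediction error multiplied by 0.1, simulating
#'   reduced dopamine signaling.
#' * `dual_rate` — negative rewards multiplied by 2 and positive rewards
#'   divided by 2 before updates (faster learning from negative experience).
#' * `high_discount` — explicit discount factor `gamma = 0.5` instead of 0.9.
#' * `high_exploration` — softmax action selection with temperature `tau = 1`
#'   instead of epsilon-greedy.
#' * `random_deletion` — a random fraction of connections deleted outright
#'   (an alternative spine-loss implementation; see [random_deletion()]).
#'
#' @param name Variant name (see above).
#' @param base Base configuration the override is applied to.
#' @param lambda_spine Weight-decay setting of the spine-loss model.
#' @return A [learning_config()].
#' @examples
#' variant_config("spine_loss")$weight_decay
#' @export
variant_config <- function(name, base = learning_config(), lambda_spine = 0.02) {
  name <- match.arg(name, variant_names())
  cfg <- base
  cfg$weight_decay <- 0
  cfg$deletion_fraction <- 0
  switch(name,
    healthy = NULL,
    spine_loss = { cfg$weight_decay <- lambda_spine },
    reduced_rpe = { cfg$rpe_scale <- 0.1 },
    dual_rate = {
      cfg$negative_reward_scale <- 2
      cfg$positive_reward_scale <- 0.5
    },
    high_discount = { cfg$gamma <- 0.5 },
    high_exploration = {
      cfg$policy <- "softmax"
      cfg$tau <- 1
    },
    random_deletion = { cfg$deletion_fraction <- 0.5 }
  )
  attr(cfg, "variant") <- name
  cfg
}

#' @rdname variant_config
#' @export
variant_names <- function() {
  c("healthy", "spine_loss", "reduced_rpe", "dual_rate",
    "high_discount", "high_exploration", "random_deletion")
}

#' Asymmetric reward scaling
#'
#' Multiplies negative rewards by `negative_reward_scale` and positive
#' rewards by `positive_reward_scale` before they enter the TD target.
#'
#' @param r Reward (finite scalar or vector).
#' @param config A [learning_config()].
#' @export
scale_reward <- function(r, config) {
  ifelse(r < 0, r * config$negative_reward_scale,
         ifelse(r > 0, r * config$positive_reward_scale, 0))
}

#' Softmax action-selection probabilities
#'
#' `P(a|s) = exp(V(s,a)/tau) / sum_b exp(V(s,b)/tau)`, computed with
#' max-subtraction for overflow safety.
#'
#' @param values Action-value vector.
#' @param tau Temperature (> 0). Higher temperatures approach the uniform
#'   distribution; lower temperatures concentrate on the argmax.
#' @return Probability vector summing to 1.
#' @export
softmax_policy <- function(values, tau = 1) {
  if (tau <= 0) stop("softmax temperature tau must be > 0")
  z <- values / tau
  e <- exp(z - max(z))
  e / sum(e)
}

#' Randomly delete network connections
#'
#' Sets an exact-count uniformly random subset of each weight matrix to zero
#' and installs permanent masks so learning never revives the deleted
#' connections. Biases are untouched. Uses R's global RNG.
#'
#' @param net A `network_params`.
#' @param fraction Fraction of connections to delete in each weight matrix
#'   (`round(fraction * length(w))` entries, exactly).
#' @return The masked `network_params`.
#' @export
random_deletion <- function(net, fraction) {
  stopifnot(fraction >= 0, fraction <= 1)
  if (fraction == 0) return(net)
  del_mask <- function(n) {
    k <- round(fraction * n)
    m <- rep(1, n)
    m[sample.int(n, k)] <- 0
    m
  }
  m_in <- matrix(del_mask(length(net$w_in)), nrow(net$w_in), ncol(net$w_in))
  m_out <- matrix(del_mask(length(net$w_out)), nrow(net$w_out), ncol(net$w_out))
  net$mask_in <- if (is.null(net$mask_in)) m_in else net$mask_in * m_in
  net$mask_out <- if (is.null(net$mask_out)) m_out else net$mask_out * m_out
  net$w_in <- net$w_in * net$mask_in
  net$w_out <- net$w_out * net$mask_out
  net
}
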