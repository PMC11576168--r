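# The value network: 100 binary inputs -> 10 tanh hidden units -> 3 linear
# outputs (action values for turn left / turn right / forward).

#' Initialize value-network parameters
#'
#' Weights and biases are drawn uniformly from `[-scale, scale]` using R's
#' global RNG (draw order: input weights, hidden biases, output weights,
#' output biases, each column-major), so an initial network is fully
#' determined by the seed in effect.
#'
#' @param n_input,n_hidden,n_output Layer sizes (fixed at 100/10/3 by the
#'   observation encoding and action set; changeable for toy fixtures).
#' @param scale Half-width of the uniform initialization.
#' @return A `network_params` object: list with `w_in` (input x hidden
#'   connection weights), `b_hidden`, `w_out` (hidden x output), `b_out`, and
#'   optional deletion masks `mask_in`, `mask_out` (see [random_deletion()]).
#' @export
network_init <- function(n_input = 100, n_hidden = 10, n_output = 3, scale = 0.1) {
  net <- list(
    w_in = matrix(stats::runif(n_input * n_hidden, -scale, scale), n_input, n_hidden),
    b_hidden = stats::runif(n_hidden, -scale, scale),
    w_out = matrix(stats::runif(n_hidden * n_output, -scale, scale), n_hidden, n_output),
    b_out = stats::runif(n_output, -scale, scale),
    mask_in = NULL,
    mask_out = NULL
  )
  class(net) <- "network_params"
  net
}

#' Build a network from given parameter arrays
#'
#' @param w_in,b_hidden,w_out,b_out Parameter arrays with consistent shapes.
#' @param mask_in,mask_out Optional binary deletion masks.
#' @export
network_params <- function(w_in, b_hidden, w_out, b_out,
                           mask_in = NULL, mask_out = NULL) {
  net <- list(w_in = as.matrix(w_in), b_hidden = as.numeric(b_hidden),
              w_out = as.matrix(w_out), b_out = as.numeric(b_out),
              mask_in = mask_in, mask_out = mask_out)
  stopifnot(ncol(net$w_in) == length(net$b_hidden),
            nrow(net$w_out) == length(net$b_hidden),
            ncol(net$w_out) == length(net$b_out),
            all(is.finite(net$w_in)), all(is.finite(net$w_out)),
            all(is.finite(net$b_hidden)), all(is.finite(net$b_out)))
  class(net) <- "network_params"
  net
}

#' @export
print.network_params <- function(x, ...) {
  cat(sprintf("<network_params> %d -> %d (tanh) -> %d (linear); %d weights, %d biases%s\n",
              nrow(x$w_in), length(x$b_hidden), length(x$b_out),
              length(x$w_in) + length(x$w_out),
              length(x$b_hidden) + length(x$b_out),
              if (!is.null(x$mask_in)) sprintf("; %d connections deleted",
                sum(x$mask_in == 0) + sum(x$mask_out == 0)) else ""))
  invisible(x)
}

hidden_activation <- function(net, obs) {
  tanh(net$b_hidden + drop(crossprod(net$w_in, obs)))
}

#' Network forward pass
#'
#' Computes the three action values
#' `V(s, ) = b_out + t(w_out) %*% tanh(b_hidden + t(w_in) %*% obs)`.
#'
#' @param net A `network_params` object.
#' @param obs Binary observation vector (length matching `nrow(net$w_in)`).
#' @return Named numeric vector of length 3
#'   (`turn_left`, `turn_right`, `forward`).
#' @export
forward_pass <- function(net, obs) {
  if (length(obs) != nrow(net$w_in))
    stop(sprintf("observation length %d does not match network input size %d",
                 length(obs), nrow(net$w_in)))
  v <- net$b_out + drop(crossprod(net$w_out, hidden_activation(net, obs)))
  if (length(v) == length(ACTIONS)) names(v) <- ACTIONS
  v
}

#' Semi-gradient of the squared TD error
#'
#' Returns the gradient of `delta^2` with respect to every weight and bias,
#' treating the TD target as a constant (semi-gradient), i.e.
#' `d(delta^2)/d(theta) = -2 * delta * dV(s,a)/d(theta)`.
#'
#' @param net A `network_params` object.
#' @param obs Observation at which `delta` was computed.
#' @param action Action taken (name or index).
#' @param delta The TD error computed from `(net, obs, action)`.
#' @return List with components `w_in`, `b_hidden`, `w_out`, `b_out` shaped
#'   like the corresponding parameters.
#' @export
td_gradients <- function(net, obs, action, delta) {
  a <- action_index(action)
  h <- hidden_activation(net, obs)
  g_out <- matrix(0, nrow(net$w_out), ncol(net$w_out))
  g_bout <- numeric(length(net$b_out))
  g_bout[a] <- -2 * delta
  g_out[, a] <- -2 * delta * h
  dz <- (-2 * delta * net$w_out[, a]) * (1 - h^2)
  g_in <- obs %o% dz
  list(w_in = g_in, b_hidden = dz, w_out = g_out, b_out = g_bout)
}

#' Gradient-plus-decay parameter update
#'
#' Applies `w <- w * (1 - alpha*lambda) - alpha * grad` to every connection
#' weight and `b <- b - alpha * grad` to every bias: weight decay shrinks
#' connection strengths toward zero in proportion to their magnitude (the
#' simulated spine loss) but never touches biases. Deleted connections
#' (zeroed by [random_deletion()]) stay at zero.
#'
#' @param net A `network_params` object.
#' @param grads Gradient list as returned by [td_gradients()].
#' @param config A [learning_config()]; uses `alpha` and `weight_decay`.
#' @return The updated `network_params`.
#' @export
apply_update <- function(net, grads, config) {
  al <- config$alpha * config$weight_decay
  net$w_in <- net$w_in * (1 - al) - config$alpha * grads$w_in
  net$w_out <- net$w_out * (1 - al) - config$alpha * grads$w_out
  net$b_hidden <- net$b_hidden - config$alpha * grads$b_hidden
  net$b_out <- net$b_out - config$alpha * grads$b_out
  if (!is.null(net$mask_in)) net$w_in <- net$w_in * net$mask_in
  if (!is.null(net$mask_out)) net$w_out <- net$w_out * net$mask_out
  if (!all(is.finite(net$w_in)) || !all(is.finite(net$w_out)) ||
      !all(is.finite(net$b_hidden)) || !all(is.finite(net$b_out)))
    stop("non-finite parameter after update (learning rate too large?)")
  net
}

action_index <- function(action) {
  if (is.character(action)) match(match.arg(action, ACTIONS), ACTIONS)
  else as.integer(action)
}

#' Serialize network parameters to JSON
#'
#' Writes a versioned JSON container of nested arrays; exact round trip of
#' doubles is preserved via full-precision encoding.
#'
#' @param net A `network_params`.
#' @param path File path.
#' @export
write_network <- function(net, path) {
  payload <- list(
    format = "spinesim-network", version = 1L,
    w_in = net$w_in, b_hidden = net$b_hidden,
    w_out = net$w_out, b_out = net$b_out,
    mask_in = net$mask_in, mask_out = net$mask_out
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "spinesim-network"))
    stop("not a spinesim network file")
  network_params(p$w_in, p$b_hidden, p$w_out, p$b_out,
                 mask_in = p$mask_in, mask_out = p$mask_out)
}
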