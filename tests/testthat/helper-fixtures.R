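# Shared fixtures: small worlds and hand-built networks.

# 1 x 6 corridor: agent starts at the west end facing the goal at the east end.
corridor_world <- function(length = 6) {
  world_config(width = length, height = 1, n_optional_goals = 0,
               required_goal_pos = c(length, 1), hazard_positions = list(),
               include_optional = FALSE, include_hazards = FALSE,
               start_pos = c(1, 1), start_heading = "E")
}

# default room without randomness in object placement
bare_room <- function() {
  world_config(include_optional = FALSE, include_hazards = FALSE)
}

# all-zero network of standard shape
zero_net <- function(n_input = 100, n_hidden = 10, n_output = 3) {
  network_params(matrix(0, n_input, n_hidden), numeric(n_hidden),
                 matrix(0, n_hidden, n_output), numeric(n_output))
}

# network with constant action values (b_out only)
const_net <- function(values) {
  net <- zero_net()
  net$b_out <- as.numeric(values)
  net
}

random_net <- function(scale = 0.5, n_input = 100, n_hidden = 10, n_output = 3) {
  network_params(
    matrix(stats::runif(n_input * n_hidden, -scale, scale), n_input, n_hidden),
    stats::runif(n_hidden, -scale, scale),
    matrix(stats::runif(n_hidden * n_output, -scale, scale), n_hidden, n_output),
    stats::runif(n_output, -scale, scale)
  )
}

# independent central finite differences of the semi-gradient objective
# (target held constant) for every parameter of `net`
fd_gradients <- function(net, obs, action, delta, h = 1e-5) {
  a <- spinesim:::action_index(action)
  target <- delta + forward_pass(net, obs)[[a]]
  obj <- function(n) (target - forward_pass(n, obs)[[a]])^2
  g <- list()
  for (field in c("w_in", "b_hidden", "w_out", "b_out")) {
    par <- net[[field]]
    gp <- par
    for (i in seq_along(par)) {
      np <- net; np[[field]][i] <- par[i] + h
      nm <- net; nm[[field]][i] <- par[i] - h
      gp[i] <- (obj(np) - obj(nm)) / (2 * h)
    }
    g[[field]] <- gp
  }
  g
}

# brute-force minimal action count to the goal by breadth-first search over
# action sequences using only the public step function
bfs_distance_oracle <- function(state, config, max_depth = 30) {
  key <- function(s) paste(s$agent_pos[1], s$agent_pos[2], s$heading)
  if (all(state$agent_pos == state$required_goal_pos)) return(0L)
  frontier <- list(state)
  seen <- key(state)
  for (depth in seq_len(max_depth)) {
    nxt <- list()
    for (s in frontier) {
      for (a in c("turn_left", "turn_right", "forward")) {
        st <- world_step(s, a, config)
        if (st$done && all(st$state$agent_pos == st$state$required_goal_pos))
          return(depth)
        k <- key(st$state)
        if (!k %in% seen && !st$state$done) {
          seen <- c(seen, k)
          s2 <- st$state
          s2$step_count <- 0L # keep searching beyond the step cap
          nxt[[length(nxt) + 1L]] <- s2
        }
      }
    }
    frontier <- nxt
    if (!length(frontier)) break
  }
  stop("goal not reached within max_depth")
}

# bit index (1-based) for window cell at forward offset f (0..4), lateral
# offset l (-2..2, positive right) and channel ch (1 wall, 2 optional,
# 3 required, 4 hazard) -- independent restatement of the documented layout
bit_index <- function(f, l, ch) {
  cell <- (5 - f - 1) * 5 + (l + 3)
  (cell - 1) * 4 + ch
}
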