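# Simulated room: geometry, transitions, rewards, and the egocentric
# binary observation fed to the value network.

# Headings are 1=N, 2=E, 3=S, 4=W; turn_right rotates clockwise.
HEADINGS <- c("N", "E", "S", "W")
ACTIONS <- c("turn_left", "turn_right", "forward")
# forward displacement per heading, (col, row); row 1 is the north edge
.FDC <- c(0L, 1L, 0L, -1L)
.FDR <- c(-1L, 0L, 1L, 0L)

#' Configure the simulated room
#'
#' The world is a rectangular room of `width` x `height` cells surrounded by
#' walls. It contains several "optional" goals that are placed uniformly at
#' random on free cells at the start of each episode and pay a small reward
#' when collected, one "required" goal at a fixed position that pays a large
#' reward and ends the episode, and hazards at fixed positions that punish the
#' agent (negative reward) each time they are stepped on but do not end the
#' episode. The agent starts every episode at the same pose and chooses among
#' three actions: turn left, turn right, move forward.
#'
#' Coordinates are 1-based `(col, row)` with row 1 at the north edge; cells
#' outside `1..width` x `1..height` are walls.
#'
#' @param width,height Room size in cells (default 9 x 9).
#' @param n_optional_goals Number of optional goals re-placed each episode.
#' @param required_goal_pos `(col, row)` of the fixed required goal.
#' @param hazard_positions List of `(col, row)` hazard cells.
#' @param reward_optional,reward_required,reward_hazard Reward magnitudes;
#'   must satisfy `0 < reward_optional < reward_required` and
#'   `reward_hazard < 0`.
#' @param max_steps_per_episode Step cap guaranteeing termination.
#' @param include_optional,include_hazards Switch optional goals / hazards off
#'   to obtain the simplified task.
#' @param start_pos,start_heading Fixed agent start pose.
#' @return A `world_config` object (a validated list).
#' @examples
#' w <- world_config()
#' ep <- world_reset(w)
#' length(ep$observation) # 100
#' @export
world_config <- function(width = 9, height = 9,
                         n_optional_goals = 3,
                         required_goal_pos = c(9, 9),
                         hazard_positions = list(c(2, 1)),
                         reward_optional = 1,
                         reward_required = 10,
                         reward_hazard = -5,
                         max_steps_per_episode = 500,
                         include_optional = TRUE,
                         include_hazards = TRUE,
                         start_pos = c(1, 1),
                         start_heading = "E") {
  cfg <- list(
    width = as.integer(width), height = as.integer(height),
    n_optional_goals = as.integer(n_optional_goals),
    required_goal_pos = as.integer(required_goal_pos),
    hazard_positions = lapply(hazard_positions, as.integer),
    reward_optional = as.numeric(reward_optional),
    reward_required = as.numeric(reward_required),
    reward_hazard = as.numeric(reward_hazard),
    max_steps_per_episode = as.integer(max_steps_per_episode),
    include_optional = isTRUE(include_optional),
    include_hazards = isTRUE(include_hazards),
    start_pos = as.integer(start_pos),
    start_heading = match.arg(start_heading, HEADINGS)
  )
  class(cfg) <- "world_config"
  validate_world_config(cfg)
  cfg
}

validate_world_config <- function(cfg) {
  stopifnot(cfg$width >= 1, cfg$height >= 1,
            cfg$n_optional_goals >= 0,
            cfg$reward_optional > 0,
            cfg$reward_required > cfg$reward_optional,
            cfg$reward_hazard < 0,
            cfg$max_steps_per_episode >= 1)
  inb <- function(p) all(p >= 1L) && p[1] <= cfg$width && p[2] <= cfg$height
  if (!inb(cfg$required_goal_pos)) stop("required goal outside the room")
  if (!inb(cfg$start_pos)) stop("start position outside the room")
  haz <- if (cfg$include_hazards) cfg$hazard_positions else list()
  occ <- c(list(cfg$required_goal_pos), haz)
  keys <- vapply(occ, function(p) paste(p, collapse = ","), character(1))
  if (anyDuplicated(keys)) stop("required goal and hazards must occupy distinct cells")
  if (cfg$include_hazards && !all(vapply(cfg$hazard_positions, inb, logical(1))))
    stop("hazard outside the room")
  n_free <- cfg$width * cfg$height - length(occ) - 1L # minus the start cell
  if (cfg$include_optional && cfg$n_optional_goals > n_free)
    stop("room too small to place all optional goals on distinct free cells")
  invisible(cfg)
}

#' @export
print.world_config <- function(x, ...) {
  cat(sprintf("<world_config> %dx%d room, %d optional goal(s)%s, %d hazard(s)%s\n",
              x$width, x$height, x$n_optional_goals,
              if (x$include_optional) "" else " (off)",
              length(x$hazard_positions),
              if (x$include_hazards) "" else " (off)"))
  cat(sprintf("  start (%d,%d) facing %s; required goal (%d,%d); rewards %+g/%+g/%+g; step cap %d\n",
              x$start_pos[1], x$start_pos[2], x$start_heading,
              x$required_goal_pos[1], x$required_goal_pos[2],
              x$reward_optional, x$reward_required, x$reward_hazard,
              x$max_steps_per_episode))
  invisible(x)
}

# Free cells available for optional-goal placement, in fixed row-major order
# (row 1..height outer, col 1..width inner). Excludes the required goal,
# active hazards, and the agent start cell. Returned as linear ids
# (row-1)*width + col.
free_cells <- function(cfg) {
  W <- cfg$width
  occ <- c(list(cfg$required_goal_pos, cfg$start_pos),
           if (cfg$include_hazards) cfg$hazard_positions else list())
  occ_id <- vapply(occ, function(p) (p[2] - 1L) * W + p[1], integer(1))
  ids <- integer(0)
  for (r in seq_len(cfg$height)) ids <- c(ids, (r - 1L) * W + seq_len(W))
  setdiff(ids, occ_id)
}

# Partial Fisher-Yates draw of n items from x using floor(runif()*k) indexing;
# mirrored verbatim by the C++ engine so both consume identical RNG draws.
sample_cells <- function(x, n) {
  m <- length(x)
  if (n > m) stop("room too small to place all optional goals")
  if (n == 0L) return(integer(0))
  for (k in seq_len(n)) {
    j <- k + floor(stats::runif(1) * (m - k + 1))
    j <- min(as.integer(j), m) # guard the measure-zero runif()==1 edge
    tmp <- x[k]; x[k] <- x[j]; x[j] <- tmp
  }
  x[seq_len(n)]
}

id_to_pos <- function(id, width) cbind((id - 1L) %% width + 1L, (id - 1L) %/% width + 1L)

#' Start a new episode
#'
#' Places the agent at its fixed start pose and (when enabled) scatters the
#' optional goals uniformly at random over free cells. Uses R's global RNG;
#' call [set.seed()] for reproducibility.
#'
#' @param config A [world_config()].
#' @return List with elements `state` (a `world_state`) and `observation`
#'   (binary vector of length 100).
#' @export
world_reset <- function(config) {
  n <- if (config$include_optional) config$n_optional_goals else 0L
  ids <- sample_cells(free_cells(config), n)
  state <- structure(list(
    agent_pos = config$start_pos,
    heading = config$start_heading,
    optional_goal_positions = id_to_pos(ids, config$width),
    hazard_positions = if (config$include_hazards)
      do.call(rbind, config$hazard_positions) else matrix(integer(0), 0, 2),
    required_goal_pos = config$required_goal_pos,
    step_count = 0L,
    done = FALSE
  ), class = "world_state")
  list(state = state, observation = observe(state, config))
}

#' Advance the world by one action
#'
#' Turning rotates the heading 90 degrees without moving; `forward` moves one
#' cell unless a wall blocks it. Entering an optional-goal cell collects it
#' (reward `reward_optional`, goal removed); entering the required-goal cell
#' pays `reward_required` and ends the episode; entering a hazard cell pays
#' `reward_hazard` (the hazard persists and the episode continues). Reaching
#' the step cap ends the episode with no terminal reward.
#'
#' @param state A `world_state` (not done).
#' @param action One of `"turn_left"`, `"turn_right"`, `"forward"`.
#' @param config The [world_config()].
#' @return List with `state`, `observation`, `reward`, `done`, and `event`
#'   (one of `"none"`, `"optional"`, `"required"`, `"hazard"`).
#' @export
world_step <- function(state, action, config) {
  if (isTRUE(state$done)) stop("world_step() called on a finished episode")
  a <- match.arg(action, ACTIONS)
  h <- match(state$heading, HEADINGS)
  reward <- 0
  event <- "none"
  if (a == "turn_left") {
    h <- if (h == 1L) 4L else h - 1L
  } else if (a == "turn_right") {
    h <- if (h == 4L) 1L else h + 1L
  } else {
    nc <- state$agent_pos[1] + .FDC[h]
    nr <- state$agent_pos[2] + .FDR[h]
    if (nc >= 1L && nc <= config$width && nr >= 1L && nr <= config$height) {
      state$agent_pos <- c(nc, nr)
      opt <- state$optional_goal_positions
      if (nrow(opt) > 0) {
        hit <- which(opt[, 1] == nc & opt[, 2] == nr)
        if (length(hit)) {
          reward <- reward + config$reward_optional
          state$optional_goal_positions <- opt[-hit, , drop = FALSE]
          event <- "optional"
        }
      }
      haz <- state$hazard_positions
      if (nrow(haz) > 0 && any(haz[, 1] == nc & haz[, 2] == nr)) {
        reward <- reward + config$reward_hazard
        event <- "hazard"
      }
      if (nc == state$required_goal_pos[1] && nr == state$required_goal_pos[2]) {
        reward <- reward + config$reward_required
        state$done <- TRUE
        event <- "required"
      }
    }
  }
  state$heading <- HEADINGS[h]
  state$step_count <- state$step_count + 1L
  if (!state$done && state$step_count >= config$max_steps_per_episode) state$done <- TRUE
  list(state = state, observation = observe(state, config),
       reward = reward, done = state$done, event = event)
}

#' Egocentric binary observation
#'
#' Encodes the agent's 5 x 5 visual field as 100 binary values: 25 window
#' cells times 4 object channels (`wall`, `optional`, `required`, `hazard`).
#' The window is rotated so the agent faces "up" and sits at the bottom-center
#' cell, giving a forward-biased view (4 cells ahead, 2 to each side). Cells
#' outside the room encode `wall`; empty in-room cells encode 0 on all
#' channels. Bit index for window cell `(wr, wc)` (row 1 farthest ahead) and
#' channel `ch` is `((wr-1)*5 + wc - 1)*4 + ch`.
#'
#' @param state A `world_state`.
#' @param config The [world_config()].
#' @return Numeric binary vector of length 100.
#' @export
observe <- function(state, config) {
  obs <- numeric(100)
  h <- match(state$heading, HEADINGS)
  hr <- if (h == 4L) 1L else h + 1L # heading to the agent's right
  ac <- state$agent_pos[1]; ar <- state$agent_pos[2]
  opt <- state$optional_goal_positions
  haz <- state$hazard_positions
  req <- state$required_goal_pos
  for (f in 0:4) {
    for (l in -2:2) {
      c_ <- ac + f * .FDC[h] + l * .FDC[hr]
      r_ <- ar + f * .FDR[h] + l * .FDR[hr]
      cell <- (5 - f - 1) * 5 + (l + 3) # window row 5-f, col l+3
      base <- (cell - 1) * 4
      if (c_ < 1 || c_ > config$width || r_ < 1 || r_ > config$height) {
        obs[base + 1] <- 1
      } else {
        if (nrow(opt) > 0 && any(opt[, 1] == c_ & opt[, 2] == r_)) obs[base + 2] <- 1
        if (c_ == req[1] && r_ == req[2]) obs[base + 3] <- 1
        if (nrow(haz) > 0 && any(haz[, 1] == c_ & haz[, 2] == r_)) obs[base + 4] <- 1
      }
    }
  }
  obs
}

#' Minimal action distance to the required goal
#'
#' Breadth-first search over `(cell, heading)` poses, where each turn or
#' forward move costs one action, from the agent's pose to the required-goal
#' cell (any heading).
#'
#' @inheritParams observe
#' @return Integer number of actions.
#' @export
distance_to_goal <- function(state, config) {
  W <- config$width; H <- config$height
  goal <- state$required_goal_pos
  pose_id <- function(c_, r_, h) ((r_ - 1L) * W + (c_ - 1L)) * 4L + h
  start <- pose_id(state$agent_pos[1], state$agent_pos[2], match(state$heading, HEADINGS))
  if (state$agent_pos[1] == goal[1] && state$agent_pos[2] == goal[2]) return(0L)
  dist <- rep(NA_integer_, W * H * 4L)
  dist[start] <- 0L
  queue <- start
  while (length(queue)) {
    cur <- queue[1]; queue <- queue[-1]
    h <- (cur - 1L) %% 4L + 1L
    cell <- (cur - 1L) %/% 4L
    c_ <- cell %% W + 1L; r_ <- cell %/% W + 1L
    d <- dist[cur]
    push <- function(id) {
      if (is.na(dist[id])) { dist[id] <<- d + 1L; queue <<- c(queue, id) }
    }
    push(pose_id(c_, r_, if (h == 1L) 4L else h - 1L))
    push(pose_id(c_, r_, if (h == 4L) 1L else h + 1L))
    nc <- c_ + .FDC[h]; nr <- r_ + .FDR[h]
    if (nc >= 1L && nc <= W && nr >= 1L && nr <= H) {
      if (nc == goal[1] && nr == goal[2]) return(d + 1L)
      push(pose_id(nc, nr, h))
    }
  }
  stop("required goal unreachable from this pose")
}

#' Construct an arbitrary world state
#'
#' Builds a `world_state` with a prescribed agent pose and object layout,
#' chiefly for probe scenarios and tests. Objects default to the config's
#' fixed layout with no optional goals.
#'
#' @inheritParams observe
#' @param agent_pos `(col, row)` of the agent.
#' @param heading One of `"N"`, `"E"`, `"S"`, `"W"`.
#' @param optional_goals List of `(col, row)` positions (default none).
#' @param hazards List of `(col, row)` positions (default: config's hazards).
#' @export
make_world_state <- function(config, agent_pos, heading,
                             optional_goals = list(),
                             hazards = NULL) {
  if (is.null(hazards))
    hazards <- if (config$include_hazards) config$hazard_positions else list()
  to_mat <- function(ps) if (length(ps)) do.call(rbind, lapply(ps, as.integer))
    else matrix(integer(0), 0, 2)
  structure(list(
    agent_pos = as.integer(agent_pos),
    heading = match.arg(heading, HEADINGS),
    optional_goal_positions = to_mat(optional_goals),
    hazard_positions = to_mat(hazards),
    required_goal_pos = config$required_goal_pos,
    step_count = 0L,
    done = FALSE
  ), class = "world_state")
}

#' Read / write a world configuration as YAML
#'
#' @param path File path.
#' @param config A [world_config()].
#' @return `read_world_config()` returns a `world_config`;
#'   `write_world_config()` returns `path` invisibly.
#' @export
read_world_config <- function(path) {
  y <- yaml::read_yaml(path)
  y$hazard_positions <- lapply(y$hazard_positions, unlist)
  do.call(world_config, y)
}

#' @rdname read_world_config
#' @export
write_world_config <- function(config, path) {
  y <- unclass(config)
  y$hazard_positions <- lapply(y$hazard_positions, as.list)
  yaml::write_yaml(y, path)
  invisible(path)
}
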