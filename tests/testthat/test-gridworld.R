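test_that("world_config validates geometry and reward ordering", {
  expect_s3_class(world_config(), "world_config")
  expect_error(world_config(reward_optional = -1), "reward_optional")
  expect_error(world_config(reward_required = 0.5), "reward_required")
  expect_error(world_config(reward_hazard = 1), "reward_hazard")
  expect_error(world_config(required_goal_pos = c(10, 9)), "outside")
  expect_error(world_config(hazard_positions = list(c(9, 9))), "distinct")
  # a 2x2 room cannot host 3 optional goals next to goal and start
  expect_error(world_config(width = 2, height = 2, required_goal_pos = c(2, 2),
                            hazard_positions = list(), n_optional_goals = 3),
               "too small")
})

test_that("reset is seed-deterministic and places the configured objects", {
  w <- world_config()
  set.seed(11); a <- world_reset(w)
  set.seed(11); b <- world_reset(w)
  expect_identical(a, b)
  expect_equal(nrow(a$state$optional_goal_positions), 3)
  expect_identical(a$state$agent_pos, c(1L, 1L))
  expect_identical(a$state$heading, "E")
  expect_false(a$state$done)
  expect_equal(a$state$step_count, 0L)
  # optional goals land on free cells only
  occupied <- rbind(w$required_goal_pos, w$start_pos,
                    do.call(rbind, w$hazard_positions))
  placed <- a$state$optional_goal_positions
  expect_false(any(apply(placed, 1, function(p)
    any(occupied[, 1] == p[1] & occupied[, 2] == p[2]))))

  simple <- world_config(include_optional = FALSE)
  set.seed(11)
  expect_equal(nrow(world_reset(simple)$state$optional_goal_positions), 0)
})

test_that("turning rotates in place and is self-inverse", {
  w <- bare_room()
  st <- make_world_state(w, c(5, 5), "N")
  a <- world_step(st, "turn_left", w)
  expect_identical(a$state$heading, "W")
  expect_identical(a$state$agent_pos, st$agent_pos)
  expect_equal(a$reward, 0)
  b <- world_step(a$state, "turn_right", w)
  expect_identical(b$state$heading, st$heading)
  expect_identical(b$state$agent_pos, st$agent_pos)
  # full clockwise tour
  s <- st
  for (k in 1:4) s <- world_step(s, "turn_right", w)$state
  expect_identical(s$heading, "N")
})

test_that("forward moves, walls block, and entering cells pays the rewards", {
  w <- world_config()
  # wall: facing west from the west edge
  st <- make_world_state(w, c(1, 5), "W", hazards = list())
  out <- world_step(st, "forward", w)
  expect_identical(out$state$agent_pos, c(1L, 5L))
  expect_equal(out$reward, 0)

  # optional goal: collected once, removed, episode continues
  st <- make_world_state(w, c(4, 5), "E", optional_goals = list(c(5, 5)),
                         hazards = list())
  out <- world_step(st, "forward", w)
  expect_equal(out$reward, w$reward_optional)
  expect_false(out$done)
  expect_equal(nrow(out$state$optional_goal_positions), 0)
  expect_identical(out$event, "optional")

  # required goal: large reward and termination
  st <- make_world_state(w, c(8, 9), "E", hazards = list())
  out <- world_step(st, "forward", w)
  expect_equal(out$reward, w$reward_required)
  expect_true(out$done)

  # hazard: punishment, persists, episode continues
  st <- make_world_state(w, c(5, 5), "E", hazards = list(c(6, 5)))
  out <- world_step(st, "forward", w)
  expect_equal(out$reward, w$reward_hazard)
  expect_false(out$done)
  expect_equal(nrow(out$state$hazard_positions), 1)

  expect_error(world_step(out$state |> (\(s) { s$done <- TRUE; s })(),
                          "forward", w), "finished")
})

test_that("the step cap terminates the episode without a terminal reward", {
  w <- world_config(max_steps_per_episode = 3)
  st <- make_world_state(w, c(5, 5), "N", hazards = list())
  for (k in 1:2) {
    out <- world_step(st, "turn_left", w)
    st <- out$state
    expect_false(out$done)
  }
  out <- world_step(st, "turn_left", w)
  expect_true(out$done)
  expect_equal(out$reward, 0)
})

test_that("observation is a 100-bit one-hot-per-cell encoding", {
  w <- world_config()
  set.seed(5)
  ep <- world_reset(w)
  expect_length(ep$observation, 100)
  expect_true(all(ep$observation %in% c(0, 1)))
  # object channels mutually exclusive per cell
  m <- matrix(ep$observation, nrow = 4)
  expect_true(all(colSums(m[2:4, ]) <= 1))

  # mid-room, nothing in the window -> all zero
  st <- make_world_state(w, c(5, 5), "S", hazards = list())
  expect_equal(observe(st, w), numeric(100))

  # single optional goal directly ahead -> one bit in the optional channel
  # of the cell directly above bottom-center
  st <- make_world_state(w, c(5, 5), "S", optional_goals = list(c(5, 6)),
                         hazards = list())
  obs <- observe(st, w)
  expect_equal(sum(obs), 1)
  expect_equal(which(obs == 1), bit_index(f = 1, l = 0, ch = 2))
})

test_that("observation encoding is injective over distinct window contents", {
  w <- world_config()
  # independent renderer: what is in each of the 25 window cells
  window_content <- function(st) {
    h <- match(st$heading, c("N", "E", "S", "W"))
    fwd <- list(c(0, -1), c(1, 0), c(0, 1), c(-1, 0))[[h]]
    rgt <- list(c(0, -1), c(1, 0), c(0, 1), c(-1, 0))[[h %% 4 + 1]]
    out <- character(0)
    for (f in 0:4) for (l in -2:2) {
      p <- st$agent_pos + f * fwd + l * rgt
      cell <- if (p[1] < 1 || p[1] > 9 || p[2] < 1 || p[2] > 9) "wall"
      else {
        opt <- st$optional_goal_positions
        haz <- st$hazard_positions
        if (nrow(opt) && any(opt[, 1] == p[1] & opt[, 2] == p[2])) "optional"
        else if (all(p == st$required_goal_pos)) "required"
        else if (nrow(haz) && any(haz[, 1] == p[1] & haz[, 2] == p[2])) "hazard"
        else "empty"
      }
      out <- c(out, cell)
    }
    paste(out, collapse = ",")
  }
  set.seed(42)
  states <- sample_world_states(60, w)
  obs_keys <- vapply(states, function(s) paste(observe(s, w), collapse = ""), "")
  content_keys <- vapply(states, window_content, "")
  # equal encodings <=> equal window contents
  expect_identical(outer(obs_keys, obs_keys, "=="),
                   outer(content_keys, content_keys, "=="))
})

test_that("observation is equivariant under global rotation of the world", {
  # rotate the whole room (square) by 90 degrees clockwise together with the
  # agent's pose: the egocentric view must not change
  w <- world_config(hazard_positions = list(c(3, 2)))
  rot_pos <- function(p, n = 9) c(n + 1 - p[2], p[1])
  rot_head <- function(h) c(N = "E", E = "S", S = "W", W = "N")[[h]]
  w_rot <- world_config(required_goal_pos = rot_pos(w$required_goal_pos),
                        hazard_positions = list(rot_pos(c(3, 2))),
                        start_pos = rot_pos(w$start_pos),
                        start_heading = "S")
  set.seed(9)
  for (i in 1:10) {
    st <- sample_world_states(1, w)[[1]]
    st_rot <- make_world_state(
      w_rot, rot_pos(st$agent_pos), rot_head(st$heading),
      optional_goals = apply(st$optional_goal_positions, 1, rot_pos,
                             simplify = FALSE),
      hazards = apply(st$hazard_positions, 1, rot_pos, simplify = FALSE))
    expect_equal(observe(st_rot, w_rot), observe(st, w))
  }
})

test_that("distance_to_goal matches a brute-force action search", {
  w <- bare_room()
  on_goal <- make_world_state(w, c(9, 9), "N")
  expect_equal(distance_to_goal(on_goal, w), 0)
  facing <- make_world_state(w, c(8, 9), "E")
  expect_equal(distance_to_goal(facing, w), 1)
  away <- make_world_state(w, c(8, 9), "W")
  expect_equal(distance_to_goal(away, w), 3) # two turns plus a forward
  set.seed(3)
  for (i in 1:8) {
    st <- sample_world_states(1, w)[[1]]
    expect_equal(distance_to_goal(st, w), bfs_distance_oracle(st, w))
  }
})

test_that("episode reward accounting balances collected objects", {
  w <- world_config()
  cfg <- learning_config(epsilon = 0.5)
  ag <- train_agent(w, cfg, episodes = 40, seed = 21)
  tr <- ag$trace
  reached <- tr[tr$reached_goal, ]
  expect_gt(nrow(reached), 0)
  expect_equal(reached$reward,
               w$reward_required + reached$optional_collected * w$reward_optional +
                 reached$hazard_hits * w$reward_hazard)
  # optional goals are never collected twice
  expect_true(all(tr$optional_collected <= w$n_optional_goals))
})

test_that("world configuration round-trips through YAML", {
  w <- world_config(width = 7, height = 6, n_optional_goals = 2,
                    required_goal_pos = c(7, 6),
                    hazard_positions = list(c(3, 3), c(5, 2)),
                    reward_hazard = -2.5, start_heading = "S")
  path <- withr::local_tempfile(fileext = ".yaml")
  write_world_config(w, path)
  expect_equal(read_world_config(path), w)
})
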