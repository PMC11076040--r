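test_that("reset places resting agents uniformly in the initial box", {
  cfg <- tiny_cond(2)
  set.seed(1)
  for (i in 1:20) {
    w <- reset_world(cfg)
    expect_true(all(abs(w$positions) <= 0.5))
    expect_true(all(w$velocities == 0))
    expect_identical(w$step, 0L)
  }
  # degenerate box pins everyone at the origin
  w0 <- reset_world(tiny_cond(1, init_range = 0))
  expect_true(all(w0$positions == 0))
  # same seed, same state
  set.seed(42)
  a <- reset_world(cfg)
  set.seed(42)
  b <- reset_world(cfg)
  expect_identical(a, b)
})

test_that("action decoding points action 1 at the opponent and negates it at 7", {
  w <- make_world(rbind(c(-0.3, 0.1), c(0.4, 0.5)))
  to_prey <- c(0.7, 0.4) / sqrt(sum(c(0.7, 0.4)^2))
  a1 <- action_to_acceleration(1, w, 1)
  expect_equal(a1 / sqrt(sum(a1^2)), to_prey, tolerance = 1e-12)
  expect_equal(sqrt(sum(a1^2)), w$config$prey_accel * w$config$mobility)
  expect_equal(action_to_acceleration(7, w, 1), -a1, tolerance = 1e-12)
  expect_equal(action_to_acceleration(13, w, 1), c(0, 0))
  # prey magnitude is unscaled; its frame points at the nearest predator
  ap <- action_to_acceleration(1, w, 2)
  expect_equal(sqrt(sum(ap^2)), w$config$prey_accel)
  expect_equal(ap / sqrt(sum(ap^2)), -to_prey, tolerance = 1e-12)
  expect_error(action_to_acceleration(14, w, 1), "1..13")
})

test_that("all twelve directions are distinct, 30 degrees apart, mirror-symmetric", {
  w <- make_world(rbind(c(0.2, -0.1), c(-0.4, 0.3)))
  dirs <- t(sapply(1:12, function(a) action_to_acceleration(a, w, 1)))
  dirs <- dirs / sqrt(rowSums(dirs^2))
  # consecutive actions are 30 degrees apart
  for (a in 1:11) {
    expect_equal(sum(dirs[a, ] * dirs[a + 1, ]), cos(pi / 6), tolerance = 1e-9)
  }
  # action pairs (2,12), (3,11) ... mirror about the u axis
  for (a in 2:6) {
    m <- 14 - a
    u <- dirs[1, ]
    expect_equal(sum(dirs[a, ] * u), sum(dirs[m, ] * u), tolerance = 1e-9)
  }
})

test_that("integration follows the damped semi-implicit update", {
  cfg <- tiny_cond(1, damping = 0.75)
  w <- make_world(rbind(c(0, 0), c(0.5, 0.5)),
    rbind(c(1, 0), c(0, 0)),
    config = cfg
  )
  nxt <- integrate_world(w, matrix(0, 2, 2))
  expect_equal(nxt$velocities[1, ], c(0.75, 0))
  expect_equal(nxt$positions[1, ], c(0.075, 0))
  expect_identical(nxt$step, 1L)
  # zero velocity and acceleration is a fixed point
  still <- integrate_world(make_world(rbind(c(0.1, 0.2), c(-0.2, 0))),
    matrix(0, 2, 2))
  expect_equal(still$positions, rbind(c(0.1, 0.2), c(-0.2, 0)))
  # geometric decay oracle: after k coasting steps speed is damping^k
  v <- c(0.8, -0.6)
  wk <- make_world(rbind(c(0, 0), c(0.5, 0.5)), rbind(v, c(0, 0)),
    config = cfg
  )
  for (k in 1:6) wk <- integrate_world(wk, matrix(0, 2, 2))
  expect_equal(wk$velocities[1, ], v * 0.75^6, tolerance = 1e-12)
})

test_that("event detection applies capture > out-of-area > timeout", {
  cfg <- tiny_cond(1)
  at <- function(p, q, step = 0) {
    make_world(rbind(p, q), step = step, config = cfg)
  }
  expect_equal(detect_events(at(c(0.2, 0.2), c(0.2, 0.2)))$event, "capture")
  expect_equal(detect_events(at(c(0, 0), c(0.1, 0)))$event, "capture") # inclusive
  expect_equal(detect_events(at(c(0, 0), c(0.2, 0)))$event, "none")
  expect_equal(detect_events(at(c(1.01, 0), c(0, 0)))$event, "predator_out")
  expect_equal(detect_events(at(c(1, 0), c(0, 0)))$event, "none") # boundary inside
  expect_equal(detect_events(at(c(0, 0), c(0, -1.2)))$event, "prey_out")
  expect_equal(detect_events(at(c(0.5, 0), c(0, 0), step = 300))$event, "timeout")
  # capture wins over simultaneous out-of-area and timeout
  both <- at(c(1.2, 0), c(1.21, 0), step = 300)
  expect_equal(detect_events(both)$event, "capture")
})

test_that("capture is translation- and rotation-invariant", {
  cfg <- tiny_cond(1)
  set.seed(3)
  for (i in 1:25) {
    p <- matrix(stats::runif(4, -0.4, 0.4), 2, 2)
    ev <- detect_events(make_world(p, config = cfg))$event
    shift <- matrix(rep(stats::runif(2, -0.2, 0.2), each = 2), 2, 2)
    expect_equal(detect_events(make_world(p + shift, config = cfg))$event, ev)
    th <- stats::runif(1, 0, 2 * pi)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    expect_equal(detect_events(make_world(p %*% t(R), config = cfg))$event, ev)
  }
})

test_that("rewards match the sharing rules and events", {
  sh <- tiny_cond(3, sharing = "shared")
  ind <- tiny_cond(3, sharing = "individual")
  expect_equal(compute_rewards("capture", 2, sh), c(1, 1, 1, -1))
  expect_equal(compute_rewards("capture", 2, ind), c(0, 1, 0, -1))
  expect_equal(compute_rewards("predator_out", 1, ind), c(-1, 0, 0, 0))
  expect_equal(compute_rewards("prey_out", 4, sh), c(0, 0, 0, -1))
  expect_equal(compute_rewards("timeout", NA, sh), c(0, 0, 0, 0))
  expect_error(compute_rewards("capture", NA, sh), "catcher")
})

test_that("step composes decode, integrate, detect, reward deterministically", {
  cfg <- tiny_cond(1)
  w <- make_world(rbind(c(-0.4, 0), c(0.4, 0)), config = cfg)
  out <- step_world(w, c(13, 13))
  expect_equal(out$state$positions, w$positions)
  expect_equal(out$event, "none")
  expect_false(out$terminal)
  # a constructed closing geometry captures in one step
  close_w <- make_world(rbind(c(0, 0), c(0.12, 0)),
    rbind(c(0.3, 0), c(0, 0)),
    config = cfg
  )
  out2 <- step_world(close_w, c(1, 13))
  expect_equal(out2$event, "capture")
  expect_equal(out2$rewards, c(1, -1))
  expect_error(step_world(out2$state, c(1, 1)), "terminal")
})

test_that("a full timeout episode accumulates zero reward", {
  cfg <- tiny_cond(1, time_limit = 3) # 30 steps
  w <- make_world(rbind(c(-0.4, 0), c(0.4, 0)), config = cfg)
  total <- c(0, 0)
  for (k in 1:30) {
    out <- step_world(w, c(13, 13))
    total <- total + out$rewards
    w <- out$state
  }
  expect_true(out$terminal)
  expect_equal(out$event, "timeout")
  expect_equal(total, c(0, 0))
})

test_that("scripted flee episode exits at the closed-form crossing step", {
  cfg <- tiny_cond(1)
  # predator resting directly behind the prey: flee is exactly +x forever
  state <- make_world(rbind(c(-0.99, 0), c(0, 0)), config = cfg)
  # independent kinematics oracle for the 1-D recursion
  v <- 0
  x <- 0
  k <- 0
  while (x <= 1) {
    v <- cfg$damping * v + cfg$prey_accel * cfg$dt
    x <- x + v * cfg$dt
    k <- k + 1
  }
  steps <- 0
  repeat {
    out <- step_world(state, c(13, scripted_action(
      scripted_policy("flee"), state, 2
    )))
    state <- out$state
    steps <- steps + 1
    if (out$terminal) break
  }
  expect_equal(out$event, "prey_out")
  expect_equal(steps, k)
})

test_that("replaying logged actions reproduces a C++ rollout exactly", {
  cfg <- condition_config(2, "slow", "shared")
  pol <- list(rule_policy(), rule_policy(), scripted_policy("evasive"))
  set.seed(31)
  sim <- simulate_episodes(pol, cfg, 3)
  rec <- sim$records
  for (ep in unique(rec$episode)) {
    d <- rec[rec$episode == ep, ]
    first <- d[d$step == 0, ]
    state <- world_state(
      cbind(first$x, first$y), cbind(first$vx, first$vy), 0, cfg
    )
    for (s in sort(unique(d$step))) {
      row <- d[d$step == s, ]
      # logged pre-step state matches the replayed state bit for bit
      expect_identical(
        unname(state$positions), unname(cbind(row$x, row$y))
      )
      out <- step_world(state, row$action)
      expect_equal(out$rewards, row$reward, ignore_attr = TRUE)
      state <- out$state
    }
    expect_true(out$terminal)
    expect_equal(out$event, d$event[nrow(d)])
  }
})

test_that("R and C++ rollouts are stream-identical under one seed", {
  cfg <- condition_config(2, "slow", "shared")
  pol <- list(rule_policy(), rule_policy(), scripted_policy("evasive"))
  set.seed(7)
  rec_cpp <- simulate_episodes(pol, cfg, 2)$records
  set.seed(7)
  rec_r <- rbind(
    generate_scripted_episode(pol, cfg, 1),
    generate_scripted_episode(pol, cfg, 2)
  )
  expect_equal(nrow(rec_cpp), nrow(rec_r))
  expect_equal(rec_cpp$action, rec_r$action)
  expect_identical(rec_cpp$x, rec_r$x)
  expect_identical(rec_cpp$vy, rec_r$vy)
  expect_equal(rec_cpp$event, rec_r$event)
})

test_that("coasting kinetic energy is non-increasing", {
  cfg <- tiny_cond(1)
  set.seed(5)
  w <- random_world(cfg)
  for (k in 1:20) {
    ke0 <- sum(w$velocities^2)
    w <- integrate_world(w, matrix(0, 2, 2))
    expect_lte(sum(w$velocities^2), ke0)
  }
})

test_that("episode records serialize to CSV and back", {
  cfg <- condition_config(2, "slow", "shared")
  set.seed(9)
  rec <- generate_scripted_episode(
    list(rule_policy(), rule_policy(), scripted_policy("evasive")), cfg
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write_episode_csv(rec, path)
  back <- read_episode_csv(path)
  expect_equal(nrow(back), nrow(rec))
  expect_equal(back$action, rec$action)
  expect_equal(back$x, rec$x, tolerance = 1e-12)
  # the binary container round-trips the object exactly
  rds <- withr::local_tempfile(fileext = ".rds")
  write_episode_rds(rec, rds)
  expect_identical(read_episode_rds(rds), rec)
})
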