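slow2 <- function() condition_config(2, "slow", "shared")

rule_world <- function(p1, p2, prey, v = NULL) {
  make_world(rbind(p1, p2, prey), v, config = slow2())
}

test_that("orientation reproduces the worked configuration and its mirror", {
  # closer predator (0.2, 0.3), prey (0.5, 0.2)
  w <- rule_world(c(0.2, 0.3), c(0.9, -0.9), c(0.5, 0.2))
  expect_equal(cw_or_ccw(w), "CW")
  # reflecting across the x axis flips the rotation sense
  wm <- rule_world(c(0.2, -0.3), c(0.9, 0.9), c(0.5, -0.2))
  expect_equal(cw_or_ccw(wm), "CCW")
  # dominant-component tie goes to x
  wt <- rule_world(c(0.1, 0.1), c(0.9, -0.9), c(0.4, 0.4))
  r <- c(0.3, 0.3) # |x| == |y|: x wins, sign +, prey quadrant (+,+)
  expect_equal(cw_or_ccw(wt), "CW")
})

test_that("orientation flips with the chase's rotation sense on a ring", {
  # tail chase around the arena: predator behind the prey on a circle.
  # Clockwise chase at the top: prey east of predator.
  w_cw <- rule_world(c(-0.2, 0.7), c(-0.9, -0.9), c(0.3, 0.7))
  expect_equal(cw_or_ccw(w_cw), "CW")
  # Counterclockwise chase at the top: prey west of predator.
  w_ccw <- rule_world(c(0.2, 0.7), c(0.9, -0.9), c(-0.3, 0.7))
  expect_equal(cw_or_ccw(w_ccw), "CCW")
})

test_that("role assignment follows the closer-predator branching", {
  cfg <- rule_config()
  # predator 1 closest: it chases
  w <- rule_world(c(0.3, 0.1), c(-0.8, -0.8), c(0.5, 0.2))
  r <- assign_roles(w, cfg)
  expect_equal(r[["predator1"]], "chase")
  # ... and with the chase tight (closer distance < 0.4), predator 2 ambushes
  expect_equal(r[["predator2"]], "ambush")
  # loose chase: predator 2 joins the chase instead
  w2 <- rule_world(c(0.3, 0.1), c(-0.8, -0.8), c(-0.5, 0.9))
  expect_equal(
    assign_roles(w2, cfg),
    c(predator1 = "chase", predator2 = "chase")
  )
  # predator 2 closest and tight: predator 1 takes the shortcut
  w3 <- rule_world(c(-0.8, -0.8), c(0.3, 0.1), c(0.5, 0.2))
  expect_equal(
    assign_roles(w3, cfg),
    c(predator1 = "shortcut", predator2 = "chase")
  )
  # predator 2 closest but loose: predator 1 approaches
  w4 <- rule_world(c(-0.8, -0.8), c(-0.2, 0.9), c(0.5, 0.2))
  expect_equal(assign_roles(w4, cfg)[["predator1"]], "approach")
  # exact tie counts predator 1 as closer
  w5 <- rule_world(c(0.3, 0), c(-0.3, 0), c(0, 0))
  expect_equal(assign_roles(w5, cfg)[["predator1"]], "chase")
  expect_error(
    assign_roles(make_world(rbind(c(0, 0), c(0.5, 0.5)))),
    "2 predators"
  )
})

test_that("chase cascade hits its printed anchors", {
  cfg <- rule_config()
  # own outer edge band, CW context -> action 3
  w <- rule_world(c(0.95, 0.95), c(-0.9, -0.9), c(0.5, 0.2))
  expect_equal(cw_or_ccw(w), "CW")
  expect_equal(chase_action(w, 1, cfg), 3L)
  # prey central (drive out), CW context, predator mid-arena -> action 11
  w2 <- rule_world(c(-0.2, 0.3), c(-0.9, -0.9), c(0.1, 0.1))
  expect_equal(cw_or_ccw(w2), "CW")
  expect_equal(chase_action(w2, 1, cfg), 11L)
  # aligned velocities (psi = 0) with prey outside the bands -> action 1
  w3 <- rule_world(c(0, 0), c(-0.9, -0.2), c(0.7, 0.2),
    v = rbind(c(1, 0), c(0, 0), c(1, 0))
  )
  expect_equal(chase_action(w3, 1, cfg), 1L)
  # psi bins: 30 degrees -> 2, 90 degrees -> 3 (either sign)
  rot <- function(th) c(cos(th), sin(th))
  w4 <- rule_world(c(0, 0), c(-0.9, -0.2), c(0.7, 0.2),
    v = rbind(c(1, 0), c(0, 0), rot(pi / 6))
  )
  expect_equal(chase_action(w4, 1, cfg), 2L)
  w5 <- rule_world(c(0, 0), c(-0.9, -0.2), c(0.7, 0.2),
    v = rbind(c(1, 0), c(0, 0), rot(-pi / 2))
  )
  expect_equal(chase_action(w5, 1, cfg), 3L)
})

test_that("shortcut and approach defer to edge bands then commit", {
  cfg <- rule_config()
  # mid-arena CW -> shortcut 2, approach 1
  w <- rule_world(c(0.2, 0.3), c(0.3, 0.1), c(0.5, 0.2))
  expect_equal(cw_or_ccw(w), "CW")
  expect_equal(shortcut_action(w, 1, cfg), 2L)
  expect_equal(approach_action(w, 1, cfg), 1L)
  # mid-arena CCW -> shortcut 12
  wm <- rule_world(c(0.2, -0.3), c(0.3, -0.1), c(0.5, -0.2))
  expect_equal(cw_or_ccw(wm), "CCW")
  expect_equal(shortcut_action(wm, 1, cfg), 12L)
  # inside the 0.8 edge ring both fall back to the band action
  we <- rule_world(c(0.85, 0.1), c(0.3, 0.1), c(0.5, 0.2))
  band <- if (cw_or_ccw(we) == "CW") 2L else 12L
  expect_equal(shortcut_action(we, 1, cfg), band)
  expect_equal(approach_action(we, 1, cfg), band)
})

test_that("ambush heads for the prey-side reference point and holds there", {
  cfg <- rule_config()
  # printed example: predator (-0.2, 0.8), prey (-0.2, -0.8) -> action 12
  w <- rule_world(c(-0.2, 0.8), c(0.9, 0.9), c(-0.2, -0.8))
  expect_equal(ambush_action(w, 1, cfg), 12L)
  # prey y flips sign -> reference point switches to the top
  wt <- rule_world(c(-0.2, 0.8), c(0.9, 0.9), c(-0.2, 0.8) + c(0, 0.01))
  # (prey nearly on top of predator 1 is fine for the reference choice)
  ref_top <- cfg$ambush_top
  one_step <- function(state, a) {
    acc <- action_to_acceleration(a, state, 1)
    v <- state$config$damping * state$velocities[1, ] + acc * state$config$dt
    state$positions[1, ] + v * state$config$dt
  }
  d_top <- vapply(
    cfg$ambush_actions,
    function(a) sum((one_step(wt, a) - ref_top)^2), numeric(1)
  )
  expect_equal(
    ambush_action(wt, 1, cfg),
    cfg$ambush_actions[which.min(d_top)]
  )
  # exactly at the reference point the predator holds (minimal move)
  wr <- make_world(rbind(cfg$ambush_bottom, c(0.9, 0.9), c(0.5, -0.9)),
    config = slow2()
  )
  a0 <- ambush_action(wr, 1, cfg)
  expect_true(a0 %in% cfg$ambush_actions)
  d0 <- vapply(
    cfg$ambush_actions,
    function(a) sum((one_step(wr, a) - cfg$ambush_bottom)^2), numeric(1)
  )
  expect_equal(a0, cfg$ambush_actions[which.min(d0)])
})

test_that("the cascade is total and deterministic on random worlds", {
  set.seed(61)
  cfg <- rule_config()
  for (rep in 1:60) {
    w <- random_world(slow2(), pos_range = 0.99)
    for (i in 1:2) {
      a <- rule_based_action(w, i, cfg)
      expect_true(a %in% 1:12)
      expect_identical(rule_based_action(w, i, cfg), a)
    }
  }
})

test_that("R and C++ rule policies agree on logged rollout states", {
  cond <- slow2()
  set.seed(62)
  sim <- simulate_episodes(
    list(rule_policy(), rule_policy(), scripted_policy("evasive")),
    cond, 5
  )
  rec <- sim$records
  for (ep in unique(rec$episode)) {
    d <- rec[rec$episode == ep, ]
    for (s in unique(d$step)) {
      row <- d[d$step == s, ]
      w <- world_state(cbind(row$x, row$y), cbind(row$vx, row$vy), s, cond)
      expect_equal(rule_based_action(w, 1), row$action[1])
      expect_equal(rule_based_action(w, 2), row$action[2])
    }
  }
})
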