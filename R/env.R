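#' World state
#'
#' Positions and velocities of every agent disk at one time step.
#' Agents are ordered predators first (1..n_predators), prey last.
#'
#' @param positions (n_agents x 2) matrix of absolute positions.
#' @param velocities (n_agents x 2) matrix of absolute velocities.
#' @param step step index (0 at reset).
#' @param config the [condition_config()] the state belongs to.
#' @return an object of class `world_state`.
#' @export
world_state <- function(positions, velocities, step = 0L,
                        config = condition_config()) {
  positions <- matrix(as.numeric(positions), ncol = 2)
  velocities <- matrix(as.numeric(velocities), ncol = 2)
  na <- n_agents(config)
  stopifnot(
    nrow(positions) == na, nrow(velocities) == na,
    is.finite(positions), is.finite(velocities),
    step >= 0
  )
  structure(
    list(
      positions = positions, velocities = velocities,
      step = as.integer(step), config = config
    ),
    class = "world_state"
  )
}

#' @export
print.world_state <- function(x, ...) {
  cat(sprintf(
    "<world_state> step %d, %d predator(s) + prey\n", x$step,
    x$config$n_predators
  ))
  roles <- c(rep("predator", x$config$n_predators), "prey")
  for (i in seq_len(nrow(x$positions))) {
    cat(sprintf(
      "  %-8s pos (% .3f, % .3f)  vel (% .3f, % .3f)\n", roles[i],
      x$positions[i, 1], x$positions[i, 2],
      x$velocities[i, 1], x$velocities[i, 2]
    ))
  }
  invisible(x)
}

prey_index <- function(state) n_agents(state$config)

#' Draw a fresh initial world state
#'
#' All agents start at rest at i.i.d. uniform positions on the initial
#' box \eqn{[-\mathrm{init\_range}, \mathrm{init\_range}]^2}. Randomness
#' comes from R's RNG, so `set.seed()` makes resets reproducible.
#' Coordinates are drawn agent by agent, x before y (the same order the
#' C++ core uses, so the two routes are stream-identical).
#'
#' @param config a [condition_config()].
#' @return a [world_state()] at step 0.
#' @export
reset_world <- function(config = condition_config()) {
  na <- n_agents(config)
  u <- stats::runif(2 * na, -config$init_range, config$init_range)
  pos <- matrix(u, ncol = 2, byrow = TRUE)
  world_state(pos, matrix(0, na, 2), 0L, config)
}

#' Relative coordinate frame of an agent
#'
#' The u axis points from the agent toward its reference opponent: the
#' prey for predators, the nearest predator for the prey (ties broken
#' toward the lowest predator index). The v axis is u rotated 90 degrees
#' clockwise, so action angles are measured clockwise from u — the
#' convention under which the rule-based edge turns point into the
#' arena for both chase orientations. When agent and opponent coincide
#' the frame falls back to the absolute axes.
#'
#' @param state a [world_state()].
#' @param agent agent index (1-based; prey is `n_predators + 1`).
#' @return list with unit vectors `u` and `v`.
#' @export
relative_frame <- function(state, agent) {
  np <- state$config$n_predators
  p <- state$positions
  if (agent <= np) {
    target <- p[np + 1L, ] - p[agent, ]
  } else {
    d2 <- rowSums((p[seq_len(np), , drop = FALSE] -
      matrix(p[agent, ], np, 2, byrow = TRUE))^2)
    target <- p[which.min(d2), ] - p[agent, ]
  }
  nrm <- sqrt(sum(target^2))
  u <- if (nrm < 1e-12) c(1, 0) else target / nrm
  list(u = u, v = c(u[2], -u[1]))
}

#' Decode a discrete action into an acceleration vector
#'
#' Actions 1-12 accelerate at angles \eqn{(a-1) \times 30^\circ}
#' clockwise from the agent's u axis ([relative_frame()]); action 1
#' therefore points straight at the reference opponent and action 7
#' directly away from it. Action 13 is "do nothing". Predators get the
#' mobility-scaled magnitude, the prey the baseline `prey_accel`.
#'
#' @param action integer in 1..13.
#' @param state a [world_state()].
#' @param agent agent index.
#' @param config a [condition_config()]; defaults to the state's own.
#' @return length-2 acceleration vector in the absolute frame.
#' @export
action_to_acceleration <- function(action, state, agent,
                                   config = state$config) {
  if (!(length(action) == 1 && action %in% 1:13)) {
    stop("action must be a single integer in 1..13")
  }
  if (action == 13) {
    return(c(0, 0))
  }
  fr <- relative_frame(state, agent)
  theta <- (action - 1) * pi / 6
  mag <- config$prey_accel *
    if (agent <= config$n_predators) config$mobility else 1
  mag * (cos(theta) * fr$u + sin(theta) * fr$v)
}

#' Advance the physics one step
#'
#' Semi-implicit Euler with viscous damping: velocities update first
#' (`v' = damping * v + a * dt`), then positions (`p' = p + v' * dt`).
#' Predator disks pass through each other; only predator-prey contact
#' matters (see [detect_events()]).
#'
#' @param state a [world_state()].
#' @param accelerations (n_agents x 2) matrix of accelerations.
#' @param config a [condition_config()]; defaults to the state's own.
#' @return the next [world_state()], step index incremented.
#' @export
integrate_world <- function(state, accelerations, config = state$config) {
  acc <- matrix(as.numeric(accelerations), ncol = 2)
  stopifnot(nrow(acc) == n_agents(config))
  v <- config$damping * state$velocities + acc * config$dt
  p <- state$positions + v * config$dt
  world_state(p, v, state$step + 1L, config)
}

#' Detect the terminal event of a state
#'
#' Capture means some predator-prey centre distance is at or below the
#' disk diameter (the sum of the two radii). Out-of-area means a disk
#' centre strictly outside the arena (the boundary itself counts as
#' inside); agents are checked in index order, predators before prey.
#' Timeout fires once the step index reaches the episode cap. Precedence
#' is capture > out-of-area > timeout, so exactly one label is returned.
#'
#' @param state a [world_state()].
#' @param config a [condition_config()]; defaults to the state's own.
#' @return list with `event` (one of `"none"`, `"capture"`,
#'   `"predator_out"`, `"prey_out"`, `"timeout"`) and `who` (the
#'   catching predator or exiting agent index, else `NA`).
#' @export
detect_events <- function(state, config = state$config) {
  np <- config$n_predators
  p <- state$positions
  prey <- p[np + 1L, ]
  d <- sqrt(rowSums((p[seq_len(np), , drop = FALSE] -
    matrix(prey, np, 2, byrow = TRUE))^2))
  hit <- which(d <= config$agent_diameter)
  if (length(hit) > 0) {
    return(list(event = "capture", who = hit[1]))
  }
  hw <- config$arena_half_width
  out <- which(abs(p[, 1]) > hw | abs(p[, 2]) > hw)
  if (length(out) > 0) {
    who <- out[1]
    return(list(
      event = if (who <= np) "predator_out" else "prey_out",
      who = who
    ))
  }
  if (state$step >= n_steps(config)) {
    return(list(event = "timeout", who = NA_integer_))
  }
  list(event = "none", who = NA_integer_)
}

#' Per-agent rewards for an event
#'
#' Capture pays +1 to every predator under shared reward, and only to
#' the catcher under individual reward; the prey gets -1 either way. An
#' agent leaving the arena is punished -1 (no one else is paid). Timeout
#' pays 0 to everyone; prey success is an outcome label, not a reward.
#'
#' @param event event label from [detect_events()].
#' @param who catcher / offender index (required for `"capture"` and the
#'   out-of-area events).
#' @param config a [condition_config()].
#' @return numeric reward vector, one entry per agent.
#' @export
compute_rewards <- function(event, who, config) {
  na <- n_agents(config)
  np <- config$n_predators
  r <- numeric(na)
  if (event == "capture") {
    if (is.na(who)) stop("capture event needs a catcher index")
    r[na] <- -1
    if (config$sharing == "shared") r[seq_len(np)] <- 1 else r[who] <- 1
  } else if (event == "predator_out") {
    if (is.na(who)) stop("out-of-area event needs an agent index")
    r[who] <- -1
  } else if (event == "prey_out") {
    r[na] <- -1
  } else if (!event %in% c("timeout", "none")) {
    stop("unknown event '", event, "'")
  }
  r
}

#' Step the world under one joint action
#'
#' Composes action decoding, integration, event detection and reward
#' assignment. A pure function of `(state, actions, config)`: replaying
#' a logged action sequence from the logged initial state reproduces the
#' trajectory exactly.
#'
#' @param state a non-terminal [world_state()].
#' @param actions integer vector of actions (1..13), one per agent.
#' @param config a [condition_config()]; defaults to the state's own.
#' @return an object of class `step_outcome`: list with `state` (the
#'   next world state), `rewards`, `terminal`, `event`, `who`.
#' @export
step_world <- function(state, actions, config = state$config) {
  na <- n_agents(config)
  stopifnot(length(actions) == na)
  if (detect_events(state, config)$event != "none") {
    stop("cannot step a terminal state")
  }
  acc <- t(vapply(
    seq_len(na),
    function(i) action_to_acceleration(actions[i], state, i, config),
    numeric(2)
  ))
  nxt <- integrate_world(state, acc, config)
  ev <- detect_events(nxt, config)
  structure(
    list(
      state = nxt,
      rewards = compute_rewards(ev$event, ev$who, config),
      terminal = ev$event != "none",
      event = ev$event,
      who = ev$who
    ),
    class = "step_outcome"
  )
}

#' @export
print.step_outcome <- function(x, ...) {
  cat(sprintf(
    "<step_outcome> step %d, event %s%s, rewards [%s]\n",
    x$state$step, x$event,
    if (!is.na(x$who)) sprintf(" (agent %d)", x$who) else "",
    paste(format(x$rewards), collapse = ", ")
  ))
  invisible(x)
}

event_names <- c("none", "capture", "predator_out", "prey_out", "timeout")

event_from_code <- function(code) event_names[code + 1L]
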