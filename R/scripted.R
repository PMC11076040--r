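#' Closest-direction action for a desired heading
#'
#' Picks the action (1..12) whose decoded acceleration direction is
#' closest (maximum dot product, ties to the lowest action) to a desired
#' absolute direction. Returns 13 for a zero direction.
#'
#' @param direction length-2 desired direction (absolute frame).
#' @param state a [world_state()].
#' @param agent agent index.
#' @return an action in 1..13.
#' @export
action_toward <- function(direction, state, agent) {
  nrm <- sqrt(sum(direction^2))
  if (nrm < 1e-12) {
    return(13L)
  }
  dir <- direction / nrm
  fr <- relative_frame(state, agent)
  best <- 1L
  bd <- -Inf
  for (a in 1:12) {
    theta <- (a - 1) * pi / 6
    e <- cos(theta) * fr$u + sin(theta) * fr$v
    d <- sum(e * dir)
    if (d > bd + 1e-12) {
      bd <- d
      best <- a
    }
  }
  best
}

#' Scripted controller specification
#'
#' Deterministic or noise-driven controllers used as synthetic stand-ins
#' for trained or human players when generating fixture episodes and
#' cloning corpora:
#' * `stationary` — always action 13 (do nothing).
#' * `pursuit` — always action 1 (straight at the reference opponent);
#'   pure pursuit for a predator.
#' * `flee` — always action 7 (straight away from the reference
#'   opponent).
#' * `straight` — hold a fixed absolute `direction`, optionally with
#'   zero-mean Gaussian angular noise of sd `noise_sd` radians.
#' * `random_walk` — a uniform action in 1..12 each step.
#' * `evasive` — the package's scripted prey, a forage-flee evader
#'   emulating a trained prey's edge-ring occupancy: while no predator
#'   is within `flight_distance` it idles (drifting back inside the
#'   `orbit_radius` ring if it finds itself outside); when pressed it
#'   sprints along the tangent direction that increases distance to the
#'   nearest predator, with a radial correction of strength
#'   `radial_gain` that keeps it off the boundary, the heading rotated
#'   by Gaussian angular noise (`noise_sd` radians, default 0.35).
#'
#' @param name controller name (above).
#' @param noise_sd angular noise sd in radians; defaults to 0.35 for
#'   `evasive` and 0 otherwise.
#' @param direction absolute direction for `straight`.
#' @param orbit_radius,radial_gain,flight_distance evasive-controller
#'   parameters (see above).
#' @return an object of class `scripted_policy`.
#' @export
scripted_policy <- function(name = c(
                              "evasive", "pursuit", "flee", "stationary",
                              "straight", "random_walk"
                            ),
                            noise_sd = NULL, direction = c(1, 0),
                            orbit_radius = 0.8, radial_gain = 4,
                            flight_distance = 0.45) {
  name <- match.arg(name)
  if (is.null(noise_sd)) noise_sd <- if (name == "evasive") 0.35 else 0
  stopifnot(
    noise_sd >= 0, length(direction) == 2,
    orbit_radius > 0, flight_distance > 0
  )
  structure(
    list(
      type = "scripted", name = name, noise_sd = noise_sd,
      direction = as.numeric(direction), orbit_radius = orbit_radius,
      radial_gain = radial_gain, flight_distance = flight_distance
    ),
    class = c("scripted_policy", "agent_policy")
  )
}

#' Evaluate a scripted controller at a state
#'
#' The R reference for the controllers in [scripted_policy()]; the C++
#' rollout mirrors it draw for draw.
#'
#' @param policy a [scripted_policy()].
#' @param state a [world_state()].
#' @param agent agent index.
#' @return an action in 1..13.
#' @export
scripted_action <- function(policy, state, agent) {
  config <- state$config
  np <- config$n_predators
  switch(policy$name,
    stationary = 13L,
    pursuit = 1L,
    flee = 7L,
    straight = {
      dir <- policy$direction
      if (policy$noise_sd > 0) {
        dir <- rotate2(dir, stats::rnorm(1) * policy$noise_sd)
      }
      action_toward(dir, state, agent)
    },
    random_walk = as.integer(floor(stats::runif(1) * 12) + 1),
    evasive = {
      p <- state$positions
      d2 <- rowSums((p[seq_len(np), , drop = FALSE] -
        matrix(p[agent, ], np, 2, byrow = TRUE))^2)
      j <- which.min(d2)
      dn <- sqrt(d2[j])
      rho <- sqrt(sum(p[agent, ]^2))
      if (dn > policy$flight_distance) {
        if (rho <= policy$orbit_radius) {
          return(13L)
        }
        dir <- -p[agent, ] / rho
      } else {
        away <- p[agent, ] - p[j, ]
        nrm <- sqrt(sum(away^2))
        away <- if (nrm < 1e-12) c(1, 0) else away / nrm
        out <- if (rho < 1e-6) away else p[agent, ] / rho
        tang <- c(-out[2], out[1])
        if (sum(tang * away) < 0) tang <- -tang
        dir <- tang + policy$radial_gain * (policy$orbit_radius - rho) * out
        nrm <- sqrt(sum(dir^2))
        dir <- if (nrm < 1e-12) c(1, 0) else dir / nrm
      }
      if (policy$noise_sd > 0) {
        dir <- rotate2(dir, stats::rnorm(1) * policy$noise_sd)
      }
      action_toward(dir, state, agent)
    }
  )
}

rotate2 <- function(v, angle) {
  c(
    cos(angle) * v[1] - sin(angle) * v[2],
    sin(angle) * v[1] + cos(angle) * v[2]
  )
}

#' Policy wrappers for simulation
#'
#' `net_policy()` wraps trained `policy_params` for greedy (or
#' epsilon-greedy) play; `rule_policy()` plugs the rule-based predator
#' into an agent slot. Together with [scripted_policy()] these are the
#' three policy kinds [simulate_episodes()] accepts.
#'
#' @param params a `policy_params` object.
#' @param epsilon exploration probability during play (0 = greedy).
#' @return an `agent_policy` object.
#' @export
net_policy <- function(params, epsilon = 0) {
  stopifnot(inherits(params, "policy_params"), epsilon >= 0, epsilon <= 1)
  structure(
    list(type = "net", params = unclass_params(params), epsilon = epsilon),
    class = c("net_policy", "agent_policy")
  )
}

#' @rdname net_policy
#' @param cfg a [rule_config()].
#' @export
rule_policy <- function(cfg = rule_config()) {
  structure(
    list(type = "rule", cfg = cfg),
    class = c("rule_policy", "agent_policy")
  )
}

unclass_params <- function(p) {
  out <- unclass(p)
  attributes(out) <- list(names = names(out))
  out
}

#' Evaluate any agent policy at a state (R reference path)
#'
#' @param policy an `agent_policy`.
#' @param state a [world_state()].
#' @param agent agent index.
#' @return an action in 1..13.
#' @export
policy_action <- function(policy, state, agent) {
  switch(policy$type,
    net = {
      s <- build_state_vector(state, agent)
      q <- q_forward(policy$params, s)
      select_action(q, policy$epsilon)
    },
    rule = rule_based_action(state, agent, policy$cfg),
    scripted = scripted_action(policy, state, agent),
    stop("unknown policy type")
  )
}
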