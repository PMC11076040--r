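#' Experimental condition configuration
#'
#' Bundles one cell of the study design (number of predators, relative
#' mobility, reward sharing) with the physics constants of the
#' chase-and-escape world. Defaults reproduce the study arena: a
#' \eqn{[-1, 1]^2} square, 0.1-diameter disks, 0.1 s time step, 30 s
#' episode limit, initial positions uniform on \eqn{[-0.5, 0.5]^2}.
#'
#' @param n_predators number of predators (1, 2 or 3); there is always
#'   exactly one prey.
#' @param mobility predator acceleration relative to the prey's, either a
#'   keyword (`"fast"` = 1.2, `"equal"` = 1.0, `"slow"` = 0.8) or one of
#'   those numeric values.
#' @param sharing `"individual"` (only the catcher is rewarded) or
#'   `"shared"` (every predator is rewarded on capture).
#' @param dt step duration in seconds.
#' @param time_limit episode cap in seconds; `time_limit / dt` must be a
#'   whole number of steps.
#' @param arena_half_width half-width of the square play area.
#' @param agent_diameter disk diameter; capture means centre distance
#'   at or below this value.
#' @param init_range half-width of the uniform initial-position box.
#' @param prey_accel prey acceleration magnitude (length units / s^2).
#'   The default 4 makes an unopposed agent cross the arena in about 2 s.
#' @param damping per-step multiplicative velocity retention in (0, 1];
#'   the viscous-resistance discretization keeps `damping * v` each step.
#'
#' @return an object of class `condition_config`.
#' @export
condition_config <- function(n_predators = 2,
                             mobility = c("slow", "equal", "fast"),
                             sharing = c("shared", "individual"),
                             dt = 0.1,
                             time_limit = 30,
                             arena_half_width = 1,
                             agent_diameter = 0.1,
                             init_range = 0.5,
                             prey_accel = 4,
                             damping = 0.75) {
  if (is.character(mobility)) {
    mobility <- match.arg(mobility)
    mobility <- c(fast = 1.2, equal = 1.0, slow = 0.8)[[mobility]]
  }
  sharing <- match.arg(sharing)
  stopifnot(
    n_predators %in% 1:3,
    mobility %in% c(1.2, 1.0, 0.8),
    dt > 0,
    abs(time_limit / dt - round(time_limit / dt)) < 1e-9,
    agent_diameter > 0, agent_diameter < 2 * arena_half_width,
    init_range >= 0, init_range < arena_half_width,
    prey_accel >= 0,
    damping > 0, damping <= 1
  )
  structure(
    list(
      n_predators = as.integer(n_predators),
      mobility = mobility,
      sharing = sharing,
      dt = dt,
      time_limit = time_limit,
      arena_half_width = arena_half_width,
      agent_diameter = agent_diameter,
      init_range = init_range,
      prey_accel = prey_accel,
      damping = damping
    ),
    class = "condition_config"
  )
}

#' @export
print.condition_config <- function(x, ...) {
  mob <- c("1.2" = "fast", "1" = "equal", "0.8" = "slow")[[as.character(x$mobility)]]
  cat(sprintf(
    "<condition_config> %d predator(s) x %s (%.1f) x %s\n", x$n_predators,
    mob, x$mobility, x$sharing
  ))
  cat(sprintf(
    "  dt %.2fs, limit %.0fs (%d steps), arena +/-%.1f, diameter %.2f\n",
    x$dt, x$time_limit, n_steps(x), x$arena_half_width, x$agent_diameter
  ))
  cat(sprintf(
    "  init range +/-%.2f, prey accel %.1f, damping %.2f\n",
    x$init_range, x$prey_accel, x$damping
  ))
  invisible(x)
}

n_agents <- function(config) config$n_predators + 1L

n_steps <- function(config) as.integer(round(config$time_limit / config$dt))

#' Learner configuration
#'
#' Hyperparameters of the independent dueling double-DQN learners with
#' prioritized replay. Defaults are the study's training constants:
#' discount 0.9, prioritization exponent 0.6, Adam learning rate 1e-6,
#' minibatch 32, replay capacity 1e4, target-network sync every 2000
#' episodes, epsilon annealed linearly from 1 to 0.1 over the first 1e4
#' episodes, and 1e6 training episodes at full scale (override
#' `total_episodes` for desk-scale runs).
#'
#' @param gamma discount factor in \[0, 1\].
#' @param alpha prioritization exponent (0 gives uniform replay).
#' @param beta importance-sampling exponent in \[0, 1\] (constant, no
#'   annealing).
#' @param lr Adam learning rate.
#' @param batch minibatch size.
#' @param replay_capacity ring-buffer size of the replay memory.
#' @param target_sync_every target-network copy period, in episodes.
#' @param total_episodes number of training episodes.
#' @param eps_start,eps_end,eps_anneal_episodes linear epsilon schedule:
#'   `eps_start` at episode 0 falling to `eps_end` at
#'   `eps_anneal_episodes`, constant afterwards.
#' @param priority_eps floor added to |TD error| so every transition
#'   stays sampleable.
#' @param huber_delta Huber-loss threshold between the quadratic and
#'   linear branches.
#'
#' @return an object of class `learner_config`.
#' @export
learner_config <- function(gamma = 0.9,
                           alpha = 0.6,
                           beta = 0.4,
                           lr = 1e-6,
                           batch = 32,
                           replay_capacity = 1e4,
                           target_sync_every = 2000,
                           total_episodes = 1e6,
                           eps_start = 1,
                           eps_end = 0.1,
                           eps_anneal_episodes = 1e4,
                           priority_eps = 1e-6,
                           huber_delta = 1) {
  stopifnot(
    gamma >= 0, gamma <= 1,
    alpha >= 0,
    beta >= 0, beta <= 1,
    lr > 0,
    batch >= 1,
    replay_capacity >= batch,
    target_sync_every >= 1,
    total_episodes >= 0,
    eps_start >= 0, eps_start <= 1,
    eps_end >= 0, eps_end <= 1,
    eps_anneal_episodes >= 0,
    priority_eps > 0,
    huber_delta > 0
  )
  structure(
    list(
      gamma = gamma, alpha = alpha, beta = beta, lr = lr,
      batch = as.integer(batch),
      replay_capacity = as.integer(replay_capacity),
      target_sync_every = as.integer(target_sync_every),
      total_episodes = as.integer(total_episodes),
      eps_start = eps_start, eps_end = eps_end,
      eps_anneal_episodes = as.integer(eps_anneal_episodes),
      priority_eps = priority_eps, huber_delta = huber_delta
    ),
    class = "learner_config"
  )
}

#' @export
print.learner_config <- function(x, ...) {
  cat("<learner_config>\n")
  cat(sprintf(
    "  gamma %.2f, alpha %.2f, beta %.2f, lr %g, batch %d, replay %d\n",
    x$gamma, x$alpha, x$beta, x$lr, x$batch, x$replay_capacity
  ))
  cat(sprintf(
    "  target sync %d ep, epsilon %.2f -> %.2f over %d ep, %d episodes\n",
    x$target_sync_every, x$eps_start, x$eps_end, x$eps_anneal_episodes,
    x$total_episodes
  ))
  invisible(x)
}

#' Rule-based predator configuration
#'
#' Thresholds of the hand-specified two-predator chaser/blocker policies:
#' the role-branch distance threshold, the edge-avoidance and drive-out
#' coordinate bands, the velocity-alignment angle bins, and the two
#' ambush reference points (bottom and top centre of the arena).
#'
#' @param distance_threshold role-branch distance threshold (length
#'   units).
#' @param ambush_bottom,ambush_top the two ambush reference points, as
#'   `c(x, y)`. The bottom point is used while the prey's y is at or
#'   below 0, the top point otherwise.
#'
#' @return an object of class `rule_config`.
#' @export
rule_config <- function(distance_threshold = 0.4,
                        ambush_bottom = c(-0.1, -0.5),
                        ambush_top = c(0, 0.6)) {
  stopifnot(
    distance_threshold > 0,
    length(ambush_bottom) == 2, length(ambush_top) == 2
  )
  structure(
    list(
      distance_threshold = distance_threshold,
      ambush_bottom = as.numeric(ambush_bottom),
      ambush_top = as.numeric(ambush_top),
      psi_bins = c(-Inf, -50, -15, 15, 50, Inf),
      psi_actions = c(3L, 2L, 1L, 2L, 3L),
      ambush_actions = c(3L, 8L, 12L)
    ),
    class = "rule_config"
  )
}

#' @export
print.rule_config <- function(x, ...) {
  cat(sprintf(
    "<rule_config> branch threshold %.2f, ambush refs (%.2f,%.2f)/(%.2f,%.2f)\n",
    x$distance_threshold, x$ambush_bottom[1], x$ambush_bottom[2],
    x$ambush_top[1], x$ambush_top[2]
  ))
  invisible(x)
}

#' Behavioral-cloning configuration
#'
#' Training constants for cloning a rule-based predator into a
#' one-hidden-layer softmax network: hidden width 32, Adam learning rate
#' 1e-4, minibatch 32, 2000 epochs at full scale.
#'
#' @param hidden hidden-layer width.
#' @param lr Adam learning rate.
#' @param batch minibatch size.
#' @param epochs training epochs (validation accuracy selects the saved
#'   weights).
#' @return an object of class `clone_config`.
#' @export
clone_config <- function(hidden = 32, lr = 1e-4, batch = 32, epochs = 2000) {
  stopifnot(hidden >= 1, lr > 0, batch >= 1, epochs >= 1)
  structure(
    list(
      hidden = as.integer(hidden), lr = lr,
      batch = as.integer(batch), epochs = as.integer(epochs)
    ),
    class = "clone_config"
  )
}

#' Greedy evaluation protocol
#'
#' The study's evaluation recipe: a fixed number of greedy (epsilon = 0)
#' episodes under each of several random seeds that control only the
#' initial positions.
#'
#' @param episodes_per_seed episodes simulated under each seed.
#' @param n_seeds number of distinct seeds.
#' @param condition a [condition_config()].
#' @return an object of class `evaluation_protocol`.
#' @export
evaluation_protocol <- function(episodes_per_seed = 100, n_seeds = 10,
                                condition = condition_config()) {
  stopifnot(
    episodes_per_seed >= 1, n_seeds >= 1,
    inherits(condition, "condition_config")
  )
  structure(
    list(
      episodes_per_seed = as.integer(episodes_per_seed),
      n_seeds = as.integer(n_seeds),
      epsilon = 0,
      condition = condition
    ),
    class = "evaluation_protocol"
  )
}
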