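#' Simulate episodes under fixed policies
#'
#' Runs whole episodes in the C++ core under one policy per agent slot
#' (predators first, prey last), each episode starting from a fresh
#' random initial state ([reset_world()] semantics; control it with
#' `set.seed()`). Episodes end at capture, an arena exit, or the time
#' limit.
#'
#' @param policies list of `agent_policy` objects ([net_policy()],
#'   [rule_policy()], [scripted_policy()]), one per agent.
#' @param condition a [condition_config()].
#' @param episodes number of episodes.
#' @param record if `TRUE`, return the full per-step trajectory table.
#' @param rule_cfg the [rule_config()] used by any rule-based slots.
#' @return list with `outcomes` (one row per episode: `episode`,
#'   `steps`, `duration`, `event`, `catcher`, per-agent returns) and,
#'   when recording, `records` — an `episode_record` data frame with one
#'   row per agent-step and columns `episode`, `step`, `agent`, `role`,
#'   `x`, `y`, `vx`, `vy`, `action`, `reward`, `event`. Positions and
#'   velocities are those at which the action was chosen; `event` labels
#'   the outcome of the step taken from there.
#' @export
simulate_episodes <- function(policies, condition, episodes = 100,
                              record = TRUE, rule_cfg = rule_config()) {
  na <- n_agents(condition)
  if (length(policies) != na) {
    stop("need ", na, " policies (one per agent slot), got ", length(policies))
  }
  stopifnot(all(vapply(policies, inherits, logical(1), "agent_policy")))
  spec <- lapply(policies, function(p) {
    if (p$type == "net") {
      list(type = "net", params = p$params, epsilon = p$epsilon)
    } else if (p$type == "rule") {
      list(type = "rule")
    } else {
      list(
        type = "scripted", name = p$name, noise_sd = p$noise_sd,
        orbit_radius = p$orbit_radius, radial_gain = p$radial_gain,
        flight_distance = p$flight_distance, direction = p$direction
      )
    }
  })
  res <- cpp_rollout(
    unclass(condition), spec, unclass(rule_cfg),
    as.integer(episodes), record
  )
  roles <- agent_labels(condition)
  ret <- res$returns
  colnames(ret) <- paste0("return_", roles)
  outcomes <- data.frame(
    episode = res$episode,
    steps = res$steps,
    duration = res$steps * condition$dt,
    event = event_from_code(res$event),
    catcher = res$catcher
  )
  outcomes <- cbind(outcomes, as.data.frame(ret))
  out <- list(outcomes = outcomes, condition = condition)
  if (record) {
    out$records <- episode_record(data.frame(
      episode = res$rec_episode,
      step = res$rec_step,
      agent = res$rec_agent,
      role = roles[res$rec_agent],
      x = res$rec_x, y = res$rec_y,
      vx = res$rec_vx, vy = res$rec_vy,
      action = res$rec_action,
      reward = res$rec_reward,
      event = event_from_code(res$rec_event)
    ), condition)
  }
  class(out) <- "simulation_result"
  out
}

#' @export
print.simulation_result <- function(x, ...) {
  tab <- table(x$outcomes$event)
  cat(sprintf(
    "<simulation_result> %d episodes: %s\n", nrow(x$outcomes),
    paste(names(tab), as.integer(tab), sep = "=", collapse = ", ")
  ))
  invisible(x)
}

#' Episode record table
#'
#' Tags a per-agent-step trajectory data frame with the condition it
#' was generated under. One row per agent and step; see
#' [simulate_episodes()] for the columns.
#'
#' @param df the trajectory data frame.
#' @param condition the generating [condition_config()].
#' @return the data frame with class `episode_record`.
#' @export
episode_record <- function(df, condition) {
  needed <- c(
    "episode", "step", "agent", "role", "x", "y", "vx", "vy",
    "action", "reward", "event"
  )
  stopifnot(all(needed %in% names(df)))
  structure(df,
    class = c("episode_record", "data.frame"),
    condition = condition
  )
}

#' Generate one scripted fixture episode (R reference path)
#'
#' Steps the R environment under scripted / rule-based / network
#' policies, producing the same record layout as [simulate_episodes()].
#' This is the slow, transparent route used for fixtures and for
#' checking the C++ rollout; both consume RNG draws in the same order,
#' so the two routes produce identical episodes under the same seed.
#'
#' @param policies list of `agent_policy` objects, one per agent.
#' @param condition a [condition_config()].
#' @param episode_id value for the `episode` column.
#' @return an `episode_record` data frame for one episode, with the
#'   outcome row as attribute `outcome`.
#' @export
generate_scripted_episode <- function(policies, condition, episode_id = 1L) {
  na <- n_agents(condition)
  stopifnot(length(policies) == na)
  state <- reset_world(condition)
  # initial draws that already satisfy a terminal predicate are redrawn
  # (the C++ rollout does the same, keeping the RNG streams aligned)
  while (detect_events(state)$event != "none") state <- reset_world(condition)
  roles <- agent_labels(condition)
  rows <- list()
  returns <- numeric(na)
  repeat {
    actions <- vapply(
      seq_len(na),
      function(i) as.integer(policy_action(policies[[i]], state, i)),
      integer(1)
    )
    out <- step_world(state, actions)
    rows[[length(rows) + 1L]] <- data.frame(
      episode = episode_id,
      step = state$step,
      agent = seq_len(na),
      role = roles,
      x = state$positions[, 1], y = state$positions[, 2],
      vx = state$velocities[, 1], vy = state$velocities[, 2],
      action = actions,
      reward = out$rewards,
      event = out$event
    )
    returns <- returns + out$rewards
    state <- out$state
    if (out$terminal) break
  }
  rec <- do.call(rbind, rows)
  outcome <- data.frame(
    episode = episode_id,
    steps = state$step,
    duration = state$step * condition$dt,
    event = out$event,
    catcher = if (out$event == "capture") out$who else NA_integer_
  )
  for (i in seq_len(na)) outcome[[paste0("return_", roles[i])]] <- returns[i]
  structure(
    episode_record(rec, condition),
    outcome = outcome
  )
}

#' Write / read episode records
#'
#' Serialization of the columnar trajectory table: plain CSV (loses the
#' condition attribute) or a binary RDS container (round-trips the
#' `episode_record` object exactly, condition included).
#'
#' @param records an `episode_record`.
#' @param path file path.
#' @return `read_episode_csv()` returns the data frame (untagged;
#'   re-attach a condition with [episode_record()] if needed);
#'   `read_episode_rds()` returns the `episode_record`.
#' @export
write_episode_csv <- function(records, path) {
  utils::write.csv(as.data.frame(records), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_episode_csv
#' @export
read_episode_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname write_episode_csv
#' @export
write_episode_rds <- function(records, path) {
  stopifnot(inherits(records, "episode_record"))
  saveRDS(records, path)
  invisible(path)
}

#' @rdname write_episode_csv
#' @export
read_episode_rds <- function(path) {
  out <- readRDS(path)
  stopifnot(inherits(out, "episode_record"))
  out
}
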