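#' Greedy evaluation over seeds
#'
#' Runs the evaluation protocol: for each seed, `episodes_per_seed`
#' greedy episodes (epsilon forced to 0 on network policies; rule-based
#' and deterministic scripted policies are greedy by construction). The
#' seed controls only the random initial positions, so rerunning with
#' the same seeds reproduces the summary exactly.
#'
#' @param policies list of `agent_policy` objects, one per agent slot.
#' @param protocol an [evaluation_protocol()].
#' @param seeds integer seeds, one per protocol seed slot; defaults to
#'   `seq_len(n_seeds)`.
#' @param record if `TRUE`, keep the full trajectory tables.
#' @param rule_cfg the [rule_config()] for rule-based slots.
#' @return list with `outcomes` (all episodes, with a `seed` column),
#'   `summary` (an [summarize_outcomes()] result) and, when recording,
#'   `records` (with a `seed` column).
#' @export
evaluate_policies <- function(policies, protocol, seeds = NULL,
                              record = FALSE, rule_cfg = rule_config()) {
  stopifnot(inherits(protocol, "evaluation_protocol"))
  if (is.null(seeds)) seeds <- seq_len(protocol$n_seeds)
  stopifnot(length(seeds) == protocol$n_seeds, !anyDuplicated(seeds))
  policies <- lapply(policies, function(p) {
    if (p$type == "net") p$epsilon <- protocol$epsilon
    p
  })
  outs <- vector("list", length(seeds))
  recs <- vector("list", length(seeds))
  for (k in seq_along(seeds)) {
    set.seed(seeds[k])
    sim <- simulate_episodes(
      policies, protocol$condition, protocol$episodes_per_seed,
      record = record, rule_cfg = rule_cfg
    )
    sim$outcomes$seed <- seeds[k]
    outs[[k]] <- sim$outcomes
    if (record) {
      sim$records$seed <- seeds[k]
      recs[[k]] <- sim$records
    }
  }
  outcomes <- do.call(rbind, outs)
  out <- list(
    outcomes = outcomes,
    summary = summarize_outcomes(outcomes)
  )
  if (record) {
    rec <- do.call(rbind, lapply(recs, as.data.frame))
    out$records <- episode_record(rec, protocol$condition)
  }
  out
}

#' The study's condition grid
#'
#' Full factorial of predator count (1-3), relative mobility
#' (fast / equal / slow) and reward sharing (individual / shared), with
#' the sharing factor collapsed in the one-predator cells where it is
#' meaningless: 15 cells in total.
#'
#' @return data frame with columns `n_predators`, `mobility`,
#'   `sharing`.
#' @export
condition_grid <- function() {
  g <- expand.grid(
    n_predators = 1:3,
    mobility = c("fast", "equal", "slow"),
    sharing = c("individual", "shared"),
    stringsAsFactors = FALSE
  )
  g$sharing[g$n_predators == 1] <- "individual"
  g <- unique(g)
  rownames(g) <- NULL
  g[order(g$n_predators, g$mobility, g$sharing), ]
}

#' Train and evaluate every cell of a condition grid
#'
#' For each grid row: trains independent learners under the cell's
#' condition, then evaluates the final greedy policies under the
#' protocol. At the full-scale learner defaults this is a very long
#' computation; pass a desk-scale [learner_config()] for exploratory
#' runs.
#'
#' @param grid data frame as from [condition_grid()] (possibly a
#'   subset).
#' @param learner a [learner_config()].
#' @param protocol_episodes,protocol_seeds evaluation protocol size.
#' @param base_seed seed offset; cell k trains under
#'   `base_seed + k` and evaluates under seeds derived from it.
#' @param ... physics arguments forwarded to [condition_config()].
#' @return data frame: one row per cell with the success proportion,
#'   SEM and mean duration, plus the list of `training_run`s as
#'   attribute `runs`.
#' @export
run_condition_grid <- function(grid = condition_grid(),
                               learner = learner_config(),
                               protocol_episodes = 100,
                               protocol_seeds = 10,
                               base_seed = 1,
                               ...) {
  if (nrow(grid) == 0) {
    return(structure(data.frame(), runs = list()))
  }
  rows <- vector("list", nrow(grid))
  runs <- vector("list", nrow(grid))
  for (k in seq_len(nrow(grid))) {
    cond <- condition_config(
      n_predators = grid$n_predators[k],
      mobility = grid$mobility[k],
      sharing = grid$sharing[k],
      ...
    )
    set.seed(base_seed + k)
    run <- train_agents(cond, learner)
    pol <- lapply(run$params, net_policy)
    ev <- evaluate_policies(
      pol,
      evaluation_protocol(protocol_episodes, protocol_seeds, cond),
      seeds = base_seed * 1000 + seq_len(protocol_seeds)
    )
    rows[[k]] <- data.frame(
      n_predators = grid$n_predators[k],
      mobility = grid$mobility[k],
      sharing = grid$sharing[k],
      H = ev$summary$H,
      H_sem = ev$summary$H_sem,
      mean_duration = ev$summary$mean_duration
    )
    runs[[k]] <- run
  }
  structure(do.call(rbind, rows), runs = runs)
}

# Polynomial rolling hash over the serialized object (mod 2^31 - 1);
# stable fingerprint for matching checkpoints to the configuration
# that produced them.
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 0
  for (b in bytes) h <- (h * 257 + b + 1) %% 2147483647
  sprintf("%08x", h)
}

#' Save / load a training run
#'
#' A run directory holds the configuration as YAML (with a fingerprint
#' of the condition + learner configuration), the per-agent weights,
#' the per-episode log as CSV, and optionally checkpoints. Loading
#' recomputes the fingerprint and refuses a directory whose
#' configuration no longer matches its weights.
#'
#' @param run a `training_run` from [train_agents()].
#' @param dir directory to create/use.
#' @return `save_run()` the directory invisibly; `load_run()` the
#'   restored `training_run`.
#' @export
save_run <- function(run, dir) {
  stopifnot(inherits(run, "training_run"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- list(
    condition = unclass(run$condition),
    learner = unclass(run$learner),
    hash = config_hash(list(unclass(run$condition), unclass(run$learner)))
  )
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  saveRDS(
    list(
      params = run$params, checkpoints = run$checkpoints,
      checkpoint_episodes = run$checkpoint_episodes
    ),
    file.path(dir, "weights.rds")
  )
  utils::write.csv(run$log, file.path(dir, "log.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname save_run
#' @export
load_run <- function(dir) {
  cfg <- yaml::read_yaml(file.path(dir, "config.yaml"))
  condition <- do.call(condition_config, cfg$condition)
  learner <- do.call(learner_config, cfg$learner)
  hash <- config_hash(list(unclass(condition), unclass(learner)))
  if (!identical(hash, cfg$hash)) {
    stop(
      "configuration fingerprint mismatch: stored ", cfg$hash,
      ", recomputed ", hash
    )
  }
  w <- readRDS(file.path(dir, "weights.rds"))
  log <- utils::read.csv(file.path(dir, "log.csv"))
  structure(
    list(
      params = w$params, checkpoints = w$checkpoints,
      checkpoint_episodes = w$checkpoint_episodes,
      log = log, condition = condition, learner = learner
    ),
    class = "training_run"
  )
}
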