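#' Exploration schedule
#'
#' Epsilon falls linearly from `eps_start` at episode 0 to `eps_end` at
#' episode `eps_anneal_episodes` and stays there.
#'
#' @param episode 0-based episode index.
#' @param config a [learner_config()].
#' @return epsilon in \[0, 1\].
#' @export
epsilon_schedule <- function(episode, config = learner_config()) {
  stopifnot(all(episode >= 0))
  n <- config$eps_anneal_episodes
  frac <- if (n > 0) pmin(episode / n, 1) else 1
  config$eps_start + (config$eps_end - config$eps_start) * frac
}

#' Double-DQN learning targets
#'
#' The online network chooses the next action, the target network
#' evaluates it:
#' \deqn{y = r + \gamma\, Q_{target}(s', \arg\max_{a'} Q_{online}(s', a')),}
#' with no bootstrap on terminal transitions. With identical online and
#' target weights this reduces to the plain max-bootstrap target.
#'
#' @param batch list of [transition()]s.
#' @param online,target `policy_params` of the online and target nets.
#' @param gamma discount factor.
#' @return numeric vector of per-item targets.
#' @export
ddqn_target <- function(batch, online, target, gamma = 0.9) {
  vapply(batch, function(t) {
    if (t$terminal) {
      return(t$r)
    }
    astar <- which.max(q_forward(online, t$s2)$Q)
    t$r + gamma * q_forward(target, t$s2)$Q[astar]
  }, numeric(1))
}

#' Huber loss
#'
#' Quadratic inside `|r| <= delta`, linear outside:
#' \eqn{0.5 r^2} vs \eqn{\delta(|r| - 0.5\delta)}. The linear tails are
#' what keeps large TD errors from producing extreme gradient updates.
#'
#' @param residual numeric residuals.
#' @param delta branch threshold.
#' @return elementwise loss values.
#' @export
huber_loss <- function(residual, delta = 1) {
  a <- abs(residual)
  ifelse(a <= delta, 0.5 * residual^2, delta * (a - 0.5 * delta))
}

huber_grad <- function(residual, delta = 1) {
  pmin(pmax(residual, -delta), delta)
}

#' Importance-weighted Huber loss and its gradients
#'
#' The training objective for one minibatch: the mean over items of
#' `weight * Huber(y - Q(s, a))`. Gradients flow only through the
#' selected action value `Q(s, a)` (via the dueling aggregation), never
#' through the target `y`. This is the reference implementation the
#' fused C++ learner is checked against; gradients are returned for
#' every parameter array of the network.
#'
#' @param batch list of [transition()]s.
#' @param targets per-item targets from [ddqn_target()].
#' @param weights per-item importance-sampling weights.
#' @param online `policy_params` of the online network.
#' @param huber_delta Huber threshold.
#' @return list with `loss` (scalar), `td_errors` (per item), and
#'   `grads` (list shaped like the `policy_params`).
#' @export
loss_and_grads <- function(batch, targets, weights, online,
                           huber_delta = 1) {
  B <- length(batch)
  stopifnot(length(targets) == B, length(weights) == B)
  g <- lapply(online, function(x) array(0, dim = dim(x) %||% length(x)))
  loss <- 0
  td <- numeric(B)
  for (b in seq_len(B)) {
    t <- batch[[b]]
    s <- t$s
    h1p <- as.numeric(online$W1 %*% s) + online$b1
    h1 <- relu(h1p)
    h2p <- as.numeric(online$W2 %*% h1) + online$b2
    h2 <- relu(h2p)
    hap <- as.numeric(online$Wa1 %*% h2) + online$ba1
    ha <- relu(hap)
    A <- as.numeric(online$Wa2 %*% ha) + online$ba2
    hvp <- as.numeric(online$Wv1 %*% h2) + online$bv1
    hv <- relu(hvp)
    V <- as.numeric(online$Wv2 %*% hv) + online$bv2
    Q <- V + A - mean(A)
    a <- t$a
    delta <- targets[b] - Q[a]
    td[b] <- delta
    loss <- loss + weights[b] * huber_loss(delta, huber_delta)
    gq <- -(weights[b] * huber_grad(delta, huber_delta)) / B

    gA <- gq * (as.numeric(seq_len(13) == a) - 1 / 13)
    gV <- gq
    # value head
    g$Wv2 <- g$Wv2 + gV * matrix(hv, 1)
    g$bv2 <- g$bv2 + gV
    ghv <- gV * as.numeric(online$Wv2) * (hvp > 0)
    g$Wv1 <- g$Wv1 + ghv %o% h2
    g$bv1 <- g$bv1 + ghv
    # advantage head
    g$Wa2 <- g$Wa2 + gA %o% ha
    g$ba2 <- g$ba2 + gA
    gha <- as.numeric(t(online$Wa2) %*% gA) * (hap > 0)
    g$Wa1 <- g$Wa1 + gha %o% h2
    g$ba1 <- g$ba1 + gha
    # trunk
    gh2 <- (as.numeric(t(online$Wa1) %*% gha) +
      as.numeric(t(online$Wv1) %*% ghv)) * (h2p > 0)
    g$W2 <- g$W2 + gh2 %o% h1
    g$b2 <- g$b2 + gh2
    gh1 <- as.numeric(t(online$W2) %*% gh2) * (h1p > 0)
    g$W1 <- g$W1 + gh1 %o% s
    g$b1 <- g$b1 + gh1
  }
  list(loss = loss / B, td_errors = td, grads = g)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Train independent learners in a condition
#'
#' Runs the full independent-learning loop in the fused C++ core: every
#' agent (predators and prey) owns its network, target network, Adam
#' optimizer and prioritized replay memory; acting is epsilon-greedy
#' under the annealed schedule; each agent takes one prioritized
#' double-DQN gradient step per environment step once its memory holds
#' a full minibatch; target networks are refreshed every
#' `target_sync_every` episodes. Fully reproducible under `set.seed()`.
#'
#' @param condition a [condition_config()].
#' @param learner a [learner_config()]; set `total_episodes` for
#'   desk-scale runs.
#' @param init_params optional list of `policy_params`, one per agent;
#'   drawn fresh (from R's RNG) when omitted.
#' @param checkpoint_at episode numbers at which to snapshot all
#'   weights; defaults to every 10% of the run plus the final episode.
#' @return an object of class `training_run`: list with `params` (final
#'   per-agent weights), `checkpoints` + `checkpoint_episodes`, `log`
#'   (per-episode data frame: steps, event, per-agent return, epsilon,
#'   per-agent mean loss), `condition`, `learner`.
#' @export
train_agents <- function(condition, learner = learner_config(),
                         init_params = NULL, checkpoint_at = NULL) {
  na <- n_agents(condition)
  dim <- state_vector_length(condition)
  if (is.null(init_params)) {
    init_params <- replicate(na, init_policy_params(dim), simplify = FALSE)
  }
  stopifnot(length(init_params) == na)
  if (is.null(checkpoint_at)) {
    checkpoint_at <- unique(pmax(
      1L,
      round(seq(0.1, 1, by = 0.1) * learner$total_episodes)
    ))
    if (learner$total_episodes == 0) checkpoint_at <- integer(0)
  }
  if (learner$total_episodes == 0) {
    return(structure(
      list(
        params = init_params, checkpoints = list(),
        checkpoint_episodes = integer(0),
        log = data.frame(), condition = condition, learner = learner
      ),
      class = "training_run"
    ))
  }
  res <- cpp_train(
    unclass(condition), init_params, learner$gamma, learner$alpha,
    learner$beta, learner$lr, learner$batch, learner$replay_capacity,
    learner$target_sync_every, learner$total_episodes, learner$eps_start,
    learner$eps_end, learner$eps_anneal_episodes, learner$priority_eps,
    learner$huber_delta, as.integer(checkpoint_at)
  )
  ret <- res$log_return
  loss <- res$log_loss
  colnames(ret) <- paste0("return_", agent_labels(condition))
  colnames(loss) <- paste0("loss_", agent_labels(condition))
  log <- data.frame(
    episode = res$log_episode,
    steps = res$log_steps,
    event = event_from_code(res$log_event),
    epsilon = res$log_epsilon
  )
  log <- cbind(log, as.data.frame(ret), as.data.frame(loss))
  structure(
    list(
      params = res$params,
      checkpoints = res$checkpoints,
      checkpoint_episodes = res$checkpoint_episodes,
      log = log,
      condition = condition,
      learner = learner
    ),
    class = "training_run"
  )
}

#' @export
print.training_run <- function(x, ...) {
  n <- nrow(x$log)
  cat(sprintf(
    "<training_run> %d episodes, %d agent(s), %d checkpoint(s)\n",
    n, length(x$params), length(x$checkpoints)
  ))
  if (n > 0) {
    tail_n <- max(1, round(n / 10))
    tail_log <- x$log[seq(n - tail_n + 1, n), ]
    cat(sprintf(
      "  last %d%%: mean steps %.1f, capture rate %.3f\n",
      round(100 * tail_n / n), mean(tail_log$steps),
      mean(tail_log$event == "capture")
    ))
  }
  invisible(x)
}

agent_labels <- function(condition) {
  c(paste0("pred", seq_len(condition$n_predators)), "prey")
}
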