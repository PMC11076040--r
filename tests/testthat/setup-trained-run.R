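# Shared expensive fixture: one scaled-down independent-learning run in
# the one-predator fast condition (2e4 episodes, paper hyperparameters
# otherwise), with checkpoints at thirds. Trained once here and reused
# by the learning-trajectory and acceptance tests.

trained_cache <- new.env(parent = emptyenv())

scaled_run <- function() {
  if (is.null(trained_cache$run)) {
    cond <- condition_config(1, "fast", "individual")
    lc <- learner_config(total_episodes = 2e4)
    set.seed(101)
    trained_cache$run <- train_agents(
      cond, lc,
      checkpoint_at = c(6667, 13334, 20000)
    )
    trained_cache$condition <- cond
  }
  trained_cache$run
}

scaled_condition <- function() {
  scaled_run()
  trained_cache$condition
}
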