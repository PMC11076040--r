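test_that("epsilon anneals linearly then stays at the floor", {
  cfg <- learner_config()
  expect_equal(epsilon_schedule(0, cfg), 1)
  expect_equal(epsilon_schedule(5000, cfg), 0.55)
  expect_equal(epsilon_schedule(1e4, cfg), 0.1)
  expect_equal(epsilon_schedule(5e5, cfg), 0.1)
})

test_that("double-DQN targets bootstrap through the online argmax", {
  set.seed(11)
  online <- init_policy_params(8)
  target <- init_policy_params(8)
  batch <- lapply(1:6, function(i) {
    transition(stats::rnorm(8), sample(13, 1), sample(c(-1, 0, 1), 1),
      stats::rnorm(8),
      terminal = i <= 2
    )
  })
  y <- ddqn_target(batch, online, target, gamma = 0.9)
  # terminal items carry no bootstrap; gamma 0 reduces to the reward
  expect_equal(y[1:2], vapply(batch[1:2], `[[`, numeric(1), "r"))
  expect_equal(
    ddqn_target(batch, online, target, gamma = 0),
    vapply(batch, `[[`, numeric(1), "r")
  )
  # brute-force oracle: enumerate all 13 actions explicitly
  for (i in 3:6) {
    qo <- oracle_forward(online, batch[[i]]$s2)$Q
    qt <- oracle_forward(target, batch[[i]]$s2)$Q
    expect_equal(y[i], batch[[i]]$r + 0.9 * qt[which.max(qo)],
      tolerance = 1e-10
    )
  }
  # online == target collapses to the plain max bootstrap
  y2 <- ddqn_target(batch, online, online, gamma = 0.9)
  for (i in 3:6) {
    expect_equal(
      y2[i],
      batch[[i]]$r + 0.9 * max(oracle_forward(online, batch[[i]]$s2)$Q),
      tolerance = 1e-10
    )
  }
})

test_that("Huber loss matches its piecewise closed form", {
  expect_equal(huber_loss(0.5), 0.125)
  expect_equal(huber_loss(10), 9.5)
  expect_equal(huber_loss(-10), 9.5)
  expect_equal(huber_loss(c(0, 1, -1)), c(0, 0.5, 0.5))
  # and through the minibatch objective with unit weight
  set.seed(12)
  online <- init_policy_params(8)
  t1 <- transition(stats::rnorm(8), 4, 0, stats::rnorm(8), TRUE)
  q <- q_forward(online, t1$s)$Q[4]
  out <- loss_and_grads(list(t1), q + 0.5, 1, online)
  expect_equal(out$loss, 0.125, tolerance = 1e-10)
  out2 <- loss_and_grads(list(t1), q + 10, 1, online)
  expect_equal(out2$loss, 9.5, tolerance = 1e-9)
})

test_that("exact targets give zero loss and zero gradients", {
  set.seed(13)
  online <- init_policy_params(8)
  batch <- lapply(1:3, function(i) {
    transition(stats::rnorm(8), i, 0, stats::rnorm(8), TRUE)
  })
  y <- vapply(
    seq_along(batch),
    function(i) q_forward(online, batch[[i]]$s)$Q[batch[[i]]$a],
    numeric(1)
  )
  out <- loss_and_grads(batch, y, rep(1, 3), online)
  expect_equal(out$loss, 0, tolerance = 1e-20)
  expect_lt(max(abs(unlist(out$grads))), 1e-12)
  # with an exactly-zero network the gradients vanish identically
  z <- zero_params(8)
  yz <- rep(0, 3)
  outz <- loss_and_grads(batch, yz, rep(1, 3), z)
  expect_identical(outz$loss, 0)
  for (g in outz$grads) expect_true(all(g == 0))
})

test_that("gradients agree with finite differences", {
  set.seed(14)
  online <- init_policy_params(6)
  batch <- lapply(1:4, function(i) {
    transition(stats::rnorm(6), sample(13, 1), 0, stats::rnorm(6), TRUE)
  })
  y <- stats::rnorm(4)
  w <- stats::runif(4, 0.5, 1)
  out <- loss_and_grads(batch, y, w, online)
  eps <- 1e-6
  for (nm in c("W1", "ba2", "Wv2", "b2", "Wa1")) {
    idx <- sample(length(online[[nm]]), 3)
    for (j in idx) {
      up <- online
      up[[nm]][j] <- up[[nm]][j] + eps
      dn <- online
      dn[[nm]][j] <- dn[[nm]][j] - eps
      fd <- (loss_and_grads(batch, y, w, up)$loss -
        loss_and_grads(batch, y, w, dn)$loss) / (2 * eps)
      expect_equal(as.numeric(out$grads[[nm]][j]), fd, tolerance = 1e-4)
    }
  }
})

test_that("minibatch loss is invariant under permuting the batch", {
  set.seed(15)
  online <- init_policy_params(8)
  batch <- lapply(1:8, function(i) {
    transition(stats::rnorm(8), sample(13, 1), 0, stats::rnorm(8), TRUE)
  })
  y <- stats::rnorm(8)
  w <- stats::runif(8)
  l1 <- loss_and_grads(batch, y, w, online)$loss
  p <- sample(8)
  l2 <- loss_and_grads(batch[p], y[p], w[p], online)$loss
  expect_equal(l1, l2, tolerance = 1e-12)
})

test_that("training runs are seed-reproducible and zero-episode runs are no-ops", {
  cond <- tiny_cond(1, "fast")
  lc <- learner_config(total_episodes = 0)
  set.seed(30)
  init <- replicate(2, init_policy_params(8), simplify = FALSE)
  run0 <- train_agents(cond, lc, init_params = init)
  expect_identical(run0$params, init)
  expect_equal(nrow(run0$log), 0)

  lc <- learner_config(total_episodes = 25)
  set.seed(31)
  a <- train_agents(cond, lc, checkpoint_at = c(10, 25))
  set.seed(31)
  b <- train_agents(cond, lc, checkpoint_at = c(10, 25))
  expect_identical(a$checkpoints, b$checkpoints)
  expect_identical(a$log, b$log)
  expect_equal(a$checkpoint_episodes, c(10, 25))
  # weights actually moved
  expect_false(identical(a$params[[1]]$W1, a$checkpoints[[1]][[1]]$W1))
  # log invariants: epsilon schedule recorded, rewards in range
  expect_equal(a$log$epsilon, epsilon_schedule(0:24, lc))
  expect_true(all(a$log$return_prey %in% c(-1, 0)))
  expect_true(all(a$log$return_pred1 %in% c(-1, 0, 1)))
})
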