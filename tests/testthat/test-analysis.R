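test_that("outcome summaries count captures and prey exits as predator success", {
  oc <- data.frame(
    event = c(
      rep("capture", 50), rep("prey_out", 10),
      rep("timeout", 40)
    ),
    duration = c(rep(5, 60), rep(30, 40))
  )
  s <- summarize_outcomes(oc)
  expect_equal(s$H, 0.6)
  expect_equal(s$n_episodes, 100)
  all_cap <- data.frame(event = rep("capture", 100), duration = rep(2, 100))
  expect_equal(summarize_outcomes(all_cap)$H, 1)
  all_to <- data.frame(event = rep("timeout", 20), duration = rep(30, 20))
  s2 <- summarize_outcomes(all_to)
  expect_equal(s2$H, 0)
  expect_equal(s2$mean_duration, 30)
  # per-seed SEM: two seeds with H 0.4 and 0.6 give mean 0.5, sem 0.1
  oc$seed <- rep(c(1, 2), 50)
  oc$event[oc$seed == 1] <- rep(c("capture", "timeout"), c(20, 30))
  oc$event[oc$seed == 2] <- rep(c("capture", "timeout"), c(30, 20))
  s3 <- summarize_outcomes(oc)
  expect_equal(s3$H, 0.5)
  expect_equal(s3$H_sem, 0.1)
  # predator and prey successes partition the episodes
  expect_equal(
    sum(s3$per_seed$H * s3$per_seed$n) +
      sum((1 - s3$per_seed$H) * s3$per_seed$n),
    nrow(oc)
  )
  expect_error(summarize_outcomes(oc[0, ]), "no episodes")
})

test_that("the independence prediction is exact and monotone", {
  expect_equal(theoretical_prediction(0.5, 2), 0.75)
  expect_equal(theoretical_prediction(0, 1:3), c(0, 0, 0))
  expect_equal(theoretical_prediction(1, 1:3), c(1, 1, 1))
  expect_equal(theoretical_prediction(0.2, 3), 1 - 0.8^3)
  for (H1 in seq(0.05, 0.95, by = 0.05)) {
    Hn <- theoretical_prediction(H1, 1:5)
    expect_true(all(diff(Hn) > 0))
    expect_gte(Hn[1], H1 - 1e-12)
  }
  expect_error(theoretical_prediction(1.2, 2))
  expect_error(theoretical_prediction(0.5, 0))
})

test_that("heat maps conserve counts and localize a stationary agent", {
  cond <- condition_config(2, "slow", "shared")
  rec <- synthetic_records(data.frame(
    episode = 1L, agent = 1L,
    x = rep(0.31, 25), y = rep(-0.62, 25)
  ), cond)
  h <- heat_map(rec, 1)
  expect_equal(sum(h), 25)
  expect_equal(max(h), 25) # a single bin holds everything
  expect_equal(dim(h), c(40L, 40L))
  # conservation under arbitrary positions, including boundary clamps
  set.seed(81)
  rec2 <- synthetic_records(data.frame(
    episode = 1L, agent = 2L,
    x = stats::runif(500, -1.05, 1.05), y = stats::runif(500, -1.05, 1.05)
  ), cond)
  expect_equal(sum(heat_map(rec2, 2)), 500)
  expect_equal(sum(heat_map(rec2, 2, bins = 17)), 500)
})

test_that("heat-map correlation is 1 on itself, NA when constant, 0 under the null", {
  cond <- condition_config(2, "slow", "shared")
  set.seed(82)
  rec <- synthetic_records(data.frame(
    episode = 1L, agent = rep(1:2, each = 2000),
    x = stats::runif(4000, -1, 1), y = stats::runif(4000, -1, 1)
  ), cond)
  h1 <- heat_map(rec, 1)
  h2 <- heat_map(rec, 2)
  expect_equal(heatmap_correlation(h1, h1), 1)
  # two independent uniform occupancies: r inside the permutation null band
  r_obs <- heatmap_correlation(h1, h2)
  null_r <- replicate(200, stats::cor(sample(as.numeric(h1)), as.numeric(h2)))
  expect_lt(abs(r_obs), max(abs(stats::quantile(null_r, c(0.005, 0.995)))) + 0.02)
  # scaling invariance: counts vs frequencies give the same r
  h1f <- h1
  class(h1f) <- "heat_map"
  h1f[] <- h1 / sum(h1)
  expect_equal(heatmap_correlation(h1f, h2), r_obs, tolerance = 1e-12)
  const <- h1
  const[] <- 3L
  expect_warning(rc <- heatmap_correlation(const, h2), "constant")
  expect_true(is.na(rc))
})

test_that("concordance is 1 against itself, 0 against a disjoint policy, chance against noise", {
  cond1 <- tiny_cond(1, "fast")
  set.seed(83)
  params <- init_policy_params(8)
  rec <- generate_scripted_episode(
    list(net_policy(params), scripted_policy("evasive")), cond1
  )
  expect_equal(as.numeric(concordance_rate(rec, params)), 1)
  # a policy that always picks action 1 never matches all-13 records
  rec13 <- generate_scripted_episode(
    list(scripted_policy("stationary"), scripted_policy("evasive")), cond1
  )
  expect_equal(as.numeric(concordance_rate(rec13, zero_params(8))), 0)
  # uniform-random recorded actions vs a fixed policy: about 1/12
  set.seed(84)
  recs <- lapply(1:12, function(k) {
    generate_scripted_episode(
      list(scripted_policy("random_walk"), scripted_policy("evasive")),
      cond1, k
    )
  })
  rec_rand <- episode_record(do.call(rbind, recs), cond1)
  cr <- as.numeric(concordance_rate(rec_rand, params))
  n <- sum(rec_rand$agent == 1)
  expect_lt(abs(cr - 1 / 12), 4 * sqrt((1 / 12) * (11 / 12) / n) + 0.01)
})

test_that("concordance projects the multi-predator state onto the solo layout", {
  cond2 <- condition_config(2, "slow", "shared")
  set.seed(85)
  solo <- init_policy_params(8)
  sim <- simulate_episodes(
    list(rule_policy(), rule_policy(), scripted_policy("evasive")),
    cond2, 3
  )
  rec <- sim$records
  cr <- concordance_rate(rec, solo)
  expect_length(attr(cr, "per_predator"), 2)
  # oracle: rebuild each predator-1 state as a one-predator world (the
  # deleted-block projection is exactly "predator 1 alone with the prey")
  # and query the solo net through the ordinary featurization
  hand <- logical(0)
  for (ep in unique(rec$episode)) {
    d <- rec[rec$episode == ep, ]
    for (s in unique(d$step)) {
      row <- d[d$step == s, ]
      w1 <- world_state(
        cbind(row$x, row$y)[c(1, 3), ], cbind(row$vx, row$vy)[c(1, 3), ],
        s, tiny_cond(1, "slow")
      )
      svec <- build_state_vector(w1, 1)
      hand <- c(hand, which.max(q_forward(solo, svec)$Q) == row$action[1])
    }
  }
  expect_equal(attr(cr, "per_predator")[1], mean(hand), tolerance = 1e-12)
})

test_that("circular correlation matches the direct-formula oracle and drops 13s", {
  a <- c(1, 3, 5, 7, 9, 11, 2, 4, 13, 6)
  b <- c(2, 4, 6, 8, 10, 12, 3, 5, 7, 13)
  r <- circular_correlation(a, b)
  expect_equal(r, oracle_circcor(a, b), tolerance = 1e-12)
  # pairs with 13 were dropped: recompute on the clean subset
  keep <- a != 13 & b != 13
  expect_equal(r, circular_correlation(a[keep], b[keep]))
  # identical varied sequences correlate perfectly
  expect_equal(circular_correlation(a[keep], a[keep]), 1)
  # rotating both sequences by a common angle leaves r unchanged
  rot <- function(x, k) ((x - 1 + k) %% 12) + 1
  expect_equal(circular_correlation(rot(a[keep], 5), rot(b[keep], 5)), r,
    tolerance = 1e-9
  )
  # reflecting one sequence flips the sign
  refl <- function(x) ((12 - (x - 1)) %% 12) + 1
  expect_equal(circular_correlation(a[keep], refl(b[keep])), -r,
    tolerance = 1e-9
  )
  expect_error(circular_correlation(c(13, 13, 1), c(1, 2, 13)), "pairs")
})

test_that("distance-moved shares match hand-integrated path lengths", {
  cond <- condition_config(2, "slow", "shared")
  # predator 1 walks a unit square (path 0.8), predator 2 stays put
  df <- data.frame(
    episode = 1L,
    step = rep(0:4, times = 3),
    agent = rep(1:3, each = 5),
    x = c(0, 0.2, 0.2, 0, 0, rep(0.5, 5), rep(-0.5, 5)),
    y = c(0, 0, 0.2, 0.2, 0, rep(0.5, 5), rep(-0.5, 5))
  )
  rec <- synthetic_records(df, cond)
  shares <- distance_moved_ratio(rec)
  expect_equal(as.numeric(shares), c(1, 0))
  # unequal scripted speeds: shares equal the hand-computed ratio
  df2 <- df
  df2$x[df2$agent == 2] <- seq(0, 0.4, by = 0.1)
  rec2 <- synthetic_records(df2, cond)
  s2 <- distance_moved_ratio(rec2)
  expect_equal(as.numeric(s2), c(0.8, 0.4) / 1.2, tolerance = 1e-12)
  # identical trajectories split evenly
  df3 <- df
  df3$x[df3$agent == 2] <- df3$x[df3$agent == 1]
  df3$y[df3$agent == 2] <- df3$y[df3$agent == 1]
  expect_equal(
    as.numeric(distance_moved_ratio(synthetic_records(df3, cond))),
    c(0.5, 0.5)
  )
  df4 <- df
  df4$x <- 0
  df4$y <- 0
  expect_error(distance_moved_ratio(synthetic_records(df4, cond)), "movement")
})

test_that("embeddings are 2-D with percentile-clipped channels", {
  set.seed(86)
  hidden <- rbind(
    matrix(stats::rnorm(30 * 32, mean = 0), 30, 32),
    matrix(stats::rnorm(30 * 32, mean = 4), 30, 32)
  )
  ch <- data.frame(V = stats::rnorm(60), sd_Q = stats::runif(60))
  emb <- embed_representations(hidden, ch, perplexity = 8, max_iter = 120)
  expect_equal(dim(emb$coords), c(60L, 2L))
  # clip bounds equal the order-statistics oracle
  sv <- sort(ch$V)
  expect_equal(
    emb$clip_bounds[, "V"],
    stats::quantile(ch$V, c(0.05, 0.95), names = FALSE),
    ignore_attr = TRUE
  )
  expect_equal(
    unname(emb$clip_bounds["p05", "sd_Q"]),
    unname(stats::quantile(ch$sd_Q, 0.05))
  )
  # the two well-separated clusters stay separated in the embedding
  d_within <- stats::dist(emb$coords[1:30, ])
  centroid1 <- colMeans(emb$coords[1:30, ])
  centroid2 <- colMeans(emb$coords[31:60, ])
  expect_gt(sqrt(sum((centroid1 - centroid2)^2)), stats::median(d_within))
  expect_error(embed_representations(hidden[1, , drop = FALSE]), "2 states")
  expect_error(
    embed_representations(matrix(1, 10, 5)),
    "identical"
  )
})

test_that("representation collection rebuilds states and channels from records", {
  cond <- tiny_cond(1, "fast")
  set.seed(87)
  params <- init_policy_params(8)
  rec <- generate_scripted_episode(
    list(net_policy(params), scripted_policy("evasive")), cond
  )
  rep1 <- collect_representations(rec, params, 1)
  n <- sum(rec$agent == 1)
  expect_equal(dim(rep1$advantage), c(n, 32L))
  expect_equal(dim(rep1$value), c(n, 32L))
  expect_equal(names(rep1$channels), c("V", "sd_Q", "dist_pred1"))
  # constant Q would give sd 0; here just check sd_Q is the row sd of Q
  S <- collabhunt:::rebuild_state_vectors(rec, 1)
  f <- q_forward(params, S)
  expect_equal(rep1$channels$sd_Q, apply(f$Q, 1, stats::sd))
  # distances match the logged geometry
  p1 <- rec[rec$agent == 1, ]
  pr <- rec[rec$agent == 2, ]
  expect_equal(
    rep1$channels$dist_pred1,
    sqrt((p1$x - pr$x)^2 + (p1$y - pr$y)^2)
  )
})
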