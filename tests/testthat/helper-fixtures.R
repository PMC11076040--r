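# Shared fixtures: tiny conditions, hand-placed worlds, and independent
# oracle implementations used to cross-check the package's operations.

tiny_cond <- function(n_predators = 1, mobility = "equal", ...) {
  condition_config(n_predators = n_predators, mobility = mobility, ...)
}

make_world <- function(positions, velocities = NULL, step = 0,
                       config = tiny_cond(nrow(positions) - 1)) {
  if (is.null(velocities)) velocities <- matrix(0, nrow(positions), 2)
  world_state(positions, velocities, step, config)
}

random_world <- function(config, pos_range = 0.9, vel_range = 1.5) {
  na <- config$n_predators + 1
  world_state(
    matrix(stats::runif(2 * na, -pos_range, pos_range), na, 2),
    matrix(stats::runif(2 * na, -vel_range, vel_range), na, 2),
    0, config
  )
}

# Independent dueling-network forward pass: plain loops, no shared code
# with q_forward().
oracle_forward <- function(p, s) {
  lin <- function(W, b, x) {
    out <- numeric(nrow(W))
    for (o in seq_len(nrow(W))) out[o] <- sum(W[o, ] * x) + b[o]
    out
  }
  r <- function(x) ifelse(x > 0, x, 0)
  h1 <- r(lin(p$W1, p$b1, s))
  h2 <- r(lin(p$W2, p$b2, h1))
  ha <- r(lin(p$Wa1, p$ba1, h2))
  A <- lin(p$Wa2, p$ba2, ha)
  hv <- r(lin(p$Wv1, p$bv1, h2))
  V <- lin(p$Wv2, p$bv2, hv)[1]
  list(V = V, A = A, Q = V + A - mean(A), ha = ha, hv = hv)
}

# Independent circular-correlation evaluation (direct formula).
oracle_circcor <- function(a, b) {
  keep <- a != 13 & b != 13
  th <- (a[keep] - 1) * 30 * pi / 180
  ph <- (b[keep] - 1) * 30 * pi / 180
  tb <- atan2(sum(sin(th)) / length(th), sum(cos(th)) / length(th))
  pb <- atan2(sum(sin(ph)) / length(ph), sum(cos(ph)) / length(ph))
  num <- sum(sin(th - tb) * sin(ph - pb))
  num / sqrt(sum(sin(th - tb)^2) * sum(sin(ph - pb)^2))
}

# A policy_params object with every weight zero (Q identically 0, greedy
# action 1 by tie-break).
zero_params <- function(n_inputs = 8) {
  p <- init_policy_params(n_inputs)
  for (nm in names(p)) p[[nm]][] <- 0
  p
}

# Synthetic episode-record table built directly (no simulation), for
# analysis-stage oracles.
synthetic_records <- function(df, condition) {
  defaults <- list(
    step = 0L, role = "predator", vx = 0, vy = 0, action = 1L,
    reward = 0, event = "none"
  )
  for (nm in names(defaults)) if (is.null(df[[nm]])) df[[nm]] <- defaults[[nm]]
  episode_record(df, condition)
}
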