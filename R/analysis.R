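#' Summarize predation outcomes
#'
#' Successful predation is the sum of captures and prey arena exits;
#' predator exits and timeouts count as prey success, so predator and
#' prey successes partition the episodes. Duration is the episode end
#' time, capped by the 30 s limit. When a `seed` column is present the
#' summary reports the mean and SEM across seeds of the per-seed values.
#'
#' @param outcomes outcome data frame from [simulate_episodes()] or
#'   [evaluate_policies()] (columns `event`, `duration`, optionally
#'   `seed`).
#' @return an object of class `outcome_summary`: list with `H` (success
#'   proportion), `H_sem`, `mean_duration`, `duration_sem`, `per_seed`,
#'   `n_episodes`.
#' @export
summarize_outcomes <- function(outcomes) {
  if (nrow(outcomes) == 0) stop("no episodes to summarize")
  stopifnot(all(c("event", "duration") %in% names(outcomes)))
  success <- outcomes$event %in% c("capture", "prey_out")
  if (!is.null(outcomes$seed)) {
    per <- data.frame(
      seed = sort(unique(outcomes$seed)),
      H = as.numeric(tapply(success, outcomes$seed, mean)),
      mean_duration = as.numeric(tapply(outcomes$duration, outcomes$seed, mean)),
      n = as.integer(tapply(success, outcomes$seed, length))
    )
  } else {
    per <- data.frame(
      seed = NA_integer_, H = mean(success),
      mean_duration = mean(outcomes$duration), n = nrow(outcomes)
    )
  }
  sem <- function(x) {
    if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else NA_real_
  }
  structure(
    list(
      H = mean(per$H),
      H_sem = sem(per$H),
      mean_duration = mean(per$mean_duration),
      duration_sem = sem(per$mean_duration),
      per_seed = per,
      n_episodes = nrow(outcomes)
    ),
    class = "outcome_summary"
  )
}

#' @export
print.outcome_summary <- function(x, ...) {
  cat(sprintf(
    "<outcome_summary> %d episodes over %d seed(s)\n", x$n_episodes,
    nrow(x$per_seed)
  ))
  cat(sprintf(
    "  success proportion H = %.3f%s\n", x$H,
    if (!is.na(x$H_sem)) sprintf(" +/- %.3f (SEM)", x$H_sem) else ""
  ))
  cat(sprintf(
    "  mean duration %.2f s%s\n", x$mean_duration,
    if (!is.na(x$duration_sem)) {
      sprintf(" +/- %.2f (SEM)", x$duration_sem)
    } else {
      ""
    }
  ))
  invisible(x)
}

#' Independence prediction for group success
#'
#' If n predators each succeeded independently with the solitary
#' proportion \eqn{H_1}, the group proportion would be
#' \deqn{H_n = 1 - (1 - H_1)^n.}
#' Observed success above this curve signals synergy between predators.
#'
#' @param H1 solitary success proportion in \[0, 1\].
#' @param n number of predators (>= 1).
#' @return the predicted proportion \eqn{H_n}.
#' @export
theoretical_prediction <- function(H1, n) {
  stopifnot(all(H1 >= 0), all(H1 <= 1), all(n >= 1))
  1 - (1 - H1)^n
}

#' Occupancy heat map
#'
#' Counts an agent's logged positions on an equal-width `bins x bins`
#' grid over the arena \eqn{[-1, 1]^2} (40 x 40 = 1600 cells by
#' default). Bins are half-open on the right/top except the last, which
#' is closed; the rare logged position outside the arena is clamped to
#' the boundary bin so the total count always equals the number of
#' logged agent-steps.
#'
#' @param records an `episode_record`.
#' @param agent agent index to map.
#' @param bins grid resolution per axis.
#' @return a `heat_map`: integer count matrix (rows = x bins, columns =
#'   y bins) with attributes `agent`, `episodes`, `breaks`.
#' @export
heat_map <- function(records, agent, bins = 40) {
  rows <- records[records$agent == agent, ]
  if (nrow(rows) == 0) stop("no records for agent ", agent)
  cond <- attr(records, "condition")
  hw <- if (is.null(cond)) 1 else cond$arena_half_width
  breaks <- seq(-hw, hw, length.out = bins + 1)
  ix <- findInterval(rows$x, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  iy <- findInterval(rows$y, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- tabulate((iy - 1L) * bins + ix, nbins = bins * bins)
  structure(
    matrix(as.integer(counts), bins, bins),
    class = "heat_map",
    agent = agent,
    episodes = length(unique(rows$episode)),
    breaks = breaks
  )
}

#' @export
print.heat_map <- function(x, ...) {
  cat(sprintf(
    "<heat_map> %dx%d bins, agent %s, %d episodes, %d positions\n",
    nrow(x), ncol(x), attr(x, "agent"), attr(x, "episodes"), sum(x)
  ))
  invisible(x)
}

#' Plot an occupancy heat map
#'
#' @param x a [heat_map()].
#' @param ... passed to [graphics::image()].
#' @export
plot.heat_map <- function(x, ...) {
  br <- attr(x, "breaks")
  mids <- (br[-1] + br[-length(br)]) / 2
  graphics::image(mids, mids, unclass(x),
    xlab = "x", ylab = "y",
    main = sprintf("agent %s occupancy", attr(x, "agent")), ...
  )
  invisible(x)
}

#' Correlation between two occupancy maps
#'
#' Product-moment correlation of the flattened count vectors; scaling
#' either map (counts vs frequencies) leaves it unchanged. A constant
#' map has no defined correlation and yields `NA` with a warning.
#'
#' @param a,b `heat_map` objects of identical dimensions.
#' @return Pearson r, or `NA` if either map is constant.
#' @export
heatmap_correlation <- function(a, b) {
  stopifnot(all(dim(a) == dim(b)))
  va <- as.numeric(a)
  vb <- as.numeric(b)
  if (stats::sd(va) == 0 || stats::sd(vb) == 0) {
    warning("constant heat map: correlation undefined")
    return(NA_real_)
  }
  stats::cor(va, vb)
}

#' Concordance with the solo-trained policy
#'
#' For every logged predator step in a multi-predator episode set,
#' rebuilds the state the predator would see if it were alone with the
#' prey — own absolute position, own velocity and the prey block in the
#' prey-directed frame, i.e. the multi-predator feature vector with the
#' other-predator blocks deleted — queries the solo policy greedily,
#' and reports the fraction of logged actions the solo policy would
#' have chosen too.
#'
#' @param records an `episode_record` from a 2- or 3-predator condition.
#' @param solo_params `policy_params` trained (or defined) in the
#'   one-predator condition (8 inputs).
#' @return overall concordance proportion, with per-predator values as
#'   attribute `per_predator`.
#' @export
concordance_rate <- function(records, solo_params) {
  if (ncol(solo_params$W1) != 8) {
    stop("solo policy must take the 8-dimensional one-predator state")
  }
  cond <- attr(records, "condition")
  if (is.null(cond)) stop("records carry no condition attribute")
  np <- cond$n_predators
  prey <- records[records$agent == np + 1L, ]
  key <- function(df) paste(df$episode, df$step)
  pk <- key(prey)
  per <- numeric(np)
  total_match <- 0L
  total_n <- 0L
  for (i in seq_len(np)) {
    pred <- records[records$agent == i, ]
    j <- match(key(pred), pk)
    stopifnot(!anyNA(j))
    qx <- prey$x[j]
    qy <- prey$y[j]
    # prey-directed frame
    tx <- qx - pred$x
    ty <- qy - pred$y
    nrm <- sqrt(tx^2 + ty^2)
    deg <- nrm < 1e-12
    ux <- ifelse(deg, 1, tx / nrm)
    uy <- ifelse(deg, 0, ty / nrm)
    rvx <- prey$vx[j] - pred$vx
    rvy <- prey$vy[j] - pred$vy
    S <- cbind(
      pred$x, pred$y,
      pred$vx * ux + pred$vy * uy, pred$vx * uy - pred$vy * ux,
      tx * ux + ty * uy, tx * uy - ty * ux,
      rvx * ux + rvy * uy, rvx * uy - rvy * ux
    )
    act <- greedy_actions(solo_params, S)
    per[i] <- mean(act == pred$action)
    total_match <- total_match + sum(act == pred$action)
    total_n <- total_n + nrow(pred)
  }
  structure(total_match / total_n, per_predator = per)
}

#' Circular correlation of two action sequences
#'
#' Directional actions 1..12 map to angles \eqn{(a-1) \times 30^\circ};
#' pairs containing action 13 (do nothing) are dropped. The statistic
#' is the angular-deviation product estimator
#' \deqn{r = \frac{\sum_i \sin(\theta_i - \bar\theta)\sin(\phi_i - \bar\phi)}
#'   {\sqrt{\sum_i \sin^2(\theta_i - \bar\theta)\sum_i \sin^2(\phi_i - \bar\phi)}}}
#' with \eqn{\bar\theta,\bar\phi} the circular means. It is invariant
#' under rotating both sequences by a common angle and flips sign when
#' one sequence is reflected.
#'
#' @param actions_a,actions_b paired integer action sequences (1..13).
#' @return r in \[-1, 1\]; `NA` with a warning when either sequence has
#'   no angular dispersion.
#' @export
circular_correlation <- function(actions_a, actions_b) {
  stopifnot(length(actions_a) == length(actions_b))
  keep <- !is.na(actions_a) & !is.na(actions_b) &
    actions_a != 13 & actions_b != 13
  a <- actions_a[keep]
  b <- actions_b[keep]
  if (length(a) < 2) stop("fewer than 2 valid (non-13) pairs")
  th <- (a - 1) * pi / 6
  ph <- (b - 1) * pi / 6
  tbar <- atan2(mean(sin(th)), mean(cos(th)))
  pbar <- atan2(mean(sin(ph)), mean(cos(ph)))
  st <- sin(th - tbar)
  sp <- sin(ph - pbar)
  den <- sqrt(sum(st^2) * sum(sp^2))
  if (den == 0) {
    warning("degenerate angular dispersion: circular correlation undefined")
    return(NA_real_)
  }
  sum(st * sp) / den
}

#' Ratio of distance moved among predators
#'
#' Sums each predator's per-step displacements over the logged episodes
#' and reports each predator's share of the summed path lengths — a
#' simple index of how unevenly the hunting effort is divided.
#'
#' @param records an `episode_record` with at least two predators.
#' @return named share vector summing to 1, with the per-episode share
#'   table as attribute `per_episode`.
#' @export
distance_moved_ratio <- function(records) {
  cond <- attr(records, "condition")
  if (is.null(cond)) stop("records carry no condition attribute")
  np <- cond$n_predators
  if (np < 2) stop("distance ratios need at least 2 predators")
  eps <- sort(unique(records$episode))
  path <- matrix(0, length(eps), np)
  for (i in seq_len(np)) {
    pred <- records[records$agent == i, ]
    pred <- pred[order(pred$episode, pred$step), ]
    dx <- diff(pred$x)
    dy <- diff(pred$y)
    same <- diff(pred$episode) == 0
    d <- sqrt(dx^2 + dy^2)[same]
    ep <- pred$episode[-1][same]
    agg <- tapply(d, factor(ep, levels = eps), sum, default = 0)
    path[, i] <- as.numeric(agg)
  }
  total <- sum(path)
  if (total == 0) stop("no movement logged")
  shares <- colSums(path) / total
  names(shares) <- paste0("pred", seq_len(np))
  per <- path / pmax(rowSums(path), .Machine$double.eps)
  colnames(per) <- names(shares)
  structure(shares, per_episode = data.frame(episode = eps, per))
}

#' Two-dimensional embedding of hidden representations
#'
#' Embeds the 32-unit stream activations with t-distributed stochastic
#' neighbor embedding (exact, O(n^2); implemented in the package) and
#' attaches per-state coloring channels — typically the state value V,
#' the standard deviation of Q across the 13 actions, and predator-prey
#' distances — each with its color range clipped to the channel's 5th
#' and 95th percentiles to blunt extreme values.
#'
#' @param hidden numeric matrix of hidden activations (one state per
#'   row, >= 2 rows).
#' @param channels optional data frame of per-state coloring channels.
#' @param perplexity t-SNE perplexity.
#' @param max_iter gradient-descent iterations.
#' @return an `embedding_table`: list with `coords` (n x 2), `channels`,
#'   and `clip_bounds` (5th/95th percentile per channel).
#' @export
embed_representations <- function(hidden, channels = NULL, perplexity = 30,
                                  max_iter = 400) {
  hidden <- as.matrix(hidden)
  n <- nrow(hidden)
  if (n < 2) stop("need at least 2 states to embed")
  if (!is.null(channels)) {
    channels <- as.data.frame(channels)
    stopifnot(nrow(channels) == n)
  }
  if (stats::sd(as.numeric(hidden)) == 0) {
    stop("degenerate input: all hidden vectors identical")
  }
  coords <- tsne_exact(hidden, perplexity = perplexity, max_iter = max_iter)
  clip <- NULL
  if (!is.null(channels)) {
    clip <- vapply(
      channels,
      function(ch) stats::quantile(ch, c(0.05, 0.95), names = FALSE),
      numeric(2)
    )
    rownames(clip) <- c("p05", "p95")
  }
  structure(
    list(coords = coords, channels = channels, clip_bounds = clip),
    class = "embedding_table"
  )
}

#' @export
print.embedding_table <- function(x, ...) {
  cat(sprintf(
    "<embedding_table> %d states, %d channel(s)\n", nrow(x$coords),
    if (is.null(x$channels)) 0L else ncol(x$channels)
  ))
  invisible(x)
}

# Exact t-SNE (Gaussian input affinities calibrated to the target
# perplexity by bisection; Student-t low-dimensional kernel; early
# exaggeration and momentum as in the reference algorithm).
tsne_exact <- function(X, perplexity = 30, max_iter = 400, eta = 100) {
  n <- nrow(X)
  perplexity <- min(perplexity, (n - 1) / 3)
  D2 <- as.matrix(stats::dist(X))^2
  target <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    di <- D2[i, -i]
    beta <- 1
    lo <- -Inf
    hi <- Inf
    for (iter in 1:50) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw <= 0) {
        H <- 0
      } else {
        pj <- w / sw
        H <- -sum(ifelse(pj > 0, pj * log(pj), 0))
      }
      if (abs(H - target) < 1e-5) break
      if (H > target) {
        lo <- beta
        beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2
      } else {
        hi <- beta
        beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2
      }
    }
    w <- exp(-di * beta)
    pj <- if (sum(w) > 0) w / sum(w) else rep(1 / (n - 1), n - 1)
    P[i, -i] <- pj
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)
  Y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2)
  G <- matrix(0, n, 2)
  gain <- matrix(1, n, 2)
  exag <- 4
  for (iter in seq_len(max_iter)) {
    Pe <- if (iter <= 100) P * exag else P
    sumY <- rowSums(Y^2)
    num <- 1 / (1 + outer(sumY, sumY, "+") - 2 * tcrossprod(Y))
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    L <- (Pe - Q) * num
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    momentum <- if (iter <= 250) 0.5 else 0.8
    gain <- ifelse(sign(grad) != sign(G), gain + 0.2, gain * 0.8)
    gain[gain < 0.01] <- 0.01
    G <- momentum * G - eta * gain * grad
    Y <- Y + G
    Y <- sweep(Y, 2, colMeans(Y))
  }
  colnames(Y) <- c("dim1", "dim2")
  Y
}

#' Hidden activations and coloring channels from logged episodes
#'
#' Rebuilds the state vector of one agent at every logged step, runs the
#' policy network, and returns the two 32-unit stream activations
#' together with the standard coloring channels (V, SD of Q across
#' actions, distance from each predator to the prey).
#'
#' @param records an `episode_record`.
#' @param params the agent's `policy_params`.
#' @param agent agent index whose states are rebuilt.
#' @return list with `advantage`, `value` (n x 32 matrices) and
#'   `channels` (data frame).
#' @export
collect_representations <- function(records, params, agent) {
  cond <- attr(records, "condition")
  if (is.null(cond)) stop("records carry no condition attribute")
  S <- rebuild_state_vectors(records, agent)
  f <- q_forward(params, S)
  np <- cond$n_predators
  ch <- data.frame(
    V = f$V,
    sd_Q = apply(f$Q, 1, stats::sd)
  )
  rows <- records[records$agent == agent, ]
  key <- paste(rows$episode, rows$step)
  prey <- records[records$agent == np + 1L, ]
  j <- match(key, paste(prey$episode, prey$step))
  for (i in seq_len(np)) {
    pred <- records[records$agent == i, ]
    k <- match(key, paste(pred$episode, pred$step))
    ch[[paste0("dist_pred", i)]] <-
      sqrt((pred$x[k] - prey$x[j])^2 + (pred$y[k] - prey$y[j])^2)
  }
  list(advantage = f$hidden_advantage, value = f$hidden_value, channels = ch)
}

# Vectorized reconstruction of one agent's state vectors from a record
# table (same layout as build_state_vector).
rebuild_state_vectors <- function(records, agent) {
  cond <- attr(records, "condition")
  np <- cond$n_predators
  na <- np + 1L
  self <- records[records$agent == agent, ]
  key <- paste(self$episode, self$step)
  other_tabs <- lapply(seq_len(na), function(j) {
    tab <- records[records$agent == j, ]
    tab[match(key, paste(tab$episode, tab$step)), ]
  })
  # frame target: prey for predators, nearest predator for the prey
  if (agent <= np) {
    tgt <- other_tabs[[na]]
    tx <- tgt$x - self$x
    ty <- tgt$y - self$y
  } else {
    dists <- vapply(
      seq_len(np),
      function(j) {
        (other_tabs[[j]]$x - self$x)^2 + (other_tabs[[j]]$y - self$y)^2
      },
      numeric(nrow(self))
    )
    dists <- matrix(dists, nrow = nrow(self))
    nearest <- max.col(-dists, ties.method = "first")
    tx <- ty <- numeric(nrow(self))
    for (j in seq_len(np)) {
      pick <- nearest == j
      tx[pick] <- other_tabs[[j]]$x[pick] - self$x[pick]
      ty[pick] <- other_tabs[[j]]$y[pick] - self$y[pick]
    }
  }
  nrm <- sqrt(tx^2 + ty^2)
  deg <- nrm < 1e-12
  ux <- ifelse(deg, 1, tx / nrm)
  uy <- ifelse(deg, 0, ty / nrm)
  S <- cbind(
    self$x, self$y,
    self$vx * ux + self$vy * uy, self$vx * uy - self$vy * ux
  )
  for (j in setdiff(seq_len(na), agent)) {
    o <- other_tabs[[j]]
    dx <- o$x - self$x
    dy <- o$y - self$y
    dvx <- o$vx - self$vx
    dvy <- o$vy - self$vy
    S <- cbind(
      S,
      dx * ux + dy * uy, dx * uy - dy * ux,
      dvx * ux + dvy * uy, dvx * uy - dvy * ux
    )
  }
  S
}
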