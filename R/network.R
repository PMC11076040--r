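#' State featurization for the Q-network
#'
#' An agent observes its own absolute position, its own velocity rotated
#' into its relative frame ([relative_frame()]), and, for every other
#' agent in index order, the relative position and relative velocity
#' (other minus self) rotated into the same frame. Length is
#' `4 + 4 * (n_agents - 1)`; all agents in a condition share one input
#' dimensionality. For a predator the prey block always sits last, which
#' is what lets [concordance_rate()] project a multi-predator state onto
#' the solo layout by deleting the other-predator blocks.
#'
#' @param state a [world_state()].
#' @param agent agent index.
#' @param config a [condition_config()]; defaults to the state's own.
#' @return numeric state vector.
#' @export
build_state_vector <- function(state, agent, config = state$config) {
  na <- n_agents(config)
  stopifnot(agent >= 1, agent <= na)
  fr <- relative_frame(state, agent)
  rot <- rbind(fr$u, fr$v) # rows: u, v
  p <- state$positions
  v <- state$velocities
  own <- c(p[agent, ], as.numeric(rot %*% v[agent, ]))
  others <- setdiff(seq_len(na), agent)
  blocks <- vapply(others, function(j) {
    c(
      as.numeric(rot %*% (p[j, ] - p[agent, ])),
      as.numeric(rot %*% (v[j, ] - v[agent, ]))
    )
  }, numeric(4))
  c(own, as.numeric(blocks))
}

state_vector_length <- function(config) 4L + 4L * config$n_predators

#' Initialize dueling-network weights
#'
#' The four-layer dueling architecture: two 64-unit fully connected
#' trunk layers, then a 32-unit advantage stream with 13 outputs and a
#' 32-unit value stream with one output, all ReLU. Weights and biases
#' are fan-in-scaled uniform, drawn from R's RNG (seedable with
#' `set.seed()`).
#'
#' @param n_inputs input dimensionality (see [state_vector_length()]).
#' @return an object of class `policy_params`: named list of weight
#'   matrices `W1, b1, W2, b2, Wa1, ba1, Wa2, ba2, Wv1, bv1, Wv2, bv2`.
#' @export
init_policy_params <- function(n_inputs) {
  lay <- function(n_out, n_in) {
    b <- 1 / sqrt(n_in)
    list(
      W = matrix(stats::runif(n_out * n_in, -b, b), n_out, n_in),
      b = stats::runif(n_out, -b, b)
    )
  }
  l1 <- lay(64, n_inputs)
  l2 <- lay(64, 64)
  a1 <- lay(32, 64)
  a2 <- lay(13, 32)
  v1 <- lay(32, 64)
  v2 <- lay(1, 32)
  structure(
    list(
      W1 = l1$W, b1 = l1$b, W2 = l2$W, b2 = l2$b,
      Wa1 = a1$W, ba1 = a1$b, Wa2 = a2$W, ba2 = a2$b,
      Wv1 = v1$W, bv1 = v1$b, Wv2 = v2$W, bv2 = v2$b
    ),
    class = "policy_params", n_inputs = as.integer(n_inputs)
  )
}

#' @export
print.policy_params <- function(x, ...) {
  cat(sprintf(
    "<policy_params> dueling net: %d -> 64 -> 64 -> {32 -> 13 adv, 32 -> 1 val}\n",
    ncol(x$W1)
  ))
  invisible(x)
}

relu <- function(x) pmax(x, 0)

#' Forward pass of the dueling Q-network
#'
#' Computes the state value V, the 13 advantages A, and the action
#' values through the mean-subtracted aggregation
#' \deqn{Q(s,a) = V(s) + (A(s,a) - \frac{1}{|A|}\sum_{a'} A(s,a')),}
#' which pins the mean of Q over actions to V and makes Q invariant to
#' adding a constant to every advantage.
#'
#' @param params a `policy_params` object.
#' @param s a state vector, or a matrix of states (one row each).
#' @return for a single state, an object of class `q_values` (list with
#'   `V`, `A`, `Q`, `hidden_advantage`, `hidden_value`); for a matrix,
#'   a list of matrices `V`, `A`, `Q`, `hidden_advantage`,
#'   `hidden_value` with one row per state.
#' @export
q_forward <- function(params, s) {
  single <- is.null(dim(s))
  S <- if (single) matrix(s, nrow = 1) else as.matrix(s)
  if (ncol(S) != ncol(params$W1)) stop("state length mismatch")
  h1 <- relu(sweep(S %*% t(params$W1), 2, params$b1, "+"))
  h2 <- relu(sweep(h1 %*% t(params$W2), 2, params$b2, "+"))
  ha <- relu(sweep(h2 %*% t(params$Wa1), 2, params$ba1, "+"))
  A <- sweep(ha %*% t(params$Wa2), 2, params$ba2, "+")
  hv <- relu(sweep(h2 %*% t(params$Wv1), 2, params$bv1, "+"))
  V <- as.numeric(hv %*% t(params$Wv2)) + params$bv2
  Q <- V + A - rowMeans(A)
  if (single) {
    structure(
      list(
        V = V[1], A = as.numeric(A), Q = as.numeric(Q),
        hidden_advantage = as.numeric(ha), hidden_value = as.numeric(hv)
      ),
      class = "q_values"
    )
  } else {
    list(V = V, A = A, Q = Q, hidden_advantage = ha, hidden_value = hv)
  }
}

#' @export
print.q_values <- function(x, ...) {
  cat(sprintf(
    "<q_values> V = %.4f, argmax Q = action %d\n", x$V, which.max(x$Q)
  ))
  invisible(x)
}

#' Epsilon-greedy action selection
#'
#' With probability `epsilon` a uniform action over the 13 candidates;
#' otherwise the greedy argmax of Q, ties broken toward the lowest
#' action index. When `epsilon` is 0 no random number is drawn, so
#' greedy rollouts consume no RNG.
#'
#' @param q a `q_values` object from [q_forward()], or a bare numeric
#'   Q vector of length 13.
#' @param epsilon exploration probability in \[0, 1\].
#' @return an action in 1..13.
#' @export
select_action <- function(q, epsilon = 0) {
  stopifnot(epsilon >= 0, epsilon <= 1)
  Q <- if (inherits(q, "q_values")) q$Q else as.numeric(q)
  stopifnot(length(Q) == 13)
  if (epsilon > 0 && stats::runif(1) < epsilon) {
    return(floor(stats::runif(1) * 13) + 1)
  }
  which.max(Q) # first maximum = lowest index
}

#' Hidden representations of the two streams
#'
#' The post-ReLU activations of the 32-unit advantage-stream and
#' value-stream layers, the internal representations that
#' [embed_representations()] visualizes.
#'
#' @inheritParams q_forward
#' @return list with `advantage` and `value` (32-vectors, or matrices
#'   with one row per state).
#' @export
extract_hidden <- function(params, s) {
  f <- q_forward(params, s)
  list(advantage = f$hidden_advantage, value = f$hidden_value)
}

#' Greedy actions of a policy over many states
#'
#' @param params a `policy_params` object.
#' @param states matrix of state vectors (one row each).
#' @return integer vector of greedy actions (ties to lowest index).
#' @export
greedy_actions <- function(params, states) {
  Q <- q_forward(params, states)$Q
  max.col(Q, ties.method = "first")
}
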