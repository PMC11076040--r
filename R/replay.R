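#' A single replay transition
#'
#' The unit stored in replay memory: state, action, reward, next state,
#' terminal flag. Terminal transitions carry no bootstrap term in the
#' learning target.
#'
#' @param s,s2 state vectors before and after the step.
#' @param a action taken (1..13).
#' @param r reward received (-1, 0 or +1).
#' @param terminal whether the episode ended at `s2`.
#' @return an object of class `transition`.
#' @export
transition <- function(s, a, r, s2, terminal = FALSE) {
  stopifnot(
    length(s) == length(s2), a %in% 1:13, r %in% c(-1, 0, 1),
    is.logical(terminal)
  )
  structure(
    list(
      s = as.numeric(s), a = as.integer(a), r = r,
      s2 = as.numeric(s2), terminal = terminal
    ),
    class = "transition"
  )
}

#' Prioritized replay memory
#'
#' A fixed-capacity ring buffer of transitions with per-item priorities.
#' New items enter at the running maximum priority (1 while the memory
#' is empty) so they are replayed at least once; the oldest item is
#' evicted at capacity. Implemented as a mutable environment, so
#' [add_transition()] and [update_priorities()] modify it in place.
#'
#' @param capacity maximum number of stored transitions.
#' @return an object of class `replay_memory`.
#' @export
replay_memory <- function(capacity = 1e4) {
  stopifnot(capacity >= 1)
  m <- new.env(parent = emptyenv())
  m$capacity <- as.integer(capacity)
  m$items <- vector("list", capacity)
  m$priority <- numeric(capacity)
  m$size <- 0L
  m$head <- 1L
  m$max_priority <- 1
  class(m) <- "replay_memory"
  m
}

#' @export
print.replay_memory <- function(x, ...) {
  cat(sprintf(
    "<replay_memory> %d / %d transitions, max priority %.4g\n",
    x$size, x$capacity, x$max_priority
  ))
  invisible(x)
}

#' Number of stored transitions
#' @param memory a [replay_memory()].
#' @return integer size.
#' @export
memory_size <- function(memory) memory$size

#' Store a transition
#'
#' Inserts at the running maximum priority; evicts the oldest item once
#' the buffer is full.
#'
#' @param memory a [replay_memory()].
#' @param t a [transition()].
#' @return the memory, invisibly (modified in place).
#' @export
add_transition <- function(memory, t) {
  stopifnot(inherits(t, "transition"))
  memory$items[[memory$head]] <- t
  memory$priority[memory$head] <- memory$max_priority
  memory$head <- memory$head %% memory$capacity + 1L
  memory$size <- min(memory$size + 1L, memory$capacity)
  invisible(memory)
}

#' Sample a prioritized minibatch
#'
#' Items are drawn with replacement with probability
#' \deqn{P(i) = p_i^\alpha / \sum_k p_k^\alpha,}
#' so `alpha = 0` gives uniform sampling. Importance-sampling weights
#' \eqn{w_i = (N P(i))^{-\beta}} (with N the current size) are
#' normalized by the batch maximum; `beta = 0` makes every weight 1.
#'
#' @param memory a [replay_memory()].
#' @param batch number of items to draw.
#' @param alpha prioritization exponent.
#' @param beta importance-sampling exponent.
#' @return list with `transitions` (list), `indices` (storage slots) and
#'   `weights` (normalized IS weights).
#' @export
sample_batch <- function(memory, batch = 32, alpha = 0.6, beta = 0.4) {
  n <- memory$size
  if (n < batch) stop("memory holds ", n, " < ", batch, " transitions")
  pa <- memory$priority[seq_len(n)]^alpha
  prob <- pa / sum(pa)
  idx <- sample.int(n, batch, replace = TRUE, prob = prob)
  w <- (n * prob[idx])^(-beta)
  w <- w / max(w)
  list(
    transitions = memory$items[idx],
    indices = idx,
    weights = w
  )
}

#' Update priorities from TD errors
#'
#' Sets \eqn{p_i = |\delta_i| + \epsilon_p}; the small floor keeps
#' zero-error transitions sampleable. The running maximum used for new
#' insertions is raised when exceeded.
#'
#' @param memory a [replay_memory()].
#' @param indices storage slots returned by [sample_batch()].
#' @param td_errors TD errors of those items.
#' @param priority_eps the positive floor.
#' @return the memory, invisibly (modified in place).
#' @export
update_priorities <- function(memory, indices, td_errors,
                              priority_eps = 1e-6) {
  stopifnot(
    length(indices) == length(td_errors),
    all(indices >= 1), all(indices <= memory$size),
    priority_eps > 0
  )
  p <- abs(td_errors) + priority_eps
  memory$priority[indices] <- p
  memory$max_priority <- max(memory$max_priority, p)
  invisible(memory)
}
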