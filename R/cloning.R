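#' Behavioral-cloning dataset from logged episodes
#'
#' Collects one predator's rebuilt state vectors and logged actions
#' from an episode record and splits them into train / validation /
#' test sets that are disjoint by episode (1000 / 100 / 100 episodes at
#' full scale). Episodes are assigned to splits in episode order.
#'
#' @param records an `episode_record` (e.g. rule-based rollouts).
#' @param agent predator index whose behavior is cloned.
#' @param split integer episode counts `c(train, validation, test)`;
#'   scaled down proportionally if the record holds fewer episodes.
#' @return an object of class `clone_dataset`: list of `train`,
#'   `validation`, `test`, each with `x` (state matrix) and `y`
#'   (actions).
#' @export
build_clone_dataset <- function(records, agent,
                                split = c(1000, 100, 100)) {
  stopifnot(length(split) == 3, all(split >= 1))
  eps <- sort(unique(records$episode))
  if (length(eps) < sum(split)) {
    stop(
      "need ", sum(split), " episodes for the requested split, have ",
      length(eps)
    )
  }
  S <- rebuild_state_vectors(records, agent)
  rows <- records[records$agent == agent, ]
  bounds <- cumsum(split)
  pick <- function(lo, hi) {
    ids <- eps[seq(lo, hi)]
    sel <- rows$episode %in% ids
    list(x = S[sel, , drop = FALSE], y = rows$action[sel])
  }
  structure(
    list(
      train = pick(1, bounds[1]),
      validation = pick(bounds[1] + 1, bounds[2]),
      test = pick(bounds[2] + 1, bounds[3]),
      agent = agent
    ),
    class = "clone_dataset"
  )
}

#' @export
print.clone_dataset <- function(x, ...) {
  cat(sprintf(
    "<clone_dataset> agent %d: %d train / %d validation / %d test steps\n",
    x$agent, length(x$train$y), length(x$validation$y), length(x$test$y)
  ))
  invisible(x)
}

#' Initialize a clone network
#'
#' One hidden layer (width 32 by default), 13-way softmax output. The
#' `linear` variant applies no activation to the hidden layer, so the
#' whole map is linear up to the softmax; the `relu` variant is the
#' nonlinear control.
#'
#' @param n_inputs input dimensionality.
#' @param variant `"relu"` or `"linear"`.
#' @param hidden hidden width.
#' @return an object of class `clone_net`.
#' @export
init_clone_net <- function(n_inputs, variant = c("relu", "linear"),
                           hidden = 32) {
  variant <- match.arg(variant)
  b1 <- 1 / sqrt(n_inputs)
  b2 <- 1 / sqrt(hidden)
  structure(
    list(
      W1 = matrix(stats::runif(hidden * n_inputs, -b1, b1), hidden, n_inputs),
      b1 = stats::runif(hidden, -b1, b1),
      W2 = matrix(stats::runif(13 * hidden, -b2, b2), 13, hidden),
      b2 = stats::runif(13, -b2, b2),
      variant = variant
    ),
    class = "clone_net"
  )
}

#' @export
print.clone_net <- function(x, ...) {
  cat(sprintf(
    "<clone_net> %s: %d -> %d -> 13 (softmax)\n", x$variant,
    ncol(x$W1), nrow(x$W1)
  ))
  invisible(x)
}

#' Clone-network forward pass
#'
#' Softmax action probabilities for one state or a matrix of states.
#'
#' @param net a [init_clone_net()] object.
#' @param s state vector or matrix (one row per state).
#' @return probability vector (or matrix) over the 13 actions; rows sum
#'   to 1.
#' @export
clone_forward <- function(net, s) {
  single <- is.null(dim(s))
  S <- if (single) matrix(s, nrow = 1) else as.matrix(s)
  if (ncol(S) != ncol(net$W1)) stop("state length mismatch")
  H <- sweep(S %*% t(net$W1), 2, net$b1, "+")
  if (net$variant == "relu") H <- relu(H)
  Z <- sweep(H %*% t(net$W2), 2, net$b2, "+")
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  P <- E / rowSums(E)
  if (single) as.numeric(P) else P
}

clone_accuracy <- function(net, x, y) {
  if (length(y) == 0) {
    return(NA_real_)
  }
  mean(max.col(clone_forward(net, x), ties.method = "first") == y)
}

#' Train a behavioral clone
#'
#' Minimizes the cross-entropy \eqn{E = -\sum_k t_k \log y_k} over the
#' training split with Adam (learning rate 1e-4, minibatch 32 by
#' default), evaluating validation accuracy once per epoch and keeping
#' the weights of the best validation epoch. Randomness (minibatch
#' shuffling, initialization) comes from R's RNG.
#'
#' @param dataset a [build_clone_dataset()].
#' @param variant `"relu"` or `"linear"`.
#' @param config a [clone_config()]; lower `epochs` for desk-scale
#'   runs.
#' @return an object of class `clone_fit`: list with `net` (best
#'   weights), `accuracy` (train / validation / test), `history`
#'   (per-epoch loss and validation accuracy), `best_epoch`.
#' @export
train_clone <- function(dataset, variant = c("relu", "linear"),
                        config = clone_config()) {
  variant <- match.arg(variant)
  x <- dataset$train$x
  y <- dataset$train$y
  n <- length(y)
  if (n == 0 || length(dataset$validation$y) == 0) {
    stop("empty train or validation split")
  }
  net <- init_clone_net(ncol(x), variant, config$hidden)
  shapes <- c("W1", "b1", "W2", "b2")
  m <- v <- lapply(net[shapes], function(w) array(0, dim(w) %||% length(w)))
  tstep <- 0
  best <- list(net = net, acc = -Inf, epoch = 0L)
  history <- data.frame()
  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n)
    total_loss <- 0
    nb <- 0
    for (start in seq(1, n, by = config$batch)) {
      idx <- ord[seq(start, min(start + config$batch - 1, n))]
      B <- length(idx)
      xb <- x[idx, , drop = FALSE]
      yb <- y[idx]
      Hp <- sweep(xb %*% t(net$W1), 2, net$b1, "+")
      H <- if (variant == "relu") relu(Hp) else Hp
      Z <- sweep(H %*% t(net$W2), 2, net$b2, "+")
      Z <- Z - apply(Z, 1, max)
      E <- exp(Z)
      P <- E / rowSums(E)
      total_loss <- total_loss -
        sum(log(pmax(P[cbind(seq_len(B), yb)], 1e-12)))
      nb <- nb + B
      # gradient of mean cross-entropy
      dZ <- P
      dZ[cbind(seq_len(B), yb)] <- dZ[cbind(seq_len(B), yb)] - 1
      dZ <- dZ / B
      gW2 <- t(dZ) %*% H
      gb2 <- colSums(dZ)
      dH <- dZ %*% net$W2
      if (variant == "relu") dH <- dH * (Hp > 0)
      gW1 <- t(dH) %*% xb
      gb1 <- colSums(dH)
      g <- list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2)
      tstep <- tstep + 1
      c1 <- 1 - 0.9^tstep
      c2 <- 1 - 0.999^tstep
      for (w in shapes) {
        m[[w]] <- 0.9 * m[[w]] + 0.1 * g[[w]]
        v[[w]] <- 0.999 * v[[w]] + 0.001 * g[[w]]^2
        net[[w]] <- net[[w]] -
          config$lr * (m[[w]] / c1) / (sqrt(v[[w]] / c2) + 1e-8)
      }
    }
    val_acc <- clone_accuracy(net, dataset$validation$x, dataset$validation$y)
    history <- rbind(history, data.frame(
      epoch = epoch, train_loss = total_loss / nb, val_accuracy = val_acc
    ))
    if (val_acc > best$acc) {
      best <- list(net = net, acc = val_acc, epoch = epoch)
    }
  }
  structure(
    list(
      net = best$net,
      accuracy = c(
        train = clone_accuracy(best$net, x, y),
        validation = best$acc,
        test = clone_accuracy(best$net, dataset$test$x, dataset$test$y)
      ),
      history = history,
      best_epoch = best$epoch,
      variant = variant
    ),
    class = "clone_fit"
  )
}

#' @export
print.clone_fit <- function(x, ...) {
  cat(sprintf(
    "<clone_fit> %s variant, best epoch %d\n", x$variant, x$best_epoch
  ))
  cat(sprintf(
    "  accuracy: train %.3f, validation %.3f, test %.3f\n",
    x$accuracy["train"], x$accuracy["validation"], x$accuracy["test"]
  ))
  invisible(x)
}
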