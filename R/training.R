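#' @title Training protocol
#' @description Per-fold optimization with mean cross-entropy loss, Adam,
#'   elementwise gradient clipping and teacher forcing: during training the
#'   previous epoch's ground-truth stage (one-hot) is the refinement input,
#'   which makes epochs conditionally independent and lets mini-batches mix
#'   subjects freely. One checkpoint is kept per training epoch; the top
#'   fraction by validation macro-F1 is selected for ensembling.
#' @name training
NULL

#' Training configuration
#'
#' Defaults follow the full-scale protocol (batch 64, 70 epochs, learning
#' rate 1e-4, elementwise gradient clip 0.1, dropout 0.5, top-10%
#' checkpoint ensembling).
#'
#' @param batch_size mini-batch size.
#' @param n_epochs number of passes over the training set.
#' @param learning_rate Adam step size.
#' @param grad_clip_value elementwise gradient clip bound (absolute value).
#' @param checkpoint_fraction fraction of per-epoch checkpoints kept for
#'   ensembling (selected by validation macro-F1).
#' @param seed seed controlling initialization, batch order and dropout.
#' @return A `"train_config"` list.
#' @export
train_config <- function(batch_size = 64L, n_epochs = 70L,
                         learning_rate = 1e-4, grad_clip_value = 0.1,
                         checkpoint_fraction = 0.10, seed = 1L) {
  stopifnot(batch_size >= 1, n_epochs >= 1, learning_rate > 0,
            grad_clip_value > 0, checkpoint_fraction > 0,
            checkpoint_fraction <= 1)
  structure(list(batch_size = as.integer(batch_size),
                 n_epochs = as.integer(n_epochs),
                 learning_rate = learning_rate,
                 grad_clip_value = grad_clip_value,
                 checkpoint_fraction = checkpoint_fraction,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Cross-entropy loss for a single prediction
#'
#' `-sum(y * log(y_hat))` with `y_hat` clipped away from zero at 1e-12;
#' for one-hot `y` this is minus the log-probability of the true class.
#'
#' @param y one-hot (or general) length-5 target vector.
#' @param y_hat length-5 probability vector.
#' @return Nonnegative scalar.
#' @export
cross_entropy_loss <- function(y, y_hat) {
  -sum(y * log(pmax(y_hat, 1e-12)))
}

#' Clip a gradient elementwise
#' @param g numeric vector/array of gradients.
#' @param clip bound; every component is forced into `[-clip, clip]`.
#' @return Clipped gradients.
#' @export
clip_gradient <- function(g, clip = 0.1) pmin(pmax(g, -clip), clip)

#' Initialize Adam optimizer state
#' @param n number of parameters.
#' @return List with first/second moment vectors and step counter.
#' @export
adam_init <- function(n) list(m = numeric(n), v = numeric(n), t = 0L)

#' One Adam update step
#'
#' Standard Adam with bias correction: `m <- b1 m + (1-b1) g`,
#' `v <- b2 v + (1-b2) g^2`, `theta <- theta - lr * mhat / (sqrt(vhat) +
#' eps)`.
#'
#' @param theta parameter vector.
#' @param grad gradient vector (same length).
#' @param state optimizer state from [adam_init()].
#' @param lr learning rate.
#' @param beta1,beta2,eps Adam moment decays and stabilizer (framework
#'   defaults 0.9 / 0.999 / 1e-8).
#' @return List with updated `theta` and `state`.
#' @export
adam_step <- function(theta, grad, state, lr = 1e-4, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  theta <- theta - lr * mhat / (sqrt(vhat) + eps)
  list(theta = theta, state = state)
}

params_flatten <- function(p) unlist(p, use.names = FALSE)

params_unflatten <- function(p, vec) {
  assign_rec <- function(p, pos) {
    if (is.list(p)) {
      for (i in seq_along(p)) {
        r <- assign_rec(p[[i]], pos)
        p[[i]] <- r$p
        pos <- r$pos
      }
    } else {
      n <- length(p)
      p[] <- vec[pos:(pos + n - 1L)]
      pos <- pos + n
    }
    list(p = p, pos = pos)
  }
  assign_rec(p, 1L)$p
}

# Stack recordings into training tensors with teacher-forced previous-stage
# inputs: the first epoch of every recording gets the uniform 1/5 vector,
# later epochs the one-hot ground truth of their predecessor.
build_training_set <- function(recordings) {
  Xs <- lapply(recordings, function(r) unclass(r$epochs))
  X <- do.call(abind3, Xs)
  y <- do.call(c, lapply(recordings, function(r) as.integer(r$labels)))
  prev <- do.call(rbind, lapply(recordings, function(r) {
    n <- length(r$labels)
    p <- matrix(1 / N_STAGES, 1, N_STAGES)
    if (n > 1L) p <- rbind(p, one_hot_stages(r$labels[seq_len(n - 1L)]))
    p
  }))
  list(X = X, y = y, Y = one_hot_stages(hypnogram(y)), prev = prev)
}

abind3 <- function(...) {
  xs <- list(...)
  d <- dim(xs[[1]])
  n <- sum(vapply(xs, function(x) dim(x)[1], numeric(1)))
  out <- array(0, c(n, d[2], d[3]))
  at <- 0L
  for (x in xs) {
    out[at + seq_len(dim(x)[1]), , ] <- x
    at <- at + dim(x)[1]
  }
  out
}

#' Train the model on one cross-validation fold
#'
#' Runs `n_epochs` passes of teacher-forced mini-batch training. After each
#' pass the model is evaluated on the validation recording by sequential
#' inference (its own feedback loop, as at test time) and a checkpoint of
#' the parameters is stored. Gradients are clipped elementwise to
#' `grad_clip_value` before the Adam update. Everything is deterministic
#' for a fixed `seed`.
#'
#' @param train_recordings list of [recording()]s (preprocessed, 5-class).
#' @param val_recording a [recording()] used for checkpoint ranking.
#' @param model_cfg a [model_config()].
#' @param train_cfg a [train_config()].
#' @param verbose print per-epoch progress.
#' @return List with `model` (final), `history` (data.frame of train_loss,
#'   val_accuracy, val_mf1, checkpoint_id), `checkpoints` (list of
#'   parameter snapshots), and the configs.
#' @export
train_fold <- function(train_recordings, val_recording, model_cfg,
                       train_cfg = train_config(), verbose = FALSE) {
  if (length(train_recordings) == 0L) stop("empty training set")
  set.seed(train_cfg$seed)
  model <- init_model(model_cfg)
  ds <- build_training_set(train_recordings)
  n <- dim(ds$X)[1]
  theta <- params_flatten(model$params)
  opt <- adam_init(length(theta))
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_accuracy = numeric(0), val_mf1 = numeric(0),
                        checkpoint_id = integer(0))
  checkpoints <- vector("list", train_cfg$n_epochs)
  for (ep in seq_len(train_cfg$n_epochs)) {
    ord <- sample.int(n)
    losses <- numeric(0)
    for (b0 in seq(1L, n, by = train_cfg$batch_size)) {
      idx <- ord[b0:min(b0 + train_cfg$batch_size - 1L, n)]
      lg <- model_loss_grads(model,
                             ds$X[idx, , , drop = FALSE],
                             ds$prev[idx, , drop = FALSE],
                             ds$Y[idx, , drop = FALSE], train = TRUE)
      model <- lg$model  # batch-norm running statistics advanced
      g <- clip_gradient(params_flatten(lg$grads),
                         train_cfg$grad_clip_value)
      theta <- params_flatten(model$params)
      st <- adam_step(theta, g, opt, lr = train_cfg$learning_rate)
      opt <- st$state
      model$params <- params_unflatten(model$params, st$theta)
      losses <- c(losses, lg$loss)
    }
    trace <- sequential_infer(val_recording, model)
    m <- compute_metrics(val_recording$labels, trace$stages)
    checkpoints[[ep]] <- model$params
    history <- rbind(history, data.frame(
      epoch = ep, train_loss = mean(losses), val_accuracy = m$accuracy,
      val_mf1 = m$macro_f1, checkpoint_id = ep))
    if (verbose) {
      message(sprintf("epoch %d: loss %.4f val acc %.1f val MF1 %.1f",
                      ep, mean(losses), m$accuracy, m$macro_f1))
    }
  }
  list(model = model, history = history, checkpoints = checkpoints,
       model_cfg = model_cfg, train_cfg = train_cfg)
}

#' Select the top checkpoints by validation macro-F1
#'
#' Keeps `ceiling(fraction * n)` checkpoints with the highest validation
#' MF1; ties are broken in favor of the later training epoch. With the
#' full-scale protocol (70 epochs, fraction 0.10) this keeps 7 models.
#'
#' @param history data.frame with `val_mf1` and `checkpoint_id` columns.
#' @param fraction fraction of checkpoints to keep.
#' @return Integer vector of selected checkpoint ids.
#' @export
select_checkpoints <- function(history, fraction = 0.10) {
  if (nrow(history) == 0L) stop("empty training history")
  k <- as.integer(ceiling(fraction * nrow(history)))
  ord <- order(history$val_mf1, history$checkpoint_id, decreasing = TRUE)
  sort(history$checkpoint_id[ord[seq_len(k)]])
}
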