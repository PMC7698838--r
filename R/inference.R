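#' @title Sequential inference and ensembling
#' @description At test time the refinement input for epoch `t` is the
#'   model's own output probability vector at epoch `t-1` (uniform 1/5 for
#'   the first epoch), decoded sequentially per recording. Checkpoint
#'   ensembling combines the per-epoch probability vectors of several
#'   models by maximum likelihood (product of probabilities, i.e. sum of
#'   logs). Decision fusion combines independently trained single-channel
#'   models by plurality vote or maximum posterior probability.
#' @name inference
NULL

# Per-epoch fused features and attention weights in inference mode,
# computed in batches: the CNN branches and channel fusion do not depend on
# the previous-stage feedback, only the classifier head does.
fused_features <- function(model, X, chunk = 256L) {
  n <- dim(X)[1]
  cfg <- model$config
  nC <- if (cfg$fusion == "data") 1L else cfg$n_channels
  fused <- NULL
  alpha <- matrix(0, n, nC)
  for (b0 in seq(1L, n, by = chunk)) {
    idx <- b0:min(b0 + chunk - 1L, n)
    fw <- model_forward(model, X[idx, , , drop = FALSE],
                        prev = matrix(1 / N_STAGES, length(idx), N_STAGES),
                        train = FALSE)
    if (is.null(fused)) fused <- matrix(0, n, ncol(fw$fused))
    fused[idx, ] <- fw$fused
    alpha[idx, ] <- fw$alpha
  }
  list(fused = fused, alpha = alpha)
}

#' Sequentially decode one recording
#'
#' Epoch `t`'s refinement input is the model's output probability vector at
#' epoch `t-1` (the uniform vector for epoch 1). Only the classifier head
#' depends on that feedback, so the per-epoch fused channel features are
#' precomputed in batches and the sequential loop carries just the previous
#' probability vector (O(1) state between epochs).
#'
#' @param rec a [recording()] (or an [epoch_array()]).
#' @param model a `"sleep_model"` in its trained state; inference mode is
#'   used throughout (dropout off, batch-norm running statistics).
#' @param init_prev optional length-5 probability vector used as the first
#'   epoch's previous-stage input (default uniform); lets decoding restart
#'   from a stored cut point.
#' @return A `"prediction_trace"` list with `probs` `[n, 5]`, `stages` (a
#'   [hypnogram()], per-epoch argmax with ties to the lowest stage index)
#'   and `alpha` `[n, C]` attention weights.
#' @export
sequential_infer <- function(rec, model, init_prev = NULL) {
  ep <- if (inherits(rec, "recording")) rec$epochs else rec
  X <- unclass(ep)
  if (length(dim(X)) == 2L) dim(X) <- c(dim(X), 1L)
  n <- dim(X)[1]
  cfg <- model$config
  ff <- fused_features(model, X)
  probs <- matrix(0, n, N_STAGES)
  prev <- if (is.null(init_prev)) rep(1 / N_STAGES, N_STAGES) else init_prev
  head <- model$params$head
  for (t in seq_len(n)) {
    u <- ff$fused[t, ]
    if (cfg$use_refinement) {
      v_c <- as.vector(prev %*% head$E) + head$b_e
      u <- c(v_c, u)
    }
    pr <- row_softmax(rbind(as.vector(u %*% head$Wc) + head$bc))
    probs[t, ] <- pr
    prev <- as.vector(pr)
  }
  structure(list(probs = probs,
                 stages = hypnogram(max.col(probs, ties.method = "first") - 1L),
                 alpha = ff$alpha),
            class = "prediction_trace")
}

#' @export
print.prediction_trace <- function(x, ...) {
  cat("<prediction_trace>", nrow(x$probs), "epochs\n")
  invisible(x)
}

#' Maximum-likelihood ensemble of prediction traces
#'
#' Per epoch, the combined score of a stage is the sum over models of the
#' log probability assigned to it (equivalently the product of
#' probabilities); the argmax wins, ties going to the lowest stage index.
#'
#' @param traces list of K `"prediction_trace"` objects for the same
#'   recording (equal lengths).
#' @return A [hypnogram()].
#' @export
ensemble_predict <- function(traces) {
  if (length(traces) < 1L) stop("need at least one trace")
  n <- nrow(traces[[1]]$probs)
  if (!all(vapply(traces, function(tr) nrow(tr$probs), numeric(1)) == n)) {
    stop("all traces must have equal length")
  }
  score <- Reduce(`+`, lapply(traces, function(tr)
    log(pmax(tr$probs, 1e-12))))
  hypnogram(max.col(score, ties.method = "first") - 1L)
}

#' Decision-level fusion of single-channel model outputs
#'
#' @param per_channel_traces list of C `"prediction_trace"` objects, one
#'   per independently trained single-channel model.
#' @param mode `"vote"` (per-epoch plurality of the channel argmaxes) or
#'   `"map"` (argmax of the product of channel probability vectors). Ties
#'   go to the lowest stage index.
#' @return A [hypnogram()].
#' @export
decision_fusion <- function(per_channel_traces, mode = c("vote", "map")) {
  mode <- match.arg(mode)
  if (length(per_channel_traces) < 1L) stop("need at least one trace")
  n <- nrow(per_channel_traces[[1]]$probs)
  if (!all(vapply(per_channel_traces, function(tr) nrow(tr$probs),
                  numeric(1)) == n)) {
    stop("all traces must have equal length")
  }
  if (mode == "map") return(ensemble_predict(per_channel_traces))
  votes <- vapply(per_channel_traces, function(tr)
    max.col(tr$probs, ties.method = "first"), numeric(n))
  if (is.null(dim(votes))) votes <- rbind(votes)
  hypnogram(apply(votes, 1L, function(v)
    which.max(tabulate(v, nbins = N_STAGES))) - 1L)
}
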