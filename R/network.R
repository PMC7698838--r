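#' @title Multi-branch network with residual attention fusion and embedded
#'   stage refinement
#' @description One CNN branch per signal channel (parameters are not
#'   shared across channels), each made of five conv/batch-norm/ReLU blocks
#'   followed by global average pooling into a feature vector `v_i`. The
#'   channel features are fused either naively (average, concatenation) or
#'   by self-attention with a residual mean term,
#'   `V_fusion = v_avg + sum_i alpha_i v_i`, where the mean acts as a floor
#'   on every channel's contribution so attention cannot saturate on a
#'   single channel. The previous epoch's stage (one-hot ground truth in
#'   training, predicted probability vector at inference) is re-encoded to a
#'   dense vector `v_c` and concatenated with `V_fusion`; because the final
#'   layer is affine, the logits decompose additively into a signal term and
#'   a stage-refinement term, `P = W_c v_c + W_f V_fusion`.
#' @name network
NULL

#' Default backbone blocks: (kernel_length, stride, n_filters) per block
#' @return List of 5 integer triples.
#' @export
default_blocks <- function() {
  list(c(5L, 3L, 64L), c(5L, 3L, 64L), c(3L, 2L, 128L),
       c(3L, 1L, 128L), c(3L, 1L, 256L))
}

#' Tiny backbone for scaled-down experiments and tests
#' @return List of 5 integer triples with small filter counts.
#' @export
tiny_blocks <- function() {
  list(c(5L, 3L, 8L), c(5L, 3L, 8L), c(3L, 2L, 16L),
       c(3L, 1L, 16L), c(3L, 1L, 32L))
}

#' Temporal length after each backbone block
#' @param input_len input samples per epoch.
#' @param blocks list of (kernel, stride, filters) triples.
#' @return Integer vector, one length per block.
#' @export
backbone_shape_chain <- function(input_len, blocks = default_blocks()) {
  L <- input_len
  vapply(blocks, function(b) {
    L <<- conv_output_length(L, b[1], b[2])
    L
  }, integer(1))
}

#' Model configuration
#'
#' @param input_len samples per epoch fed to each branch (e.g. 3000 for
#'   30 s at 100 Hz).
#' @param channels channel names; one CNN branch per channel (except data
#'   fusion, which stacks all channels into a single branch).
#' @param blocks backbone blocks (kernel, stride, filters); the last
#'   block's filter count is the feature dimension after pooling.
#' @param fusion one of `"residual_attention"`, `"attention_only"`,
#'   `"average"`, `"concat"`, `"data"`.
#' @param use_refinement if `TRUE`, the previous epoch's stage vector is
#'   encoded and concatenated with the fused features.
#' @param encoding_dim length of the stage encoding (default: feature dim).
#' @param dropout dropout rate on the classifier input in training mode.
#' @param bn_momentum,bn_eps batch normalization running-statistics decay
#'   and variance epsilon.
#' @param seed seed for parameter initialization.
#' @return A `"model_config"` list.
#' @export
model_config <- function(input_len, channels, blocks = default_blocks(),
                         fusion = c("residual_attention", "attention_only",
                                    "average", "concat", "data"),
                         use_refinement = TRUE, encoding_dim = NULL,
                         dropout = 0.5, bn_momentum = 0.99, bn_eps = 1e-3,
                         seed = 1L) {
  fusion <- match.arg(fusion)
  channels <- as.character(channels)
  C <- length(channels)
  if (C < 1L) stop("need at least one channel")
  chain <- backbone_shape_chain(input_len, blocks)
  if (any(chain < 1L)) stop("input length ", input_len,
                            " collapses below 1 sample in the backbone")
  d <- blocks[[length(blocks)]][3]
  if (is.null(encoding_dim)) encoding_dim <- d
  fused_dim <- switch(fusion, concat = d * C, d)
  structure(list(input_len = as.integer(input_len), channels = channels,
                 n_channels = C, blocks = blocks, feature_dim = as.integer(d),
                 fusion = fusion, use_refinement = isTRUE(use_refinement),
                 encoding_dim = as.integer(encoding_dim),
                 fused_dim = as.integer(fused_dim), dropout = dropout,
                 bn_momentum = bn_momentum, bn_eps = bn_eps,
                 seed = as.integer(seed), shape_chain = chain),
            class = "model_config")
}

he_init <- function(nr, nc, fan_in) {
  matrix(stats::rnorm(nr * nc, sd = sqrt(2 / fan_in)), nr, nc)
}

branch_init <- function(blocks, c_in) {
  lapply(blocks, function(b) {
    k <- b[1]; f <- b[3]
    W <- he_init(k * c_in, f, k * c_in)
    c_in <<- f
    list(W = W, bn = bn_init(f))
  })
}

#' Initialize standalone attention parameters
#'
#' `W_iv` (per-channel, feature x feature), shared `W` (C*feature x
#' feature), bias `b`, and per-channel score projectors `w_is` mapping the
#' hidden activation to the scalar channel score
#' `s_i = w_is . ReLU(W_iv v_i + W V + b)`.
#'
#' @param d feature dimension.
#' @param C number of channels.
#' @param seed RNG seed.
#' @return List with `W_iv` (list of C matrices), `W`, `b`, `w_is`.
#' @export
attention_params <- function(d, C, seed = 1L) {
  set.seed(seed)
  list(W_iv = lapply(seq_len(C), function(i) he_init(d, d, d)),
       W = he_init(d * C, d, d * C),
       b = rep(0, d),
       w_is = lapply(seq_len(C), function(i)
         stats::rnorm(d, sd = sqrt(1 / d))))
}

#' Initialize a model from its configuration
#' @param config a [model_config()].
#' @return A `"sleep_model"` list with `config` and `params`.
#' @export
init_model <- function(config) {
  stopifnot(inherits(config, "model_config"))
  set.seed(config$seed)
  d <- config$feature_dim
  C <- config$n_channels
  params <- list()
  if (config$fusion == "data") {
    params$branches <- list(branch_init(config$blocks, C))
  } else {
    params$branches <- lapply(seq_len(C), function(i)
      branch_init(config$blocks, 1L))
  }
  if (config$fusion %in% c("residual_attention", "attention_only")) {
    params$attention <- list(
      W_iv = lapply(seq_len(C), function(i) he_init(d, d, d)),
      W = he_init(d * C, d, d * C),
      b = rep(0, d),
      w_is = lapply(seq_len(C), function(i)
        stats::rnorm(d, sd = sqrt(1 / d))))
  }
  in_dim <- config$fused_dim +
    if (config$use_refinement) config$encoding_dim else 0L
  params$head <- list(Wc = he_init(in_dim, N_STAGES, in_dim),
                      bc = rep(0, N_STAGES))
  if (config$use_refinement) {
    params$head$E <- he_init(N_STAGES, config$encoding_dim, N_STAGES)
    params$head$b_e <- rep(0, config$encoding_dim)
  }
  structure(list(config = config, params = params), class = "sleep_model")
}

#' @export
print.sleep_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(paste0("<sleep_model> %d-channel, input %d, fusion '%s', ",
                     "refinement %s\n"),
              cfg$n_channels, cfg$input_len, cfg$fusion,
              if (cfg$use_refinement) "on" else "off"))
  cat("shape chain:", paste(cfg$shape_chain, collapse = " -> "),
      "-> GAP ->", cfg$feature_dim, "\n")
  invisible(x)
}

branch_forward <- function(bp, Xc, cfg, train) {
  caches <- vector("list", length(cfg$blocks))
  X <- Xc
  for (j in seq_along(cfg$blocks)) {
    blk <- cfg$blocks[[j]]
    cf <- conv1d_forward(X, bp[[j]]$W, blk[1], blk[2])
    bf <- bn_forward(cf$out, bp[[j]]$bn, train, cfg$bn_momentum, cfg$bn_eps)
    bp[[j]]$bn <- bf$params
    rf <- relu_forward(bf$out)
    caches[[j]] <- list(conv = cf$cache, bn = bf$cache, relu = rf$cache)
    X <- rf$out
  }
  gf <- gap_forward(X)
  list(v = gf$out, params = bp,
       cache = list(blocks = caches, gap = gf$cache))
}

branch_backward <- function(bp, cache, dv, cfg) {
  dX <- gap_backward(dv, cache$gap)
  grads <- vector("list", length(cfg$blocks))
  for (j in rev(seq_along(cfg$blocks))) {
    blk <- cfg$blocks[[j]]
    cj <- cache$blocks[[j]]
    dX <- relu_backward(dX, cj$relu)
    bb <- bn_backward(dX, cj$bn, bp[[j]]$bn)
    cb <- conv1d_backward(bb$dX, cj$conv, bp[[j]]$W, blk[1], blk[2])
    grads[[j]] <- list(W = cb$dW,
                       bn = list(gamma = bb$dgamma, beta = bb$dbeta,
                                 running_mean = bp[[j]]$bn$running_mean * 0,
                                 running_var = bp[[j]]$bn$running_var * 0))
    dX <- cb$dX
  }
  grads
}

#' Compute attention weights over channel features
#'
#' Scores each channel from its own feature and the concatenation of all
#' channel features, `s_i = w_is . ReLU(W_iv v_i + W V + b)`, and applies a
#' numerically stabilized softmax across channels.
#'
#' @param v list of C channel feature matrices `[batch, d]` (numeric
#'   vectors are treated as one-row matrices).
#' @param params attention parameters as from [attention_params()].
#' @return Matrix `[batch, C]` of weights summing to 1 per row.
#' @export
attention_weights <- function(v, params) {
  attention_forward(v, params)$alpha
}

attention_forward <- function(vlist, ap) {
  vlist <- lapply(vlist, function(x) if (is.null(dim(x))) rbind(x) else x)
  C <- length(vlist)
  B <- nrow(vlist[[1]])
  Vcat <- do.call(cbind, vlist)
  shared <- Vcat %*% ap$W
  H <- vector("list", C)
  mask <- vector("list", C)
  S <- matrix(0, B, C)
  for (i in seq_len(C)) {
    Z <- vlist[[i]] %*% ap$W_iv[[i]] + shared +
      rep(ap$b, each = B)
    mask[[i]] <- Z > 0
    H[[i]] <- Z * mask[[i]]
    S[, i] <- H[[i]] %*% ap$w_is[[i]]
  }
  alpha <- row_softmax(S)
  list(alpha = alpha,
       cache = list(Vcat = Vcat, H = H, mask = mask, vlist = vlist))
}

# dalpha: [B, C] gradient wrt attention weights. Returns per-channel feature
# gradients plus attention parameter gradients.
attention_backward <- function(dalpha, fw, ap) {
  cache <- fw$cache
  alpha <- fw$alpha
  C <- length(cache$vlist)
  B <- nrow(alpha)
  d <- ncol(cache$vlist[[1]])
  ds <- alpha * (dalpha - rowSums(alpha * dalpha))  # softmax jacobian
  dv <- lapply(seq_len(C), function(i) matrix(0, B, d))
  dW_iv <- vector("list", C)
  dw_is <- vector("list", C)
  dW <- matrix(0, d * C, d)
  db <- rep(0, d)
  dVcat <- matrix(0, B, d * C)
  for (i in seq_len(C)) {
    dH <- tcrossprod(ds[, i], ap$w_is[[i]])          # [B, d]
    dw_is[[i]] <- as.vector(crossprod(cache$H[[i]], ds[, i]))
    dZ <- dH * cache$mask[[i]]
    dW_iv[[i]] <- crossprod(cache$vlist[[i]], dZ)
    dv[[i]] <- dv[[i]] + tcrossprod(dZ, ap$W_iv[[i]])
    dW <- dW + crossprod(cache$Vcat, dZ)
    db <- db + colSums(dZ)
    dVcat <- dVcat + tcrossprod(dZ, ap$W)
  }
  for (i in seq_len(C)) {
    cols <- ((i - 1) * d + 1):(i * d)
    dv[[i]] <- dv[[i]] + dVcat[, cols, drop = FALSE]
  }
  list(dv = dv,
       grads = list(W_iv = dW_iv, W = dW, b = db, w_is = dw_is))
}

#' Residual attention fusion
#'
#' `V_fusion = v_avg + sum_i alpha_i v_i`: the attention-weighted channel
#' sum plus the unweighted channel mean, which guarantees every channel a
#' floor contribution of `1/C` even when its attention weight saturates
#' at 0.
#'
#' @param v list of C feature matrices `[batch, d]` or numeric vectors.
#' @param alpha weights `[batch, C]` (or length-C vector), rows on the
#'   simplex.
#' @return Fused features `[batch, d]`.
#' @export
fuse_residual <- function(v, alpha) {
  v <- lapply(v, function(x) if (is.null(dim(x))) rbind(x) else x)
  if (is.null(dim(alpha))) alpha <- rbind(alpha)
  C <- length(v)
  if (ncol(alpha) != C) {
    stop("alpha has ", ncol(alpha), " columns but there are ", C, " channels")
  }
  v_avg <- Reduce(`+`, v) / C
  out <- v_avg
  for (i in seq_len(C)) out <- out + alpha[, i] * v[[i]]
  out
}

#' Channel fusion ablation variants
#'
#' @param v list of C feature matrices `[batch, d]`.
#' @param mode `"average"` (channel mean), `"concat"` (concatenation),
#'   `"attention_only"` (weighted sum, no residual mean), or
#'   `"residual_attention"`.
#' @param params attention parameters, required for the attention modes.
#' @return Fused feature matrix (`[batch, d]`, or `[batch, d*C]` for
#'   `"concat"`).
#' @export
fuse_variant <- function(v, mode = c("average", "concat", "attention_only",
                                     "residual_attention"), params = NULL) {
  mode <- match.arg(mode)
  v <- lapply(v, function(x) if (is.null(dim(x))) rbind(x) else x)
  C <- length(v)
  switch(mode,
    average = Reduce(`+`, v) / C,
    concat = do.call(cbind, v),
    attention_only = {
      if (is.null(params)) stop("attention modes need attention params")
      alpha <- attention_weights(v, params)
      out <- 0
      for (i in seq_len(C)) out <- out + alpha[, i] * v[[i]]
      out
    },
    residual_attention = {
      if (is.null(params)) stop("attention modes need attention params")
      fuse_residual(v, attention_weights(v, params))
    })
}

#' Encode the previous epoch's stage vector
#'
#' A single affine map from the length-5 stage vector (one-hot ground truth
#' during training, predicted probabilities at inference) to a dense
#' encoding concatenated with the fused signal features.
#'
#' @param stage_vec length-5 nonnegative vector with sum at most 1 (+1e-6),
#'   or a matrix of such rows.
#' @param params list with `E` (5 x encoding_dim) and `b_e`.
#' @return Encoding matrix `[batch, encoding_dim]`.
#' @export
encode_previous_stage <- function(stage_vec, params) {
  if (is.null(dim(stage_vec))) stage_vec <- rbind(stage_vec)
  if (ncol(stage_vec) != N_STAGES) {
    stop("stage vector must have length ", N_STAGES)
  }
  if (any(stage_vec < -1e-9) || any(rowSums(stage_vec) > 1 + 1e-6)) {
    stop("stage vector entries must be >= 0 with sum <= 1")
  }
  stage_vec %*% params$E + rep(params$b_e, each = nrow(stage_vec))
}

#' Classify from the stage encoding and fused features
#'
#' The classifier is dropout -> affine -> softmax on the concatenation
#' `[v_c, V_fusion]`; by linearity the logits decompose additively into a
#' refinement term and a signal term.
#'
#' @param v_c stage encoding `[batch, encoding_dim]` (or vector).
#' @param V_fusion fused features `[batch, fused_dim]` (or vector).
#' @param head list with `Wc` ((encoding_dim + fused_dim) x 5) and `bc`.
#' @param train_mode if `TRUE`, dropout is applied (stochastic).
#' @param dropout dropout rate used in train mode.
#' @param return_logits return pre-softmax logits instead of probabilities
#'   (useful for checking the additive refinement decomposition).
#' @return Probability (or logit) matrix `[batch, 5]`.
#' @export
classify <- function(v_c, V_fusion, head, train_mode = FALSE,
                     dropout = 0.5, return_logits = FALSE) {
  if (is.null(dim(v_c))) v_c <- rbind(v_c)
  if (is.null(dim(V_fusion))) V_fusion <- rbind(V_fusion)
  u <- cbind(v_c, V_fusion)
  if (train_mode && dropout > 0) {
    mask <- matrix(stats::rbinom(length(u), 1L, 1 - dropout),
                   nrow(u)) / (1 - dropout)
    u <- u * mask
  }
  logits <- u %*% head$Wc + rep(head$bc, each = nrow(u))
  if (return_logits) logits else row_softmax(logits)
}

#' Full forward pass
#'
#' @param model a `"sleep_model"`.
#' @param X signal epochs `[batch, input_len, n_channels]` (a matrix is
#'   treated as single-channel).
#' @param prev previous-stage vectors `[batch, 5]`; required when the model
#'   uses embedded refinement (uniform 1/5 rows for sequence starts).
#' @param train training mode: batch statistics in batch norm, dropout
#'   active, running statistics updated (returned in `$model`).
#' @return List with `probs`, `logits`, `alpha`, `v` (per-channel feature
#'   list), `fused`, `v_c`, `cache` (for backprop) and `model` (with
#'   updated batch-norm running statistics when `train = TRUE`).
#' @export
model_forward <- function(model, X, prev = NULL, train = FALSE) {
  cfg <- model$config
  p <- model$params
  if (length(dim(X)) == 2L) dim(X) <- c(dim(X), 1L)
  if (dim(X)[2] != cfg$input_len) {
    stop("epoch length ", dim(X)[2], " does not match configured input ",
         "length ", cfg$input_len)
  }
  B <- dim(X)[1]
  att <- NULL
  if (cfg$fusion == "data") {
    bf <- branch_forward(p$branches[[1]], X, cfg, train)
    p$branches[[1]] <- bf$params
    vlist <- list(bf$v)
    bcache <- list(bf$cache)
    fused <- bf$v
    alpha <- matrix(1, B, 1)
  } else {
    if (dim(X)[3] != cfg$n_channels) {
      stop("expected ", cfg$n_channels, " channels, got ", dim(X)[3])
    }
    vlist <- vector("list", cfg$n_channels)
    bcache <- vector("list", cfg$n_channels)
    for (i in seq_len(cfg$n_channels)) {
      bf <- branch_forward(p$branches[[i]], X[, , i, drop = FALSE], cfg,
                           train)
      p$branches[[i]] <- bf$params
      vlist[[i]] <- bf$v
      bcache[[i]] <- bf$cache
    }
    if (cfg$fusion %in% c("residual_attention", "attention_only")) {
      att <- attention_forward(vlist, p$attention)
      alpha <- att$alpha
      fused <- 0
      for (i in seq_len(cfg$n_channels)) {
        fused <- fused + alpha[, i] * vlist[[i]]
      }
      if (cfg$fusion == "residual_attention") {
        fused <- fused + Reduce(`+`, vlist) / cfg$n_channels
      }
    } else if (cfg$fusion == "average") {
      fused <- Reduce(`+`, vlist) / cfg$n_channels
      alpha <- matrix(1 / cfg$n_channels, B, cfg$n_channels)
    } else {  # concat
      fused <- do.call(cbind, vlist)
      alpha <- matrix(1 / cfg$n_channels, B, cfg$n_channels)
    }
  }
  v_c <- NULL
  u <- fused
  if (cfg$use_refinement) {
    if (is.null(prev)) stop("model uses embedded refinement; supply prev")
    if (is.null(dim(prev))) prev <- rbind(prev)
    v_c <- prev %*% p$head$E + rep(p$head$b_e, each = B)
    u <- cbind(v_c, fused)
  }
  mask <- NULL
  u_d <- u
  if (train && cfg$dropout > 0) {
    mask <- matrix(stats::rbinom(length(u), 1L, 1 - cfg$dropout),
                   nrow(u)) / (1 - cfg$dropout)
    u_d <- u * mask
  }
  logits <- u_d %*% p$head$Wc + rep(p$head$bc, each = B)
  probs <- row_softmax(logits)
  list(probs = probs, logits = logits, alpha = alpha, v = vlist,
       fused = fused, v_c = v_c,
       cache = list(u = u, u_d = u_d, mask = mask, att = att,
                    branch = bcache, prev = prev, B = B),
       model = structure(list(config = cfg, params = p),
                         class = "sleep_model"))
}

zero_like <- function(p) rapply(p, function(x) x * 0, how = "replace")

# Backward pass from dlogits; returns gradients with the same structure as
# model$params (batch-norm running statistics get zero gradients).
model_backward <- function(model, fw, dlogits) {
  cfg <- model$config
  p <- fw$model$params
  cache <- fw$cache
  B <- cache$B
  grads <- zero_like(p)
  grads$head$Wc <- crossprod(cache$u_d, dlogits)
  grads$head$bc <- colSums(dlogits)
  du <- tcrossprod(dlogits, p$head$Wc)
  if (!is.null(cache$mask)) du <- du * cache$mask
  if (cfg$use_refinement) {
    enc <- cfg$encoding_dim
    dv_c <- du[, seq_len(enc), drop = FALSE]
    dfused <- du[, (enc + 1):ncol(du), drop = FALSE]
    grads$head$E <- crossprod(cache$prev, dv_c)
    grads$head$b_e <- colSums(dv_c)
  } else {
    dfused <- du
  }
  C <- cfg$n_channels
  d <- cfg$feature_dim
  if (cfg$fusion == "data") {
    dv <- list(dfused)
  } else if (cfg$fusion == "average") {
    dv <- lapply(seq_len(C), function(i) dfused / C)
  } else if (cfg$fusion == "concat") {
    dv <- lapply(seq_len(C), function(i)
      dfused[, ((i - 1) * d + 1):(i * d), drop = FALSE])
  } else {
    alpha <- fw$alpha
    vlist <- fw$v
    dv <- lapply(seq_len(C), function(i) {
      g <- alpha[, i] * dfused
      if (cfg$fusion == "residual_attention") g <- g + dfused / C
      g
    })
    dalpha <- vapply(seq_len(C), function(i)
      rowSums(dfused * vlist[[i]]), numeric(B))
    if (is.null(dim(dalpha))) dalpha <- rbind(dalpha)
    ab <- attention_backward(dalpha, cache$att, p$attention)
    for (i in seq_len(C)) dv[[i]] <- dv[[i]] + ab$dv[[i]]
    grads$attention <- ab$grads
  }
  for (i in seq_along(p$branches)) {
    grads$branches[[i]] <- branch_backward(p$branches[[i]],
                                           cache$branch[[i]], dv[[i]], cfg)
  }
  grads
}

# Mean cross-entropy loss and parameter gradients for one mini-batch.
model_loss_grads <- function(model, X, prev, Y, train = TRUE) {
  fw <- model_forward(model, X, prev, train = train)
  B <- nrow(Y)
  loss <- -mean(rowSums(Y * log(pmax(fw$probs, 1e-12))))
  dlogits <- (fw$probs - Y) / B
  grads <- model_backward(model, fw, dlogits)
  list(loss = loss, grads = grads, model = fw$model)
}

#' Extract per-channel CNN features in inference mode
#'
#' @param model a `"sleep_model"`.
#' @param epochs `[n, input_len]` matrix (or vector for one epoch) of
#'   single-channel epochs.
#' @param channel branch index (its parameters are channel-specific).
#' @return Feature matrix `[n, feature_dim]`.
#' @export
extract_features <- function(model, epochs, channel = 1L) {
  cfg <- model$config
  if (is.null(dim(epochs))) epochs <- rbind(epochs)
  if (ncol(epochs) != cfg$input_len) {
    stop("epoch length ", ncol(epochs), " does not match configured ",
         "input length ", cfg$input_len)
  }
  X <- array(epochs, c(nrow(epochs), ncol(epochs), 1L))
  branch_forward(model$params$branches[[channel]], X, cfg, FALSE)$v
}
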